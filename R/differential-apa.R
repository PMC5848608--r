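# Differential tandem-UTR usage between two conditions: the tandem UTR
# isoform switch index (TSI), exact testing with BH-FDR control,
# lengthened/shortened classification, and the downstream trend and overlap
# statistics coupling 3' UTR change with expression change.

#' Tandem UTR isoform switch index (TSI)
#'
#' Signed, bounded statistic for the shift in tandem poly(A)-site usage
#' between two conditions: the change in effective 3' UTR length normalized
#' by the distance between the outermost sites,
#' `TSI = (L_eff_B - L_eff_A) / (d_max - d_min)`. For a two-site gene this
#' is exactly the distal usage fraction in B minus that in A. TSI lies in
#' `[-1, 1]`; positive values indicate 3' UTR lengthening in B relative to
#' A, and `tsi(A, B) = -tsi(B, A)`.
#'
#' @param distance tandem-site distances to the stop codon (>= 2 sites,
#'   strictly increasing).
#' @param count_a,count_b per-site tag counts in conditions A and B.
#' @return TSI, or `NA_real_` for single-site genes or zero totals.
#' @export
tsi <- function(distance, count_a, count_b) {
  if (length(distance) < 2) return(NA_real_)
  if (sum(count_a) <= 0 || sum(count_b) <= 0) return(NA_real_)
  la <- effective_utr_length(distance, count_a)
  lb <- effective_utr_length(distance, count_b)
  (lb - la) / (max(distance) - min(distance))
}

#' Exact test for a tandem-site usage shift
#'
#' Collapses the per-site counts to proximal (first site) versus distal
#' (all remaining sites pooled) totals and applies a two-sided Fisher's
#' exact test to the 2x2 table `[proximal, distal] x [A, B]`. A table with
#' any zero margin carries no information about usage change and returns
#' p = 1.
#'
#' @param counts_a,counts_b per-site tag counts (site 1 = proximal).
#' @return two-sided p-value.
#' @export
tsi_test <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b), length(counts_a) >= 2)
  tab <- matrix(c(counts_a[1], sum(counts_a[-1]),
                  counts_b[1], sum(counts_b[-1])), nrow = 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1.0)
  stats::fisher.test(round(tab))$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values: `q_(i) = min_(j >= i) p_(j) * n / j`, capped at 1
#' and mapped back to input order. `NA` p-values propagate as `NA` and do
#' not count towards `n`.
#'
#' @param p p-values in `[0, 1]` (may contain `NA`).
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Classify genes as lengthened / shortened / unchanged
#'
#' A gene is called lengthened when `q <= fdr_cut` and TSI > 0, shortened
#' when `q <= fdr_cut` and TSI < 0, otherwise unchanged.
#'
#' @param tsi TSI values.
#' @param q BH q-values.
#' @param fdr_cut FDR threshold.
#' @return character vector of calls (`NA` where TSI or q is `NA`).
#' @export
classify_tsi <- function(tsi, q, fdr_cut = 0.05) {
  ifelse(is.na(tsi) | is.na(q), NA_character_,
         ifelse(q <= fdr_cut & tsi > 0, "lengthened",
                ifelse(q <= fdr_cut & tsi < 0, "shortened", "unchanged")))
}

#' Per-gene differential tandem-UTR usage table
#'
#' Computes TSI, the exact usage-shift test, BH q-values and the
#' lengthened/shortened call for every multi-site gene in an
#' `apa_profiles` table. Replicates within a condition are pooled (counts
#' summed) before testing by default; `replicate_mode = "stouffer"` instead
#' tests matched replicate pairs separately and combines the two-sided
#' p-values with signed Stouffer weights.
#'
#' Single-site genes cannot switch tandem isoforms and are excluded (their
#' number is logged).
#'
#' @param profiles an `apa_profiles` data frame.
#' @param samples_a,samples_b sample ids belonging to each condition.
#' @param fdr_cut FDR threshold for the call.
#' @param replicate_mode `"pooled"` (default) or `"stouffer"`.
#' @return data frame: `gene_id`, `n_sites`, `proximal_a`, `distal_a`,
#'   `proximal_b`, `distal_b` (collapsed counts), `tsi`, `p_value`,
#'   `q_value`, `call`.
#' @export
tsi_table <- function(profiles, samples_a, samples_b, fdr_cut = 0.05,
                      replicate_mode = c("pooled", "stouffer")) {
  replicate_mode <- match.arg(replicate_mode)
  cols_a <- paste0("count_", samples_a)
  cols_b <- paste0("count_", samples_b)
  sp <- split(profiles, profiles$gene_id)
  n_single <- sum(vapply(sp, nrow, integer(1)) < 2)
  if (n_single > 0) {
    message("differential_apa: excluded ", n_single,
            " single-site gene(s) from TSI analysis")
  }
  rows <- lapply(sp, function(p) {
    if (nrow(p) < 2) return(NULL)
    p <- p[order(p$distance), ]
    na <- rowSums(as.matrix(p[, cols_a, drop = FALSE]))
    nb <- rowSums(as.matrix(p[, cols_b, drop = FALSE]))
    if (replicate_mode == "pooled" ||
        length(samples_a) != length(samples_b)) {
      pv <- tsi_test(na, nb)
    } else {
      zs <- vapply(seq_along(samples_a), function(i) {
        ca <- p[[cols_a[i]]]; cb <- p[[cols_b[i]]]
        pi <- tsi_test(ca, cb)
        ti <- tsi(p$distance, ca, cb)
        if (is.na(ti) || pi >= 1) return(0)
        sign(ti) * stats::qnorm(1 - pi / 2)
      }, numeric(1))
      z <- sum(zs) / sqrt(length(zs))
      pv <- 2 * stats::pnorm(-abs(z))
    }
    data.frame(gene_id = p$gene_id[1], n_sites = nrow(p),
               proximal_a = na[1], distal_a = sum(na[-1]),
               proximal_b = nb[1], distal_b = sum(nb[-1]),
               tsi = tsi(p$distance, na, nb), p_value = pv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene_id = character(0), n_sites = integer(0),
                      proximal_a = numeric(0), distal_a = numeric(0),
                      proximal_b = numeric(0), distal_b = numeric(0),
                      tsi = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), call = character(0),
                      stringsAsFactors = FALSE))
  }
  out$q_value <- bh_fdr(out$p_value)
  out$call <- classify_tsi(out$tsi, out$q_value, fdr_cut)
  rownames(out) <- NULL
  out
}

#' Count lengthened/shortened genes at relative-change cut-offs
#'
#' A gene is lengthened at cut-off `c` when its effective 3' UTR length
#' changed by at least the fraction `c`: `(L_B - L_A) / L_A >= c`;
#' shortened when `<= -c`. Genes with `L_A = 0` or missing lengths are
#' excluded. Counts are nested: looser cut-offs can only give more genes.
#'
#' @param l_a,l_b named vectors of effective lengths per gene in conditions
#'   A and B (matched by position).
#' @param cutoffs relative-change thresholds.
#' @return data frame: `cutoff`, `n_lengthened`, `n_shortened`,
#'   `n_evaluated`.
#' @export
count_length_changes <- function(l_a, l_b, cutoffs = c(0.05, 0.10, 0.20)) {
  stopifnot(length(l_a) == length(l_b))
  ok <- !is.na(l_a) & !is.na(l_b) & l_a > 0
  rel <- (l_b[ok] - l_a[ok]) / l_a[ok]
  do.call(rbind, lapply(cutoffs, function(cc) {
    data.frame(cutoff = cc,
               n_lengthened = sum(rel >= cc),
               n_shortened = sum(rel <= -cc),
               n_evaluated = sum(ok))
  }))
}

#' Expression change classification with FPKM floor
#'
#' Genes must have FPKM >= `min_fpkm` in both samples to be considered;
#' among those, a gene is `up` when `b / a >= fc`, `down` when
#' `a / b >= fc`, and `neither` otherwise. The fold-change boundary is
#' inclusive.
#'
#' @param fpkm_a,fpkm_b expression values (FPKM) per gene.
#' @param fc fold-change threshold.
#' @param min_fpkm detection floor applied to both samples.
#' @return character vector in `{"up", "down", "neither", "excluded"}`.
#' @export
expression_filter <- function(fpkm_a, fpkm_b, fc = 1.5, min_fpkm = 1.0) {
  stopifnot(length(fpkm_a) == length(fpkm_b), all(fpkm_a >= 0, na.rm = TRUE),
            all(fpkm_b >= 0, na.rm = TRUE))
  out <- rep("excluded", length(fpkm_a))
  ok <- !is.na(fpkm_a) & !is.na(fpkm_b) &
    fpkm_a >= min_fpkm & fpkm_b >= min_fpkm
  out[ok & fpkm_b / fpkm_a >= fc] <- "up"
  out[ok & fpkm_a / fpkm_b >= fc] <- "down"
  out[ok & out == "excluded"] <- "neither"
  out
}

#' Exact binomial test for the down- vs up-regulation trend
#'
#' Tests whether, among genes passing the expression filters, significantly
#' more are down-regulated than up-regulated (or vice versa): a two-sided
#' exact binomial test of `n_down` successes in `n_down + n_up` trials
#' against p = 0.5 (the two-sided p sums all outcome probabilities not
#' exceeding that of the observed count).
#'
#' @param n_down,n_up gene counts after expression filtering.
#' @return a `trend_result` list: `n_down`, `n_up`, `p_value`, `direction`
#'   (`"down"`, `"up"` or `"none"`).
#' @export
binomial_trend_test <- function(n_down, n_up) {
  if (n_down + n_up < 1) stop("no classified genes", call. = FALSE)
  p <- stats::binom.test(n_down, n_down + n_up, p = 0.5)$p.value
  structure(list(n_down = n_down, n_up = n_up, p_value = p,
                 direction = if (n_down > n_up) "down"
                             else if (n_up > n_down) "up" else "none"),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("trend: %d down vs %d up (direction %s), binomial p = %.3g\n",
              x$n_down, x$n_up, x$direction, x$p_value))
  invisible(x)
}

#' Hypergeometric over-enrichment test for two gene sets
#'
#' One-sided (over-enrichment) hypergeometric tail probability of observing
#' at least the realized intersection of two gene sets drawn from a common
#' universe; the standard test for, e.g., the overlap of lengthened-UTR
#' genes between two senescence models.
#'
#' @param set1,set2 character vectors of gene ids (deduplicated).
#' @param universe_size number of genes in the common universe.
#' @return list: `overlap`, `expected` (under independence), `p_value`.
#' @export
overlap_test <- function(set1, set2, universe_size) {
  set1 <- unique(set1); set2 <- unique(set2)
  m <- length(set1); n2 <- length(set2)
  if (m > universe_size || n2 > universe_size) {
    stop("universe smaller than one of the sets", call. = FALSE)
  }
  k <- length(intersect(set1, set2))
  p <- stats::phyper(k - 1, m, universe_size - m, n2, lower.tail = FALSE)
  list(overlap = k, expected = m * n2 / universe_size, p_value = p)
}
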