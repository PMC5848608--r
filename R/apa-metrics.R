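# Per-gene APA summary statistics: effective 3' UTR length, Z-score
# profiles across samples, and the RUD index from RNA-seq coverage.

#' Effective 3' UTR length (tag-weighted mean distance)
#'
#' The effective 3' UTR length of a gene in one sample is the tag-count
#' weighted mean of its tandem poly(A)-site distances to the stop codon:
#' `L_eff = sum(d_i * n_i) / sum(n_i)`. It summarizes proximal/distal usage
#' in a single bp value: moving tag mass from proximal to distal sites
#' strictly increases it, and it is invariant to rescaling all counts.
#'
#' @param distance site distances to the stop codon (bp, >= 0).
#' @param count tag counts at those sites (same length).
#' @return the weighted mean in bp, or `NA_real_` when the total count is
#'   zero (missing, never 0).
#' @export
effective_utr_length <- function(distance, count) {
  stopifnot(length(distance) == length(count))
  if (!length(count)) return(NA_real_)
  if (any(count < 0)) stop("apa_metrics: negative tag count", call. = FALSE)
  tot <- sum(count)
  if (tot <= 0) return(NA_real_)
  sum(distance * count) / tot
}

#' Effective 3' UTR length matrix over genes and samples
#'
#' @param profiles an `apa_profiles` data frame (see [assign_clusters()]).
#' @param samples sample ids; defaults to `attr(profiles, "samples")`.
#' @return numeric matrix (genes x samples) of effective lengths; `NA` where
#'   a gene has no tags in a sample.
#' @export
effective_utr_lengths <- function(profiles, samples = attr(profiles, "samples")) {
  genes <- unique(profiles$gene_id)
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  sp <- split(profiles, profiles$gene_id)
  for (g in names(sp)) {
    p <- sp[[g]]
    for (s in samples) {
      out[g, s] <- effective_utr_length(p$distance, p[[paste0("count_", s)]])
    }
  }
  out[genes, , drop = FALSE]
}

# condition-level effective lengths with replicate counts pooled per gene
.effective_utr_length_pooled <- function(profiles, samples) {
  cols <- paste0("count_", samples)
  sp <- split(profiles, profiles$gene_id)
  vapply(sp, function(p) {
    n <- rowSums(as.matrix(p[, cols, drop = FALSE]))
    effective_utr_length(p$distance, n)
  }, numeric(1))
}

#' Z-score transform effective 3' UTR lengths across samples
#'
#' Standardizes each gene's effective-length profile across samples:
#' `z = (L - mean(L)) / sd(L)` with the sample (n - 1) standard deviation.
#' A gene with identical lengths in all samples (sd = 0) gets an all-zero
#' row; genes with fewer than two non-missing values get `NA`.
#'
#' @param L genes x samples matrix from [effective_utr_lengths()].
#' @return matrix of the same shape.
#' @export
zscore_profile <- function(L) {
  L <- as.matrix(L)
  z <- t(apply(L, 1, function(x) {
    ok <- !is.na(x)
    out <- rep(NA_real_, length(x))
    if (sum(ok) < 2) return(out)
    s <- stats::sd(x[ok])
    out[ok] <- if (s == 0) 0 else (x[ok] - mean(x[ok])) / s
    out
  }))
  dimnames(z) <- dimnames(L)
  z
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file (0-based half-open on disk; converted on
#'   import).
#' @return a [GenomicRanges::GRanges] with a numeric `score` (reads/bp).
#' @export
read_coverage <- function(path) {
  if (!file.exists(path)) {
    stop("apa_metrics: bedGraph not found: ", path, call. = FALSE)
  }
  rtracklayer::import(path, format = "bedGraph")
}

# mean coverage (reads/bp) over a 1-based inclusive span; bases without a
# bedGraph record count as zero coverage
.mean_coverage <- function(coverage, chrom, start, end) {
  width <- end - start + 1
  if (width <= 0) return(NA_real_)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, coverage, ignore.strand = TRUE)
  if (!length(hits)) return(0)
  sub <- coverage[S4Vectors::subjectHits(hits)]
  ov_start <- pmax(GenomicRanges::start(sub), start)
  ov_end <- pmin(GenomicRanges::end(sub), end)
  sum(sub$score * (ov_end - ov_start + 1)) / width
}

#' RUD index for one gene from RNA-seq coverage
#'
#' The relative usage of distal poly(A) sites (RUD) compares mean RNA-seq
#' coverage over the alternative UTR (aUTR: proximal site to distal site,
#' present only in the long isoform) with the common UTR (cUTR: stop codon
#' to proximal site, shared by both isoforms):
#' `RUD = mean_cov(aUTR) / mean_cov(cUTR)`. Full distal usage gives
#' RUD close to 1, exclusive proximal usage gives 0.
#'
#' @param gene_model one row of a `gene_models` data frame.
#' @param proximal,distal stop-codon distances (bp) of the proximal and
#'   distal site (`distal > proximal >= 1`).
#' @param coverage a coverage [GenomicRanges::GRanges] from
#'   [read_coverage()].
#' @return a list with the cUTR/aUTR spans (1-based genomic), their mean
#'   coverages, and `rud` (`NA` when the cUTR has zero coverage).
#' @export
rud_index <- function(gene_model, proximal, distal, coverage) {
  stopifnot(nrow(gene_model) == 1L)
  if (distal <= proximal) {
    stop("apa_metrics: aUTR has zero width (distal <= proximal)",
         call. = FALSE)
  }
  if (proximal < 1) {
    stop("apa_metrics: proximal site must lie downstream of the stop codon",
         call. = FALSE)
  }
  sp <- gene_model$stop_pos
  if (gene_model$strand == "+") {
    cutr <- c(sp + 1, sp + proximal)
    autr <- c(sp + proximal + 1, sp + distal)
  } else {
    cutr <- c(sp - proximal, sp - 1)
    autr <- c(sp - distal, sp - proximal - 1)
  }
  mc <- .mean_coverage(coverage, gene_model$chrom, cutr[1], cutr[2])
  ma <- .mean_coverage(coverage, gene_model$chrom, autr[1], autr[2])
  rud <- if (is.na(mc) || mc == 0) NA_real_ else ma / mc
  list(gene_id = gene_model$gene_id, cutr = cutr, autr = autr,
       mean_coverage_cutr = mc, mean_coverage_autr = ma, rud = rud)
}

#' RUD index table over all genes with >= 2 tandem sites
#'
#' For genes with more than two tandem sites, the two sites with the highest
#' pooled tag counts define the proximal/distal pair (the nearer of the two
#' is proximal); RUD is an inherently two-region statistic.
#'
#' @param profiles an `apa_profiles` data frame.
#' @param gene_models output of [read_gene_models()].
#' @param coverage a coverage [GenomicRanges::GRanges].
#' @return data frame: `gene_id`, `proximal`, `distal` (bp distances),
#'   `mean_coverage_cutr`, `mean_coverage_autr`, `rud`.
#' @export
rud_table <- function(profiles, gene_models, coverage) {
  sp <- split(profiles, profiles$gene_id)
  rows <- lapply(names(sp), function(g) {
    p <- sp[[g]]
    if (nrow(p) < 2) return(NULL)
    top2 <- order(-p$total, p$distance)[1:2]
    d <- sort(p$distance[top2])
    if (d[1] < 1) return(NULL)
    gm <- gene_models[gene_models$gene_id == g, , drop = FALSE]
    if (!nrow(gm)) return(NULL)
    r <- rud_index(gm, d[1], d[2], coverage)
    data.frame(gene_id = g, proximal = d[1], distal = d[2],
               mean_coverage_cutr = r$mean_coverage_cutr,
               mean_coverage_autr = r$mean_coverage_autr,
               rud = r$rud, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), proximal = integer(0),
                      distal = integer(0), mean_coverage_cutr = numeric(0),
                      mean_coverage_autr = numeric(0), rud = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
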