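# Poly(A)-site cluster calling and QC.
#
# Tags are clustered per (chromosome, strand) by single linkage: tags whose
# positions differ by at most `window_bp` join one cluster. The representative
# position of a cluster is the position with the highest pooled tag count
# (ties broken towards the 5'-most position in transcription direction),
# which downstream code treats as the cleavage site.

# PAS hexamer priority list: canonical first, then the common single-base
# variants reported across poly(A)-site catalogues.
.pas_hexamers <- c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA",
                   "AATATA", "AATACA", "CATAAA", "GATAAA", "AATGAA",
                   "TTTAAA", "ACTAAA")

#' Cluster 3'-end tags into poly(A)-site clusters
#'
#' Pools one or more tag tracks and performs strand-aware single-linkage
#' clustering: within a chromosome and strand, tags whose positions differ
#' by at most `window_bp` are merged into one cluster. Per-sample counts are
#' summed over the cluster.
#'
#' Clusters whose pooled count falls below `min_count` are dropped (singleton
#' noise); the total tag count they carried is retained in
#' `attr(x, "dropped_tags")` so that tag-count conservation can be audited:
#' input total = sum of reported cluster counts + dropped tags.
#'
#' @param tracks a `tag_track` or list of them (distinct `sample_id`s).
#' @param window_bp single-linkage window, bp (>= 1).
#' @param min_count minimum pooled tag count for a cluster to be reported.
#' @return a `pa_clusters` data frame: `chrom`, `start`, `end` (1-based
#'   inclusive span of member tags), `strand`, `rep_pos`, one `count_<sample>`
#'   column per sample, `total`. Attributes: `samples`, `window_bp`,
#'   `dropped_clusters`, `dropped_tags`.
#' @export
cluster_tags <- function(tracks, window_bp = 24, min_count = 3) {
  if (inherits(tracks, "tag_track")) tracks <- list(tracks)
  stopifnot(length(window_bp) == 1L, window_bp >= 1)
  samples <- vapply(tracks, function(t) attr(t, "sample_id"), character(1))
  if (anyDuplicated(samples)) {
    stop("pa_calling: duplicated sample_id among tag tracks", call. = FALSE)
  }
  count_cols <- paste0("count_", samples)
  long <- do.call(rbind, Map(function(t, s) {
    if (!nrow(t)) return(NULL)
    data.frame(chrom = t$chrom, pos = t$pos, strand = t$strand,
               count = t$count, sample = s, stringsAsFactors = FALSE)
  }, tracks, samples))

  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      rep_pos = integer(0), stringsAsFactors = FALSE)
  for (cc in count_cols) empty[[cc]] <- integer(0)
  empty$total <- integer(0)
  if (is.null(long) || !nrow(long)) {
    return(structure(empty, class = c("pa_clusters", "data.frame"),
                     samples = samples, window_bp = window_bp,
                     dropped_clusters = 0L, dropped_tags = 0L))
  }

  # pool counts per unique (chrom, strand, position)
  key <- paste(long$chrom, long$strand, sprintf("%012d", long$pos), sep = "\r")
  tot <- rowsum(as.numeric(long$count), key)
  ukey <- rownames(tot)
  per_sample <- vapply(samples, function(s) {
    i <- long$sample == s
    v <- numeric(length(ukey))
    if (any(i)) {
      x <- rowsum(as.numeric(long$count[i]), key[i])
      v[match(rownames(x), ukey)] <- x[, 1]
    }
    v
  }, numeric(length(ukey)))
  per_sample <- matrix(per_sample, ncol = length(samples),
                       dimnames = list(NULL, samples))
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  pos_df <- data.frame(chrom = parts[, 1], strand = parts[, 2],
                       pos = as.integer(parts[, 3]), total = tot[, 1],
                       stringsAsFactors = FALSE)
  # ukey sort order is (chrom, strand, zero-padded position): already the
  # order single-linkage needs
  new_block <- c(TRUE, pos_df$chrom[-1] != pos_df$chrom[-nrow(pos_df)] |
                   pos_df$strand[-1] != pos_df$strand[-nrow(pos_df)])
  gap <- c(0L, diff(pos_df$pos))
  cid <- cumsum(new_block | gap > window_bp)

  cl_start <- tapply(pos_df$pos, cid, min)
  cl_end <- tapply(pos_df$pos, cid, max)
  cl_total <- tapply(pos_df$total, cid, sum)
  # representative: max pooled count, tie -> 5'-most in transcription sense
  tie_pos <- ifelse(pos_df$strand == "+", pos_df$pos, -pos_df$pos)
  o <- order(cid, -pos_df$total, tie_pos)
  first <- o[!duplicated(cid[o])]
  cl <- data.frame(chrom = pos_df$chrom[first],
                   start = as.integer(cl_start),
                   end = as.integer(cl_end),
                   strand = pos_df$strand[first],
                   rep_pos = pos_df$pos[first],
                   stringsAsFactors = FALSE)
  for (j in seq_along(samples)) {
    cl[[count_cols[j]]] <- as.integer(rowsum(per_sample[, j], cid)[, 1])
  }
  cl$total <- as.integer(cl_total)

  keep <- cl$total >= min_count
  dropped_tags <- sum(cl$total[!keep])
  cl <- cl[keep, , drop = FALSE]
  cl <- cl[order(cl$chrom, cl$start, cl$strand), ]
  rownames(cl) <- NULL
  structure(cl, class = c("pa_clusters", "data.frame"),
            samples = samples, window_bp = window_bp,
            dropped_clusters = sum(!keep),
            dropped_tags = as.integer(dropped_tags))
}

#' Flag internal-priming (A-rich mispriming) artifacts
#'
#' Oligo(dT) priming at genomic A stretches creates false poly(A) sites. A
#' cluster is flagged when the `window_bp`-nt genomic window immediately
#' downstream (transcription direction) of its representative position
#' contains at least `a_run` consecutive adenosines or at least `a_count`
#' adenosines in total, read in transcription-strand sense. Windows running
#' past the chromosome end are truncated (and logged).
#'
#' @param clusters a `pa_clusters` data frame.
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param a_run minimum run of consecutive A triggering the flag.
#' @param a_count minimum total A count in the window triggering the flag.
#' @param window_bp width of the downstream window.
#' @return `clusters` with a logical `internal_priming` column.
#' @export
flag_internal_priming <- function(clusters, genome, a_run = 6, a_count = 7,
                                  window_bp = 10) {
  genome <- .as_genome(genome)
  if (!nrow(clusters)) {
    clusters$internal_priming <- logical(0)
    return(clusters)
  }
  plus <- clusters$strand == "+"
  start <- ifelse(plus, clusters$rep_pos + 1L, clusters$rep_pos - window_bp)
  end <- ifelse(plus, clusters$rep_pos + window_bp, clusters$rep_pos - 1L)
  win <- .window_seq(genome, clusters$chrom, start, end, clusters$strand)
  n_a <- nchar(win) - nchar(gsub("A", "", win, fixed = TRUE))
  max_run <- vapply(gregexpr("A+", win), function(m) {
    if (m[1] == -1L) 0L else max(attr(m, "match.length"))
  }, integer(1))
  clusters$internal_priming <- max_run >= a_run | n_a >= a_count
  clusters
}

#' Annotate poly(A) signal (PAS) hexamers upstream of each cluster
#'
#' Searches the `search_bp` nt upstream of the representative position
#' (transcription-strand sense) for the canonical PAS `AATAAA`, then
#' `ATTAAA`, then the common single-base variants. The highest-priority
#' hexamer present is reported together with the distance (bp) from the
#' representative position to the hexamer start; among several occurrences
#' of that hexamer the one closest to the site wins.
#'
#' @param clusters a `pa_clusters` data frame.
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param search_bp upstream search window, nt.
#' @param hexamers priority-ordered candidate hexamers.
#' @return `clusters` with `pas_hexamer` (`NA` if none found) and
#'   `pas_offset` (bp upstream of `rep_pos`; `NA` if none) columns.
#' @export
annotate_pas <- function(clusters, genome, search_bp = 40,
                         hexamers = .pas_hexamers) {
  genome <- .as_genome(genome)
  if (!nrow(clusters)) {
    clusters$pas_hexamer <- character(0)
    clusters$pas_offset <- integer(0)
    return(clusters)
  }
  plus <- clusters$strand == "+"
  start <- ifelse(plus, clusters$rep_pos - search_bp, clusters$rep_pos + 1L)
  end <- ifelse(plus, clusters$rep_pos - 1L, clusters$rep_pos + search_bp)
  win <- .window_seq(genome, clusters$chrom, start, end, clusters$strand)
  hex <- rep(NA_character_, nrow(clusters))
  off <- rep(NA_integer_, nrow(clusters))
  for (i in seq_along(win)) {
    w <- nchar(win[i])
    if (w < 6) next
    for (h in hexamers) {
      m <- gregexpr(h, win[i], fixed = TRUE)[[1]]
      if (m[1] != -1L) {
        # string index i0 maps to sense distance w - i0 + 1 upstream of rep_pos
        hex[i] <- h
        off[i] <- min(w - as.integer(m) + 1L)
        break
      }
    }
  }
  clusters$pas_hexamer <- hex
  clusters$pas_offset <- off
  clusters
}

#' Assign poly(A) clusters to genes and order tandem sites
#'
#' A cluster is assigned to a gene when its representative position falls in
#' the gene's pA search space on the same strand. Internally-primed clusters
#' are excluded unless `include_flagged = TRUE`. A cluster inside two genes'
#' search spaces goes to the gene whose stop codon is nearer; exact ties go
#' to the 5'-most gene in genomic order (logged).
#'
#' @param clusters a `pa_clusters` data frame (ideally after
#'   [flag_internal_priming()]).
#' @param gene_models output of [read_gene_models()].
#' @param include_flagged keep internally-primed clusters?
#' @return an `apa_profiles` data frame: one row per (gene, tandem site) with
#'   `gene_id`, `site_index` (1 = proximal), `distance` (bp from the stop
#'   codon), `chrom`, `strand`, `rep_pos`, per-sample `count_*` columns and
#'   `total`, sorted by gene and ascending distance. `attr(x, "samples")`
#'   carries the sample ids.
#' @export
assign_clusters <- function(clusters, gene_models, include_flagged = FALSE) {
  samples <- attr(clusters, "samples")
  cl <- clusters
  if (!include_flagged && "internal_priming" %in% names(cl)) {
    cl <- cl[!cl$internal_priming, , drop = FALSE]
  }
  count_cols <- paste0("count_", samples)
  empty <- data.frame(gene_id = character(0), site_index = integer(0),
                      distance = integer(0), chrom = character(0),
                      strand = character(0), rep_pos = integer(0),
                      stringsAsFactors = FALSE)
  for (cc in count_cols) empty[[cc]] <- integer(0)
  empty$total <- integer(0)
  if (!nrow(cl)) {
    return(structure(empty, class = c("apa_profiles", "data.frame"),
                     samples = samples))
  }
  cgr <- GenomicRanges::GRanges(cl$chrom,
                                IRanges::IRanges(cl$rep_pos, cl$rep_pos),
                                strand = cl$strand)
  ggr <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(gene_models$search_start, gene_models$search_end),
    strand = gene_models$strand)
  hits <- GenomicRanges::findOverlaps(cgr, ggr)
  if (!length(hits)) {
    return(structure(empty, class = c("apa_profiles", "data.frame"),
                     samples = samples))
  }
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  d <- .stop_distance(cl$rep_pos[q], gene_models$stop_pos[s],
                      gene_models$strand[s])
  # nearest stop codon wins; ties -> 5'-most gene in genomic order
  o <- order(q, d, gene_models$gene_start[s])
  qo <- q[o]
  keep <- !duplicated(qo)
  # log clusters whose best stop-codon distance is shared by >1 gene
  best <- split(d[o], qo)
  n_tie <- sum(vapply(best, function(x) length(x) > 1 && x[1] == x[2],
                      logical(1)))
  if (n_tie > 0) {
    message("pa_calling: ", n_tie, " cluster(s) equidistant between two ",
            "genes' stop codons; assigned to the 5'-most gene")
  }
  qi <- q[o][keep]
  si <- s[o][keep]
  di <- d[o][keep]

  prof <- data.frame(gene_id = gene_models$gene_id[si],
                     distance = as.integer(di),
                     chrom = cl$chrom[qi], strand = cl$strand[qi],
                     rep_pos = cl$rep_pos[qi], stringsAsFactors = FALSE)
  for (cc in count_cols) prof[[cc]] <- cl[[cc]][qi]
  prof$total <- cl$total[qi]
  prof <- prof[order(prof$gene_id, prof$distance), ]
  prof$site_index <- stats::ave(seq_len(nrow(prof)), prof$gene_id,
                                FUN = seq_along)
  prof <- prof[, c("gene_id", "site_index", "distance", "chrom", "strand",
                   "rep_pos", count_cols, "total")]
  rownames(prof) <- NULL
  structure(prof, class = c("apa_profiles", "data.frame"), samples = samples)
}

#' Summarize called clusters for quality control
#'
#' Reports the genomic-feature distribution of representative positions
#' (3' UTR / CDS / intron / intergenic, in that precedence), the fraction of
#' clusters with the canonical PAS `AATAAA`, and the fraction flagged as
#' internal priming. Run [annotate_pas()] and [flag_internal_priming()]
#' first.
#'
#' @param clusters a `pa_clusters` data frame.
#' @param gene_models output of [read_gene_models()].
#' @return a `qc_summary` list: `fraction_by_feature` (named numeric summing
#'   to 1), `fraction_with_canonical_PAS`,
#'   `fraction_flagged_internal_priming`, `n_clusters`.
#' @export
qc_summary <- function(clusters, gene_models) {
  if (!nrow(clusters)) stop("no clusters to summarize", call. = FALSE)
  cgr <- GenomicRanges::GRanges(clusters$chrom,
                                IRanges::IRanges(clusters$rep_pos,
                                                 clusters$rep_pos),
                                strand = clusters$strand)
  gm <- gene_models
  has_utr <- gm$utr3_end >= gm$utr3_start
  utr <- GenomicRanges::GRanges(gm$chrom[has_utr],
                                IRanges::IRanges(gm$utr3_start[has_utr],
                                                 gm$utr3_end[has_utr]),
                                strand = gm$strand[has_utr])
  cds <- attr(gene_models, "cds")
  cdsgr <- GenomicRanges::GRanges(cds$chrom,
                                  IRanges::IRanges(cds$start, cds$end),
                                  strand = cds$strand)
  span <- attr(gene_models, "gene_span")
  spgr <- GenomicRanges::GRanges(span$chrom,
                                 IRanges::IRanges(span$gene_start,
                                                  span$gene_end),
                                 strand = span$strand)
  in_utr <- GenomicRanges::countOverlaps(cgr, utr) > 0
  in_cds <- GenomicRanges::countOverlaps(cgr, cdsgr) > 0
  in_gene <- GenomicRanges::countOverlaps(cgr, spgr) > 0
  feature <- ifelse(in_utr, "utr3",
                    ifelse(in_cds, "cds",
                           ifelse(in_gene, "intron", "intergenic")))
  frac <- vapply(c(utr3 = "utr3", cds = "cds", intron = "intron",
                   intergenic = "intergenic"),
                 function(f) mean(feature == f), numeric(1))
  canon <- if ("pas_hexamer" %in% names(clusters)) {
    mean(!is.na(clusters$pas_hexamer) & clusters$pas_hexamer == "AATAAA")
  } else NA_real_
  flagged <- if ("internal_priming" %in% names(clusters)) {
    mean(clusters$internal_priming)
  } else NA_real_
  structure(list(fraction_by_feature = frac,
                 fraction_with_canonical_PAS = canon,
                 fraction_flagged_internal_priming = flagged,
                 n_clusters = nrow(clusters)),
            class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("poly(A) cluster QC (", x$n_clusters, " clusters)\n", sep = "")
  cat("  feature distribution:\n")
  for (f in names(x$fraction_by_feature)) {
    cat(sprintf("    %-10s %.3f\n", f, x$fraction_by_feature[[f]]))
  }
  cat(sprintf("  canonical PAS (AATAAA): %.3f\n",
              x$fraction_with_canonical_PAS))
  cat(sprintf("  flagged internal priming: %.3f\n",
              x$fraction_flagged_internal_priming))
  invisible(x)
}

#' Write called clusters to TSV and BED
#'
#' The BED carries the cluster span with the pooled count as score; the TSV
#' keeps all columns (per-sample counts, PAS annotation, priming flag).
#'
#' @param clusters a `pa_clusters` data frame.
#' @param tsv_path,bed_path output paths (either may be `NULL` to skip).
#' @return invisibly, a character vector of the files written.
#' @export
write_clusters <- function(clusters, tsv_path = NULL, bed_path = NULL) {
  written <- character(0)
  if (!is.null(tsv_path)) {
    write.table(as.data.frame(clusters), tsv_path, sep = "\t",
                quote = FALSE, row.names = FALSE, na = "NA")
    written <- c(written, tsv_path)
  }
  if (!is.null(bed_path) && nrow(clusters)) {
    gr <- GenomicRanges::GRanges(clusters$chrom,
                                 IRanges::IRanges(clusters$start,
                                                  clusters$end),
                                 strand = clusters$strand)
    gr$name <- paste0("pa_", seq_len(nrow(clusters)))
    gr$score <- clusters$total
    rtracklayer::export(gr, bed_path, format = "BED")
    written <- c(written, bed_path)
  }
  invisible(written)
}
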