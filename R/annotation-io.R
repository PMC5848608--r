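#' Build strand-aware gene 3'-end models from a GTF annotation
#'
#' Parses a GTF (Ensembl dialect, 1-based inclusive; converted on import) and
#' derives, per protein-coding gene, the geometry against which poly(A)-site
#' distances are measured: the last base of the stop codon (distance origin,
#' d = 0), the UTR portion of the 3'-most exon, and the genomic search space
#' in which pA clusters may be assigned to the gene.
#'
#' When a gene has several transcripts with a CDS, the transcript whose stop
#' codon lies 3'-most in the direction of transcription defines the model,
#' so that each gene has a single distance origin. The pA search space runs
#' from the stop codon to the annotated 3' end plus `max_utr3_extension`
#' (called distal sites often lie beyond annotation); it is truncated where
#' it would run into the next annotated gene on the same strand.
#'
#' Genes without CDS features are skipped and recorded in
#' `attr(x, "skipped")`; genes whose stop codon cannot be placed inside
#' their 3'-most exon are skipped with a warning.
#'
#' @param gtf_path path to a GTF file with `exon`, `CDS` and (preferably)
#'   `stop_codon` features carrying `gene_id`/`transcript_id` attributes.
#'   If `stop_codon` is absent for a transcript the 3'-most CDS base is used.
#' @param max_utr3_extension search space extension beyond the annotated
#'   3' end, in bp.
#' @return a `gene_models` data frame with one row per gene: `gene_id`,
#'   `chrom`, `strand`, `stop_pos` (1-based last base of the stop codon),
#'   `utr3_start`/`utr3_end` (1-based inclusive; may be empty when the stop
#'   codon abuts the transcript end), `search_start`/`search_end`,
#'   `gene_start`/`gene_end`. Attributes: `skipped` (gene ids without CDS),
#'   `cds` and `gene_span` data frames used for QC feature classification.
#' @export
read_gene_models <- function(gtf_path, max_utr3_extension = 1000) {
  if (!file.exists(gtf_path)) {
    stop("annotation_io: GTF not found: ", gtf_path, call. = FALSE)
  }
  gr <- tryCatch(
    rtracklayer::import(gtf_path, format = "gtf"),
    error = function(e) {
      stop("annotation_io: failed to parse GTF '", gtf_path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id %||% NA_character_),
    stringsAsFactors = FALSE)

  all_genes <- unique(df$gene_id[!is.na(df$gene_id)])
  cds <- df[df$type == "CDS" & !is.na(df$transcript_id), ]
  skipped <- setdiff(all_genes, unique(cds$gene_id))

  sc_by_tx <- split(df[df$type == "stop_codon", ], df$transcript_id[df$type == "stop_codon"])
  ex_by_tx <- split(df[df$type == "exon", ], df$transcript_id[df$type == "exon"])
  cds_by_tx <- split(cds, cds$transcript_id)

  unresolved <- character(0)
  tx_rows <- lapply(names(cds_by_tx), function(tx) {
    cc <- cds_by_tx[[tx]]
    strand <- cc$strand[1]
    if (!strand %in% c("+", "-")) return(NULL)
    scc <- sc_by_tx[[tx]]
    stop_pos <- if (!is.null(scc) && nrow(scc)) {
      if (strand == "+") max(scc$end) else min(scc$start)
    } else {
      if (strand == "+") max(cc$end) else min(cc$start)
    }
    ee <- ex_by_tx[[tx]]
    if (is.null(ee) || !nrow(ee)) ee <- cc
    if (strand == "+") {
      last <- ee[which.max(ee$end), , drop = FALSE]
      if (stop_pos < last$start || stop_pos > last$end) {
        unresolved <<- c(unresolved, cc$gene_id[1]); return(NULL)
      }
      utr_start <- stop_pos + 1; utr_end <- last$end
    } else {
      last <- ee[which.min(ee$start), , drop = FALSE]
      if (stop_pos < last$start || stop_pos > last$end) {
        unresolved <<- c(unresolved, cc$gene_id[1]); return(NULL)
      }
      utr_start <- last$start; utr_end <- stop_pos - 1
    }
    data.frame(gene_id = cc$gene_id[1], transcript_id = tx,
               chrom = cc$chrom[1], strand = strand, stop_pos = stop_pos,
               utr3_start = utr_start, utr3_end = utr_end,
               gene_start = min(ee$start), gene_end = max(ee$end),
               stringsAsFactors = FALSE)
  })
  tx_df <- do.call(rbind, tx_rows)
  if (is.null(tx_df) || !nrow(tx_df)) {
    stop("annotation_io: no gene with a resolvable stop codon in ", gtf_path,
         call. = FALSE)
  }
  lost <- setdiff(unique(unresolved), tx_df$gene_id)
  if (length(lost)) {
    warning("annotation_io: skipped ", length(lost),
            " gene(s) with CDS but no resolvable stop codon: ",
            paste(utils::head(lost, 5), collapse = ", "))
    skipped <- union(skipped, lost)
  }

  # per gene keep the transcript whose stop codon is 3'-most in transcription
  # direction (single distance origin per gene)
  key <- ifelse(tx_df$strand == "+", tx_df$stop_pos, -tx_df$stop_pos)
  o <- order(tx_df$gene_id, -key)
  gm <- tx_df[o, ][!duplicated(tx_df$gene_id[o]), ]
  gm <- gm[order(gm$chrom, gm$gene_start), ]
  rownames(gm) <- NULL

  # pA search space: stop codon -> annotated 3' end + extension, truncated at
  # the next annotated gene on the same strand
  gm$search_start <- ifelse(gm$strand == "+", gm$stop_pos,
                            pmin(gm$utr3_start, gm$stop_pos) - max_utr3_extension)
  gm$search_end <- ifelse(gm$strand == "+",
                          pmax(gm$utr3_end, gm$stop_pos) + max_utr3_extension,
                          gm$stop_pos)
  gm$search_start <- pmax(gm$search_start, 1L)
  for (i in seq_len(nrow(gm))) {
    same <- gm$chrom == gm$chrom[i] & gm$strand == gm$strand[i] &
      gm$gene_id != gm$gene_id[i]
    if (gm$strand[i] == "+") {
      nxt <- gm$gene_start[same & gm$gene_start > gm$gene_end[i]]
      if (length(nxt)) {
        gm$search_end[i] <- min(gm$search_end[i], min(nxt) - 1L)
      }
    } else {
      prv <- gm$gene_end[same & gm$gene_end < gm$gene_start[i]]
      if (length(prv)) {
        gm$search_start[i] <- max(gm$search_start[i], max(prv) + 1L)
      }
    }
  }

  structure(gm[, c("gene_id", "transcript_id", "chrom", "strand", "stop_pos",
                   "utr3_start", "utr3_end", "search_start", "search_end",
                   "gene_start", "gene_end")],
            class = c("gene_models", "data.frame"),
            skipped = skipped,
            cds = cds[, c("chrom", "start", "end", "strand", "gene_id")],
            gene_span = gm[, c("chrom", "gene_start", "gene_end", "strand",
                               "gene_id")])
}

#' Read aligned 3'-end tags from a BED6 file
#'
#' Each BED record represents aligned PA-seq tags: the strand-aware 3' end of
#' the record is taken as the tag's cleavage position and the score column as
#' the tag count. Records at the same (chrom, position, strand) are
#' aggregated with counts summed.
#'
#' @param bed_path BED6 file; score holds the tag count (integer >= 1);
#'   strand must be `+` or `-`.
#' @param sample_id label attached to the track (used as the per-sample count
#'   column name downstream).
#' @return a `tag_track` data frame with columns `chrom`, `pos` (1-based),
#'   `strand`, `count`, sorted by position; `attr(x, "sample_id")` holds the
#'   label. An empty file yields an empty track.
#' @export
read_tags <- function(bed_path, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!file.exists(bed_path)) {
    stop("annotation_io: BED not found: ", bed_path, call. = FALSE)
  }
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  if (file.size(bed_path) == 0) {
    return(structure(empty, class = c("tag_track", "data.frame"),
                     sample_id = sample_id))
  }
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (!length(gr)) {
    return(structure(empty, class = c("tag_track", "data.frame"),
                     sample_id = sample_id))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("annotation_io: tag records must carry an explicit +/- strand (",
         sum(!strand %in% c("+", "-")), " offending record(s) in ",
         bed_path, ")", call. = FALSE)
  }
  score <- gr$score
  if (is.null(score) || any(is.na(score))) {
    stop("annotation_io: BED score column must hold the tag count",
         call. = FALSE)
  }
  if (any(score < 1)) {
    stop("annotation_io: tag counts (BED score) must be >= 1; found ",
         min(score), call. = FALSE)
  }
  pos <- ifelse(strand == "+", GenomicRanges::end(gr),
                GenomicRanges::start(gr))
  key <- paste(as.character(GenomicRanges::seqnames(gr)), strand,
               sprintf("%012d", pos), sep = "\r")
  tot <- rowsum(as.numeric(score), key)
  parts <- do.call(rbind, strsplit(rownames(tot), "\r", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 3]),
                    strand = parts[, 2], count = as.integer(tot[, 1]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$strand), ]
  rownames(out) <- NULL
  structure(out, class = c("tag_track", "data.frame"), sample_id = sample_id)
}

#' Write a tag track back to BED6
#'
#' Inverse of [read_tags()]: each row becomes a single-base BED6 record with
#' the count in the score column. Round-tripping a track through
#' `write_tags()`/`read_tags()` reproduces it exactly.
#'
#' @param track a `tag_track` data frame.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(track$pos, track$pos),
    strand = track$strand)
  gr$name <- rep("tag", length(gr))
  gr$score <- track$count
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that trims FASTA
#' headers to the first word so sequence names match GTF/BED chromosome
#' names.
#'
#' @param fasta_path path to a (plain or bgzipped) FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("annotation_io: FASTA not found: ", fasta_path, call. = FALSE)
  }
  x <- Biostrings::readDNAStringSet(fasta_path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

.as_genome <- function(genome) {
  if (.is_dna(genome)) genome else read_genome(genome)
}

# extract genomic windows as transcription-sense character strings;
# coordinates clamped to chromosome bounds (truncated windows are logged)
.window_seq <- function(genome, chrom, start, end, strand) {
  out <- character(length(chrom))
  clipped <- 0L
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (!ch %in% names(genome)) {
      stop("pa_calling: chromosome '", ch, "' absent from genome FASTA",
           call. = FALSE)
    }
    len <- length(genome[[ch]])
    s <- pmax(1L, as.integer(start[i]))
    e <- pmin(len, as.integer(end[i]))
    clipped <- clipped + sum(s != start[i] | e != end[i])
    e <- pmax(e, s - 1L)  # fully off-chromosome -> empty string
    v <- Biostrings::extractAt(genome[[ch]], IRanges::IRanges(s, e))
    x <- as.character(v)
    neg <- strand[i] == "-"
    if (any(neg)) {
      x[neg] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(x[neg])))
    }
    out[i] <- x
  }
  if (clipped > 0) {
    message("pa_calling: ", clipped,
            " sequence window(s) truncated at chromosome bounds")
  }
  out
}
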