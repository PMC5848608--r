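# Independent oracles (kept free of the implementation paths they check)
# and small in-code fixtures.

# Fisher's exact two-sided p by full hypergeometric enumeration over all
# tables with the observed margins.
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1))
  }, numeric(1))
  p_obs <- probs[match(a, xs)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up by the hand formula q_(i) = min_{j >= i} p_(j) * n / j.
hand_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Two-sided exact binomial p against 0.5 by direct enumeration.
enum_binom_p <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# ---- hand-built two-gene fixture (one gene per strand) -------------------
# geneP ('+'): span 101-1100, stop codon ends at 400, 3' UTR 401-1100.
# geneM ('-'): span 2001-3000, 3' UTR 2001-2600, stop codon last base 2601.
fixture_gtf <- function(path = tempfile(fileext = ".gtf"),
                        extra_lines = character(0)) {
  at <- function(g, tx = NULL) {
    if (is.null(tx)) sprintf('gene_id "%s";', g)
    else sprintf('gene_id "%s"; transcript_id "%s";', g, tx)
  }
  l <- c(
    sprintf("chrT\ttest\tgene\t101\t1100\t.\t+\t.\t%s", at("geneP")),
    sprintf("chrT\ttest\ttranscript\t101\t1100\t.\t+\t.\t%s", at("geneP", "geneP.t1")),
    sprintf("chrT\ttest\texon\t101\t1100\t.\t+\t.\t%s", at("geneP", "geneP.t1")),
    sprintf("chrT\ttest\tCDS\t101\t397\t.\t+\t0\t%s", at("geneP", "geneP.t1")),
    sprintf("chrT\ttest\tstop_codon\t398\t400\t.\t+\t0\t%s", at("geneP", "geneP.t1")),
    sprintf("chrT\ttest\tgene\t2001\t3000\t.\t-\t.\t%s", at("geneM")),
    sprintf("chrT\ttest\ttranscript\t2001\t3000\t.\t-\t.\t%s", at("geneM", "geneM.t1")),
    sprintf("chrT\ttest\texon\t2001\t3000\t.\t-\t.\t%s", at("geneM", "geneM.t1")),
    sprintf("chrT\ttest\tCDS\t2604\t3000\t.\t-\t0\t%s", at("geneM", "geneM.t1")),
    sprintf("chrT\ttest\tstop_codon\t2601\t2603\t.\t-\t0\t%s", at("geneM", "geneM.t1")),
    extra_lines)
  writeLines(l, path)
  path
}

# a GTF gene with exons but no CDS (non-coding), appendable to fixture_gtf
noncoding_gene_lines <- function() {
  c(sprintf("chrT\ttest\tgene\t4001\t4500\t.\t+\t.\t%s",
            'gene_id "geneNC";'),
    sprintf("chrT\ttest\texon\t4001\t4500\t.\t+\t.\t%s",
            'gene_id "geneNC"; transcript_id "geneNC.t1";'))
}

fixture_genome <- function(len = 5000, seed = 99) {
  set.seed(seed)
  x <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(x) <- "chrT"
  x
}

# write a BED6 file from (pos, strand, count) triplets; single-base records
fixture_bed <- function(pos, strand, count,
                        path = tempfile(fileext = ".bed"),
                        chrom = "chrT") {
  writeLines(sprintf("%s\t%d\t%d\ttag\t%d\t%s",
                     chrom, pos - 1L, pos, count, strand), path)
  path
}

# a tag_track built directly in memory
make_track <- function(pos, strand, count, sample_id = "s1",
                       chrom = "chrT") {
  structure(data.frame(chrom = rep(chrom, length(pos)),
                       pos = as.integer(pos),
                       strand = strand, count = as.integer(count),
                       stringsAsFactors = FALSE),
            class = c("tag_track", "data.frame"), sample_id = sample_id)
}

# a minimal pa_clusters-like frame for sequence-window operations
make_clusters <- function(rep_pos, strand, chrom = "chrT") {
  data.frame(chrom = chrom, start = rep_pos, end = rep_pos,
             strand = strand, rep_pos = as.integer(rep_pos),
             stringsAsFactors = FALSE)
}

# an apa_profiles frame from per-gene site lists
make_profiles <- function(gene_id, distance, counts, samples,
                          strand = "+", chrom = "chrT", stop_pos = 0L) {
  df <- data.frame(gene_id = gene_id, site_index = NA_integer_,
                   distance = as.integer(distance), chrom = chrom,
                   strand = strand,
                   rep_pos = as.integer(ifelse(strand == "+",
                                               stop_pos + distance,
                                               stop_pos - distance)),
                   stringsAsFactors = FALSE)
  for (s in names(counts)) df[[paste0("count_", s)]] <- counts[[s]]
  df$total <- rowSums(as.matrix(df[, paste0("count_", names(counts)),
                                   drop = FALSE]))
  df <- df[order(df$gene_id, df$distance), ]
  df$site_index <- stats::ave(seq_len(nrow(df)), df$gene_id, FUN = seq_along)
  structure(df, class = c("apa_profiles", "data.frame"),
            samples = samples)
}
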