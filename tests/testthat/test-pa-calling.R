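# Single-linkage cluster calling, internal-priming filter, PAS annotation,
# gene assignment and QC.

test_that("single-linkage clustering merges tags within the window", {
  tr <- make_track(pos = c(100, 101, 105), strand = "+",
                   count = c(5, 9, 2))
  cl <- cluster_tags(tr, window_bp = 24, min_count = 1)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$rep_pos, 101L)
  expect_equal(cl$total, 16L)
  expect_equal(c(cl$start, cl$end), c(100L, 105L))
})

test_that("tags separated by more than the window form distinct clusters", {
  tr <- make_track(pos = c(100, 200), strand = "+", count = c(5, 5))
  cl <- cluster_tags(tr, window_bp = 24, min_count = 1)
  expect_equal(nrow(cl), 2L)
})

test_that("opposite strands never merge", {
  tr <- make_track(pos = c(100, 100), strand = c("+", "-"), count = c(5, 5))
  cl <- cluster_tags(tr, window_bp = 24, min_count = 1)
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$strand, c("+", "-"))
})

test_that("representative ties break to the 5'-most position in transcription sense", {
  plus <- cluster_tags(make_track(c(100, 110), "+", c(7, 7)),
                       window_bp = 24, min_count = 1)
  minus <- cluster_tags(make_track(c(100, 110), "-", c(7, 7)),
                        window_bp = 24, min_count = 1)
  expect_equal(plus$rep_pos, 100L)
  expect_equal(minus$rep_pos, 110L)
})

test_that("tag counts are conserved: clusters plus dropped equal the input", {
  set.seed(21)
  tracks <- lapply(1:3, function(i) {
    make_track(pos = sample(1:2000, 300, replace = TRUE),
               strand = sample(c("+", "-"), 300, replace = TRUE),
               count = sample(1:10, 300, replace = TRUE),
               sample_id = paste0("s", i))
  })
  total_in <- sum(vapply(tracks, function(t) sum(t$count), numeric(1)))
  cl <- cluster_tags(tracks, window_bp = 24, min_count = 5)
  expect_identical(sum(cl$total) + attr(cl, "dropped_tags"),
                   as.integer(total_in))
  # per-sample columns sum to the cluster totals
  cc <- as.matrix(cl[, paste0("count_s", 1:3)])
  expect_equal(unname(rowSums(cc)), as.numeric(cl$total))
})

test_that("clustering is invariant to input record order", {
  set.seed(22)
  tr <- make_track(pos = sample(1:500, 80), strand = sample(c("+", "-"), 80, TRUE),
                   count = sample(1:9, 80, TRUE))
  shuffled <- tr[sample(nrow(tr)), ]
  attr(shuffled, "sample_id") <- "s1"
  class(shuffled) <- c("tag_track", "data.frame")
  a <- cluster_tags(tr, 24, 1)
  b <- cluster_tags(shuffled, 24, 1)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("internal-priming rule flags A-runs and A-rich windows", {
  # '+' clusters at rep 10: downstream window = genomic 11-20
  windows <- c("AAAAAACGTA",  # 6 consecutive A -> flagged
               "ACGTACGTAC",  # clean -> not flagged
               "AAAAAGAAAA")  # 9 A, longest run 5 -> flagged by count rule
  for (i in seq_along(windows)) {
    genome <- Biostrings::DNAStringSet(setNames(
      paste0("CCCCCCCCCC", windows[i], "CCCC"), "chrT"))
    cl <- flag_internal_priming(make_clusters(10, "+"), genome)
    expect_identical(cl$internal_priming, i != 2, label = windows[i])
  }
})

test_that("internal-priming window is read in transcription sense on '-'", {
  # '-' cluster at rep 20: downstream window = genomic 10-19, revcomp
  genome <- Biostrings::DNAStringSet(setNames(
    paste0("CCCCCCCCC", "TACGTTTTTT", "CCCCCCCC"), "chrT"))
  # revcomp("TACGTTTTTT") = "AAAAAACGTA": 6 consecutive A in sense
  cl <- flag_internal_priming(make_clusters(20, "-"), genome)
  expect_true(cl$internal_priming)
  cl2 <- flag_internal_priming(make_clusters(20, "+"), genome)
  expect_false(cl2$internal_priming)
})

test_that("windows truncated at the chromosome end are tolerated", {
  genome <- Biostrings::DNAStringSet(setNames("CCCCCAAA", "chrT"))
  expect_message(
    cl <- flag_internal_priming(make_clusters(5, "+"), genome),
    "truncated")
  expect_false(cl$internal_priming)
})

test_that("PAS annotation reports the canonical hexamer and its offset", {
  # AATAAA planted so its start lies 21 nt upstream of rep_pos = 100
  base <- rep("C", 120)
  base[79:84] <- c("A", "A", "T", "A", "A", "A")
  genome <- Biostrings::DNAStringSet(setNames(paste(base, collapse = ""), "chrT"))
  cl <- annotate_pas(make_clusters(100, "+"), genome)
  expect_equal(cl$pas_hexamer, "AATAAA")
  expect_equal(cl$pas_offset, 21L)
})

test_that("canonical AATAAA outranks ATTAAA even when farther away", {
  base <- rep("C", 120)
  base[65:70] <- c("A", "A", "T", "A", "A", "A")   # offset 35
  base[85:90] <- c("A", "T", "T", "A", "A", "A")   # offset 15
  genome <- Biostrings::DNAStringSet(setNames(paste(base, collapse = ""), "chrT"))
  cl <- annotate_pas(make_clusters(100, "+"), genome)
  expect_equal(cl$pas_hexamer, "AATAAA")
  expect_equal(cl$pas_offset, 35L)
})

test_that("absent PAS yields missing hexamer and offset", {
  genome <- Biostrings::DNAStringSet(setNames(strrep("CG", 100), "chrT"))
  cl <- annotate_pas(make_clusters(100, "+"), genome)
  expect_true(is.na(cl$pas_hexamer))
  expect_true(is.na(cl$pas_offset))
})

test_that("clusters are assigned to genes by stop-codon distance, strand-aware", {
  gm <- read_gene_models(fixture_gtf())
  tr <- list(make_track(c(600, 1000, 2301), c("+", "+", "-"), c(10, 20, 30)))
  cl <- cluster_tags(tr, 24, 1)
  cl$internal_priming <- FALSE
  prof <- assign_clusters(cl, gm)
  p <- prof[prof$gene_id == "geneP", ]
  expect_equal(p$distance, c(200L, 600L))
  expect_equal(p$site_index, c(1L, 2L))      # proximal first
  m <- prof[prof$gene_id == "geneM", ]
  expect_equal(m$distance, 300L)
})

test_that("internally primed clusters are excluded from assignment by default", {
  gm <- read_gene_models(fixture_gtf())
  cl <- cluster_tags(list(make_track(c(600, 1000), "+", c(10, 20))), 24, 1)
  cl$internal_priming <- c(FALSE, TRUE)
  prof <- assign_clusters(cl, gm)
  expect_equal(prof$distance, 200L)
  prof_all <- assign_clusters(cl, gm, include_flagged = TRUE)
  expect_equal(nrow(prof_all), 2L)
})

test_that("overlapping genes: nearer stop codon wins, exact ties go 5'-most", {
  at <- function(g, tx) sprintf('gene_id "%s"; transcript_id "%s";', g, tx)
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    # two '+' genes sharing the stop position 400 but started at 51 / 101
    sprintf("chrT\ttest\texon\t51\t1100\t.\t+\t.\t%s", at("gA", "gA.t")),
    sprintf("chrT\ttest\tCDS\t51\t397\t.\t+\t0\t%s", at("gA", "gA.t")),
    sprintf("chrT\ttest\tstop_codon\t398\t400\t.\t+\t0\t%s", at("gA", "gA.t")),
    sprintf("chrT\ttest\texon\t101\t1100\t.\t+\t.\t%s", at("gB", "gB.t")),
    sprintf("chrT\ttest\tCDS\t101\t397\t.\t+\t0\t%s", at("gB", "gB.t")),
    sprintf("chrT\ttest\tstop_codon\t398\t400\t.\t+\t0\t%s", at("gB", "gB.t")),
    # a third gene with a farther stop codon
    sprintf("chrT\ttest\texon\t51\t1100\t.\t+\t.\t%s", at("gC", "gC.t")),
    sprintf("chrT\ttest\tCDS\t51\t197\t.\t+\t0\t%s", at("gC", "gC.t")),
    sprintf("chrT\ttest\tstop_codon\t198\t200\t.\t+\t0\t%s", at("gC", "gC.t"))),
    gtf)
  gm <- read_gene_models(gtf)
  cl <- cluster_tags(list(make_track(500, "+", 10)), 24, 1)
  cl$internal_priming <- FALSE
  expect_message(prof <- assign_clusters(cl, gm), "equidistant")
  # distance to gA/gB stops = 100 (tie, gA is 5'-most); to gC = 300
  expect_equal(prof$gene_id, "gA")
})

test_that("QC summary partitions clusters over genomic features", {
  gm <- read_gene_models(fixture_gtf())
  genome <- fixture_genome()
  tr <- list(make_track(c(600, 2301, 200, 3500), c("+", "-", "+", "+"),
                        c(10, 10, 10, 10)))
  cl <- cluster_tags(tr, 24, 1)
  cl <- flag_internal_priming(cl, genome)
  cl <- annotate_pas(cl, genome)
  qc <- qc_summary(cl, gm)
  expect_equal(sum(qc$fraction_by_feature), 1, tolerance = 1e-9)
  # 600 (UTR of geneP), 2301 (UTR of geneM), 200 (CDS of geneP), 3500 (intergenic)
  expect_equal(unname(qc$fraction_by_feature["utr3"]), 0.5)
  expect_equal(unname(qc$fraction_by_feature["cds"]), 0.25)
  expect_equal(unname(qc$fraction_by_feature["intergenic"]), 0.25)
  expect_true(qc$fraction_with_canonical_PAS >= 0 &&
                qc$fraction_with_canonical_PAS <= 1)
})

test_that("QC on zero clusters is an error", {
  gm <- read_gene_models(fixture_gtf())
  cl <- cluster_tags(list(make_track(integer(0), character(0), integer(0))),
                     24, 1)
  expect_error(qc_summary(cl, gm), "no clusters")
})

test_that("all-canonical clusters give canonical-PAS fraction 1", {
  base <- rep("C", 300)
  base[79:84] <- c("A", "A", "T", "A", "A", "A")
  base[179:184] <- c("A", "A", "T", "A", "A", "A")
  genome <- Biostrings::DNAStringSet(setNames(paste(base, collapse = ""), "chrT"))
  cl <- make_clusters(c(100, 200), "+")
  cl <- annotate_pas(cl, genome)
  cl$internal_priming <- FALSE
  gm <- read_gene_models(fixture_gtf())
  qc <- qc_summary(cl, gm)
  expect_equal(qc$fraction_with_canonical_PAS, 1.0)
})
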