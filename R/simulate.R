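# Ground-truth simulator for the whole pipeline: a synthetic chromosome
# with annotated genes, tandem poly(A) sites (canonical PAS planted 21 nt
# upstream, U/G-rich element downstream of the cleavage site), A-run
# mispriming decoys, Dirichlet-multinomial PA-seq tag counts, stepwise
# RNA-seq coverage, and expression tables. Every generator is
# seed-deterministic and records the truth needed to score each stage.

.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x <- alpha / sum(alpha) else x <- x / sum(x)
  x
}

#' Simulate a genome, gene annotation and APA ground truth
#'
#' Lays out `n_genes` single-exon protein-coding genes (random strand) along
#' one synthetic chromosome. Each gene carries a CDS, a 3' UTR of
#' `utr_len_range` bp and 1-3 tandem poly(A) sites; at each true site the
#' canonical PAS `AATAAA` is planted 21 nt upstream (transcription sense)
#' and the 12 nt downstream of the cleavage position are drawn from a
#' U/G-rich alphabet (mimicking the downstream element of genuine sites,
#' and guaranteeing they are not A-rich). A configurable fraction of UTRs
#' additionally receives an A-run decoy (6-10 adenosines) at least 60 bp
#' from any true site, emulating internal-priming targets.
#'
#' Baseline usage fractions (smoothed Dirichlet) and an expression level
#' (log-normal FPKM) are drawn per gene and stored identically for both
#' conditions; [make_senescence_scenario()] perturbs them.
#'
#' @param n_genes number of genes (>= 1).
#' @param seed RNG seed; the same seed reproduces byte-identical files.
#' @param out_dir directory receiving `genome.fa` and `annotation.gtf`.
#' @param utr_len_range,cds_len,intergenic_bp gene geometry (bp).
#' @param n_sites_range range of tandem pA sites per gene; genes with short
#'   UTRs may receive fewer than drawn.
#' @param decoy_fraction fraction of genes given an A-run decoy.
#' @param chrom_name chromosome name.
#' @param fpkm_meanlog,fpkm_sdlog log-normal expression parameters.
#' @return an `apa_truth` list: `genes` (geometry plus `fpkm_a`/`fpkm_b`),
#'   `sites` (`gene_id`, `site_index`, `distance`, `pos`, `f_a`, `f_b`),
#'   `decoys` (`gene_id`, `distance`, `anchor_pos`, `run_length`), `chrom`,
#'   `chrom_len`, `seed`, and `paths` (fasta, gtf).
#' @export
simulate_genome_and_annotation <- function(n_genes, seed = 1L,
    out_dir = tempfile("utrshift_sim_"),
    utr_len_range = c(500, 3000), cds_len = 300L, intergenic_bp = 500L,
    n_sites_range = c(1L, 3L), decoy_fraction = 0.3,
    chrom_name = "chrSim", fpkm_meanlog = log(20), fpkm_sdlog = 1) {
  stopifnot(n_genes >= 1, cds_len >= 9, utr_len_range[1] >= 300)
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  genes <- vector("list", n_genes)
  sites <- vector("list", n_genes)
  decoys <- vector("list", n_genes)
  cursor <- intergenic_bp + 1L

  for (g in seq_len(n_genes)) {
    gid <- sprintf("g%05d", g)
    strand <- sample(c("+", "-"), 1)
    utr_len <- round(stats::runif(1, utr_len_range[1], utr_len_range[2]))
    ks <- seq(n_sites_range[1], n_sites_range[2])
    k_drawn <- if (length(ks) == 1L) ks else sample(ks, 1)
    # site distances: first site 100-250 bp after the stop, then gaps of
    # 150-400 bp, keeping an 80 bp downstream margin inside the UTR
    max_d <- utr_len - 80
    d <- integer(0)
    cur <- round(stats::runif(1, 100, 250))
    while (length(d) < k_drawn && cur <= max_d) {
      d <- c(d, cur)
      cur <- cur + round(stats::runif(1, 150, 400))
    }
    k <- length(d)
    f <- if (k == 1) 1 else {
      x <- .rdirichlet1(rep(4, k))
      (x + 0.15) / (1 + 0.15 * k)  # keep every site's usage bounded away from 0
    }
    e0 <- stats::rlnorm(1, fpkm_meanlog, fpkm_sdlog)
    gene_len <- cds_len + utr_len
    gene_start <- cursor
    gene_end <- cursor + gene_len - 1L
    if (strand == "+") {
      stop_pos <- gene_start + cds_len - 1L
      site_pos <- stop_pos + d
    } else {
      stop_pos <- gene_start + utr_len
      site_pos <- stop_pos - d
    }
    # decoy: A-run at >= 60 bp from every true site, inside the UTR
    dec <- NULL
    if (stats::runif(1) < decoy_fraction) {
      run_len <- sample(6:10, 1)
      for (try in 1:20) {
        dd <- round(stats::runif(1, 60, utr_len - 40))
        if (all(abs(dd - d) >= 60)) {
          anchor <- if (strand == "+") stop_pos + dd - 1L else stop_pos - dd + 1L
          dec <- data.frame(gene_id = gid, distance = dd,
                            anchor_pos = anchor, run_length = run_len,
                            stringsAsFactors = FALSE)
          break
        }
      }
    }
    genes[[g]] <- data.frame(
      gene_id = gid, chrom = chrom_name, strand = strand,
      gene_start = gene_start, gene_end = gene_end, stop_pos = stop_pos,
      cds_len = cds_len, utr_len = utr_len, n_sites = k,
      fpkm_a = e0, fpkm_b = e0, stringsAsFactors = FALSE)
    sites[[g]] <- data.frame(
      gene_id = gid, site_index = seq_len(k), distance = d, pos = site_pos,
      f_a = f, f_b = f, stringsAsFactors = FALSE)
    decoys[[g]] <- dec
    cursor <- gene_end + intergenic_bp + 1L
  }
  genes <- do.call(rbind, genes)
  sites <- do.call(rbind, sites)
  decoys <- do.call(rbind, decoys)
  if (is.null(decoys)) {
    decoys <- data.frame(gene_id = character(0), distance = integer(0),
                         anchor_pos = integer(0), run_length = integer(0),
                         stringsAsFactors = FALSE)
  }
  chrom_len <- cursor + intergenic_bp

  # chromosome sequence with planted motifs
  base <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  gu <- function(n) sample(c("G", "T", "C"), n, replace = TRUE,
                           prob = c(0.35, 0.45, 0.20))
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i]
    strand <- genes$strand[match(sites$gene_id[i], genes$gene_id)]
    if (strand == "+") {
      base[(p - 21):(p - 16)] <- c("A", "A", "T", "A", "A", "A")
      base[(p + 1):(p + 12)] <- gu(12)
    } else {
      base[(p + 16):(p + 21)] <- c("T", "T", "T", "A", "T", "T")
      # sense U/G-rich letters complement to {C, A, G} on the plus strand
      base[(p - 12):(p - 1)] <- rev(chartr("GTC", "CAG", gu(12)))
    }
  }
  if (nrow(decoys)) {
    for (i in seq_len(nrow(decoys))) {
      strand <- genes$strand[match(decoys$gene_id[i], genes$gene_id)]
      rl <- decoys$run_length[i]
      a <- decoys$anchor_pos[i]
      if (strand == "+") {
        base[(a + 1):(a + rl)] <- "A"
      } else {
        base[(a - rl):(a - 1)] <- "T"
      }
    }
  }
  dna <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(dna) <- chrom_name
  fasta <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(dna, fasta)
  gtf <- file.path(out_dir, "annotation.gtf")
  .write_gtf(genes, gtf)

  structure(list(genes = genes, sites = sites, decoys = decoys,
                 chrom = chrom_name, chrom_len = chrom_len, seed = seed,
                 paths = list(fasta = fasta, gtf = gtf, out_dir = out_dir)),
            class = "apa_truth")
}

# Ensembl-dialect GTF for the simulated single-exon genes; CDS excludes the
# stop codon, which is written as its own feature
.write_gtf <- function(genes, path) {
  lines <- character(0)
  attr_of <- function(gid, tx = NULL) {
    if (is.null(tx)) sprintf('gene_id "%s";', gid)
    else sprintf('gene_id "%s"; transcript_id "%s";', gid, tx)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx <- paste0(g$gene_id, ".t1")
    if (g$strand == "+") {
      cds <- c(g$gene_start, g$stop_pos - 3L)
      stopc <- c(g$stop_pos - 2L, g$stop_pos)
    } else {
      cds <- c(g$stop_pos + 3L, g$gene_end)
      stopc <- c(g$stop_pos, g$stop_pos + 2L)
    }
    feat <- function(type, s, e, at) {
      sprintf("%s\tutrshift_sim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$chrom, type, s, e, g$strand,
              if (type %in% c("CDS", "stop_codon")) "0" else ".", at)
    }
    lines <- c(lines,
               feat("gene", g$gene_start, g$gene_end, attr_of(g$gene_id)),
               feat("transcript", g$gene_start, g$gene_end,
                    attr_of(g$gene_id, tx)),
               feat("exon", g$gene_start, g$gene_end, attr_of(g$gene_id, tx)),
               feat("CDS", cds[1], cds[2], attr_of(g$gene_id, tx)),
               feat("stop_codon", stopc[1], stopc[2], attr_of(g$gene_id, tx)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' True TSI per gene from simulator ground truth
#'
#' @param truth an `apa_truth` object.
#' @return data frame `gene_id`, `tsi_true` (`NA` for single-site genes).
#' @export
true_tsi <- function(truth) {
  sp <- split(truth$sites, truth$sites$gene_id)
  out <- data.frame(gene_id = names(sp),
                    tsi_true = vapply(sp, function(s) {
                      if (nrow(s) < 2) return(NA_real_)
                      (sum(s$distance * s$f_b) - sum(s$distance * s$f_a)) /
                        (max(s$distance) - min(s$distance))
                    }, numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate PA-seq tags for one condition
#'
#' Per gene, site totals are drawn Dirichlet-multinomial around the true
#' usage fractions (`rho = 0` recovers the plain multinomial; `rho` is the
#' usual DM overdispersion/intraclass correlation). Tag positions are
#' jittered around each true site with a discretized Gaussian (sd
#' `jitter_sd`, truncated at `jitter_max` bp) mimicking cleavage
#' heterogeneity. Genes carrying a decoy receive Poisson
#' (`decoy_rate * depth_per_gene`) mispriming tags tightly clustered (sd 1,
#' truncated at 2 bp) at the base immediately upstream of the A run, where
#' oligo(dT) mispriming anchors.
#'
#' @param truth an `apa_truth` object.
#' @param condition `"A"` or `"B"` (selects `f_a`/`f_b` truth fractions).
#' @param depth_per_gene expected tags per gene.
#' @param rho Dirichlet-multinomial overdispersion (0 = multinomial).
#' @param decoy_rate decoy tag rate as a fraction of gene depth.
#' @param jitter_sd,jitter_max cleavage-site jitter parameters (bp).
#' @param sample_id track label; defaults to `sim_<condition>`.
#' @param seed RNG seed.
#' @param out_bed optional path; when given the track is also written as
#'   BED6.
#' @return a `tag_track` data frame (see [read_tags()]).
#' @export
simulate_pa_tags <- function(truth, condition = c("A", "B"),
                             depth_per_gene = 200, rho = 0,
                             decoy_rate = 0.05, jitter_sd = 4,
                             jitter_max = 10L, sample_id = NULL,
                             seed = 1L, out_bed = NULL) {
  condition <- match.arg(condition)
  stopifnot(depth_per_gene >= 1, rho >= 0, rho < 1)
  set.seed(seed)
  fcol <- if (condition == "A") "f_a" else "f_b"
  sample_id <- sample_id %||% paste0("sim_", condition)
  sp <- split(truth$sites, truth$sites$gene_id)
  dec <- truth$decoys
  genes <- truth$genes

  acc_pos <- vector("list", length(sp) * 2L)
  acc_strand <- vector("list", length(sp) * 2L)
  ai <- 0L
  for (gid in names(sp)) {
    s <- sp[[gid]]
    strand <- genes$strand[match(gid, genes$gene_id)]
    f <- s[[fcol]]
    p <- if (rho > 0) .rdirichlet1(f * (1 - rho) / rho) else f
    n <- as.vector(stats::rmultinom(1, depth_per_gene, p))
    site_of_tag <- rep(seq_along(n), times = n)
    if (length(site_of_tag)) {
      off <- round(stats::rnorm(length(site_of_tag), 0, jitter_sd))
      off <- pmax(-jitter_max, pmin(jitter_max, off))
      ai <- ai + 1L
      acc_pos[[ai]] <- s$pos[site_of_tag] + off
      acc_strand[[ai]] <- rep(strand, length(site_of_tag))
    }
    di <- dec[dec$gene_id == gid, , drop = FALSE]
    if (nrow(di) && decoy_rate > 0) {
      nd <- stats::rpois(1, decoy_rate * depth_per_gene)
      if (nd > 0) {
        off <- pmax(-2L, pmin(2L, round(stats::rnorm(nd, 0, 1))))
        sgn <- if (strand == "+") 1L else -1L
        ai <- ai + 1L
        acc_pos[[ai]] <- di$anchor_pos[1] + sgn * off
        acc_strand[[ai]] <- rep(strand, nd)
      }
    }
  }
  pos_all <- unlist(acc_pos[seq_len(ai)])
  strand_all <- unlist(acc_strand[seq_len(ai)])
  key <- paste(strand_all, sprintf("%012d", pos_all), sep = "\r")
  tot <- rowsum(rep(1, length(key)), key)
  parts <- do.call(rbind, strsplit(rownames(tot), "\r", fixed = TRUE))
  track <- data.frame(chrom = truth$chrom, pos = as.integer(parts[, 2]),
                      strand = parts[, 1], count = as.integer(tot[, 1]),
                      stringsAsFactors = FALSE)
  track <- track[order(track$chrom, track$pos, track$strand), ]
  rownames(track) <- NULL
  track <- structure(track, class = c("tag_track", "data.frame"),
                     sample_id = sample_id)
  if (!is.null(out_bed)) write_tags(track, out_bed)
  track
}

#' Simulate RNA-seq coverage and an expression table for one condition
#'
#' Coverage over a gene's 3' UTR falls stepwise after each tandem pA site:
#' between site j and site j+1 the per-base Poisson mean is proportional to
#' the summed usage of all sites distal to j (every transcript covers the
#' cUTR; only distal-isoform transcripts cover the aUTR). Per-base depths
#' are scaled by the gene's expression relative to the simulation mean. The
#' expression table reports the true FPKM with multiplicative log-normal
#' noise.
#'
#' @param truth an `apa_truth` object.
#' @param condition `"A"` or `"B"`.
#' @param mean_coverage average cUTR coverage (reads/bp) at mean expression.
#' @param expr_noise_sd log-normal sd of the reported FPKM.
#' @param seed RNG seed.
#' @param out_bedgraph,out_expr optional output paths (bedGraph / TSV).
#' @return list: `coverage` ([GenomicRanges::GRanges] with `score`),
#'   `expression` (data frame `gene_id`, `fpkm`).
#' @export
simulate_rnaseq <- function(truth, condition = c("A", "B"),
                            mean_coverage = 100, expr_noise_sd = 0.2,
                            seed = 1L, out_bedgraph = NULL, out_expr = NULL) {
  condition <- match.arg(condition)
  stopifnot(mean_coverage > 0)
  set.seed(seed)
  fcol <- if (condition == "A") "f_a" else "f_b"
  ecol <- if (condition == "A") "fpkm_a" else "fpkm_b"
  genes <- truth$genes
  e <- genes[[ecol]]
  scale <- e / mean(e)
  sp <- split(truth$sites, truth$sites$gene_id)

  seg_start <- integer(0); seg_end <- integer(0); seg_val <- numeric(0)
  for (gi in seq_len(nrow(genes))) {
    gid <- genes$gene_id[gi]
    s <- sp[[gid]]
    if (is.null(s) || !nrow(s)) next
    s <- s[order(s$distance), ]
    f <- s[[fcol]]
    k <- nrow(s)
    bounds <- c(0L, s$distance)           # sense distances of segment edges
    lam_seg <- mean_coverage * scale[gi] *
      vapply(seq_len(k), function(j) sum(f[j:k]), numeric(1))
    # per-base Poisson draw over sense positions 1..d_k, then run-length
    # compress in genomic order
    dk <- s$distance[k]
    lam <- rep(lam_seg, times = diff(bounds))
    depth <- stats::rpois(dk, lam)
    if (genes$strand[gi] == "+") {
      gpos <- genes$stop_pos[gi] + seq_len(dk)
    } else {
      gpos <- genes$stop_pos[gi] - seq_len(dk)
      depth <- rev(depth)
      gpos <- rev(gpos)
    }
    r <- rle(depth)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    keep <- r$values > 0
    seg_start <- c(seg_start, gpos[starts[keep]])
    seg_end <- c(seg_end, gpos[ends[keep]])
    seg_val <- c(seg_val, r$values[keep])
  }
  cov <- GenomicRanges::GRanges(truth$chrom,
                                IRanges::IRanges(seg_start, seg_end),
                                score = seg_val)
  cov <- GenomicRanges::sort(cov)
  expr <- data.frame(gene_id = genes$gene_id,
                     fpkm = e * exp(stats::rnorm(nrow(genes), 0,
                                                 expr_noise_sd)),
                     stringsAsFactors = FALSE)
  if (!is.null(out_bedgraph)) {
    rtracklayer::export(cov, out_bedgraph, format = "bedGraph")
  }
  if (!is.null(out_expr)) {
    write.table(expr, out_expr, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(coverage = cov, expression = expr)
}

#' Build a full two-condition senescence-style scenario
#'
#' Generates a complete dataset pair (condition A = early / proliferating,
#' condition B = senescent): genome, annotation, replicated PA-seq tag
#' tracks per condition, RNA-seq coverage, and an expression table. A
#' designated fraction of multi-site genes shifts its distal usage up by
#' `shift` in condition B (3' UTR lengthening); for those genes the
#' condition-A distal fraction is drawn from U(0.15, 0.45) and the distal
#' gain is taken entirely from the proximal site, so the full shift always
#' applies and the true TSI equals `shift` exactly. Each lengthened gene is down-regulated in B with
#' probability `coupling` (expression ratio drawn from
#' `1/down_fc_range`); all remaining genes keep their expression up to mild
#' log-normal noise.
#'
#' @param n_genes number of genes.
#' @param frac_lengthened fraction of genes given a true lengthening shift.
#' @param shift increase in distal usage fraction in condition B.
#' @param coupling probability that a lengthened gene is down-regulated.
#' @param seed RNG seed (sub-generators use small fixed offsets from it).
#' @param depth_per_gene total PA-seq depth per gene and condition, split
#'   evenly over `n_replicates` tracks.
#' @param rho Dirichlet-multinomial overdispersion of tag counts.
#' @param mean_coverage RNA-seq coverage scale (reads/bp).
#' @param n_replicates tag tracks per condition.
#' @param down_fc_range fold-change range for coupled down-regulation.
#' @param out_dir output directory for all files.
#' @param ... forwarded to [simulate_genome_and_annotation()].
#' @return the updated `apa_truth` object, with `scenario` (ids of shifted
#'   and coupled genes, parameters) and `paths` extended by `tags_a`,
#'   `tags_b` (named vectors), `coverage_a`, `coverage_b`, `expression`.
#' @export
make_senescence_scenario <- function(n_genes, frac_lengthened = 0.2,
                                     shift = 0.3, coupling = 0.7, seed = 1L,
                                     depth_per_gene = 200, rho = 0,
                                     mean_coverage = 100, n_replicates = 2,
                                     down_fc_range = c(1.6, 2.5),
                                     out_dir = tempfile("utrshift_scenario_"),
                                     ...) {
  stopifnot(frac_lengthened >= 0, frac_lengthened <= 1, shift >= 0,
            coupling >= 0, coupling <= 1)
  truth <- simulate_genome_and_annotation(n_genes, seed = seed,
                                          out_dir = out_dir, ...)
  set.seed(seed + 1L)
  genes <- truth$genes
  sites <- truth$sites
  multi <- genes$gene_id[genes$n_sites >= 2]
  n_shift <- round(frac_lengthened * n_genes)
  if (length(multi) < n_shift) {
    stop("synthetic_data: not enough multi-site genes (",
         length(multi), ") for frac_lengthened = ", frac_lengthened,
         call. = FALSE)
  }
  shifted <- if (n_shift > 0) sort(sample(multi, n_shift)) else character(0)

  if (shift > 0.45) {
    stop("synthetic_data: shift > 0.45 cannot be absorbed by the proximal ",
         "site under the baseline usage draw", call. = FALSE)
  }
  for (gid in shifted) {
    i <- which(sites$gene_id == gid)
    k <- length(i)
    # redraw usage so the full shift applies: the distal gain is taken
    # entirely from the proximal site, making the true TSI exactly `shift`
    fd_a <- stats::runif(1, 0.15, 0.45)
    mid <- if (k > 2) rep(0.1 / (k - 2), k - 2) else numeric(0)
    f_a <- c(1 - fd_a - sum(mid), mid, fd_a)
    f_b <- f_a
    f_b[1] <- f_b[1] - shift
    f_b[k] <- f_b[k] + shift
    sites$f_a[i] <- f_a
    sites$f_b[i] <- f_b
  }

  coupled <- shifted[stats::runif(length(shifted)) < coupling]
  ratio <- rep(NA_real_, nrow(genes))
  down_i <- match(coupled, genes$gene_id)
  genes$fpkm_b <- genes$fpkm_a * exp(stats::rnorm(nrow(genes), 0, 0.1))
  if (length(down_i)) {
    genes$fpkm_b[down_i] <- genes$fpkm_a[down_i] /
      stats::runif(length(down_i), down_fc_range[1], down_fc_range[2])
  }
  truth$genes <- genes
  truth$sites <- sites

  rep_depth <- max(1L, round(depth_per_gene / n_replicates))
  tags_a <- character(0); tags_b <- character(0)
  idx <- 0L
  for (cond in c("A", "B")) {
    for (r in seq_len(n_replicates)) {
      idx <- idx + 1L
      sid <- paste0(cond, r)
      bed <- file.path(out_dir, paste0("tags_", sid, ".bed"))
      simulate_pa_tags(truth, cond, depth_per_gene = rep_depth, rho = rho,
                       sample_id = sid, seed = seed + 100L + idx,
                       out_bed = bed)
      if (cond == "A") tags_a[sid] <- bed else tags_b[sid] <- bed
    }
  }
  cov_a <- file.path(out_dir, "coverage_A.bedGraph")
  cov_b <- file.path(out_dir, "coverage_B.bedGraph")
  rs_a <- simulate_rnaseq(truth, "A", mean_coverage = mean_coverage,
                          seed = seed + 200L, out_bedgraph = cov_a)
  rs_b <- simulate_rnaseq(truth, "B", mean_coverage = mean_coverage,
                          seed = seed + 201L, out_bedgraph = cov_b)
  expr <- data.frame(gene_id = rs_a$expression$gene_id,
                     fpkm_a = rs_a$expression$fpkm,
                     fpkm_b = rs_b$expression$fpkm,
                     stringsAsFactors = FALSE)
  expr_path <- file.path(out_dir, "expression.tsv")
  write.table(expr, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(out_dir, "truth_sites.tsv")
  write.table(truth$sites, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  truth$scenario <- list(shifted = shifted, coupled = coupled,
                         shift = shift, coupling = coupling,
                         frac_lengthened = frac_lengthened,
                         depth_per_gene = depth_per_gene, rho = rho,
                         n_replicates = n_replicates)
  truth$paths <- c(truth$paths,
                   list(tags_a = tags_a, tags_b = tags_b,
                        coverage_a = cov_a, coverage_b = cov_b,
                        expression = expr_path, truth_sites = truth_path))
  truth
}
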