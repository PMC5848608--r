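# End-to-end orchestration: callpeaks -> metrics -> difftsi -> trend (+ RUD),
# driven by a single serializable configuration. All analysis stages are
# deterministic; randomness lives only in the simulator.

#' Build a pipeline run configuration
#'
#' Collects input paths and every tunable threshold into a single object
#' that serializes to/from YAML, so a run can be reproduced from its
#' recorded configuration alone.
#'
#' @param gtf,fasta annotation GTF and genome FASTA paths.
#' @param tags_a,tags_b named character vectors of BED6 tag paths per
#'   condition (names become sample ids; unnamed paths get basenames).
#' @param out_dir output directory.
#' @param coverage_a,coverage_b optional bedGraph coverage per condition
#'   (enables the RUD table).
#' @param expression optional TSV `gene_id`, `fpkm_a`, `fpkm_b` (enables
#'   the expression-coupling trend test).
#' @param window_bp,min_count clustering parameters.
#' @param a_run,a_count,priming_window_bp internal-priming rule.
#' @param pas_search_bp PAS search window.
#' @param max_utr3_extension pA search space extension beyond annotation.
#' @param fdr,fc,min_fpkm differential-usage and expression thresholds.
#' @param cutoffs relative-change grid for lengthened/shortened counting.
#' @return a `utrshift_config` list.
#' @export
pipeline_config <- function(gtf, fasta, tags_a, tags_b, out_dir,
                            coverage_a = NULL, coverage_b = NULL,
                            expression = NULL,
                            window_bp = 24, min_count = 3,
                            a_run = 6, a_count = 7, priming_window_bp = 10,
                            pas_search_bp = 40, max_utr3_extension = 1000,
                            fdr = 0.05, fc = 1.5, min_fpkm = 1,
                            cutoffs = c(0.05, 0.10, 0.20)) {
  name_paths <- function(x) {
    x <- unlist(x)  # tolerate the YAML list form
    if (is.null(names(x)) || any(names(x) == "")) {
      names(x) <- tools::file_path_sans_ext(basename(x))
    }
    x
  }
  structure(list(gtf = gtf, fasta = fasta,
                 tags_a = name_paths(tags_a), tags_b = name_paths(tags_b),
                 coverage_a = coverage_a, coverage_b = coverage_b,
                 expression = expression, out_dir = out_dir,
                 window_bp = window_bp, min_count = min_count,
                 a_run = a_run, a_count = a_count,
                 priming_window_bp = priming_window_bp,
                 pas_search_bp = pas_search_bp,
                 max_utr3_extension = max_utr3_extension,
                 fdr = fdr, fc = fc, min_fpkm = min_fpkm,
                 cutoffs = cutoffs),
            class = "utrshift_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return `read_config` returns a `utrshift_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}

#' @rdname read_config
#' @param config a `utrshift_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  # named vectors serialize as YAML maps so sample ids survive the round trip
  x$tags_a <- as.list(x$tags_a)
  x$tags_b <- as.list(x$tags_b)
  yaml::write_yaml(x, path)
  invisible(path)
}

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}

#' Run the full APA pipeline
#'
#' Executes annotation parsing, tag clustering, internal-priming filtering,
#' PAS annotation, gene assignment, effective 3' UTR lengths with Z-score
#' profiles, TSI differential usage with BH-FDR, length-change counting at
#' a cut-off grid, the expression-coupling binomial trend test (when an
#' expression table is configured) and the RUD table (when coverage is
#' configured). All tabular outputs are written as TSV (missing values as
#' the literal `NA`), clusters additionally as BED6, and a YAML report with
#' the exact configuration, its hash and per-stage gene counts.
#'
#' Any stage failure aborts with a message naming the stage.
#'
#' @param config a `utrshift_config` (or path to its YAML serialization).
#' @return a `utrshift_report` list (also serialized to
#'   `<out_dir>/report.yaml`): configuration, config hash, stage counts, QC
#'   summary, lengthened/shortened counts, trend results, output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "utrshift_config"))
  logs <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    logs <<- c(logs, msg)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!file.exists(config$gtf)) {
    stop("annotation_io: GTF not found: ", config$gtf, call. = FALSE)
  }
  for (p in c(config$tags_a, config$tags_b)) {
    if (!file.exists(p)) {
      stop("annotation_io: tag BED not found: ", p, call. = FALSE)
    }
  }
  if (is.null(config$fasta) || !file.exists(config$fasta)) {
    stop("pa_calling: internal-priming filter requires the genome FASTA ",
         "(missing: ", config$fasta %||% "<unset>", ")", call. = FALSE)
  }

  say("stage annotation_io: reading gene models from ", config$gtf)
  gm <- read_gene_models(config$gtf, config$max_utr3_extension)
  say("  ", nrow(gm), " gene model(s); ", length(attr(gm, "skipped")),
      " gene(s) skipped (no CDS)")

  tracks <- c(
    Map(read_tags, config$tags_a, names(config$tags_a)),
    Map(read_tags, config$tags_b, names(config$tags_b)))
  samples_a <- names(config$tags_a)
  samples_b <- names(config$tags_b)
  total_tags <- sum(vapply(tracks, function(t) sum(t$count), numeric(1)))
  say("stage pa_calling: clustering ", total_tags, " tags from ",
      length(tracks), " track(s)")
  clusters <- cluster_tags(tracks, window_bp = config$window_bp,
                           min_count = config$min_count)
  genome <- read_genome(config$fasta)
  clusters <- flag_internal_priming(clusters, genome,
                                    a_run = config$a_run,
                                    a_count = config$a_count,
                                    window_bp = config$priming_window_bp)
  clusters <- annotate_pas(clusters, genome,
                           search_bp = config$pas_search_bp)
  say("  ", nrow(clusters), " cluster(s); ",
      sum(clusters$internal_priming), " flagged internal priming; ",
      attr(clusters, "dropped_clusters"), " below min_count")
  qc <- if (nrow(clusters)) qc_summary(clusters, gm) else NULL

  profiles <- assign_clusters(clusters, gm)
  n_genes_prof <- length(unique(profiles$gene_id))
  say("stage apa_metrics: ", n_genes_prof, " gene(s) with assigned sites")
  L <- effective_utr_lengths(profiles)
  Z <- zscore_profile(L)
  l_a <- .effective_utr_length_pooled(profiles, samples_a)
  l_b <- .effective_utr_length_pooled(profiles, samples_b)
  len_changes <- count_length_changes(l_a, l_b[names(l_a)],
                                      cutoffs = config$cutoffs)

  say("stage differential_apa: TSI testing (",
      paste(samples_a, collapse = ","), " vs ",
      paste(samples_b, collapse = ","), ")")
  tsi_tab <- tsi_table(profiles, samples_a, samples_b,
                       fdr_cut = config$fdr)
  n_len <- sum(tsi_tab$call == "lengthened", na.rm = TRUE)
  n_sho <- sum(tsi_tab$call == "shortened", na.rm = TRUE)
  say("  ", nrow(tsi_tab), " gene(s) tested; ", n_len, " lengthened, ",
      n_sho, " shortened at FDR <= ", config$fdr)

  trend_lengthened <- NULL
  trend_shortened <- NULL
  expr_class <- NULL
  if (!is.null(config$expression)) {
    if (!file.exists(config$expression)) {
      stop("differential_apa: expression table not found: ",
           config$expression, call. = FALSE)
    }
    expr <- read.delim(config$expression, stringsAsFactors = FALSE)
    cls <- expression_filter(expr$fpkm_a, expr$fpkm_b,
                             fc = config$fc, min_fpkm = config$min_fpkm)
    expr_class <- data.frame(gene_id = expr$gene_id, class = cls,
                             stringsAsFactors = FALSE)
    for (side in c("lengthened", "shortened")) {
      ids <- tsi_tab$gene_id[!is.na(tsi_tab$call) & tsi_tab$call == side]
      sub <- cls[match(ids, expr$gene_id)]
      nd <- sum(sub == "down", na.rm = TRUE)
      nu <- sum(sub == "up", na.rm = TRUE)
      tr <- if (nd + nu >= 1) binomial_trend_test(nd, nu) else NULL
      if (side == "lengthened") trend_lengthened <- tr else
        trend_shortened <- tr
      say("  trend among ", side, " genes: ", nd, " down vs ", nu, " up",
          if (!is.null(tr)) paste0(" (binomial p = ",
                                   signif(tr$p_value, 3), ")") else
            " (no genes past expression filters)")
    }
  }

  rud_a <- rud_b <- NULL
  if (!is.null(config$coverage_a)) {
    say("stage apa_metrics: RUD from RNA-seq coverage")
    rud_a <- rud_table(profiles, gm, read_coverage(config$coverage_a))
    if (!is.null(config$coverage_b)) {
      rud_b <- rud_table(profiles, gm, read_coverage(config$coverage_b))
    }
  }

  out <- function(f) file.path(config$out_dir, f)
  paths <- list(clusters_tsv = out("clusters.tsv"),
                clusters_bed = out("clusters.bed"),
                leff = out("effective_utr_length.tsv"),
                zscore = out("zscore.tsv"),
                tsi = out("tsi.tsv"),
                length_changes = out("length_changes.tsv"),
                report = out("report.yaml"),
                log = out("run.log"))
  write_clusters(clusters, paths$clusters_tsv, paths$clusters_bed)
  .write_tsv(data.frame(gene_id = rownames(L), L, check.names = FALSE),
             paths$leff)
  .write_tsv(data.frame(gene_id = rownames(Z), Z, check.names = FALSE),
             paths$zscore)
  .write_tsv(tsi_tab, paths$tsi)
  .write_tsv(len_changes, paths$length_changes)
  if (!is.null(rud_a)) {
    paths$rud_a <- .write_tsv(rud_a, out("rud_A.tsv"))
  }
  if (!is.null(rud_b)) {
    paths$rud_b <- .write_tsv(rud_b, out("rud_B.tsv"))
  }

  stage_counts <- c(genes_annotated = nrow(gm),
                    genes_with_sites = n_genes_prof,
                    genes_tested = nrow(tsi_tab),
                    genes_called = n_len + n_sho)
  report <- structure(list(
    package_version = as.character(utils::packageVersion("utrshift")),
    config = unclass(config),
    config_hash = .config_hash(config),
    stage_counts = as.list(stage_counts),
    total_tags = total_tags,
    qc = if (!is.null(qc)) unclass(qc) else NULL,
    n_lengthened = n_len, n_shortened = n_sho,
    length_changes = len_changes,
    trend_lengthened = if (!is.null(trend_lengthened))
      unclass(trend_lengthened) else NULL,
    trend_shortened = if (!is.null(trend_shortened))
      unclass(trend_shortened) else NULL,
    paths = paths), class = "utrshift_report")

  yaml::write_yaml(lapply(report, function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }), paths$report)
  writeLines(c(paste0("utrshift ", report$package_version,
                      " run at ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               paste0("config hash: ", report$config_hash), logs),
             paths$log)
  report
}

#' @export
print.utrshift_report <- function(x, ...) {
  cat("utrshift pipeline report\n")
  cat("  genes: ", x$stage_counts$genes_annotated, " annotated, ",
      x$stage_counts$genes_with_sites, " with sites, ",
      x$stage_counts$genes_tested, " tested\n", sep = "")
  cat("  calls: ", x$n_lengthened, " lengthened, ", x$n_shortened,
      " shortened\n", sep = "")
  if (!is.null(x$trend_lengthened)) {
    cat(sprintf("  lengthened-gene expression trend: %d down vs %d up, p = %.3g\n",
                x$trend_lengthened$n_down, x$trend_lengthened$n_up,
                x$trend_lengthened$p_value))
  }
  cat("  outputs in ", dirname(x$paths$report), "\n", sep = "")
  invisible(x)
}
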