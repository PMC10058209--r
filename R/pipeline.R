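#' Analysis configuration
#'
#' Collects the fixed thresholds of the stratification pipeline so every run
#' can echo them into its log and report headers.
#'
#' @param p_threshold DEG p-value cutoff (strict); default 0.05.
#' @param fc_threshold Absolute linear-scale fold-change cutoff (strict);
#'   default 2.
#' @param var_rule Cumulative explained-variance rule for the PCA; default
#'   0.75.
#' @param offset Background-correction offset (linear scale); default 50.
#' @param percentile Anchor percentile of the shift normalization; default
#'   75.
#' @param distance_pcs Components used for centroid distances: `2` or
#'   `"retained"`.
#' @param linear_scale Set `TRUE` when the input matrix holds linear-scale
#'   raw intensities that still need background correction and log2
#'   transformation.
#' @param seed Seed recorded with the run (and used when the cohort is
#'   simulated on the fly).
#' @return A list of class `run_config`.
#' @export
run_config <- function(p_threshold = 0.05, fc_threshold = 2, var_rule = 0.75,
                       offset = 50, percentile = 75, distance_pcs = 2,
                       linear_scale = FALSE, seed = 1L) {
  cfg <- list(
    p_threshold = p_threshold, fc_threshold = fc_threshold,
    var_rule = var_rule, offset = offset, percentile = percentile,
    distance_pcs = distance_pcs, linear_scale = linear_scale,
    seed = as.integer(seed)
  )
  structure(cfg, class = "run_config")
}

# Short deterministic hash of a config, for report headers.
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2^28
  sprintf("%07x", h)
}

#' Run the full stratification analysis
#'
#' Executes the end-to-end flow: normalization by both routes, both DEG
#' pipelines on the reference group, signature-PCA nearest-centroid
#' classification of the held-out test group, accuracy-based pipeline
#' selection, AK stratification with the winning pipeline, and downstream
#' characterization (AK_L-vs-AK_NL differential analysis, SCC-signature
#' overlap, hierarchical clustering, grade composition).
#'
#' The two competing routes are:
#' \describe{
#'   \item{`paired`}{quantile normalization, per-probe paired linear model
#'     (diagnosis + patient), Benjamini-Hochberg adjusted p.}
#'   \item{`ttest`}{75th-percentile-shift normalization, two-group pooled
#'     t test, Bonferroni adjusted p.}
#' }
#' Both select DEGs at adjusted p < `p_threshold` and |FC| >
#' `fc_threshold`. AK truth labels and histological grades are never read
#' during classification; grades are joined into reports only.
#'
#' @param expr Expression matrix (probes x samples, log2 unless
#'   `config$linear_scale`); `NULL` to simulate a cohort from
#'   `cohort` on the fly.
#' @param meta Sample metadata (see [generate_cohort()] for the columns);
#'   `NULL` when simulating.
#' @param config A [run_config()].
#' @param cohort A [cohort_params()] used when `expr` is `NULL`.
#' @return A list of class `ak_analysis` with elements `signatures`,
#'   `deg_tables`, `classifiers`, `test_records`, `accuracy`, `selection`,
#'   `stratification`, `downstream`, `log`, `config`, and (when simulated)
#'   `truth`.
#' @export
run_full_analysis <- function(expr = NULL, meta = NULL,
                              config = run_config(),
                              cohort = cohort_params(seed = config$seed)) {
  log_lines <- character()
  note <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }
  fail <- function(stage, msg) {
    stop(sprintf("stage '%s' failed: %s", stage, msg), call. = FALSE)
  }
  hash <- config_hash(config)
  note("config", sprintf("hash %s seed %d thresholds: p < %g, |FC| > %g, var rule %g",
                         hash, config$seed, config$p_threshold,
                         config$fc_threshold, config$var_rule))

  truth <- NULL
  if (is.null(expr)) {
    cohort_data <- generate_cohort(cohort)
    expr <- cohort_data$expr
    meta <- cohort_data$meta
    truth <- cohort_data$truth
    note("simulate", sprintf("synthetic cohort: %d probes x %d samples",
                             nrow(expr), ncol(expr)))
  }
  if (is.null(meta)) fail("input", "no sample metadata")
  meta <- match_labels(expr, meta)

  if (isTRUE(config$linear_scale)) {
    expr <- log2(background_correct(expr, offset = config$offset))
    note("background", sprintf("offset %g, log2-transformed", config$offset))
  }

  norm <- list(
    paired = quantile_normalize(expr),
    ttest = percentile_shift_normalize(expr, percentile = config$percentile)
  )
  note("normalize", sprintf("quantile + %gth-percentile shift on %d arrays",
                            config$percentile, ncol(expr)))

  ref <- meta$group_role == "reference"
  tst <- meta$group_role == "test"
  ak <- meta$group_role == "ak"
  ref_ids <- meta$sample_id[ref]
  if (sum(ref) < 4L) fail("degs", "too few reference samples")

  deg_tables <- list(
    paired = paired_linear_model(norm$paired[, ref_ids, drop = FALSE],
                                 meta[ref, ], adjust = "BH"),
    ttest = two_group_ttest(norm$ttest[, ref_ids, drop = FALSE],
                            meta[ref, ]$site_class, adjust = "bonferroni")
  )
  signatures <- list(
    paired = select_degs(deg_tables$paired, config$p_threshold,
                         config$fc_threshold, use_adjusted = TRUE,
                         contrast = "L_vs_NL", pipeline = "paired"),
    ttest = select_degs(deg_tables$ttest, config$p_threshold,
                        config$fc_threshold, use_adjusted = TRUE,
                        contrast = "L_vs_NL", pipeline = "ttest")
  )
  note("degs", sprintf("paired route: %d DEGs; ttest route: %d DEGs",
                       nrow(signatures$paired), nrow(signatures$ttest)))
  for (id in names(signatures)) {
    if (nrow(signatures[[id]]) == 0L) {
      fail("degs", sprintf("pipeline '%s' produced an empty signature", id))
    }
  }

  classifiers <- list()
  test_records <- list()
  accuracy <- list()
  if (sum(tst) < 1L) fail("classify", "no test samples")
  for (id in names(signatures)) {
    classifiers[[id]] <- fit_centroid_classifier(
      norm[[id]], meta, signatures[[id]],
      var_rule = config$var_rule, distance_pcs = config$distance_pcs
    )
    test_records[[id]] <- predict(
      classifiers[[id]], norm[[id]][, meta$sample_id[tst], drop = FALSE],
      labels = c("NL", "L")
    )
    accuracy[[id]] <- evaluate_accuracy(
      test_records[[id]],
      stats::setNames(meta$site_class[tst], meta$sample_id[tst])
    )
    note("classify", sprintf("%s route: accuracy %d/%d (%d%%)", id,
                             accuracy[[id]]$n - accuracy[[id]]$n_misclassified,
                             accuracy[[id]]$n, accuracy[[id]]$percent))
  }

  selection <- select_pipeline(accuracy, tie_breaker = "ttest")
  note("select", sprintf("selected '%s'%s", selection$selected,
                         if (selection$tie) " (tie, broken toward ttest)" else ""))
  sel <- selection$selected

  stratification <- NULL
  downstream <- list()
  if (sum(ak) == 0L) {
    note("stratify", "no AK samples; stratification skipped")
  } else {
    ak_ids <- meta$sample_id[ak]
    stratification <- stratify_ak(
      classifiers[[sel]], norm[[sel]][, ak_ids, drop = FALSE],
      grades = meta$histology[ak]
    )
    note("stratify", sprintf("%d AK_NL, %d AK_L",
                             stratification$counts["AK_NL"],
                             stratification$counts["AK_L"]))

    downstream$grade_composition <- grade_composition(stratification$records)

    ak_labels <- stratification$records$classification
    if (min(table(factor(ak_labels, levels = c("AK_NL", "AK_L")))) >= 2L) {
      prog <- deg_ak(norm[[sel]][, ak_ids, drop = FALSE], ak_labels,
                     p_threshold = config$p_threshold,
                     abs_fc_threshold = config$fc_threshold)
      downstream$progression <- prog
      downstream$overlap <- tryCatch(
        signature_overlap(prog$signature, signatures[[sel]]),
        error = function(e) NULL
      )
      note("characterize", sprintf(
        "%d progression DEGs; %s%% overlap with the SCC signature",
        nrow(prog$signature),
        if (is.null(downstream$overlap)) "NA" else
          sprintf("%.0f", downstream$overlap$percent)
      ))
    } else {
      note("characterize", "a subclass has < 2 samples; progression DEGs skipped")
    }
  }

  sig_ids <- signatures[[sel]]$probe_id
  downstream$reference_tree <- hcluster(
    norm[[sel]][sig_ids, ref_ids, drop = FALSE], axis = "samples"
  )
  note("cluster", sprintf("complete-linkage tree of %d reference samples on %d probes",
                          length(ref_ids), length(sig_ids)))

  structure(list(
    signatures = signatures, deg_tables = deg_tables,
    classifiers = classifiers, test_records = test_records,
    accuracy = accuracy, selection = selection,
    stratification = stratification, downstream = downstream,
    truth = truth, meta = meta, normalized = norm,
    log = log_lines, config = config, config_hash = hash
  ), class = "ak_analysis")
}

#' @export
print.ak_analysis <- function(x, ...) {
  cat("AK stratification analysis\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

#' Write the analysis bundle to a directory
#'
#' Emits the published-table-style AK classification report, both DEG
#' tables, the selected signature, the reference dendrogram (Newick) and
#' the run log. Every file header carries the config hash and seed.
#'
#' @param result An `ak_analysis` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("akstrat run config %s seed %d", result$config_hash,
                 result$config$seed)
  for (id in names(result$deg_tables)) {
    path <- file.path(dir, sprintf("deg_table_%s.tsv", id))
    con <- file(path, "wt"); writeLines(paste0("# ", hdr), con)
    utils::write.table(result$deg_tables[[id]], con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    close(con)
  }
  sel <- result$selection$selected
  sig_path <- file.path(dir, "signature_selected.tsv")
  con <- file(sig_path, "wt"); writeLines(paste0("# ", hdr), con)
  utils::write.table(as.data.frame(result$signatures[[sel]]), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(result$stratification)) {
    write_classification_tsv(result$stratification$records,
                             file.path(dir, "ak_classification.tsv"),
                             header = hdr)
  }
  writeLines(c(paste0("# ", hdr),
               dendrogram_newick(result$downstream$reference_tree)),
             file.path(dir, "reference_tree.nwk"))
  writeLines(c(paste0("# ", hdr), result$log), file.path(dir, "run_log.txt"))
  invisible(dir)
}
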