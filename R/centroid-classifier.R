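#' Fit a signature-PCA nearest-centroid classifier
#'
#' The core estimator of the package. The expression matrix is restricted to
#' a signature's probes; a PCA is computed with the reference samples as
#' observations and the signature probes as variables (probes centered by
#' their reference means, not variance-scaled); the NL and L reference
#' centroids are the mean coordinates of each reference group in the plane
#' of the first two principal components. New samples are then labeled by
#' the nearer centroid under Euclidean distance in that plane.
#'
#' The number of components retained for inspection, `k_retained`, is the
#' smallest k whose cumulative explained-variance ratio exceeds `var_rule`
#' (default 0.75). Distances, however, are always computed on the first two
#' components unless `distance_pcs = "retained"`.
#'
#' @param m Numeric matrix of log2 intensities (probes x samples) covering
#'   at least the signature probes and the reference samples.
#' @param meta Sample metadata (`sample_id`, `site_class`, `group_role`);
#'   rows with `group_role == "reference"` define the fitting set.
#' @param signature A `deg_signature` from [select_degs()], or a character
#'   vector of probe ids.
#' @param var_rule Cumulative explained-variance threshold (strict) fixing
#'   `k_retained`; default 0.75.
#' @param distance_pcs `2` (default) to measure centroid distances in the
#'   first-two-component plane, or `"retained"` to use all retained
#'   components.
#' @return An object of class `centroid_classifier` with elements
#'   `probe_ids`, `center` (per-probe reference means), `rotation`
#'   (orthonormal loadings, each column's largest-magnitude coefficient made
#'   positive), `var_ratio`, `k_retained`, `ref_scores`, `ref_labels`,
#'   `centroid_NL`, `centroid_L`, `distance_pcs` and `pipeline` (copied from
#'   the signature's provenance).
#' @seealso [predict.centroid_classifier()], [stratify_ak()],
#'   [evaluate_accuracy()]
#' @export
fit_centroid_classifier <- function(m, meta, signature, var_rule = 0.75,
                                    distance_pcs = 2) {
  probe_ids <- if (is.character(signature)) signature else signature$probe_id
  if (length(probe_ids) == 0L) stop("signature is empty", call. = FALSE)
  missing <- setdiff(probe_ids, rownames(m))
  if (length(missing)) {
    stop("signature probes absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  meta <- match_labels(m, meta)
  ref <- meta$group_role == "reference"
  if (sum(ref) < 3L) stop("need at least 3 reference samples", call. = FALSE)
  ref_labels <- meta$site_class[ref]
  if (!all(ref_labels %in% c("NL", "L"))) {
    stop("reference samples must be labeled NL or L", call. = FALSE)
  }

  x <- t(m[probe_ids, meta$sample_id[ref], drop = FALSE])  # samples x probes
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  # sign convention: largest-|loading| coefficient positive per component
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rotation <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")

  var_ratio <- pc$sdev^2 / sum(pc$sdev^2)
  k_retained <- which(cumsum(var_ratio) > var_rule)[1]
  if (is.na(k_retained)) k_retained <- length(var_ratio)

  if (ncol(scores) < 2L) {
    scores <- cbind(scores, 0)
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  }
  obj <- structure(list(
    probe_ids = probe_ids,
    center = pc$center,
    rotation = rotation,
    var_ratio = var_ratio,
    k_retained = k_retained,
    var_rule = var_rule,
    ref_scores = scores,
    ref_labels = ref_labels,
    centroid_NL = colMeans(scores[ref_labels == "NL", 1:2, drop = FALSE]),
    centroid_L = colMeans(scores[ref_labels == "L", 1:2, drop = FALSE]),
    distance_pcs = distance_pcs,
    pipeline = if (is.character(signature)) NA_character_ else attr(signature, "pipeline")
  ), class = "centroid_classifier")
  if (!identical(distance_pcs, 2) && !identical(distance_pcs, "retained")) {
    stop("'distance_pcs' must be 2 or \"retained\"", call. = FALSE)
  }
  if (identical(distance_pcs, "retained")) {
    k <- max(2L, obj$k_retained)
    obj$centroid_NL <- colMeans(scores[ref_labels == "NL", seq_len(k), drop = FALSE])
    obj$centroid_L <- colMeans(scores[ref_labels == "L", seq_len(k), drop = FALSE])
  }
  obj
}

#' Project samples into a fitted signature-PCA space
#'
#' Centers each sample's signature profile by the reference means stored in
#' the model and applies the loading matrix. Projection is linear, so the
#' reference samples reproduce the scores used during fitting and the
#' reference mean profile maps to the origin.
#'
#' @param model A `centroid_classifier`.
#' @param m Numeric matrix (probes x samples) containing every signature
#'   probe.
#' @return Score matrix, samples x components.
#' @export
project <- function(model, m) {
  stopifnot(inherits(model, "centroid_classifier"))
  missing <- setdiff(model$probe_ids, rownames(m))
  if (length(missing)) {
    stop("samples are missing signature probes: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- t(m[model$probe_ids, , drop = FALSE])
  sweep(x, 2, model$center, "-") %*% model$rotation
}

#' Nearest-centroid classification of projected samples
#'
#' Computes, for each sample, the Euclidean distance to the NL and L
#' reference centroids (in the first-two-component plane unless the model
#' was fitted with `distance_pcs = "retained"`) and assigns the label of the
#' closer centroid. A sample exactly equidistant from both centroids is
#' assigned the NL-side label and flagged as a tie.
#'
#' @param model A `centroid_classifier`.
#' @param scores Score matrix from [project()].
#' @param labels Length-2 character vector: the labels for the NL-side and
#'   L-side assignment, e.g. `c("NL", "L")` for test samples or
#'   `c("AK_NL", "AK_L")` for AK stratification.
#' @param grades Optional character vector of histopathological grades,
#'   aligned with the rows of `scores`, joined into the report.
#' @return A data.frame of classification records: `sample_id`, `grade`,
#'   `dist_to_NL`, `dist_to_L`, `classification`, `tie`.
#' @export
classify_nearest_centroid <- function(model, scores,
                                      labels = c("NL", "L"), grades = NULL) {
  stopifnot(inherits(model, "centroid_classifier"), length(labels) == 2L)
  k <- length(model$centroid_NL)
  s <- scores[, seq_len(k), drop = FALSE]
  d_nl <- sqrt(rowSums(sweep(s, 2, model$centroid_NL, "-")^2))
  d_l <- sqrt(rowSums(sweep(s, 2, model$centroid_L, "-")^2))
  tie <- d_nl == d_l
  data.frame(
    sample_id = if (!is.null(rownames(scores))) rownames(scores) else
      sprintf("sample%02d", seq_along(d_nl)),
    grade = if (is.null(grades)) NA_character_ else as.character(grades),
    dist_to_NL = d_nl,
    dist_to_L = d_l,
    classification = ifelse(d_nl <= d_l, labels[1], labels[2]),
    tie = tie,
    stringsAsFactors = FALSE
  )
}

#' Classify distance pairs that are already computed
#'
#' Applies the nearest-centroid decision rule directly to precomputed
#' (distance-to-NL, distance-to-L) pairs — useful for validating the rule
#' against a published classification table. Ties go to the NL-side label.
#'
#' @param dist_to_nl,dist_to_l Numeric vectors of distances.
#' @param labels Length-2 character vector of output labels.
#' @return Character vector of assigned labels.
#' @export
classify_distance_pairs <- function(dist_to_nl, dist_to_l,
                                    labels = c("AK_NL", "AK_L")) {
  stopifnot(length(dist_to_nl) == length(dist_to_l), length(labels) == 2L)
  ifelse(dist_to_nl <= dist_to_l, labels[1], labels[2])
}

#' @describeIn fit_centroid_classifier Project new samples and label them by
#'   the nearest reference centroid.
#' @param object A `centroid_classifier`.
#' @param newdata Expression matrix (probes x samples).
#' @param labels,grades Passed to [classify_nearest_centroid()].
#' @param ... Unused.
#' @export
predict.centroid_classifier <- function(object, newdata,
                                        labels = c("NL", "L"),
                                        grades = NULL, ...) {
  classify_nearest_centroid(object, project(object, newdata),
                            labels = labels, grades = grades)
}

#' Stratify AK samples into AK_NL and AK_L
#'
#' Projects AK samples into the fitted signature-PCA space and labels each
#' by the nearer reference centroid: `AK_NL` (healthy-like) when closer to
#' the NL centroid, `AK_L` (carcinoma-like) when closer to the L centroid.
#'
#' @param model A fitted `centroid_classifier`.
#' @param m Expression matrix (probes x samples) of the AK samples.
#' @param grades Optional histopathological grades (`AK_I`/`AK_II`/`AK_III`)
#'   joined into the report; never used in classification.
#' @return A list of class `ak_stratification`: `records` (classification
#'   records; see [classify_nearest_centroid()]) and `counts` (named vector
#'   with the AK_NL and AK_L totals).
#' @export
stratify_ak <- function(model, m, grades = NULL) {
  rec <- predict(model, m, labels = c("AK_NL", "AK_L"), grades = grades)
  counts <- c(
    AK_NL = sum(rec$classification == "AK_NL"),
    AK_L = sum(rec$classification == "AK_L")
  )
  structure(list(records = rec, counts = counts), class = "ak_stratification")
}

#' @export
print.ak_stratification <- function(x, ...) {
  cat(sprintf("AK stratification: %d AK_NL, %d AK_L (n = %d)\n",
              x$counts["AK_NL"], x$counts["AK_L"], nrow(x$records)))
  if (any(x$records$tie)) {
    cat("  ties (assigned AK_NL):",
        paste(x$records$sample_id[x$records$tie], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classification accuracy against a ground-truth labeling
#'
#' @param records Classification records (from
#'   [predict.centroid_classifier()] or [classify_nearest_centroid()]).
#' @param truth Character vector of true labels, either aligned with the
#'   records or named by sample id.
#' @return A list of class `accuracy_report`: `accuracy` (exact fraction),
#'   `percent` (rounded to a whole percent, half away from zero), `n`,
#'   `n_misclassified`, `misclassified` (sample ids), `pipeline`.
#' @export
evaluate_accuracy <- function(records, truth) {
  if (nrow(records) == 0L) stop("no classification records", call. = FALSE)
  if (!is.null(names(truth))) {
    truth <- truth[records$sample_id]
  }
  if (length(truth) != nrow(records) || anyNA(truth)) {
    stop("every record needs a truth label", call. = FALSE)
  }
  ok <- records$classification == truth
  acc <- mean(ok)
  structure(list(
    accuracy = acc,
    percent = floor(100 * acc + 0.5),
    n = nrow(records),
    n_misclassified = sum(!ok),
    misclassified = records$sample_id[!ok],
    pipeline = attr(records, "pipeline")
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Accuracy: %d/%d correct = %.1f%% (reported %d%%)\n",
              x$n - x$n_misclassified, x$n, 100 * x$accuracy, x$percent))
  if (x$n_misclassified > 0) {
    cat("  misclassified:", paste(x$misclassified, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Select the better DEG pipeline by held-out classification accuracy
#'
#' Compares two accuracy reports computed on the same test set and returns
#' the id of the pipeline with the higher exact accuracy. On an exact tie
#' the pipeline named by `tie_breaker` wins (by default the plain t-test
#' route, which carries fewer modeling assumptions); the tie is recorded in
#' the result.
#'
#' @param reports Named list of two `accuracy_report` objects; names are the
#'   pipeline ids.
#' @param tie_breaker Pipeline id preferred on a tie; defaults to the second
#'   report's name.
#' @return A list of class `pipeline_selection`: `selected`, `accuracies`
#'   (named numeric), `tie` (logical).
#' @export
select_pipeline <- function(reports, tie_breaker = NULL) {
  if (length(reports) != 2L || is.null(names(reports)) ||
      any(!nzchar(names(reports)))) {
    stop("'reports' must be a named list of two accuracy reports",
         call. = FALSE)
  }
  ns <- vapply(reports, function(r) r$n, numeric(1))
  if (any(ns == 0)) stop("empty accuracy report", call. = FALSE)
  if (ns[1] != ns[2]) {
    stop("accuracy reports cover different test-set sizes", call. = FALSE)
  }
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  if (is.null(tie_breaker)) tie_breaker <- names(reports)[2]
  tie <- acc[1] == acc[2]
  selected <- if (tie) tie_breaker else names(acc)[which.max(acc)]
  structure(list(selected = selected, accuracies = acc, tie = tie),
            class = "pipeline_selection")
}

#' @export
print.pipeline_selection <- function(x, ...) {
  cat(sprintf("Selected pipeline: %s (%s)%s\n", x$selected,
              paste(sprintf("%s = %.1f%%", names(x$accuracies),
                            100 * x$accuracies), collapse = ", "),
              if (x$tie) " [tie, broken deterministically]" else ""))
  invisible(x)
}

#' @export
print.centroid_classifier <- function(x, ...) {
  cat(sprintf(
    "Signature-PCA nearest-centroid classifier (%d probes, %d reference samples)\n",
    length(x$probe_ids), nrow(x$ref_scores)
  ))
  cat(sprintf("  k_retained = %d (cumulative explained variance > %g%%)\n",
              x$k_retained, 100 * x$var_rule))
  cat(sprintf("  explained variance PC1/PC2: %.1f%% / %.1f%%\n",
              100 * x$var_ratio[1],
              100 * ifelse(length(x$var_ratio) > 1, x$var_ratio[2], 0)))
  cat(sprintf("  centroid NL: (%.2f, %.2f)  centroid L: (%.2f, %.2f)\n",
              x$centroid_NL[1], x$centroid_NL[2],
              x$centroid_L[1], x$centroid_L[2]))
  invisible(x)
}

#' @export
summary.centroid_classifier <- function(object, ...) {
  print(object)
  cat("  cumulative explained variance:",
      paste(sprintf("%.3f", cumsum(object$var_ratio)[seq_len(min(5, length(object$var_ratio)))]),
            collapse = " "), "\n")
  invisible(object)
}

#' @describeIn fit_centroid_classifier Plot reference scores and centroids
#'   in the first-two-component plane; extra samples can be overlaid via
#'   `newdata`.
#' @param x A `centroid_classifier`.
#' @export
plot.centroid_classifier <- function(x, newdata = NULL, ...) {
  s <- x$ref_scores[, 1:2, drop = FALSE]
  col <- ifelse(x$ref_labels == "L", "firebrick", "forestgreen")
  extra <- if (!is.null(newdata)) project(x, newdata)[, 1:2, drop = FALSE]
  xlim <- range(c(s[, 1], if (!is.null(extra)) extra[, 1]))
  ylim <- range(c(s[, 2], if (!is.null(extra)) extra[, 2]))
  plot(s, col = col, pch = 19, xlab = "PC1", ylab = "PC2",
       xlim = xlim, ylim = ylim,
       main = "Signature PCA: reference samples and centroids", ...)
  if (!is.null(extra)) points(extra, pch = 17, col = "grey40")
  points(rbind(x$centroid_NL[1:2], x$centroid_L[1:2]), pch = 3, cex = 2,
         lwd = 2, col = c("forestgreen", "firebrick"))
  legend("topright", legend = c("NL ref", "L ref", "centroid"),
         col = c("forestgreen", "firebrick", "black"),
         pch = c(19, 19, 3), bty = "n")
  invisible(x)
}
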