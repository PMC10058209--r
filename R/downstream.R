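#' Uncentered correlation distance
#'
#' `1 - cosine similarity` computed without mean-centering:
#' `1 - sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))`. Ranges over
#' \[0, 2\]: 0 for parallel vectors, 1 for orthogonal, 2 for antiparallel.
#'
#' @param x,y Numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return A single distance in \[0, 2\].
#' @export
uncentered_correlation_distance <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero vector has no direction", call. = FALSE)
  1 - sum(x * y) / (nx * ny)
}

# Pairwise uncentered-correlation distances between the columns of `x`.
uncentered_cor_dist <- function(x) {
  norms <- sqrt(colSums(x^2))
  zero <- which(norms == 0)
  if (length(zero)) {
    ids <- if (!is.null(colnames(x))) colnames(x)[zero] else zero
    stop("zero vector(s): ", paste(ids, collapse = ", "), call. = FALSE)
  }
  sim <- crossprod(x) / tcrossprod(norms)
  d <- 1 - sim
  d[d < 0] <- 0   # clip numerical noise at the parallel end
  stats::as.dist(d)
}

#' Agglomerative clustering under uncentered correlation
#'
#' Complete-linkage hierarchical clustering of probes or samples with the
#' uncentered-correlation distance — the Cluster 3.0 convention used for
#' expression heat maps. Complete linkage guarantees non-decreasing merge
#' heights.
#'
#' @param m Numeric expression matrix (probes x samples).
#' @param axis Cluster `"samples"` (columns, default) or `"probes"` (rows).
#' @return A [stats::hclust] tree; cut it with [stats::cutree()] and export
#'   it with [dendrogram_newick()].
#' @export
hcluster <- function(m, axis = c("samples", "probes")) {
  axis <- match.arg(axis)
  x <- if (axis == "samples") m else t(m)
  if (ncol(x) < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  stats::hclust(uncentered_cor_dist(x), method = "complete")
}

#' Export a dendrogram as Newick text
#'
#' @param hc An [stats::hclust] tree.
#' @param file Optional path; when `""` (default) the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
dendrogram_newick <- function(hc, file = "") {
  ape::write.tree(ape::as.phylo(hc), file = file)
}

#' AK-progression differential analysis (AK_L vs AK_NL)
#'
#' Two-group pooled t test of the carcinoma-like against the healthy-like AK
#' subclass, thresholded at raw p < `p_threshold` and |FC| >
#' `abs_fc_threshold`. No multiple-testing correction is applied by default
#' for this contrast (set `adjust` to change that).
#'
#' @param m Expression matrix (probes x samples) of the AK samples.
#' @param ak_labels Character vector aligned with `colnames(m)` with values
#'   `AK_NL`/`AK_L` (e.g. the `classification` column of
#'   [stratify_ak()] records).
#' @param p_threshold,abs_fc_threshold Selection thresholds; defaults 0.05
#'   and 2.
#' @param adjust Correction recorded in `p_adj`; `"none"` by default, in
#'   which case selection uses the raw p.
#' @return A list: `table` (the full DEG table) and `signature` (the
#'   thresholded `deg_signature`, contrast `AKL_vs_AKNL`).
#' @export
deg_ak <- function(m, ak_labels, p_threshold = 0.05, abs_fc_threshold = 2,
                   adjust = c("none", "BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  tab <- two_group_ttest(m, ak_labels, group_nl = "AK_NL", group_l = "AK_L",
                         adjust = adjust)
  sig <- select_degs(tab, p_threshold = p_threshold,
                     abs_fc_threshold = abs_fc_threshold,
                     use_adjusted = !identical(adjust, "none"),
                     contrast = "AKL_vs_AKNL", pipeline = "ttest")
  list(table = tab, signature = sig)
}

#' Overlap of a progression signature with the SCC signature
#'
#' Fraction of the progression signature's identifiers that also occur in
#' the SCC signature. The denominator is always the progression signature,
#' so the measure is asymmetric by construction.
#'
#' @param progression,scc `deg_signature` objects (or character vectors of
#'   ids) at the same identifier level.
#' @return A list: `percent` (0-100), `fraction`, `shared` (common ids),
#'   `n_progression`, `n_scc`.
#' @export
signature_overlap <- function(progression, scc) {
  ids_of <- function(s) {
    if (is.character(s)) return(unique(s))
    unique(if (!is.null(s$symbol)) s$symbol else s$probe_id)
  }
  a <- ids_of(progression); b <- ids_of(scc)
  if (length(a) == 0L) stop("empty progression signature", call. = FALSE)
  shared <- intersect(a, b)
  frac <- length(shared) / length(a)
  list(percent = 100 * frac, fraction = frac, shared = shared,
       n_progression = length(a), n_scc = length(b))
}

# Significance stars at the 0.05 / 0.01 / 0.005 convention.
p_stars <- function(p) {
  ifelse(p < 0.005, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Marker trends across the four disease stages
#'
#' For each marker (row), summarizes group means and SDs for the four stage
#' groups NL, AK_NL, AK_L and L, runs a one-way ANOVA, and adjusts all six
#' pairwise comparisons with Tukey's HSD (classical equal-variance form via
#' the studentized-range distribution). Stars follow the
#' 0.05 / 0.01 / 0.005 convention, `ns` otherwise.
#'
#' @param m Expression matrix (markers x samples).
#' @param groups Character or factor vector aligned with `colnames(m)` with
#'   values in `NL`, `AK_NL`, `AK_L`, `L`; every group needs at least 2
#'   samples.
#' @return A list of class `marker_trend`: `summary` (marker, group, n,
#'   mean, sd), `anova` (marker, F, p), `tukey` (marker, comparison, diff,
#'   p_adj, stars).
#' @export
marker_trend <- function(m, groups) {
  lev <- c("NL", "AK_NL", "AK_L", "L")
  groups <- factor(as.character(groups), levels = lev)
  if (length(groups) != ncol(m)) {
    stop("'groups' must have one entry per column", call. = FALSE)
  }
  if (anyNA(groups)) stop("unknown group label", call. = FALSE)
  cnt <- table(groups)
  if (any(cnt < 2)) {
    stop("groups with < 2 samples: ",
         paste(names(cnt)[cnt < 2], collapse = ", "), call. = FALSE)
  }
  markers <- rownames(m)
  if (is.null(markers)) markers <- sprintf("marker%02d", seq_len(nrow(m)))

  summaries <- vector("list", nrow(m))
  anovas <- vector("list", nrow(m))
  tukeys <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    fit <- stats::aov(y ~ groups)
    av <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$groups
    summaries[[i]] <- data.frame(
      marker = markers[i], group = lev, n = as.integer(cnt[lev]),
      mean = tapply(y, groups, mean)[lev],
      sd = tapply(y, groups, stats::sd)[lev],
      stringsAsFactors = FALSE
    )
    anovas[[i]] <- data.frame(
      marker = markers[i], F = av[["F value"]][1], p = av[["Pr(>F)"]][1],
      stringsAsFactors = FALSE
    )
    tukeys[[i]] <- data.frame(
      marker = markers[i], comparison = rownames(tk),
      diff = tk[, "diff"], p_adj = tk[, "p adj"],
      stars = p_stars(tk[, "p adj"]),
      stringsAsFactors = FALSE
    )
  }
  out <- list(
    summary = do.call(rbind, summaries),
    anova = do.call(rbind, anovas),
    tukey = do.call(rbind, tukeys)
  )
  rownames(out$summary) <- rownames(out$anova) <- rownames(out$tukey) <- NULL
  structure(out, class = "marker_trend")
}

#' @export
print.marker_trend <- function(x, ...) {
  cat(sprintf("Marker trends for %d marker(s) across NL / AK_NL / AK_L / L\n",
              nrow(x$anova)))
  print(x$anova)
  invisible(x)
}

#' Histological grade composition of the AK subclasses
#'
#' @param records Classification records carrying a `grade` column (e.g.
#'   from [stratify_ak()]).
#' @return A data.frame with one row per subclass and grade: `classification`,
#'   `grade`, `n`, `percent` (of that subclass, rounded to a whole percent).
#' @export
grade_composition <- function(records) {
  if (!all(c("classification", "grade") %in% names(records))) {
    stop("records need 'classification' and 'grade' columns", call. = FALSE)
  }
  tab <- table(records$classification, records$grade)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("classification", "grade", "n")
  totals <- rowSums(tab)[out$classification]
  out$percent <- ifelse(totals > 0, floor(100 * out$n / totals + 0.5), 0)
  out[order(out$classification, out$grade), , drop = FALSE]
}
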