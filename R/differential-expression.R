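#' @title Differential-expression tables
#' @description Internal constructor shared by the two DEG routes. A DEG
#'   table is a data.frame with one row per probe carrying group means (log2),
#'   the log2 fold change (L minus NL), the signed linear-scale fold change
#'   (`2^log2fc` for up, `-2^(-log2fc)` for down, so `|signed_fc| >= 1`),
#'   the t statistic, raw and adjusted p-values, and the direction.
#' @noRd
build_deg_table <- function(probe_ids, mean_nl, mean_l, t_stat, df, p_raw,
                            adjust = c("BH", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  log2fc <- mean_l - mean_nl
  signed_fc <- ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc))
  p_adj <- switch(adjust,
    BH = adjust_bh(p_raw),
    bonferroni = adjust_bonferroni(p_raw),
    none = p_raw
  )
  data.frame(
    probe_id = probe_ids,
    mean_NL = mean_nl,
    mean_L = mean_l,
    log2fc = log2fc,
    signed_fc = signed_fc,
    t_stat = t_stat,
    df = df,
    p_raw = p_raw,
    p_adj = p_adj,
    direction = ifelse(log2fc >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
}

# Extract and validate the NL/L site-class labels for a set of columns.
match_labels <- function(m, meta) {
  if (!all(c("sample_id", "site_class") %in% names(meta))) {
    stop("'meta' needs columns 'sample_id' and 'site_class'", call. = FALSE)
  }
  idx <- match(colnames(m), meta$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from metadata: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  meta[idx, , drop = FALSE]
}

#' Per-probe paired linear model (diagnosis + patient)
#'
#' Fits, for every probe, an ordinary least-squares linear model of log2
#' expression on the diagnosis factor (NL vs L) plus patient indicator
#' variables, and tests the diagnosis coefficient with a two-sided t test on
#' the residual degrees of freedom. On a complete paired design (every
#' patient contributing exactly one NL and one L sample) this reproduces the
#' paired t test probe by probe. No empirical-Bayes variance moderation is
#' applied: the per-probe statistic is the classical OLS t.
#'
#' @param m Numeric matrix of log2 intensities (probes x samples); column
#'   names must appear in `meta$sample_id`.
#' @param meta Sample metadata with columns `sample_id`, `patient_id` and
#'   `site_class` (values `NL`/`L`) covering the columns of `m`. Every
#'   patient must contribute at least one NL and one L sample.
#' @param adjust Multiple-testing correction for the `p_adj` column;
#'   Benjamini-Hochberg by default.
#' @return A DEG table (data.frame) with one row per probe: `probe_id`,
#'   `mean_NL`, `mean_L`, `log2fc`, `signed_fc`, `t_stat`, `df`, `p_raw`,
#'   `p_adj`, `direction`. Probes with zero residual variance and zero
#'   effect get `t_stat = 0`, `p_raw = 1` so downstream set algebra stays
#'   total.
#' @export
paired_linear_model <- function(m, meta, adjust = c("BH", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  meta <- match_labels(m, meta)
  if (!"patient_id" %in% names(meta)) {
    stop("'meta' needs a 'patient_id' column", call. = FALSE)
  }
  if (!all(meta$site_class %in% c("NL", "L"))) {
    stop("paired model expects only NL and L samples", call. = FALSE)
  }
  per_patient <- table(meta$patient_id, meta$site_class)
  bad <- rownames(per_patient)[per_patient[, "NL"] == 0 | per_patient[, "L"] == 0]
  if (length(bad)) {
    stop("patients lacking an NL or L sample: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  diagnosis <- factor(meta$site_class, levels = c("NL", "L"))
  patient <- factor(meta$patient_id)
  X <- stats::model.matrix(~ diagnosis + patient)
  qx <- qr(X)
  n <- nrow(X)
  df <- n - qx$rank
  if (df < 1L) stop("no residual degrees of freedom", call. = FALSE)

  Y <- t(m)                       # samples x probes
  coefs <- qr.coef(qx, Y)         # p x probes
  res <- qr.resid(qx, Y)
  rss <- colSums(res^2)
  s2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))
  j <- which(colnames(X) == "diagnosisL")
  se <- sqrt(s2 * xtx_inv[j, j])
  beta <- coefs[j, ]

  t_stat <- beta / se
  degenerate <- se < 1e-12
  t_stat[degenerate & abs(beta) < 1e-10] <- 0
  t_stat[degenerate & abs(beta) >= 1e-10] <-
    sign(beta[degenerate & abs(beta) >= 1e-10]) * Inf
  p_raw <- 2 * stats::pt(-abs(t_stat), df)

  is_l <- meta$site_class == "L"
  build_deg_table(
    probe_ids = rownames(m),
    mean_nl = rowMeans(m[, !is_l, drop = FALSE]),
    mean_l = rowMeans(m[, is_l, drop = FALSE]),
    t_stat = t_stat, df = df, p_raw = p_raw, adjust = adjust
  )
}

#' Per-probe two-group pooled-variance t test
#'
#' The GeneSpring-style route: for every probe, a classical equal-variance
#' (pooled) two-sample t test of the L group against the NL group, two
#' sided, with Bonferroni adjustment by default.
#'
#' @param m Numeric matrix of log2 intensities (probes x samples).
#' @param labels Character or factor vector aligned with `colnames(m)` (or a
#'   metadata data.frame with `sample_id` and `site_class`), giving each
#'   sample's class. `group_l`/`group_nl` name the two levels compared.
#' @param group_nl,group_l The labels of the baseline and elevated groups;
#'   defaults `"NL"` and `"L"`.
#' @param adjust Multiple-testing correction; Bonferroni by default for this
#'   route.
#' @return A DEG table; see [paired_linear_model()] for the columns.
#' @export
two_group_ttest <- function(m, labels, group_nl = "NL", group_l = "L",
                            adjust = c("bonferroni", "BH", "none")) {
  adjust <- match.arg(adjust)
  if (is.data.frame(labels)) {
    labels <- match_labels(m, labels)$site_class
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(m)) {
    stop("'labels' must have one entry per column of 'm'", call. = FALSE)
  }
  in_nl <- labels == group_nl
  in_l <- labels == group_l
  n1 <- sum(in_nl); n2 <- sum(in_l)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs at least 2 samples (got ", n1, " ", group_nl,
         ", ", n2, " ", group_l, ")", call. = FALSE)
  }
  x1 <- m[, in_nl, drop = FALSE]
  x2 <- m[, in_l, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / df
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  delta <- m2 - m1
  t_stat <- delta / se
  degenerate <- se < 1e-12
  t_stat[degenerate & abs(delta) < 1e-10] <- 0
  t_stat[degenerate & abs(delta) >= 1e-10] <-
    sign(delta[degenerate & abs(delta) >= 1e-10]) * Inf
  p_raw <- 2 * stats::pt(-abs(t_stat), df)
  build_deg_table(
    probe_ids = rownames(m),
    mean_nl = m1, mean_l = m2,
    t_stat = t_stat, df = df, p_raw = p_raw, adjust = adjust
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (FDR), same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("'p' must be p-values in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return `min(1, length(p) * p)` elementwise.
#' @export
adjust_bonferroni <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("'p' must be p-values in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "bonferroni")
}

#' Threshold a DEG table into a signature
#'
#' Selects probes with p-value strictly below `p_threshold` and absolute
#' linear-scale fold change strictly above `abs_fc_threshold` (so
#' `|FC| > 2` is `|log2fc| > 1`; a probe at exactly FC = 2 is excluded).
#'
#' @param tab A DEG table from [paired_linear_model()] or
#'   [two_group_ttest()].
#' @param p_threshold P-value cutoff (strict); default 0.05.
#' @param abs_fc_threshold Absolute fold-change cutoff (strict, linear
#'   scale); default 2.
#' @param use_adjusted Use the `p_adj` column (default) or `p_raw`.
#' @param contrast Label recorded on the signature (e.g. `"L_vs_NL"`).
#' @param pipeline Provenance tag naming the route that produced the table.
#' @return A `deg_signature`: a data.frame of the selected rows (`probe_id`,
#'   `direction`, `signed_fc`, `p`), with the thresholds, contrast and
#'   pipeline stored as attributes.
#' @export
select_degs <- function(tab, p_threshold = 0.05, abs_fc_threshold = 2,
                        use_adjusted = TRUE, contrast = "L_vs_NL",
                        pipeline = NA_character_) {
  if (p_threshold <= 0 || abs_fc_threshold <= 0) {
    stop("thresholds must be > 0", call. = FALSE)
  }
  p <- if (use_adjusted) tab$p_adj else tab$p_raw
  keep <- p < p_threshold & abs(tab$signed_fc) > abs_fc_threshold
  sig <- data.frame(
    probe_id = tab$probe_id[keep],
    direction = tab$direction[keep],
    signed_fc = tab$signed_fc[keep],
    p = p[keep],
    stringsAsFactors = FALSE
  )
  structure(sig,
    class = c("deg_signature", "data.frame"),
    p_threshold = p_threshold, abs_fc_threshold = abs_fc_threshold,
    use_adjusted = use_adjusted, contrast = contrast, pipeline = pipeline
  )
}

#' @export
print.deg_signature <- function(x, ...) {
  cat(sprintf(
    "DEG signature '%s' (%s): %d probes (%d up, %d down); p < %g, |FC| > %g (%s p)\n",
    attr(x, "contrast"),
    ifelse(is.na(attr(x, "pipeline")), "unspecified pipeline", attr(x, "pipeline")),
    nrow(x), sum(x$direction == "up"), sum(x$direction == "down"),
    attr(x, "p_threshold"), attr(x, "abs_fc_threshold"),
    if (isTRUE(attr(x, "use_adjusted"))) "adjusted" else "raw"
  ))
  invisible(x)
}

#' Collapse a probe-level signature to gene symbols
#'
#' Maps probes to gene symbols and deduplicates. Probes without a symbol are
#' retained under their probe id. When several probes share a symbol, the
#' probe with the smallest p-value represents it; if those probes disagree
#' on direction, the conflict is reported via a `conflicts` attribute (the
#' smallest-p probe still wins).
#'
#' @param sig A `deg_signature` from [select_degs()].
#' @param symbol_map Named character vector, probe id -> gene symbol. May be
#'   partial; `NA` entries are treated as unmapped.
#' @return A `deg_signature` at symbol level with columns `symbol`,
#'   `probe_id`, `direction`, `signed_fc`, `p`, plus a character vector
#'   attribute `conflicts` naming symbols whose probes disagreed on
#'   direction.
#' @export
collapse_to_symbols <- function(sig, symbol_map) {
  symbols <- unname(symbol_map[sig$probe_id])
  symbols[is.na(symbols) | symbols == ""] <- sig$probe_id[is.na(symbols) | symbols == ""]
  ord <- order(symbols, sig$p, method = "radix")
  s <- sig[ord, , drop = FALSE]
  symbols <- symbols[ord]
  first <- !duplicated(symbols)
  ndir <- tapply(s$direction, symbols, function(d) length(unique(d)))
  conflicts <- names(ndir)[ndir > 1]
  out <- data.frame(
    symbol = symbols[first],
    probe_id = s$probe_id[first],
    direction = s$direction[first],
    signed_fc = s$signed_fc[first],
    p = s$p[first],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out,
    class = c("deg_signature", "data.frame"),
    p_threshold = attr(sig, "p_threshold"),
    abs_fc_threshold = attr(sig, "abs_fc_threshold"),
    use_adjusted = attr(sig, "use_adjusted"),
    contrast = attr(sig, "contrast"),
    pipeline = attr(sig, "pipeline"),
    level = "symbol",
    conflicts = conflicts
  )
}
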