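# Small in-code fixtures shared across test files.

# A tiny deterministic expression matrix with named dimensions.
tiny_matrix <- function(values, n_probes, n_samples,
                        probe_ids = sprintf("P%02d", seq_len(n_probes)),
                        sample_ids = sprintf("S%02d", seq_len(n_samples))) {
  matrix(values, nrow = n_probes, ncol = n_samples,
         dimnames = list(probe_ids, sample_ids))
}

# A complete paired design: n patients x (NL, L).
paired_meta <- function(n_patients) {
  data.frame(
    sample_id = c(sprintf("PT%02d_NL", seq_len(n_patients)),
                  sprintf("PT%02d_L", seq_len(n_patients))),
    patient_id = rep(sprintf("PT%02d", seq_len(n_patients)), 2),
    histology = rep(c("H", "SCC"), each = n_patients),
    site_class = rep(c("NL", "L"), each = n_patients),
    group_role = "reference",
    stringsAsFactors = FALSE
  )
}

# Random paired matrix matching paired_meta(n_patients).
random_paired_matrix <- function(n_probes, n_patients) {
  meta <- paired_meta(n_patients)
  m <- matrix(rnorm(n_probes * 2 * n_patients), nrow = n_probes,
              dimnames = list(sprintf("P%03d", seq_len(n_probes)),
                              meta$sample_id))
  list(m = m, meta = meta)
}

# Brute-force BH step-up, written directly from the definition.
bh_brute_force <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running_min <- 1
  for (i in rev(seq_len(n))) {
    running_min <- min(running_min, n / i * p[ord[i]])
    adj[ord[i]] <- running_min
  }
  pmin(adj, 1)
}

# Brute-force complete linkage on a distance matrix: at each step merge the
# pair of clusters with the smallest maximum pairwise item distance.
complete_linkage_brute_force <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          h <- max(d[clusters[[i]], clusters[[j]]])
          if (h < best_h) { best_h <- h; best <- c(i, j) }
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
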