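test_that("paired linear model reproduces the closed-form paired t test", {
  # 3 patients with paired differences (L - NL) of 1, 2, 3:
  # t = mean(d) / (sd(d)/sqrt(3)) = 2 / (1/sqrt(3)) = 3.464, df = 2
  meta <- paired_meta(3)
  nl <- c(5, 6, 7)
  l <- nl + c(1, 2, 3)
  m <- tiny_matrix(c(nl, l), 1, 6, probe_ids = "P1",
                   sample_ids = meta$sample_id)
  tab <- paired_linear_model(m, meta)
  expect_equal(tab$t_stat, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(tab$df, 2)
  expect_equal(tab$p_raw, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  expect_equal(tab$p_raw, 0.0742, tolerance = 1e-3)
})

test_that("paired model equals the paired t test probe-by-probe on random designs", {
  set.seed(10)
  for (n_pat in c(3, 5, 8)) {
    fx <- random_paired_matrix(25, n_pat)
    tab <- paired_linear_model(fx$m, fx$meta)
    for (i in seq_len(nrow(fx$m))) {
      nl <- fx$m[i, fx$meta$site_class == "NL"]
      l <- fx$m[i, fx$meta$site_class == "L"]
      tt <- t.test(l, nl, paired = TRUE)
      expect_equal(tab$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(tab$p_raw[i], tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("degenerate probes and invalid pairing are handled", {
  meta <- paired_meta(3)
  m <- tiny_matrix(rep(4, 12), 2, 6, sample_ids = meta$sample_id)
  tab <- paired_linear_model(m, meta)
  expect_equal(tab$t_stat, c(0, 0))
  expect_equal(tab$p_raw, c(1, 1))

  broken <- meta[meta$sample_id != "PT02_L", ]
  expect_error(
    paired_linear_model(m[, broken$sample_id], broken), "PT02"
  )
})

test_that("two-group pooled t test matches the textbook closed form", {
  # {1,2,3} vs {4,5,6}: pooled sd = 1, t = 3/sqrt(2/3) = 3.674, df = 4
  m <- tiny_matrix(c(1, 2, 3, 4, 5, 6), 1, 6)
  tab <- two_group_ttest(m, c("NL", "NL", "NL", "L", "L", "L"))
  expect_equal(abs(tab$t_stat), 3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(tab$df, 4)
  expect_equal(tab$p_raw, 0.0213, tolerance = 1e-3)
  expect_equal(tab$p_raw,
               t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)$p.value,
               tolerance = 1e-12)

  flat <- tiny_matrix(rep(2, 6), 1, 6)
  tab0 <- two_group_ttest(flat, c("NL", "NL", "NL", "L", "L", "L"))
  expect_equal(tab0$t_stat, 0)
  expect_equal(tab0$p_raw, 1)

  expect_error(two_group_ttest(m, c("NL", "L", "L", "L", "L", "L")),
               "at least 2")
})

test_that("pooled t-test p agrees with a permutation p on a 4+4 example", {
  set.seed(42)
  x <- c(0.2, 1.1, -0.3, 0.8)
  y <- c(1.9, 2.4, 1.2, 2.8)
  m <- tiny_matrix(c(x, y), 1, 8)
  labels <- rep(c("NL", "L"), each = 4)
  tab <- two_group_ttest(m, labels)
  obs <- abs(tab$t_stat)
  pool <- c(x, y)
  combos <- combn(8, 4)
  perm_t <- apply(combos, 2, function(idx) {
    a <- pool[idx]; b <- pool[-idx]
    abs(t.test(b, a, var.equal = TRUE)$statistic)
  })
  perm_p <- mean(perm_t >= obs - 1e-12)
  # exact permutation null (all 70 splits) vs the t distribution
  expect_equal(tab$p_raw, perm_p, tolerance = 0.05)
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  set.seed(11)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_bh(p), bh_brute_force(p), tolerance = 1e-12)
  }
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Bonferroni adjustment is min(1, m p)", {
  expect_equal(adjust_bonferroni(rep(0.01, 10))[1], 0.1)
  expect_equal(adjust_bonferroni(rep(0.5, 10))[1], 1)
  expect_equal(adjust_bonferroni(0.3), 0.3)
  set.seed(12)
  p <- runif(30)
  expect_equal(adjust_bonferroni(p), pmin(1, 30 * p))
})

test_that("DEG tables satisfy their structural invariants", {
  set.seed(13)
  fx <- random_paired_matrix(40, 5)
  tab <- paired_linear_model(fx$m, fx$meta, adjust = "BH")
  expect_true(all(tab$p_adj >= tab$p_raw - 1e-15))
  expect_true(all(abs(tab$signed_fc) >= 1))
  expect_true(all((tab$direction == "up") == (tab$log2fc >= 0)))
  expect_equal(tab$log2fc, tab$mean_L - tab$mean_NL)
})

test_that("signature selection applies strict thresholds", {
  tab <- data.frame(
    probe_id = c("a", "b", "c", "d"),
    signed_fc = c(2.5, 1.9, 2.0, -2.5),
    p_raw = c(0.04, 0.04, 0.04, 0.04),
    p_adj = c(0.04, 0.04, 0.04, 0.06),
    direction = c("up", "up", "up", "down"),
    stringsAsFactors = FALSE
  )
  sig <- select_degs(tab, use_adjusted = TRUE)
  expect_equal(sig$probe_id, "a")        # b: FC too small; c: FC == 2; d: p
  expect_equal(sig$direction, "up")
  sig_raw <- select_degs(tab, use_adjusted = FALSE)
  expect_setequal(sig_raw$probe_id, c("a", "d"))
  expect_error(select_degs(tab, p_threshold = 0), "> 0")
})

test_that("symbol collapsing deduplicates and resolves direction conflicts", {
  sig <- structure(
    data.frame(
      probe_id = c("p1", "p2", "p3", "p4", "p5"),
      direction = c("up", "up", "down", "up", "down"),
      signed_fc = c(3, 2.5, -4, 2.2, -2.1),
      p = c(0.001, 0.01, 0.0001, 0.02, 0.03),
      stringsAsFactors = FALSE
    ),
    class = c("deg_signature", "data.frame")
  )
  map <- c(p1 = "GENEA", p2 = "GENEA", p3 = "GENEB", p4 = "GENEB")
  out <- collapse_to_symbols(sig, map)
  # GENEA: two same-direction probes -> one entry (smaller p wins)
  # GENEB: conflicting directions -> smaller-p probe wins, conflict logged
  # p5 unmapped -> kept under its probe id
  expect_equal(nrow(out), 3)
  expect_equal(out$probe_id[out$symbol == "GENEA"], "p1")
  expect_equal(out$direction[out$symbol == "GENEB"], "down")
  expect_equal(attr(out, "conflicts"), "GENEB")
  expect_true("p5" %in% out$symbol)

  # fully unmapped signature keeps its size
  none <- collapse_to_symbols(sig, c(zzz = "X"))
  expect_equal(nrow(none), 5)
})

test_that("BH-route signature recovers planted DEGs with controlled FDR", {
  sens <- fdr <- numeric(5)
  for (s in 1:5) {
    co <- generate_cohort(cohort_params(seed = s))
    ref <- co$meta[co$meta$group_role == "reference", ]
    m <- quantile_normalize(co$expr[, ref$sample_id])
    tab <- paired_linear_model(m, ref, adjust = "BH")
    sig <- select_degs(tab, use_adjusted = TRUE)
    planted <- co$truth$planted_degs$probe_id
    sens[s] <- mean(planted %in% sig$probe_id)
    fdr[s] <- if (nrow(sig)) mean(!sig$probe_id %in% planted) else 0
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdr), 0.1)
})

test_that("the paired route beats the unpaired t test when patient effects dominate", {
  recovered <- matrix(NA_real_, 5, 2,
                      dimnames = list(NULL, c("paired", "ttest")))
  for (s in 1:5) {
    co <- generate_cohort(cohort_params(
      patient_effect_sd = 3, noise_sd = 1, planted_log2fc = 1.6, seed = s
    ))
    ref <- co$meta[co$meta$group_role == "reference", ]
    m <- co$expr[, ref$sample_id]
    planted <- co$truth$planted_degs$probe_id
    tab_p <- paired_linear_model(m, ref, adjust = "BH")
    tab_t <- two_group_ttest(m, ref$site_class, adjust = "BH")
    recovered[s, "paired"] <-
      sum(planted %in% select_degs(tab_p, abs_fc_threshold = 1.5)$probe_id)
    recovered[s, "ttest"] <-
      sum(planted %in% select_degs(tab_t, abs_fc_threshold = 1.5)$probe_id)
  }
  expect_gt(mean(recovered[, "paired"]), mean(recovered[, "ttest"]))
})
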