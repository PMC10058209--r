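# Build a classifier from an explicit reference matrix (probes x samples).
fit_ref <- function(m, labels, ...) {
  meta <- data.frame(
    sample_id = colnames(m), patient_id = colnames(m),
    histology = ifelse(labels == "L", "SCC", "H"),
    site_class = labels, group_role = "reference",
    stringsAsFactors = FALSE
  )
  fit_centroid_classifier(m, meta, rownames(m), ...)
}

test_that("explained variance follows the rank of the data", {
  # samples on a line in probe space: one component explains everything
  base <- c(1, 2, 3)
  m <- sapply(c(0, 1, 2, 3), function(a) a * base)
  dimnames(m) <- list(paste0("P", 1:3), paste0("S", 1:4))
  clf <- fit_ref(m, c("NL", "NL", "L", "L"))
  expect_equal(clf$var_ratio[1], 1, tolerance = 1e-12)
  expect_equal(clf$k_retained, 1)

  # three uncorrelated equal-variance coordinates: ratios 1/3 each and the
  # >75% rule keeps all three (cumulative 0.33, 0.67, 1.00)
  h <- contr.helmert(4)                    # orthogonal, zero-sum columns
  iso <- t(h %*% diag(1 / sqrt(colSums(h^2))))
  dimnames(iso) <- list(paste0("P", 1:3), paste0("S", 1:4))
  clf_iso <- fit_ref(iso, c("NL", "NL", "L", "L"))
  expect_equal(clf_iso$var_ratio, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(clf_iso$k_retained, 3)
  # ratios are non-increasing in general
  set.seed(20)
  m2 <- matrix(rnorm(80), 8, 10,
               dimnames = list(paste0("P", 1:8), paste0("S", 1:10)))
  clf2 <- fit_ref(m2, rep(c("NL", "L"), 5))
  expect_true(all(diff(clf2$var_ratio) <= 1e-12))
  expect_equal(clf2$k_retained, which(cumsum(clf2$var_ratio) > 0.75)[1])
})

test_that("projection is consistent, linear and centered", {
  set.seed(21)
  m <- matrix(rnorm(60, 8), 6, 10,
              dimnames = list(paste0("P", 1:6), paste0("S", 1:10)))
  labels <- rep(c("NL", "L"), each = 5)
  clf <- fit_ref(m, labels)
  # projecting the training samples reproduces the fitted scores
  expect_equal(project(clf, m), clf$ref_scores, tolerance = 1e-10)
  # the reference mean profile maps to the origin
  mean_profile <- matrix(rowMeans(m), ncol = 1,
                         dimnames = list(rownames(m), "avg"))
  expect_equal(unname(project(clf, mean_profile))[1, ], rep(0, ncol(clf$rotation)),
               tolerance = 1e-10)
  # doubling a centered profile doubles the score
  x1 <- m[, 1, drop = FALSE]
  doubled <- clf$center + 2 * (x1[, 1] - clf$center)
  doubled <- matrix(doubled, ncol = 1, dimnames = list(rownames(m), "dbl"))
  expect_equal(unname(project(clf, doubled)), 2 * unname(project(clf, x1)),
               tolerance = 1e-10)
  # probe order is irrelevant
  perm <- sample(nrow(m))
  clf_perm <- fit_ref(m[perm, ], labels)
  expect_equal(abs(project(clf_perm, m[perm, ])), abs(project(clf, m)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # missing probes are named in the error
  expect_error(project(clf, m[-2, ]), "P2")
})

test_that("nearest-centroid labels match the published 21-sample table", {
  tab <- published_ak_table()
  expect_equal(nrow(tab), 21)
  calls <- classify_distance_pairs(tab$dist_to_NL, tab$dist_to_L)
  expect_identical(calls, tab$classification)
  expect_equal(sum(calls == "AK_NL"), 12)
  expect_equal(sum(calls == "AK_L"), 9)
})

test_that("classification records follow the distance geometry and tie rule", {
  m <- matrix(c(0, 0, 10, 10, 0, 10), 1, 6,
              dimnames = list("P1", paste0("S", 1:6)))
  m <- rbind(m, 0)
  rownames(m) <- c("P1", "P2")
  clf <- fit_ref(m[, 1:4], c("NL", "NL", "L", "L"))
  rec <- predict(clf, m[, 5:6, drop = FALSE])
  expect_equal(rec$classification, c("NL", "L"))
  expect_true(all(rec$dist_to_NL >= 0 & rec$dist_to_L >= 0))
  # equidistant sample: NL-side label plus a tie flag
  mid <- matrix(c(5, 0), 2, 1, dimnames = list(c("P1", "P2"), "mid"))
  rec_mid <- predict(clf, mid, labels = c("AK_NL", "AK_L"))
  expect_equal(rec_mid$classification, "AK_NL")
  expect_true(rec_mid$tie)
})

test_that("labels are invariant under a rigid rotation of scores and centroids", {
  set.seed(22)
  m <- matrix(rnorm(100, 8), 10, 10,
              dimnames = list(paste0("P", 1:10), paste0("S", 1:10)))
  m[1:5, 6:10] <- m[1:5, 6:10] + 3
  clf <- fit_ref(m, rep(c("NL", "L"), each = 5))
  new <- matrix(rnorm(30, 8), 10, 3,
                dimnames = list(paste0("P", 1:10), paste0("T", 1:3)))
  scores <- project(clf, new)
  rec <- classify_nearest_centroid(clf, scores)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  clf_rot <- clf
  clf_rot$centroid_NL <- drop(R %*% clf$centroid_NL)
  clf_rot$centroid_L <- drop(R %*% clf$centroid_L)
  scores_rot <- scores
  scores_rot[, 1:2] <- scores[, 1:2] %*% t(R)
  rec_rot <- classify_nearest_centroid(clf_rot, scores_rot)
  expect_equal(rec_rot$classification, rec$classification)
  expect_equal(rec_rot$dist_to_NL, rec$dist_to_NL, tolerance = 1e-10)
})

test_that("accuracy reports carry exact fractions and rounded percents", {
  rec <- data.frame(
    sample_id = sprintf("S%02d", 1:19),
    classification = c(rep("L", 10), rep("NL", 9)),
    stringsAsFactors = FALSE
  )
  truth_1_wrong <- c(rep("L", 10), rep("NL", 8), "L")
  acc1 <- evaluate_accuracy(rec, truth_1_wrong)
  expect_equal(acc1$accuracy, 18 / 19)
  expect_equal(acc1$percent, 95)
  expect_equal(acc1$misclassified, "S19")

  truth_2_wrong <- c(rep("L", 10), rep("NL", 7), "L", "L")
  acc2 <- evaluate_accuracy(rec, truth_2_wrong)
  expect_equal(acc2$accuracy, 17 / 19)
  # 89.47% rounds to 89 under round-half-away-from-zero
  expect_equal(acc2$percent, 89)

  all_right <- evaluate_accuracy(rec, rec$classification)
  expect_equal(all_right$percent, 100)
  expect_error(evaluate_accuracy(rec[0, ], character(0)), "no classification")
  expect_error(evaluate_accuracy(rec, rep(NA_character_, 19)), "truth")
})

test_that("pipeline selection prefers the higher exact accuracy", {
  mk <- function(acc, n) structure(
    list(accuracy = acc, percent = floor(100 * acc + 0.5), n = n,
         n_misclassified = round(n * (1 - acc)), misclassified = character(0)),
    class = "accuracy_report"
  )
  sel <- select_pipeline(list(paired = mk(17 / 19, 19), ttest = mk(18 / 19, 19)))
  expect_equal(sel$selected, "ttest")
  expect_false(sel$tie)
  sel2 <- select_pipeline(list(paired = mk(18 / 19, 19), ttest = mk(17 / 19, 19)))
  expect_equal(sel2$selected, "paired")
  # exact tie goes to the t-test route deterministically
  sel3 <- select_pipeline(list(paired = mk(1, 19), ttest = mk(1, 19)),
                          tie_breaker = "ttest")
  expect_equal(sel3$selected, "ttest")
  expect_true(sel3$tie)
  expect_error(select_pipeline(list(paired = mk(1, 19), ttest = mk(1, 0))),
               "empty")
  expect_error(select_pipeline(list(paired = mk(1, 19), ttest = mk(1, 10))),
               "different")
})

test_that("AK stratification recovers extreme planted mixtures", {
  hits <- numeric(10)
  for (s in 1:10) {
    weights <- c(runif(12, 0, 0.2), runif(9, 0.8, 1))
    co <- generate_cohort(cohort_params(ak_mixture_weights = weights, seed = s))
    ref_meta <- co$meta
    m <- quantile_normalize(co$expr)
    ref <- ref_meta$group_role == "reference"
    tab <- paired_linear_model(m[, ref_meta$sample_id[ref]], ref_meta[ref, ])
    sig <- select_degs(tab, pipeline = "paired")
    clf <- fit_centroid_classifier(m, ref_meta, sig)
    ak_ids <- ref_meta$sample_id[ref_meta$group_role == "ak"]
    strat <- stratify_ak(clf, m[, ak_ids])
    hits[s] <- mean(strat$records$classification ==
                      co$truth$ak_true_subclass[strat$records$sample_id])
  }
  expect_gte(mean(hits), 0.95)
})

test_that("all AK samples at the NL centroid are labeled AK_NL", {
  set.seed(23)
  m <- matrix(rnorm(100, 8), 10, 10,
              dimnames = list(paste0("P", 1:10), paste0("S", 1:10)))
  m[1:4, 6:10] <- m[1:4, 6:10] + 4
  labels <- rep(c("NL", "L"), each = 5)
  clf <- fit_ref(m, labels)
  nl_mean <- rowMeans(m[, 1:5])
  aks <- matrix(rep(nl_mean, 3), ncol = 3,
                dimnames = list(rownames(m), paste0("AK", 1:3)))
  strat <- stratify_ak(clf, aks)
  expect_equal(unname(strat$counts), c(3L, 0L))
})
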