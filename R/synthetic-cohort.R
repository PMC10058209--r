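#' Parameters for a synthetic AK cohort
#'
#' Bundles and validates the parameters of the synthetic-cohort generator.
#' The defaults reproduce the structure of the study cohort the pipeline was
#' designed for: 14 reference patients each contributing one paired
#' non-lesional (NL) and one lesional (L) sample, a held-out test group of
#' 9 NL + 10 L unpaired samples, and 21 actinic keratosis (AK) samples built
#' as convex mixtures of the NL and L mean expression profiles.
#'
#' @param n_ref_patients Number of reference patients; each contributes one
#'   NL and one L sample sharing a patient-level intercept.
#' @param n_test_nl,n_test_l Held-out test-group sizes (unpaired samples).
#' @param n_ak Number of AK samples.
#' @param n_probes Number of probes on the simulated array.
#' @param n_planted_degs Number of probes given a true expression shift in
#'   L-class tissue; half up-, half down-regulated.
#' @param planted_log2fc Absolute log2 fold change planted at DEG probes.
#' @param patient_effect_sd SD of the per-patient Gaussian intercept (log2
#'   units) shared by that patient's samples.
#' @param noise_sd SD of the i.i.d. Gaussian measurement noise (log2 units).
#' @param baseline_mean,baseline_sd Mean and SD of the per-probe baseline
#'   log2 intensities.
#' @param ak_mixture_weights Numeric vector of length `n_ak` with values in
#'   \[0, 1\]: AK sample j has expected profile
#'   `w_j * L_mean + (1 - w_j) * NL_mean`. The default spreads 12 weights
#'   below 0.5 and 9 above, mirroring the 12 AK_NL / 9 AK_L split of the
#'   original cohort.
#' @param seed Integer seed; the generated cohort is a pure function of the
#'   parameter set including the seed.
#'
#' @return An object of class `cohort_params` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_params <- function(n_ref_patients = 14L,
                          n_test_nl = 9L,
                          n_test_l = 10L,
                          n_ak = 21L,
                          n_probes = 2000L,
                          n_planted_degs = 200L,
                          planted_log2fc = 3.0,
                          patient_effect_sd = 1.0,
                          noise_sd = 0.5,
                          baseline_mean = 7.0,
                          baseline_sd = 1.5,
                          ak_mixture_weights = NULL,
                          seed = 1L) {
  if (is.null(ak_mixture_weights)) {
    n_lo <- ceiling(n_ak * 12 / 21)
    n_hi <- n_ak - n_lo
    ak_mixture_weights <- c(
      if (n_lo > 0) seq(0.05, 0.40, length.out = n_lo),
      if (n_hi > 0) seq(0.60, 0.95, length.out = n_hi)
    )
  }
  p <- list(
    n_ref_patients = as.integer(n_ref_patients),
    n_test_nl = as.integer(n_test_nl),
    n_test_l = as.integer(n_test_l),
    n_ak = as.integer(n_ak),
    n_probes = as.integer(n_probes),
    n_planted_degs = as.integer(n_planted_degs),
    planted_log2fc = as.numeric(planted_log2fc),
    patient_effect_sd = as.numeric(patient_effect_sd),
    noise_sd = as.numeric(noise_sd),
    baseline_mean = as.numeric(baseline_mean),
    baseline_sd = as.numeric(baseline_sd),
    ak_mixture_weights = as.numeric(ak_mixture_weights),
    seed = as.integer(seed)
  )
  counts <- c("n_ref_patients", "n_test_nl", "n_test_l", "n_probes")
  for (nm in counts) {
    if (length(p[[nm]]) != 1L || is.na(p[[nm]]) || p[[nm]] < 1L) {
      stop(sprintf("'%s' must be a single count >= 1", nm), call. = FALSE)
    }
  }
  if (p$n_ak < 0L) stop("'n_ak' must be >= 0", call. = FALSE)
  if (p$n_planted_degs < 0L || p$n_planted_degs > p$n_probes) {
    stop("'n_planted_degs' must lie in [0, n_probes]", call. = FALSE)
  }
  if (length(p$ak_mixture_weights) != p$n_ak) {
    stop(sprintf(
      "'ak_mixture_weights' has length %d but n_ak = %d",
      length(p$ak_mixture_weights), p$n_ak
    ), call. = FALSE)
  }
  if (p$n_ak > 0L && (any(p$ak_mixture_weights < 0) || any(p$ak_mixture_weights > 1))) {
    stop("all mixture weights must lie in [0, 1]", call. = FALSE)
  }
  if (p$patient_effect_sd < 0 || p$noise_sd < 0 || p$baseline_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  structure(p, class = "cohort_params")
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic AK cohort parameters\n")
  cat(sprintf(
    "  reference: %d patients (paired NL + L); test: %d NL + %d L; AK: %d\n",
    x$n_ref_patients, x$n_test_nl, x$n_test_l, x$n_ak
  ))
  cat(sprintf(
    "  probes: %d (%d planted DEGs at |log2FC| = %g)\n",
    x$n_probes, x$n_planted_degs, x$planted_log2fc
  ))
  cat(sprintf(
    "  patient effect SD %g, noise SD %g, seed %d\n",
    x$patient_effect_sd, x$noise_sd, x$seed
  ))
  invisible(x)
}

# Run `expr` under a private RNG stream seeded with `seed`; the caller's
# .Random.seed is untouched.
with_cohort_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic expression cohort with planted ground truth
#'
#' Simulates a probes-by-samples log2 expression matrix with the statistical
#' structure the stratification pipeline assumes:
#' \itemize{
#'   \item Reference patients contribute a paired NL and L sample; both share
#'     an additive per-patient Gaussian intercept, so the paired linear model
#'     has within-patient signal to exploit over the unpaired t-test.
#'   \item A fixed probe subset is planted with a signed `planted_log2fc`
#'     shift in every L-class sample (half up, half down).
#'   \item AK sample j has expected profile
#'     `w_j * L_mean + (1 - w_j) * NL_mean` plus i.i.d. Gaussian noise, where
#'     `L_mean`/`NL_mean` are the noise-free class mean profiles. Its true
#'     subclass is `AK_L` when `w_j >= 0.5`, else `AK_NL`.
#' }
#' All randomness flows through one stream seeded by `params$seed`; identical
#' parameters yield identical cohorts and the caller's RNG state is left
#' untouched.
#'
#' @param params A [cohort_params()] object.
#' @return A list of class `synthetic_cohort`:
#'   \describe{
#'     \item{`expr`}{numeric matrix of log2 intensities, probes x samples,
#'       with probe/sample ids as dimnames.}
#'     \item{`meta`}{data.frame with columns `sample_id`, `patient_id`,
#'       `histology` (`H`/`AK_I`/`AK_II`/`AK_III`/`SCC`), `site_class`
#'       (`NL`/`L`/`AK`) and `group_role` (`reference`/`test`/`ak`).}
#'     \item{`truth`}{list with `planted_degs` (data.frame of probe id and
#'       signed planted log2FC), `ak_true_subclass` (named character vector)
#'       and `ak_mixture_weights`.}
#'     \item{`params`}{the input parameters.}
#'   }
#' @examples
#' cohort <- generate_cohort(cohort_params(seed = 42))
#' dim(cohort$expr)
#' table(cohort$meta$group_role)
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  with_cohort_rng(p$seed, {
    probe_ids <- sprintf("P%05d", seq_len(p$n_probes))

    n_up <- ceiling(p$n_planted_degs / 2)
    planted_idx <- seq_len(p$n_planted_degs)
    planted_sign <- rep(c(1, -1), c(n_up, p$n_planted_degs - n_up))
    planted_shift <- numeric(p$n_probes)
    planted_shift[planted_idx] <- planted_sign * p$planted_log2fc

    baseline <- stats::rnorm(p$n_probes, p$baseline_mean, p$baseline_sd)
    nl_mean <- baseline
    l_mean <- baseline + planted_shift

    ref_patients <- sprintf("RP%02d", seq_len(p$n_ref_patients))
    ref_effect <- stats::rnorm(p$n_ref_patients, 0, p$patient_effect_sd)

    sample_cols <- list()
    meta_rows <- list()
    add_sample <- function(id, patient, histology, site, role, mean_profile,
                           patient_shift) {
      sample_cols[[id]] <<- mean_profile + patient_shift +
        stats::rnorm(p$n_probes, 0, p$noise_sd)
      meta_rows[[id]] <<- data.frame(
        sample_id = id, patient_id = patient, histology = histology,
        site_class = site, group_role = role, stringsAsFactors = FALSE
      )
    }

    for (i in seq_len(p$n_ref_patients)) {
      add_sample(sprintf("REF%02d_NL", i), ref_patients[i], "H", "NL",
                 "reference", nl_mean, ref_effect[i])
      add_sample(sprintf("REF%02d_L", i), ref_patients[i], "SCC", "L",
                 "reference", l_mean, ref_effect[i])
    }
    for (i in seq_len(p$n_test_nl)) {
      add_sample(sprintf("TST%02d_NL", i), sprintf("TPN%02d", i), "H", "NL",
                 "test", nl_mean, stats::rnorm(1, 0, p$patient_effect_sd))
    }
    for (i in seq_len(p$n_test_l)) {
      add_sample(sprintf("TST%02d_L", i), sprintf("TPL%02d", i), "SCC", "L",
                 "test", l_mean, stats::rnorm(1, 0, p$patient_effect_sd))
    }
    ak_grades <- c("AK_I", "AK_II", "AK_III")
    if (p$n_ak > 0L) {
      for (j in seq_len(p$n_ak)) {
        w <- p$ak_mixture_weights[j]
        add_sample(sprintf("AK%02d", j), sprintf("APK%02d", j),
                   ak_grades[(j - 1L) %% 3L + 1L], "AK", "ak",
                   w * l_mean + (1 - w) * nl_mean, 0)
      }
    }

    expr <- do.call(cbind, sample_cols)
    rownames(expr) <- probe_ids
    meta <- do.call(rbind, meta_rows)
    rownames(meta) <- NULL

    ak_ids <- meta$sample_id[meta$group_role == "ak"]
    truth <- list(
      planted_degs = data.frame(
        probe_id = probe_ids[planted_idx],
        planted_log2fc = planted_shift[planted_idx],
        stringsAsFactors = FALSE
      ),
      ak_true_subclass = stats::setNames(
        ifelse(p$ak_mixture_weights >= 0.5, "AK_L", "AK_NL"), ak_ids
      ),
      ak_mixture_weights = stats::setNames(p$ak_mixture_weights, ak_ids)
    )
    structure(
      list(expr = expr, meta = meta, truth = truth, params = p),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic AK cohort: %d probes x %d samples (%d planted DEGs, seed %d)\n",
    nrow(x$expr), ncol(x$expr), nrow(x$truth$planted_degs), x$params$seed
  ))
  print(table(role = x$meta$group_role, site = x$meta$site_class))
  invisible(x)
}
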