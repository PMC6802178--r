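clip <- function(x, range) pmin(pmax(x, range[1L]), range[2L])

patient_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 97911) * 20011 + i * 104729) %% 2147483629)
}

#' Default ground-truth coefficient map for the synthetic cohort
#'
#' Per task, the coefficient of each of the 13 explanatory variables in the
#' latent task ability.  Subfield mTD coefficients are positive (higher mTD =
#' less damage = better functioning), logMAR acuity coefficients negative
#' (higher logMAR = worse acuity).  Age is a pure null variable (all-zero
#' column), so that specificity of the importance analysis is testable.
#' Reading/letter tasks load on the better eye's acuity; ambulation and
#' dining tasks load on lower subfields, dining specifically on the
#' lower-right quadrants.
#'
#' @return 7 x 13 numeric matrix (tasks x variables).
#' @export
default_truth_map <- function() {
  tasks <- c("letters", "sentences", "walking", "going_out", "dining",
             "dressing", "miscellaneous")
  B <- matrix(0, 7L, 13L, dimnames = list(tasks, feature_names()))
  B["letters", "bcva_better"] <- -1
  B["sentences", c("bcva_better", "mtd_inner_lower_right",
                   "mtd_outer_lower_right")] <- c(-0.5, 0.35, 0.35)
  B["walking", c("mtd_inner_lower_left", "mtd_lower")] <- c(0.6, 0.5)
  B["going_out", c("mtd_inner_lower_left", "mtd_inner_lower_right",
                   "mtd_lower")] <- c(0.5, 0.4, 0.4)
  B["dining", c("mtd_inner_lower_right", "mtd_outer_lower_right",
                "mtd_lower")] <- c(0.6, 0.6, 0.3)
  B["dressing", "bcva_better"] <- -1
  B["miscellaneous", c("mtd_lower", "mtd_outer_lower_left",
                       "bcva_better")] <- c(0.5, 0.4, -0.4)
  B
}

#' Synthetic cohort configuration
#'
#' Parameters of the seeded synthetic advanced-glaucoma cohort.  Defaults
#' emulate the scale of the study population without claiming to reproduce
#' it: advanced damage (better-eye MD around -17 dB, worse around -26 dB),
#' an upper-hemifield-dominant loss pattern, relative central sparing,
#' acuity tied to central damage, spatially correlated field noise (shared
#' quadrant- and hemifield-level random effects plus independent point
#' noise), and questionnaire responses generated from a rating-scale Rasch
#' model whose latent task abilities follow `truth_map`.
#'
#' @param n number of patients.
#' @param seed integer master seed; every quantity is reproducible from it.
#' @param age_mean,age_sd,age_range age distribution (years, truncated).
#' @param base_better,base_better_sd,base_worse,base_worse_sd global damage
#'   level (dB) of the better/worse eye.
#' @param central_offset relative central sparing of the 10-2 region (dB).
#' @param upper_offset additional damage of the upper hemifield (dB,
#'   negative = upper worse).
#' @param hemi_sd,eye_hemi_sd patient- and eye-level hemifield effect SDs.
#' @param quadrant_sd SD of the shared quadrant-subfield random effects.
#' @param point_sd independent per-point noise SD (dB).
#' @param visit_sd between-visit shift SD for the two 10-2 assessments.
#' @param td_range truncation range of TD values (dB).
#' @param bcva_intercept,bcva_slope,bcva_noise,bcva_range logMAR acuity
#'   model: `logMAR = intercept + slope * central mTD + noise`, clipped.
#' @param rel_fail_prob probability that a test's reliability indices exceed
#'   an eligibility cap.
#' @param truth_map 7 x 13 coefficient matrix, see [default_truth_map()].
#' @param ability_scale SD (logits) of the systematic part of latent task
#'   ability.
#' @param ability_noise SD (logits) of the residual latent noise.
#' @param delta,tau generating item difficulties (length 30) and rating-scale
#'   thresholds (length 2).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 300L, seed = 1L,
                          age_mean = 62.5, age_sd = 12.2, age_range = c(30, 90),
                          base_better = -17, base_better_sd = 6,
                          base_worse = -26, base_worse_sd = 3,
                          central_offset = 3, upper_offset = -6,
                          hemi_sd = 1.5, eye_hemi_sd = 1,
                          quadrant_sd = 3, point_sd = 2, visit_sd = 1,
                          td_range = c(-35, 5),
                          bcva_intercept = 0.0, bcva_slope = -0.006,
                          bcva_noise = 0.05, bcva_range = c(-0.2, 1.5),
                          rel_fail_prob = 0.01,
                          truth_map = default_truth_map(),
                          ability_scale = 1.5, ability_noise = 0.5,
                          delta = seq(-1.2, 1.2, length.out = 30L),
                          tau = c(-0.8, 0.8)) {
  cfg <- as.list(environment())
  if (!is.numeric(n) || n < 1L) stop("invalid config: n must be >= 1", call. = FALSE)
  cfg$n <- as.integer(n)
  if (!all(dim(truth_map) == c(7L, 13L)) || !all(is.finite(truth_map))) {
    stop("invalid config: truth_map must be a finite 7 x 13 matrix", call. = FALSE)
  }
  if (length(delta) != 30L || length(tau) != 2L ||
      !all(is.finite(c(delta, tau)))) {
    stop("invalid config: need 30 finite item difficulties and 2 thresholds",
         call. = FALSE)
  }
  for (nm in c("age_sd", "base_better_sd", "base_worse_sd", "hemi_sd",
               "eye_hemi_sd", "quadrant_sd", "point_sd", "visit_sd",
               "bcva_noise", "ability_scale", "ability_noise")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0 || !is.finite(cfg[[nm]])) {
      stop("invalid config: ", nm, " must be a finite non-negative number",
           call. = FALSE)
    }
  }
  structure(cfg, class = "cohort_config")
}

rel_draw <- function(cfg) {
  if (stats::runif(1) < cfg$rel_fail_prob) {
    which_bad <- sample(3L, 1L)
    caps <- c(0.20, 0.15, 0.33)
    out <- c(stats::runif(1, 0, 0.15), stats::runif(1, 0, 0.12),
             stats::runif(1, 0, 0.28))
    out[which_bad] <- stats::runif(1, caps[which_bad], min(1, caps[which_bad] + 0.15))
    out
  } else {
    c(stats::runif(1, 0, 0.15), stats::runif(1, 0, 0.12), stats::runif(1, 0, 0.28))
  }
}

#' Simulate one patient's perimetry and clinical record
#'
#' Generates, deterministically from `config$seed` and the patient index,
#' two 10-2 tests and one 24-2 test per eye (total deviations = global eye
#' damage + hemifield and quadrant random effects + point noise, truncated),
#' plus the derived clinical record (age, refraction, IOP, MD per eye, and
#' logMAR acuity tied to the eye's central 10-2 damage).
#'
#' @param config a [cohort_config()].
#' @param patient patient index (1-based).
#' @return A list with `fields` (6 [monocular_field()]s), `clinical`
#'   (one-row data frame) and `tests` (6-row reliability data frame).
#' @export
simulate_fields <- function(config, patient) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(patient_seed(config$seed, patient))
  id <- sprintf("P%04d", patient)
  age <- clip(stats::rnorm(1, config$age_mean, config$age_sd), config$age_range)
  base <- sort(c(stats::rnorm(1, config$base_better, config$base_better_sd),
                 stats::rnorm(1, config$base_worse, config$base_worse_sd)),
               decreasing = TRUE)
  base <- clip(base, c(-33, -5))
  if (stats::runif(1) < 0.5) base <- rev(base)  # which eye is better
  names(base) <- c("OD", "OS")
  # hemifield offsets are centred so the eye's base stays its mean damage
  hemi_p <- c(upper = stats::rnorm(1, config$upper_offset / 2, config$hemi_sd),
              lower = stats::rnorm(1, -config$upper_offset / 2, config$hemi_sd))
  quad_p <- stats::rnorm(8L, 0, config$quadrant_sd)

  grid10 <- vf_grid("10-2")
  labs10 <- as.integer(assign_subfields(grid10))
  up10 <- grid10$y > 0
  fields <- list()
  tests <- list()
  clin <- list(patient_id = id, age = age,
               refraction_od = stats::rnorm(1, -2.8, 4),
               refraction_os = stats::rnorm(1, -2.8, 4),
               iop_od = clip(stats::rnorm(1, 12.8, 2.7), c(5, 30)),
               iop_os = clip(stats::rnorm(1, 12.8, 2.7), c(5, 30)))
  dates <- c(v1 = "2020-03-15", v2 = "2020-09-15", t24 = "2020-05-15")
  for (eye in c("OD", "OS")) {
    hemi_e <- hemi_p + stats::rnorm(2L, 0, config$eye_hemi_sd)
    quad_e <- quad_p + stats::rnorm(8L, 0, config$quadrant_sd / 2)
    region10 <- base[[eye]] + config$central_offset +
      ifelse(up10, hemi_e[1L], hemi_e[2L]) + quad_e[labs10]
    td10 <- lapply(1:2, function(v) {
      clip(region10 + stats::rnorm(1, 0, config$visit_sd) +
             stats::rnorm(length(region10), 0, config$point_sd),
           config$td_range)
    })
    grid24 <- vf_grid("24-2", if (eye == "OD") "right" else "left")
    td24 <- clip(base[[eye]] + ifelse(grid24$y > 0, hemi_e[1L], hemi_e[2L]) +
                   stats::rnorm(nrow(grid24), 0, config$point_sd),
                 config$td_range)
    md_e <- mean(td24)
    inner_mtd <- mean(((td10[[1L]] + td10[[2L]]) / 2)[sqrt(grid10$x^2 + grid10$y^2) <= 5])
    logmar <- clip(config$bcva_intercept + config$bcva_slope * inner_mtd +
                     stats::rnorm(1, 0, config$bcva_noise), config$bcva_range)
    rel <- replicate(3L, rel_draw(config))
    for (v in 1:2) {
      fields[[paste0(eye, "_10_2_v", v)]] <- monocular_field(
        id, eye, "10-2", td10[[v]], date = dates[[v]],
        fl_rate = rel[1L, v], fp_rate = rel[2L, v], fn_rate = rel[3L, v],
        md = mean(td10[[v]]))
    }
    fields[[paste0(eye, "_24_2")]] <- monocular_field(
      id, eye, "24-2", td24, date = dates[["t24"]],
      fl_rate = rel[1L, 3L], fp_rate = rel[2L, 3L], fn_rate = rel[3L, 3L],
      md = md_e)
    clin[[paste0("md_", tolower(eye))]] <- md_e
    clin[[paste0("bcva_logmar_", tolower(eye))]] <- logmar
    clin[[paste0("bcva_", tolower(eye))]] <- 10^(-logmar)
  }
  tests <- do.call(rbind, lapply(fields, function(f) {
    data.frame(patient_id = id, eye = f$eye, pattern = f$pattern,
               date = f$date, fl_rate = f$fl_rate, fp_rate = f$fp_rate,
               fn_rate = f$fn_rate, stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  list(fields = fields, clinical = as.data.frame(clin), tests = tests)
}

#' Simulate questionnaire responses from latent task abilities
#'
#' Latent ability of patient n on task t is the standardised linear
#' combination of the 13 explanatory variables given by `config$truth_map`,
#' scaled to `ability_scale` logits, plus `ability_noise` Gaussian noise.
#' Item responses are then drawn from the rating-scale Rasch model with the
#' configured item difficulties and thresholds, each item using its own
#' task's latent ability.
#'
#' @param config a [cohort_config()].
#' @param features data frame holding the 13 explanatory variables (one row
#'   per patient), e.g. from [simulate_cohort()] or [assemble_features()].
#' @param schema a [vrqol_schema()].
#' @return Integer matrix patients x 30 of categories 0/1/2 with the latent
#'   ability matrix attached as attribute `theta`.
#' @export
simulate_responses <- function(config, features, schema = vrqol_schema()) {
  stopifnot(inherits(config, "cohort_config"))
  X <- as.matrix(as.data.frame(features)[, feature_names(), drop = FALSE])
  B <- config$truth_map
  if (!identical(colnames(B), colnames(X))) {
    stop("truth map columns must match the 13 feature names", call. = FALSE)
  }
  n <- nrow(X)
  set.seed(patient_seed(config$seed, 0L))
  lin <- X %*% t(B)  # n x 7
  z <- apply(lin, 2L, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
  })
  z <- matrix(z, nrow = n)
  theta <- config$ability_scale * z +
    matrix(stats::rnorm(n * 7L, 0, config$ability_noise), n, 7L)
  colnames(theta) <- rownames(B)
  task_of <- match(schema$items$task, rownames(B))
  resp <- matrix(0L, n, 30L, dimnames = list(rownames(X), schema$items$item))
  kappa <- rsm_kappa(config$delta, config$tau)
  for (i in seq_len(30L)) {
    pr <- rasch_probs(theta[, task_of[i]], kappa[i, , drop = FALSE])
    u <- stats::runif(n)
    resp[, i] <- ifelse(u < pr$P0, 0L, ifelse(u < pr$P0 + pr$P1, 1L, 2L))
  }
  ids <- rownames(as.data.frame(features))
  if ("patient_id" %in% names(as.data.frame(features))) {
    ids <- as.data.frame(features)$patient_id
  }
  rownames(resp) <- ids
  attr(resp, "theta") <- theta
  resp
}

#' Assemble the per-patient feature table from integrated fields
#'
#' Computes, per patient, the 8 quadrant-subfield mTDs of the averaged 10-2
#' IVF, the 2 hemifield mTDs of the 24-2 IVF, the better/worse-eye logMAR
#' acuities and age: the 13 explanatory variables of the analysis.
#'
#' @param ivf10 named list (by patient id) of averaged 10-2 `ivf_field`s.
#' @param ivf24 named list (by patient id) of 24-2 `ivf_field`s.
#' @param clinical clinical data frame (needs `patient_id`, `age`,
#'   `bcva_logmar_od`, `bcva_logmar_os`).
#' @param scheme optional 10-2 [subfield_scheme()].
#' @return A [feature_table()] with `patient_id` plus the 13 variables.
#' @export
assemble_features <- function(ivf10, ivf24, clinical, scheme = NULL) {
  ids <- clinical$patient_id
  stopifnot(all(ids %in% names(ivf10)), all(ids %in% names(ivf24)))
  rows <- lapply(ids, function(id) {
    sm10 <- subfield_mtd(ivf10[[id]], scheme)
    sm24 <- subfield_mtd(ivf24[[id]])
    v10 <- stats::setNames(sm10$mtd, paste0("mtd_", gsub(" ", "_", sm10$subfield)))
    v24 <- stats::setNames(sm24$mtd, paste0("mtd_", sm24$subfield))
    as.data.frame(as.list(c(v10, v24)))
  })
  mtds <- do.call(rbind, rows)
  out <- data.frame(patient_id = ids, age = clinical$age,
                    bcva_better = pmin(clinical$bcva_logmar_od,
                                       clinical$bcva_logmar_os),
                    bcva_worse = pmax(clinical$bcva_logmar_od,
                                      clinical$bcva_logmar_os),
                    stringsAsFactors = FALSE)
  feature_table(cbind(out, mtds))
}

#' Simulate a complete seeded cohort
#'
#' Runs the full generator: per-patient fields ([simulate_fields()]),
#' best-location integration and averaging of the two 10-2 assessments,
#' subfield summaries, the feature table, and Rasch-model questionnaire
#' responses driven by the configured truth map.  Identical seeds give
#' identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return A list: `config`, `fields` (flat list of monocular fields),
#'   `clinical`, `tests`, `ivf10`/`ivf24` (named lists of integrated
#'   fields), `features` (a [feature_table()]), `responses` and the latent
#'   `theta` truth matrix.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  pats <- lapply(seq_len(config$n), function(i) simulate_fields(config, i))
  clinical <- do.call(rbind, lapply(pats, `[[`, "clinical"))
  tests <- do.call(rbind, lapply(pats, `[[`, "tests"))
  rownames(clinical) <- rownames(tests) <- NULL
  ivf10 <- list(); ivf24 <- list()
  for (p in pats) {
    f <- p$fields
    id <- p$clinical$patient_id
    ivf10[[id]] <- average_fields(
      integrate_best_location(f$OD_10_2_v1, f$OS_10_2_v1),
      integrate_best_location(f$OD_10_2_v2, f$OS_10_2_v2))
    ivf24[[id]] <- integrate_best_location(f$OD_24_2, f$OS_24_2)
  }
  clinical$mtd_10_2 <- vapply(clinical$patient_id,
                              function(id) mean(ivf10[[id]]$td), numeric(1L))
  clinical$mtd_24_2 <- vapply(clinical$patient_id,
                              function(id) mean(ivf24[[id]]$td), numeric(1L))
  features <- assemble_features(ivf10, ivf24, clinical)
  responses <- simulate_responses(config, features)
  list(config = config,
       fields = unlist(lapply(pats, `[[`, "fields"), recursive = FALSE),
       clinical = clinical, tests = tests, ivf10 = ivf10, ivf24 = ivf24,
       features = features, responses = responses,
       theta = attr(responses, "theta"))
}
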