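#' Eligibility criteria for the advanced-glaucoma cohort
#'
#' Defaults mirror the study's inclusion rules: reproducible mean deviation
#' of at most -20 dB in either eye, decimal best-corrected visual acuity of
#' at least 0.5 (20/40) in both eyes, and reliable fields on every test
#' (fixation loss < 20%, false positives < 15%, false negatives < 33%).
#'
#' @param md_max MD inclusion threshold in dB (eligible if either eye's MD is
#'   `<= md_max`).
#' @param bcva_min minimum decimal BCVA, both eyes.
#' @param fl_max,fp_max,fn_max reliability caps (strict `<`), as fractions.
#' @return A list of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(md_max = -20, bcva_min = 0.5,
                                 fl_max = 0.20, fp_max = 0.15, fn_max = 0.33) {
  stopifnot(is.finite(md_max), is.finite(bcva_min),
            fl_max > 0, fl_max < 1, fp_max > 0, fp_max < 1,
            fn_max > 0, fn_max < 1)
  structure(list(md_max = md_max, bcva_min = bcva_min,
                 fl_max = fl_max, fp_max = fp_max, fn_max = fn_max),
            class = "eligibility_criteria")
}

#' Filter patients by eligibility
#'
#' A patient is eligible iff (MD_od <= threshold or MD_os <= threshold), both
#' decimal BCVAs are at or above the minimum, and every one of the patient's
#' tests passes all three reliability caps.  Excluded patients carry the
#' first failed rule (checked in the order MD, BCVA, reliability).
#'
#' @param clinical data frame with one row per patient: `patient_id`,
#'   `md_od`, `md_os` (dB), `bcva_od`, `bcva_os` (decimal acuity).
#' @param tests data frame with one row per test: `patient_id`, `fl_rate`,
#'   `fp_rate`, `fn_rate` (fractions).
#' @param criteria an [eligibility_criteria()].
#' @return A list with `eligible` (vector of patient ids) and `excluded`
#'   (data frame `patient_id`, `reason`).
#' @export
eligibility_filter <- function(clinical, tests,
                               criteria = eligibility_criteria()) {
  need <- c("patient_id", "md_od", "md_os", "bcva_od", "bcva_os")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) {
    stop("clinical records are missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyNA(clinical[need])) {
    stop("clinical records contain missing values", call. = FALSE)
  }
  needt <- c("patient_id", "fl_rate", "fp_rate", "fn_rate")
  misst <- setdiff(needt, names(tests))
  if (length(misst)) {
    stop("test records are missing field(s): ", paste(misst, collapse = ", "),
         call. = FALSE)
  }
  bad_test <- tests$fl_rate >= criteria$fl_max |
    tests$fp_rate >= criteria$fp_max | tests$fn_rate >= criteria$fn_max
  unreliable <- unique(tests$patient_id[bad_test])

  reason <- rep(NA_character_, nrow(clinical))
  md_ok <- clinical$md_od <= criteria$md_max | clinical$md_os <= criteria$md_max
  bcva_ok <- clinical$bcva_od >= criteria$bcva_min &
    clinical$bcva_os >= criteria$bcva_min
  rel_ok <- !(clinical$patient_id %in% unreliable)
  reason[!rel_ok] <- "reliability"
  reason[!bcva_ok] <- "BCVA"
  reason[!md_ok] <- "MD"
  eligible <- clinical$patient_id[is.na(reason)]
  excluded <- data.frame(patient_id = clinical$patient_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  list(eligible = eligible, excluded = excluded)
}

#' Spearman correlation screen with Bonferroni correction
#'
#' Spearman rank correlations (average ranks for ties) between every
#' explanatory variable and every RADPAI score, with two-sided p-values from
#' the t approximation and a Bonferroni flag at family size
#' variables x responses (13 x 8 = 104 for the default analysis, giving the
#' per-comparison threshold 0.05 / 104 = 0.00048).
#'
#' @param features data frame of explanatory variables (numeric columns).
#' @param abilities data frame of RADPAI scores (numeric columns).
#' @param alpha family-wise level (default 0.05).
#' @return A long data frame of class `correlation_table` with columns
#'   `variable`, `response`, `rho`, `p_value`, `significant`; attributes
#'   `family_size` and `threshold`.
#' @export
spearman_matrix <- function(features, abilities, alpha = 0.05) {
  features <- as.data.frame(features)
  abilities <- as.data.frame(abilities)
  n <- nrow(features)
  stopifnot(nrow(abilities) == n)
  if (n < 10L) stop("correlation screen needs at least 10 complete cases", call. = FALSE)
  family <- ncol(features) * ncol(abilities)
  threshold <- alpha / family
  out <- expand.grid(variable = names(features), response = names(abilities),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rho <- NA_real_; out$p_value <- NA_real_
  for (k in seq_len(nrow(out))) {
    x <- features[[out$variable[k]]]
    y <- abilities[[out$response[k]]]
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
      warning("constant column: rho undefined for ", out$variable[k], " vs ",
              out$response[k], call. = FALSE)
      next
    }
    rho <- stats::cor(rank(x), rank(y))
    out$rho[k] <- rho
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    out$p_value[k] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  out$significant <- !is.na(out$p_value) & out$p_value < threshold
  structure(out, family_size = family, threshold = threshold, n = n,
            class = c("correlation_table", "data.frame"))
}

#' @export
print.correlation_table <- function(x, digits = 3, ...) {
  cat(sprintf("Spearman screen: %d comparisons, Bonferroni threshold p < %.5f\n",
              attr(x, "family_size"), attr(x, "threshold")))
  wide <- stats::reshape(
    data.frame(variable = x$variable, response = x$response,
               cell = ifelse(x$significant, sprintf("%.*f", digits, x$rho), "NS")),
    idvar = "variable", timevar = "response", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA with Scheffe post-hoc contrasts
#'
#' Compares the subfield mTD distributions across groups (the eight 10-2 IVF
#' quadrant subfields in the main analysis): overall F test plus the Scheffe
#' pairwise p-value matrix
#' \eqn{p_{ij} = P\{F_{k-1,N-k} > S_{ij}^2 / (k-1)\}} with
#' \eqn{S_{ij}^2 = (\bar x_i - \bar x_j)^2 / (MSE (1/n_i + 1/n_j))}.
#'
#' @param values numeric vector of observations, or a data frame/matrix whose
#'   columns are the groups.
#' @param groups factor of group labels (ignored when `values` is a data
#'   frame/matrix).
#' @return A list of class `anova_scheffe`: `F`, `df`, `p_value`, `means`,
#'   `scheffe` (pairwise p matrix).
#' @export
anova_scheffe <- function(values, groups = NULL) {
  if (is.matrix(values) || is.data.frame(values)) {
    d <- as.data.frame(values)
    groups <- factor(rep(names(d), each = nrow(d)), levels = names(d))
    values <- unlist(d, use.names = FALSE)
  } else {
    groups <- factor(groups)
  }
  cnt <- table(groups)
  if (length(cnt) < 2L || any(cnt < 2L)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  k <- length(cnt); N <- length(values)
  mse <- tab["Residuals", "Mean Sq"]
  means <- tapply(values, groups, mean)
  Fstat <- tab[1L, "F value"]
  scheffe <- matrix(NA_real_, k, k, dimnames = list(names(cnt), names(cnt)))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      s2 <- (means[i] - means[j])^2 / (mse * (1 / cnt[i] + 1 / cnt[j]))
      p <- stats::pf(s2 / (k - 1), k - 1, N - k, lower.tail = FALSE)
      scheffe[i, j] <- scheffe[j, i] <- p
    }
  }
  structure(list(F = unname(Fstat), df = c(k - 1L, N - k),
                 p_value = unname(tab[1L, "Pr(>F)"]),
                 means = means, mse = unname(mse), scheffe = scheffe),
            class = "anova_scheffe")
}

#' @export
print.anova_scheffe <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p_value))
  cat("group means:\n"); print(round(x$means, 2))
  invisible(x)
}

#' Paired t-test on hemifield damage
#'
#' Classical two-sided paired t-test, used to compare upper versus lower
#' 24-2 IVF hemifield mTDs across patients.
#'
#' @param upper,lower paired numeric vectors (same patients).
#' @return A list of class `paired_t`: `t`, `df`, `p_value`, `mean_diff`
#'   (upper minus lower).
#' @export
paired_t <- function(upper, lower) {
  stopifnot(length(upper) == length(lower), length(upper) >= 2L)
  d <- upper - lower
  if (stats::sd(d) < 1e-12) {
    if (all(abs(d) < 1e-12)) {
      return(structure(list(t = 0, df = length(d) - 1L, p_value = 1,
                            mean_diff = 0), class = "paired_t"))
    }
    stop("degenerate: zero variance of paired differences", call. = FALSE)
  }
  ht <- stats::t.test(upper, lower, paired = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_diff = unname(ht$estimate)),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("paired t-test: t(%d) = %.3f, p = %.3g, mean difference %.2f\n",
              x$df, x$t, x$p_value, x$mean_diff))
  invisible(x)
}

#' Assign the better and worse eye
#'
#' Better eye = lower logMAR BCVA; ties broken by higher (less damaged) MD,
#' then OD.
#'
#' @param bcva_od,bcva_os logMAR acuities.
#' @param md_od,md_os mean deviations (dB), used for ties.
#' @return Character vector `"OD"`/`"OS"` naming the better eye.
#' @export
better_eye <- function(bcva_od, bcva_os, md_od = NULL, md_os = NULL) {
  out <- ifelse(bcva_od < bcva_os, "OD",
                ifelse(bcva_od > bcva_os, "OS", NA))
  tie <- is.na(out)
  if (any(tie)) {
    if (!is.null(md_od) && !is.null(md_os)) {
      out[tie] <- ifelse(md_od[tie] >= md_os[tie], "OD", "OS")
    } else {
      out[tie] <- "OD"
    }
  }
  out
}

#' Cohort descriptive summary (mean and SD per variable)
#'
#' Demographics-table-shaped summary: age, refraction, IOP, MD and BCVA of
#' the better and worse eye (better eye = lower logMAR, ties by higher MD
#' then OD), and whole-field IVF mean TDs when supplied.
#'
#' @param clinical data frame with `age`, `bcva_logmar_od`, `bcva_logmar_os`,
#'   `md_od`, `md_os`, optionally `refraction_od`, `refraction_os`, `iop_od`,
#'   `iop_os`, `mtd_10_2`, `mtd_24_2`.
#' @return Data frame `variable`, `mean`, `sd` (SD 0 for a single patient).
#' @export
descriptives <- function(clinical) {
  be <- better_eye(clinical$bcva_logmar_od, clinical$bcva_logmar_os,
                   clinical$md_od, clinical$md_os)
  pick <- function(od, os, better) ifelse(be == (if (better) "OD" else "OS"), od, os)
  rows <- list(age = clinical$age,
               `MD of better eye (dB)` = pick(clinical$md_od, clinical$md_os, TRUE),
               `MD of worse eye (dB)` = pick(clinical$md_od, clinical$md_os, FALSE),
               `BCVA in better eye (logMAR)` =
                 pick(clinical$bcva_logmar_od, clinical$bcva_logmar_os, TRUE),
               `BCVA in worse eye (logMAR)` =
                 pick(clinical$bcva_logmar_od, clinical$bcva_logmar_os, FALSE))
  if (all(c("refraction_od", "refraction_os") %in% names(clinical))) {
    rows[["refraction of better eye (D)"]] <-
      pick(clinical$refraction_od, clinical$refraction_os, TRUE)
    rows[["refraction of worse eye (D)"]] <-
      pick(clinical$refraction_od, clinical$refraction_os, FALSE)
  }
  if (all(c("iop_od", "iop_os") %in% names(clinical))) {
    rows[["IOP of better eye (mmHg)"]] <- pick(clinical$iop_od, clinical$iop_os, TRUE)
    rows[["IOP of worse eye (mmHg)"]] <- pick(clinical$iop_od, clinical$iop_os, FALSE)
  }
  for (nm in c("mtd_10_2", "mtd_24_2")) {
    if (nm %in% names(clinical)) {
      rows[[paste("mean TD of", sub("mtd_", "", nm), "IVF (dB)")]] <- clinical[[nm]]
    }
  }
  sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)
  data.frame(variable = names(rows),
             mean = vapply(rows, mean, numeric(1L)),
             sd = vapply(rows, sd0, numeric(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}
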