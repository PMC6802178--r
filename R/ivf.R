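#' Monocular total-deviation field
#'
#' Container for one eye's Humphrey test: per-point total deviation (TD, dB;
#' the difference between measured sensitivity and the age-corrected normal),
#' reliability indices and mean deviation.  TD must be supplied for every
#' point of the pattern's grid, in the grid's row order (or as a data frame
#' with `x`, `y`, `td` columns, which is re-ordered to the grid).
#'
#' @param patient_id scalar identifier.
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @param pattern `"10-2"` or `"24-2"`.
#' @param td numeric vector of TD values aligned with [vf_grid()] rows, or a
#'   data frame with columns `x`, `y`, `td`.
#' @param date test date (anything coercible by [as.Date()]; optional).
#' @param fl_rate,fp_rate,fn_rate fixation-loss, false-positive and
#'   false-negative rates as fractions in \[0, 1\].
#' @param md mean deviation (dB); defaults to the unweighted mean TD.
#' @return An object of class `vf_field`.
#' @export
monocular_field <- function(patient_id, eye = c("OD", "OS"),
                            pattern = c("10-2", "24-2"), td,
                            date = NA, fl_rate = 0, fp_rate = 0, fn_rate = 0,
                            md = NULL) {
  eye <- match.arg(eye)
  pattern <- as.character(pattern)[1L]
  grid <- vf_grid(pattern, laterality = if (pattern == "24-2") {
    if (eye == "OD") "right" else "left"
  } else "none")
  if (is.data.frame(td)) {
    stopifnot(all(c("x", "y", "td") %in% names(td)))
    i <- match(paste(grid$x, grid$y), paste(td$x, td$y))
    if (anyNA(i)) {
      stop("incomplete field: TD missing for ", sum(is.na(i)),
           " grid point(s)", call. = FALSE)
    }
    td <- td$td[i]
  }
  td <- as.numeric(td)
  if (length(td) != nrow(grid) || !all(is.finite(td))) {
    stop("incomplete field: need one finite TD value per grid point (",
         nrow(grid), " for ", pattern, ")", call. = FALSE)
  }
  rates <- c(fl_rate = fl_rate, fp_rate = fp_rate, fn_rate = fn_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("reliability rates must be fractions in [0, 1]", call. = FALSE)
  }
  structure(list(patient_id = patient_id, eye = eye, pattern = pattern,
                 date = date, grid = grid, td = td,
                 fl_rate = unname(fl_rate), fp_rate = unname(fp_rate),
                 fn_rate = unname(fn_rate),
                 md = if (is.null(md)) mean(td) else as.numeric(md)),
            class = "vf_field")
}

#' @export
print.vf_field <- function(x, ...) {
  cat(sprintf("%s field, patient %s, eye %s: mean TD %.1f dB (MD %.1f dB)\n",
              x$pattern, x$patient_id, x$eye, mean(x$td), x$md))
  invisible(x)
}

new_ivf_field <- function(patient_id, pattern, grid, td, model) {
  structure(list(patient_id = patient_id, pattern = pattern,
                 grid = grid, td = td, model = model),
            class = "ivf_field")
}

#' @export
print.ivf_field <- function(x, ...) {
  cat(sprintf("binocular IVF (%s model), patient %s, %s: %d points, mean TD %.1f dB\n",
              x$model, x$patient_id, x$pattern, length(x$td), mean(x$td)))
  invisible(x)
}

check_integrable <- function(field_od, field_os) {
  if (!inherits(field_od, "vf_field") || !inherits(field_os, "vf_field")) {
    stop("integration error: inputs must be monocular vf_field objects",
         call. = FALSE)
  }
  if (!identical(field_od$pattern, field_os$pattern)) {
    stop("integration error: pattern mismatch (", field_od$pattern, " vs ",
         field_os$pattern, ")", call. = FALSE)
  }
  if (!identical(field_od$patient_id, field_os$patient_id)) {
    stop("integration error: patient mismatch", call. = FALSE)
  }
}

integrate_fields <- function(field_od, field_os, combine, model) {
  check_integrable(field_od, field_os)
  cp <- corresponding_points(field_od$grid, field_os$grid)
  x <- c(cp$pairs$x, field_od$grid$x[cp$unmatched_od],
         field_os$grid$x[cp$unmatched_os])
  y <- c(cp$pairs$y, field_od$grid$y[cp$unmatched_od],
         field_os$grid$y[cp$unmatched_os])
  # matched points are combined; nasal-step points (24-2) keep the single
  # available eye's value
  td <- c(combine(field_od$td[cp$pairs$i_od], field_os$td[cp$pairs$i_os]),
          field_od$td[cp$unmatched_od], field_os$td[cp$unmatched_os])
  o <- order(-y, x)
  grid <- structure(data.frame(x = x[o], y = y[o]),
                    pattern = field_od$pattern, laterality = "none",
                    class = c("vf_grid", "data.frame"))
  rownames(grid) <- NULL
  new_ivf_field(field_od$patient_id, field_od$pattern, grid, td[o], model)
}

#' Best-location binocular integration
#'
#' Combines the two eyes' total-deviation maps into a binocular integrated
#' visual field (IVF) by recording, at each pair of corresponding locations,
#' the better (maximum) TD of the two eyes.  24-2 nasal-step points, which
#' have no fellow-eye counterpart, carry the single eye's value.
#'
#' @param field_od,field_os [monocular_field()] objects for the right and
#'   left eye: same patient, same pattern, complete TD maps.
#' @return An `ivf_field` with `model = "best_location"`.
#' @examples
#' g <- vf_grid("10-2")
#' od <- monocular_field("p1", "OD", "10-2", rep(-5, 68))
#' os <- monocular_field("p1", "OS", "10-2", rep(-12, 68))
#' all(integrate_best_location(od, os)$td == -5)
#' @export
integrate_best_location <- function(field_od, field_os) {
  integrate_fields(field_od, field_os, pmax, "best_location")
}

#' Quadratic binocular-summation integration
#'
#' Alternative binocular model: TDs are linearised to relative sensitivities
#' \eqn{s = 10^{TD/10}}, combined by quadratic summation
#' \eqn{(s_{OD}^2 + s_{OS}^2)^{1/2}}, and re-expressed in dB.  Two equal
#' inputs therefore gain \eqn{10\log_{10}\sqrt{2} \approx 1.5} dB over either
#' eye, and the combined value never falls below the better eye.
#'
#' @inheritParams integrate_best_location
#' @return An `ivf_field` with `model = "binocular_summation"`.
#' @export
integrate_binocular_summation <- function(field_od, field_os) {
  combine <- function(a, b) 10 * log10(sqrt(10^(a / 5) + 10^(b / 5)))
  integrate_fields(field_od, field_os, combine, "binocular_summation")
}

#' Average two integrated fields point by point
#'
#' Used to average the two 10-2 IVF assessments taken around the VRQoL
#' interview date.  Fields must agree in patient, pattern and model; values
#' are averaged per location in double precision.
#'
#' @param f1,f2 `ivf_field` objects.
#' @return An `ivf_field` of per-point means.
#' @export
average_fields <- function(f1, f2) {
  if (!inherits(f1, "ivf_field") || !inherits(f2, "ivf_field")) {
    stop("averaging error: inputs must be ivf_field objects", call. = FALSE)
  }
  if (!identical(f1$pattern, f2$pattern) ||
      !identical(f1$patient_id, f2$patient_id) ||
      !identical(f1$model, f2$model)) {
    stop("averaging error: fields differ in pattern, patient or model",
         call. = FALSE)
  }
  i <- match(paste(f1$grid$x, f1$grid$y), paste(f2$grid$x, f2$grid$y))
  if (anyNA(i)) stop("averaging error: grids do not match", call. = FALSE)
  new_ivf_field(f1$patient_id, f1$pattern, f1$grid,
                (f1$td + f2$td[i]) / 2, f1$model)
}

#' Subfield mean total deviations
#'
#' Arithmetic mean TD per subfield label of a binocular IVF (the mTD), plus
#' the whole-field mean as an attribute.  This is the damage summary the
#' downstream correlation screen and random forest consume.
#'
#' @param ivf an `ivf_field` (or a [monocular_field()]).
#' @param scheme a [subfield_scheme()] compatible with the field's pattern;
#'   defaults to the pattern's default scheme (8 quadrant subfields for 10-2
#'   with a 5-degree inner/outer boundary; upper/lower hemifields for 24-2).
#' @return A data frame of class `subfield_summary` with columns `subfield`,
#'   `n`, `mtd`, and attribute `overall` (whole-field mean TD).
#' @export
subfield_mtd <- function(ivf, scheme = NULL) {
  if (!inherits(ivf, c("ivf_field", "vf_field"))) {
    stop("'ivf' must be an ivf_field or vf_field", call. = FALSE)
  }
  lab <- assign_subfields(ivf$grid, scheme)
  mtd <- tapply(ivf$td, lab, mean)
  n <- as.integer(table(lab))
  out <- data.frame(subfield = levels(lab), n = n,
                    mtd = as.numeric(mtd[levels(lab)]))
  rownames(out) <- NULL
  structure(out, overall = mean(ivf$td),
            class = c("subfield_summary", "data.frame"))
}

#' @export
print.subfield_summary <- function(x, digits = 1, ...) {
  cat("subfield mean total deviations (dB):\n")
  print(data.frame(subfield = x$subfield, n = x$n, mtd = round(x$mtd, digits)))
  cat(sprintf("whole field: %.1f dB\n", attr(x, "overall")))
  invisible(x)
}

#' Read monocular fields from a long-format CSV
#'
#' Expected columns: `patient_id, eye, date, pattern, x_deg, y_deg, td_db,
#' fl_rate, fp_rate, fn_rate, md_db` (one row per test point; reliability and
#' MD constant within a test).  One test = one `patient_id` x `eye` x
#' `pattern` x `date` combination.
#'
#' @param path CSV file path.
#' @return A list of [monocular_field()] objects.
#' @export
read_fields_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "eye", "date", "pattern", "x_deg", "y_deg", "td_db",
            "fl_rate", "fp_rate", "fn_rate", "md_db")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("fields CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  date_key <- ifelse(is.na(d$date), "", as.character(d$date))
  key <- interaction(d$patient_id, d$eye, d$pattern, date_key, drop = TRUE)
  lapply(split(d, key), function(g) {
    monocular_field(g$patient_id[1L], g$eye[1L], g$pattern[1L],
                    data.frame(x = g$x_deg, y = g$y_deg, td = g$td_db),
                    date = g$date[1L], fl_rate = g$fl_rate[1L],
                    fp_rate = g$fp_rate[1L], fn_rate = g$fn_rate[1L],
                    md = g$md_db[1L])
  })
}

#' Write monocular fields to a long-format CSV
#'
#' Inverse of [read_fields_csv()].
#'
#' @param fields list of [monocular_field()] objects.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_fields_csv <- function(fields, path) {
  rows <- lapply(fields, function(f) {
    data.frame(patient_id = f$patient_id, eye = f$eye, date = f$date,
               pattern = f$pattern, x_deg = f$grid$x, y_deg = f$grid$y,
               td_db = f$td, fl_rate = f$fl_rate, fp_rate = f$fp_rate,
               fn_rate = f$fn_rate, md_db = f$md)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
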