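#' Humphrey test-point grid
#'
#' Generate the test-point layout of a Humphrey Field Analyzer pattern in
#' visual-space coordinates (degrees of eccentricity; positive x = right of
#' fixation, positive y = superior).  The 10-2 pattern covers the central 10
#' degrees with 68 points spaced 2 degrees apart (odd-integer coordinates with
#' \eqn{x^2 + y^2 \le 82}); the 24-2 pattern has 54 points spaced 6 degrees
#' apart, including two nasal-step points at 27 degrees eccentricity on the
#' nasal side of the tested eye.  Both eyes are expressed in visual-space
#' (field) coordinates, so corresponding points of the two eyes share
#' coordinates and no retinal flip is ever applied.
#'
#' @param pattern `"10-2"` or `"24-2"`.
#' @param laterality `"right"`, `"left"` or `"none"`; which eye the grid is
#'   for.  Required for 24-2 because the two nasal-step points sit on the
#'   nasal side (negative x for a right eye, positive x for a left eye).
#' @return A data frame of class `vf_grid` with columns `x` and `y` (degrees)
#'   and attributes `pattern` and `laterality`.
#' @examples
#' nrow(vf_grid("10-2"))           # 68
#' nrow(vf_grid("24-2", "right"))  # 54
#' @export
vf_grid <- function(pattern = c("10-2", "24-2"),
                    laterality = c("none", "right", "left")) {
  pattern <- as.character(pattern)[1L]
  if (!pattern %in% c("10-2", "24-2")) {
    stop("unsupported pattern: '", pattern, "' (use \"10-2\" or \"24-2\")",
         call. = FALSE)
  }
  laterality <- match.arg(laterality)
  key <- paste(pattern, laterality)
  cached <- .grid_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (pattern == "10-2") {
    odd <- seq(-9L, 9L, by = 2L)
    pts <- expand.grid(x = odd, y = odd, KEEP.OUT.ATTRS = FALSE)
    pts <- pts[pts$x^2 + pts$y^2 <= 82, , drop = FALSE]
  } else {
    if (laterality == "none") {
      stop("laterality (\"right\" or \"left\") is required for the 24-2 pattern",
           call. = FALSE)
    }
    # half-row widths by |y|; the 24-2 core is 52 points
    half <- list(`21` = c(3L, 9L),
                 `15` = c(3L, 9L, 15L),
                 `9`  = c(3L, 9L, 15L, 21L),
                 `3`  = c(3L, 9L, 15L, 21L))
    rows <- lapply(c(21L, 15L, 9L, 3L, -3L, -9L, -15L, -21L), function(yy) {
      ax <- half[[as.character(abs(yy))]]
      data.frame(x = c(-rev(ax), ax), y = yy)
    })
    pts <- do.call(rbind, rows)
    nasal_x <- if (laterality == "right") -27L else 27L
    pts <- rbind(pts, data.frame(x = c(nasal_x, nasal_x), y = c(3L, -3L)))
  }
  # reading order: top row first, left to right
  pts <- pts[order(-pts$y, pts$x), , drop = FALSE]
  rownames(pts) <- NULL
  out <- structure(pts, pattern = pattern, laterality = laterality,
                   class = c("vf_grid", "data.frame"))
  .grid_cache[[key]] <- out
  out
}

# the grids are tiny and immutable; cache them per pattern/laterality
.grid_cache <- new.env(parent = emptyenv())

#' @export
print.vf_grid <- function(x, ...) {
  cat(sprintf("Humphrey %s test-point grid: %d points (laterality: %s)\n",
              attr(x, "pattern"), nrow(x), attr(x, "laterality")))
  invisible(x)
}

#' Subfield labelling scheme
#'
#' Defines how grid points are partitioned into subfields.  For the 10-2
#' pattern the central field is split into eight quadrant subfields: the four
#' quadrants (upper/lower x right/left), each divided into an inner part
#' within `boundary` degrees of fixation and an outer part beyond it.  For
#' the 24-2 pattern the field is split into upper and lower hemifields.
#'
#' @param pattern `"10-2"` or `"24-2"`.
#' @param boundary inner/outer split radius in degrees (10-2 only).  Points at
#'   exactly the boundary eccentricity count as inner; no default-grid point
#'   sits at exactly 5 degrees, so the tie rule is inert for the default.
#' @param metric eccentricity metric for the inner/outer split: `"euclidean"`
#'   (\eqn{\sqrt{x^2+y^2}}) or `"chebyshev"` (\eqn{\max(|x|,|y|)}).
#' @return A list of class `subfield_scheme`.
#' @export
subfield_scheme <- function(pattern = c("10-2", "24-2"), boundary = 5,
                            metric = c("euclidean", "chebyshev")) {
  pattern <- as.character(pattern)[1L]
  if (!pattern %in% c("10-2", "24-2")) {
    stop("unsupported pattern: '", pattern, "'", call. = FALSE)
  }
  metric <- match.arg(metric)
  stopifnot(is.numeric(boundary), length(boundary) == 1L,
            is.finite(boundary), boundary > 0)
  labels <- if (pattern == "10-2") {
    as.vector(outer(c("inner", "outer"),
                    c("upper right", "upper left", "lower left", "lower right"),
                    paste))
  } else {
    c("upper", "lower")
  }
  structure(list(pattern = pattern, boundary = boundary, metric = metric,
                 labels = labels),
            class = "subfield_scheme")
}

#' @export
print.subfield_scheme <- function(x, ...) {
  cat(sprintf("subfield scheme for %s: %s\n", x$pattern,
              paste(x$labels, collapse = ", ")))
  if (x$pattern == "10-2") {
    cat(sprintf("  inner/outer boundary: %g degrees (%s eccentricity)\n",
                x$boundary, x$metric))
  }
  invisible(x)
}

#' Assign every grid point to its subfield
#'
#' Total partition of the grid: each 10-2 point gets one of the eight
#' quadrant-subfield labels (`"inner lower right"`, ...), each 24-2 point
#' `"upper"` or `"lower"`.  No test point lies on an axis, so quadrant and
#' hemifield membership is never tied.
#'
#' @param grid a [vf_grid()] (or any data frame with `x`, `y` columns and a
#'   `pattern` attribute).
#' @param scheme a [subfield_scheme()] for the same pattern.
#' @return A factor of subfield labels, one per grid point, with levels in the
#'   scheme's canonical order.
#' @export
assign_subfields <- function(grid, scheme = NULL) {
  pattern <- attr(grid, "pattern")
  if (is.null(pattern)) stop("grid carries no 'pattern' attribute", call. = FALSE)
  if (is.null(scheme)) scheme <- subfield_scheme(pattern)
  if (!inherits(scheme, "subfield_scheme")) {
    stop("'scheme' must be a subfield_scheme", call. = FALSE)
  }
  if (!identical(scheme$pattern, pattern)) {
    stop("incompatible scheme: scheme is for ", scheme$pattern,
         " but grid is ", pattern, call. = FALSE)
  }
  x <- grid$x
  y <- grid$y
  if (any(x == 0 | y == 0)) {
    stop("grid has points on an axis; subfield assignment would be ambiguous",
         call. = FALSE)
  }
  if (pattern == "24-2") {
    lab <- ifelse(y > 0, "upper", "lower")
  } else {
    ecc <- if (scheme$metric == "euclidean") sqrt(x^2 + y^2) else pmax(abs(x), abs(y))
    ring <- ifelse(ecc <= scheme$boundary, "inner", "outer")
    quad <- ifelse(y > 0,
                   ifelse(x > 0, "upper right", "upper left"),
                   ifelse(x > 0, "lower right", "lower left"))
    lab <- paste(ring, quad)
  }
  factor(lab, levels = scheme$labels)
}

#' Match corresponding test points between the two eyes
#'
#' Points are matched by identical visual-space coordinates.  Two 10-2 grids
#' match completely (68 pairs); right- and left-eye 24-2 grids share the
#' 52-point core and each eye keeps its 2 nasal-step points unmatched (they
#' mirror between eyes).
#'
#' @param grid_od,grid_os [vf_grid()] objects of the same pattern.
#' @return A list with `pairs` (data frame `x`, `y`, `i_od`, `i_os`: row
#'   indices into each grid) and integer vectors `unmatched_od`,
#'   `unmatched_os`.
#' @export
corresponding_points <- function(grid_od, grid_os) {
  p1 <- attr(grid_od, "pattern"); p2 <- attr(grid_os, "pattern")
  if (is.null(p1) || is.null(p2) || !identical(p1, p2)) {
    stop("incompatible grids: patterns differ (", p1, " vs ", p2, ")",
         call. = FALSE)
  }
  key_od <- paste(grid_od$x, grid_od$y)
  key_os <- paste(grid_os$x, grid_os$y)
  i_os <- match(key_od, key_os)
  matched <- !is.na(i_os)
  pairs <- data.frame(x = grid_od$x[matched], y = grid_od$y[matched],
                      i_od = which(matched), i_os = i_os[matched])
  list(pairs = pairs,
       unmatched_od = which(!matched),
       unmatched_os = which(!(key_os %in% key_od)))
}

#' Export a grid with its subfield labels
#'
#' Writes `pattern, x_deg, y_deg, subfield` as CSV or JSON.
#'
#' @param grid a [vf_grid()].
#' @param path output file; format chosen by extension (`.json` for JSON,
#'   otherwise CSV).
#' @param scheme optional [subfield_scheme()]; defaults to the pattern's
#'   default scheme.
#' @return The exported data frame, invisibly.
#' @export
write_grid <- function(grid, path, scheme = NULL) {
  out <- data.frame(pattern = attr(grid, "pattern"),
                    x_deg = grid$x, y_deg = grid$y,
                    subfield = as.character(assign_subfields(grid, scheme)))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, dataframe = "rows", pretty = TRUE)
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(out)
}
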