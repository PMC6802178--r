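test_that("10-2 grid is the 68-point central layout with 2-degree spacing", {
  g <- vf_grid("10-2")
  expect_s3_class(g, "vf_grid")
  expect_identical(nrow(g), 68L)
  expect_true(all(abs(g$x) %% 2 == 1))     # odd coordinates
  expect_true(all(abs(g$y) %% 2 == 1))
  expect_true(all(g$x^2 + g$y^2 <= 82))
  expect_true(all(abs(g$x) <= 9 & abs(g$y) <= 9))
  expect_false(anyDuplicated(paste(g$x, g$y)) > 0)
  # closed under each single sign flip and under the point reflection
  key <- sort(paste(g$x, g$y))
  expect_identical(sort(paste(-g$x, g$y)), key)
  expect_identical(sort(paste(g$x, -g$y)), key)
  expect_identical(sort(paste(-g$x, -g$y)), key)
})

test_that("24-2 grid has 54 points with laterality-dependent nasal step", {
  gr <- vf_grid("24-2", "right")
  gl <- vf_grid("24-2", "left")
  expect_identical(nrow(gr), 54L)
  expect_identical(nrow(gl), 54L)
  # nasal step: 27 degrees on the nasal side (left in visual space for OD)
  expect_identical(sort(gr$y[abs(gr$x) == 27]), c(-3L, 3L))
  expect_true(all(gr$x[abs(gr$x) == 27] == -27))
  expect_true(all(gl$x[abs(gl$x) == 27] == 27))
  # core closed under point reflection except the nasal step
  core <- gr[abs(gr$x) < 27, ]
  expect_setequal(paste(-core$x, -core$y), paste(core$x, core$y))
  # 12 points within 10 degrees of fixation
  expect_identical(sum(sqrt(gr$x^2 + gr$y^2) <= 10), 12L)
  # no point on an axis for either pattern
  expect_true(all(gr$x != 0 & gr$y != 0))
})

test_that("grid generation rejects bad inputs", {
  expect_error(vf_grid("30-2"), "unsupported pattern")
  expect_error(vf_grid("24-2"), "laterality")
  expect_error(vf_grid("24-2", "none"), "laterality")
})

test_that("default 10-2 subfields partition into 4 inner / 13 outer per quadrant", {
  g <- vf_grid("10-2")
  lab <- assign_subfields(g)
  expect_false(anyNA(lab))                 # total mapping
  expect_identical(length(lab), nrow(g))   # partition: one label per point
  cnt <- table(lab)
  expect_true(all(cnt[grep("^inner", names(cnt))] == 4L))
  expect_true(all(cnt[grep("^outer", names(cnt))] == 13L))
  # brute-force enumeration oracle for the inner sets
  inner_oracle <- sqrt(g$x^2 + g$y^2) <= 5
  expect_identical(grepl("^inner", as.character(lab)), inner_oracle)
  # spot checks
  i1 <- which(g$x == 1 & g$y == -1)
  expect_identical(as.character(lab[i1]), "inner lower right")
  i2 <- which(g$x == -7 & g$y == 5)
  expect_identical(as.character(lab[i2]), "outer upper left")
})

test_that("inner + outer counts per quadrant sum to 17 for any boundary in (0, 10)", {
  g <- vf_grid("10-2")
  for (b in c(0.5, 2, 5, 7.2, 9.9)) {
    lab <- assign_subfields(g, subfield_scheme("10-2", boundary = b))
    quad <- sub("^(inner|outer) ", "", as.character(lab))
    expect_true(all(table(quad) == 17L), info = paste("boundary", b))
  }
})

test_that("chebyshev eccentricity metric matches its enumeration oracle", {
  g <- vf_grid("10-2")
  lab <- assign_subfields(g, subfield_scheme("10-2", metric = "chebyshev"))
  oracle <- pmax(abs(g$x), abs(g$y)) <= 5
  expect_identical(grepl("^inner", as.character(lab)), oracle)
  expect_identical(sum(oracle), 36L)  # 9 per quadrant for |x|,|y| in {1,3,5}
})

test_that("24-2 hemifield labels split 27/27 and schemes must match the pattern", {
  g <- vf_grid("24-2", "left")
  lab <- assign_subfields(g)
  expect_identical(as.integer(table(lab)), c(27L, 27L))
  expect_identical(as.character(lab), ifelse(g$y > 0, "upper", "lower"))
  expect_error(assign_subfields(g, subfield_scheme("10-2")), "incompatible scheme")
})

test_that("corresponding points match 10-2 fully and leave 24-2 nasal steps unmatched", {
  g <- vf_grid("10-2")
  cp <- corresponding_points(g, g)
  expect_identical(nrow(cp$pairs), 68L)
  expect_length(cp$unmatched_od, 0L)
  expect_identical(cp$pairs$i_od, cp$pairs$i_os)  # identity pairing

  gr <- vf_grid("24-2", "right"); gl <- vf_grid("24-2", "left")
  cp24 <- corresponding_points(gr, gl)
  expect_identical(nrow(cp24$pairs), 52L)
  expect_length(cp24$unmatched_od, 2L)
  expect_length(cp24$unmatched_os, 2L)
  expect_true(all(abs(gr$x[cp24$unmatched_od]) == 27))
  expect_error(corresponding_points(g, gr), "incompatible")
})

test_that("grid export writes pattern, coordinates and subfield labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_grid(vf_grid("10-2"), path)
  got <- read.csv(path)
  expect_identical(nrow(got), 68L)
  expect_named(got, c("pattern", "x_deg", "y_deg", "subfield"))
  expect_identical(sort(unique(got$subfield)),
                   sort(subfield_scheme("10-2")$labels))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_grid(vf_grid("24-2", "left"), jpath)
  expect_identical(length(jsonlite::read_json(jpath)), 54L)
})
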