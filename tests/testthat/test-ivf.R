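test_that("best-location integration takes the per-point maximum (oracle check)", {
  set.seed(101)
  for (r in 1:20) {
    od <- random_field(eye = "OD")
    os <- random_field(eye = "OS")
    ivf <- integrate_best_location(od, os)
    expect_identical(ivf$model, "best_location")
    # independent per-point oracle: match by coordinates, take max
    key <- paste(ivf$grid$x, ivf$grid$y)
    oracle <- pmax(od$td[match(key, paste(od$grid$x, od$grid$y))],
                   os$td[match(key, paste(os$grid$x, os$grid$y))])
    expect_equal(ivf$td, oracle)
  }
})

test_that("best-location is symmetric, dominant and idempotent on equal fields", {
  set.seed(7)
  od <- random_field(eye = "OD")
  os <- random_field(eye = "OS")
  a <- integrate_best_location(od, os)
  b <- integrate_best_location(os, od)
  expect_equal(a$td[order(a$grid$x, a$grid$y)], b$td[order(b$grid$x, b$grid$y)])
  expect_true(all(a$td >= od$td) && all(a$td >= os$td))
  same <- monocular_field("p1", "OS", "10-2", od$td)
  expect_equal(integrate_best_location(od, same)$td, od$td)
  # -5 vs -12 keeps -5
  f1 <- monocular_field("p1", "OD", "10-2", rep(-5, 68))
  f2 <- monocular_field("p1", "OS", "10-2", rep(-12, 68))
  expect_true(all(integrate_best_location(f1, f2)$td == -5))
})

test_that("24-2 nasal-step points carry the single eye's value through integration", {
  set.seed(11)
  od <- random_field(eye = "OD", pattern = "24-2")
  os <- random_field(eye = "OS", pattern = "24-2")
  ivf <- integrate_best_location(od, os)
  expect_identical(length(ivf$td), 56L)  # 52 shared + 2 nasal per eye
  i_od <- ivf$grid$x == -27
  expect_equal(ivf$td[i_od],
               od$td[match(paste(ivf$grid$x[i_od], ivf$grid$y[i_od]),
                           paste(od$grid$x, od$grid$y))])
  i_os <- ivf$grid$x == 27
  expect_equal(ivf$td[i_os],
               os$td[match(paste(ivf$grid$x[i_os], ivf$grid$y[i_os]),
                           paste(os$grid$x, os$grid$y))])
})

test_that("integration validates pattern, patient and completeness", {
  od <- random_field(eye = "OD")
  os24 <- random_field(eye = "OS", pattern = "24-2")
  expect_error(integrate_best_location(od, os24), "pattern mismatch")
  other <- monocular_field("p2", "OS", "10-2", rep(-1, 68))
  expect_error(integrate_best_location(od, other), "patient mismatch")
  expect_error(monocular_field("p1", "OD", "10-2", rep(-1, 60)),
               "incomplete field")
  expect_error(monocular_field("p1", "OD", "10-2", c(rep(-1, 67), NA)),
               "incomplete field")
  expect_error(monocular_field("p1", "OD", "10-2", rep(-1, 68), fl_rate = 1.2),
               "rates")
})

test_that("binocular summation follows the quadratic sensitivity formula", {
  set.seed(21)
  od <- random_field(eye = "OD")
  os <- random_field(eye = "OS")
  ivf <- integrate_binocular_summation(od, os)
  expect_identical(ivf$model, "binocular_summation")
  # independent re-evaluation: dB -> linear sensitivity, quadratic sum, back
  key <- paste(ivf$grid$x, ivf$grid$y)
  a <- od$td[match(key, paste(od$grid$x, od$grid$y))]
  b <- os$td[match(key, paste(os$grid$x, os$grid$y))]
  oracle <- 10 * log10(sqrt((10^(a / 10))^2 + (10^(b / 10))^2))
  expect_equal(ivf$td, oracle)
  # dominance over both eyes
  expect_true(all(ivf$td >= pmax(a, b)))
  # equal inputs gain exactly 10*log10(sqrt(2)) dB
  twin <- monocular_field("p1", "OS", "10-2", od$td)
  expect_equal(integrate_binocular_summation(od, twin)$td,
               od$td + 10 * log10(sqrt(2)))
})

test_that("averaging two assessments is a per-point mean and validates inputs", {
  set.seed(31)
  od <- random_field(eye = "OD"); os <- random_field(eye = "OS")
  f1 <- integrate_best_location(od, os)
  expect_equal(average_fields(f1, f1)$td, f1$td)  # idempotent
  od2 <- monocular_field("p1", "OD", "10-2", od$td - 10)
  os2 <- monocular_field("p1", "OS", "10-2", os$td - 10)
  f2 <- integrate_best_location(od2, os2)
  expect_equal(average_fields(f1, f2)$td, (f1$td + f2$td) / 2)
  c1 <- monocular_field("p1", "OD", "10-2", rep(-10, 68))
  c2 <- monocular_field("p1", "OS", "10-2", rep(-20, 68))
  # constant -10 and -20 fields integrate to -10; shifting both by -10 and
  # averaging gives -15
  g1 <- integrate_best_location(c1, c2)
  g2 <- integrate_best_location(
    monocular_field("p1", "OD", "10-2", rep(-20, 68)),
    monocular_field("p1", "OS", "10-2", rep(-30, 68)))
  expect_true(all(average_fields(g1, g2)$td == -15))
  expect_error(average_fields(f1, integrate_binocular_summation(od, os)),
               "averaging error")
})

test_that("subfield mTDs are per-label means and aggregate to the whole field", {
  g <- vf_grid("10-2")
  lab <- assign_subfields(g)
  # constant field
  f <- monocular_field("p1", "OD", "10-2", rep(-13.2, 68))
  os <- monocular_field("p1", "OS", "10-2", rep(-13.2, 68))
  sm <- subfield_mtd(integrate_best_location(f, os))
  expect_true(all(sm$mtd == -13.2))
  expect_identical(sum(sm$n), 68L)
  expect_equal(attr(sm, "overall"), -13.2)

  # the four inner-lower-right points set to -1..-4, rest 0
  td <- rep(0, 68)
  td[lab == "inner lower right"] <- c(-1, -2, -3, -4)
  ivf <- integrate_best_location(
    monocular_field("p1", "OD", "10-2", td),
    monocular_field("p1", "OS", "10-2", td))
  sm2 <- subfield_mtd(ivf)
  expect_equal(sm2$mtd[sm2$subfield == "inner lower right"], -2.5)
  expect_true(all(sm2$mtd[sm2$subfield != "inner lower right"] == 0))

  # seeded field vs independent group-by-mean oracle
  set.seed(41)
  ivf3 <- integrate_best_location(random_field(eye = "OD"), random_field(eye = "OS"))
  sm3 <- subfield_mtd(ivf3)
  lab3 <- assign_subfields(ivf3$grid)
  oracle <- tapply(ivf3$td, lab3, mean)
  expect_equal(sm3$mtd, as.numeric(oracle[sm3$subfield]))
  # whole-field mTD equals the point-count-weighted mean of subfield mTDs
  expect_equal(attr(sm3, "overall"), sum(sm3$mtd * sm3$n) / sum(sm3$n))
})

test_that("improving a monocular point never lowers the IVF or its subfield means", {
  set.seed(51)
  od <- random_field(eye = "OD"); os <- random_field(eye = "OS")
  base <- integrate_best_location(od, os)
  sm0 <- subfield_mtd(base)
  for (r in 1:10) {
    td2 <- od$td + runif(68, 0, 3) * rbinom(68, 1, 0.3)
    up <- integrate_best_location(monocular_field("p1", "OD", "10-2", td2), os)
    expect_true(all(up$td >= base$td - 1e-12))
    expect_true(all(subfield_mtd(up)$mtd >= sm0$mtd - 1e-12))
  }
})

test_that("fields round-trip through the long CSV format", {
  set.seed(61)
  f1 <- random_field("pA", "OD")
  f2 <- random_field("pA", "OS", pattern = "24-2")
  path <- withr::local_tempfile(fileext = ".csv")
  write_fields_csv(list(f1, f2), path)
  back <- read_fields_csv(path)
  expect_length(back, 2L)
  got <- back[[which(vapply(back, function(f) f$pattern, "") == "10-2")]]
  expect_equal(got$td, f1$td)
  expect_identical(got$eye, "OD")
})
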