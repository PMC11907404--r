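test_that("equilibrium correction scales by the tube/dialysate volume ratio", {
  expect_equal(equilibrium_correction(0.9), 0.3)
  expect_equal(equilibrium_correction(0.9, digestion_setup(v_dialysate_mL = 20)),
               0.9)
  expect_equal(equilibrium_correction(0), 0)
})

test_that("the three bioaccessibility variants agree with direct arithmetic", {
  # fresh rosemary Cu: D = 0.32, T = 0.38 ug/g at 2.5 g, V_t/V_d = 20/60
  D <- 0.32 * 2.5; T_ <- 0.38 * 2.5
  D_r <- equilibrium_correction(D)
  expect_equal(as.numeric(bioaccessibility(D, D_r, T_)), 60.95238, tolerance = 1e-6)
  expect_equal(as.numeric(bioaccessibility(D, D_r, T_, "literal")), 65.75342,
               tolerance = 1e-6)
  expect_equal(as.numeric(bioaccessibility(D, D_r, T_, "uncorrected")), 45.71429,
               tolerance = 1e-6)
})

test_that("variants coincide where the correction vanishes and at D = 0", {
  expect_equal(as.numeric(bioaccessibility(2, 0, 3, "corrected_share")),
               as.numeric(bioaccessibility(2, 0, 3, "uncorrected")))
  for (v in c("corrected_share", "literal", "uncorrected")) {
    expect_equal(as.numeric(bioaccessibility(0, 0, 3, v)), 0)
  }
  expect_error(bioaccessibility(0, 0, 0), "zero denominator")
})

test_that("B is monotone in D and the corrected share stays below 100 when D_r <= T", {
  setup <- digestion_setup()
  kr <- setup$v_tube_mL / setup$v_dialysate_mL
  set.seed(13)
  for (v in c("corrected_share", "literal", "uncorrected")) {
    for (i in 1:30) {
      D <- runif(1, 0, 5); T_ <- runif(1, 0.5, 10)
      D_r <- D * kr
      b1 <- as.numeric(suppressWarnings(bioaccessibility(D, D_r, T_, v)))
      D2 <- D + 0.5
      b2 <- as.numeric(suppressWarnings(bioaccessibility(D2, D2 * kr, T_, v)))
      expect_gt(b2, b1)
      if (v == "corrected_share" && D_r <= T_) expect_lte(b1, 100)
    }
  }
})

test_that("a corrected share above 100 warns instead of clamping", {
  # D_r > T forces B > 100: the value is returned, with a warning
  expect_warning(b <- bioaccessibility(3, 2, 1), "mass-balance inconsistency")
  expect_gt(as.numeric(b), 100)
})

test_that("variant metadata is carried on results and survives a round trip", {
  expect_equal(attr(bioaccessibility(1, 0.2, 2, "literal"), "variant"), "literal")
  rec <- tibble::tibble(herb = "rosemary", form = "fresh", element = "Cu",
                        dialyzable = 0.32, nondialyzable = 0.38)
  tab <- bioaccess_table(rec, variant = "uncorrected")
  expect_equal(tab$variant, "uncorrected")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$variant, "uncorrected")
  expect_equal(back$B, tab$B, tolerance = 1e-9)
})

test_that("bioaccess_table converts contents to amounts with per-form masses", {
  rec <- tibble::tibble(
    herb = c("rosemary", "rosemary"), form = c("fresh", "lyophilizate"),
    element = "Cu", dialyzable = c(0.32, 1.07), nondialyzable = c(0.38, 1.28)
  )
  tab <- bioaccess_table(rec)
  expect_equal(tab$D, c(0.32 * 2.5, 1.07 * 0.5))
  expect_equal(tab$T_amount, c(0.38 * 2.5, 1.28 * 0.5))
  expect_equal(tab$D_r, tab$D * 20 / 60)
})

test_that("bioaccess_matrix is dense with censored cells flagged as NA", {
  rec <- tibble::tibble(
    herb = "rosemary", form = c("fresh", "dried"), element = "Cr",
    dialyzable = c(0.07, NA), nondialyzable = c(0.20, 1.68)
  )
  m <- bioaccess_matrix(rec)
  expect_equal(dim(m), c(2L, 1L))
  expect_equal(sum(is.na(m)), 1L)
  expect_equal(attr(m, "variant"), "corrected_share")
  # single uncensored record equals the scalar statistic
  single <- bioaccess_matrix(rec[1, ])
  D <- 0.07 * 2.5; T_ <- 0.20 * 2.5
  expect_equal(unname(single[1, 1]),
               as.numeric(bioaccessibility(D, equilibrium_correction(D), T_)))
})
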