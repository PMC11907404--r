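doses <- reference_doses()

test_that("the registry ships the documented reference doses", {
  expect_equal(doses$ptmi$value[doses$ptmi$element == "Cd"], 25)
  expect_equal(doses$bmdl$value[doses$bmdl$element == "As"], 0.06)
  expect_setequal(doses$bmdl$value[doses$bmdl$element == "Pb"], c(0.63, 1.50))
  expect_equal(doses$rda$value[doses$rda$element == "Mn" &
                                 doses$rda$sex == "women"], 1800)
  expect_equal(doses$eu_limits$value[doses$eu_limits$element == "Cd" &
                                       doses$eu_limits$category == "herbs"], 0.1)
})

test_that("PTMI percent reproduces the printed cadmium endpoint", {
  expect_equal(ptmi_percent(115, "Cd", doses = doses), 0.23)
  expect_equal(ptmi_percent(0, "Cd", doses = doses), 0)
  set.seed(21)
  for (i in 1:20) {
    c_ng <- runif(1, 0, 500)
    expect_equal(ptmi_percent(c_ng, "Cd", doses = doses),
                 100 * (c_ng / 1000 * 1 * 30 / 60) / 25, tolerance = 1e-12)
  }
  expect_error(ptmi_percent(10, "Zz", doses = doses), "no unique PTMI")
})

test_that("BMDL percent reproduces the printed As and Pb endpoints", {
  expect_equal(signif_half_up(bmdl_percent(1148, "As", "skin_cancer",
                                           doses = doses)), 32)
  expect_equal(signif_half_up(bmdl_percent(1884, "Pb", "kidney",
                                           doses = doses)), 5)
  expect_equal(bmdl_percent(0, "As", "skin_cancer", doses = doses), 0)
  expect_error(bmdl_percent(10, "Pb", "liver", doses = doses), "no unique BMDL")
})

test_that("RDA coverage reproduces the printed manganese endpoints", {
  expect_equal(signif_half_up(rda_percent(345, "Mn", "women", doses = doses)), 19)
  expect_equal(signif_half_up(rda_percent(46.7, "Mn", "women", portion_g = 25,
                                          doses = doses)), 65)
  expect_equal(rda_percent(0, "Mn", "women", doses = doses), 0)
})

test_that("the manganese RDA range over the printed panel rounds to 0.7-19", {
  hp <- herb_panel()
  mn <- hp$total[hp$element == "Mn"]
  vals <- c(vapply(mn, rda_percent, numeric(1), element = "Mn", sex = "women",
                   doses = doses),
            vapply(mn, rda_percent, numeric(1), element = "Mn", sex = "men",
                   doses = doses))
  rs <- range_summary(vals)
  expect_equal(unname(rs), c(0.67, 19), ignore_attr = TRUE)
  expect_equal(unname(attr(rs, "raw")[2]), 345 / 1800 * 100, tolerance = 1e-12)
})

test_that("EU limit checks pass below and fail above the limit", {
  ok <- eu_limit_check(0.115, "Cd", "supplements", doses = doses)
  expect_true(ok$pass)
  expect_equal(ok$margin, 1 - 0.115)
  expect_true(eu_limit_check(0.1, "Cd", "herbs", doses = doses)$pass)
  expect_equal(eu_limit_check(0.1, "Cd", "herbs", doses = doses)$margin, 0)
  expect_false(eu_limit_check(0.12, "Cd", "herbs", doses = doses)$pass)
})

test_that("indices are linear in content and intake, inverse-linear in body weight", {
  sc <- exposure_scenario()
  sc2 <- exposure_scenario(intake_g_per_day = 2)
  sc_bw <- exposure_scenario(body_weight_kg = 120)
  for (c_ng in c(15, 115, 700)) {
    base <- ptmi_percent(c_ng, "Cd", sc, doses)
    expect_equal(ptmi_percent(2 * c_ng, "Cd", sc, doses), 2 * base)
    expect_equal(ptmi_percent(c_ng, "Cd", sc2, doses), 2 * base)
    expect_equal(ptmi_percent(c_ng, "Cd", sc_bw, doses), base / 2)
    b <- bmdl_percent(c_ng, "As", "skin_cancer", sc, doses)
    expect_equal(bmdl_percent(2 * c_ng, "As", "skin_cancer", sc, doses), 2 * b)
    expect_equal(bmdl_percent(c_ng, "As", "skin_cancer", sc_bw, doses), b / 2)
  }
  expect_equal(rda_percent(50, "Zn", "men", portion_g = 50, doses = doses),
               50 * rda_percent(50, "Zn", "men", portion_g = 1, doses = doses))
})

test_that("monthly and daily time bases are consistent", {
  # a PTMI-style monthly quotient equals 30 daily quotients at the same dose
  sc <- exposure_scenario()
  c_ng <- 115
  daily_quotient <- 100 * (c_ng / 1000 * sc$intake_g_per_day /
                             sc$body_weight_kg) / 25
  expect_equal(ptmi_percent(c_ng, "Cd", sc, doses), 30 * daily_quotient)
})

test_that("range_summary brackets its input and rounds half-up to 2 sf", {
  expect_equal(unname(range_summary(0.23)), c(0.23, 0.23), ignore_attr = TRUE)
  expect_equal(unname(range_summary(c(1.1, 2.7, 5.0))), c(1.1, 5.0),
               ignore_attr = TRUE)
  vals <- c(0.664, 3.1, 19.17)
  rs <- range_summary(vals)
  raw <- attr(rs, "raw")
  expect_true(all(vals >= raw[1] & vals <= raw[2]))
  expect_equal(unname(rs), c(0.66, 19), ignore_attr = TRUE)
  expect_error(range_summary(numeric(0)))
})

test_that("signif_half_up rounds halves away from zero", {
  expect_equal(signif_half_up(c(19.17, 64.86, 0.2295, 31.89, 11.85)),
               c(19, 65, 0.23, 32, 12))
  expect_equal(signif_half_up(0.125, 2), 0.13)
  expect_equal(signif_half_up(-0.125, 2), -0.13)
  expect_equal(signif_half_up(0), 0)
})
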