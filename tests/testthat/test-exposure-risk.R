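adult <- exposure_parameters("adult")
child <- exposure_parameters("child")

test_that("average daily dose follows C IR EF ED / (BW AT)", {
  # frozen hand arithmetic: 0.00234 * 2 * 365 * 70 / (66.1 * 25550)
  expect_equal(average_daily_dose(0.00234, adult, "carcinogenic"),
               7.08018e-5, tolerance = 1e-5)
  expect_equal(average_daily_dose(0, adult, "carcinogenic"), 0)
  # EF * ED = AT cancellation: adult carcinogenic 365 * 70 = 25550
  c_mg_L <- 0.00572
  expect_equal(average_daily_dose(c_mg_L, adult, "carcinogenic"),
               c_mg_L * adult$IR / adult$BW)
  expect_error(average_daily_dose(-1, adult, "carcinogenic"), "non-negative")
})

test_that("deterministic CR reproduces the published adult and child values", {
  cr_ice <- carcinogenic_risk(
    average_daily_dose(convert_concentration(2.34, "ug/L", "mg/L"),
                       adult, "carcinogenic"), sf = 1.5)
  expect_equal(cr_ice$value, 1.06e-4, tolerance = 5e-3)
  expect_true(cr_ice$exceeds_threshold)

  cr_water <- carcinogenic_risk(
    average_daily_dose(0.00572, adult, "carcinogenic"), sf = 1.5)
  expect_equal(cr_water$value, 2.60e-4, tolerance = 5e-3)

  cr_child <- carcinogenic_risk(
    average_daily_dose(0.00572, child, "carcinogenic"), sf = 1.5)
  expect_equal(cr_child$value, 3.75e-4, tolerance = 5e-3)

  expect_equal(carcinogenic_risk(0, sf = 1.5)$value, 0)
  expect_false(carcinogenic_risk(0, sf = 1.5)$exceeds_threshold)
})

test_that("deterministic HQ and HI reproduce the published Hg values", {
  hq_adult <- hazard_quotient(
    average_daily_dose(convert_concentration(7.90, "ng/L", "mg/L"),
                       adult, "noncarcinogenic"), rfd = 3e-4)
  expect_equal(hq_adult$value, 7.97e-4, tolerance = 5e-3)

  hq_child <- hazard_quotient(
    average_daily_dose(convert_concentration(7.90, "ng/L", "mg/L"),
                       child, "noncarcinogenic"), rfd = 3e-4)
  hi_child <- hazard_index(hq_child)
  expect_equal(hi_child$value, 1.15e-3, tolerance = 5e-3)
  # single-element HI equals its HQ
  expect_equal(hi_child$value, hq_child$value)

  expect_equal(hazard_quotient(3e-4, rfd = 3e-4)$value, 1)
  expect_equal(hazard_index(c(0.01, 0.02))$value, 0.03)
  expect_error(hazard_index(numeric(0)), "at least one")
  expect_error(hazard_quotient(1, rfd = 0), "positive")
})

test_that("CR and HQ are linear in C and IR and inverse in BW", {
  set.seed(11)
  for (i in 1:10) {
    c0 <- runif(1, 1e-6, 1e-2); ir <- runif(1, 0.5, 3)
    bw <- runif(1, 10, 100); lam <- runif(1, 0.1, 5)
    p1 <- exposure_parameters("adult", IR = ir, BW = bw)
    p2 <- exposure_parameters("adult", IR = lam * ir, BW = bw)
    p3 <- exposure_parameters("adult", IR = ir, BW = lam * bw)
    base <- carcinogenic_risk(average_daily_dose(c0, p1), sf = 1.5)$value
    expect_equal(carcinogenic_risk(
      average_daily_dose(lam * c0, p1), sf = 1.5)$value, lam * base)
    expect_equal(carcinogenic_risk(
      average_daily_dose(c0, p2), sf = 1.5)$value, lam * base)
    expect_equal(carcinogenic_risk(
      average_daily_dose(c0, p3), sf = 1.5)$value, base / lam)
  }
})

test_that("risk classification uses strict thresholds", {
  cr <- carcinogenic_risk(2.6e-4 / 1.5, sf = 1.5)
  expect_equal(classify_risk(cr), "unacceptable")
  hi <- hazard_index(1.15e-3)
  expect_equal(classify_risk(hi), "negligible")
  # exactly at threshold -> acceptable / negligible
  at <- carcinogenic_risk(1e-4 / 1.5, sf = 1.5)
  expect_equal(classify_risk(at), "acceptable")
  expect_false(at$exceeds_threshold)
  expect_equal(classify_risk(hazard_quotient(3e-4, rfd = 3e-4)), "negligible")
})

test_that("the deterministic risk table reproduces the published layout", {
  means <- tibble::tibble(
    site_id = "MEAN", medium = c("ice", "water", "ice", "water"),
    depth_top_cm = 0, depth_bottom_cm = 5,
    element = c("As", "As", "Hg", "Hg"),
    concentration = c(2.34, 5.72, 7.90, 0.37),
    unit = c("ug/L", "ug/L", "ng/L", "ug/L"))
  tab <- risk_table(means)
  get <- function(g, el, med, metric) {
    tab$value[tab$group == g & tab$element %in% el & tab$medium == med &
                tab$metric == metric]
  }
  expect_equal(get("adult", "As", "ice", "CR"), 1.06e-4, tolerance = 5e-3)
  expect_equal(get("adult", "As", "water", "CR"), 2.60e-4, tolerance = 5e-3)
  expect_equal(get("child", "As", "water", "CR"), 3.75e-4, tolerance = 5e-3)
  expect_equal(get("adult", "Hg", "ice", "HQ"), 7.97e-4, tolerance = 5e-3)
  expect_equal(tab$value[tab$group == "child" & tab$medium == "ice" &
                           tab$metric == "HI"], 1.15e-3, tolerance = 5e-3)
  expect_equal(unique(tab$class[tab$metric == "CR"]), "unacceptable")
  expect_equal(unique(tab$class[tab$metric %in% c("HQ", "HI")]), "negligible")
})

test_that("the stated 0.7 L/d child intake remains available as an override", {
  alt <- exposure_parameters("child", IR = 0.7)
  expect_equal(alt$IR, 0.7)
  cr <- carcinogenic_risk(average_daily_dose(0.00572, alt), sf = 1.5)
  expect_equal(cr$value, 0.7 * 3.7467e-4, tolerance = 1e-4)
})
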