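test_that("single-factor index divides by the standard and classifies", {
  res <- single_factor_index(5.72, 50)
  expect_equal(res$value, 0.1144)
  expect_equal(res$class, "clean")
  # boundary: lower bound inclusive
  expect_equal(single_factor_index(1, 1)$class, "slight pollution")
  expect_equal(single_factor_index(0, 50)$value, 0)
  expect_error(single_factor_index(1, 0), "positive")
  # linearity in ci
  ci <- runif(20, 0, 10)
  expect_equal(single_factor_index(2 * ci, 50)$value,
               2 * single_factor_index(ci, 50)$value)
})

test_that("geo-accumulation index follows log2(Cn / (K Bn))", {
  expect_equal(geo_accumulation_index(0.0375, 0.025)$value, 0)
  expect_equal(geo_accumulation_index(0.075, 0.025)$value, 1)
  # frozen hand evaluation at the observed sediment As mean and background:
  # log2(7.47 / (1.5 * 9.68)) = -0.95886
  expect_equal(geo_accumulation_index(7.47, 9.68)$value, -0.95886,
               tolerance = 1e-5)
  # scale invariance in (cn, bn)
  lambda <- c(0.1, 3, 42)
  for (l in lambda) {
    expect_equal(geo_accumulation_index(l * 0.06, l * 0.025)$value,
                 geo_accumulation_index(0.06, 0.025)$value)
  }
  expect_error(geo_accumulation_index(0, 0.025), "zero_as_below_scale")
  res <- geo_accumulation_index(0, 0.025, zero_as_below_scale = TRUE)
  expect_equal(res$value, -Inf)
  expect_equal(res$class, "no pollution")
})

test_that("Igeo class boundaries are lower-inclusive above zero", {
  # k = bn = 1 keeps cn / (k bn) an exact power of two at the boundaries
  vals <- c(-3, 0, 0.5, 1, 1.99, 2, 3, 4, 5, 7)
  expect_equal(
    geo_accumulation_index(2^vals, bn = 1, k = 1)$class,
    c("no pollution", "no pollution", "mild pollution",
      "partial moderate pollution", "partial moderate pollution",
      "moderate pollution", "heavy pollution", "severe pollution",
      "extremely severe pollution", "extremely severe pollution"))
})

test_that("risk assessment code is the F1 share in percent", {
  rec <- speciation_record("P9", 0, 5, "Hg", 15.8, 20, 30, 34.2)
  res <- risk_assessment_code(rec)
  expect_equal(res$value, 15.8)
  expect_equal(res$class, "medium risk")
  expect_equal(risk_assessment_code(
    speciation_record("X", 0, 5, "Hg", 0, 1, 1, 2))$value, 0)
  expect_equal(risk_assessment_code(
    speciation_record("X", 0, 5, "Hg", 1, 1, 1, 1))$value, 25)
  # invariance to rescaling all four fractions
  a <- speciation_record("X", 0, 5, "As", 0.2, 0.5, 0.1, 3)
  b <- speciation_record("X", 0, 5, "As", 2, 5, 1, 30)
  expect_equal(risk_assessment_code(a)$value, risk_assessment_code(b)$value)
})

test_that("RAC class scale is contiguous with low risk spanning [1, 10]", {
  expect_equal(classify_rac(c(0, 0.9, 1, 9.9, 10, 10.5, 30, 31, 50, 51)),
               c("no risk", "no risk", "low risk", "low risk", "low risk",
                 "medium risk", "medium risk", "high risk", "high risk",
                 "extremely high risk"))
})

test_that("SQG classification keeps TEL/PEL boundaries in the middle class", {
  expect_equal(sqg_classify(0.035, 0.17, 0.48), "rare biotoxic effects")
  expect_equal(sqg_classify(7.47, 5.90, 17.0), "occasional biotoxic effects")
  expect_equal(sqg_classify(17.0, 5.90, 17.0), "occasional biotoxic effects")
  expect_equal(sqg_classify(5.90, 5.90, 17.0), "occasional biotoxic effects")
  expect_equal(sqg_classify(17.1, 5.90, 17.0), "frequent biotoxic effects")
})

test_that("RAC summary reproduces the published per-element statistics", {
  t5 <- load_rac_fixture()
  hg <- summarize_rac(t5[t5$element == "Hg", ])
  expect_equal(round(hg$mean, 1), 7.7)
  expect_equal(hg$min, 2.5)
  expect_equal(hg$max, 15.8)
  as_ <- summarize_rac(t5[t5$element == "As", ])
  expect_equal(as_$max, 3.7)
  expect_equal(as.numeric(as_$class_fractions["no risk"]), 18 / 32)
  expect_equal(as.numeric(as_$class_fractions["low risk"]), 14 / 32)
  expect_true(all(t5$rac_percent[t5$element == "As"] <= 10))
  one <- summarize_rac(tibble::tibble(value = 4.2))
  expect_equal(one$mean, 4.2)
  expect_equal(one$min, one$max)
  expect_error(summarize_rac(tibble::tibble(value = numeric(0))), "no RAC")
})

test_that("class labels re-derive from stored values on all fixtures", {
  t5 <- load_rac_fixture()
  rac_tbl <- tibble::tibble(
    site_id = t5$site_id, depth_top_cm = t5$depth_cm - 5,
    depth_bottom_cm = t5$depth_cm, element = t5$element,
    f1 = t5$rac_percent, f2 = 100 - t5$rac_percent, f3 = 0, f4 = 0)
  res <- risk_assessment_code(rac_tbl)
  expect_equal(res$class, classify_rac(res$value))

  idx <- compute_indices(printed_means("observed"), speciation = rac_tbl)
  pi_rows <- idx[idx$index == "Pi", ]
  expect_equal(pi_rows$class,
               single_factor_index(pi_rows$value, 1)$class)
})

test_that("batch index table covers water Pi, sediment Igeo and RAC", {
  m <- printed_means("observed")
  sp <- speciation_record("P9", 0, 5, "Hg", 1.58, 2, 3, 3.42)
  idx <- compute_indices(m, sp)
  expect_setequal(unique(idx$index), c("Pi", "Igeo", "RAC"))
  # water As Pi from the observed mean
  expect_equal(idx$value[idx$index == "Pi" & idx$element == "As" &
                           idx$medium == "water"], 0.1144)
  # sediment Igeo present for both elements
  expect_equal(sum(idx$index == "Igeo"), 2)
})
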