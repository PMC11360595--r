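test_that("fixed seed reproduces the dataset bit for bit", {
  cfg <- synthetic_config()
  expect_identical(generate_profiles(cfg, seed = 9),
                   generate_profiles(cfg, seed = 9))
  expect_identical(generate_speciation(cfg, seed = 10),
                   generate_speciation(cfg, seed = 10))
})

test_that("generated data are strictly positive and schema-valid", {
  d <- generate_profiles(synthetic_config(), seed = 21)
  expect_true(all(d$concentration > 0))
  expect_silent(validate_measurements(d))
  sp <- generate_speciation(synthetic_config(), seed = 22)
  expect_true(all(as.matrix(sp[, c("f1", "f2", "f3", "f4")]) >= 0))
  expect_silent(validate_speciation(sp))
})

test_that("layer geometry follows the configured ranges", {
  cfg <- synthetic_config()
  d <- generate_profiles(cfg, seed = 33)
  by_depth <- dplyr::summarise(
    dplyr::group_by(d, site_id, medium),
    depth = max(depth_bottom_cm), n_layers = dplyr::n_distinct(depth_top_cm),
    .groups = "drop")
  ice <- by_depth[by_depth$medium == "ice", ]
  expect_true(all(ice$depth >= 40 - 2.5 & ice$depth <= 60 + 2.5))
  wat <- by_depth[by_depth$medium == "water", ]
  expect_true(all(wat$depth >= 80 - 2.5 & wat$depth <= 150 + 2.5))
  sed <- by_depth[by_depth$medium == "sediment", ]
  expect_true(all(sed$n_layers >= 2 & sed$n_layers <= 5))
  # layers tile [0, depth) in 5-cm slices
  expect_true(all(d$depth_bottom_cm - d$depth_top_cm == 5))
})

test_that("water profiles rise toward the bottom and ice peaks mid-depth", {
  cfg <- synthetic_config(n_sites = 400)
  d <- generate_profiles(cfg, seed = 44, media = c("ice", "water"))
  w <- d[d$medium == "water" & d$element == "As", ]
  deep <- dplyr::slice_max(dplyr::group_by(w, site_id), depth_top_cm,
                           n = 1, with_ties = FALSE)
  surf <- w[w$depth_top_cm == 0, ]
  expect_gt(mean(deep$concentration), mean(surf$concentration))
  ice <- d[d$medium == "ice" & d$element == "Hg", ]
  mid <- ice[ice$depth_top_cm >= 20 & ice$depth_bottom_cm <= 40, ]
  top <- ice[ice$depth_bottom_cm <= 10, ]
  expect_gt(mean(mid$concentration), mean(top$concentration))
})

test_that("unit enrichment factors give a flat expected profile", {
  cfg <- synthetic_config(n_sites = 600, ice_enrichment = 1,
                          water_bottom_enrichment = 1, layer_cv = 0.05)
  d <- generate_profiles(cfg, seed = 55, media = "water")
  w <- d[d$element == "As", ]
  per_site <- dplyr::group_by(w, site_id)
  deep <- dplyr::slice_max(per_site, depth_top_cm, n = 1, with_ties = FALSE)
  surf <- w[w$depth_top_cm == 0, ]
  # normalised by site mean the two layers are exchangeable
  ratio <- mean(deep$concentration) / mean(surf$concentration)
  expect_equal(ratio, 1, tolerance = 0.05)
})

test_that("site means recover the configured distributions at large n", {
  cfg <- synthetic_config(n_sites = 10000)
  d <- generate_profiles(cfg, seed = 66, media = "water")
  sm <- dplyr::summarise(dplyr::group_by(d, site_id, element),
                         m = mean(concentration), .groups = "drop")
  for (el in c("As", "Hg")) {
    v <- sm$m[sm$element == el]
    target <- cfg$concentrations$mean[cfg$concentrations$element == el &
                                        cfg$concentrations$medium == "water"]
    expect_lt(abs(mean(v) - target), 3 * sd(v) / sqrt(length(v)))
  }
})

test_that("speciation splits conserve the layer total", {
  cfg <- synthetic_config()
  sed <- generate_profiles(cfg, seed = 77, media = "sediment")
  sp <- generate_speciation(cfg, seed = 78, sediment = sed)
  joined <- dplyr::inner_join(
    sp, sed, by = c("site_id", "depth_top_cm", "depth_bottom_cm", "element"))
  expect_equal(joined$f1 + joined$f2 + joined$f3 + joined$f4,
               joined$concentration)
})

test_that("degenerate Dirichlet gives every layer the mean proportions", {
  cfg <- synthetic_config(dirichlet_concentration = Inf)
  sp <- generate_speciation(cfg, seed = 88)
  rac <- risk_assessment_code(sp)
  hg <- rac$value[rac$element == "Hg"]
  expect_equal(hg, rep(100 * 8.0 / (8.0 + 13.4 + 26.8 + 51.6), length(hg)))
  expect_true(all(rac$class[rac$element == "Hg"] == "low risk"))
})

test_that("mean RAC recovers the configured F1 share at many layers", {
  cfg <- synthetic_config(n_sites = 4000)
  sp <- generate_speciation(cfg, seed = 99)
  rac <- risk_assessment_code(sp)
  for (el in c("Hg", "As")) {
    v <- rac$value[rac$element == el]
    target <- 100 * cfg$speciation_means[[el]][1]
    expect_lt(abs(mean(v) - target), 3 * sd(v) / sqrt(length(v)))
  }
})

test_that("the recovery report lands in the configured classes", {
  cfg <- synthetic_config(n_sites = 2000)
  d <- generate_profiles(cfg, seed = 111, media = c("water", "sediment"))
  sp <- generate_speciation(cfg, seed = 112,
                            sediment = d[d$medium == "sediment", ])
  rep <- parameter_recovery_check(d, sp)
  pi_as <- rep[rep$quantity == "mean water Pi" & rep$element == "As", ]
  expect_equal(pi_as$value, 5.72 / 50, tolerance = 0.05)
  expect_equal(pi_as$class, "clean")
  sed_hg <- rep[rep$quantity == "mean sediment concentration" &
                  rep$element == "Hg", ]
  expect_equal(sed_hg$class, "rare biotoxic effects")
  sed_as <- rep[rep$quantity == "mean sediment concentration" &
                  rep$element == "As", ]
  expect_equal(sed_as$class, "occasional biotoxic effects")
  rac_hg <- rep[rep$quantity == "mean RAC percent" & rep$element == "Hg", ]
  expect_equal(rac_hg$class, "low risk")
})

test_that("impossible configurations are rejected", {
  expect_error(synthetic_config(ice_enrichment = 0.5))
  expect_error(synthetic_config(layer_cv = 0))
  expect_error(synthetic_config(speciation_means = list(Hg = c(1, 2, 3))))
})
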