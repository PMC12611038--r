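test_that("generators are deterministic under a fixed seed", {
  sc <- experiment_scenario(seed = 5)
  expect_identical(generate_quality(sc), generate_quality(sc))
  expect_identical(generate_nutrients(sc), generate_nutrients(sc))
  h1 <- generate_harvest_series(sc)
  h2 <- generate_harvest_series(sc)
  expect_identical(h1, h2)
  expect_identical(simulate_cnd_window(seed = 9),
                   simulate_cnd_window(seed = 9))
  # different seeds give different draws
  sc2 <- experiment_scenario(seed = 6)
  expect_false(identical(generate_quality(sc), generate_quality(sc2)))
})

test_that("a degenerate scenario collapses to the grand means", {
  eff <- default_factor_effects()
  eff <- lapply(eff, function(m) m * 0)
  sc <- experiment_scenario(
    seed = 1, grand_means = c(SFW = 4.77, TSS = 18, FF = 400),
    factor_effects = eff,
    year_effects = list(SFW = rep(0, 5), TSS = rep(0, 5), FF = rep(0, 5)),
    noise_sd = c(SFW = 0, TSS = 0, FF = 0))
  q <- generate_quality(sc)
  expect_equal(nrow(q), 16 * 5 * 3)
  expect_true(all(q$SFW == 4.77))
  expect_true(all(q$TSS == 18))
})

test_that("generated level means recover planted effects within 3 SE", {
  eff <- default_factor_effects()
  eff <- lapply(eff, function(m) m * 0)
  eff$SFW["L3", "CaO"] <- 0.3
  sc <- experiment_scenario(seed = 2, factor_effects = eff,
                            year_effects = list(SFW = rep(0, 5),
                                                TSS = rep(0, 5),
                                                FF = rep(0, 5)),
                            noise_sd = c(SFW = 0.05, TSS = 0.05, FF = 1))
  q <- generate_quality(sc)
  ra <- range_analysis(q, "SFW")
  se <- 0.05 * sqrt(2 / 60)   # each level mean averages 60 draws
  gap <- ra$level_means["L3", "CaO"] - ra$level_means["L1", "CaO"]
  expect_lt(abs(gap - 0.3), 3 * se)
})

test_that("level means converge to scenario effects at large replication", {
  eff <- default_factor_effects()
  sc <- experiment_scenario(seed = 3, n_reps = 200,
                            year_effects = list(SFW = rep(0, 5),
                                                TSS = rep(0, 5),
                                                FF = rep(0, 5)))
  q <- generate_quality(sc)
  ra <- range_analysis(q, "TSS", use_treatment_means = FALSE)
  n_per_level <- nrow(q) / 4
  se <- sc$noise_sd[["TSS"]] / sqrt(n_per_level)
  for (f in colnames(eff$TSS)) {
    centred <- ra$level_means[, f] - mean(ra$level_means[, f])
    expect_true(all(abs(centred - eff$TSS[, f]) < 3 * se * sqrt(2)))
  }
})

test_that("nutrient observations reduce to baselines without noise", {
  sc <- experiment_scenario(seed = 4)
  sc$plant_baseline$cv <- 0
  sc$soil_baseline$cv <- 0
  sc$soil_response[] <- 0
  nn <- generate_nutrients(sc)
  pb <- sc$plant_baseline
  key <- paste(nn$plant$stage, nn$plant$tissue, nn$plant$element)
  bkey <- paste(pb$stage, pb$tissue, pb$element)
  expect_equal(nn$plant$value, pb$baseline[match(key, bkey)])
  sb <- sc$soil_baseline
  skey <- paste(nn$soil$stage, nn$soil$element)
  expect_equal(nn$soil$value, sb$baseline[match(skey,
               paste(sb$stage, sb$element))])
  expect_true(all(nn$plant$value > 0))
})

test_that("soil dose response is recovered by least squares", {
  sc <- experiment_scenario(seed = 12)
  sc$soil_cv <- 0.05
  sc$soil_baseline$cv <- 0.05
  nn <- generate_nutrients(sc)
  des <- build_design()$treatments
  gsn <- nn$soil[nn$soil$stage == "GS" & nn$soil$element == "N", ]
  dose <- des$N_dose[match(gsn$treatment, des$treatment)]
  slope <- coef(lm(gsn$value ~ dose))[2]
  expect_lt(abs(slope - sc$soil_response[["N"]]),
            0.2 * sc$soil_response[["N"]])
})

test_that("harvest series has the full grid, positive monotone masses", {
  sc <- experiment_scenario(seed = 8)
  h <- generate_harvest_series(sc)
  expect_equal(nrow(h), 7 * 7 * 3 * 3 * 5)
  expect_true(all(h$concentration > 0))
  expect_true(all(h$dry_mass > 0))
  stages <- c("GS", "IFS", "EBS", "SDS", "VS", "MS", "DS")
  whole <- aggregate(dry_mass ~ year + tree + stage,
                     data = h[h$element == "N", ], FUN = sum)
  for (yr in unique(whole$year)) for (tr in unique(whole$tree)) {
    w <- whole[whole$year == yr & whole$tree == tr, ]
    expect_true(all(diff(w$dry_mass[match(stages, w$stage)]) >= 0))
  }
})

test_that("a noiseless harvest reproduces its closed-form uptake exactly", {
  sc <- experiment_scenario(seed = 10)
  sc$harvest$mass_tree_sd <- 0
  sc$harvest$conc_cv <- 0
  h <- generate_harvest_series(sc)
  sd1 <- stage_demand(h)
  target <- sc$harvest$uptake_per_1000kg * sc$harvest$yield_per_tree
  for (el in names(target)) {
    a <- sd1$awp[sd1$awp$element == el & sd1$awp$year == 1, ]
    expect_equal(a$awp[a$stage == "DS"] - a$awp[a$stage == "GS"],
                 unname(target[el]), tolerance = 1e-10)
  }
})

test_that("default harvest calibration recovers per-yield uptake within 5%", {
  sc <- experiment_scenario(seed = 1)
  h <- generate_harvest_series(sc)
  sd1 <- stage_demand(h)
  yields <- attr(h, "yields")
  ur <- uptake_reference()
  for (el in ur$element) {
    py <- sd1$per_year[sd1$per_year$element == el, ]
    uptake <- sum(py$dts) / length(unique(py$year))
    per_1000 <- uptake / mean(yields$yield_kg)
    want <- ur$total_per_1000kg[ur$element == el]
    expect_lt(abs(per_1000 - want) / want, 0.05)
  }
})

test_that("the planted-window generator flags its structure", {
  d <- simulate_cnd_window(seed = 2)
  expect_equal(nrow(d), 80)
  expect_equal(sum(d$in_top), 16)
  expect_true(all(d$value > 0))
  expect_equal(range(d$fqi_norm), c(0, 1))
  pl <- attr(d, "planted")
  expect_true(pl[1] >= 14 && pl[2] <= 16)
  expect_true(attr(d, "boundary") > 0.5)
})
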