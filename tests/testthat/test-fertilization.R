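test_that("the dose rule zeroes at the gate and collapses at base yield", {
  m <- fertilization_models()
  # x at or above x_max: no fertilizer, for every pair
  expect_true(all(pfa(m$x_max, m$a, m$b, m$x_max, 0.25, 3000) == 0))
  expect_true(all(pfa(m$x_max * 1.5, m$a, m$b, m$x_max, 0.25, 3000) == 0))
  # at the 1500 kg reference yield the bracket collapses: PFA = ax + b
  for (i in seq_len(nrow(m))) {
    x <- m$x_max[i] / 3
    expect_equal(pfa(x, m$a[i], m$b[i], m$x_max[i], 0.2, 1500),
                 max(m$a[i] * x + m$b[i], 0))
  }
  # x = 0 at base yield returns the intercept
  expect_equal(pfa(rep(0, nrow(m)), m$a, m$b, m$x_max, 0.5, 1500), m$b)
})

test_that("the worked germination-interval N example reproduces", {
  val <- pfa(0.2, a = -10.5800, b = 3.5549, x_max = 0.336,
             fr = 0.2531, ey = 3000)
  expect_equal(val, (-10.58 * 0.2 + 3.5549) * (0.7469 + 0.5062),
               tolerance = 1e-12)
  expect_equal(round(val, 4), 1.8031)
})

test_that("dose response is monotone in soil test and linear in yield", {
  m <- fertilization_models()
  for (i in seq_len(nrow(m))) {
    xs <- seq(0, m$x_max[i] * 1.2, length.out = 40)
    doses <- pfa(xs, m$a[i], m$b[i], m$x_max[i], 0.3, 2500)
    expect_true(all(diff(doses) <= 1e-12))
  }
  # linearity in EY below the gate
  eys <- c(1500, 2000, 3000)
  d <- pfa(0.1, -10.58, 3.5549, 0.336, 0.2531, eys)
  slopes <- diff(d) / diff(eys)
  expect_equal(slopes[1], slopes[2], tolerance = 1e-12)
})

test_that("negative responses are floored with a warning", {
  # slope drives ax + b negative before the gate
  expect_warning(out <- pfa(0.9, a = -10, b = 1, x_max = 1,
                            fr = 0.2, ey = 1500), "floored")
  expect_equal(out, 0)
  expect_error(pfa(-0.1, -1, 1, 1, 0.2, 1500), "non-negative")
})

test_that("annual plans compose independent dose calls", {
  m <- fertilization_models()
  set.seed(14)
  soil <- data.frame(stage = m$start_stage, element = m$soil_element,
                     value = runif(nrow(m), 0, 1.2) * m$x_max)
  soil <- soil[!duplicated(paste(soil$stage, soil$element)), ]
  plan <- annual_plan(soil, ey = 2400)
  fr <- setNames(uptake_reference()$fruit_ratio,
                 c("N", "P2O5", "K2O", "CaO", "MgO"))
  for (i in seq_len(nrow(plan$plan))) {
    p <- plan$plan[i, ]
    expect_equal(p$pfa, pfa(p$x, p$a, p$b, p$x_max, fr[[p$element]], 2400))
  }
  expect_equal(unname(plan$annual),
               unname(tapply(plan$plan$pfa, plan$plan$element,
                             sum)[names(plan$annual)]))
})

test_that("saturated soils get an all-zero plan and intercepts at zero", {
  m <- fertilization_models()
  rich <- data.frame(stage = m$start_stage, element = m$soil_element,
                     value = m$x_max * 2)
  rich <- rich[!duplicated(paste(rich$stage, rich$element)), ]
  expect_true(all(annual_plan(rich)$plan$pfa == 0))
  poor <- rich; poor$value <- 0
  plan <- annual_plan(poor, ey = 1500)
  expect_equal(plan$plan$pfa, m$b)
  expect_error(annual_plan(rich[-1, ]), "GS_N")
})

test_that("demand-ratio splitting conserves the annual dose", {
  expect_equal(unname(split_by_demand_ratio(100, c(14, 18, 52, 7, 9))),
               c(14, 18, 52, 7, 9))
  expect_equal(unname(split_by_demand_ratio(7, c(0, 0, 3, 0, 0))),
               c(0, 0, 7, 0, 0))
  set.seed(25)
  for (i in 1:20) {
    r <- runif(5)
    expect_equal(sum(split_by_demand_ratio(123.4, r)), 123.4,
                 tolerance = 1e-12)
  }
  expect_error(split_by_demand_ratio(1, c(0, 0)), "zero")
  expect_error(split_by_demand_ratio(1, c(-1, 2)), "non-negative")
})

test_that("the blend solver inverts single-product and known mixes", {
  out <- solve_blend(c(K2O = 54.02))
  expect_equal(unname(out$products["potassium sulfate"]), 100,
               tolerance = 1e-8)
  expect_equal(sum(out$residual^2), 0, tolerance = 1e-10)
  zero <- solve_blend(c(N = 0))
  expect_true(all(zero$products == 0))
  # construct-then-solve: delivered nutrients recovered
  cat <- fertilizer_catalog()
  set.seed(33)
  for (i in 1:10) {
    mix <- runif(nrow(cat), 0, 50)
    target <- colSums(mix * as.matrix(cat[, c("N", "P2O5", "K2O",
                                              "CaO", "MgO")]))
    out <- solve_blend(target)
    expect_equal(out$delivered, target, tolerance = 1e-6)
    expect_true(all(out$products >= 0))
  }
  expect_error(solve_blend(c(N = 1), fertilizer_catalog()[0, ]), "empty")
})

test_that("oxide conversions are inverse and use standard stoichiometry", {
  expect_equal(oxide_to_element(2.2914, "P2O5"), 1)
  expect_equal(element_to_oxide(1, "K"), 1.2046)
  x <- c(1.3, 4.5)
  expect_equal(
    oxide_to_element(element_to_oxide(x, c("Ca", "Mg")),
                     c("CaO", "MgO")), x)
  expect_error(element_to_oxide(1, "Zn"), "unknown")
})
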