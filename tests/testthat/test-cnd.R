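test_that("coefficient of variation follows the direct formula", {
  x <- c(1, 2, 3)
  plant <- data.frame(stage = "FBS", tissue = "leaf", element = "N",
                      value = x)
  sel <- select_diagnostic_tissue(plant)
  expect_equal(sel$cv_table$cv, 100 * sd(x) / mean(x))
  # constant series: CV 0, always wins
  plant2 <- rbind(plant,
                  data.frame(stage = "VS", tissue = "leaf", element = "N",
                             value = c(5, 5, 5)))
  sel2 <- select_diagnostic_tissue(plant2)
  expect_equal(sel2$selection$stage, "VS")
  expect_equal(sel2$selection$cv, 0)
})

test_that("the low-noise tissue is selected per element", {
  set.seed(19)
  wins <- 0
  for (s in 1:30) {
    plant <- expand.grid(stage = c("FBS", "VS"), tissue = c("leaf", "fruit"),
                         element = "N", unit = 1:40,
                         stringsAsFactors = FALSE)
    quiet <- plant$stage == "FBS" & plant$tissue == "leaf"
    plant$value <- 10 * exp(rnorm(nrow(plant), 0,
                                  ifelse(quiet, 0.05, 0.1)))
    sel <- select_diagnostic_tissue(plant)$selection
    if (sel$stage == "FBS" && sel$tissue == "leaf") wins <- wins + 1
  }
  expect_gte(wins, 29)
})

test_that("cumulative variance-ratio curve matches brute-force enumeration", {
  set.seed(2)
  for (i in 1:10) {
    n <- sample(c(10, 15, 30), 1)
    v <- runif(n, 5, 15)
    f <- runif(n)
    cur <- cumulative_variance_function(v, f)
    oracle <- oracle_cumvar(v, f)
    expect_equal(cur$x, oracle$x, tolerance = 1e-12)
    expect_equal(cur$F, oracle$F, tolerance = 1e-10)
  }
})

test_that("cumulative curve ends at 100 and is non-decreasing", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    cur <- cumulative_variance_function(runif(n), runif(n))
    expect_equal(cur$F[nrow(cur)], 100)
    expect_true(all(diff(cur$F) >= 0))
    expect_true(all(diff(cur$x) <= 0))
  }
})

test_that("tied scores stay in one subgroup", {
  f <- c(rep(0.9, 4), 0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  v <- rnorm(10)
  cur <- cumulative_variance_function(v, f, m_min = 3)
  # split at j = 3 would separate tied units; first admissible is j = 4
  expect_false(3 %in% cur$j)
  expect_true(min(cur$j) >= 4)
})

test_that("cumulative curve input validation errors are specific", {
  expect_error(cumulative_variance_function(1:5, rep(0.5, 5)),
               "at least")
  expect_error(cumulative_variance_function(1:9, rep(0.5, 9)), "equal")
  expect_error(cumulative_variance_function(1:9, 9:1, m_min = 1), "m_min")
})

test_that("cubic fit recovers exact published coefficients", {
  x <- seq(0.05, 0.95, length.out = 30)
  ref <- cnd_reference_table()
  for (v in c("FBS_L_N", "GS_Ca", "VS_Mg")) {
    r <- ref[ref$variable == v, ]
    F <- r$A * x^3 + r$B * x^2 + r$C * x + r$D
    fit <- fit_cubic(x = x, F = F)
    expect_equal(unname(fit$coefficients),
                 c(r$A, r$B, r$C, r$D), tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
    expect_equal(fit$cutoff, -r$B / (3 * r$A), tolerance = 1e-9)
  }
})

test_that("linear points leave the cutoff undefined with a warning", {
  x <- seq(0, 1, length.out = 20)
  expect_warning(fit <- fit_cubic(x = x, F = 3 * x + 1), "undefined")
  expect_true(is.na(fit$cutoff))
  expect_error(fit_cubic(x = rep(1:3, 5), F = rnorm(15)), "distinct")
})

test_that("noisy cubic fits have small coefficient bias", {
  set.seed(77)
  A <- -61.412; B <- 150.17; C <- -191.27; D <- 105.24
  coefs <- replicate(200, {
    x <- runif(80)
    F <- A * x^3 + B * x^2 + C * x + D + rnorm(80, 0, 1)
    fit_cubic(x = x, F = F)$coefficients
  })
  bias <- abs(rowMeans(coefs) - c(A = A, B = B, C = C, D = D)) /
    abs(c(A, B, C, D))
  expect_true(all(bias < 0.02))
})

test_that("inflection cutoff equals the closed form and the numeric root", {
  expect_equal(round(inflection_cutoff(-61.412, 150.17), 4), 0.8151)
  expect_equal(round(inflection_cutoff(62.153, -96.819), 4), 0.5193)
  expect_equal(inflection_cutoff(1, 0), 0)
  expect_error(inflection_cutoff(0, 5), "undefined")
  # numeric root of the fitted second derivative 6Ax + 2B
  set.seed(13)
  for (i in 1:10) {
    A <- runif(1, -300, 300); B <- runif(1, -300, 300)
    if (abs(A) < 1) next
    root <- uniroot(function(x) 6 * A * x + 2 * B, c(-50, 50))$root
    expect_equal(inflection_cutoff(A, B), root, tolerance = 1e-10)
  }
})

test_that("sub-population selection and fractions behave", {
  f <- seq(0, 1, length.out = 80)
  sub <- select_high_subpop(f, f[68])
  expect_equal(sub$size, 13)
  expect_equal(sub$fraction, 16.25)
  expect_equal(select_high_subpop(f, 0)$fraction, 100)
  expect_error(select_high_subpop(f, 2), "review")
})

test_that("optimum range is the subset min/max", {
  expect_equal(unname(optimum_range(c(7.192, 9.0, 12.516))),
               c(7.192, 12.516))
  expect_error(optimum_range(5), ">= 2")
  set.seed(6)
  v <- rnorm(30)
  expect_equal(unname(optimum_range(v)), c(min(v), max(v)))
})

test_that("optimum range shrinks (or holds) as the cutoff rises", {
  set.seed(8)
  f <- runif(60); v <- runif(60, 5, 15)
  cuts <- sort(runif(5, 0.1, 0.8))
  widths <- sapply(cuts, function(ct) {
    idx <- select_high_subpop(f, ct)$index
    diff(unname(optimum_range(v[idx])))
  })
  expect_true(all(diff(widths) <= 1e-12))
})

test_that("communal cutoff is the maximum defined plant cutoff", {
  expect_equal(communal_cutoff(c(0.8151, 0.6597, 0.5507, 0.3860, 0.4655)),
               0.8151)
  expect_equal(communal_cutoff(c(NA, 0.4)), 0.4)
  expect_equal(communal_cutoff(0.7), 0.7)
  expect_error(communal_cutoff(NA_real_), "no defined")
})

test_that("correlations match the covariance formula and flag significance", {
  x <- c(1, 2, 4, 7, 11); y <- c(2, 1, 5, 8, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tab <- correlation_table(data.frame(a = x), data.frame(b = y))
  expect_equal(tab$r, r_hand, tolerance = 1e-12)
  perf <- correlation_table(data.frame(a = 1:10),
                            data.frame(b = 2 * (1:10) + 3))
  expect_equal(perf$r, 1)
  expect_lt(perf$p, 1e-8)
  expect_warning(correlation_table(data.frame(a = rep(1, 5)),
                                   data.frame(b = rnorm(5))), "constant")
})

test_that("independent pairs reject at roughly the nominal rate", {
  set.seed(21)
  rejections <- mean(replicate(600, {
    correlation_table(data.frame(a = rnorm(80)),
                      data.frame(b = rnorm(80)))$p < 0.05
  }))
  expect_gte(rejections, 0.03)
  expect_lte(rejections, 0.07)
})
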