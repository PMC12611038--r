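test_that("level means from the published treatment means match the
           published level block", {
  q <- quality_treatment_means()
  for (tr in c("SFW", "TSS", "FF", "FQI")) {
    ra <- range_analysis(q, tr)
    printed <- quality_level_means()
    printed <- printed[printed$trait == tr, ]
    for (i in seq_len(5)) {
      f <- printed$factor[i]
      expect_equal(unname(ra$level_means[, f]),
                   unname(unlist(printed[i, c("L1", "L2", "L3", "L4")])),
                   tolerance = 0.006)
    }
  }
})

test_that("grand mean equals the mean of level means for every factor", {
  q <- quality_treatment_means()
  ra <- range_analysis(q, "FQI")
  grand <- mean(q$FQI)
  for (f in colnames(ra$level_means))
    expect_equal(mean(ra$level_means[, f]), grand, tolerance = 1e-12)
})

test_that("range analysis recovers planted best levels on noiseless data", {
  design <- build_design()
  set.seed(31)
  for (rep in 1:20) {
    planted <- sample(1:4, 5, replace = TRUE)
    eff <- matrix(0, 4, 5, dimnames = list(NULL, design$factors))
    for (k in 1:5) eff[planted[k], k] <- 0.5
    lv <- as.matrix(design$treatments[, design$factors])
    q <- data.frame(
      treatment = design$treatments$treatment,
      value = 10 + rowSums(vapply(1:5, function(k) eff[lv[, k], k],
                                  numeric(16))))
    ra <- range_analysis(q, "value")
    expect_equal(unname(ra$best_level), planted)
  }
})

test_that("a constant trait yields zero ranges and a tie warning", {
  q <- data.frame(treatment = paste0("T", 1:16), value = 1)
  expect_warning(ra <- range_analysis(q, "value"), "tie")
  expect_equal(unname(ra$ranges), rep(0, 5))
  expect_equal(ra$best_combination, "N1P1K1Ca1Mg1")
})

test_that("missing treatments are reported by name", {
  q <- data.frame(treatment = paste0("T", 1:15), value = rnorm(15))
  expect_error(range_analysis(q, "value"), "T16")
})

test_that("factor F values put a planted strong factor first", {
  design <- build_design()
  set.seed(17)
  lv <- as.matrix(design$treatments[, design$factors])
  hits <- 0
  for (s in 1:30) {
    k <- sample(1:5, 1)
    eff <- c(-0.9, -0.3, 0.3, 0.9)
    recs <- do.call(rbind, lapply(1:5, function(rep) data.frame(
      treatment = design$treatments$treatment,
      value = 10 + eff[lv[, k]] + rnorm(16, 0, 0.45))))
    ff <- factor_f_values(recs, "value", design)
    if (which.max(ff$f_values) == k) hits <- hits + 1
  }
  expect_gte(hits, 29)
})

test_that("balanced main-effect sums of squares decompose the total", {
  design <- build_design()
  set.seed(23)
  recs <- do.call(rbind, lapply(1:3, function(rep) data.frame(
    treatment = design$treatments$treatment,
    value = rnorm(16, 10, 1))))
  ff <- factor_f_values(recs, "value", design)
  an <- ff$anova
  total_ss <- sum((recs$value - mean(recs$value))^2)
  expect_equal(sum(an[["Sum Sq"]]), total_ss, tolerance = 1e-8)
})

test_that("the published F values order as published", {
  f <- c(N = 1.17, P2O5 = 1.15, K2O = 0.41, CaO = 0.27, MgO = 0.74)
  expect_equal(factor_order_string(f), "N > P > Mg > K > Ca")
  f_tss <- c(N = 2.14, P2O5 = 0.52, K2O = 0.70, CaO = 1.27, MgO = 0.32)
  expect_equal(factor_order_string(f_tss), "N > Ca > K > P > Mg")
})

test_that("F values require replication", {
  q <- data.frame(treatment = paste0("T", 1:16), value = rnorm(16))
  expect_error(factor_f_values(q, "value"), "replicate")
})

test_that("zero-noise, zero-effect data yield vanishing F values", {
  design <- build_design()
  recs <- do.call(rbind, lapply(1:3, function(rep) data.frame(
    treatment = design$treatments$treatment, value = 5)))
  ff <- suppressWarnings(factor_f_values(recs, "value", design))
  expect_true(all(ff$f_values < 1e-6))
  expect_equal(ff$order_string, "N > P > K > Ca > Mg")  # stable tie-break
})

test_that("LSD letters match brute-force pairwise decisions", {
  set.seed(9)
  for (case in 1:10) {
    k <- sample(3:6, 1)
    recs <- data.frame(
      treatment = rep(paste0("T", 1:k), each = 4),
      value = rnorm(4 * k, rep(runif(k, 0, 3), each = 4), 0.5))
    grp <- lsd_groups(recs, "value")
    pairs <- oracle_lsd_pairs(recs, "value")
    for (i in seq_len(nrow(grp))) for (j in seq_len(nrow(grp))) {
      if (i == j) next
      share <- any(strsplit(grp$group[i], "")[[1]] %in%
                   strsplit(grp$group[j], "")[[1]])
      differ <- pairs[grp$treatment[i], grp$treatment[j]]
      if (share) expect_false(differ)
    }
    # treatments in no common group must differ significantly
    # (balanced case: contiguous intervals capture all ns pairs)
    for (i in seq_len(nrow(grp))) for (j in seq_len(nrow(grp))) {
      if (i >= j) next
      share <- any(strsplit(grp$group[i], "")[[1]] %in%
                   strsplit(grp$group[j], "")[[1]])
      if (!share)
        expect_true(pairs[grp$treatment[i], grp$treatment[j]])
    }
  }
})

test_that("LSD letters collapse and separate in the obvious cases", {
  recs <- data.frame(treatment = rep(c("A", "B", "C"), each = 3),
                     value = rep(5, 9))
  grp <- lsd_groups(recs, "value")
  expect_true(all(grp$group == "a"))
  two <- make_two_group_records()
  grp2 <- lsd_groups(two, "value")
  expect_equal(sort(unique(grp2$group)), c("a", "b"))
  expect_error(lsd_groups(data.frame(treatment = "A", value = 1), "value"),
               "2 treatments")
})
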