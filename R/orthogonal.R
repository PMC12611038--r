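# Orthogonal-design screening: per-level means, range analysis, factor
# F values, LSD letter groupings and best-level combinations.

#' Range analysis of an orthogonal trial trait
#'
#' Computes, for each design factor, the four level means of a trait, the
#' range (max - min) of those level means, the best (trait-maximizing)
#' level, and the concatenated best-level combination. Level means are by
#' default computed from treatment means (each treatment weighted
#' equally), so published treatment-mean tables reproduce the published
#' level block; set `use_treatment_means = FALSE` to weight raw
#' replicates instead (identical on balanced data).
#'
#' @param records data.frame with a treatment column and the trait column;
#'   one or more rows (replicates) per treatment.
#' @param trait Name of the trait column.
#' @param design An `l16_design`, default [build_design()].
#' @param treatment Name of the treatment column (default `"treatment"`).
#' @param use_treatment_means Average replicates to treatment means first
#'   (default `TRUE`).
#' @return An object of class `range_analysis`: list with `trait`,
#'   `level_means` (4 x 5 matrix), `ranges`, `best_level` (named integer
#'   vector), and `best_combination` (label).
#' @examples
#' q <- quality_treatment_means()
#' q$value <- q$FQI
#' range_analysis(q, "FQI")$best_combination  # "N3P1K2Ca1Mg2"
#' @export
range_analysis <- function(records, trait, design = build_design(),
                           treatment = "treatment",
                           use_treatment_means = TRUE) {
  if (!all(c(treatment, trait) %in% names(records)))
    stop("records must have columns ", treatment, " and ", trait)
  des <- design$treatments
  missing_tr <- setdiff(des$treatment, records[[treatment]])
  if (length(missing_tr))
    stop("no records for treatment(s): ",
         paste(missing_tr, collapse = ", "))
  v <- records[[trait]]
  tr <- records[[treatment]]
  if (use_treatment_means) {
    tm <- tapply(v, tr, mean)
    v <- as.numeric(tm[des$treatment])
    lv <- as.matrix(des[, design$factors])
  } else {
    lv <- as.matrix(des[match(tr, des$treatment), design$factors])
  }
  level_means <- matrix(NA_real_, 4, length(design$factors),
                        dimnames = list(paste0("L", 1:4), design$factors))
  for (f in design$factors)
    level_means[, f] <- as.numeric(tapply(v, factor(lv[, f], 1:4), mean))
  ranges <- apply(level_means, 2, function(z) max(z) - min(z))
  best <- apply(level_means, 2, function(z) {
    w <- which(z == max(z))
    if (length(w) > 1)
      warning("tie among level means; lowest level taken")
    w[1]
  })
  structure(list(trait = trait, level_means = level_means,
                 ranges = ranges,
                 best_level = stats::setNames(as.integer(best),
                                              design$factors),
                 best_combination = combination_label(best)),
            class = "range_analysis")
}

#' @export
print.range_analysis <- function(x, ...) {
  cat("Range analysis of", x$trait, "\n\n")
  print(round(rbind(x$level_means, Range = x$ranges), 4))
  cat("\nBest levels:", x$best_combination, "\n")
  invisible(x)
}

#' Factor F values from replicated orthogonal-trial data
#'
#' Fits the main-effects ANOVA of the trait on all five design factors
#' (each as a 4-level categorical) with the residual error taken from
#' replicate variation after removing all main effects, and returns each
#' factor's `F = MS_factor / MS_error` together with the descending-F
#' influence ordering (ties broken by design factor order).
#'
#' @inheritParams range_analysis
#' @return List with `f_values` (named numeric), `factor_order`
#'   (character vector), `order_string` (e.g. `"N > P > Mg > K > Ca"`),
#'   and the underlying `anova` table.
#' @export
factor_f_values <- function(records, trait, design = build_design(),
                            treatment = "treatment") {
  des <- design$treatments
  tr <- records[[treatment]]
  counts <- table(tr)
  if (any(counts < 2) || length(counts) < 16)
    stop("F values need >= 2 replicate observations per treatment")
  lv <- des[match(tr, des$treatment), design$factors]
  dat <- data.frame(y = records[[trait]],
                    lapply(lv, function(z) factor(z, 1:4)))
  names(dat) <- c("y", design$factors)
  fml <- stats::as.formula(paste("y ~", paste(design$factors,
                                              collapse = " + ")))
  fit <- stats::aov(fml, data = dat)
  an <- stats::anova(fit)
  ms <- an[["Mean Sq"]]
  mse <- max(ms[nrow(an)], .Machine$double.eps)  # guard exact-fit data
  f <- ms[seq_along(design$factors)] / mse
  # degenerate data (no effects, no noise): treat numeric dust as zero
  dust <- .Machine$double.eps * (mean(abs(dat$y)) + 1)^2
  f[ms[seq_along(design$factors)] < dust] <- 0
  names(f) <- design$factors
  ord <- order(-f, seq_along(f))
  labels <- .factor_codes[design$factors][ord]
  list(f_values = f,
       factor_order = unname(labels),
       order_string = factor_order_string(f),
       anova = an)
}

#' Influence-order string from factor F values
#'
#' @param f_values Named numeric vector of F values in design factor
#'   order (names may be factor names or short codes).
#' @return A string such as `"N > P > Mg > K > Ca"`.
#' @examples
#' factor_order_string(c(N = 1.17, P2O5 = 1.15, K2O = 0.41,
#'                       CaO = 0.27, MgO = 0.74))
#' @export
factor_order_string <- function(f_values) {
  nm <- names(f_values)
  codes <- ifelse(nm %in% names(.factor_codes), .factor_codes[nm], nm)
  ord <- order(-f_values, seq_along(f_values))
  paste(codes[ord], collapse = " > ")
}

#' LSD letter groupings of treatment means
#'
#' One-way ANOVA across treatments followed by Fisher's least significant
#' difference test on all pairs; treatments that do not differ
#' significantly share a letter. Letters are assigned on the means sorted
#' in descending order (`a` contains the top mean). Designed for balanced
#' data; with unequal replication the per-pair LSD uses the pair's own
#' standard error.
#'
#' @param records data.frame with treatment and trait columns, >= 2
#'   replicates per treatment.
#' @param trait Trait column name.
#' @param treatment Treatment column name.
#' @param alpha Significance level, default 0.05.
#' @return data.frame with `treatment`, `mean`, `n`, `group` (letters),
#'   sorted by descending mean.
#' @export
lsd_groups <- function(records, trait, treatment = "treatment",
                       alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  tr <- factor(records[[treatment]])
  if (nlevels(tr) < 2) stop("need >= 2 treatments")
  y <- records[[trait]]
  means <- tapply(y, tr, mean)
  ns <- tapply(y, tr, length)
  df_err <- length(y) - nlevels(tr)
  if (df_err < 1) stop("LSD needs replication within treatments")
  mse <- sum(tapply(y, tr, function(z) sum((z - mean(z))^2))) / df_err
  tcrit <- stats::qt(1 - alpha / 2, df_err)
  ord <- order(-means)
  m <- means[ord]; n <- ns[ord]
  k <- length(m)
  differ <- function(i, j) {
    lsd <- tcrit * sqrt(mse * (1 / n[i] + 1 / n[j]))
    abs(m[i] - m[j]) > lsd
  }
  # maximal contiguous non-significant intervals on the sorted means
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(vapply(i:j, function(a) differ(a, j + 1),
                                logical(1))))
      j <- j + 1
    intervals[[i]] <- c(i, j)
  }
  keep <- rep(TRUE, k)
  for (i in seq_len(k))
    for (j in seq_len(k))
      if (i != j && intervals[[j]][1] <= intervals[[i]][1] &&
          intervals[[i]][2] <= intervals[[j]][2] &&
          !identical(intervals[[i]], intervals[[j]]))
        keep[i] <- FALSE
  ivs <- unique(intervals[keep])
  ivs <- ivs[order(vapply(ivs, `[`, numeric(1), 1))]
  groups <- character(k)
  for (g in seq_along(ivs)) {
    idx <- ivs[[g]][1]:ivs[[g]][2]
    groups[idx] <- paste0(groups[idx], letters[g])
  }
  data.frame(treatment = names(m), mean = as.numeric(m),
             n = as.integer(n), group = groups,
             row.names = NULL, stringsAsFactors = FALSE)
}
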