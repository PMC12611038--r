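# Compositional nutrient diagnosis machinery: diagnostic tissue/stage
# selection by coefficient of variation, cumulative variance-ratio
# functions of normalized FQI, cubic fits and inflection cutoffs,
# high-FQI reference sub-populations and optimum nutrient ranges.

#' Select the diagnostic tissue and stage per element by lowest CV
#'
#' For every stage x tissue x element combination, computes the
#' coefficient of variation (100 * sample SD / mean) of the nutrient
#' concentration across experimental units; per element, the stage x
#' tissue with the lowest CV is the diagnostic sampling combination
#' (nutrient concentrations there are most stable across fertilization
#' treatments).
#'
#' @param plant data.frame with columns `stage`, `tissue`, `element`,
#'   `value` (one row per unit x variable; >= 2 rows per variable).
#' @return List with `selection` (data.frame: `element`, `stage`,
#'   `tissue`, `cv`) and `cv_table` (all CVs).
#' @export
select_diagnostic_tissue <- function(plant) {
  need <- c("stage", "tissue", "element", "value")
  if (!all(need %in% names(plant)))
    stop("plant table must have columns ", paste(need, collapse = ", "))
  key <- interaction(plant$stage, plant$tissue, plant$element, drop = TRUE)
  sp <- split(plant$value, key)
  info <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
  mu <- vapply(sp, mean, numeric(1))
  sdv <- vapply(sp, stats::sd, numeric(1))
  if (any(mu == 0)) {
    warning("variables with zero mean excluded from CV ranking")
    keep <- mu != 0
    info <- info[keep, , drop = FALSE]; mu <- mu[keep]; sdv <- sdv[keep]
  }
  cv_table <- data.frame(stage = info[, 1], tissue = info[, 2],
                         element = info[, 3], cv = 100 * sdv / mu,
                         stringsAsFactors = FALSE)
  sel <- do.call(rbind, lapply(split(cv_table, cv_table$element),
                               function(d) d[which.min(d$cv), ]))
  rownames(sel) <- NULL
  list(selection = sel[, c("element", "stage", "tissue", "cv")],
       cv_table = cv_table)
}

#' Cumulative variance-ratio function of normalized FQI
#'
#' Units are sorted by normalized FQI in descending order. For every
#' admissible split `j` (top-`j` units = candidate high-FQI group, `j`
#' from `m_min` to `n - m_min`), the between-subpopulation variance ratio
#' `V_j = Var(top j) / Var(rest)` is computed; the cumulative function is
#' the running sum of the `V_j`, normalized so the last admissible split
#' reaches 100. Each point is reported at `X_j`, the normalized FQI of
#' the j-th sorted unit, so the function is non-decreasing in `j` and
#' non-increasing in `X`. Units tied on `fqi_norm` are kept in the same
#' subgroup (splits inside a tie group are not admissible).
#'
#' @param values Nutrient concentrations (mg/g), one per unit.
#' @param fqi_norm Normalized FQI in `[0, 1]`, one per unit.
#' @param m_min Minimum subgroup size (default 3).
#' @param orientation `"top_over_rest"` (default; reproduces the
#'   published curve shape) or `"rest_over_top"`.
#' @return data.frame with columns `j`, `x` (split FQI), `v` (variance
#'   ratio) and `F` (cumulative, percent).
#' @export
cumulative_variance_function <- function(values, fqi_norm, m_min = 3,
                                         orientation = c("top_over_rest",
                                                         "rest_over_top")) {
  orientation <- match.arg(orientation)
  n <- length(values)
  stopifnot(length(fqi_norm) == n)
  if (m_min < 2) stop("m_min must be >= 2 (variance needs 2 points)")
  if (n < 2 * m_min + 1)
    stop("need at least 2*m_min + 1 = ", 2 * m_min + 1, " units")
  if (length(unique(fqi_norm)) == 1)
    stop("fqi_norm values are all equal")
  ord <- order(fqi_norm, decreasing = TRUE)
  v <- values[ord]; f <- fqi_norm[ord]
  js <- (m_min:(n - m_min))
  js <- js[f[js] > f[js + 1]]  # keep tie groups together
  if (!length(js)) stop("no admissible splits (ties span the range)")
  ratio <- rep(NA_real_, length(js))
  skipped <- FALSE
  for (k in seq_along(js)) {
    j <- js[k]
    v_top <- stats::var(v[1:j]); v_rest <- stats::var(v[(j + 1):n])
    num <- if (orientation == "top_over_rest") v_top else v_rest
    den <- if (orientation == "top_over_rest") v_rest else v_top
    if (den == 0 || num == 0) { skipped <- TRUE; next }
    ratio[k] <- num / den
  }
  if (skipped) warning("splits with a zero-variance subgroup skipped")
  keep <- !is.na(ratio)
  if (!any(keep)) stop("all splits had zero-variance subgroups")
  js <- js[keep]; ratio <- ratio[keep]
  data.frame(j = js, x = f[js], v = ratio,
             F = 100 * cumsum(ratio) / sum(ratio))
}

#' Fit the cubic cumulative-variance function
#'
#' Ordinary least-squares fit of `F = A X^3 + B X^2 + C X + D` to the
#' points of a cumulative variance-ratio curve, with R-squared about the
#' mean and the inflection cutoff `-B/(3A)` attached.
#'
#' @param points data.frame with columns `x` and `F`
#'   (from [cumulative_variance_function()]), or two numeric vectors via
#'   `x`/`F` arguments.
#' @param x,F Alternative vector interface.
#' @return An object of class `cutoff_fit`: list with `coefficients`
#'   (named `A`, `B`, `C`, `D`), `r_squared`, `cutoff` (NA with a warning
#'   when the cubic term vanishes), `n_points`.
#' @export
fit_cubic <- function(points = NULL, x = points$x, F = points$F) {
  if (length(unique(x)) < 4)
    stop("cubic fit needs >= 4 distinct x values")
  fit <- stats::lm(F ~ x + I(x^2) + I(x^3))
  cf <- stats::coef(fit)
  coefficients <- c(A = unname(cf[4]), B = unname(cf[3]),
                    C = unname(cf[2]), D = unname(cf[1]))
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((F - mean(F))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  scale <- max(abs(coefficients), .Machine$double.eps)
  cutoff <- if (abs(coefficients["A"]) < 1e-8 * scale) {
    warning("cubic term ~ 0: inflection cutoff undefined")
    NA_real_
  } else inflection_cutoff(coefficients["A"], coefficients["B"])
  structure(list(coefficients = coefficients, r_squared = r2,
                 cutoff = unname(cutoff), n_points = length(x)),
            class = "cutoff_fit")
}

#' @export
print.cutoff_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("F(X) = %.4g X^3 + %.4g X^2 + %.4g X + %.4g\n",
              cf["A"], cf["B"], cf["C"], cf["D"]))
  cat(sprintf("R^2 = %.4f   cutoff Y = -B/(3A) = %.4f   (n = %d)\n",
              x$r_squared, x$cutoff, x$n_points))
  invisible(x)
}

#' Inflection-point cutoff of a cubic
#'
#' The zero of the second derivative `6 A X + 2 B` of
#' `A X^3 + B X^2 + C X + D`, i.e. `Y = -B / (3 A)`.
#'
#' @param A,B Cubic and quadratic coefficients; `A` must be nonzero.
#' @return The inflection abscissa.
#' @examples
#' inflection_cutoff(-61.412, 150.17)  # 0.8151
#' @export
inflection_cutoff <- function(A, B) {
  if (any(A == 0)) stop("A = 0: inflection cutoff undefined")
  -B / (3 * A)
}

#' Select the high-FQI reference sub-population
#'
#' Units whose normalized FQI is at or above the cutoff.
#'
#' @param fqi_norm Normalized FQI per unit.
#' @param cutoff Finite cutoff value.
#' @return List with `index` (selected positions), `size` and `fraction`
#'   (percent of all units).
#' @export
select_high_subpop <- function(fqi_norm, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  idx <- which(fqi_norm >= cutoff)
  if (!length(idx))
    stop("no units at or above cutoff ", cutoff,
         "; review the cutoff value")
  list(index = idx, size = length(idx),
       fraction = 100 * length(idx) / length(fqi_norm))
}

#' Optimum nutrient range over a reference sub-population
#'
#' The minimum and maximum of a nutrient over the high-FQI reference
#' sub-population, interpreted as the sufficiency window.
#'
#' @param values Nutrient values of the sub-population (>= 2).
#' @return Named numeric vector `c(low=, high=)`.
#' @export
optimum_range <- function(values) {
  if (length(values) < 2)
    stop("optimum range needs a sub-population of >= 2 units")
  c(low = min(values), high = max(values))
}

#' Communal cutoff across diagnostic variables
#'
#' The communal cutoff is the maximum defined per-variable cutoff across
#' the plant diagnostic variables: the strictest single criterion, so the
#' communal reference sub-population is high-FQI under every variable's
#' own curve.
#'
#' @param fits A list of `cutoff_fit` objects or a numeric vector of
#'   cutoffs (NAs allowed).
#' @return The communal cutoff value.
#' @examples
#' communal_cutoff(c(0.8151, 0.6597, 0.5507, 0.3860, 0.4655))  # 0.8151
#' @export
communal_cutoff <- function(fits) {
  cuts <- if (is.numeric(fits)) fits
          else vapply(fits, function(f) f$cutoff, numeric(1))
  cuts <- cuts[is.finite(cuts)]
  if (!length(cuts)) stop("no defined cutoffs")
  max(cuts)
}

#' Full CND diagnosis over a set of nutrient variables
#'
#' For each nutrient variable (column), builds the cumulative
#' variance-ratio curve against normalized FQI, fits the cubic, extracts
#' the inflection cutoff, and derives two optimum ranges: range 1 from
#' the variable's own cutoff and range 2 from the communal cutoff (the
#' maximum cutoff across the designated plant variables, or across all
#' variables when none are flagged as plant).
#'
#' @param nutrients data.frame or matrix, units x variables (mg/g).
#' @param fqi_norm Normalized FQI per unit.
#' @param plant_vars Character vector naming the columns whose cutoffs
#'   define the communal cutoff (default: all columns). Only cutoffs
#'   that select a reference sub-population of at least 2 units are
#'   eligible (a cutoff beyond the observed score range diagnoses
#'   nothing); if no plant-variable cutoff qualifies, the rule falls
#'   back to the eligible cutoffs of all variables.
#' @param m_min,orientation Passed to [cumulative_variance_function()].
#' @return List with `table` (one row per variable: coefficients,
#'   `r_squared`, `cutoff`, `subpop_size`, `subpop_fraction`, range
#'   bounds), `communal_cutoff`, `fits`, `curves`.
#' @export
cnd_diagnosis <- function(nutrients, fqi_norm,
                          plant_vars = colnames(nutrients),
                          m_min = 3, orientation = "top_over_rest") {
  nutrients <- as.data.frame(nutrients)
  vars <- colnames(nutrients)
  curves <- fits <- stats::setNames(vector("list", length(vars)), vars)
  for (v in vars) {
    curves[[v]] <- cumulative_variance_function(nutrients[[v]], fqi_norm,
                                                m_min = m_min,
                                                orientation = orientation)
    fits[[v]] <- fit_cubic(curves[[v]])
  }
  eligible <- function(vs) {
    cuts <- vapply(fits[vs], function(f) f$cutoff, numeric(1))
    cuts[is.finite(cuts) & vapply(cuts, function(ct)
      is.finite(ct) && sum(fqi_norm >= ct) >= 2, logical(1))]
  }
  comm_pool <- eligible(intersect(plant_vars, vars))
  if (!length(comm_pool)) comm_pool <- eligible(vars)
  comm <- communal_cutoff(comm_pool)
  rows <- lapply(vars, function(v) {
    f <- fits[[v]]
    cut1 <- f$cutoff
    # a cutoff outside the observed score range leaves range 1 undefined
    sub1 <- if (is.finite(cut1))
      tryCatch(select_high_subpop(fqi_norm, cut1),
               error = function(e) NULL) else NULL
    sub2 <- select_high_subpop(fqi_norm, comm)
    r1 <- if (!is.null(sub1) && sub1$size >= 2)
      optimum_range(nutrients[[v]][sub1$index]) else c(low = NA, high = NA)
    r2 <- if (sub2$size >= 2)
      optimum_range(nutrients[[v]][sub2$index]) else c(low = NA, high = NA)
    data.frame(variable = v,
               A = f$coefficients["A"], B = f$coefficients["B"],
               C = f$coefficients["C"], D = f$coefficients["D"],
               r_squared = f$r_squared, cutoff = cut1,
               subpop_size = if (is.null(sub1)) NA_integer_ else sub1$size,
               subpop_fraction = if (is.null(sub1)) NA_real_
                                 else sub1$fraction,
               range1_low = r1["low"], range1_high = r1["high"],
               range2_low = r2["low"], range2_high = r2["high"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), communal_cutoff = comm,
       fits = fits, curves = curves)
}

#' Pairwise Pearson correlations between nutrients and quality traits
#'
#' Standard Pearson correlation with two-sided p-values for every
#' nutrient x trait pair, with significance stars at 0.05 / 0.01 / 0.001.
#' Pairs with a zero-variance series are skipped with a warning.
#'
#' @param nutrients data.frame, units x nutrient variables.
#' @param traits data.frame, units x quality traits.
#' @return data.frame with `nutrient`, `trait`, `r`, `p`, `stars`.
#' @export
correlation_table <- function(nutrients, traits) {
  nutrients <- as.data.frame(nutrients); traits <- as.data.frame(traits)
  if (nrow(nutrients) != nrow(traits))
    stop("nutrients and traits must have the same number of units")
  if (nrow(nutrients) < 3) stop("need >= 3 paired observations")
  out <- list(); skipped <- FALSE
  for (nv in names(nutrients)) for (tv in names(traits)) {
    x <- nutrients[[nv]]; y <- traits[[tv]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) { skipped <- TRUE; next }
    ct <- stats::cor.test(x, y, method = "pearson")
    p <- ct$p.value
    out[[length(out) + 1]] <- data.frame(
      nutrient = nv, trait = tv, r = unname(ct$estimate), p = p,
      stars = if (p < 0.001) "***" else if (p < 0.01) "**"
              else if (p < 0.05) "*" else "",
      stringsAsFactors = FALSE)
  }
  if (skipped) warning("pairs with a constant series skipped")
  do.call(rbind, out)
}
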