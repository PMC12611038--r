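# The precision fertilization model: piecewise soil-test response with
# the optimum-range gate, annual plan assembly, demand-ratio dose
# splitting and a non-negative least-squares fertilizer blend solver.

#' Precision fertilization amount for one interval and element
#'
#' The piecewise dose rule: when the soil test `x` has reached the upper
#' bound of the optimum range (`x >= x_max`) no fertilizer is applied;
#' otherwise the linear soil-test response `a x + b` is scaled by the
#' yield-expectation bracket `(1 - FR) + FR * EY / 1500`, where FR is the
#' fruit-to-whole-plant uptake ratio of the element and EY the expected
#' yield (kg) on the 1500 kg reference basis. A negative response value
#' is floored at zero with a warning (a fertilizer amount cannot be
#' negative; the gate only addresses `x >= x_max`).
#'
#' @param x Soil-test value, mg/g (>= 0).
#' @param a,b Linear model slope and intercept.
#' @param x_max Optimum-range upper bound (gate), mg/g.
#' @param fr Fruit uptake ratio in `[0, 1]`.
#' @param ey Expected yield, kg (> 0).
#' @return Fertilizer amount, kg (>= 0).
#' @examples
#' pfa(0.2, a = -10.58, b = 3.5549, x_max = 0.336,
#'     fr = 0.2531, ey = 3000)  # 1.8031
#' @export
pfa <- function(x, a, b, x_max, fr, ey) {
  if (any(x < 0)) stop("soil test x must be non-negative")
  if (any(ey <= 0)) stop("expected yield must be positive")
  if (any(fr < 0 | fr > 1)) stop("fruit ratio must be in [0, 1]")
  raw <- (a * x + b) * ((1 - fr) + fr * ey / 1500)
  out <- ifelse(x >= x_max, 0, pmax(raw, 0))
  if (any(x < x_max & raw < 0))
    warning("negative model response floored at 0")
  out
}

#' Annual precision fertilization plan
#'
#' Applies the piecewise dose rule to every interval x element pair in
#' phenological order: at each stage the soil test of the interval's
#' start stage is re-evaluated against its optimum-range gate, so a pair
#' whose soil test is sufficient contributes zero while the remaining
#' pairs follow the linear response. Returns the per-pair doses and the
#' annual totals per element (oxide basis).
#'
#' @param soil_tests data.frame with columns `stage`, `element`
#'   (elemental basis: N, P, K, Ca, Mg), `value` (mg/g); one row per
#'   start stage x element.
#' @param models Model table, default [fertilization_models()].
#' @param fr Named fruit-ratio vector per oxide element; default from
#'   [uptake_reference()].
#' @param ey Expected yield, kg (default 1500, the reference basis).
#' @return List with `plan` (interval x element doses and gates) and
#'   `annual` (named per-element totals, kg).
#' @export
annual_plan <- function(soil_tests, models = fertilization_models(),
                        fr = NULL, ey = 1500) {
  if (is.null(fr)) {
    ur <- uptake_reference()
    fr <- stats::setNames(ur$fruit_ratio, .factors)
  }
  need <- c("stage", "element", "value")
  if (!all(need %in% names(soil_tests)))
    stop("soil_tests must have columns ", paste(need, collapse = ", "))
  key <- paste(soil_tests$stage, soil_tests$element)
  mkey <- paste(models$start_stage, models$soil_element)
  i <- match(mkey, key)
  if (anyNA(i))
    stop("missing soil test for: ",
         paste(unique(paste0(models$start_stage[is.na(i)], "_",
                             models$soil_element[is.na(i)])),
               collapse = ", "))
  plan <- models
  plan$x <- soil_tests$value[i]
  plan$fr <- fr[plan$element]
  plan$ey <- ey
  plan$pfa <- mapply(pfa, x = plan$x, a = plan$a, b = plan$b,
                     x_max = plan$x_max, fr = plan$fr, ey = ey)
  annual <- tapply(plan$pfa, plan$element, sum)[.factors]
  list(plan = plan, annual = annual)
}

#' Split an annual dose over stages by demand ratios
#'
#' `dose_i = annual * ratio_i / sum(ratios)`; the splits sum exactly to
#' the annual dose.
#'
#' @param annual Annual dose (kg).
#' @param ratios Non-negative stage ratios, not all zero (names kept).
#' @return Stage doses (kg).
#' @examples
#' split_by_demand_ratio(100, c(14, 18, 52, 7, 9))
#' @export
split_by_demand_ratio <- function(annual, ratios) {
  if (any(ratios < 0)) stop("ratios must be non-negative")
  s <- sum(ratios)
  if (s == 0) stop("ratios must not all be zero")
  annual * ratios / s
}

#' Solve a physical fertilizer blend for nutrient targets
#'
#' Finds non-negative product masses minimizing the squared deviation of
#' delivered nutrients from the targets (non-negative least squares over
#' the catalog's nutrient-fraction matrix), and reports the delivered
#' amounts and per-nutrient residuals.
#'
#' @param targets Named numeric vector of target nutrient amounts (kg,
#'   oxide basis; names among `N, P2O5, K2O, CaO, MgO`), all >= 0.
#' @param catalog Product table, default [fertilizer_catalog()].
#' @return List with `products` (named kg per product), `delivered`
#'   (named kg per nutrient), `residual` (targets - delivered).
#' @examples
#' solve_blend(c(K2O = 54.02))  # 100 kg potassium sulfate
#' @export
solve_blend <- function(targets, catalog = fertilizer_catalog()) {
  if (nrow(catalog) == 0) stop("empty fertilizer catalog")
  if (any(targets < 0)) stop("targets must be non-negative")
  nutrients <- intersect(.factors, names(catalog))
  b <- stats::setNames(rep(0, length(nutrients)), nutrients)
  bad <- setdiff(names(targets), nutrients)
  if (length(bad)) stop("unknown target nutrient: ",
                        paste(bad, collapse = ", "))
  b[names(targets)] <- targets
  A <- t(as.matrix(catalog[, nutrients]))
  colnames(A) <- catalog$product
  sol <- pracma::lsqnonneg(A, as.numeric(b))
  products <- stats::setNames(sol$x, catalog$product)
  delivered <- stats::setNames(as.numeric(A %*% sol$x), nutrients)
  list(products = products, delivered = delivered,
       residual = b - delivered)
}
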