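# Stage-wise nutrient demand accounting from destructive-harvest data:
# whole-plant content, between-stage demand, demand ratios, and uptake
# per unit yield.

#' Whole-plant nutrient content (AWP)
#'
#' Sum over tissues of nutrient concentration (mg/g dry mass) times
#' tissue dry mass (g), divided by 1000, giving grams of nutrient in the
#' whole plant.
#'
#' @param concentration Concentrations per tissue (mg/g).
#' @param dry_mass Dry masses per tissue (g), same length.
#' @return Whole-plant nutrient content in g.
#' @examples
#' awp(10, 100)  # 1 g
#' @export
awp <- function(concentration, dry_mass) {
  stopifnot(length(concentration) == length(dry_mass))
  if (any(concentration < 0) || any(dry_mass < 0))
    stop("concentrations and masses must be non-negative")
  sum(concentration * dry_mass) / 1000
}

#' Between-stage nutrient demand (DTS)
#'
#' Difference of whole-plant content between the later and earlier stage
#' of an interval. May be negative (net remobilization or loss) and is
#' reported signed.
#'
#' @param awp_later,awp_prev Whole-plant contents (g).
#' @return Demand in g (signed).
#' @export
dts <- function(awp_later, awp_prev) awp_later - awp_prev

#' Between-stage demand ratio (RTS)
#'
#' The interval demand as a percentage of the full-season (first to last
#' stage) demand. Signed by default, matching the defining ratio; set
#' `absolute = TRUE` to use absolute interval demands (their share of the
#' summed absolute demands).
#'
#' @param dts_interval Interval demand(s), g.
#' @param dts_total Full-season demand, g (nonzero).
#' @param absolute Use absolute values (default `FALSE`).
#' @return Percent(s).
#' @export
rts <- function(dts_interval, dts_total, absolute = FALSE) {
  if (absolute) {
    tot <- sum(abs(dts_interval))
    if (tot == 0) stop("all interval demands are zero")
    return(100 * abs(dts_interval) / tot)
  }
  if (dts_total == 0) stop("full-season demand is zero")
  100 * dts_interval / dts_total
}

#' Stage-wise demand summary of a destructive-harvest series
#'
#' Computes, per element and year: the whole-plant content (AWP) at each
#' stage (tissue means over trees first, then summed over tissues), the
#' between-stage demands (DTS) for consecutive stage intervals, and the
#' demand ratios (RTS) relative to the full-season demand. Per-year
#' summaries are computed first and then averaged across years. Fruit is
#' harvested at maturation: when the final (deciduous) stage carries no
#' fruit rows, the maturation-stage fruit content is carried into the
#' final stage total, so harvested fruit stays in the season's books.
#'
#' @param harvest data.frame with columns `year`, `tree`, `stage`,
#'   `tissue`, `element`, `concentration` (mg/g), `dry_mass` (g).
#' @param stages Stage order (default the seven phenological stages).
#' @param fruit_tissue Name of the fruit tissue (default
#'   `"inflorescences/fruit"`).
#' @return List with `awp` (year x stage x element, long data.frame),
#'   `demand` (per interval x element: `dts`, `rts`, averaged over
#'   years), and `per_year` (un-averaged interval table).
#' @export
stage_demand <- function(harvest,
                         stages = c("GS", "IFS", "EBS", "SDS", "VS",
                                    "MS", "DS"),
                         fruit_tissue = "inflorescences/fruit") {
  need <- c("year", "tree", "stage", "tissue", "element",
            "concentration", "dry_mass")
  if (!all(need %in% names(harvest)))
    stop("harvest must have columns ", paste(need, collapse = ", "))
  if (any(harvest$concentration < 0) || any(harvest$dry_mass < 0))
    stop("concentrations and masses must be non-negative")
  harvest$stage <- as.character(harvest$stage)
  miss <- setdiff(stages, unique(harvest$stage))
  if (length(miss)) stop("missing stages: ", paste(miss, collapse = ", "))

  # mean content per tissue over trees, then sum over tissues
  agg <- stats::aggregate(
    cbind(content = harvest$concentration * harvest$dry_mass / 1000),
    by = list(year = harvest$year, stage = harvest$stage,
              tissue = harvest$tissue, element = harvest$element),
    FUN = mean)
  awp_tab <- stats::aggregate(content ~ year + stage + element, data = agg,
                              FUN = sum)
  names(awp_tab)[names(awp_tab) == "content"] <- "awp"

  last <- stages[length(stages)]
  ms_stage <- stages[length(stages) - 1]
  has_fruit_last <- any(agg$stage == last & agg$tissue == fruit_tissue)
  if (!has_fruit_last) {
    fruit_ms <- agg[agg$stage == ms_stage & agg$tissue == fruit_tissue, ]
    if (nrow(fruit_ms)) {
      add <- stats::aggregate(content ~ year + element, data = fruit_ms,
                              FUN = sum)
      i <- match(paste(awp_tab$year, awp_tab$element)[awp_tab$stage == last],
                 paste(add$year, add$element))
      awp_tab$awp[awp_tab$stage == last] <-
        awp_tab$awp[awp_tab$stage == last] + add$content[i]
    }
  }

  intervals <- paste(stages[-length(stages)], stages[-1], sep = "-")
  per_year <- list()
  for (yr in unique(awp_tab$year)) for (el in unique(awp_tab$element)) {
    a <- awp_tab[awp_tab$year == yr & awp_tab$element == el, ]
    a <- a[match(stages, a$stage), ]
    d <- diff(a$awp)
    total <- a$awp[length(stages)] - a$awp[1]
    per_year[[length(per_year) + 1]] <- data.frame(
      year = yr, element = el, interval = intervals,
      awp_prev = a$awp[-length(stages)], awp_later = a$awp[-1],
      dts = d, rts = rts(d, total), stringsAsFactors = FALSE)
  }
  per_year <- do.call(rbind, per_year)
  demand <- stats::aggregate(cbind(dts, rts) ~ interval + element,
                             data = per_year, FUN = mean)
  demand <- demand[order(match(demand$element, c("N", "P", "K", "Ca", "Mg")),
                         match(demand$interval, intervals)), ]
  rownames(demand) <- NULL
  list(awp = awp_tab, demand = demand, per_year = per_year)
}

#' Nutrient uptake per 1000 kg fruit and fruit uptake ratio
#'
#' Converts annual whole-plant uptake per tree into kg of nutrient per
#' 1000 kg of fruit produced, and the fruit-to-whole-plant uptake ratio
#' FR used by the precision fertilization model.
#'
#' @param uptake Annual whole-plant nutrient uptake, g per tree.
#' @param yield Fruit yield, kg per tree (> 0).
#' @param fruit_uptake Annual nutrient uptake into fruit, g per tree
#'   (<= `uptake`).
#' @return List with `total_per_1000kg` (kg), `fruit_per_1000kg` (kg),
#'   `fruit_ratio` (fraction).
#' @examples
#' uptake_per_yield(43.7, 10, 11.1)
#' @export
uptake_per_yield <- function(uptake, yield, fruit_uptake) {
  if (any(yield <= 0)) stop("yield must be positive")
  if (any(fruit_uptake > uptake))
    stop("fruit uptake cannot exceed whole-plant uptake")
  list(total_per_1000kg = uptake / yield,
       fruit_per_1000kg = fruit_uptake / yield,
       fruit_ratio = fruit_uptake / uptake)
}
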