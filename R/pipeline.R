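# End-to-end orchestration: synthetic or user data -> FQI -> orthogonal
# analysis -> CND diagnosis -> demand constants -> fertilization plan,
# with CSV interchange between stages and a run log.

#' Build a run configuration
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Seed for synthetic data (required when no input files are
#'   given).
#' @param quality,plant,soil Optional CSV paths with user data (tidy
#'   layouts as written by the synthetic generators); when `NULL`,
#'   synthetic data are generated from `scenario`.
#' @param scenario An [experiment_scenario()]; defaults to
#'   `experiment_scenario(seed)`.
#' @param weights TOPSIS weights (default [fqi_weights()]).
#' @param cohort FQI cohort rule (`"year"` or `"pooled"`).
#' @param m_min,orientation CND options.
#' @param ey Expected yield (kg) for the fertilization plan.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = NULL, quality = NULL, plant = NULL,
                       soil = NULL, scenario = NULL,
                       weights = fqi_weights(), cohort = "year",
                       m_min = 3, orientation = "top_over_rest",
                       ey = 1500) {
  synthetic <- is.null(quality)
  if (synthetic && is.null(seed) && is.null(scenario))
    stop("synthetic runs need a seed (or a scenario)")
  for (p in c(quality, plant, soil))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  if (!synthetic && (is.null(plant) || is.null(soil)))
    stop("CND diagnosis requested without plant/soil nutrient files")
  if (is.null(scenario) && synthetic)
    scenario <- experiment_scenario(seed = seed)
  structure(list(out_dir = out_dir, seed = seed, quality = quality,
                 plant = plant, soil = soil, scenario = scenario,
                 weights = weights, cohort = cohort, m_min = m_min,
                 orientation = orientation, ey = ey,
                 synthetic = synthetic),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the experiment tables, scores the fruit quality
#' index, performs the orthogonal range/F analysis per trait, runs the
#' CND diagnosis over plant diagnostic and soil variables, assembles the
#' stage-wise demand constants, and derives a precision fertilization
#' plan from the mean soil tests. Writes `quality.csv`, `fqi.csv`,
#' `factor_report.csv`, `cnd_report.csv`, `demand_report.csv`,
#' `plan.csv` and `run_log.txt` to the configured directory; reruns with
#' the same seed are identical.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return The report bundle (named list of data.frames), invisibly.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- build_design()

  # --- data
  if (config$synthetic) {
    quality <- generate_quality(config$scenario, design)
    nutrients <- generate_nutrients(config$scenario, design)
    plant <- nutrients$plant; soil <- nutrients$soil
  } else {
    quality <- utils::read.csv(config$quality)
    plant <- utils::read.csv(config$plant)
    soil <- utils::read.csv(config$soil)
  }
  say("stage data: ", nrow(quality), " quality records, ",
      nrow(plant), " plant and ", nrow(soil), " soil observations")

  # --- FQI
  scored <- fqi_scores(quality, config$weights, cohort = config$cohort)
  say("stage fqi: scored ", nrow(scored), " records in ",
      length(unique(scored$year)), " cohort(s)")

  # --- orthogonal analysis
  fqi_by_tr <- summarize_by_treatment(scored, "fqi")
  factor_report <- list()
  for (tr in c("SFW", "TSS", "FF", "fqi")) {
    ra <- range_analysis(scored, tr, design)
    ff <- factor_f_values(scored, tr, design)
    factor_report[[tr]] <- data.frame(
      trait = tr, factor = design$factors,
      t(ra$level_means), range = ra$ranges,
      best_level = ra$best_level, f_value = ff$f_values,
      order_string = ff$order_string,
      best_combination = ra$best_combination,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  factor_report <- do.call(rbind, factor_report)
  say("stage orthogonal: best FQI combination ",
      factor_report$best_combination[factor_report$trait == "fqi"][1])

  # --- CND over treatment-year units
  unit_fqi <- stats::aggregate(fqi ~ treatment + year, data = scored,
                               FUN = mean)
  unit_fqi$fqi_norm <- normalize_fqi(unit_fqi$fqi)
  ukey <- paste(unit_fqi$treatment, unit_fqi$year)

  diag_sel <- select_diagnostic_tissue(plant)$selection
  pkey <- paste(plant$stage, plant$tissue, plant$element)
  dkey <- paste(diag_sel$stage, diag_sel$tissue, diag_sel$element)
  pd <- plant[pkey %in% dkey, ]
  pd$variable <- paste(pd$stage, substr(toupper(pd$tissue), 1, 1),
                       pd$element, sep = "_")
  soil$variable <- paste(soil$stage, soil$element, sep = "_")
  long <- rbind(
    data.frame(unit = paste(pd$treatment, pd$year), variable = pd$variable,
               value = pd$value, stringsAsFactors = FALSE),
    data.frame(unit = paste(soil$treatment, soil$year),
               variable = soil$variable, value = soil$value,
               stringsAsFactors = FALSE))
  wide <- stats::reshape(long, idvar = "unit", timevar = "variable",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[match(ukey, wide$unit), ]
  plant_vars <- unique(pd$variable)
  cnd <- cnd_diagnosis(wide[, setdiff(names(wide), "unit")],
                       unit_fqi$fqi_norm, plant_vars = plant_vars,
                       m_min = config$m_min,
                       orientation = config$orientation)
  say("stage cnd: communal cutoff ", round(cnd$communal_cutoff, 4),
      " over ", length(plant_vars), " plant variables")

  # --- demand constants
  demand_report <- merge(demand_proportions(), uptake_reference(),
                         by = "element", sort = FALSE)
  say("stage demand: shipped constants for ",
      length(unique(demand_report$element)), " elements")

  # --- fertilization plan from mean soil tests
  soil_tests <- stats::aggregate(value ~ stage + element, data = soil,
                                 FUN = mean)
  plan <- annual_plan(soil_tests, ey = config$ey)
  blend <- solve_blend(pmax(plan$annual, 0))
  plan_out <- plan$plan[, c("interval", "element", "x", "x_max", "pfa")]
  say("stage fertilize: annual totals (kg) ",
      paste(sprintf("%s=%.2f", names(plan$annual), plan$annual),
            collapse = ", "))

  bundle <- list(quality = quality, fqi = scored,
                 fqi_by_treatment = fqi_by_tr,
                 factor_report = factor_report,
                 cnd_report = cnd$table, demand_report = demand_report,
                 plan = plan_out,
                 blend = data.frame(product = names(blend$products),
                                    kg = as.numeric(blend$products)))
  paths <- c(quality = "quality.csv", fqi = "fqi.csv",
             factor_report = "factor_report.csv",
             cnd_report = "cnd_report.csv",
             demand_report = "demand_report.csv", plan = "plan.csv",
             blend = "blend.csv")
  for (nm in names(paths))
    utils::write.csv(bundle[[nm]], file.path(config$out_dir, paths[nm]),
                     row.names = FALSE)
  log_lines <- c(
    paste("vinefert", as.character(utils::packageVersion("vinefert"))),
    paste("seed:", if (is.null(config$seed)) "(files)" else config$seed),
    paste("cohort:", config$cohort), paste("m_min:", config$m_min),
    paste("orientation:", config$orientation),
    paste("expected yield:", config$ey),
    paste("records:", nrow(quality), "quality /", nrow(plant),
          "plant /", nrow(soil), "soil"))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(bundle)
}

#' Render report tables in the published layouts
#'
#' Reshapes a report bundle into the familiar trial-report layouts: the
#' treatment block with the L1-L4 level block, best level and F value per
#' trait; and the diagnosis table with the cubic function, R-squared,
#' cutoff and both optimum ranges per variable.
#'
#' @param bundle Output of [run_all()].
#' @return List with `quality_table` and `cnd_table` data.frames.
#' @export
render_tables <- function(bundle) {
  if (is.null(bundle$factor_report) || is.null(bundle$cnd_report))
    stop("incomplete bundle: need factor_report and cnd_report")
  fr <- bundle$factor_report
  quality_table <- do.call(rbind, lapply(split(fr, fr$trait), function(d) {
    vals <- rbind(t(as.matrix(d[, c("L1", "L2", "L3", "L4")])),
                  d$best_level, round(d$f_value, 2))
    block <- data.frame(trait = d$trait[1],
                        row = c(paste0("L", 1:4), "Best level", "F value"),
                        vals, stringsAsFactors = FALSE)
    names(block) <- c("trait", "row", d$factor)
    block
  }))
  rownames(quality_table) <- NULL
  cr <- bundle$cnd_report
  cnd_table <- data.frame(
    variable = cr$variable,
    fun = sprintf("F(X) = %.4g X^3 + %.4g X^2 + %.4g X + %.4g",
                  cr$A, cr$B, cr$C, cr$D),
    r_squared = round(cr$r_squared, 4), A = round(cr$A, 3),
    B = round(cr$B, 3), cutoff = round(cr$cutoff, 4),
    range1 = sprintf("%.3f-%.3f", cr$range1_low, cr$range1_high),
    range2 = sprintf("%.3f-%.3f", cr$range2_low, cr$range2_high),
    stringsAsFactors = FALSE)
  list(quality_table = quality_table, cnd_table = cnd_table)
}
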