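#!/usr/bin/env Rscript
# Compositional nutrient diagnosis on the synthetic treatment-years:
# CV-based diagnostic tissue selection, cumulative variance-ratio
# curves of normalized FQI, cubic fits, inflection cutoffs, the
# communal cutoff, and optimum nutrient ranges; plus the planted-window
# recovery summary over 100 seeds.

library(vinefert)

plant <- read.csv("results/data/plant_nutrients.csv")
soil <- read.csv("results/data/soil_nutrients.csv")
scored <- read.csv("results/fqi.csv")

sel <- select_diagnostic_tissue(plant)$selection
write.csv(sel, "results/diagnostic_tissues.csv", row.names = FALSE)
message("diagnostic tissue per element: ",
        paste(sel$element, paste0(sel$stage, "/", sel$tissue),
              collapse = ", "))

# one unit per treatment-year, pooled normalized FQI
unit <- aggregate(fqi ~ treatment + year, data = scored, FUN = mean)
unit$fqi_norm <- normalize_fqi(unit$fqi)
ukey <- paste(unit$treatment, unit$year)

pk <- paste(plant$stage, plant$tissue, plant$element)
sk <- paste(sel$stage, sel$tissue, sel$element)
pd <- plant[pk %in% sk, ]
pd$variable <- paste(pd$stage, toupper(substr(pd$tissue, 1, 1)),
                     pd$element, sep = "_")
soil$variable <- paste(soil$stage, soil$element, sep = "_")
long <- rbind(
  data.frame(unit = paste(pd$treatment, pd$year),
             variable = pd$variable, value = pd$value),
  data.frame(unit = paste(soil$treatment, soil$year),
             variable = soil$variable, value = soil$value))
wide <- reshape(long, idvar = "unit", timevar = "variable",
                direction = "wide")
names(wide) <- sub("^value\\.", "", names(wide))
wide <- wide[match(ukey, wide$unit), ]

cnd <- cnd_diagnosis(wide[, setdiff(names(wide), "unit")],
                     unit$fqi_norm, plant_vars = unique(pd$variable))
write.csv(cnd$table, "results/cnd_report.csv", row.names = FALSE)
message("communal cutoff (max over plant variables): ",
        round(cnd$communal_cutoff, 4))

# planted-window recovery: the property the cutoff machinery must have
res <- sapply(1:100, function(s) {
  d <- simulate_cnd_window(seed = s)
  fit <- fit_cubic(suppressWarnings(
    cumulative_variance_function(d$value, d$fqi_norm)))
  c(fit$cutoff, attr(d, "boundary"))
})
message("planted-window recovery over 100 seeds: median cutoff ",
        round(median(res[1, ]), 3), " vs median boundary ",
        round(median(res[2, ]), 3))
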