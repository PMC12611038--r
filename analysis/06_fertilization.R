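#!/usr/bin/env Rscript
# Precision fertilization: apply the piecewise soil-test dose rule to
# the season-mean soil tests, split annual doses over stages by the
# measured demand proportions, and solve a physical fertilizer blend.

library(vinefert)

soil <- read.csv("results/data/soil_nutrients.csv")
soil_tests <- aggregate(value ~ stage + element, data = soil, FUN = mean)

ey <- 3000  # kg expected yield for this plan
plan <- annual_plan(soil_tests, ey = ey)
write.csv(plan$plan[, c("interval", "element", "x", "x_max", "pfa")],
          "results/plan.csv", row.names = FALSE)
message("annual fertilizer need (kg, oxide basis) at EY = ", ey, ": ",
        paste(names(plan$annual), round(plan$annual, 2),
              sep = "=", collapse = ", "))

blend <- solve_blend(pmax(plan$annual, 0))
used <- blend$products[blend$products > 1e-9]
write.csv(data.frame(product = names(blend$products),
                     kg = round(as.numeric(blend$products), 3)),
          "results/blend.csv", row.names = FALSE)
message("blend: ", paste(names(used), round(used, 1),
                         sep = " = ", collapse = ", "), " kg")
message("unmet nutrient targets (kg): ",
        paste(names(blend$residual), round(blend$residual, 3),
              sep = "=", collapse = ", "))

# stage split of the annual doses by measured demand proportions
dp <- demand_proportions()
splits <- do.call(rbind, lapply(names(plan$annual), function(ox) {
  el <- c(N = "N", P2O5 = "P", K2O = "K", CaO = "Ca", MgO = "Mg")[[ox]]
  r <- dp[dp$element == el, ]
  data.frame(element = ox, interval = r$interval,
             dose = split_by_demand_ratio(plan$annual[[ox]], r$proportion))
}))
write.csv(splits, "results/stage_doses.csv", row.names = FALSE)
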