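#!/usr/bin/env Rscript
# Stage-wise nutrient demand accounting on the destructive-harvest
# series: whole-plant content per stage, interval demands and ratios,
# and per-yield uptake with the fruit uptake ratio.

library(vinefert)

harvest <- read.csv("results/data/harvest.csv")
yields <- read.csv("results/data/yields.csv")

sd1 <- stage_demand(harvest)
write.csv(sd1$demand, "results/demand_report.csv", row.names = FALSE)
write.csv(sd1$awp, "results/awp_by_stage.csv", row.names = FALSE)

mean_yield <- mean(yields$yield_kg)
up <- sapply(split(sd1$per_year, sd1$per_year$element), function(d)
  sum(d$dts) / length(unique(d$year)))
per_1000 <- round(up / mean_yield, 2)
message("uptake per 1000 kg fruit (kg): ",
        paste(names(per_1000), per_1000, sep = "=", collapse = ", "))
message("reference values: ",
        paste(uptake_reference()$element,
              uptake_reference()$total_per_1000kg,
              sep = "=", collapse = ", "))

write.csv(data.frame(element = names(per_1000),
                     uptake_per_1000kg = as.numeric(per_1000),
                     mean_yield_kg = mean_yield),
          "results/uptake_per_yield.csv", row.names = FALSE)
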