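#!/usr/bin/env Rscript
# Generate the synthetic trial: 16 orthogonal fertilization treatments
# x 5 seasons x 3 replicates of fruit quality, plant/soil nutrient
# observations per treatment-year, and a 3-season destructive-harvest
# series. Everything downstream reads these tables.

library(vinefert)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scenario <- experiment_scenario(seed = 20240301)
design <- build_design()

quality <- generate_quality(scenario, design)
nutrients <- generate_nutrients(scenario, design)
harvest <- generate_harvest_series(scenario)

write.csv(quality, file.path(out, "quality.csv"), row.names = FALSE)
write.csv(nutrients$plant, file.path(out, "plant_nutrients.csv"),
          row.names = FALSE)
write.csv(nutrients$soil, file.path(out, "soil_nutrients.csv"),
          row.names = FALSE)
write.csv(harvest, file.path(out, "harvest.csv"), row.names = FALSE)
write.csv(attr(harvest, "yields"), file.path(out, "yields.csv"),
          row.names = FALSE)

message("quality records:   ", nrow(quality))
message("plant observations: ", nrow(nutrients$plant))
message("soil observations:  ", nrow(nutrients$soil))
message("harvest rows:       ", nrow(harvest))
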