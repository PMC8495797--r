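#!/usr/bin/env Rscript
# Stage 6: project scaled thermal response curves onto seasonally
# averaged bias-corrected bottom temperature, yielding spring and fall
# habitat-quality maps for the shelf-wide survey, observer and
# laboratory models.

suppressPackageStartupMessages(library(thermhab))

data_dir <- "results/data"
out <- "results/maps"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

WORLD_SEED <- as.integer(readLines(file.path(data_dir, "world_seed.txt")))
grid <- grid_spec(lat_range = c(37.5, 41), lon_range = c(-75.5, -72.5),
                  res_model = 0.05, res_clim = 0.1)
world <- gen_temperature_world(grid, years = 1985:2015, seed = WORLD_SEED)
biases <- lapply(names(world$clim), function(d)
  compute_bias_field(
    decadal_monthly_mean_regrid(world$model, d, world$clim[[d]]),
    climatology_bottom(world$clim[[d]])))
names(biases) <- names(world$clim)
corrected <- apply_bias(world$model, biases)

curves <- list(
  NEFSC = local({
    d <- read_trawls(file.path(data_dir, "trawls_NEFSC.csv"))
    fit_presence_curve(d$temp_model_c[!is.na(d$temp_model_c)],
                       d$presence[!is.na(d$temp_model_c)])
  }),
  Observer = local({
    d <- read_trawls(file.path(data_dir, "trawls_Observer.csv"))
    fit_presence_curve(d$temp_model_c[!is.na(d$temp_model_c)],
                       d$presence[!is.na(d$temp_model_c)])
  }),
  lab = fit_scope_curve(utils::read.csv(file.path(data_dir, "lab_scope.csv"))))

for (season in c("spring", "fall")) {
  sm <- seasonal_mean(corrected, season, years = 1985:2015)
  cat(sprintf("%s mean bottom temperature: %.1f to %.1f C\n", season,
              min(sm$temp, na.rm = TRUE), max(sm$temp, na.rm = TRUE)))
  for (nm in names(curves)) {
    map <- project_habitat(curves[[nm]], sm, label = nm)
    write_habitat_map(map, file.path(out, sprintf("habitat_%s_%s.csv",
                                                  nm, season)))
    q <- map$quality[!is.na(map$quality)]
    cat(sprintf("  %-8s habitat quality: mean %.2f, share above 0.5: %4.1f%%\n",
                nm, mean(q), 100 * mean(q > 0.5)))
  }
}
cat("stage 6 done: maps under", out, "\n")
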