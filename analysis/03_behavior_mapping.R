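#!/usr/bin/env Rscript
# Stage 3: one behavior map in depth -- scattered observations with
# cell-free voids to a dense GP behavior surface (the false-null
# correction), with EI-optimized hyperparameters and hold-out validation.
#
# Writes: results/mapping/{map_axonal_growth.csv, map_heat.png,
#         optimizer_trace.csv, size_response_curve.csv, metrics.csv}

library(nanomap)
out <- file.path("results", "mapping")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2024

topo <- exponential_profile()          # 20 um -> 0.1 um across 1 cm
cal <- fit_size_calibration(topo)
model <- response_model("axonal_growth", 5)
sc <- make_scene(topo, model, density_per_cm2 = 10000, void_fraction = 0.3,
                 seed = seed, height_um = 10000)
cat(sprintf("Scene: %d cells, %d cell-free void regions (30%% of area)\n",
            nrow(sc$cells), nrow(sc$void_regions)))

obs <- assemble_observations(
  data.frame(id = sc$cells$id, x_um = sc$cells$x_um, y_um = sc$cells$y_um,
             z = sc$cells$z), "z", behavior_name = "axonal_growth")
sp <- split_holdout(obs, 0.10, seed = sub_seed(seed, "split"))
cat(sprintf("Hold-out split: %d train / %d test (90/10)\n",
            nrow(sp$train), nrow(sp$test)))

hyp <- optimize_hyperparameters(sp$train, n_iterations = 15,
                                seed = sub_seed(seed, "hyper"),
                                max_train = 400)
write.csv(hyp$trace, file.path(out, "optimizer_trace.csv"), row.names = FALSE)
cat(sprintf("EI search: %d evaluations, best NLML %.1f\n",
            nrow(hyp$trace), min(hyp$trace$objective)))
surf <- fit_surface(sp$train, hyp, max_train = 400)
print(surf)
err <- holdout_error(surf, sp$test)
cat(sprintf("Hold-out: RMSE %.3f, R^2 %.3f\n", err$rmse, err$r2))

grid <- predict_grid(surf)             # 250,000-point map
cat(sprintf("Prediction grid: %d points (%d x %d)\n", grid$n_points,
            length(grid$x_um), length(grid$y_um)))
write.csv(data.frame(x_um = rep(grid$x_um, times = length(grid$y_um)),
                     y_um = rep(grid$y_um, each = length(grid$x_um)),
                     z_mean = as.vector(grid$z_mean),
                     z_sd = as.vector(grid$z_sd)),
          file.path(out, "map_axonal_growth.csv"), row.names = FALSE)
png(file.path(out, "map_heat.png"), 1000, 520)
par(mfrow = c(1, 2))
plot_behavior_grid(grid, "mean")
plot_behavior_grid(grid, "sd")
dev.off()

cv <- marginalize_to_size_curve(grid, cal, 8, size_range = c(0.1, 20))
write.csv(as.data.frame(cv), file.path(out, "size_response_curve.csv"),
          row.names = FALSE)
opt <- optimal_feature_size(cv)
cat(sprintf("Size-response curve argmax: bin %d (%.2f-%.2f um), true peak 5 um\n",
            opt$bin, cv$size_lo_um[opt$bin], cv$size_hi_um[opt$bin]))
write.csv(data.frame(rmse = err$rmse, r2 = err$r2,
                     grid_points = grid$n_points,
                     best_bin = opt$bin, best_size_um = opt$size_um),
          file.path(out, "metrics.csv"), row.names = FALSE)
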