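#!/usr/bin/env Rscript
# Stage 3: the resource-availability surface and gap map.
#
# Evaluates RA at every point of a 0.5 degree lattice over the study bbox:
# RA(l) = sum over centers of [1 / max(RL, 1)] * decay(d; z), capped-inverse
# decay with z = 30 km. RA < 1 flags a resource gap — a location without one
# adequately loaded center's worth of reachable capacity.

suppressPackageStartupMessages(library(resourcegaps))

centers <- read_centers("results/data/centers.csv")
loads <- utils::read.csv("results/loads.csv")
params <- metric_params()

bbox <- c(25, 49, -124, -67)
grid <- availability_grid(bbox, resolution_deg = 0.5, loads, centers, params)

write_grid_geojson(grid, "results/availability_grid.geojson")
write_table_csv(grid, "results/availability_grid.csv")

cat(sprintf("grid: %d points at 0.5 degree over lat %g..%g, lon %g..%g\n",
            nrow(grid), bbox[1], bbox[2], bbox[3], bbox[4]))
cat(sprintf("RA: median %.3f, max %.3f\n", median(grid$ra), max(grid$ra)))
cat(sprintf("%.1f%% of grid points are resource gaps (RA < 1)\n",
            100 * mean(grid$gap)))
cat("wrote results/availability_grid.geojson, results/availability_grid.csv\n")
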