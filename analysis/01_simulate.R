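#!/usr/bin/env Rscript
# Stage 0: build the synthetic study area.
#
# Generates the "us_like_small" scenario — 300 census-like regions with
# log-normal populations and land areas over a continental-US-like bounding
# box, and 80 diagnostic centers placed population-weighted, each staffed by
# 5 specialists attending ~200 patients/year — and writes the region and
# center tables that the later stages read.

suppressPackageStartupMessages(library(resourcegaps))

seed <- 20260924L
cfg <- scenario_preset("us_like_small", seed = seed)
regions <- generate_regions(cfg)
centers <- generate_centers(regions, cfg)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
write_table_csv(regions, "results/data/regions.csv")
write_table_csv(centers, "results/data/centers.csv")

cat(sprintf("regions: %d (total population %s, median %s)\n",
            nrow(regions),
            format(sum(regions$population), big.mark = ","),
            format(median(regions$population), big.mark = ",")))
cat(sprintf("centers: %d (capacity %s screenings/year)\n",
            nrow(centers),
            format(sum(centers$s * centers$o), big.mark = ",")))
cat("wrote results/data/regions.csv, results/data/centers.csv\n")
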