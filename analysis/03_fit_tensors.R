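#!/usr/bin/env Rscript
# Stage 3 -- tensor fitting and metric maps.
#
# Fits the diffusion tensor per pixel by exact log-linear solve of the
# six-direction system, derives FA/MD/AD/RD, and interpolates the metric
# maps from 0.78 mm to 0.2 mm with a monotone cubic spline.

suppressPackageStartupMessages(library(spinaldti))

out <- "results/analysis"
avg <- read_dwi_stack(file.path(out, "example_averaged"))
scheme <- diffusion_scheme(b = 750)

maps <- compute_maps(avg, scheme)
cat(sprintf("Fitted %d pixels; %d negative eigenvalues clamped\n",
            maps$qc$n_fit, maps$qc$n_clamped))

imaps <- interpolate_maps(maps, target_spacing = 0.2)
cat(sprintf("Interpolated %dx%d (0.78 mm) -> %dx%d (0.2 mm)\n",
            nrow(maps$FA), ncol(maps$FA), nrow(imaps$FA), ncol(imaps$FA)))

write_metric_maps(maps, out, "native")
write_metric_maps(imaps, out, "interp")

spec <- phantom_spec(n_repetitions = 32, seed = 1)
lab <- phantom_label_map(spec)[48:80, 48:80]
for (rg in list(c("DC", 7, 8), c("PT", 5, 6), c("AH", 9, 10))) {
  px <- lab %in% as.integer(rg[2:3])
  cat(sprintf("Native-map mean FA in true %s region: %.3f\n",
              rg[1], mean(maps$FA[px], na.rm = TRUE)))
}
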