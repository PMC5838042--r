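#!/usr/bin/env Rscript
# Neighborhood richness and basal-area diversity of the two synthetic
# plots: per-species mean neighbor species/individual counts within 5 m,
# ordinary least squares of each response on the species' total basal
# area with Pearson correlations, and Shannon/Simpson indices (whole plot
# and a 4 x 4 grid of 25 m quadrats for a within-plot range).

library(stemspat)

indir <- "results/plots"
outdir <- "results/community"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

rows <- list(); fits <- list(); quads <- list()
for (plot in c("plot1_like", "plot2_like")) {
  pat <- read_stem_table(file.path(indir, paste0(plot, ".csv")))
  ns <- neighborhood_stats(pat, radius = 5)
  rows[[plot]] <- cbind(plot = plot, ns)
  for (resp in c("species", "individuals")) {
    fit <- fit_focal_regression(ns, resp)
    fits[[paste(plot, resp)]] <- data.frame(
      plot = plot, response = resp, slope = fit$slope,
      intercept = fit$intercept, pearson_r = fit$r, p = fit$p,
      n_species = fit$n)
    cat(sprintf("%s: neighbor %s ~ basal area: r = %+.3f (p = %.3f)\n",
                plot, resp, fit$r, fit$p))
  }
  div <- diversity_indices(pat)
  cat(sprintf("%s: Shannon H = %.3f nats, Simpson D = %.3f (%d species)\n",
              plot, div$H, div$D, div$n_species))
  quads[[paste(plot, "whole")]] <- data.frame(
    plot = plot, quadrat = "whole", H = div$H, D = div$D,
    n_species = div$n_species)
  for (qx in 0:3) for (qy in 0:3) {
    q <- window_rect(qx * 25, (qx + 1) * 25, qy * 25, (qy + 1) * 25)
    dq <- diversity_indices(pat, quadrat = q)
    quads[[paste(plot, qx, qy)]] <- data.frame(
      plot = plot, quadrat = sprintf("q%d%d", qx, qy), H = dq$H, D = dq$D,
      n_species = dq$n_species)
  }
}
write.csv(do.call(rbind, c(rows, list(make.row.names = FALSE))),
          file.path(outdir, "neighborhood.csv"), row.names = FALSE)
write.csv(do.call(rbind, c(fits, list(make.row.names = FALSE))),
          file.path(outdir, "neighborhood_fits.csv"), row.names = FALSE)
write.csv(do.call(rbind, c(quads, list(make.row.names = FALSE))),
          file.path(outdir, "diversity.csv"), row.names = FALSE)
cat("community tables written to", outdir, "\n")
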