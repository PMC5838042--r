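#!/usr/bin/env Rscript
# Generates the two synthetic study plots and writes their stem tables,
# generator configurations and composition summaries under results/.
#
# plot1_like: two congeners (QS n = 543, QV n = 214) clustered on a shared
# habitat gradient with a shared-parents positive link, plus 10 rarer
# heterospecifics thinned around both congeners.
# plot2_like: three congeners (QS 340, QV 169, QA 170) with divergent
# gradients and thinning links (QV and QA thinned around QS), plus 10
# heterospecifics.

library(stemspat)

seed <- 20260101L
outdir <- "results/plots"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

for (name in c("plot1_like", "plot2_like")) {
  pat <- generate_fixture(name, seed = seed)
  write_stem_table(pat, file.path(outdir, paste0(name, ".csv")))
  cfg <- switch(name, plot1_like = stemspat:::plot1_config(),
                plot2_like = stemspat:::plot2_config())
  cfg$seed <- seed
  write_community_config(cfg, file.path(outdir, paste0(name, "_config.yaml")))
  tab <- sort(table(pat$species), decreasing = TRUE)
  comp <- data.frame(species = names(tab), n = as.integer(tab),
                     basal_area_m2 = vapply(names(tab), function(s) {
                       sum(basal_area(pat$dbh[pat$species == s]))
                     }, numeric(1)))
  write.csv(comp, file.path(outdir, paste0(name, "_composition.csv")),
            row.names = FALSE)
  cat(sprintf("%s: %d stems, %d species (seed %d)\n",
              name, npoints(pat), length(tab), seed))
  print(utils::head(comp, 5))
}
cat("stem tables, configs and composition summaries written to", outdir, "\n")
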