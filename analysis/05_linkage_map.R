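#!/usr/bin/env Rscript
# F2 linkage mapping end to end on a simulated 26-chromosome genome:
# ABH simulation, pairwise EM recombination fractions, grouping,
# SARF ordering, Kosambi positions, double-crossover cleaning,
# segregation distortion, crossover counts and recombination bins.
# Writes results/map.tsv, results/abh.loc, results/distortion.tsv,
# results/crossovers.tsv, results/bins.tsv.

suppressPackageStartupMessages(library(polymap))
dir.create("results", showWarnings = FALSE)

map_truth <- simulate_genome_map(26, 20, 135)
# mild distortion at a handful of markers, female allele favored
dist <- data.frame(marker = map_truth$marker[seq(5, 520, by = 40)],
                   wA = 1, wH = 0.9, wB = 0.55)
f2 <- simulate_f2(map_truth, 118, distortion = dist,
                  missing_rate = 0.01, seed = 31)

# corrupt a few markers (poor scoring quality) so cleaning has work
set.seed(32)
noisy <- map_truth$marker[seq(10, 520, by = 104)]
for (mk in noisy) {
  flip <- sample(118, 18)
  f2$abh[mk, flip] <- sample(c("A", "H", "B"), 18, TRUE)
}

map <- build_map(f2$abh)
cat(sprintf("grouping recovered %d linkage groups over %d markers\n",
            length(unique(map$group)), nrow(map)))

# double-crossover threshold set for this map's ~7 cM marker spacing,
# where genuine double crossovers between neighbours are expected
# (about 1 per marker over 118 individuals); at sub-cM spacing the
# default of 2 applies
cleaned <- clean_markers(map, f2$abh, max_doubles = 5)
cat(sprintf("cleaning removed %d markers (%d injected noisy ones)\n",
            length(cleaned$removed),
            sum(noisy %in% cleaned$removed)))
map <- cleaned$map

lens <- tapply(map$cm, map$group, max)
cat(sprintf("total map length %.1f cM (truth %.0f cM); mean group %.1f cM\n",
            sum(lens), 26 * 135, mean(lens)))
write_map(map, "results/map.tsv")
write_abh(f2$abh[map$marker, ], "results/abh.loc",
          dialect = "joinmap_loc")

sd_res <- segregation_distortion(f2$abh)
write.table(sd_res$per_marker, "results/distortion.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("distorted markers: %.1f%% (het-deficit among them %.1f%%)\n",
            sd_res$summary$distorted_pct,
            sd_res$summary$het_deficit_pct_of_distorted))

xo <- count_crossovers(f2$abh, map)
write.table(data.frame(individual = colnames(xo$per_group),
                       crossovers = xo$per_individual,
                       outlier = xo$outliers),
            "results/crossovers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("crossovers per individual: %d-%d, mean %.1f; per group %.2f\n",
            min(xo$per_individual), max(xo$per_individual),
            mean(xo$per_individual), mean(xo$per_group)))

bins <- recombination_bins(f2$abh, map)
write.table(bins, "results/bins.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("recombination bins: mean %.1f bins/group, %.2f markers/bin\n",
            mean(bins$n_bins), mean(bins$markers_per_bin)))
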