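#!/usr/bin/env Rscript
# Map-vs-reference synteny on the map from 05: alignment positions are
# synthesized collinear with the true map, with two reciprocal
# translocation blocks injected (the classic 2/3 and 4/5 arm exchanges
# of tetraploid cotton are the motivating case). Detects the blocks
# and reports breakpoint intervals and kb/cM scale statistics.
# Writes results/synteny.tsv and results/translocations.tsv.

suppressPackageStartupMessages(library(polymap))
stopifnot(file.exists("results/map.tsv"))
map <- read_map("results/map.tsv")

groups <- unique(map$group)
chrom_of <- setNames(sprintf("chr%02d", seq_along(groups)), groups)
pos <- do.call(rbind, lapply(groups, function(g) {
  mk <- map$marker[map$group == g]
  cm <- map$cm[map$group == g]
  # collinear: bp proportional to cM at ~500 kb / cM
  data.frame(marker = mk, chrom = chrom_of[[g]],
             bp = round(1e6 + cm * 5e5), mapped = TRUE)
}))
# inject reciprocal translocation blocks between the first two groups
b1 <- map$marker[map$group == groups[1]][8:14]
b2 <- map$marker[map$group == groups[2]][8:14]
pos$chrom[match(b1, pos$marker)] <- chrom_of[[groups[2]]]
pos$bp[match(b1, pos$marker)] <- seq(2.17e7, 2.95e7, length.out = 7)
pos$chrom[match(b2, pos$marker)] <- chrom_of[[groups[1]]]
pos$bp[match(b2, pos$marker)] <- seq(1.67e7, 2.10e7, length.out = 7)

write_position_table(pos, "results/positions.tsv")
dp <- dotplot_table(map, read_position_table("results/positions.tsv"))
cat(sprintf("dot-plot table: %d markers, coverage %.2f\n", nrow(dp),
            attr(dp, "coverage")))
write.table(dp, "results/synteny.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tr <- detect_translocations(dp, min_run = 5)
write.table(tr, "results/translocations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("translocation calls:\n")
print(tr[c("group", "expected_chrom", "observed_chrom", "n_markers",
           "ref_start_mb", "ref_end_mb")])

lens <- tapply(map$cm, map$group, max)
gi <- data.frame(group = names(lens),
                 subgenome = rep(c("A", "D"), length.out = 26),
                 length_cm = as.numeric(lens))
ms <- map_scale_stats(gi, c(A = 1600, D = 800))
cat(sprintf("map scale: %.0f kb/cM (A), %.0f kb/cM (D), total %.1f cM\n",
            ms$kb_per_cm["A"], ms$kb_per_cm["D"], ms$total_cm))
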