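#!/usr/bin/env Rscript
# Array content selection on a synthetic candidate pool: design-score,
# beadtype and uniqueness filters, precedence deduplication, and
# quota-based panel assembly with exhaustive genic inclusion.
# Writes results/design_{ledger,selection,composition}.tsv.

suppressPackageStartupMessages(library(polymap))
dir.create("results", showWarnings = FALSE)
set.seed(11)

n <- 20000
bases <- c("A", "C", "G", "T")
# allele pairs with a realistic transition:transversion ratio ~2:1
pairs_pool <- c("A/G", "C/T", "A/C", "A/T", "C/G", "G/T")
pair <- sample(pairs_pool, n, TRUE,
               prob = c(1 / 3, 1 / 3, 1 / 12, 1 / 12, 1 / 12, 1 / 12))
cands <- data.frame(
  id = sprintf("snp%05d", seq_len(n)),
  alleles = pair,
  design_score = round(rbeta(n, 9, 1.5), 3),
  flank_identity = round(pmin(100 - rexp(n, 2), 100), 2),
  probe_identity = round(pmin(100 - rexp(n, 2), 100), 2),
  dataset = sample(sprintf("set%02d", 1:13), n, TRUE),
  precedence = sample(1:13, n, TRUE),
  genic = sample(c("genic", "nongenic", "unclassified"), n, TRUE,
                 prob = c(0.4, 0.55, 0.05)),
  stringsAsFactors = FALSE)
cands$flank <- sprintf("%s[%s]%s",
                       replicate(n, paste(sample(bases, 12, TRUE),
                                          collapse = "")),
                       cands$alleles,
                       replicate(n, paste(sample(bases, 12, TRUE),
                                          collapse = "")))
# plant cross-dataset duplicates that survive the filters, to exercise
# precedence collapse
dup_src <- sample(n, 40)
dup_dst <- sample(setdiff(seq_len(n), dup_src), 40)
cands$flank[dup_dst] <- cands$flank[dup_src]
cands$alleles[dup_dst] <- cands$alleles[dup_src]
pass_idx <- c(dup_src, dup_dst)
cands$design_score[pass_idx] <- 0.95
cands$flank_identity[pass_idx] <- 100
cands$probe_identity[pass_idx] <- 100
cands$alleles[pass_idx] <- "A/G"
cands$flank[pass_idx] <- sub("\\[[ACGT]/[ACGT]\\]", "[A/G]",
                             cands$flank[pass_idx])

filt <- filter_candidates(cands)
cat(sprintf("filters retained %d / %d candidates (%.1f%%)\n",
            length(filt$retained), n, retention_rate(filt)))
print(table(filt$ledger$fail_filter, useNA = "ifany"))

kept <- cands[cands$id %in% filt$retained, ]
dedup <- dedup_by_precedence(kept)
cat(sprintf("deduplication collapsed %d duplicate candidates\n",
            nrow(kept) - length(dedup$retained)))

final_pool <- kept[kept$id %in% dedup$retained, ]
quota <- round(0.8 * nrow(final_pool))
panel <- assemble_panel(final_pool, quota, seed = 11)
cat(sprintf("panel of %d markers assembled; composition:\n", quota))
print(panel$composition)

write.table(filt$ledger, "results/design_ledger.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(id = panel$retained),
            "results/design_selection.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(panel$composition, "results/design_composition.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
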