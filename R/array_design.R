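# Candidate-SNP filtering and array content selection for a
# two-fluorophore Infinium design: beadtype economics, design-score and
# uniqueness thresholds, cross-dataset deduplication by publication
# precedence, and quota-based panel assembly.

DYE_CHANNEL <- c(A = 1L, T = 1L, C = 2L, G = 2L)

#' Beadtype class of an allele pair
#'
#' Under the two-fluorophore chemistry a SNP needs a single beadtype
#' (Infinium II) when its two alleles report in different fluorophore
#' channels, and two beadtypes (Infinium I) when both alleles share a
#' channel. The default dye map is `{A, T}` vs `{C, G}`; under it the
#' transitions (A/G, C/T) are always one-bead while the transversions
#' A/T and C/G need two beads. `rule = "transversion"` instead applies
#' the looser literal rule that every transversion needs two beadtypes.
#'
#' @param a1,a2 Allele bases (vectors of single characters, A/C/G/T).
#' @param rule `"channel"` (default) or `"transversion"`.
#' @return Character vector, `"one_bead"` or `"two_bead"`; symmetric in
#'   allele order.
#' @export
beadtype_class <- function(a1, a2, rule = c("channel", "transversion")) {
  rule <- match.arg(rule)
  a1 <- toupper(a1); a2 <- toupper(a2)
  bad <- !(a1 %in% names(DYE_CHANNEL)) | !(a2 %in% names(DYE_CHANNEL))
  if (any(bad))
    stop_fmt("non-ACGT allele: %s",
             paste(unique(c(a1[bad], a2[bad])), collapse = ", "))
  if (any(a1 == a2)) stop_fmt("alleles must be distinct")
  if (rule == "channel") {
    unname(ifelse(DYE_CHANNEL[a1] != DYE_CHANNEL[a2], "one_bead",
                  "two_bead"))
  } else {
    purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
    unname(ifelse(purine[a1] == purine[a2], "one_bead", "two_bead"))
  }
}

split_alleles <- function(alleles) {
  parts <- strsplit(alleles, "/", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop_fmt("alleles must be written as 'X/Y'")
  list(a1 = vapply(parts, `[`, "", 1), a2 = vapply(parts, `[`, "", 2))
}

#' Filter SNP candidates for array design
#'
#' Applies the content filters in order — design score, beadtype,
#' flanking-sequence uniqueness, probe uniqueness — recording the first
#' failing filter for every rejected candidate. Thresholds follow the
#' usual array-design practice: design score strictly above 0.8,
#' uniqueness strictly above 99% for both the 100-bp flank and the
#' designed probe, one-bead (Infinium II) assays only.
#'
#' @param candidates data.frame with columns `id`, `alleles` ("X/Y"),
#'   `design_score`, `flank_identity`, `probe_identity` (percent unique
#'   identity) and optionally `dataset`, `precedence`, `genic`,
#'   `flank`.
#' @param design_score_min,flank_identity_min,probe_identity_min
#'   Filter thresholds (strict inequalities).
#' @param beadtype Required beadtype class (`"one_bead"`; `NA` disables
#'   the filter).
#' @param rule Beadtype rule, see [beadtype_class()].
#' @return A `panel_selection`: list with `retained` (ids), `ledger`
#'   (data.frame id, pass, fail_filter), `retention_rate` and `counts`.
#' @export
filter_candidates <- function(candidates, design_score_min = 0.8,
                              flank_identity_min = 99,
                              probe_identity_min = 99,
                              beadtype = "one_bead",
                              rule = "channel") {
  n <- nrow(candidates)
  if (n == 0)
    return(panel_selection(character(0),
                           data.frame(id = character(0),
                                      pass = logical(0),
                                      fail_filter = character(0)),
                           candidates))
  al <- split_alleles(candidates$alleles)
  fail <- rep(NA_character_, n)
  fail[is.na(fail) & !(candidates$design_score > design_score_min)] <-
    "design_score"
  if (!is.na(beadtype)) {
    bt <- beadtype_class(al$a1, al$a2, rule)
    fail[is.na(fail) & bt != beadtype] <- "beadtype"
  }
  fail[is.na(fail) &
         !(candidates$flank_identity > flank_identity_min)] <-
    "flank_uniqueness"
  fail[is.na(fail) &
         !(candidates$probe_identity > probe_identity_min)] <-
    "probe_uniqueness"
  ledger <- data.frame(id = candidates$id, pass = is.na(fail),
                       fail_filter = fail, stringsAsFactors = FALSE)
  panel_selection(candidates$id[is.na(fail)], ledger, candidates)
}

panel_selection <- function(retained, ledger, candidates, seed = NULL) {
  counts <- NULL
  if (!is.null(candidates$dataset) && length(retained)) {
    kept <- candidates[candidates$id %in% retained, , drop = FALSE]
    counts <- as.data.frame(table(dataset = kept$dataset),
                            stringsAsFactors = FALSE)
  }
  structure(list(retained = retained, ledger = ledger, counts = counts,
                 retention_rate = if (nrow(ledger))
                   length(retained) / nrow(ledger) else NA_real_,
                 seed = seed),
            class = "panel_selection")
}

#' Retention rate of a selection, in percent
#'
#' @param retained,input Counts (or a `panel_selection` as sole
#'   argument).
#' @param digits Rounding (default 1, matching the reporting
#'   convention).
#' @return Percent retained.
#' @export
retention_rate <- function(retained, input = NULL, digits = 1) {
  if (inherits(retained, "panel_selection"))
    return(round(100 * retained$retention_rate, digits))
  round(100 * retained / input, digits)
}

# Duplicate key: the flank with the SNP site masked to its (sorted)
# allele pair, so identical context sequences collapse regardless of
# allele order notation.
dedup_key <- function(flank, alleles) {
  al <- split_alleles(alleles)
  pair <- paste0("[", pmin(al$a1, al$a2), "/", pmax(al$a1, al$a2), "]")
  key <- gsub("\\[[ACGT]/[ACGT]\\]", "@", toupper(flank))
  paste0(key, "|", pair)
}

#' Collapse duplicate candidates by publication precedence
#'
#' Candidates whose flank + SNP sequences are identical over their full
#' length (exact string match with the SNP site masked to the allele
#' pair) collapse to the single candidate with the best (lowest)
#' precedence rank. Idempotent.
#'
#' @param candidates data.frame with columns `id`, `alleles`, `flank`
#'   (SNP site written as `[X/Y]`), `precedence`.
#' @return A `panel_selection`; the ledger's `fail_filter` is
#'   `"duplicate"` for collapsed candidates.
#' @export
dedup_by_precedence <- function(candidates) {
  key <- dedup_key(candidates$flank, candidates$alleles)
  keep <- unlist(lapply(split(seq_len(nrow(candidates)), key),
                        function(i)
                          i[which.min(candidates$precedence[i])]),
                 use.names = FALSE)
  pass <- seq_len(nrow(candidates)) %in% keep
  ledger <- data.frame(id = candidates$id, pass = pass,
                       fail_filter = ifelse(pass, NA, "duplicate"),
                       stringsAsFactors = FALSE)
  panel_selection(candidates$id[pass], ledger, candidates)
}

#' Assemble the final array panel under quotas
#'
#' Genic candidates are taken exhaustively (up to the total quota);
#' the remainder is filled with a seeded uniform sample of nongenic
#' (and unclassified) candidates without replacement.
#'
#' @param candidates data.frame of retained candidates with columns
#'   `id` and `genic` (`"genic"`, `"nongenic"`, `"unclassified"`).
#' @param total Total panel size.
#' @param seed Integer seed for the nongenic sampling.
#' @return A `panel_selection` with a `composition` data.frame
#'   (class, count, percent).
#' @export
assemble_panel <- function(candidates, total, seed = 1) {
  genic <- candidates$id[candidates$genic == "genic"]
  other <- candidates$id[candidates$genic != "genic"]
  if (total > nrow(candidates))
    stop_fmt("quota %d exceeds available candidates (%d short)",
             total, total - nrow(candidates))
  take_genic <- utils::head(genic, total)
  n_fill <- total - length(take_genic)
  set.seed(seed)
  fill <- if (n_fill > 0) sample(other, n_fill) else character(0)
  retained <- c(take_genic, fill)
  ledger <- data.frame(id = candidates$id,
                       pass = candidates$id %in% retained,
                       fail_filter = ifelse(candidates$id %in% retained,
                                            NA, "quota"),
                       stringsAsFactors = FALSE)
  sel <- panel_selection(retained, ledger, candidates, seed = seed)
  cls <- candidates$genic[match(retained, candidates$id)]
  comp <- as.data.frame(table(class = cls), stringsAsFactors = FALSE)
  comp$percent <- round(100 * comp$Freq / total, 1)
  sel$composition <- comp
  sel
}
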