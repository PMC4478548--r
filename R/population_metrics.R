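# Replicate-similarity, residual-heterozygosity and minor-allele
# frequency summaries over genotype call tables.

#' Percent similarity between two genotype call vectors
#'
#' Identical calls over the jointly called markers, in percent; markers
#' uncalled (`NC`) in either sample are excluded from the denominator
#' (pairwise-complete convention). Used to quantify technical and
#' biological replicate reproducibility.
#'
#' @param calls_1,calls_2 Call vectors (`AA/AB/BB/NC`) over the same
#'   marker universe.
#' @param replicate_type Optional label (`technical`,
#'   `same_seed_source`, `diff_seed_source`, `pool_vs_individual`).
#' @return List with `percent` (NA when no marker is jointly called),
#'   `n_joint`, `n_identical`, `replicate_type`.
#' @export
pairwise_similarity <- function(calls_1, calls_2,
                                replicate_type = NA_character_) {
  if (length(calls_1) != length(calls_2))
    stop_fmt("call vectors must cover the same marker universe")
  joint <- calls_1 != "NC" & calls_2 != "NC" & !is.na(calls_1) &
    !is.na(calls_2)
  n_joint <- sum(joint)
  n_id <- sum(calls_1[joint] == calls_2[joint])
  list(percent = if (n_joint) 100 * n_id / n_joint else NA_real_,
       n_joint = n_joint, n_identical = n_id,
       replicate_type = replicate_type)
}

#' Residual heterozygosity of a sample, in percent
#'
#' Share of heterozygous (`AB`) calls among this sample's non-missing
#' calls over a set of polymorphic markers — the standard measure of
#' within-line heterogeneity for inbred material and seed pools.
#'
#' @param calls Named call vector for one sample.
#' @param polymorphic_markers Marker ids to restrict to (must be
#'   non-empty).
#' @return Percent heterozygous calls (NA when nothing is called).
#' @export
residual_heterozygosity <- function(calls, polymorphic_markers = NULL) {
  if (!is.null(polymorphic_markers)) {
    if (!length(polymorphic_markers))
      stop_fmt("empty polymorphic marker set")
    calls <- calls[polymorphic_markers]
  }
  called <- calls[calls != "NC" & !is.na(calls)]
  if (!length(called)) return(NA_real_)
  100 * mean(called == "AB")
}

#' Minor-allele-frequency summary over an inbred panel
#'
#' Per marker, alleles are counted over the inbred samples (2 per
#' homozygote, 1 + 1 for a heterozygote) and the MAF is
#' `min(p, 1 - p)`. Reports per-marker MAFs, the mean MAF, and the
#' fraction of markers strictly above each threshold.
#'
#' @param calls Marker-by-sample call matrix.
#' @param inbred Logical vector over samples; only inbred samples are
#'   counted. Default: all samples.
#' @param thresholds Exceedance thresholds
#'   (default `c(0.05, 0.10, 0.20)`).
#' @return List with `maf` (named per-marker vector), `mean_maf`, and
#'   `exceedance` (data.frame threshold, fraction).
#' @export
maf_summary <- function(calls, inbred = NULL,
                        thresholds = c(0.05, 0.10, 0.20)) {
  if (!is.null(inbred)) calls <- calls[, inbred, drop = FALSE]
  nA <- 2 * rowSums(calls == "AA") + rowSums(calls == "AB")
  nB <- 2 * rowSums(calls == "BB") + rowSums(calls == "AB")
  tot <- nA + nB
  none <- tot == 0
  if (any(none))
    warn_fmt("%d marker(s) with zero called inbreds excluded",
             sum(none))
  p <- nA / tot
  maf <- pmin(p, 1 - p)
  maf[none] <- NA
  ok <- !is.na(maf)
  exceed <- vapply(thresholds, function(thr) mean(maf[ok] > thr),
                   numeric(1))
  list(maf = stats::setNames(maf, rownames(calls)),
       mean_maf = mean(maf[ok]),
       exceedance = data.frame(threshold = thresholds,
                               fraction = exceed))
}
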