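# Genetic-map vs reference-genome collinearity: dot-plot tables,
# modal chromosome assignment per linkage group, translocation
# detection as runs of discordant alignments, and map-scale (kb/cM)
# statistics.

#' Join a genetic map with reference alignment positions
#'
#' Inner join on marker id between a genetic map and a position table;
#' the result is the dot-plot input, sorted by (group, cM).
#'
#' @param map A [genetic_map()].
#' @param positions Position data.frame
#'   (see [read_position_table()]); unmapped rows are ignored.
#' @return data.frame (marker, group, cm, chrom, bp) with attribute
#'   `coverage` = mapped-with-position / mapped markers.
#' @export
dotplot_table <- function(map, positions) {
  pos <- positions[positions$mapped %||% TRUE &
                     !is.na(positions$bp), , drop = FALSE]
  i <- match(map$marker, pos$marker)
  out <- data.frame(marker = map$marker, group = map$group,
                    cm = map$cm, chrom = pos$chrom[i], bp = pos$bp[i],
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$chrom), , drop = FALSE]
  out <- out[order(out$group, out$cm, out$marker), ]
  rownames(out) <- NULL
  if (!nrow(out)) warn_fmt("no markers shared between map and positions")
  attr(out, "coverage") <- nrow(out) / nrow(map)
  out
}

#' Assign the expected reference chromosome of a linkage group
#'
#' The expected chromosome is the modal reference chromosome of the
#' group's aligned markers; concordance is the modal share. Ties break
#' by the larger supported bp span, then lexically.
#'
#' @param records Rows of a [dotplot_table()] for one linkage group.
#' @return List with `chrom`, `concordance`, `n`.
#' @export
assign_reference_chromosome <- function(records) {
  stopifnot(nrow(records) >= 1)
  tab <- table(records$chrom)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) {
    span <- vapply(top, function(ch) {
      b <- records$bp[records$chrom == ch]
      diff(range(b))
    }, numeric(1))
    top <- top[span == max(span)]
    top <- sort(top)[1]
  }
  list(chrom = top, concordance = as.numeric(max(tab)) / nrow(records),
       n = nrow(records))
}

#' Detect translocations as runs of discordant alignments
#'
#' Within each linkage group (ordered by cM), maximal runs of at least
#' `min_run` consecutive markers aligning to the same chromosome
#' different from the group's expected chromosome are called as
#' translocations. Each call reports the discordant chromosome, the
#' reference interval `[min bp, max bp]` of the run (Mb, 1 decimal)
#' and the map interval from the marker before the run to the marker
#' after it (clamped at group ends).
#'
#' @param records A [dotplot_table()] (one or more groups).
#' @param min_run Minimum run length (default 5).
#' @param expected Optional named vector group -> chromosome overriding
#'   the modal assignment.
#' @return data.frame of calls: group, expected_chrom, observed_chrom,
#'   n_markers, ref_start_mb, ref_end_mb, map_start_cm, map_end_cm.
#' @export
detect_translocations <- function(records, min_run = 5,
                                  expected = NULL) {
  calls <- list()
  for (g in unique(records$group)) {
    rec <- records[records$group == g, , drop = FALSE]
    rec <- rec[order(rec$cm, rec$marker), , drop = FALSE]
    exp_chrom <- if (!is.null(expected)) expected[[g]]
    else assign_reference_chromosome(rec)$chrom
    n <- nrow(rec)
    run_id <- cumsum(c(TRUE, rec$chrom[-1] != rec$chrom[-n]))
    for (rid in unique(run_id)) {
      idx <- which(run_id == rid)
      ch <- rec$chrom[idx[1]]
      if (ch == exp_chrom || length(idx) < min_run) next
      before <- if (idx[1] > 1) rec$cm[idx[1] - 1] else rec$cm[idx[1]]
      after <- if (idx[length(idx)] < n) rec$cm[idx[length(idx)] + 1]
      else rec$cm[idx[length(idx)]]
      calls[[length(calls) + 1]] <- data.frame(
        group = g, expected_chrom = exp_chrom, observed_chrom = ch,
        n_markers = length(idx),
        ref_start_mb = round(min(rec$bp[idx]) / 1e6, 1),
        ref_end_mb = round(max(rec$bp[idx]) / 1e6, 1),
        map_start_cm = before, map_end_cm = after,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(group = character(0),
                      expected_chrom = character(0),
                      observed_chrom = character(0),
                      n_markers = integer(0), ref_start_mb = numeric(0),
                      ref_end_mb = numeric(0), map_start_cm = numeric(0),
                      map_end_cm = numeric(0)))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Map-scale statistics: kb per cM and map-size change
#'
#' Computes, per subgenome, the average physical distance represented
#' by one centimorgan, `kb/cM = subgenome Mb x 1000 / total cM of its
#' groups`, and optionally the length change against a comparison map.
#'
#' @param group_info data.frame with columns `group`, `subgenome`,
#'   `length_cm`.
#' @param subgenome_mb Named vector of physical subgenome sizes in Mb
#'   (e.g. `c(A = 1600, D = 800)`).
#' @param comparison_total_cm Optional total length of a comparison
#'   map (cM).
#' @return List with `kb_per_cm` (named), `total_cm`, and when a
#'   comparison is given `reduction_cm` and `reduction_pct`.
#' @export
map_scale_stats <- function(group_info, subgenome_mb,
                            comparison_total_cm = NULL) {
  total <- sum(group_info$length_cm)
  kb <- vapply(names(subgenome_mb), function(s) {
    len <- sum(group_info$length_cm[group_info$subgenome == s])
    if (len <= 0) return(NA_real_)
    subgenome_mb[[s]] * 1000 / len
  }, numeric(1))
  out <- list(kb_per_cm = kb, total_cm = total)
  if (!is.null(comparison_total_cm)) {
    out$reduction_cm <- comparison_total_cm - total
    out$reduction_pct <- 100 * out$reduction_cm / comparison_total_cm
  }
  out
}

#' Base-graphics dot plot of map vs reference positions
#'
#' @param records A [dotplot_table()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_dotplot <- function(records, ...) {
  chroms <- sort(unique(records$chrom))
  groups <- sort(unique(records$group))
  x <- records$bp / 1e6 +
    1e3 * (match(records$chrom, chroms) - 1)
  y <- records$cm + 1e3 * (match(records$group, groups) - 1)
  graphics::plot(x, y, pch = 16, cex = 0.4,
                 xlab = "reference position (chromosome-stacked Mb)",
                 ylab = "map position (group-stacked cM)", ...)
  invisible(NULL)
}
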