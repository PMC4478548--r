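# F2 linkage-map construction: ABH recoding, two-point EM
# recombination fractions, LOD/p grouping by transitive closure, SARF
# seriation with 2-opt refinement (exhaustive for small groups),
# Kosambi distances, double-crossover cleaning and framework
# reordering.

#' Recode F2 genotype calls to ABH format
#'
#' A marker is retained only when both parents are called and are
#' opposite homozygotes; progeny are then recoded relative to parent A
#' (`A` = parent-A homozygote, `H` = heterozygote, `B` = parent-B
#' homozygote, `-` = no call). Rejected markers are listed in a ledger
#' with the reason (`parent_nc`, `parent_het`, `parents_identical`).
#' Progeny calls incompatible with the parental homozygotes cannot
#' arise for biallelic calls and `NC` is simply masked.
#'
#' @param parent_a,parent_b Named vectors of parental calls per marker
#'   (`AA/AB/BB/NC`).
#' @param progeny Marker-by-individual matrix of calls.
#' @return List with `abh` (matrix over retained markers) and
#'   `ledger` (data.frame marker, retained, reason).
#' @export
to_abh <- function(parent_a, parent_b, progeny) {
  markers <- rownames(progeny)
  pa <- parent_a[markers]
  pb <- parent_b[markers]
  reason <- rep(NA_character_, length(markers))
  reason[pa == "NC" | pb == "NC" | is.na(pa) | is.na(pb)] <- "parent_nc"
  reason[is.na(reason) & (pa == "AB" | pb == "AB")] <- "parent_het"
  reason[is.na(reason) & pa == pb] <- "parents_identical"
  keep <- is.na(reason)
  abh <- matrix("-", sum(keep), ncol(progeny),
                dimnames = list(markers[keep], colnames(progeny)))
  for (i in which(keep)) {
    g <- progeny[i, ]
    # pa[i] is AA or BB; recode relative to parent A
    a_call <- pa[i]
    b_call <- pb[i]
    out <- rep("-", length(g))
    out[g == a_call] <- "A"
    out[g == b_call] <- "B"
    out[g == "AB"] <- "H"
    abh[markers[i] == rownames(abh), ] <- out
  }
  list(abh = abh,
       ledger = data.frame(marker = markers, retained = keep,
                           reason = reason, stringsAsFactors = FALSE))
}

# F2 codominant two-locus cell probabilities (coupling phase), cells
# indexed by B-allele dosage (0/1/2) at each locus.
f2_cell_probs <- function(r) {
  p <- matrix(0, 3, 3)
  p[1, 1] <- p[3, 3] <- (1 - r)^2 / 4
  p[1, 3] <- p[3, 1] <- r^2 / 4
  p[1, 2] <- p[2, 1] <- p[2, 3] <- p[3, 2] <- r * (1 - r) / 2
  p[2, 2] <- ((1 - r)^2 + r^2) / 2
  p
}

#' Two-point recombination fraction between two ABH columns
#'
#' Maximizes the F2 codominant two-point likelihood by EM over the
#' latent recombinant-gamete count of the double-heterozygote class.
#' Reports the estimate, the LOD score `log10 L(r) / L(0.5)` and the
#' likelihood-ratio p-value of the test of `r = 0.5` (no linkage).
#'
#' @param col_i,col_j Character vectors of `A/H/B/-` codes over the
#'   same individuals.
#' @param min_joint Minimum jointly called individuals (default 20);
#'   below it the pair is undefined (`NA` estimates).
#' @param max_iter,tol EM controls.
#' @return List with `rf`, `lod`, `p_value`, `n_joint`.
#' @export
estimate_rf <- function(col_i, col_j, min_joint = 20, max_iter = 100,
                        tol = 1e-10) {
  ok <- col_i %in% c("A", "H", "B") & col_j %in% c("A", "H", "B")
  n <- sum(ok)
  if (n < min_joint)
    return(list(rf = NA_real_, lod = NA_real_, p_value = NA_real_,
                n_joint = n))
  gi <- match(col_i[ok], c("A", "H", "B"))
  gj <- match(col_j[ok], c("A", "H", "B"))
  cnt <- matrix(0, 3, 3)
  for (cell in seq_len(n)) cnt[gi[cell], gj[cell]] <-
      cnt[gi[cell], gj[cell]] + 1
  rf_em_from_counts(cnt, max_iter = max_iter, tol = tol)
}

rf_em_from_counts <- function(cnt, max_iter = 100, tol = 1e-10) {
  n <- sum(cnt)
  # known recombinant-gamete counts per cell; the double het is latent
  nrec <- matrix(c(0, 1, 2, 1, NA, 1, 2, 1, 0), 3, 3)
  r <- 0.25
  for (iter in seq_len(max_iter)) {
    e_hh <- 2 * r^2 / ((1 - r)^2 + r^2)
    num <- sum(cnt * ifelse(is.na(nrec), e_hh, nrec))
    r_new <- min(max(num / (2 * n), 1e-9), 0.5 - 1e-9)
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  ll <- function(r) sum(cnt * log(f2_cell_probs(r)), na.rm = TRUE)
  ll_r <- ll(r)
  ll_0 <- ll(0.5)
  g <- max(2 * (ll_r - ll_0), 0)
  list(rf = r, lod = (ll_r - ll_0) / log(10),
       p_value = stats::pchisq(g, df = 1, lower.tail = FALSE),
       n_joint = n)
}

#' All pairwise recombination fractions of an ABH matrix
#'
#' Vectorized two-point EM over every marker pair: the nine joint
#' genotype counts are obtained by cross-products of indicator
#' matrices, and the EM update is applied to all pairs simultaneously.
#'
#' @param abh Marker-by-individual ABH matrix.
#' @inheritParams estimate_rf
#' @return List of marker-by-marker matrices `rf`, `lod`, `p_value`,
#'   `n_joint`; pairs with fewer than `min_joint` joint calls are `NA`.
#' @export
rf_matrix <- function(abh, min_joint = 20, max_iter = 100, tol = 1e-10) {
  m <- nrow(abh)
  ind <- lapply(c("A", "H", "B"), function(code)
    matrix(as.numeric(abh == code), m, ncol(abh)))
  cnt <- list()
  for (a in 1:3) for (b in 1:3)
    cnt[[paste(a, b)]] <- tcrossprod(ind[[a]], ind[[b]])
  n <- Reduce(`+`, cnt)
  nrec_known <- cnt[["1 2"]] + cnt[["2 1"]] + cnt[["2 3"]] +
    cnt[["3 2"]] + 2 * (cnt[["1 3"]] + cnt[["3 1"]])
  hh <- cnt[["2 2"]]
  r <- matrix(0.25, m, m)
  for (iter in seq_len(max_iter)) {
    e_hh <- 2 * r^2 / ((1 - r)^2 + r^2)
    r_new <- (nrec_known + hh * e_hh) / (2 * n)
    r_new[!is.finite(r_new)] <- 0.25
    r_new <- pmin(pmax(r_new, 1e-9), 0.5 - 1e-9)
    if (max(abs(r_new - r)) < tol) { r <- r_new; break }
    r <- r_new
  }
  llm <- function(r) {
    cnt[["1 1"]] * log((1 - r)^2 / 4) + cnt[["3 3"]] *
      log((1 - r)^2 / 4) +
      (cnt[["1 3"]] + cnt[["3 1"]]) * log(pmax(r^2 / 4, 1e-300)) +
      (cnt[["1 2"]] + cnt[["2 1"]] + cnt[["2 3"]] + cnt[["3 2"]]) *
        log(pmax(r * (1 - r) / 2, 1e-300)) +
      hh * log(((1 - r)^2 + r^2) / 2)
  }
  lod <- (llm(r) - llm(matrix(0.5 - 1e-12, m, m))) / log(10)
  gstat <- pmax(2 * log(10) * lod, 0)
  p <- stats::pchisq(gstat, df = 1, lower.tail = FALSE)
  small <- n < min_joint
  r[small] <- NA; lod[small] <- NA; p[small] <- NA
  diag(r) <- 0; diag(lod) <- NA; diag(p) <- NA
  dn <- list(rownames(abh), rownames(abh))
  dimnames(r) <- dimnames(lod) <- dimnames(p) <- dimnames(n) <- dn
  list(rf = r, lod = lod, p_value = p, n_joint = n)
}

#' Partition markers into linkage groups
#'
#' Single-linkage transitive closure over all pairs satisfying the
#' linkage criterion (default: p-value at most `p_max` after
#' Bonferroni adjustment over the number of tested pairs, AND LOD at
#' least `lod_min`). The multiplicity adjustment mirrors the search
#' criterion of classic mapping software: with tens of thousands of
#' marker pairs, a raw per-pair threshold would join unrelated groups
#' through chance linkages. Groups are numbered by descending size,
#' ties by first marker name.
#'
#' @param pairwise Result of [rf_matrix()].
#' @param p_max Linkage significance criterion (default 0.05).
#' @param lod_min LOD floor (default 3) guarding against spurious
#'   closure in populations of moderate size.
#' @param p_adjust `"bonferroni"` (default) or `"none"`: whether
#'   `p_max` is divided by the number of tested pairs.
#' @return Named integer vector: group number per marker (singletons
#'   get their own groups).
#' @export
group_markers <- function(pairwise, p_max = 0.05, lod_min = 3,
                          p_adjust = c("bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  n_pairs <- sum(!is.na(pairwise$p_value)) / 2
  thr <- if (p_adjust == "bonferroni" && n_pairs > 0)
    p_max / n_pairs else p_max
  adj <- !is.na(pairwise$p_value) & pairwise$p_value <= thr &
    !is.na(pairwise$lod) & pairwise$lod >= lod_min
  m <- nrow(adj)
  comp <- rep(NA_integer_, m)
  cur <- 0L
  for (i in seq_len(m)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- table(comp)
  first <- tapply(seq_len(m), comp, min)
  ord <- order(-as.integer(sizes), first)
  renum <- integer(length(sizes))
  renum[as.integer(names(sizes))[ord]] <- seq_along(ord)
  out <- renum[comp]
  names(out) <- rownames(pairwise$rf)
  out
}

sarf <- function(order_idx, d) {
  if (length(order_idx) < 2) return(0)
  sum(d[cbind(order_idx[-length(order_idx)], order_idx[-1])])
}

permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, ifelse(sub >= i, sub + 1L, sub))))
}

order_exhaustive <- function(d) {
  n <- nrow(d)
  if (n <= 2) return(seq_len(n))
  perms <- permutations(n)
  perms <- perms[perms[, 1] < perms[, n], , drop = FALSE]  # drop mirrors
  costs <- apply(perms, 1, sarf, d = d)
  perms[which.min(costs), ]
}

order_heuristic <- function(d) {
  n <- nrow(d)
  if (n <= 2) return(seq_len(n))
  # greedy seriation from the most-linked pair
  dd <- d
  diag(dd) <- Inf
  start <- which(dd == min(dd), arr.ind = TRUE)[1, ]
  path <- as.integer(start)
  left <- setdiff(seq_len(n), path)
  while (length(left)) {
    head_d <- dd[path[1], left]
    tail_d <- dd[path[length(path)], left]
    if (min(head_d) <= min(tail_d)) {
      pick <- left[which.min(head_d)]
      path <- c(pick, path)
    } else {
      pick <- left[which.min(tail_d)]
      path <- c(path, pick)
    }
    left <- setdiff(left, pick)
  }
  improve <- TRUE
  while (improve) {
    improve <- FALSE
    best <- sarf(path, d)
    # 2-opt: reverse every segment
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        cand <- path
        cand[i:j] <- rev(cand[i:j])
        cost <- sarf(cand, d)
        if (cost < best - 1e-12) {
          path <- cand
          best <- cost
          improve <- TRUE
        }
      }
    }
    # or-opt: relocate single elements
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        cand <- append(path[-i], path[i], after = j - 1)
        cost <- sarf(cand, d)
        if (cost < best - 1e-12) {
          path <- cand
          best <- cost
          improve <- TRUE
        }
      }
    }
  }
  path
}

#' Order the markers of one linkage group
#'
#' Markers with identical ABH columns are first collapsed into bins;
#' the bins are then ordered to minimize the sum of adjacent
#' recombination fractions (SARF). Groups of at most `exhaustive_max`
#' bins are solved exactly by enumeration; larger groups use greedy
#' seriation from the most-linked pair refined by 2-opt segment
#' reversals and single-bin relocations until no move improves.
#'
#' @param abh ABH matrix restricted to the group's markers (rows).
#' @param rf Optional precomputed rf matrix over those markers.
#' @param method `"auto"` (exhaustive for small groups), `"heuristic"`
#'   or `"exhaustive"`.
#' @param exhaustive_max Bin count up to which `"auto"` enumerates
#'   (default 6).
#' @param min_joint Passed to [rf_matrix()] when `rf` is `NULL`.
#' @return List with `order` (marker ids in map order; co-segregating
#'   bin members adjacent), `bins` (bin index per marker), `sarf`.
#' @export
order_group <- function(abh, rf = NULL, method = c("auto", "heuristic",
                                                   "exhaustive"),
                        exhaustive_max = 6, min_joint = 20) {
  method <- match.arg(method)
  markers <- rownames(abh)
  key <- apply(abh, 1, paste, collapse = "")
  bin_id <- match(key, unique(key))
  reps <- match(unique(bin_id), bin_id)
  if (is.null(rf))
    rf <- rf_matrix(abh, min_joint = min_joint)$rf
  d <- rf[reps, reps, drop = FALSE]
  d[is.na(d)] <- 0.5
  nb <- length(reps)
  ord <- if (nb <= 2) seq_len(nb)
  else if (method == "exhaustive" ||
           (method == "auto" && nb <= exhaustive_max))
    order_exhaustive(d)
  else order_heuristic(d)
  # canonical orientation: first marker name <= last marker name
  first_mk <- markers[reps[ord[1]]]
  last_mk <- markers[reps[ord[nb]]]
  if (first_mk > last_mk) ord <- rev(ord)
  out <- unname(unlist(lapply(ord, function(b) markers[bin_id == b])))
  list(order = out, bins = stats::setNames(bin_id, markers),
       sarf = sarf(ord, d))
}

#' Build an F2 genetic map from an ABH matrix
#'
#' Full chain: pairwise recombination fractions, linkage grouping,
#' per-group SARF ordering and cumulative Kosambi positions (adjacent
#' co-segregating markers share a position).
#'
#' @param abh Marker-by-individual ABH matrix.
#' @inheritParams group_markers
#' @inheritParams order_group
#' @param min_group_size Groups smaller than this are kept as
#'   singleton/rump groups but still reported (default 2).
#' @return A [genetic_map()]; the pairwise tables are attached as
#'   attribute `pairwise`.
#' @export
build_map <- function(abh, p_max = 0.05, lod_min = 3, min_joint = 20,
                      method = "auto", exhaustive_max = 6,
                      min_group_size = 2,
                      p_adjust = c("bonferroni", "none")) {
  pw <- rf_matrix(abh, min_joint = min_joint)
  grp <- group_markers(pw, p_max = p_max, lod_min = lod_min,
                       p_adjust = p_adjust)
  pieces <- lapply(sort(unique(grp)), function(g) {
    mk <- names(grp)[grp == g]
    if (length(mk) == 1)
      return(data.frame(marker = mk, group = sprintf("LG%02d", g),
                        cm = 0))
    og <- order_group(abh[mk, , drop = FALSE],
                      rf = pw$rf[mk, mk, drop = FALSE],
                      method = method, exhaustive_max = exhaustive_max,
                      min_joint = min_joint)
    mk_ord <- og$order
    r_adj <- pw$rf[cbind(mk_ord[-length(mk_ord)], mk_ord[-1])]
    r_adj[is.na(r_adj)] <- 0.5 - 1e-9
    data.frame(marker = mk_ord, group = sprintf("LG%02d", g),
               cm = cumsum(c(0, kosambi(r_adj))))
  })
  df <- do.call(rbind, pieces)
  map <- genetic_map(df$marker, df$group, df$cm)
  attr(map, "pairwise") <- pw
  map
}

group_lengths <- function(map) {
  vapply(split(map$cm, map$group), function(x) max(x) - min(x),
         numeric(1))
}

# apparent double recombinants: individuals where a marker disagrees
# with both immediate (non-missing) neighbours which agree with each
# other
double_recombinant_counts <- function(abh, order_mk) {
  m <- length(order_mk)
  counts <- stats::setNames(integer(m), order_mk)
  if (m < 3) return(counts)
  x <- abh[order_mk, , drop = FALSE]
  for (i in 2:(m - 1)) {
    a <- x[i - 1, ]; b <- x[i, ]; cc <- x[i + 1, ]
    ok <- a != "-" & b != "-" & cc != "-"
    counts[i] <- sum(ok & a == cc & b != a)
  }
  counts
}

#' Remove markers causing spurious map expansion
#'
#' Iteratively removes the marker whose exclusion most reduces its
#' group's length, among markers whose apparent singleton
#' double-recombinant count exceeds `max_doubles` — the signature of a
#' poorly scored marker inflating the map with false crossovers. Stops
#' when no marker qualifies; the map length never increases.
#'
#' @param map A [genetic_map()].
#' @param abh The ABH matrix used to build the map.
#' @param max_doubles Tolerated singleton double-recombinant count
#'   (default 2).
#' @return List with `map` (rebuilt positions over the retained
#'   markers, original orders kept) and `removed` (marker ids).
#' @export
clean_markers <- function(map, abh, max_doubles = 2) {
  removed <- character(0)
  pw <- attr(map, "pairwise")
  repeat {
    changed <- FALSE
    for (g in unique(map$group)) {
      mk <- map$marker[map$group == g]
      if (length(mk) < 3) next
      dr <- double_recombinant_counts(abh, mk)
      bad <- names(dr)[dr > max_doubles]
      if (!length(bad)) next
      len0 <- max(map$cm[map$group == g])
      reductions <- vapply(bad, function(b) {
        keep <- setdiff(mk, b)
        len0 - path_length(abh, keep)
      }, numeric(1))
      if (max(reductions) <= 0) next
      drop_mk <- bad[which.max(reductions)]
      keep <- setdiff(mk, drop_mk)
      removed <- c(removed, drop_mk)
      new_cm <- path_positions(abh, keep)
      map <- map[map$marker != drop_mk, ]
      map$cm[map$group == g] <- new_cm[map$marker[map$group == g]]
      changed <- TRUE
    }
    if (!changed) break
  }
  map <- genetic_map(map$marker, map$group, map$cm)
  attr(map, "pairwise") <- pw
  list(map = map, removed = removed)
}

path_positions <- function(abh, order_mk) {
  if (length(order_mk) == 1)
    return(stats::setNames(0, order_mk))
  r <- vapply(seq_len(length(order_mk) - 1), function(i)
    estimate_rf(abh[order_mk[i], ], abh[order_mk[i + 1], ],
                min_joint = 1)$rf, numeric(1))
  r[is.na(r)] <- 0.5 - 1e-9
  stats::setNames(cumsum(c(0, kosambi(r))), order_mk)
}

path_length <- function(abh, order_mk) {
  p <- path_positions(abh, order_mk)
  max(p) - min(p)
}

#' Reorder a linkage group against a framework map
#'
#' Markers shared with the framework are fixed in the framework's
#' relative order; the group's remaining markers are inserted one by
#' one at the SARF-minimizing position. Used to correct inversions
#' across weakly linked gaps, where de novo ordering can flip a
#' segment. A warning is issued if the reordered group is longer than
#' the original.
#'
#' @param abh ABH matrix restricted to the group's markers.
#' @param framework_order Character vector of marker ids in trusted
#'   order (>= 2 must be shared with the group).
#' @return List with `order`, `cm` (named positions) and `length_cm`.
#' @export
framework_reorder <- function(abh, framework_order) {
  markers <- rownames(abh)
  shared <- framework_order[framework_order %in% markers]
  if (length(shared) < 2)
    stop_fmt("fewer than 2 markers shared with the framework")
  rf <- rf_matrix(abh, min_joint = 1)$rf
  rf[is.na(rf)] <- 0.5
  path <- match(shared, markers)
  for (mk in setdiff(markers, shared)) {
    i <- match(mk, markers)
    costs <- vapply(seq_len(length(path) + 1), function(pos) {
      cand <- append(path, i, after = pos - 1)
      sarf(cand, rf)
    }, numeric(1))
    path <- append(path, i, after = which.min(costs) - 1)
  }
  ord <- markers[path]
  cm <- path_positions(abh, ord)
  len0 <- path_length(abh, markers)
  if (max(cm) > len0 + 1e-9)
    warn_fmt("framework reorder increased group length (%.1f -> %.1f cM)",
             len0, max(cm))
  list(order = ord, cm = cm, length_cm = max(cm))
}

#' Count crossovers per individual per linkage group
#'
#' Scans each individual's non-missing codes in map order; an A-H or
#' H-B transition counts one crossover and an A-B transition two
#' (missing codes are skipped, so transitions are measured between the
#' nearest non-missing flanks). Individuals whose count in any group
#' exceeds `outlier_mult` times that group's population mean are
#' flagged as outliers.
#'
#' @param abh Marker-by-individual ABH matrix.
#' @param map A [genetic_map()] over (a subset of) the markers.
#' @param outlier_mult Outlier flag multiplier (default 2).
#' @return List with `per_group` (group-by-individual count matrix),
#'   `per_individual` (totals), `group_means`, and `outliers` (logical
#'   per individual).
#' @export
count_crossovers <- function(abh, map, outlier_mult = 2) {
  groups <- unique(map$group)
  inds <- colnames(abh)
  per_group <- matrix(0L, length(groups), length(inds),
                      dimnames = list(groups, inds))
  score <- c(A = 0L, H = 1L, B = 2L)
  for (g in groups) {
    mk <- map$marker[map$group == g]
    x <- abh[mk, , drop = FALSE]
    for (j in seq_along(inds)) {
      v <- score[x[, j][x[, j] != "-"]]
      if (length(v) > 1)
        per_group[g, j] <- sum(abs(diff(v)))
    }
  }
  means <- rowMeans(per_group)
  outliers <- apply(per_group > outlier_mult * means, 2, any)
  list(per_group = per_group, per_individual = colSums(per_group),
       group_means = means, outliers = outliers)
}

#' Recombination bins of a mapped ABH matrix
#'
#' Within each group (in map order) consecutive markers whose genotype
#' columns are identical — treating missing codes as compatible with
#' anything — merge into one recombination bin: the interval between
#' one recombination breakpoint and the next in the population.
#'
#' @inheritParams count_crossovers
#' @return data.frame per group: `n_markers`, `n_bins`,
#'   `markers_per_bin`; bin assignment per marker in attribute `bins`.
#' @export
recombination_bins <- function(abh, map) {
  res <- list()
  assignment <- stats::setNames(integer(0), character(0))
  for (g in unique(map$group)) {
    mk <- map$marker[map$group == g]
    x <- abh[mk, , drop = FALSE]
    bin <- integer(length(mk))
    bin[1] <- 1L
    consensus <- x[1, ]
    for (i in seq_along(mk)[-1]) {
      v <- x[i, ]
      compat <- all(v == consensus | v == "-" | consensus == "-")
      if (compat) {
        bin[i] <- bin[i - 1]
        upd <- consensus == "-" & v != "-"
        consensus[upd] <- v[upd]
      } else {
        bin[i] <- bin[i - 1] + 1L
        consensus <- v
      }
    }
    assignment <- c(assignment, stats::setNames(bin, mk))
    res[[g]] <- data.frame(group = g, n_markers = length(mk),
                           n_bins = max(bin),
                           markers_per_bin = length(mk) / max(bin))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "bins") <- assignment
  out
}

#' Segregation-distortion test per marker
#'
#' Chi-square goodness of fit of each marker's A/H/B counts against
#' the Mendelian F2 ratio 1:2:1 (2 degrees of freedom). Reports, per
#' marker, the statistic, p-value, a heterozygote-deficit flag
#' (observed H below expectation) and the favored parent (sign of
#' nA - nB), plus a map-level summary: distorted fraction at `alpha`,
#' heterozygote-deficit fraction among distorted markers, and the
#' ratio of female- to male-favored distorted markers.
#'
#' @param abh Marker-by-individual ABH matrix (`A` = female-parent
#'   homozygote by convention).
#' @param alpha Significance level (default 0.05).
#' @return List with `per_marker` (data.frame) and `summary` (list).
#' @export
segregation_distortion <- function(abh, alpha = 0.05) {
  nA <- rowSums(abh == "A")
  nH <- rowSums(abh == "H")
  nB <- rowSums(abh == "B")
  n <- nA + nH + nB
  empty <- n == 0
  if (any(empty))
    warn_fmt("%d all-missing marker(s) excluded from distortion test",
             sum(empty))
  exp_a <- n / 4; exp_h <- n / 2
  chi2 <- (nA - exp_a)^2 / exp_a + (nH - exp_h)^2 / exp_h +
    (nB - exp_a)^2 / exp_a
  chi2[empty] <- NA
  p <- stats::pchisq(chi2, df = 2, lower.tail = FALSE)
  per_marker <- data.frame(
    marker = rownames(abh), n = n, nA = nA, nH = nH, nB = nB,
    chi2 = chi2, p_value = p,
    distorted = !is.na(p) & p < alpha,
    het_deficit = nH < exp_h,
    favored = ifelse(nA > nB, "A", ifelse(nB > nA, "B", "none")),
    stringsAsFactors = FALSE)
  rownames(per_marker) <- NULL
  dd <- per_marker[per_marker$distorted, ]
  n_fav_a <- sum(dd$favored == "A")
  n_fav_b <- sum(dd$favored == "B")
  summary <- list(
    n_markers = sum(!empty),
    n_distorted = nrow(dd),
    distorted_pct = round(100 * nrow(dd) / max(sum(!empty), 1), 1),
    het_deficit_pct_of_distorted =
      if (nrow(dd)) round(100 * mean(dd$het_deficit), 1) else NA_real_,
    favored_female_male_ratio =
      if (n_fav_b > 0) round(n_fav_a / n_fav_b, 2) else NA_real_)
  list(per_marker = per_marker, summary = summary)
}
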