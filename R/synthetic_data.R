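# Synthetic-data generator: marker intensity clusters (the six
# canonical patterns of a tetraploid Infinium array), inbred panels
# with a realistic MAF spectrum, and F2 populations simulated as
# Markov walks along a genetic map. Every emitted datum is traceable
# to a truth record and all generators are deterministic under a seed.

#' Specification of a marker's intensity cluster pattern
#'
#' Describes the generative model of one marker: component means/sds on
#' theta, the shared signal level R, per-component genotype labels and
#' an optional null-allele rate (fraction of samples whose assay yields
#' no signal, drawn at low R).
#'
#' @param pattern Pattern id, 1-6.
#' @param mean_theta Strictly increasing component means in `[0, 1]`.
#' @param sd_theta Component standard deviations (> 0), recycled.
#' @param label Genotype label per component (`AA`, `AB`, `BB`).
#' @param weight Component (genotype) frequencies, summing to 1.
#' @param mean_r,sd_r Signal level of called samples (defaults 1, 0.1).
#' @param null_rate Null-allele rate in `[0, 1]` (default 0).
#' @return Object of class `pattern_spec`.
#' @export
pattern_spec <- function(pattern, mean_theta, sd_theta, label,
                         weight = NULL, mean_r = 1, sd_r = 0.1,
                         null_rate = 0) {
  k <- length(mean_theta)
  sd_theta <- rep_len(sd_theta, k)
  weight <- weight %||% rep(1 / k, k)
  if (k > 1 && any(diff(mean_theta) <= 0))
    stop_fmt("component mean thetas must be strictly increasing (gap > 0)")
  if (any(mean_theta < 0 | mean_theta > 1))
    stop_fmt("component means must lie in [0, 1]")
  if (any(sd_theta <= 0)) stop_fmt("component sds must be > 0")
  if (null_rate < 0 || null_rate > 1)
    stop_fmt("null_rate must lie in [0, 1]")
  if (pattern == 2 && !(k == 1 && abs(mean_theta - 0.5) < 0.15))
    stop_fmt("pattern 2 must have exactly one component centered near 0.5")
  if (pattern == 4 &&
      !any(label != "AB" & abs(mean_theta - 0.5) < 0.1))
    stop_fmt("pattern 4 must have a homozygote component near 0.5")
  structure(list(pattern = as.integer(pattern), mean_theta = mean_theta,
                 sd_theta = sd_theta, label = label,
                 weight = weight / sum(weight), mean_r = mean_r,
                 sd_r = sd_r, null_rate = null_rate),
            class = "pattern_spec")
}

#' Default pattern specifications
#'
#' One generative spec per canonical cluster pattern:
#' 1 monomorphic (single homozygous cluster); 2 intergenomic /
#' homeo-SNP (single heterozygous cluster at 0.5); 3 genome-specific
#' diploid-like marker (0.05/0.50/0.95); 4 shifted two-locus marker
#' with a homozygote cluster at 0.5; 5 compressed clusters (multiple
#' background loci); 6 extremely close clusters (many background loci,
#' separation score below 0.20).
#'
#' @return Named list of [pattern_spec] objects `p1`-`p6`.
#' @export
default_pattern_specs <- function() {
  list(
    p1 = pattern_spec(1, 0.05, 0.03, "AA"),
    p2 = pattern_spec(2, 0.50, 0.03, "AB"),
    p3 = pattern_spec(3, c(0.05, 0.50, 0.95), 0.03,
                      c("AA", "AB", "BB"), weight = c(0.4, 0.2, 0.4)),
    p4 = pattern_spec(4, c(0.05, 0.275, 0.50), 0.03,
                      c("AA", "AB", "BB"), weight = c(0.4, 0.2, 0.4)),
    p5 = pattern_spec(5, c(0.45, 0.50, 0.55), 0.033,
                      c("AA", "AB", "BB"), weight = c(0.4, 0.2, 0.4)),
    p6 = pattern_spec(6, c(0.45, 0.50, 0.55), 0.06,
                      c("AA", "AB", "BB"), weight = c(0.4, 0.2, 0.4)))
}

rnorm_trunc01 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Simulate intensities for one marker
#'
#' Each sample is assigned a mixture component according to the spec's
#' genotype frequencies; theta is drawn from a normal truncated to
#' `[0, 1]` and R from a normal around the spec's signal level.
#' Null-allele samples (signal failure) are drawn at low R with
#' uninformative theta.
#'
#' @param spec A [pattern_spec].
#' @param n_samples Number of samples (>= 1).
#' @param seed Optional integer seed.
#' @param marker Marker id.
#' @return List with `intensity` (an [intensity_table] with one marker)
#'   and `truth` (data.frame: sample, component, genotype, null).
#' @export
simulate_marker_intensities <- function(spec, n_samples, seed = NULL,
                                        marker = "m1") {
  stopifnot(inherits(spec, "pattern_spec"), n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(spec$mean_theta), n_samples, replace = TRUE,
                     prob = spec$weight)
  theta <- rnorm_trunc01(n_samples, spec$mean_theta[comp],
                         spec$sd_theta[comp])
  r <- stats::rnorm(n_samples, spec$mean_r, spec$sd_r)
  nul <- stats::runif(n_samples) < spec$null_rate
  if (any(nul)) {
    theta[nul] <- stats::runif(sum(nul))
    r[nul] <- pmax(stats::rnorm(sum(nul), 0.08, 0.04), 0)
  }
  r <- pmax(r, 0)
  samples <- sprintf("s%03d", seq_len(n_samples))
  it <- intensity_table(marker, samples,
                        theta = matrix(theta, 1), r = matrix(r, 1))
  truth <- data.frame(sample = samples, component = comp,
                      genotype = spec$label[comp], null = nul,
                      stringsAsFactors = FALSE)
  list(intensity = it, truth = truth)
}

#' Simulate a panel of markers spanning cluster patterns
#'
#' Draws `n_markers` markers with patterns sampled from
#' `pattern_freqs` (or cycled when `pattern_freqs` is `NULL`) and
#' simulates intensities for all of them over a common sample set.
#'
#' @param n_markers,n_samples Panel dimensions.
#' @param specs Named list of [pattern_spec]s
#'   (default [default_pattern_specs()]).
#' @param pattern_freqs Named numeric vector of pattern frequencies
#'   over `names(specs)`.
#' @param seed Optional integer seed.
#' @return List with `intensity`, and `truth` (data.frame: marker,
#'   pattern, status plus per-cell genotype matrix in `genotypes`).
#' @export
simulate_marker_panel <- function(n_markers, n_samples,
                                  specs = default_pattern_specs(),
                                  pattern_freqs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  which_spec <- if (is.null(pattern_freqs)) {
    rep_len(seq_along(specs), n_markers)
  } else {
    idx <- match(names(pattern_freqs), names(specs))
    idx[sample.int(length(idx), n_markers, replace = TRUE,
                   prob = pattern_freqs)]
  }
  markers <- sprintf("m%04d", seq_len(n_markers))
  samples <- sprintf("s%03d", seq_len(n_samples))
  theta <- matrix(NA_real_, n_markers, n_samples,
                  dimnames = list(markers, samples))
  r <- theta
  geno <- matrix(NA_character_, n_markers, n_samples,
                 dimnames = list(markers, samples))
  nulls <- matrix(FALSE, n_markers, n_samples)
  for (i in seq_len(n_markers)) {
    sim <- simulate_marker_intensities(specs[[which_spec[i]]], n_samples,
                                       marker = markers[i])
    theta[i, ] <- sim$intensity$theta
    r[i, ] <- sim$intensity$r
    geno[i, ] <- sim$truth$genotype
    nulls[i, ] <- sim$truth$null
  }
  pat <- vapply(specs[which_spec], `[[`, integer(1), "pattern")
  status <- c("monomorphic", "intergenomic", rep("polymorphic", 4))[pat]
  list(intensity = intensity_table(markers, samples, theta = theta, r = r),
       truth = data.frame(marker = markers, pattern = as.character(pat),
                          status = status, stringsAsFactors = FALSE),
       genotypes = geno, nulls = nulls)
}

#' Minor-allele-frequency law calibrated to a cotton inbred panel
#'
#' Returns a sampler of per-marker minor allele frequencies,
#' `MAF = 0.5 * Beta(0.427, 0.784)`, calibrated so that the simulated
#' spectrum matches the exceedance profile observed on a diverse inbred
#' panel (about 67% of markers above 0.05, 56% above 0.10, 40% above
#' 0.2, mean about 0.17).
#'
#' @param shape1,shape2 Beta shape parameters.
#' @return `function(n)` drawing `n` MAF values in `[0, 0.5]`.
#' @export
cotton_maf_law <- function(shape1 = 0.427, shape2 = 0.784) {
  function(n) 0.5 * stats::rbeta(n, shape1, shape2)
}

#' Simulate an inbred-line genotype panel
#'
#' Per marker, the B-allele frequency is drawn from `maf_law`; each
#' fully inbred line is then homozygous `BB` with that probability and
#' `AA` otherwise, except for a residual-heterozygosity rate of `AB`
#' calls emulating heterogeneous lines.
#'
#' @param n_lines,n_markers Panel dimensions.
#' @param maf_law `function(n)` returning frequencies in `[0, 0.5]`, or
#'   a numeric vector/scalar of fixed frequencies.
#' @param residual_het Per-call probability of a heterozygous call
#'   (default 0.005).
#' @param seed Optional integer seed.
#' @return List with `calls` (marker-by-line matrix of `AA/AB/BB`) and
#'   `truth` (data.frame with per-marker allele frequency `maf`).
#' @export
simulate_inbred_panel <- function(n_lines, n_markers,
                                  maf_law = cotton_maf_law(),
                                  residual_het = 0.005, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- if (is.function(maf_law)) maf_law(n_markers)
       else rep_len(maf_law, n_markers)
  if (any(q < 0 | q > 0.5))
    stop_fmt("maf_law must yield values in [0, 0.5]")
  markers <- sprintf("m%05d", seq_len(n_markers))
  lines <- sprintf("line%03d", seq_len(n_lines))
  calls <- matrix(ifelse(stats::runif(n_markers * n_lines) < q, "BB",
                         "AA"),
                  n_markers, n_lines, dimnames = list(markers, lines))
  if (residual_het > 0)
    calls[stats::runif(length(calls)) < residual_het] <- "AB"
  list(calls = calls,
       truth = data.frame(marker = markers, maf = q,
                          stringsAsFactors = FALSE))
}

#' Build an evenly spaced multi-group truth map
#'
#' @param n_groups Number of linkage groups (default 26, the
#'   allotetraploid cotton chromosome number).
#' @param markers_per_group Markers per group.
#' @param length_cm Group length in Kosambi cM (recycled).
#' @return A [genetic_map()] with evenly spaced markers.
#' @export
simulate_genome_map <- function(n_groups = 26, markers_per_group = 20,
                                length_cm = 135) {
  length_cm <- rep_len(length_cm, n_groups)
  df <- do.call(rbind, lapply(seq_len(n_groups), function(g)
    data.frame(marker = sprintf("g%02dm%02d", g,
                                seq_len(markers_per_group)),
               group = sprintf("LG%02d", g),
               cm = seq(0, length_cm[g],
                        length.out = markers_per_group))))
  genetic_map(df$marker, df$group, df$cm)
}

#' Simulate an F2 population along a genetic map
#'
#' Each gamete is a Markov walk (no interference) along each linkage
#' group: the starting parental allele is fair and switches between
#' adjacent markers with probability equal to the inverse-Kosambi of
#' the interval length. Two independent gametes form each F2
#' individual; genotypes are coded `A`/`H`/`B`. Optional per-marker
#' viability weights induce segregation distortion by rejection
#' sampling of whole individuals; an optional missing-data rate blanks
#' calls to `-`.
#'
#' @param map_truth A [genetic_map()] (>= 1 group, intervals >= 0 cM).
#' @param n_individuals Population size.
#' @param distortion Optional data.frame with columns `marker`, `wA`,
#'   `wH`, `wB`: relative viabilities of the three genotypes at that
#'   marker.
#' @param missing_rate Per-call missing probability (default 0).
#' @param seed Optional integer seed.
#' @return List with `abh` (marker-by-individual matrix of
#'   `A/H/B/-`), and `truth` holding the map, the per-individual
#'   per-group crossover counts (`crossovers`), and the complete
#'   (pre-missing) genotype matrix.
#' @export
simulate_f2 <- function(map_truth, n_individuals, distortion = NULL,
                        missing_rate = 0, seed = NULL) {
  stopifnot(nrow(map_truth) >= 1, n_individuals >= 1)
  if (!is.null(seed)) set.seed(seed)
  groups <- split(map_truth, map_truth$group)
  inds <- sprintf("ind%03d", seq_len(n_individuals))
  dist_w <- NULL
  if (!is.null(distortion)) {
    mx <- pmax(distortion$wA, distortion$wH, distortion$wB)
    dist_w <- data.frame(marker = distortion$marker,
                         wA = distortion$wA / mx,
                         wH = distortion$wH / mx,
                         wB = distortion$wB / mx)
  }
  gamete <- function(rfs, n) {
    # n haplotypes over length(rfs) + 1 loci; returns 0/1 allele matrix
    m <- length(rfs) + 1
    h <- matrix(0L, m, n)
    h[1, ] <- stats::rbinom(n, 1, 0.5)
    if (m > 1) {
      sw <- matrix(stats::rbinom((m - 1) * n, 1, rfs), m - 1, n)
      h[-1, ] <- sw
      h <- apply(h, 2, cumsum) %% 2L
    }
    h
  }
  sim_individuals <- function(n) {
    geno <- NULL
    xo <- NULL
    for (g in names(groups)) {
      gm <- groups[[g]]
      d_cm <- diff(gm$cm)
      if (any(d_cm < 0)) stop_fmt("negative map interval in group %s", g)
      rfs <- kosambi_inv(d_cm)
      h1 <- gamete(rfs, n)
      h2 <- gamete(rfs, n)
      geno <- rbind(geno, h1 + h2)
      m <- length(rfs) + 1
      xo_g <- if (m > 1)
        colSums(h1[-1, , drop = FALSE] != h1[-m, , drop = FALSE]) +
          colSums(h2[-1, , drop = FALSE] != h2[-m, , drop = FALSE])
      else rep(0, n)
      xo <- rbind(xo, xo_g)
    }
    # split() orders groups like the sorted map, so rows already align
    rownames(geno) <- map_truth$marker
    rownames(xo) <- names(groups)
    list(geno = geno, xo = xo)
  }
  accept_prob <- function(geno) {
    if (is.null(dist_w)) return(rep(1, ncol(geno)))
    p <- rep(1, ncol(geno))
    for (i in seq_len(nrow(dist_w))) {
      gg <- geno[dist_w$marker[i], ]
      w <- c(dist_w$wA[i], dist_w$wH[i], dist_w$wB[i])
      p <- p * w[gg + 1L]
    }
    p
  }
  geno <- NULL; xo <- NULL
  need <- n_individuals
  while (need > 0) {
    batch <- sim_individuals(max(need, 16L))
    keep <- which(stats::runif(ncol(batch$geno)) <=
                    accept_prob(batch$geno))
    keep <- keep[seq_len(min(length(keep), need))]
    if (length(keep)) {
      geno <- cbind(geno, batch$geno[, keep, drop = FALSE])
      xo <- cbind(xo, batch$xo[, keep, drop = FALSE])
      need <- n_individuals - ncol(geno)
    }
  }
  # restore the map's own marker order
  geno <- geno[map_truth$marker, , drop = FALSE]
  colnames(geno) <- inds
  colnames(xo) <- inds
  abh <- matrix(c("A", "H", "B")[geno + 1L], nrow(geno), ncol(geno),
                dimnames = dimnames(geno))
  if (missing_rate > 0)
    abh[stats::runif(length(abh)) < missing_rate] <- "-"
  list(abh = abh,
       truth = list(map = map_truth, crossovers = xo,
                    genotypes = matrix(c("A", "H", "B")[geno + 1L],
                                       nrow(geno), ncol(geno),
                                       dimnames = dimnames(geno))))
}

#' Render true genotypes as raw intensities
#'
#' Closes the simulation loop: a matrix of true genotype calls is
#' converted back into two-channel polar intensities using a pattern
#' spec per marker, so the cluster engine can be exercised end-to-end
#' against known truth.
#'
#' @param genotypes Marker-by-sample matrix of `AA/AB/BB` (or `A/H/B`).
#' @param specs A single [pattern_spec] or a list of one spec per
#'   marker; every genotype must have a component with that label in
#'   its marker's spec.
#' @param seed Optional integer seed.
#' @return An [intensity_table].
#' @export
genotypes_to_intensities <- function(genotypes, specs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  recode <- c(A = "AA", H = "AB", B = "BB", AA = "AA", AB = "AB",
              BB = "BB")
  markers <- rownames(genotypes) %||%
    sprintf("m%04d", seq_len(nrow(genotypes)))
  samples <- colnames(genotypes) %||%
    sprintf("s%03d", seq_len(ncol(genotypes)))
  if (inherits(specs, "pattern_spec"))
    specs <- rep(list(specs), nrow(genotypes))
  theta <- matrix(NA_real_, nrow(genotypes), ncol(genotypes),
                  dimnames = list(markers, samples))
  r <- theta
  for (i in seq_len(nrow(genotypes))) {
    sp <- specs[[i]]
    g <- recode[genotypes[i, ]]
    comp <- match(g, sp$label)
    if (anyNA(comp[!is.na(g)]))
      stop_fmt("marker %s: genotype %s has no component in its spec",
               markers[i], g[which(is.na(comp) & !is.na(g))[1]])
    ok <- !is.na(comp)
    theta[i, ok] <- rnorm_trunc01(sum(ok), sp$mean_theta[comp[ok]],
                                  sp$sd_theta[comp[ok]])
    r[i, ok] <- pmax(stats::rnorm(sum(ok), sp$mean_r, sp$sd_r), 0)
  }
  intensity_table(markers, samples, theta = theta, r = r)
}
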