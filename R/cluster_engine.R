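# Per-marker genotype cluster engine: a one-dimensional Gaussian
# mixture on theta (the allelic-ratio axis), with R used only to
# exclude low-signal samples. Component count is chosen by BIC with
# deterministic quantile initialization, so refits are reproducible.

#' Construct a per-marker cluster model
#'
#' @param marker Marker id.
#' @param k Number of mixture components (1-3; 0 marks a failed fit).
#' @param mean_theta,sd_theta,mean_r,sd_r,weight Numeric vectors of
#'   length `k`, components in strictly increasing order of
#'   `mean_theta`; weights sum to 1.
#' @param label Genotype label per component (`AA`, `AB`, `BB`).
#' @param loglik,bic Optional fit statistics.
#' @return Object of class `cluster_model`.
#' @export
cluster_model <- function(marker, k, mean_theta, sd_theta, mean_r, sd_r,
                          weight, label, loglik = NA_real_,
                          bic = NA_real_) {
  k <- as.integer(k)
  if (k > 0) {
    if (is.unsorted(mean_theta, strictly = TRUE))
      stop_fmt("component means must be strictly increasing")
    if (abs(sum(weight) - 1) > 1e-6)
      stop_fmt("component weights must sum to 1")
  }
  structure(list(marker = marker, k = k, mean_theta = mean_theta,
                 sd_theta = sd_theta, mean_r = mean_r, sd_r = sd_r,
                 weight = weight, label = label, loglik = loglik,
                 bic = bic),
            class = "cluster_model")
}

# Position-based genotype labels: homozygotes live near 0 and 1, the
# heterozygote band around 0.5. Falls back to ordinal assignment when
# positions collide (k = 3 is always AA < AB < BB).
label_components <- function(means) {
  k <- length(means)
  if (k == 3) return(c("AA", "AB", "BB"))
  lab <- ifelse(means < 1 / 3, "AA", ifelse(means <= 2 / 3, "AB", "BB"))
  if (k == 2 && lab[1] == lab[2]) lab <- c("AA", "BB")
  lab
}

em_gmm_1d <- function(z, k, min_sd = 1e-3, max_iter = 500, tol = 1e-8) {
  n <- length(z)
  qs <- stats::quantile(z, probs = (seq_len(k) - 0.5) / k, names = FALSE,
                        type = 7)
  mu <- qs + seq_len(k) * 1e-9  # break exact ties in the init
  sd0 <- max(stats::sd(z) / k, min_sd)
  if (is.na(sd0)) sd0 <- min_sd
  sigma <- rep(sd0, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(c_i)
      w[c_i] * stats::dnorm(z, mu[c_i], sigma[c_i]), numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    post <- dens / tot
    nk <- colSums(post)
    nk[nk < 1e-12] <- 1e-12
    mu <- colSums(post * z) / nk
    sigma <- sqrt(colSums(post * (z - rep(mu, each = n))^2) / nk)
    sigma <- pmax(sigma, min_sd)
    w <- nk / n
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(mu = mu[ord], sigma = sigma[ord], w = w[ord], loglik = ll,
       bic = -2 * ll + (3 * k - 1) * log(n))
}

#' Fit intensity clusters for one marker
#'
#' Fits one-dimensional Gaussian mixtures on theta for k = 1, 2, 3
#' components and selects k by the Bayesian information criterion.
#' Samples with total signal below `r_floor` (putative assay failures)
#' are excluded before fitting. Initialization is deterministic, from
#' theta quantiles.
#'
#' @param theta Numeric vector of theta values across samples.
#' @param r Optional vector of total signal R; when supplied, samples
#'   with `r < r_floor` are excluded from the fit.
#' @param marker Marker id recorded in the model.
#' @param k_max Maximum number of components (default 3).
#' @param r_floor Low-signal exclusion floor on R (default 0.3).
#' @param min_sd Lower clamp on component standard deviations.
#' @param min_callable Minimum callable samples required to fit
#'   (default 10); markers below it are returned with `k = 0` (failed).
#' @return A [cluster_model]; `k = 0` when the marker cannot be fit.
#' @export
fit_clusters <- function(theta, r = NULL, marker = "marker", k_max = 3,
                         r_floor = 0.3, min_sd = 1e-3,
                         min_callable = 10) {
  callable <- !is.na(theta)
  if (!is.null(r)) callable <- callable & !is.na(r) & r >= r_floor
  z <- theta[callable]
  if (length(z) < min_callable)
    return(cluster_model(marker, 0L, numeric(0), numeric(0), numeric(0),
                         numeric(0), numeric(0), character(0)))
  fits <- lapply(seq_len(k_max), function(k) {
    if (length(unique(z)) < k) return(NULL)
    em_gmm_1d(z, k, min_sd = min_sd)
  })
  bics <- vapply(fits, function(f) if (is.null(f)) Inf else f$bic,
                 numeric(1))
  best <- fits[[which.min(bics)]]
  k <- length(best$mu)
  rr <- if (is.null(r)) rep(NA_real_, length(z)) else r[callable]
  post <- posterior_matrix(best$mu, best$sigma, best$w, z)
  assign <- max.col(post)
  mr <- vapply(seq_len(k), function(c_i) {
    sel <- assign == c_i
    c(mean(rr[sel]), stats::sd(rr[sel]))
  }, numeric(2))
  mr[2, is.na(mr[2, ])] <- 0
  cluster_model(marker, k, best$mu, best$sigma, mr[1, ], mr[2, ],
                best$w, label_components(best$mu), best$loglik, best$bic)
}

posterior_matrix <- function(mu, sigma, w, z) {
  n <- length(z)
  dens <- vapply(seq_along(mu), function(c_i)
    w[c_i] * stats::dnorm(z, mu[c_i], sigma[c_i]), numeric(n))
  dens <- matrix(dens, nrow = n)
  tot <- rowSums(dens)
  tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
  dens / tot
}

#' Call genotypes from a fitted cluster model
#'
#' Each sample is assigned its maximum-posterior component's genotype
#' label; a sample is left uncalled (`NC`) when that posterior falls
#' below `posterior_threshold`, when its total signal R is below
#' `r_floor`, or when its intensities are missing.
#'
#' @param model A [cluster_model].
#' @param theta,r Intensity vectors over samples (r optional).
#' @inheritParams fit_clusters
#' @param posterior_threshold Minimum posterior for a call
#'   (default 0.85).
#' @return List with `calls` (character vector `AA/AB/BB/NC`),
#'   `posterior` (max posterior per sample) and `call_frequency`
#'   (= called / total samples).
#' @export
call_genotypes <- function(model, theta, r = NULL,
                           posterior_threshold = 0.85, r_floor = 0.3) {
  n <- length(theta)
  calls <- rep("NC", n)
  post <- rep(NA_real_, n)
  if (model$k > 0) {
    ok <- !is.na(theta)
    if (!is.null(r)) ok <- ok & !is.na(r) & r >= r_floor
    if (any(ok)) {
      pm <- posterior_matrix(model$mean_theta, model$sd_theta,
                             model$weight, theta[ok])
      best <- max.col(pm)
      pb <- pm[cbind(seq_len(nrow(pm)), best)]
      g <- model$label[best]
      g[pb < posterior_threshold] <- "NC"
      calls[ok] <- g
      post[ok] <- pb
    }
  }
  list(calls = calls, posterior = post,
       call_frequency = mean(calls != "NC"))
}

#' Call-frequency class of a marker
#'
#' Bins the fraction of called samples into the four canonical classes:
#' below 0.5 `failed`, 0.5-0.99 `deviant` (major sample deviations,
#' e.g. a segregating null allele), 0.99-1 `near_complete`, and exactly
#' 1 `complete`.
#'
#' @param cf Call frequency in `[0, 1]` (vectorized).
#' @return Character vector of classes.
#' @export
call_frequency_class <- function(cf) {
  if (any(cf < 0 | cf > 1, na.rm = TRUE))
    stop_fmt("call frequency must lie in [0, 1]")
  ifelse(cf < 0.5, "failed",
         ifelse(cf < 0.99, "deviant",
                ifelse(cf < 1, "near_complete", "complete")))
}

#' Cluster separation score
#'
#' An open surrogate for proprietary cluster-quality scores. For each
#' adjacent component pair the Ashman separation
#' `D = |mu2 - mu1| / sqrt(2 (sd1^2 + sd2^2))` is computed and mapped
#' to `[0, 1]` by `D / (D + d0)`; the score S is the minimum over
#' adjacent pairs, so one poorly separated pair drives the score down.
#' `d0` is calibrated so that the canonical diploid-like marker
#' (means 0.05/0.50/0.95, sd 0.03) scores 0.80. Single-component
#' models score 1 by convention.
#'
#' @param model A [cluster_model].
#' @param d0 Calibration constant (default 1.875).
#' @return Separation score S in `[0, 1]`.
#' @export
separation_score <- function(model, d0 = 1.875) {
  if (model$k <= 1) return(1)
  i <- seq_len(model$k - 1)
  gap <- abs(diff(model$mean_theta))
  pooled <- sqrt(2 * (model$sd_theta[i]^2 + model$sd_theta[i + 1]^2))
  d <- ifelse(pooled == 0, ifelse(gap == 0, 0, Inf), gap / pooled)
  s <- ifelse(is.infinite(d), 1, d / (d + d0))
  min(s)
}

#' Classify a marker from its fitted model and calls
#'
#' Applies the classification rules in order: (i) call-frequency class
#' `failed` (or an unfittable marker) gives status `failed`; (ii) a
#' single cluster is `monomorphic` (pattern 1); (iii) a marker whose
#' called inbred samples are at least `intergenomic_het` heterozygous
#' is `intergenomic` (pattern 2, a homeo-SNP reading fixed subgenome
#' differences); (iv) otherwise the marker is `polymorphic` with its
#' pattern set from the separation score S: pattern 3 for S >= 0.60,
#' pattern 4 for 0.30 <= S < 0.60 or whenever a homozygote component
#' sits within 0.1 of theta = 0.5 (the shifted two-locus signature),
#' pattern 5 for 0.20 <= S < 0.30 and pattern 6 below 0.20. Pattern-6
#' markers can optionally be demoted to failed.
#'
#' @param model A [cluster_model].
#' @param calls Character vector of calls over samples.
#' @param inbred Logical vector marking inbred-line samples (used for
#'   the homeo-SNP rule); `NULL` disables rule (iii).
#' @param intergenomic_het Heterozygosity threshold for rule (iii)
#'   (default 0.95).
#' @param demote_pattern6 If `TRUE`, pattern-6 markers get status
#'   `failed` (mirroring manual curation practice).
#' @param d0 Passed to [separation_score()].
#' @return List with status, pattern, call_frequency, cf_class,
#'   separation.
#' @export
classify_marker <- function(model, calls, inbred = NULL,
                            intergenomic_het = 0.95,
                            demote_pattern6 = FALSE, d0 = 1.875) {
  cf <- mean(calls != "NC")
  cf_class <- call_frequency_class(cf)
  s <- if (model$k > 0) separation_score(model, d0) else NA_real_
  res <- function(status, pattern)
    list(status = status, pattern = pattern, call_frequency = cf,
         cf_class = cf_class, separation = s)
  if (model$k == 0 || cf_class == "failed") return(res("failed", "none"))
  # the homeo-SNP check must precede the single-cluster rule: a marker
  # reading two fixed homeologous loci is one cluster at theta ~ 0.5
  if (!is.null(inbred)) {
    ib <- calls[inbred]
    ib <- ib[ib != "NC"]
    if (length(ib) && mean(ib == "AB") >= intergenomic_het)
      return(res("intergenomic", "2"))
  }
  if (model$k == 1) return(res("monomorphic", "1"))
  hom_mid <- any(model$label != "AB" & abs(model$mean_theta - 0.5) < 0.1)
  pattern <- if (s >= 0.30 && hom_mid) "4"
  else if (s >= 0.60) "3"
  else if (s >= 0.30) "4"
  else if (s >= 0.20) "5"
  else "6"
  if (pattern == "6" && demote_pattern6) return(res("failed", "none"))
  res("polymorphic", pattern)
}

#' Genotype and classify every marker of an intensity table
#'
#' Convenience driver: per marker, fit clusters, call genotypes and
#' classify. Thresholds are shared across markers.
#'
#' @param intensity An [intensity_table].
#' @param inbred Logical vector over samples (see [classify_marker()]).
#' @param ... Passed to [fit_clusters()], [call_genotypes()] and
#'   [classify_marker()] (matching arguments are routed by name).
#' @return List with `models` (named list of records holding `model`
#'   and `classification`), `calls` (marker-by-sample matrix) and
#'   `classifications` (data.frame, one row per marker).
#' @export
genotype_markers <- function(intensity, inbred = NULL, r_floor = 0.3,
                             posterior_threshold = 0.85,
                             intergenomic_het = 0.95,
                             demote_pattern6 = FALSE, d0 = 1.875,
                             min_callable = 10) {
  mk <- intensity$markers
  calls <- matrix("NC", length(mk), length(intensity$samples),
                  dimnames = list(mk, intensity$samples))
  models <- vector("list", length(mk))
  names(models) <- mk
  cls <- vector("list", length(mk))
  for (i in seq_along(mk)) {
    th <- intensity$theta[i, ]
    rr <- intensity$r[i, ]
    model <- fit_clusters(th, rr, marker = mk[i], r_floor = r_floor,
                          min_callable = min_callable)
    cg <- call_genotypes(model, th, rr,
                         posterior_threshold = posterior_threshold,
                         r_floor = r_floor)
    calls[i, ] <- cg$calls
    classification <- classify_marker(model, cg$calls, inbred,
                                      intergenomic_het = intergenomic_het,
                                      demote_pattern6 = demote_pattern6,
                                      d0 = d0)
    models[[i]] <- list(model = model, classification = classification)
    cls[[i]] <- data.frame(marker = mk[i],
                           status = classification$status,
                           pattern = classification$pattern,
                           call_frequency = classification$call_frequency,
                           cf_class = classification$cf_class,
                           separation = classification$separation,
                           stringsAsFactors = FALSE)
  }
  list(models = models, calls = calls,
       classifications = do.call(rbind, cls))
}

#' Per-dataset classification summary
#'
#' Tabulates marker classifications by discovery dataset: totals,
#' failed count and percent, monomorphic, intergenomic and polymorphic
#' counts, and the success rate (polymorphic / total, percent), plus a
#' Total row. Percentages are reported to 2 decimals.
#'
#' @param classifications data.frame with columns `dataset` and
#'   `status`, one row per marker. Alternatively precomputed counts can
#'   be supplied as columns `dataset`, `total`, `failed`, `monomorphic`,
#'   `intergenomic`, `polymorphic`.
#' @return data.frame with one row per dataset plus `Total`.
#' @export
classification_summary <- function(classifications) {
  if (all(c("total", "polymorphic") %in% names(classifications))) {
    counts <- classifications
  } else {
    counts <- do.call(rbind, lapply(
      split(classifications, classifications$dataset), function(d)
        data.frame(dataset = d$dataset[1], total = nrow(d),
                   failed = sum(d$status == "failed"),
                   monomorphic = sum(d$status == "monomorphic"),
                   intergenomic = sum(d$status == "intergenomic"),
                   polymorphic = sum(d$status == "polymorphic"))))
  }
  tot <- data.frame(dataset = "Total", total = sum(counts$total),
                    failed = sum(counts$failed),
                    monomorphic = sum(counts$monomorphic),
                    intergenomic = sum(counts$intergenomic),
                    polymorphic = sum(counts$polymorphic))
  out <- rbind(counts, tot)
  pct <- function(num, den) round(ifelse(den > 0, 100 * num / den, 0), 2)
  out$failed_pct <- pct(out$failed, out$total)
  out$success_rate <- pct(out$polymorphic, out$total)
  rownames(out) <- NULL
  out
}
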