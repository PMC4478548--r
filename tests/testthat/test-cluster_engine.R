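canonical_model <- function(sd = 0.03)
  cluster_model("m", 3, c(0.05, 0.5, 0.95), rep(sd, 3), rep(1, 3),
                rep(0.1, 3), rep(1 / 3, 3), c("AA", "AB", "BB"))

test_that("degenerate and well-separated fixtures fit the expected k", {
  m <- fit_clusters(rep(0.5, 40))
  expect_equal(m$k, 1L)
  expect_equal(m$mean_theta, 0.5, tolerance = 1e-6)

  # two clusters, no heterozygote band
  set.seed(30)
  th <- c(rnorm(60, 0.05, 0.02), rnorm(60, 0.95, 0.02))
  m2 <- fit_clusters(pmin(pmax(th, 0), 1))
  expect_equal(m2$k, 2L)
  expect_equal(m2$label, c("AA", "BB"))

  expect_equal(fit_clusters(rep(0.5, 5))$k, 0L)
})

test_that("cluster fitting recovers simulated pattern-3 components", {
  sp <- default_pattern_specs()$p3
  sim <- simulate_marker_intensities(sp, 200, seed = 31)
  m <- fit_clusters(sim$intensity$theta[1, ], sim$intensity$r[1, ])
  expect_equal(m$k, 3L)
  expect_true(all(abs(m$mean_theta - sp$mean_theta) < 0.02))
  expect_false(is.unsorted(m$mean_theta, strictly = TRUE))
  expect_equal(sum(m$weight), 1, tolerance = 1e-6)
})

test_that("fits agree with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  sim <- simulate_marker_intensities(default_pattern_specs()$p3, 300,
                                     seed = 32)
  th <- sim$intensity$theta[1, ]
  m <- fit_clusters(th, sim$intensity$r[1, ])
  ref <- mclust::Mclust(th, G = 3, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(m$mean_theta - sort(unname(ref$parameters$mean)))),
            0.01)
})

test_that("genotype calls use posterior and signal floors", {
  m <- canonical_model()
  cg <- call_genotypes(m, c(0.05, 0.5, 0.95), c(1, 1, 1))
  expect_equal(cg$calls, c("AA", "AB", "BB"))
  expect_true(all(cg$posterior > 0.999))
  expect_equal(cg$call_frequency, 1)

  # all samples under the R floor: call frequency 0
  cg0 <- call_genotypes(m, c(0.05, 0.5, 0.95), c(0.1, 0.05, 0.2))
  expect_true(all(cg0$calls == "NC"))
  expect_equal(cg0$call_frequency, 0)

  # call frequency is non-increasing in the posterior threshold
  set.seed(33)
  th <- runif(200)
  cfs <- vapply(c(0.5, 0.7, 0.85, 0.95, 0.99), function(p)
    call_genotypes(m, th, posterior_threshold = p)$call_frequency,
    numeric(1))
  expect_true(all(diff(cfs) <= 1e-12))
})

test_that("call-frequency classes match the canonical bins", {
  expect_equal(call_frequency_class(c(0, 0.3, 0.5, 0.7, 0.99, 0.995, 1)),
               c("failed", "failed", "deviant", "deviant",
                 "near_complete", "near_complete", "complete"))
  expect_error(call_frequency_class(1.2), "0, 1")
})

test_that("separation score is calibrated, bounded and mirror-invariant", {
  expect_equal(separation_score(canonical_model()), 0.8)
  # two coincident components score zero
  m0 <- cluster_model("m", 2, c(0.5, 0.5 + 1e-12), c(0.03, 0.03),
                      c(1, 1), c(0.1, 0.1), c(0.5, 0.5), c("AA", "BB"))
  expect_equal(separation_score(m0), 0, tolerance = 1e-6)
  # mirror theta -> 1 - theta leaves S unchanged
  m <- cluster_model("m", 3, c(0.1, 0.3, 0.5), c(0.02, 0.05, 0.03),
                     rep(1, 3), rep(0.1, 3), rep(1 / 3, 3),
                     c("AA", "AB", "BB"))
  mm <- cluster_model("m", 3, sort(1 - c(0.1, 0.3, 0.5)),
                      rev(c(0.02, 0.05, 0.03)), rep(1, 3), rep(0.1, 3),
                      rep(1 / 3, 3), c("AA", "AB", "BB"))
  expect_equal(separation_score(m), separation_score(mm))
  # monotone in every pairwise gap
  s_wide <- separation_score(cluster_model("m", 2, c(0.2, 0.8),
                                           c(0.03, 0.03), c(1, 1),
                                           c(0.1, 0.1), c(0.5, 0.5),
                                           c("AA", "BB")))
  s_narrow <- separation_score(cluster_model("m", 2, c(0.35, 0.65),
                                             c(0.03, 0.03), c(1, 1),
                                             c(0.1, 0.1), c(0.5, 0.5),
                                             c("AA", "BB")))
  expect_gt(s_wide, s_narrow)
  expect_equal(separation_score(cluster_model("m", 1, 0.5, 0.01, 1,
                                              0.1, 1, "AB")), 1)
})

test_that("marker classification follows the pattern rules", {
  n <- 100
  inbred <- rep(TRUE, n)
  # monomorphic: single cluster of homozygotes
  m1 <- cluster_model("m", 1, 0.05, 0.02, 1, 0.1, 1, "AA")
  c1 <- classify_marker(m1, rep("AA", n), inbred)
  expect_equal(c(c1$status, c1$pattern), c("monomorphic", "1"))

  # homeo-SNP: every inbred heterozygous, single mid cluster
  m2 <- cluster_model("m", 1, 0.5, 0.02, 1, 0.1, 1, "AB")
  c2 <- classify_marker(m2, rep("AB", n), inbred)
  expect_equal(c(c2$status, c2$pattern), c("intergenomic", "2"))

  # canonical diploid-like marker: pattern 3
  c3 <- classify_marker(canonical_model(),
                        rep(c("AA", "AB", "BB"), length.out = n), inbred)
  expect_equal(c(c3$status, c3$pattern), c("polymorphic", "3"))

  # shifted cluster set with a homozygote at 0.5: pattern 4
  m4 <- cluster_model("m", 3, c(0.10, 0.30, 0.50), rep(0.03, 3),
                      rep(1, 3), rep(0.1, 3), rep(1 / 3, 3),
                      c("AA", "AB", "BB"))
  c4 <- classify_marker(m4, rep(c("AA", "AB", "BB"), length.out = n),
                        inbred)
  expect_equal(c4$pattern, "4")

  # compressed clusters: patterns 5 and 6 by S bins
  m5 <- cluster_model("m", 3, c(0.45, 0.50, 0.55), rep(0.033, 3),
                      rep(1, 3), rep(0.1, 3), rep(1 / 3, 3),
                      c("AA", "AB", "BB"))
  expect_equal(classify_marker(m5, rep(c("AA", "AB", "BB"),
                                       length.out = n))$pattern, "5")
  m6 <- cluster_model("m", 3, c(0.45, 0.50, 0.55), rep(0.06, 3),
                      rep(1, 3), rep(0.1, 3), rep(1 / 3, 3),
                      c("AA", "AB", "BB"))
  c6 <- classify_marker(m6, rep(c("AA", "AB", "BB"), length.out = n))
  expect_equal(c6$pattern, "6")
  c6f <- classify_marker(m6, rep(c("AA", "AB", "BB"), length.out = n),
                         demote_pattern6 = TRUE)
  expect_equal(c(c6f$status, c6f$pattern), c("failed", "none"))

  # mostly-uncalled marker fails regardless of shape
  cf <- classify_marker(canonical_model(),
                        rep(c("AA", "NC", "NC"), length.out = n))
  expect_equal(c(cf$status, cf$pattern), c("failed", "none"))
})

test_that("classification summary reproduces per-dataset success rates", {
  counts <- data.frame(
    dataset = c("CSIRO", "Total_check"),
    total = c(17230, 63058 - 17230),
    failed = c(2048, 7857 - 2048),
    monomorphic = c(4325, 10314 - 4325),
    intergenomic = c(772, 6065 - 772),
    polymorphic = c(10085, 38822 - 10085))
  out <- classification_summary(counts)
  expect_equal(out$success_rate[out$dataset == "CSIRO"], 58.53)
  tot <- out[out$dataset == "Total", ]
  expect_equal(tot$total, 63058)
  expect_equal(tot$success_rate, 61.57)
  expect_equal(tot$failed_pct, 12.46)

  # empty dataset: zero row, no division by zero
  empty <- classification_summary(
    data.frame(dataset = character(0), status = character(0)))
  expect_equal(empty$success_rate[empty$dataset == "Total"], 0)
})
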