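test_that("pattern specs validate their geometry", {
  expect_error(pattern_spec(3, c(0.5, 0.4), 0.03, c("AA", "BB")),
               "strictly increasing")
  expect_error(pattern_spec(2, 0.9, 0.03, "AB"), "near 0.5")
  expect_error(pattern_spec(4, c(0.05, 0.3, 0.9), 0.03,
                            c("AA", "AB", "BB")), "homozygote")
  expect_error(pattern_spec(1, 0.5, 0.03, "AB", null_rate = 1.2),
               "null_rate")
})

test_that("intensity simulation is deterministic and traceable to truth", {
  sp <- default_pattern_specs()$p3
  a <- simulate_marker_intensities(sp, 50, seed = 99)
  b <- simulate_marker_intensities(sp, 50, seed = 99)
  expect_identical(a, b)
  expect_equal(nrow(a$truth), 50)
  expect_true(all(a$truth$genotype %in% c("AA", "AB", "BB")))
  # every sample's theta is near its truth component under low noise
  sp0 <- pattern_spec(3, c(0.05, 0.5, 0.95), 1e-4, c("AA", "AB", "BB"))
  sim <- simulate_marker_intensities(sp0, 100, seed = 1)
  expect_true(all(abs(sim$intensity$theta[1, ] -
                        sp0$mean_theta[sim$truth$component]) < 0.01))
})

test_that("pattern 1 yields a single component; null alleles sit at low R", {
  sp <- default_pattern_specs()$p1
  sim <- simulate_marker_intensities(sp, 80, seed = 3)
  expect_true(all(sim$truth$component == 1))

  spn <- pattern_spec(3, c(0.05, 0.5, 0.95), 0.03, c("AA", "AB", "BB"),
                      null_rate = 0.3)
  simn <- simulate_marker_intensities(spn, 2000, seed = 4)
  expect_true(all(simn$intensity$r[1, simn$truth$null] < 0.3))
  expect_equal(mean(simn$truth$null), 0.3, tolerance = 0.05)
})

test_that("inbred panels follow the MAF law", {
  none <- simulate_inbred_panel(30, 40, maf_law = 0.2,
                                residual_het = 0, seed = 5)
  expect_false(any(none$calls == "AB"))

  mono <- simulate_inbred_panel(30, 40, maf_law = 0,
                                residual_het = 0, seed = 6)
  expect_true(all(mono$calls == "AA"))

  # point mass at 0.5: empirical MAF -> 0.5 within 3 SE
  big <- simulate_inbred_panel(4000, 5, maf_law = 0.5,
                               residual_het = 0, seed = 7)
  p_hat <- rowMeans(big$calls == "BB")
  se <- sqrt(0.25 / 4000)
  expect_true(all(abs(p_hat - 0.5) < 3 * se))

  expect_error(simulate_inbred_panel(5, 5, maf_law = 0.7), "0, 0.5")
})

test_that("F2 simulation reproduces Mendelian and map structure", {
  # 0 cM pair: columns perfectly correlated
  map0 <- genetic_map(c("a", "b"), c("LG1", "LG1"), c(0, 0))
  f0 <- simulate_f2(map0, 60, seed = 8)
  expect_identical(f0$abh["a", ], f0$abh["b", ])

  # single marker segregates 1:2:1 (chi-square 95% acceptance)
  map1 <- genetic_map("a", "LG1", 0)
  f1 <- simulate_f2(map1, 400, seed = 9)
  counts <- table(factor(f1$abh["a", ], levels = c("A", "H", "B")))
  chi2 <- sum((counts - 400 * c(1, 2, 1) / 4)^2 / (400 * c(1, 2, 1) / 4))
  expect_lt(chi2, qchisq(0.95, df = 2))

  # crossovers per individual ~ 2 * sum(r_i) on a 135-cM group
  map2 <- simulate_genome_map(1, 20, 135)
  rs <- kosambi_inv(diff(map2$cm))
  f2 <- simulate_f2(map2, 118, seed = 10)
  expected <- 2 * sum(rs)
  obs <- mean(f2$truth$crossovers)
  se <- sd(f2$truth$crossovers) / sqrt(118)
  expect_lt(abs(obs - expected), 3 * se + 1e-9)
})

test_that("F2 allele and heterozygote frequencies are unbiased without distortion", {
  map <- simulate_genome_map(1, 5, 50)
  for (seed in 1:3) {
    f2 <- simulate_f2(map, 500, seed = seed)
    p_b <- mean((f2$abh == "B") + 0.5 * (f2$abh == "H"))
    se <- sqrt(0.5 * 0.5 / (2 * 500 * 5))
    expect_lt(abs(p_b - 0.5), 4 * se)
    h <- mean(f2$abh == "H")
    expect_lt(abs(h - 0.5), 4 * sqrt(0.25 / (500 * 5)))
  }
})

test_that("viability weights induce the requested distortion", {
  map <- genetic_map("a", "LG1", 0)
  dist <- data.frame(marker = "a", wA = 1, wH = 1, wB = 0.2)
  f2 <- simulate_f2(map, 2000, distortion = dist, seed = 11)
  counts <- table(factor(f2$abh["a", ], levels = c("A", "H", "B")))
  # expected 1 : 2 : 0.2 after viability selection
  expect_gt(counts[["A"]] / counts[["B"]], 3)
  sd_res <- segregation_distortion(f2$abh)
  expect_true(sd_res$per_marker$distorted[1])
})

test_that("genotypes_to_intensities closes the loop and validates labels", {
  sp <- pattern_spec(3, c(0.05, 0.5, 0.95), 1e-5, c("AA", "AB", "BB"))
  genos <- matrix(c("AA", "AB", "BB", "AA"), 2, 2,
                  dimnames = list(c("m1", "m2"), c("s1", "s2")))
  it <- genotypes_to_intensities(genos, sp, seed = 12)
  # sd -> 0 limit: caller recovers genotypes exactly
  res <- genotype_markers(it, min_callable = 2)
  expect_equal(unname(res$calls), unname(genos))

  bad <- matrix("AB", 1, 2, dimnames = list("m1", c("s1", "s2")))
  sp1 <- pattern_spec(1, 0.05, 0.03, "AA")
  expect_error(genotypes_to_intensities(bad, sp1), "no component")
})

test_that("missing-data rate blanks calls to '-'", {
  map <- simulate_genome_map(1, 10, 60)
  f2 <- simulate_f2(map, 100, missing_rate = 0.2, seed = 13)
  expect_equal(mean(f2$abh == "-"), 0.2, tolerance = 0.08)
  expect_false(any(f2$truth$genotypes == "-"))
})
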