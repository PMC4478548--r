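test_that("ABH recoding keeps only opposite-homozygote markers", {
  progeny <- matrix(c("AB", "AA", "BB", "NC",
                      "AA", "AB", "AA", "BB",
                      "AB", "AB", "AB", "AB",
                      "AA", "AA", "BB", "AB"),
                    4, 4, byrow = TRUE,
                    dimnames = list(c("m1", "m2", "m3", "m4"),
                                    sprintf("i%d", 1:4)))
  pa <- c(m1 = "AA", m2 = "AB", m3 = "AA", m4 = "BB")
  pb <- c(m1 = "BB", m2 = "BB", m3 = "AA", m4 = "NC")
  res <- to_abh(pa, pb, progeny)
  expect_equal(rownames(res$abh), "m1")
  expect_equal(unname(res$abh["m1", ]), c("H", "A", "B", "-"))
  ledger <- res$ledger
  expect_equal(ledger$reason[ledger$marker == "m2"], "parent_het")
  expect_equal(ledger$reason[ledger$marker == "m3"],
               "parents_identical")
  expect_equal(ledger$reason[ledger$marker == "m4"], "parent_nc")

  # B is coded relative to parent A even when parent A carries BB
  res2 <- to_abh(c(m1 = "BB"), c(m1 = "AA"),
                 matrix(c("BB", "AA", "AB"), 1, 3,
                        dimnames = list("m1", c("i1", "i2", "i3"))))
  expect_equal(unname(res2$abh["m1", ]), c("A", "B", "H"))
})

test_that("two-point EM matches an independent likelihood grid search", {
  map <- genetic_map(c("a", "b"), c("LG1", "LG1"), c(0, kosambi(0.2)))
  for (seed in 1:5) {
    f2 <- simulate_f2(map, 150, seed = seed)
    est <- estimate_rf(f2$abh["a", ], f2$abh["b", ])
    counts <- table(factor(f2$abh["a", ], levels = c("A", "H", "B")),
                    factor(f2$abh["b", ], levels = c("A", "H", "B")))
    grid <- optimize(function(r) f2_loglik_enum(counts, r),
                     c(1e-6, 0.5 - 1e-6), maximum = TRUE,
                     tol = 1e-9)
    expect_equal(est$rf, grid$maximum, tolerance = 1e-4)
  }
})

test_that("rf estimates behave at the cosegregation and independence limits", {
  map <- genetic_map(c("a", "b"), c("LG1", "LG1"), c(0, 0))
  f2 <- simulate_f2(map, 93, seed = 40)
  est <- estimate_rf(f2$abh["a", ], f2$abh["b", ])
  expect_lt(est$rf, 1e-6)
  expect_gt(est$lod, 3)

  # unlinked markers: r about 0.5, LOD about 0 (3 SE over seeds)
  map2 <- genetic_map(c("a", "b"), c("LG1", "LG2"), c(0, 0))
  rfs <- lods <- numeric(20)
  for (seed in 1:20) {
    f2 <- simulate_f2(map2, 200, seed = seed)
    est <- estimate_rf(f2$abh["a", ], f2$abh["b", ])
    rfs[seed] <- est$rf; lods[seed] <- est$lod
  }
  expect_lt(abs(mean(rfs) - 0.5), 3 * sd(rfs) / sqrt(20) + 0.01)
  expect_lt(mean(lods), 1)

  short <- rep(c("A", "H"), 5)
  expect_true(is.na(estimate_rf(short, short)$rf))
})

test_that("vectorized pairwise rf agrees with the scalar estimator", {
  map <- simulate_genome_map(2, 4, 30)
  f2 <- simulate_f2(map, 120, seed = 41)
  pw <- rf_matrix(f2$abh)
  for (pair in list(c(1, 2), c(3, 7), c(2, 8))) {
    est <- estimate_rf(f2$abh[pair[1], ], f2$abh[pair[2], ])
    expect_equal(pw$rf[pair[1], pair[2]], est$rf, tolerance = 1e-6)
    expect_equal(pw$lod[pair[1], pair[2]], est$lod, tolerance = 1e-4)
  }
  expect_equal(pw$rf, t(pw$rf))
})

test_that("grouping is a transitive closure under the linkage criterion", {
  # chain a-b-c linked only through adjacency joins into one group
  pw <- list(
    rf = matrix(0.1, 3, 3), lod = matrix(0, 3, 3),
    p_value = matrix(1, 3, 3), n_joint = matrix(100, 3, 3))
  for (m in c("lod", "p_value"))
    dimnames(pw[[m]]) <- list(letters[1:3], letters[1:3])
  dimnames(pw$rf) <- dimnames(pw$n_joint) <- dimnames(pw$lod)
  link <- function(i, j) {
    pw$lod[i, j] <<- pw$lod[j, i] <<- 10
    pw$p_value[i, j] <<- pw$p_value[j, i] <<- 1e-8
  }
  link(1, 2); link(2, 3)
  expect_equal(unname(group_markers(pw)), rep(1L, 3))

  # no links at all: singleton groups
  pw$lod[] <- 0; pw$p_value[] <- 1
  expect_equal(sort(unname(group_markers(pw))), 1:3)

  # two simulated chromosomes separate cleanly
  map <- simulate_genome_map(2, 6, 50)
  f2 <- simulate_f2(map, 150, seed = 42)
  grp <- group_markers(rf_matrix(f2$abh))
  expect_equal(length(unique(grp)), 2)
  expect_equal(length(unique(grp[map$marker[map$group == "LG01"]])), 1)
})

test_that("ordering minimizes SARF with an exhaustive oracle", {
  # 3-bin fixture with additive rf: the true order wins
  abh <- abh_fixture(c("AAAABBBBAABB", "AAAABBBBAABA",
                       "AAAABBBAAABA"))
  og <- order_group(abh, min_joint = 5)
  expect_equal(og$order[2], "m2")

  # heuristic equals brute force on random small groups
  set.seed(43)
  for (rep in 1:10) {
    nm <- sample(3:6, 1)
    map <- simulate_genome_map(1, nm, 25)
    f2 <- simulate_f2(map, 80, seed = rep)
    rf <- rf_matrix(f2$abh, min_joint = 5)$rf
    heur <- order_group(f2$abh, method = "heuristic", min_joint = 5)
    expect_equal(heur$sarf, brute_force_sarf(rf), tolerance = 1e-10)
  }

  # two markers: either order, same SARF
  map2 <- genetic_map(c("a", "b"), c("LG1", "LG1"), c(0, 10))
  f2 <- simulate_f2(map2, 100, seed = 44)
  expect_equal(sort(order_group(f2$abh, min_joint = 5)$order),
               c("a", "b"))
})

test_that("a simulated 20-marker group is ordered to high Kendall tau", {
  map <- simulate_genome_map(1, 20, 100)
  f2 <- simulate_f2(map, 500, seed = 45)
  og <- order_group(f2$abh)
  expect_gte(kendall_up_to_reversal(og$order, map$marker), 0.95)
})

test_that("kosambi transform is exact, monotone and convex", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.10), 25 * log(1.2 / 0.8))
  expect_equal(kosambi(0.10), 10.137, tolerance = 5e-4)
  expect_lt(abs(kosambi_inv(kosambi(0.25)) - 0.25), 1e-10)
  r <- seq(0, 0.49, by = 0.01)
  d <- kosambi(r)
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(diff(d)) > 0))
  expect_error(kosambi(0.5), "0, 0.5")
  expect_error(kosambi_inv(-1), ">= 0")
})

test_that("map cleaning removes a shuffled marker and is idempotent", {
  map_truth <- simulate_genome_map(1, 12, 60)
  f2 <- simulate_f2(map_truth, 200, seed = 46)
  abh <- f2$abh
  # corrupt one marker: 15% of its calls flip, creating spurious
  # double crossovers while the marker stays linked to its group
  set.seed(47)
  flip <- sample(200, 30)
  abh["g01m06", flip] <- sample(c("A", "H", "B"), 30, TRUE)
  map <- build_map(abh)
  len0 <- max(map$cm)
  cleaned <- clean_markers(map, abh)
  expect_true("g01m06" %in% cleaned$removed)
  expect_lt(max(cleaned$map$cm), len0)

  again <- clean_markers(cleaned$map, abh)
  expect_equal(length(again$removed), 0)
  expect_equal(again$map$cm, cleaned$map$cm)
})

test_that("crossover counting follows the transition rules", {
  abh <- abh_fixture(c("AAAAA", "AAHAA", "HHAAB", "HHABB", "BB-BB"))
  map <- genetic_map(rownames(abh), "LG1", seq(0, 40, by = 10))
  xo <- count_crossovers(abh, map)
  # per individual down the 5-marker column:
  # i1: A,A,H,H,B -> 2; i2 same -> 2; i3: A,H,A,A,(-) -> 2
  # i4: A,A,A,B,B -> 2; i5: A,A,B,B,B -> 2
  expect_equal(unname(xo$per_group["LG1", ]), c(2, 2, 2, 2, 2))

  const <- abh_fixture(c("AAA", "AAA", "AAA"))
  mapc <- genetic_map(rownames(const), "LG1", c(0, 1, 2))
  expect_true(all(count_crossovers(const, mapc)$per_group == 0))

  # missing middle: A,-,B counts the A<->B transition across the gap
  gap <- abh_fixture(c("A", "-", "B"))
  mapg <- genetic_map(rownames(gap), "LG1", c(0, 1, 2))
  expect_equal(unname(count_crossovers(gap, mapg)$per_group[1, 1]), 2)
})

test_that("recombination bins collapse cosegregating runs", {
  abh <- abh_fixture(c("AAHB", "AAHB", "ABHB", "ABHB", "ABHH"))
  map <- genetic_map(rownames(abh), "LG1", 0:4)
  bins <- recombination_bins(abh, map)
  expect_equal(bins$n_bins, 3)
  expect_equal(bins$markers_per_bin, 5 / 3)

  same <- abh_fixture(c("AHB", "AHB", "AHB"))
  maps <- genetic_map(rownames(same), "LG1", 0:2)
  expect_equal(recombination_bins(same, maps)$n_bins, 1)

  alldiff <- abh_fixture(c("AAB", "ABB", "BBB"))
  mapd <- genetic_map(rownames(alldiff), "LG1", 0:2)
  expect_equal(recombination_bins(alldiff, mapd)$n_bins, 3)

  # missing codes are wildcard-compatible
  wild <- abh_fixture(c("A-HB", "AH-B"))
  mapw <- genetic_map(rownames(wild), "LG1", 0:1)
  expect_equal(recombination_bins(wild, mapw)$n_bins, 1)
})

test_that("segregation distortion reproduces hand-computed chi-squares", {
  mk <- function(nA, nH, nB)
    matrix(c(rep("A", nA), rep("H", nH), rep("B", nB)), 1,
           dimnames = list("m1", NULL))
  perfect <- segregation_distortion(mk(25, 50, 25))
  expect_equal(perfect$per_marker$chi2, 0)
  expect_false(perfect$per_marker$distorted)

  skewed <- segregation_distortion(mk(40, 40, 13))
  exp_counts <- 93 * c(1, 2, 1) / 4
  chi_hand <- sum((c(40, 40, 13) - exp_counts)^2 / exp_counts)
  expect_equal(skewed$per_marker$chi2, chi_hand)
  expect_true(skewed$per_marker$distorted)
  expect_true(skewed$per_marker$het_deficit)
  expect_equal(skewed$per_marker$favored, "A")

  expect_warning(
    segregation_distortion(rbind(mk(10, 20, 10),
                                 matrix("-", 1, 40,
                                        dimnames = list("m2", NULL)))),
    "all-missing")
})

test_that("framework reordering fixes an inverted segment", {
  map_truth <- simulate_genome_map(1, 12, 80)
  f2 <- simulate_f2(map_truth, 200, seed = 48)
  true_order <- map_truth$marker
  # target order with a central inversion
  inv <- true_order
  inv[4:9] <- rev(inv[4:9])
  abh <- f2$abh[inv, ]
  len_inverted <- polymap:::path_length(f2$abh, inv)
  framework <- true_order[seq(1, 12, by = 2)]  # shared subset
  res <- framework_reorder(abh, framework)
  expect_gte(kendall_up_to_reversal(res$order, true_order), 0.95)
  expect_lt(res$length_cm, len_inverted)

  expect_error(framework_reorder(abh, c("g01m01", "zzz")),
               "fewer than 2")
})
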