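test_that("HoC expectations follow the order-statistics argument", {
  expect_equal(hoc_expected_paths(7), 1)
  expect_equal(hoc_expected_paths(1), 1)
  expect_equal(hoc_expected_paths(1, conditioned = TRUE), 1)
  expect_equal(hoc_expected_paths(4, conditioned = TRUE), 4)
  # conditioned sampler agrees: mean over realizations, counts from the
  # brute-force permutation oracle (independent of the DFS)
  counts <- vapply(1:3000, function(s) {
    lsc <- sample_hoc(4, seed = s, condition_antipode_min = TRUE)
    top <- global_maximum(lsc)
    brute_count_accessible(lsc, antipode(top), top)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 4), 3 * sd(counts) / sqrt(3000))
})

test_that("holey closed form matches small-case simulation", {
  expect_equal(holey_expected_paths(4, 1), 24)
  expect_equal(holey_expected_paths(2, 0.5), 1)
  for (p in c(0.4, 0.7)) {
    counts <- vapply(1:4000, function(s) {
      lsc <- sample_holey(4, p = p, seed = s,
                          condition_endpoints_viable = TRUE)
      count_lethal_free_paths(lsc, rep(0, 4), rep(1, 4))
    }, numeric(1))
    expect_lt(abs(mean(counts) - holey_expected_paths(4, p)),
              3 * sd(counts) / sqrt(4000))
  }
  # factorial growth eventually beats p^(L-1) decay
  vals <- vapply(2:25, holey_expected_paths, numeric(1), p = 0.1)
  expect_true(any(diff(vals) > 0))
  expect_gt(vals[24], vals[23])
})

test_that("Gumbel single-path probability is exact", {
  # HoC limit and continuity at c -> 0
  expect_equal(rmf_path_prob_gumbel(5, 0), 1 / 120)
  expect_lt(abs(rmf_path_prob_gumbel(5, 1e-9) - 1 / 120), 1e-10)
  expect_error(rmf_path_prob_gumbel(4, -0.1), "non-negative")
  # bounds and monotonicity in c
  cs <- seq(0, 3, by = 0.25)
  for (L in c(3, 6)) {
    v <- vapply(cs, rmf_path_prob_gumbel, numeric(1), L = L)
    expect_true(all(v >= 1 / factorial(L) - 1e-12 & v <= 1))
    expect_true(all(diff(v) > 0))
  }
  # Monte-Carlo check: fitness along a fixed antipodal path is noise plus
  # a drift of c per step toward the optimum
  set.seed(20)
  for (L in c(3, 4)) for (cc in c(0.3, 1)) {
    n <- 2e5
    X <- matrix(rgumbel(n * L), n, L)
    X <- sweep(X, 2, cc * seq_len(L), "+")
    ok <- rep(TRUE, n)
    for (k in seq_len(L - 1)) ok <- ok & (X[, k + 1] > X[, k])
    p_hat <- mean(ok)
    expect_lt(abs(p_hat - rmf_path_prob_gumbel(L, cc)),
              3 * sqrt(p_hat * (1 - p_hat) / n))
  }
  # exponential decay: successive ratios approach the Gumbel constant
  ratios <- vapply(25:30, function(L)
    rmf_path_prob_gumbel(L + 1, 1) / rmf_path_prob_gumbel(L, 1), numeric(1))
  expect_lt(diff(range(ratios)), 1e-10)
  expect_lt(abs(ratios[1] - (1 - exp(-1))), 1e-6)
})

test_that("first-order RMF expansion is exact as c -> 0", {
  expect_equal(rmf_path_prob_first_order(5, 0), 1 / 120)
  # agrees with the first-order coefficient of the exact Gumbel form
  for (L in c(3, 5)) {
    eps <- 1e-6
    slope_exact <- (rmf_path_prob_gumbel(L, eps) -
                      rmf_path_prob_gumbel(L, 0)) / eps
    slope_first <- (rmf_path_prob_first_order(L, eps, noise = "gumbel") -
                      1 / factorial(L)) / eps
    expect_equal(slope_first, slope_exact, tolerance = 1e-4)
  }
  # a density supplied as a function integrates to the same coefficient
  expect_equal(rmf_path_prob_first_order(4, 0.05, noise = stats::dnorm),
               rmf_path_prob_first_order(4, 0.05, noise = "normal"),
               tolerance = 1e-8)
  # normal-noise Monte-Carlo at small c, where the O(c^2) remainder is
  # within the Monte-Carlo band
  set.seed(21)
  L <- 4; cc <- 0.02; n <- 2e6
  X <- sweep(matrix(rnorm(n * L), n, L), 2, cc * seq_len(L), "+")
  ok <- rep(TRUE, n)
  for (k in seq_len(L - 1)) ok <- ok & (X[, k + 1] > X[, k])
  p_hat <- mean(ok)
  expect_lt(abs(p_hat - rmf_path_prob_first_order(L, cc)),
            3 * sqrt(p_hat * (1 - p_hat) / n) + cc^2)
  # expected path number L! * P grows with L at fixed positive c
  en <- vapply(4:8, function(L)
    factorial(L) * rmf_path_prob_first_order(L, 0.2), numeric(1))
  expect_true(all(diff(en) > 0))
})

test_that("expected VSG counts match enumeration and simulation", {
  m0 <- lethality_model(0, 1, 8)
  expect_equal(expected_vsg(m0, 2), choose(7, 2))
  expect_equal(expected_vsg(m0, 5), choose(7, 5))
  m <- lethality_model(0.0181139, 0.4486, 8)
  expect_equal(expected_vsg(m, 3), 28.1, tolerance = 0.01)
  # enumeration oracle: product over each subgraph's mutation multisets
  for (L in 2:5)
    expect_equal(expected_vsg(m, L),
                 enum_expected_vsg(m$p_common, 8, L, focal = 6))
  # Monte-Carlo: count fully viable focal-free subgraphs under the model
  set.seed(30)
  reps <- 3000
  bm <- fitpaths:::bit_matrix(8)
  subsets <- Filter(function(s) !(6 %in% s), combn(8, 3, simplify = FALSE))
  n_slots <- rowSums(bm[, -6])  # focal never present in these subgraphs
  counts <- vapply(seq_len(reps), function(r) {
    viable <- runif(256) < (1 - 0.02)^n_slots * (1 - 0.45)^bm[, 6]
    sum(vapply(subsets, function(loci) {
      idx <- as.integer(bm[, loci, drop = FALSE] %*% 2^(seq_along(loci) - 1))
      sub_ok <- viable[rowSums(bm[, -loci, drop = FALSE]) == 0]
      all(sub_ok)
    }, logical(1)))
  }, numeric(1))
  m2 <- lethality_model(0.02, 0.45, 8)
  expect_lt(abs(mean(counts) - expected_vsg(m2, 3)),
            3 * sd(counts) / sqrt(reps))
})

test_that("expected lethal-free paths match enumeration and simulation", {
  m0 <- lethality_model(0, 0, 8)
  expect_equal(expected_lethal_free(m0, 4), 24)
  m <- lethality_model(0.0181139, 0.448578, 8)
  # full enumeration over subgraphs and mutation orders
  for (L in 2:4)
    expect_equal(expected_lethal_free(m, L),
                 enum_expected_lethal_free(m$p_common, m$p_focal, 8, L,
                                           focal = 6))
  # monotone decreasing in p_common
  ps <- seq(0, 0.2, by = 0.05)
  vsg_v <- vapply(ps, function(p)
    expected_vsg(lethality_model(p, 0.45), 3), numeric(1))
  lf_v <- vapply(ps, function(p)
    expected_lethal_free(lethality_model(p, 0.45), 3), numeric(1))
  expect_true(all(diff(vsg_v) < 0))
  expect_true(all(diff(lf_v) < 0))
  # Monte-Carlo lethality simulation over random subgraphs
  set.seed(31)
  reps <- 4000
  bm8 <- fitpaths:::bit_matrix(8)
  p_loc <- rep(0.02, 8); p_loc[6] <- 0.45
  v_prob <- apply(bm8, 1, function(g) prod((1 - p_loc)^g))
  subsets <- combn(8, 3, simplify = FALSE)
  counts <- vapply(seq_len(reps), function(r) {
    viable <- runif(256) < v_prob
    loci <- subsets[[(r %% length(subsets)) + 1]]
    f <- as.numeric(viable)
    lsc <- subgraph(landscape(f), loci)
    count_lethal_free_paths(lsc, rep(0, 3), rep(1, 3))
  }, numeric(1))
  m2 <- lethality_model(0.02, 0.45, 8)
  expect_lt(abs(mean(counts) - expected_lethal_free(m2, 3)),
            3 * sd(counts) / sqrt(reps))
})

test_that("Poisson missing-genotype statistics are exact and stable", {
  st <- missed_genotype_stats(G = 256, N_seg = 2500, k = 1)
  expect_equal(st$lambda, 256 * (255 / 256)^2500, tolerance = 1e-12)
  expect_equal(st$lambda, 0.0144, tolerance = 0.01)
  # no sampling: everything is missed
  st0 <- missed_genotype_stats(G = 100, N_seg = 0)
  expect_equal(st0$q, 1)
  expect_equal(st0$lambda, 100)
  # cumulative is monotone in k and reaches 1
  pk <- vapply(0:10, function(k)
    missed_genotype_stats(256, 2500, k)$p_le_k, numeric(1))
  expect_true(all(diff(pk) >= 0))
  expect_equal(pk[11], 1, tolerance = 1e-9)
  # log-space arithmetic survives huge N_seg
  expect_equal(missed_genotype_stats(256, 1e7)$lambda, 0)
})

test_that("heterogeneous detection reduces to Poisson and widens with range", {
  # (near-)homogeneous probabilities: agree with the Poisson mean
  missed <- simulate_heterogeneous_detection(64, 300, lower = 1 / 64 - 1e-9,
                                             upper = 1 / 64 + 1e-9,
                                             reps = 2000, seed = 2)
  lam <- missed_genotype_stats(64, 300)$lambda
  expect_lt(abs(mean(missed) - lam), 3 * sd(missed) / sqrt(2000))
  # wider detectability spread loses more genotypes on average
  narrow <- simulate_heterogeneous_detection(64, 300, lower = 0.8 / 64,
                                             reps = 2000, seed = 3)
  wide <- simulate_heterogeneous_detection(64, 300, lower = 0.1 / 64,
                                           reps = 2000, seed = 3)
  expect_gt(mean(wide), mean(narrow))
  # deep sampling finds everything
  deep <- simulate_heterogeneous_detection(16, 5000, reps = 50, seed = 4)
  expect_true(all(deep == 0))
  expect_error(simulate_heterogeneous_detection(64, 300, lower = 0),
               "degenerate")
})
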