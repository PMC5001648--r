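test_that("pearson correlation obeys its contract and a hand oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 7)
  # textbook product-moment formula
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), manual, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_equal(pearson_correlation(x, 3 * y + 2), pearson_correlation(x, y),
               tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(1, 5L)), "variance")
  expect_error(pearson_correlation(x, y[1:4]))
})

test_that("noise-free reconstruction accuracy is perfect for both arrays", {
  study <- small_study()
  vs <- c(10L, 200L, 500L)
  tbl <- suppressWarnings(
    run_recon_accuracy(study, vs, n_samples = 1500L, sigma_e = 0, seed = 2L))
  r <- tbl$value[tbl$metric == "r_recon"]
  expect_true(all(abs(r - 1) < 1e-6))
})

test_that("recon accuracy favours the on-scalp array at matched seeds", {
  study <- small_study()
  src <- study$sources
  set.seed(10)
  vs <- sample(which(src$depth < 0.04), 12L)
  tbl <- run_recon_accuracy(study, vs, n_samples = 8000L, seed = 6L)
  r <- tbl[tbl$metric == "r_recon", ]
  wide <- reshape(r[, c("array", "vertex", "value")], idvar = "vertex",
                  timevar = "array", direction = "wide")
  expect_true(all(wide$value.opm >= wide$value.squid))
  # determinism of the whole table
  tbl2 <- run_recon_accuracy(study, vs, n_samples = 8000L, seed = 6L)
  expect_identical(tbl, tbl2)
})

test_that("point-spread profiles peak at the source and decay", {
  study <- small_study()
  j <- which.max(colSums(study$leadfields$opm^2))
  tbl <- run_recon_accuracy(study, j, arrays = "opm", n_samples = 8000L,
                            seed = 3L, point_spread = TRUE,
                            n_neighbours = 30L)
  ps <- tbl[tbl$metric == "r_point_spread", ]
  # maximal (within near-tie tolerance at finite N) at zero distance
  expect_gte(ps$value[ps$distance == 0], max(ps$value) - 0.02)
  near <- ps$value[ps$distance > 0 & ps$distance < 0.006]
  far <- ps$value[ps$distance > 0.012]
  expect_gt(mean(near), mean(far))
})

test_that("zero-amplitude interference reproduces single-dipole runs", {
  study <- small_study()
  src <- study$sources
  j <- which(src$hemisphere == "right" & src$depth < 0.035)[2L]
  bn <- run_brain_noise(study, j, "proximity", n_samples = 5000L,
                        int_amplitude = 0, seed = 14L)
  ra <- run_recon_accuracy(study, j, n_samples = 5000L, seed = 14L)
  for (a in c("squid", "opm")) {
    expect_equal(bn$value[bn$metric == "r_recon_with" & bn$array == a],
                 ra$value[ra$metric == "r_recon" & ra$array == a],
                 tolerance = 1e-12)
    expect_equal(bn$value[bn$metric == "r_recon_without" & bn$array == a],
                 ra$value[ra$metric == "r_recon" & ra$array == a],
                 tolerance = 1e-12)
  }
})

test_that("interference leakage decays with shell index and favours on-scalp", {
  study <- small_study()
  src <- study$sources
  set.seed(4)
  ok <- which(src$hemisphere == "right" & src$depth < 0.035)
  vs <- sample(ok, 8L)
  bn <- run_brain_noise(study, vs, "proximity", n_samples = 8000L, seed = 5L)
  ri <- bn[bn$metric == "r_int", ]
  m_sq <- tapply(ri$value[ri$array == "squid"], ri$replicate[ri$array == "squid"],
                 mean)
  m_op <- tapply(ri$value[ri$array == "opm"], ri$replicate[ri$array == "opm"],
                 mean)
  # interference correlation decreases from nearest to farthest shell
  expect_gt(m_sq[1L], m_sq[5L])
  expect_gt(m_op[1L], m_op[5L])
  # interference rejection is better (lower r_int) on-scalp, on average
  expect_lt(mean(m_op), mean(m_sq))
  # with-interference accuracy does not exceed the interference-free one
  rw <- bn[bn$metric == "r_recon_with", ]
  ro <- bn[bn$metric == "r_recon_without", ]
  expect_lt(mean(rw$value), mean(ro$value) + 1e-9)
})

test_that("forward-error sweeps start exact and degrade with error", {
  study <- small_study()
  src <- study$sources
  set.seed(6)
  vs <- sample(which(src$hemisphere == "right"), 6L)
  fe <- run_forward_error(study, vs, fractions = c(0, 0.15, 0.3, 0.45),
                          n_realisations = 2L, n_samples = 6000L, seed = 9L)
  # the fraction-0 column is the unperturbed reconstruction: identical
  # across realisations (no randomness enters at zero error)
  expect_equal(fe$value[fe$fraction == 0 & fe$replicate == 1L],
               fe$value[fe$fraction == 0 & fe$replicate == 2L],
               tolerance = 1e-12)
  # mean correlation decreases as the fractional error grows
  cur <- aggregate(value ~ array + fraction, fe, mean)
  for (a in c("squid", "opm")) {
    v <- cur$value[cur$array == a][order(cur$fraction[cur$array == a])]
    expect_true(all(diff(v) < 0))
  }
})

test_that("resolution runs bin pairs correctly and leak at zero distance", {
  study <- small_study()
  l_mat <- study$leadfields$opm
  # identical locations: leakage is exactly 1 (identical weights)
  cpop <- (5e-9)^2 * 2 * tcrossprod(l_mat[, 5L]) +
    diag((35e-15)^2, nrow(l_mat))
  w <- compute_weights(cpop, l_mat[, 5L], (35e-15)^2, 0.001)
  mom <- list(C = cpop)
  expect_equal(abs(opmbeam:::moment_leak_cor(mom, w$w, w$w)), 1)

  rt <- run_resolution(study, "opm", n_bins = 4L, repeats_per_bin = 3L,
                       n_samples = 5000L, seed = 13L)
  lk <- rt[rt$metric == "leakage", ]
  # realised distances respect their bins
  expect_true(all(lk$distance > (lk$bin - 1L) * 0.002 - 1e-12))
  expect_true(all(lk$distance <= lk$bin * 0.002 + 1e-12))
  expect_true(all(lk$value >= 0 & lk$value <= 1))
  s <- resolution_summary(rt)
  expect_true(all(s$per_bin$n == 3L))
})

test_that("minimum separation search starts at the nearest neighbour", {
  study <- small_study()
  src <- study$sources
  set.seed(8)
  seeds <- sample(which(src$hemisphere == "right" & src$depth < 0.035), 10L)
  tbl <- run_min_separation(study, "opm", seeds)
  ms <- tbl[tbl$metric == "min_separation", ]
  pos <- src$positions
  for (i in seq_along(seeds)) {
    k <- seeds[i]
    d <- sqrt(colSums((t(pos) - pos[k, ])^2))
    nn <- min(d[d > 1e-12])
    expect_gte(ms$value[ms$vertex == k] + 1e-12, nn)
  }
  lk <- tbl[tbl$metric == "leakage_at_min", ]
  expect_true(all(lk$value < 1 / sqrt(2)))
  # population mode is deterministic
  tbl2 <- run_min_separation(study, "opm", seeds)
  expect_identical(tbl, tbl2)
  # sampled mode agrees with the population limit at long N
  t_s <- run_min_separation(study, "opm", seeds[1L], n_samples = 100000L,
                            seed = 3L)
  expect_equal(t_s$value[t_s$metric == "min_separation"],
               ms$value[ms$vertex == seeds[1L]], tolerance = 0.35)
})

test_that("two-source leakage falls off by 60 mm separations", {
  study <- small_study()
  src <- study$sources
  pos <- src$positions
  set.seed(9)
  ks <- sample(which(src$depth < 0.035), 20L)
  leaks <- vapply(ks, function(k) {
    d <- sqrt(colSums((t(pos) - pos[k, ])^2))
    cand <- which(abs(d - 0.058) < 0.002)
    if (length(cand) == 0L) return(NA_real_)
    n <- cand[1L]
    pm <- opmbeam:::two_source_population_metrics(
      study$leadfields$squid[, k],
      study$leadfields$squid[, n, drop = FALSE], 5e-9, 35e-15, 0.001)
    abs(pm$leakage)
  }, numeric(1L))
  expect_lt(mean(leaks, na.rm = TRUE), 0.2)
})
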