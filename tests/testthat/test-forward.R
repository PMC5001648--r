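test_that("sphere fits are exact on spherical scalps and patch-consistent", {
  hs <- sphere_head()
  squid <- build_squid_array(hs, n_channels = 30L)
  sph <- fit_local_spheres(hs, squid, patch_radius = 0.05)
  expect_lt(max(abs(sph$radii - 0.1)), 1e-6)
  expect_lt(max(abs(sph$centres)), 1e-6)
  expect_equal(length(sph$radii), 30L + 29L)

  # infinite patch: all channels share one identical sphere
  sph_all <- fit_local_spheres(hs, squid, patch_radius = Inf)
  expect_true(all(abs(sph_all$radii - sph_all$radii[1L]) < 1e-12))
  expect_true(all(abs(sweep(sph_all$centres, 2L, sph_all$centres[1L, ])) <
                    1e-12))
})

test_that("patch sphere fit matches a brute-force grid search", {
  head <- small_head()
  squid <- small_squid()
  sph <- fit_local_spheres(head, squid, patch_radius = 0.06)
  i <- 1L
  p <- squid$channels[[i]]$coil_positions[1L, ]
  v <- head$scalp$vertices
  sel <- sqrt(colSums((t(v) - p)^2)) <= 0.06
  pts <- v[sel, , drop = FALSE]
  # same squared-radial-residual objective as the fit, with the optimal
  # radius profiled out for each candidate centre
  obj <- function(c3) {
    d2 <- colSums((t(pts) - c3)^2)
    sum((d2 - mean(d2))^2)
  }
  # grid search started away from the fitted solution
  best <- colMeans(pts) - c(0, 0, 0.05)
  for (step in c(0.02, 5e-3, 1e-3, 2e-4, 5e-5)) {
    grid <- expand.grid(x = best[1L] + step * (-3:3),
                        y = best[2L] + step * (-3:3),
                        z = best[3L] + step * (-3:3))
    vals <- apply(grid, 1L, obj)
    best <- as.numeric(grid[which.min(vals), ])
  }
  # brute-force optimum agrees with the algebraic fit within grid resolution
  expect_lt(sqrt(sum((best - sph$centres[i, ])^2)), 3e-4)
})

test_that("Sarvas field obeys the analytic dipole identities", {
  ctr <- c(0.01, -0.02, 0.005)
  r0 <- ctr + c(0.02, 0.03, 0.04)
  rp <- ctr + c(0.05, 0.08, 0.09)

  # radial dipole (1 nAm) is externally silent
  q_rad <- 1e-9 * (r0 - ctr) / sqrt(sum((r0 - ctr)^2))
  expect_lt(max(abs(sarvas_field(r0, q_rad, ctr, rp))), 1e-18)

  # dipole at the sphere centre is silent
  q <- 1e-9 * c(0, 1, 0)
  expect_lt(max(abs(sarvas_field(ctr, q, ctr, rp))), 1e-18)

  # linearity: doubling the moment doubles every component exactly
  b1 <- sarvas_field(r0, q, ctr, rp)
  b2 <- sarvas_field(r0, 2 * q, ctr, rp)
  expect_identical(b2, 2 * b1)

  # radial component equals the free-space dipole field's radial part
  q_tan <- 1e-9 * c(0.3, -0.2, 0.1)
  b <- sarvas_field(r0, q_tan, ctr, rp)[1L, ]
  b_free <- free_dipole_field(q_tan, r0, rp)
  rhat <- (rp - ctr) / sqrt(sum((rp - ctr)^2))
  expect_equal(sum(b * rhat), sum(b_free * rhat),
               tolerance = 1e-12)

  # preconditions
  expect_error(sarvas_field(r0, q, ctr, ctr + c(0.01, 0, 0)), "inside")
  expect_error(sarvas_field(r0, q, ctr, r0), "")
})

test_that("lead fields decompose over coils and respect silence at centres", {
  hs <- sphere_head()
  squid <- build_squid_array(hs, n_channels = 30L)
  sph <- fit_local_spheres(hs, squid)
  src <- make_source_space(hs)
  j <- 11L
  lf <- compute_lead_field(src, j, squid, sph)
  expect_s3_class(lf, "lead_field")

  # gradiometer value = inner-coil magnetometer - outer-coil magnetometer
  ch <- squid$channels[[3L]]
  b_in <- sarvas_field(src$positions[j, ], src$orientations[j, ],
                       sph$centres[3L, ], ch$coil_positions[1L, ])
  b_out <- sarvas_field(src$positions[j, ], src$orientations[j, ],
                        sph$centres[3L, ], ch$coil_positions[2L, ])
  manual <- sum(b_in * ch$coil_orientations[1L, ]) -
    sum(b_out * ch$coil_orientations[2L, ])
  expect_equal(lf$values[3L], manual, tolerance = 1e-14)

  # a dipole at a channel's sphere centre yields zero response
  sub <- list(positions = matrix(sph$centres[3L, ], 1L),
              orientations = matrix(c(1, 0, 0), 1L))
  lz <- leadfield_matrix(sub, squid, sph)
  expect_lt(abs(lz[3L, 1L]), 1e-18)
})

test_that("radial-dipole lead fields vanish on the spherical head", {
  hs <- sphere_head()
  squid <- build_squid_array(hs, n_channels = 30L)
  sph <- fit_local_spheres(hs, squid)
  src <- make_source_space(hs)
  # sphere-mode orientations are exactly radial; all local spheres are the
  # true sphere, so the whole lead-field matrix is numerically zero
  l <- leadfield_matrix(src, squid, sph)
  expect_lt(max(abs(l)), 1e-6 * 1e-13)
})

test_that("magnetometer response decays monotonically with radial standoff", {
  ctr <- c(0, 0, 0)
  r0 <- c(0, 0.05, 0.05)
  q <- 1e-9 * c(1, 0, 0)
  dirs <- (r0 / sqrt(sum(r0^2)))
  ds <- seq(0.09, 0.2, by = 0.01)
  vals <- vapply(ds, function(d) {
    sqrt(sum(sarvas_field(r0, q, ctr, dirs * d)^2))
  }, numeric(1L))
  expect_true(all(diff(vals) < 0))
})

test_that("superficial on-scalp lead fields are about tenfold stronger", {
  study <- small_study()
  src <- study$sources
  shallow <- which(src$depth < quantile(src$depth, 0.1))
  ratio <- vapply(shallow, function(j) {
    max(abs(study$leadfields$opm[, j])) / max(abs(study$leadfields$squid[, j]))
  }, numeric(1L))
  expect_gt(median(ratio), 5)
  expect_lt(median(ratio), 15)
})

test_that("SNR gain map reduces correctly in degenerate configurations", {
  study <- small_study()
  sq <- study$arrays$squid
  sph <- study$spheres$squid
  map_same <- snr_gain_map(study$sources, sq, sq, sph, sph)
  expect_true(all(abs(map_same$ratio - 1) < 1e-12, na.rm = TRUE))

  # single-channel array on a spherical head: f reduces to the absolute
  # per-channel response
  hs <- sphere_head()
  one <- build_squid_array(hs, n_channels = 1L)
  one$reference_channels <- list()
  one$reference_weights <- matrix(0, 1L, 0L)
  srcs <- make_source_space(hs)
  sph1 <- fit_local_spheres(hs, one)
  m1 <- snr_gain_map(srcs, one, one, sph1, sph1)
  l1 <- leadfield_matrix(srcs, one, sph1)
  expect_equal(m1$f_a, abs(as.numeric(l1)) * 1e-9, tolerance = 1e-12)
})

test_that("lead-field CSV export writes fT/nAm values", {
  study <- small_study()
  p <- withr::local_tempfile(fileext = ".csv")
  l <- study$leadfields$opm[, 1:5]
  write_leadfield_csv(l, vapply(study$arrays$opm$channels, `[[`,
                                character(1L), "label"), p)
  back <- read.csv(p)
  expect_equal(back$src00001, unname(l[, 1L]) * 1e6, tolerance = 1e-6)
})
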