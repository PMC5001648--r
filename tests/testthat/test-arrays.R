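test_that("helmet array has the prescribed gradiometer geometry", {
  head <- small_head()
  squid <- small_squid()
  expect_equal(n_channels(squid), 60L)
  expect_equal(length(squid$reference_channels), 29L)
  # two coils 50 mm apart along the shared radial axis
  for (ch in squid$channels[c(1L, 17L, 60L)]) {
    expect_equal(nrow(ch$coil_positions), 2L)
    expect_equal(ch$coil_weights, c(1, -1))
    gap <- sqrt(sum((ch$coil_positions[2L, ] - ch$coil_positions[1L, ])^2))
    expect_equal(gap, 0.05, tolerance = 1e-4 / 0.05)
    expect_equal(ch$coil_orientations[1L, ], ch$coil_orientations[2L, ])
  }
  # minimum inner-coil to scalp distance is the dewar standoff (posterior)
  sp <- t(vapply(squid$channels, function(ch) ch$coil_positions[1L, ],
                 numeric(3L)))
  dmin <- vapply(seq_len(nrow(sp)), function(i) {
    min(sqrt(colSums((t(head$scalp$vertices) - sp[i, ])^2)))
  }, numeric(1L))
  expect_equal(min(dmin), 0.017, tolerance = 0.5e-3 / 0.017)
  # the closest-fitting channel sits at the back of the head
  expect_lt(sp[which.min(dmin), 2L], 0)
  # anterior gap larger than posterior gap
  expect_gt(max(dmin), 0.025)
  # references at least 15 cm from the scalp
  rp <- t(vapply(squid$reference_channels, function(ch) ch$coil_positions[1L, ],
                 numeric(3L)))
  dref <- vapply(seq_len(nrow(rp)), function(i) {
    min(sqrt(colSums((t(head$scalp$vertices) - rp[i, ])^2)))
  }, numeric(1L))
  expect_true(all(dref >= 0.15 - 1e-6))
})

test_that("gradiometer channels cancel a uniform field", {
  squid <- small_squid()
  for (b in list(c(0, 0, 1), c(1, -2, 0.5))) {
    out <- vapply(squid$channels, function(ch) {
      opmbeam:::channel_field_response(ch, function(x) b)
    }, numeric(1L))
    scale <- max(abs(vapply(squid$channels, function(ch) {
      sum(abs(b * ch$coil_orientations[1L, ]))
    }, numeric(1L))), 1)
    expect_lt(max(abs(out)), 1e-12 * scale)
  }
})

test_that("on-scalp array projects the helmet layout to a 4 mm standoff", {
  head <- small_head()
  squid <- small_squid()
  opm <- small_opm()
  expect_equal(n_channels(opm), n_channels(squid))
  op <- t(vapply(opm$channels, function(ch) ch$coil_positions[1L, ],
                 numeric(3L)))
  d <- vapply(seq_len(nrow(op)), function(i) {
    min(sqrt(colSums((t(head$scalp$vertices) - op[i, ])^2)))
  }, numeric(1L))
  expect_true(all(abs(d - 0.004) < 0.5e-3))
  # every on-scalp sensor is closer to the scalp than its helmet parent
  sp <- t(vapply(squid$channels, function(ch) ch$coil_positions[1L, ],
                 numeric(3L)))
  dsq <- vapply(seq_len(nrow(sp)), function(i) {
    min(sqrt(colSums((t(head$scalp$vertices) - sp[i, ])^2)))
  }, numeric(1L))
  expect_true(all(d < dsq))
})

test_that("on-scalp projection is analytic on a spherical head", {
  hs <- sphere_head()
  squid <- build_squid_array(hs, n_channels = 40L)
  opm <- build_opm_array(squid, hs, standoff = 0.004)
  op <- t(vapply(opm$channels, function(ch) ch$coil_positions[1L, ],
                 numeric(3L)))
  expect_lt(max(abs(sqrt(rowSums(op^2)) - 0.104)), 1e-6)
  # gradiometer mode adds an outer coil on the same axis
  opg <- build_opm_array(squid, hs, mode = "gradiometer", baseline = 0.05)
  ch <- opg$channels[[5L]]
  expect_equal(nrow(ch$coil_positions), 2L)
  expect_equal(sqrt(sum((ch$coil_positions[2L, ] - ch$coil_positions[1L, ])^2)),
               0.05, tolerance = 1e-9)
})

test_that("EEG layout arrays have the published channel counts", {
  head <- small_head()
  counts <- c("10-10" = 81L, "10-5" = 329L, "10-2.5" = 1293L)
  for (s in names(counts)) {
    arr <- build_eeg_layout_array(head, s)
    expect_equal(n_channels(arr), unname(counts[s]))
    pos <- t(vapply(arr$channels, function(ch) ch$coil_positions[1L, ],
                    numeric(3L)))
    expect_gt(min(stats::dist(pos)), 0)  # all positions distinct
  }
})

test_that("midline EEG positions sit at the proportional arc fractions", {
  hs <- sphere_head()
  arr <- build_eeg_layout_array(hs, "10-10", standoff = 0.004)
  pos <- t(vapply(arr$channels, function(ch) ch$coil_positions[1L, ],
                  numeric(3L)))
  mid <- which(abs(pos[, 1L]) < 1e-9)
  # arc fraction along nasion -> inion over the vertex on a sphere
  frac <- 0.5 - atan2(pos[mid, 2L], pos[mid, 3L]) / pi
  expect_equal(sort(frac), seq(0.1, 0.9, by = 0.1), tolerance = 0.005)
})

test_that("all array coils lie strictly outside the scalp", {
  head <- small_head()
  semi <- c(0.073, 0.1065, 0.09)
  for (arr in list(small_squid(), small_opm(),
                   build_eeg_layout_array(head, "10-10"))) {
    coils <- do.call(rbind, lapply(arr$channels, `[[`, "coil_positions"))
    expect_true(all(rowSums(sweep(coils, 2L, semi, `/`)^2) > 1))
  }
})

test_that("reference balancing nulls uniform fields and gradients", {
  squid <- small_squid()
  off <- form_reference_weights(squid, "off")
  expect_true(all(off$reference_weights == 0))
  bal <- form_reference_weights(squid, "balance")
  basis <- opmbeam:::balance_basis_fields()
  for (f in basis) {
    raw <- vapply(bal$channels, opmbeam:::channel_field_response,
                  numeric(1L), field_fun = f)
    refs <- vapply(bal$reference_channels, opmbeam:::channel_field_response,
                   numeric(1L), field_fun = f)
    balanced <- raw - as.numeric(bal$reference_weights %*% refs)
    scale <- max(max(abs(refs)), max(abs(raw)), .Machine$double.eps)
    expect_lt(max(abs(balanced)), 1e-10 * scale)
  }
  expect_error(form_reference_weights(small_opm(), "balance"),
               "reference")
})

test_that("balanced channels barely differ from first-order for brain dipoles", {
  head <- small_head()
  squid <- small_squid()
  bal <- form_reference_weights(squid, "balance")
  sph <- fit_local_spheres(head, squid)
  src <- make_source_space(head)
  j <- which.max(src$positions[, 3L])  # superficial vertex under coverage
  l_first <- leadfield_matrix(list(positions = src$positions[j, , drop = FALSE],
                                   orientations = src$orientations[j, ,
                                                                   drop = FALSE]),
                              squid, sph)
  l_bal <- leadfield_matrix(list(positions = src$positions[j, , drop = FALSE],
                                 orientations = src$orientations[j, ,
                                                                 drop = FALSE]),
                            bal, sph)
  rel <- sqrt(sum((l_bal - l_first)^2) / sum(l_first^2))
  expect_lt(rel, 0.05)
})

test_that("arrays round-trip through JSON and CSV", {
  squid <- small_squid()
  bal <- form_reference_weights(squid, "balance")
  p <- withr::local_tempfile(fileext = ".json")
  write_array_json(bal, p)
  back <- read_array_json(p)
  expect_equal(n_channels(back), n_channels(bal))
  expect_equal(back$kind, bal$kind)
  expect_equal(back$reference_weights, bal$reference_weights,
               tolerance = 1e-12)
  expect_equal(back$channels[[7L]]$coil_positions,
               bal$channels[[7L]]$coil_positions)
  pc <- withr::local_tempfile(fileext = ".csv")
  write_array_csv(bal, pc)
  flat <- read.csv(pc)
  expect_equal(nrow(flat), 2L * 60L + 29L)  # 2 coils/channel + 29 refs
})
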