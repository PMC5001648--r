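# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small ellipsoidal head (smooth cortex -> analytic normals)
small_head <- function() fixture("small_head", function() {
  build_synthetic_head(cortex_vertex_target = 600L,
                       scalp_vertex_target = 1000L,
                       cortex_wrinkle_amplitude = 0)
})

# small folded head (default-style wrinkled cortex, dense enough for the
# 6-mm interferer shells)
small_folded_head <- function() fixture("small_folded_head", function() {
  build_synthetic_head(cortex_vertex_target = 5000L,
                       scalp_vertex_target = 1500L)
})

# spherical head (all semi-axes equal; cortex 20 mm inside the scalp)
sphere_head <- function(r = 0.1) fixture("sphere_head", function() {
  build_synthetic_head(ap_length = 2 * r, lr_width = 2 * r, si_height = 2 * r,
                       cortex_vertex_target = 400L,
                       scalp_vertex_target = 400L,
                       cortex_offset = 0.02,
                       cortex_wrinkle_amplitude = 0)
})

small_squid <- function() fixture("small_squid", function() {
  build_squid_array(small_head(), n_channels = 60L)
})

small_opm <- function() fixture("small_opm", function() {
  build_opm_array(small_squid(), small_head())
})

# small end-to-end study on the folded head
small_study <- function() fixture("small_study", function() {
  build_study(head = small_folded_head(),
              squid_args = list(n_channels = 60L))
})

# full-size reference study (used by the acceptance suite)
default_study <- function() fixture("default_study", function() {
  build_study()
})

# free-space current-dipole field (Biot-Savart), oracle for radial components
free_dipole_field <- function(q, r0, rp) {
  a <- rp - r0
  1e-7 * opmbeam:::cross3(q, a)[1, ] / sqrt(sum(a^2))^3
}
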