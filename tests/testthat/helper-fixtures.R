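## Shared fixtures. Expensive objects are built once per test run and
## cached; everything is generated in code (no stored data).

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

ref_params <- function() carotid_params("II")

ref_geometry <- function() {
  .cached("geom", synthetic_carotid_geometry(ref_params()))
}

## reduced protocol for unit tests: coarser quasi-static sampling, two loop
## frequencies, two axial sweeps
tiny_protocol <- function() {
  protocol_spec(qs_dt = 1, dyn_freqs = c(2.5, 10),
                ax_pressures = c(10, 100), ax_dt = 0.05)
}

tiny_dataset <- function() {
  .cached("tiny_ds",
          generate_dataset(ref_geometry(), ref_params(), tiny_protocol()))
}

## same protocol with a purely elastic ground truth
elastic_params <- function() {
  p <- ref_params()
  p$nu_e <- 0
  p$nu_c <- 0
  p
}

elastic_dataset <- function() {
  .cached("elastic_ds",
          generate_dataset(ref_geometry(), elastic_params(), tiny_protocol()))
}

## small deformation history around a reference state, uniform grid
sine_history <- function(n = 201, t_end = 2, amp = 0.05, lam0 = 1,
                         lam_z = 1) {
  tt <- seq(0, t_end, length.out = n)
  l <- lam0 + amp * sin(2 * pi * tt / t_end * 2)
  tibble::tibble(time_s = tt, lam_r = 1 / (l * lam_z), lam_th = l,
                 lam_z = lam_z)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-12)), tol)
}
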