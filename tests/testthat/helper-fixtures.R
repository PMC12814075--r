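# Shared small fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tiny_atlas <- function() {
  memo("tiny_atlas", function() make_atlas(16, c(16, 16, 10), seed = 7))
}

tiny_params <- function(...) {
  sim_params(n_subjects = 1L, n_parcels = 16L, grid_shape = c(16L, 16L, 10L),
             n_volumes = 200L, seed = 7L, ...)
}

tiny_subject <- function() {
  memo("tiny_subject", function() {
    simulate_subject(tiny_atlas(), tiny_params(), seed = 11L)
  })
}

# a bold_run wrapping a given voxel-by-time matrix on a small grid
run_from_matrix <- function(m, grid, tr = 1.6, vox = 3) {
  arr <- array(0, c(grid, ncol(m)))
  arr[] <- m
  aff <- diag(4) * c(vox, vox, vox, 1)
  bold_run(arr, aff, tr)
}
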