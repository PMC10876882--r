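# Shared fixtures, built in code and memoized across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Small, fast cohort used by most unit tests (override any argument).
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_young = 3L, n_old = 3L, tr = 0.38, n_volumes = 500L,
         grid_shape = c(12L, 12L, 8L), n_rois = 42L, seed = 101L),
    list(...))
  do.call(cohort_config, args)
}

small_cohort <- function() memo("small_cohort", generate_cohort(small_config()))

# The full study-scale cohort used by the acceptance suite.
default_cohort <- function()
  memo("default_cohort", generate_cohort(cohort_config(seed = 2024L)))

# A bare voxel_ts on a grid with concentric tissue labels, values supplied.
grid_series <- function(values, tr = 0.38, grid = c(12L, 12L, 8L)) {
  lay <- denoisebench:::cohort_layout(grid, 7L, 42L)
  voxel_ts(values, tr = tr, coords = lay$coords, tissue = lay$tissue,
           roi = lay$roi, network = lay$network, grid_shape = grid)
}

grid_layout <- function(grid = c(12L, 12L, 8L))
  denoisebench:::cohort_layout(grid, 7L, 42L)
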