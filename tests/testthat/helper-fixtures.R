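# Shared fixtures. Phantom cohorts are built once per test session and
# cached, since several files exercise the same cohort.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small two-class phantom with stores; grid/effect/seed configurable.
small_phantom <- function(grid = 12L, n1 = 15L, n0 = 15L, delta = 2,
                          seed = 3L, rescale = TRUE) {
  key <- sprintf("ph_%d_%d_%d_%s_%d_%d", grid, n1, n0, format(delta), seed,
                 rescale)
  cached(key, function() {
    cfg <- phantom_config(grid_shape = rep(grid, 3), n_converters = n1,
                          n_nonconverters = n0, effect_size = delta,
                          seed = seed)
    sim <- simulate_cohort(cfg)
    st <- phantom_stores(sim, cfg, rescale = rescale)
    list(cfg = cfg, sim = sim, st = st)
  })
}

# A subject whose scan at each month is a constant image of that month's
# value, handy for tracing carry-forward logic.
month_coded_subject <- function(months_present, label = 0L,
                                conversion_month = NA_integer_,
                                grid = c(4L, 4L, 4L)) {
  scans <- lapply(months_present, function(m) array(m, dim = grid))
  names(scans) <- as.character(months_present)
  voxhier:::new_subject("s1", label, conversion_month, scans, grid,
                        observed_months = months_present)
}

# A hand-made lrc with identity standardizer.
raw_lrc <- function(weights, bias) {
  voxhier:::new_lrc(weights, bias, center = rep(0, length(weights)),
                    scale = rep(1, length(weights)))
}

# Draw from a seeded RNG without disturbing the session stream.
with_seed_for_tests <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Fixed 6x2 dataset used for the optimizer-oracle comparison.
oracle_dataset <- function() {
  x <- rbind(c(0.1, 0.9), c(0.2, 0.8), c(0.3, 0.7),
             c(0.9, 0.1), c(0.8, 0.2), c(0.7, 0.3))
  list(x = x, y = c(0, 0, 0, 1, 1, 1))
}
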