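# Shared small-scale geometry, memoized so expensive objects (the lead
# field above all) are built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

tiny_array <- function() fixture("array32", function() make_sensor_array(32L, 120, seed = 7L))

tiny_grid <- function() fixture("grid15", function() make_source_grid(spacing = 15, radius = 90))

tiny_atlas <- function() fixture("atlas", region_atlas)

tiny_leadfield <- function() fixture("lf", function() sphere_leadfield(tiny_array(), tiny_grid()))

# One simulated single-source seizure recording reused by several tests.
tiny_seizure <- function() fixture("seizure", function() {
  grid <- tiny_grid()
  vox <- region_voxels(grid, tiny_atlas(), "MFC")[5L]
  spec <- simulation_spec(grid$voxels[vox, , drop = FALSE],
                          matrix(c(2, 6), 1L), duration_s = 8, rate_hz = 1000,
                          snr = 5, seed = 3L)
  sim <- simulate_recording(spec, tiny_array())
  list(sim = sim, vox = vox, spec = spec)
})

# Brute-force two-sided Fisher oracle: enumerate all margin-fixed tables
# via binomial coefficients and sum the probabilities not exceeding the
# observed table's (with the classical 1e-7 relative slack). Written
# independently of the implementation under test (no dhyper, no
# fisher.test).
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0L, k - n); hi <- min(k, m)
  logp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }
  probs <- exp(vapply(lo:hi, logp, numeric(1L)))
  probs <- probs / sum(probs)
  obs <- probs[a - lo + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
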