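test_that("pairwise correlation honours identity, sign flip and the null", {
  set.seed(3)
  x <- rnorm(500)
  R <- pairwise_correlation(rbind(x, x, -x))
  expect_equal(R[1, 2], 1)
  expect_equal(R[1, 3], -1)
  expect_equal(unname(diag(R)), rep(1, 3))
  expect_equal(R, t(R))

  # independent white noise pairs stay near zero
  set.seed(9)
  rr <- replicate(1000, {
    a <- rnorm(10000); b <- rnorm(10000)
    cor(a, b)
  })
  expect_gte(mean(abs(rr) < 0.05), 0.99)
})

test_that("zero-variance virtual sensors are excluded loudly, not NaN'd", {
  sig <- rbind(rnorm(100), rep(1, 100), rnorm(100))
  expect_warning(R <- pairwise_correlation(sig), "zero-variance")
  expect_equal(dim(R), c(2L, 2L))
  expect_false(anyNA(R))
  expect_equal(attr(R, "excluded"), 2L)
})

test_that("correlation matrices are positive semidefinite on full-rank input", {
  set.seed(5)
  R <- pairwise_correlation(matrix(rnorm(20 * 300), 20))
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
})

test_that("the correlation t-statistic follows its closed form", {
  expect_equal(tp_threshold(0, 50), 0)
  expect_equal(tp_threshold(0.5, 6), 0.5 * 2 / sqrt(0.75), tolerance = 1e-12)
  expect_equal(tp_threshold(0.5, 6), 1.1547, tolerance = 1e-4)
  expect_equal(tp_threshold(-0.5, 6), -tp_threshold(0.5, 6))
  expect_identical(tp_threshold(1, 10), Inf)
  expect_identical(tp_threshold(-1, 10), -Inf)
  expect_error(tp_threshold(0.5, 2), "K must be")

  # strictly increasing in |R| for fixed K, and in K for fixed R != 0
  r <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(tp_threshold(r, 30)) > 0))
  ks <- c(5, 10, 50, 200, 1000)
  expect_true(all(diff(vapply(ks, function(k) tp_threshold(0.3, k), numeric(1L))) > 0))
})

test_that("an edge survives exactly when |R| crosses the inverted threshold", {
  K <- 102L
  tcrit <- tp_critical(K, 0.05)
  expect_equal(tcrit, qt(0.975, 100))
  r_star <- uniroot(function(r) tp_threshold(r, K) - tcrit,
                    c(1e-6, 1 - 1e-9), tol = 1e-12)$root
  expect_gte(tp_threshold(r_star + 1e-6, K), tcrit)
  expect_lt(tp_threshold(r_star - 1e-6, K), tcrit)
  # cross-check against the t-distribution quantile through the exact
  # inverse map R = t / sqrt(t^2 + K - 2)
  expect_equal(r_star, tcrit / sqrt(tcrit^2 + K - 2), tolerance = 1e-9)
})

test_that("virtual-sensor selection rules are deterministic and validated", {
  fx <- tiny_seizure()
  lf <- tiny_leadfield()
  src <- beamform(bandpass(fx$sim$recording, c(8, 12))$data[, 2001:6000], lf)
  asi <- accumulate_source_imaging(src)
  nv <- n_voxels(tiny_grid())

  vs <- extract_virtual_sensors(src, asi, rule = "top_fraction", fraction = 0.01)
  expect_length(vs$node_voxels, floor(0.01 * nv))
  expect_true(all(asi$strength[vs$node_voxels] >=
                    sort(asi$strength, decreasing = TRUE)[length(vs$node_voxels)]))

  vs_roi <- extract_virtual_sensors(src, asi, rule = "roi_seeded",
                                    roi = "MFC", atlas = tiny_atlas())
  mfc <- region_voxels(tiny_grid(), tiny_atlas(), "MFC")
  expect_true(all(mfc %in% vs_roi$node_voxels))

  expect_error(extract_virtual_sensors(src, asi, rule = "top_fraction",
                                       fraction = 0), "at least 2")
})

test_that("networks store surviving signed edges once, node order free", {
  set.seed(7)
  n <- 400L
  base <- rnorm(n)
  sig <- rbind(base, base + rnorm(n, sd = 1e-6), rnorm(n))
  vs <- structure(list(node_voxels = c(10L, 20L, 30L), signals = sig,
                       selection_rule = "manual", grid = tiny_grid()),
                  class = "virtual_sensor_set")
  net <- build_network(vs, alpha = 0.05)
  e <- net$edges
  strong <- e[e$node_a == 10L & e$node_b == 20L, ]
  expect_equal(nrow(strong), 1L)
  expect_equal(strong$sign, "positive")
  expect_gt(strong$R, 0.999)
  expect_true(all(e$node_a < e$node_b))
  expect_equal(net$K, n)

  # node relabelling leaves the edge set over voxel ids unchanged
  perm <- c(3L, 1L, 2L)
  vs2 <- structure(list(node_voxels = vs$node_voxels[perm],
                        signals = sig[perm, ], selection_rule = "manual",
                        grid = tiny_grid()), class = "virtual_sensor_set")
  net2 <- build_network(vs2, alpha = 0.05)
  key <- function(x) x$edges[order(x$edges$node_a, x$edges$node_b),
                             c("node_a", "node_b", "R", "sign")]
  expect_equal(key(net2), key(net), tolerance = 1e-12)
})

test_that("null networks keep about alpha of all pairs", {
  set.seed(12)
  n_nodes <- 46L; K <- 500L
  vs <- structure(list(node_voxels = seq_len(n_nodes),
                       signals = matrix(rnorm(n_nodes * K), n_nodes),
                       selection_rule = "null", grid = tiny_grid()),
                  class = "virtual_sensor_set")
  net <- build_network(vs, alpha = 0.05)
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  rate <- nrow(net$edges) / n_pairs
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_pairs))
})

test_that("a coupled source pair is recovered as a network edge", {
  # two sources in the ROI with coupling 0.8 at SNR 5: the reconstructed
  # pair must survive thresholding in nearly every realization
  grid <- tiny_grid(); atlas <- tiny_atlas(); lf <- tiny_leadfield()
  mfc <- region_voxels(grid, atlas, "MFC")
  v <- mfc[c(3L, 40L)]
  hits <- vapply(1:25, function(s) {
    spec <- simulation_spec(grid$voxels[v, ], matrix(c(2, 6), 1L),
                            duration_s = 8, rate_hz = 1000, snr = 5,
                            coupling = 0.8, seed = s)
    sim <- simulate_recording(spec, tiny_array(), keep_signals = FALSE)
    src <- beamform(bandpass(sim$recording, c(1, 40))$data[, 2001:6000], lf)
    asi <- accumulate_source_imaging(src)
    vs <- extract_virtual_sensors(src, asi, rule = "roi_seeded",
                                  roi = "MFC", atlas = atlas)
    net <- build_network(vs)
    # the polarity of a reconstructed source is arbitrary (scalar
    # beamformer orientation sign), so recovery is judged on |R|
    any(net$edges$node_a == v[1L] & net$edges$node_b == v[2L] &
          abs(net$edges$R) > 0.4)
  }, logical(1L))
  expect_gte(mean(hits), 0.9)
})

test_that("ROI summaries count frontal and anterior-posterior edges", {
  grid <- tiny_grid(); atlas <- tiny_atlas()
  labels <- assign_regions(grid, atlas)
  mfc <- which(labels == "MFC")[1:2]
  moc <- which(labels == "MOC")[1L]
  mk_net <- function(edges) {
    structure(list(edges = edges, threshold_Tp = 2, K = 100L, alpha = 0.05,
                   n_nodes = 3L, node_voxels = c(mfc, moc), grid = grid),
              class = "connectivity_network")
  }
  net <- mk_net(data.frame(node_a = mfc[1L], node_b = mfc[2L], R = 0.9,
                           Tp = 10, sign = "positive", stringsAsFactors = FALSE))
  s <- summarize_roi(net, atlas, roi = "MFC")
  expect_equal(s$n_local_frontal_edges, 1L)
  expect_equal(s$n_anterior_posterior_edges, 0L)
  expect_equal(s$n_positive, 1L)

  cross <- mk_net(data.frame(node_a = min(mfc[1L], moc), node_b = max(mfc[1L], moc),
                             R = -0.5, Tp = -6, sign = "negative",
                             stringsAsFactors = FALSE))
  s2 <- summarize_roi(cross, atlas, roi = "MFC")
  expect_equal(s2$n_anterior_posterior_edges, 1L)
  expect_equal(s2$n_local_frontal_edges, 0L)
  expect_equal(s2$n_negative, 1L)

  empty <- mk_net(data.frame(node_a = integer(), node_b = integer(),
                             R = numeric(), Tp = numeric(), sign = character(),
                             stringsAsFactors = FALSE))
  s3 <- summarize_roi(empty, atlas, roi = "MFC")
  expect_equal(s3$n_edges + s3$n_positive + s3$n_negative, 0L)
  expect_error(summarize_roi(net, atlas, roi = "XXX"), "unknown ROI")
})
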