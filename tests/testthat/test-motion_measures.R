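test_that("mesh strain curve: rigid motion, two-point case, oracle equivalence", {
  tr <- rigid_tracks(6, 6, 12, v = c(3, -1))
  mesh <- build_moses_mesh(tr, avg_width = 10, radius_factor = 1.2)
  expect_equal(mesh_strain_curve(tr, mesh), rep(0, 12))
  # two mutual neighbours at distance 10 then 13
  two <- array(0, c(2, 2, 2))
  two[1, , 1] <- c(0, 0); two[2, , 1] <- c(10, 13)
  m2 <- build_radius_graph(two[, 1, ], 11, 1)
  expect_equal(mesh_strain_curve(two, m2), c(0, 3))
  # brute-force double-loop oracle on random tracks
  trr <- simulate_brownian_tracks(100, 8, sigma = 3, seed = 21, span = 150)
  mr <- build_moses_mesh(trr, avg_width = 15, radius_factor = 1.5)
  expect_equal(mesh_strain_curve(trr, mr), oracle_strain_curve(trr, mr),
               tolerance = 1e-9)
})

test_that("multi-channel strain curves are the average of per-channel curves", {
  tr1 <- simulate_brownian_tracks(40, 6, sigma = 2, seed = 1, span = 80)
  tr2 <- simulate_brownian_tracks(40, 6, sigma = 2, seed = 2, span = 80)
  m1 <- build_moses_mesh(tr1, 12, 1.5); m2 <- build_moses_mesh(tr2, 12, 1.5)
  both <- mesh_strain_curve(list(tr1, tr2), list(m1, m2))
  expect_equal(both, (mesh_strain_curve(tr1, m1) + mesh_strain_curve(tr2, m2)) / 2)
})

test_that("strain curve normalization and window semantics", {
  expect_equal(as.numeric(normalize_strain_curve(c(0, 1, 2, 4))),
               c(0, 0.25, 0.5, 1))
  expect_equal(as.numeric(normalize_strain_curve(rep(0, 5))), rep(0, 5))
  # max taken inside the window only; later values may exceed 1
  curve <- c(0, 1, 2, 5)
  nc <- normalize_strain_curve(curve, window = 1:3)
  expect_equal(as.numeric(nc), c(0, 0.5, 1, 2.5))
  expect_error(normalize_strain_curve(curve, window = 1:9),
               class = "motionmesh_invalid_argument")
})

test_that("mesh stability index: plateau scores 1, linear rise scores 0", {
  plateau <- c(seq(0, 1, length.out = 20), rep(1, 30))
  expect_equal(mesh_stability_index(plateau, tail = 10), 1)
  line <- seq(0, 1, length.out = 50)
  expect_equal(mesh_stability_index(line, tail = 10), 0, tolerance = 1e-12)
  expect_equal(mesh_stability_index(rep(0, 50), tail = 10), 1)
  expect_error(mesh_stability_index(line, tail = 50),
               class = "motionmesh_invalid_argument")
  expect_lte(mesh_stability_index(c(rep(0, 40), seq(0, 1, length.out = 10)),
                                  tail = 10), 1)
})

test_that("velocity order: alignment, cancellation, isotropic null", {
  tr <- rigid_tracks(5, 5, 6, v = c(2, 2))
  expect_equal(velocity_order(tr, 3), 1)
  # two equal groups in opposite directions cancel
  opp <- array(0, c(40, 3, 2))
  opp[1:20, , 1] <- outer(rep(0, 20), c(0, 2, 4), "+")
  opp[21:40, , 1] <- outer(rep(50, 20), c(0, -2, -4), "+")
  opp[, , 2] <- 5
  expect_equal(velocity_order(opp, 1), 0)
  # static tracks: undefined (reported missing)
  expect_true(is.na(velocity_order(array(1, c(5, 4, 2)), 2)))
  # isotropic random directions: psi ~ n^(-1/2)
  psis <- vapply(1:5, function(s) {
    set.seed(s)
    th <- runif(1000, 0, 2 * pi)
    tr <- array(0, c(1000, 2, 2))
    tr[, 2, 1] <- cos(th); tr[, 2, 2] <- sin(th)
    velocity_order(tr, 1)
  }, numeric(1))
  expect_true(all(psis < 0.1))
})

test_that("mesh order: 1 under rigid motion, low for independent jitter, bounded", {
  tr <- rigid_tracks(6, 6, 10, v = c(1, 3))
  mesh <- build_moses_mesh(tr, 10, 1.2)
  mo <- mesh_order(tr, mesh)
  expect_equal(mo$series, rep(1, 9))
  expect_equal(mo$mean, 1)
  jit <- simulate_brownian_tracks(400, 12, sigma = 1, seed = 31, span = 200)
  mj <- build_moses_mesh(jit, 10, 1.5)
  moj <- mesh_order(jit, mj)
  expect_lt(moj$mean, 0.2)
  expect_true(all(moj$series >= 0 & moj$series <= 1))
})

test_that("MSD exponents separate ballistic from Brownian motion", {
  bal <- simulate_ballistic_tracks(100, 50, speed = 1, seed = 1)
  expect_equal(fit_msd_exponent(msd(bal), 1:5), 2, tolerance = 0.05)
  brw <- simulate_brownian_tracks(1000, 200, sigma = 1, seed = 0)
  expect_equal(fit_msd_exponent(msd(brw), 1:20), 1, tolerance = 0.1)
  static <- array(3, c(10, 20, 2))
  expect_error(fit_msd_exponent(msd(static)),
               class = "motionmesh_degenerate_input")
})

test_that("RMSD: closed forms for static, ballistic and Brownian tracks", {
  expect_equal(rmsd(array(2, c(5, 10, 2))), rep(0, 10))
  bal <- simulate_ballistic_tracks(50, 30, speed = 1.5, seed = 2)
  expect_equal(rmsd(bal), 1.5 * (0:29), tolerance = 1e-9)
  brw <- simulate_brownian_tracks(2000, 101, sigma = 2, seed = 3)
  r <- rmsd(brw)
  expect_equal(r[101], 2 * sqrt(2 * 100), tolerance = 0.05 * 2 * sqrt(200))
  # normalized variants
  rn <- rmsd(bal, normalize = "max")
  expect_equal(max(rn), 1)
  rf <- rmsd(bal, normalize = "frame", ref_frame = 30)
  expect_equal(rf[30], 1)
})

test_that("spatial correlation: shared series, white noise, exponential recovery", {
  # all superpixels share one velocity series: correlation 1 everywhere
  set.seed(41)
  base <- matrix(rnorm(2 * 60), 60, 2)
  n <- 50
  pos <- cbind(runif(n, 0, 20), runif(n, 0, 20))
  tr <- array(0, c(n, 61, 2))
  tr[, 1, ] <- pos
  for (t in 2:61) tr[, t, ] <- tr[, t - 1, ] + rep(base[t - 1, ], each = n)
  sc <- spatial_correlation(tr, radii = 1:6, avg_width = 1)
  expect_true(all(abs(sc$correlation[is.finite(sc$correlation)] - 1) < 1e-9))
  expect_equal(sc$fit$a, 1, tolerance = 0.05)
  # independent white noise: near-zero correlation
  wn <- simulate_brownian_tracks(60, 121, sigma = 1, seed = 5, span = 20)
  scw <- spatial_correlation(wn, radii = 1:6, avg_width = 1)
  expect_true(all(abs(scw$correlation[is.finite(scw$correlation)]) < 3 / sqrt(120)))
  expect_error(spatial_correlation(array(0, c(4, 1, 2)), 1:3),
               class = "motionmesh_invalid_argument")
})

test_that("spatial correlation recovers a prescribed exponential decay", {
  set.seed(42)
  n <- 120; T_ <- 300
  pos <- cbind(runif(n, 0, 30), runif(n, 0, 30))
  d <- as.matrix(dist(pos))
  a0 <- 0.8; b0 <- 3
  C <- a0 * exp(-d / b0) + diag(1 - a0, n)
  L <- chol(C)
  tr <- array(0, c(n, T_ + 1, 2))
  tr[, 1, ] <- pos
  for (t in seq_len(T_)) {
    step <- cbind(rnorm(n), rnorm(n))
    tr[, t + 1, ] <- tr[, t, ] + crossprod(L, step)
  }
  fit <- spatial_correlation(tr, radii = 1:8, avg_width = 1)$fit
  expect_equal(fit$a, a0, tolerance = 0.1)
  expect_lt(abs(fit$b - b0) / b0, 0.3)
})

test_that("velocity cross-correlation: exact self-correlation and known lag", {
  set.seed(51)
  track <- apply(matrix(rnorm(2 * 80), 80, 2), 2, cumsum)
  v <- velocity_cross_correlation(track, track)
  expect_equal(v$value, 1, tolerance = 1e-12)
  expect_equal(v$lag, 0)
  # a sine wave against its k-frame delayed copy peaks near lag k
  t <- seq_len(120)
  vel <- sin(2 * pi * t / 24)
  k <- 6
  pi_ <- cumsum(c(0, vel)); pj <- cumsum(c(0, c(rep(0, k), vel)[seq_len(120)]))
  vj <- velocity_cross_correlation(cbind(pi_, 0 * pi_), cbind(pj, 0 * pj))
  expect_equal(abs(vj$lag), k)
  expect_gt(vj$value, 0.8)
  expect_error(velocity_cross_correlation(cbind(t, t), cbind(t, t)),
               class = "motionmesh_degenerate_input")  # constant velocity
})

test_that("VCC is bounded by 1 over random pairs and drift-invariant", {
  set.seed(52)
  vals <- vapply(1:50, function(i) {
    a <- apply(matrix(rnorm(2 * 60), 60, 2), 2, cumsum)
    b <- apply(matrix(rnorm(2 * 60), 60, 2), 2, cumsum)
    velocity_cross_correlation(a, b)$value
  }, numeric(1))
  expect_true(all(vals <= 1 + 1e-12))
  a <- apply(matrix(rnorm(2 * 60), 60, 2), 2, cumsum)
  b <- apply(matrix(rnorm(2 * 60), 60, 2), 2, cumsum)
  drift <- cbind(3 * seq_len(60), -2 * seq_len(60))
  expect_equal(velocity_cross_correlation(a, b)$value,
               velocity_cross_correlation(a + drift, b + drift)$value,
               tolerance = 1e-9)
})

test_that("sheet VCC rises when sheets lock into common oscillation", {
  set.seed(53)
  T_ <- 60; n <- 12; closure <- 30
  common <- sin(2 * pi * seq_len(T_) / 10)
  mk <- function(coupled) {
    tr <- array(0, c(n, T_ + 1, 2))
    tr[, 1, 1] <- runif(n, 0, 50); tr[, 1, 2] <- runif(n, 0, 50)
    for (t in seq_len(T_)) {
      v <- rnorm(n, sd = 0.2)
      if (coupled) v <- v + ifelse(t > closure, common[t], 0)
      tr[, t + 1, 1] <- tr[, t, 1] + v
      tr[, t + 1, 2] <- tr[, t, 2] + rnorm(n, sd = 0.2)
    }
    tr
  }
  res <- sheet_vcc(mk(TRUE), mk(TRUE), closure_frame = closure, offset = 5)
  expect_gt(res$after, res$before + 0.2)
  expect_true(res$before >= 0 && res$before <= 1)
  expect_true(res$after >= 0 && res$after <= 1)
  # independent noise: before and after comparable
  res0 <- sheet_vcc(mk(FALSE), mk(FALSE), closure_frame = closure, offset = 5)
  expect_lt(abs(res0$after - res0$before), 0.2)
})

test_that("saliency map: lattice degrees, convergence ridge, oracle counts", {
  g <- make_superpixel_grid(60, 60, 36)
  static <- array(0, c(36, 5, 2))
  static[, , 1] <- g$centroids[, 1]; static[, , 2] <- g$centroids[, 2]
  sal <- motion_saliency_map(static, g, radius_factor = 1.2)
  expect_true(all(sal >= 0))
  interior <- g$labels[25:35, 25:35]
  vals <- unique(as.vector(sal[25:35, 25:35]))
  expect_equal(length(vals), 1)  # constant away from borders
  # brute-force degree count at one frame
  d <- as.matrix(dist(g$centroids)); diag(d) <- Inf
  deg <- rowSums(d <= 1.2 * g$avg_width)
  i <- which(g$labels == g$labels[30, 30], arr.ind = TRUE)
  lab <- g$labels[30, 30]
  expect_equal(sal[30, 30], unname(deg[lab]) / sum(g$labels == lab))
  # tracks converging onto x = 60 produce a ridge there
  set.seed(61)
  n <- 120
  x0 <- c(runif(n / 2, 5, 45), runif(n / 2, 75, 115))
  y0 <- runif(n, 5, 115)
  T_ <- 25
  conv <- array(0, c(n, T_, 2))
  for (t in seq_len(T_)) {
    shiftv <- pmin(3 * (t - 1), abs(60 - x0))
    conv[, t, 1] <- x0 + sign(60 - x0) * shiftv
    conv[, t, 2] <- y0
  }
  g2 <- make_superpixel_grid(120, 120, 144)
  sal2 <- motion_saliency_map(conv, g2, radius_factor = 2)
  col_means <- colMeans(sal2)
  expect_lt(abs(which.max(col_means) - 60), 12)
})

test_that("boundary formation index scores archetypal maps correctly", {
  expect_equal(boundary_formation_index(make_saliency_fixture("constant")), 0)
  expect_equal(boundary_formation_index(make_saliency_fixture("line")), 1)
  two_level <- matrix(1, 40, 40); two_level[, 18:22] <- 10
  expect_equal(boundary_formation_index(two_level), 0.9)
  set.seed(62)
  for (i in 1:5) {
    m <- matrix(runif(400), 20, 20)
    b <- boundary_formation_index(m)
    expect_gte(b, 0); expect_lte(b, 1)
  }
})

test_that("rigid-motion invariance suite across measures", {
  tr <- rigid_tracks(6, 6, 30, v = c(2, 1))
  mesh <- build_moses_mesh(tr, 10, 1.2)
  curve <- mesh_strain_curve(tr, mesh)
  expect_equal(curve, rep(0, 30))
  expect_equal(mesh_stability_index(normalize_strain_curve(curve), tail = 10), 1)
  expect_equal(mesh_order(tr, mesh)$mean, 1)
  expect_equal(fit_msd_exponent(msd(tr), 1:5), 2, tolerance = 1e-9)
})
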