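textured_sheet_frame <- function(H = 80, W = 160, upto = 80, seed = 1) {
  set.seed(seed)
  img <- 0.05 + 0.02 * matrix(runif(H * W), H, W)
  img[, 1:upto] <- 0.6 + 0.4 * matrix(runif(H * upto), H, upto)
  img
}

test_that("k-means sheet segmentation recovers known geometry", {
  img <- textured_sheet_frame()
  mask <- segment_sheet_frame(img, "kmeans", avg_width = 9)
  truth <- matrix(FALSE, 80, 160); truth[, 1:80] <- TRUE
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.9)
  # blank image: empty mask, no error
  expect_false(any(segment_sheet_frame(matrix(0, 40, 40), "kmeans")))
  # at most one connected component survives post-processing
  img2 <- textured_sheet_frame()
  img2[20:60, 120:150] <- 0.9  # second bright object
  m2 <- segment_sheet_frame(img2, "kmeans", avg_width = 9)
  lab <- EBImage::bwlabel(EBImage::Image(m2 * 1))
  expect_lte(max(lab), 1)
})

test_that("entropy-based segmentation separates texture from smooth background", {
  set.seed(2)
  H <- 80; W <- 160
  img <- 0.5 + 0.01 * matrix(rnorm(H * W), H, W)   # smooth background
  img[, 1:80] <- matrix(runif(H * 80), H, 80)      # textured sheet
  mask <- segment_sheet_frame(img, "entropy")
  truth <- matrix(FALSE, H, W); truth[, 1:80] <- TRUE
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.75)
})

test_that("sweepline fronts find the sheet edge strip by strip", {
  mask <- matrix(FALSE, 300, 300); mask[, 1:200] <- TRUE
  fr <- sweepline_fronts(mask, "right", 100)
  expect_true(all(fr[, "x"] == 200))
  expect_lte(nrow(fr), 100)
  # sinusoidal front recovered within strip quantization
  H <- 200
  mask2 <- matrix(FALSE, H, 300)
  edge <- round(150 + 10 * sin(2 * pi * seq_len(H) / 50))
  for (r in seq_len(H)) mask2[r, 1:edge[r]] <- TRUE
  fr2 <- sweepline_fronts(mask2, "right", 100)
  got <- fr2[, "x"]
  want <- vapply(fr2[, "y"], function(y) edge[y], numeric(1))
  expect_lte(max(abs(got - want)), 2)
  expect_equal(nrow(sweepline_fronts(matrix(FALSE, 10, 10), "right")), 0)
})

test_that("gap distance curve tracks approaching fronts", {
  W <- 500; H <- 100
  masks_r <- lapply(0:19, function(t) {
    m <- matrix(FALSE, H, W); m[, 1:(50 + 4 * t)] <- TRUE; m
  })
  masks_g <- lapply(0:19, function(t) {
    m <- matrix(FALSE, H, W); m[, 450:W] <- TRUE; m
  })
  curve <- gap_distance_curve(masks_r, masks_g)
  expect_equal(as.numeric(curve), 400 - 4 * (0:19))
  same <- gap_distance_curve(masks_r[1], masks_r[1])
  expect_equal(as.numeric(same), 0)
})

test_that("gap distance pairing matches brute force on irregular fronts", {
  set.seed(3)
  H <- 120; W <- 240
  edge_r <- round(60 + 15 * sin(seq_len(H) / 9))
  edge_g <- round(180 + 12 * cos(seq_len(H) / 7))
  mr <- matrix(FALSE, H, W); mg <- matrix(FALSE, H, W)
  for (r in seq_len(H)) { mr[r, 1:edge_r[r]] <- TRUE; mg[r, edge_g[r]:W] <- TRUE }
  curve <- gap_distance_curve(list(mr), list(mg), n_strips = 100)
  fr <- sweepline_fronts(mr, "right", 100)
  fg <- sweepline_fronts(mg, "left", 100)
  d <- matrix(0, nrow(fr), nrow(fg))
  for (i in seq_len(nrow(fr))) for (j in seq_len(nrow(fg)))
    d[i, j] <- sqrt(sum((fr[i, ] - fg[j, ])^2))
  manual <- mean(c(apply(d, 1, min), apply(d, 2, min)))
  expect_equal(as.numeric(curve), manual)
})

test_that("gap closure frame is detected on clean and degenerate curves", {
  cv <- c(seq(200, 4, by = -4), rep(2, 50))
  cl <- gap_closure_frame(cv)
  expect_lte(abs(cl - 50), 2)
  expect_true(is.na(gap_closure_frame(rep(10, 40))))
  expect_error(gap_closure_frame(c(3, 2, 1)), class = "motionmesh_invalid_argument")
})

test_that("noisy closure detection stays within 5 frames in 90% of runs", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    cv <- pmax(200 - 4 * (0:99), 2) + rnorm(100, 0, 5)
    cl <- gap_closure_frame(cv)
    !is.na(cl) && abs(cl - 50) <= 5
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("boundary displacement is the normalized post-closure drift", {
  static <- rep(500, 40)
  expect_equal(boundary_displacement(static, 20, 1000), 0)
  drift <- c(rep(500, 20), seq(500, 600, length.out = 20))
  expect_equal(boundary_displacement(drift, 20, 1000), 0.1)
  expect_error(boundary_displacement(static, NA, 1000),
               class = "motionmesh_invalid_argument")
})

test_that("boundary line from masks: overlap collapse and spline fit", {
  H <- 120; W <- 300
  mr <- matrix(FALSE, H, W); mr[, 1:110] <- TRUE
  mg <- matrix(FALSE, H, W); mg[, 100:W] <- TRUE
  line <- boundary_line_from_masks(mr, mg)
  expect_true(all(line$samples$x == 105))
  expect_equal(nrow(line$samples), H)
  # tilted interface: recovered slope matches construction
  mr2 <- matrix(FALSE, H, W); mg2 <- matrix(FALSE, H, W)
  for (r in seq_len(H)) {
    c0 <- 100 + round(0.5 * r)
    mr2[r, 1:(c0 + 8)] <- TRUE
    mg2[r, (c0 - 8):W] <- TRUE
  }
  l2 <- boundary_line_from_masks(mr2, mg2)
  slope <- coef(lm(x ~ y, data = l2$samples))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.05)
  # disjoint masks: no boundary
  m0 <- matrix(FALSE, H, W); m0[, 1:50] <- TRUE
  m1 <- matrix(FALSE, H, W); m1[, 200:W] <- TRUE
  expect_null(boundary_line_from_masks(m0, m1))
})

test_that("boundary line from tracks localizes a stall interface", {
  set.seed(4)
  n <- 60; T_ <- 20
  mk <- function(x_from, x_stall, dir) {
    tr <- array(0, c(n, T_, 2))
    tr[, 1, 1] <- runif(n, x_from[1], x_from[2])
    tr[, 1, 2] <- runif(n, 5, 115)
    for (t in 2:T_) {
      step <- dir * pmin(4, abs(x_stall - tr[, t - 1, 1]))
      tr[, t, 1] <- tr[, t - 1, 1] + step + rnorm(n, sd = 0.05)
      tr[, t, 2] <- tr[, t - 1, 2] + rnorm(n, sd = 0.05)
    }
    tr
  }
  tr_r <- mk(c(10, 60), 95, +1)
  tr_g <- mk(c(140, 190), 105, -1)
  line <- boundary_line_from_tracks(tr_r, tr_g, t = T_, avg_width = 10)
  expect_false(is.null(line))
  expect_lt(abs(mean(line$samples$x) - 100), 8)
  # static tracks produce no candidates
  expect_null(boundary_line_from_tracks(array(1, c(5, 10, 2)),
                                        array(9, c(5, 10, 2)), 10, 2))
})

test_that("density filter removes isolated spurious matches", {
  set.seed(5)
  n <- 40; T_ <- 16
  tr_r <- array(0, c(n + 1, T_, 2)); tr_g <- array(0, c(n + 1, T_, 2))
  tr_r[seq_len(n), 1, 1] <- runif(n, 80, 90)
  tr_g[seq_len(n), 1, 1] <- runif(n, 92, 102)
  tr_r[seq_len(n), 1, 2] <- tr_g[seq_len(n), 1, 2] <- runif(n, 10, 110)
  # one spurious matched red/green pair far from the interface
  tr_r[n + 1, 1, ] <- c(300, 300); tr_g[n + 1, 1, ] <- c(302, 300)
  for (t in 2:T_) {
    tr_r[, t, ] <- tr_r[, t - 1, ] + cbind(rnorm(n + 1, 2, 0.1), 0)
    tr_g[, t, ] <- tr_g[, t - 1, ] + cbind(rnorm(n + 1, 2, 0.1), 0)
  }
  line <- boundary_line_from_tracks(tr_r, tr_g, t = T_, avg_width = 5)
  expect_false(is.null(line))
  expect_true(all(line$samples$y < 200))  # the outlier row was filtered out
})

test_that("infiltration fraction counts points beyond the line", {
  line <- boundary_line_from_masks(
    {m <- matrix(FALSE, 50, 120); m[, 1:52] <- TRUE; m},
    {m <- matrix(FALSE, 50, 120); m[, 48:120] <- TRUE; m})  # line at x = 50
  left <- cbind(runif(20, 0, 40), runif(20, 1, 50))
  right <- cbind(runif(20, 60, 100), runif(20, 1, 50))
  expect_equal(infiltration_fraction(left, line, "right"), 0)
  expect_equal(infiltration_fraction(right, line, "right"), 1)
  expect_equal(infiltration_fraction(rbind(left, right), line, "right"), 0.5)
  on_line <- cbind(rep(50, 5), 1:5)
  expect_equal(infiltration_fraction(on_line, line, "right"), 0)
  expect_error(infiltration_fraction(left[0, ], line, "right"),
               class = "motionmesh_degenerate_input")
})

test_that("boundary shape index: straight, semicircular, perturbed and rigid-moved lines", {
  straight <- boundary_line_from_masks(
    {m <- matrix(FALSE, 100, 60); m[, 1:32] <- TRUE; m},
    {m <- matrix(FALSE, 100, 60); m[, 28:60] <- TRUE; m})
  expect_equal(boundary_shape_index(straight), 1)
  y <- seq(-50, 50, length.out = 400)
  arc <- list(samples = data.frame(y = y, x = sqrt(50^2 - y^2)), fun = NULL)
  class(arc) <- "boundary_line"
  expect_equal(boundary_shape_index(arc), pi / 2, tolerance = 0.01)
  # rigid rotation/translation leaves the index unchanged
  th <- 0.2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts <- t(R %*% t(as.matrix(arc$samples[, c("x", "y")]))) + 10
  rot <- list(samples = data.frame(y = pts[, 2], x = pts[, 1]), fun = NULL)
  class(rot) <- "boundary_line"
  expect_equal(boundary_shape_index(rot), boundary_shape_index(arc),
               tolerance = 1e-9)
  # sinusoidal perturbation strictly increases arc length
  wavy <- list(samples = data.frame(y = y, x = 20 + 5 * sin(y / 4)), fun = NULL)
  class(wavy) <- "boundary_line"
  flat <- list(samples = data.frame(y = y, x = rep(20, length(y))), fun = NULL)
  class(flat) <- "boundary_line"
  expect_gt(boundary_shape_index(wavy), boundary_shape_index(flat))
  single <- list(samples = data.frame(y = 1, x = 1), fun = NULL)
  class(single) <- "boundary_line"
  expect_error(boundary_shape_index(single), class = "motionmesh_degenerate_input")
})

test_that("intermixing coefficients measure boundary and saliency area fractions", {
  mask <- matrix(FALSE, 100, 100); mask[, 50] <- TRUE  # 1% strip
  sal <- make_saliency_fixture("line", size = c(100, 100))
  ic <- intermixing_coefficients(mask, sal)
  expect_equal(ic$image, 0.01)
  expect_gte(ic$moses, 0); expect_lte(ic$moses, 1)
  const <- intermixing_coefficients(mask, make_saliency_fixture("constant"))
  expect_equal(const$moses, 0)
})

test_that("velocity kymographs collapse motion to x-profiles", {
  tr <- rigid_tracks(10, 6, 8, v = c(3, 0), spacing = 12)
  ky <- velocity_kymograph(tr, width = 130)
  expect_equal(ncol(ky), 2 * 10)  # auto: 2 x unique frame-0 x values
  expect_true(all(ky[is.finite(ky)] == 3))
  # opposing sheets: +v on the left half, -v on the right half
  n <- 40
  opp <- array(0, c(2 * n, 5, 2))
  opp[, 1, 1] <- c(runif(n, 1, 90), runif(n, 110, 199))
  opp[, 1, 2] <- runif(2 * n, 1, 99)
  for (t in 2:5) {
    opp[, t, ] <- opp[, t - 1, ]
    opp[1:n, t, 1] <- opp[1:n, t, 1] + 2
    opp[(n + 1):(2 * n), t, 1] <- opp[(n + 1):(2 * n), t, 1] - 2
  }
  ky2 <- velocity_kymograph(opp, n_bins = 20, width = 200)
  x <- attr(ky2, "x")
  expect_true(all(ky2[, x < 90][is.finite(ky2[, x < 90])] == 2))
  expect_true(all(ky2[, x > 110][is.finite(ky2[, x > 110])] == -2))
  # flow-field source: uniform rightward field
  fl <- array(0, c(30, 40, 2)); fl[, , 1] <- 1.5
  kf <- velocity_kymograph(list(fl, fl), n_bins = 10)
  expect_true(all(kf == 1.5))
})
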