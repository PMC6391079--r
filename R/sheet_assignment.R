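# Motion-based assignment of superpixels to migrating sheets. Uses motion
# information only: early movement thresholding, spatial connectivity,
# joint de-duplication between channels, dynamic activation, and freezing
# of unused tracks so the track count is conserved.

#' Superpixels that move within the early frames
#'
#' Returns the indices whose cumulative path length over the first
#' `n_early_frames` frame pairs exceeds `dist_thresh`.
#'
#' @param tracks `(n, T, 2)` track array.
#' @param n_early_frames early window length in frame pairs (default 2).
#' @param dist_thresh path-length threshold in pixels.
#' @return Integer index vector.
#' @export
threshold_moving_superpixels <- function(tracks, n_early_frames = 2,
                                         dist_thresh) {
  T_ <- dim(tracks)[2]
  if (n_early_frames < 1 || n_early_frames >= T_)
    stop_invalid("n_early_frames must be in [1, n_frames - 1]")
  steps <- tracks[, 2:(n_early_frames + 1), , drop = FALSE] -
    tracks[, 1:n_early_frames, , drop = FALSE]
  path <- rowSums(sqrt(steps[, , 1, drop = FALSE]^2 +
                         steps[, , 2, drop = FALSE]^2), dims = 1)
  which(path > dist_thresh)
}

#' Largest spatially connected component of a superpixel set
#'
#' Builds a radius graph on the frame-0 centroids of the given indices and
#' keeps the largest connected component (ties broken by the component
#' containing the smallest index), approximating the area covered by one
#' contiguous sheet.
#'
#' @param indices candidate superpixel indices.
#' @param centroids `n x 2` frame-0 centroid matrix (full set; rows are
#'   addressed by `indices`).
#' @param radius connection cutoff in pixels (1.2 average superpixel
#'   widths in the standard pipeline).
#' @return Subset of `indices` forming the largest component (empty input
#'   gives an empty result).
#' @export
largest_motion_component <- function(indices, centroids, radius) {
  if (radius <= 0) stop_invalid("radius must be > 0")
  if (!length(indices)) return(integer(0))
  pos <- centroids[indices, , drop = FALSE]
  d <- pdist2(pos)
  adj <- d <= radius
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {  # tie: component holding the smallest index
    first_member <- vapply(best, function(cid) min(which(comp$membership == cid)),
                           integer(1))
    best <- best[which.min(first_member)]
  }
  sort(indices[comp$membership == best])
}

#' Sheet-assignment configuration
#'
#' @param n_early_frames early-movement window, frame pairs.
#' @param dist_thresh_factor movement threshold as a fraction of the
#'   average superpixel width (over the early window).
#' @param radius_factor connectivity radius in average superpixel widths.
#' @param coverage_cutoff frame-0 area fraction above which joint
#'   red/green de-duplication is applied (conservative default 0.70 for a
#'   50:50 plating).
#' @param dynamic_activation run per-frame activation of superpixels
#'   entering the kept area (fixed-mode tracking only).
#' @param refilter re-run movement thresholding and largest-component
#'   selection after activation, over the whole video.
#' @return A named list.
#' @export
assignment_params <- function(n_early_frames = 2, dist_thresh_factor = 0.1,
                              radius_factor = 1.2, coverage_cutoff = 0.70,
                              dynamic_activation = TRUE, refilter = TRUE) {
  if (coverage_cutoff <= 0 || coverage_cutoff > 1)
    stop_invalid("coverage_cutoff must be in (0, 1]")
  list(n_early_frames = n_early_frames,
       dist_thresh_factor = dist_thresh_factor,
       radius_factor = radius_factor, coverage_cutoff = coverage_cutoff,
       dynamic_activation = dynamic_activation, refilter = refilter)
}

.early_path_length <- function(tracks, n_early) {
  steps <- tracks[, 2:(n_early + 1), , drop = FALSE] -
    tracks[, 1:n_early, , drop = FALSE]
  rowSums(sqrt(steps[, , 1, drop = FALSE]^2 + steps[, , 2, drop = FALSE]^2),
          dims = 1)
}

# per-frame activation: a non-kept superpixel joins when its centroid lies
# inside the union of the translated footprints of the currently kept set
.activate_superpixels <- function(tracks, kept, grid, fp) {
  H <- grid$height; W <- grid$width
  n <- dim(tracks)[1]; T_ <- dim(tracks)[2]
  kept_set <- kept
  for (t in seq_len(T_)) {
    if (length(kept_set) == n) break
    mask <- matrix(FALSE, H, W)
    for (i in kept_set) {
      off <- round(tracks[i, t, ] - tracks[i, 1, ])
      rr <- fp$rows[[i]] + off[2]
      cc <- fp$cols[[i]] + off[1]
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      if (any(ok)) mask[cbind(rr[ok], cc[ok])] <- TRUE
    }
    cand <- setdiff(seq_len(n), kept_set)
    x <- round(tracks[cand, t, 1]); y <- round(tracks[cand, t, 2])
    inb <- x >= 1 & x <= W & y >= 1 & y <= H
    hit <- logical(length(cand))
    hit[inb] <- mask[cbind(y[inb], x[inb])]
    kept_set <- c(kept_set, cand[hit])
  }
  sort(kept_set)
}

#' Assign superpixels to two migrating sheets from motion alone
#'
#' Runs the motion-feature sheet segmentation per channel: early-movement
#' thresholding and largest spatial component (steps 1-2); if either
#' channel claims more than `coverage_cutoff` of the frame-0 area, joint
#' de-duplication awards a superpixel claimed by both channels to the one
#' in which it moves farther over the early window (step 3); per-frame
#' dynamic activation adds superpixels entering the kept area (step 4);
#' the moving/connected filter is re-run over the whole video (step 5);
#' and all non-kept tracks are reset to their frame-0 centroid for every
#' frame so the output track count equals the input count (step 6).
#'
#' @param tracks_red,tracks_green `(n, T, 2)` track arrays on the same
#'   grid.
#' @param grid the shared [make_superpixel_grid()] partition.
#' @param params an [assignment_params()] list.
#' @return A `sheet_assignment`: list with `kept` and `frozen` index sets
#'   per channel, `coverage_fraction` per channel, and the reassigned
#'   `tracks` (same shapes as the input).
#' @export
assign_sheet_superpixels <- function(tracks_red, tracks_green, grid,
                                     params = assignment_params()) {
  if (!identical(dim(tracks_red), dim(tracks_green)))
    stop_invalid("channels must be tracked on the same grid")
  fp <- .grid_footprints(grid)
  area <- lengths(fp$rows)
  total_area <- grid$height * grid$width
  thresh <- params$dist_thresh_factor * grid$avg_width
  radius <- params$radius_factor * grid$avg_width
  T_ <- dim(tracks_red)[2]

  steps12 <- function(tracks) {
    moving <- threshold_moving_superpixels(tracks, params$n_early_frames, thresh)
    largest_motion_component(moving, grid$centroids, radius)
  }
  kept <- list(red = steps12(tracks_red), green = steps12(tracks_green))
  coverage <- vapply(kept, function(k) sum(area[k]) / total_area, numeric(1))

  if (any(coverage > params$coverage_cutoff)) {  # step 3: joint filtering
    contested <- intersect(kept$red, kept$green)
    if (length(contested)) {
      er <- .early_path_length(tracks_red, params$n_early_frames)[contested]
      eg <- .early_path_length(tracks_green, params$n_early_frames)[contested]
      kept$red <- setdiff(kept$red, contested[eg > er])
      kept$green <- setdiff(kept$green, contested[er >= eg])
    }
  }

  trk <- list(red = tracks_red, green = tracks_green)
  if (isTRUE(params$dynamic_activation)) {
    kept <- lapply(names(kept), function(ch)
      .activate_superpixels(trk[[ch]], kept[[ch]], grid, fp))
    names(kept) <- c("red", "green")
  }
  if (isTRUE(params$refilter)) {  # step 5 over the whole video
    rate <- thresh / params$n_early_frames
    kept <- lapply(names(kept), function(ch) {
      tr <- trk[[ch]]
      moving <- threshold_moving_superpixels(tr, T_ - 1, rate * (T_ - 1))
      largest_motion_component(intersect(kept[[ch]], moving),
                               grid$centroids, radius)
    })
    names(kept) <- c("red", "green")
  }

  out_tracks <- lapply(names(trk), function(ch) {
    tr <- trk[[ch]]
    frozen <- setdiff(seq_len(dim(tr)[1]), kept[[ch]])
    for (i in frozen) {  # step 6: constant tracks, count conserved
      tr[i, , 1] <- tr[i, 1, 1]
      tr[i, , 2] <- tr[i, 1, 2]
    }
    tr
  })
  names(out_tracks) <- c("red", "green")
  structure(list(kept = kept,
                 frozen = list(red = setdiff(seq_len(grid$n), kept$red),
                               green = setdiff(seq_len(grid$n), kept$green)),
                 coverage_fraction = vapply(kept, function(k)
                   sum(area[k]) / total_area, numeric(1)),
                 tracks = out_tracks),
            class = "sheet_assignment")
}
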