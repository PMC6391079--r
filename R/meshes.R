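# Graph construction over superpixels: the frozen frame-0 "MOSES" mesh,
# per-frame radius-neighbour graphs and kNN graphs. Adjacency is stored as
# a list of integer neighbour vectors plus an (m, 2) edge matrix.

.as_mesh <- function(nb, type, radius_factor = NA_real_, avg_width = NA_real_,
                     k = NA_integer_) {
  n <- length(nb)
  deg <- lengths(nb)
  ei <- rep.int(seq_len(n), deg)
  ej <- unlist(nb, use.names = FALSE)
  keep <- ei < ej
  structure(list(neighbours = nb,
                 edges = cbind(i = ei[keep], j = ej[keep]),
                 n = n, type = type, radius_factor = radius_factor,
                 avg_width = avg_width, k = k),
            class = "mesh")
}

#' @export
print.mesh <- function(x, ...) {
  cat(sprintf("mesh (%s): %d nodes, %d edges\n", x$type, x$n, nrow(x$edges)))
  invisible(x)
}

.frame_positions <- function(tracks, t) {
  matrix(tracks[, t, ], ncol = 2)
}

.radius_neighbours <- function(positions, radius) {
  d <- pdist2(positions)
  diag(d) <- Inf
  # inclusive cutoff so exact-distance ties are deterministic
  apply(d <= radius, 1, which, simplify = FALSE)
}

#' Build the frozen frame-0 (MOSES) mesh over superpixel tracks
#'
#' Connects every pair of superpixels whose frame-0 centroids lie within
#' `radius_factor` average superpixel widths of each other (Euclidean,
#' inclusive cutoff). The adjacency is frozen for the whole video, so mesh
#' statistics measure distortion relative to the initial geometry.
#'
#' @param tracks `(n, T, 2)` track array (frame-0 positions are used) or an
#'   `n x 2` matrix of frame-0 centroids.
#' @param avg_width average superpixel width in pixels (from the grid).
#' @param radius_factor cutoff in multiples of `avg_width`; 1.2 links the
#'   4-connected lattice neighbours of a regular grid.
#' @return A `mesh` object with neighbour lists and an edge matrix.
#' @export
build_moses_mesh <- function(tracks, avg_width, radius_factor = 1.2) {
  if (radius_factor <= 0) stop_invalid("radius_factor must be > 0")
  pos <- if (is_track_array(tracks)) .frame_positions(tracks, 1) else
    as.matrix(tracks)
  nb <- .radius_neighbours(pos, radius_factor * avg_width)
  .as_mesh(nb, "moses", radius_factor, avg_width)
}

#' Radius-neighbour graph at an instant
#'
#' Symmetric adjacency linking all point pairs within `radius_factor *
#' avg_width` (inclusive) of each other at their current positions; the
#' per-frame mesh behind motion saliency maps.
#'
#' @param positions `n x 2` matrix of current `(x, y)` coordinates.
#' @param radius_factor cutoff in multiples of `avg_width` (5.0 is the
#'   boundary-formation setting).
#' @param avg_width scale unit in pixels (1 makes the cutoff absolute).
#' @return A `mesh` object.
#' @export
build_radius_graph <- function(positions, radius_factor = 5, avg_width = 1) {
  if (radius_factor <= 0) stop_invalid("radius_factor must be > 0")
  nb <- .radius_neighbours(as.matrix(positions), radius_factor * avg_width)
  .as_mesh(nb, "radius", radius_factor, avg_width)
}

#' k-nearest-neighbour graph
#'
#' Links each node to its `k` nearest others (ties broken by lower index),
#' then symmetrizes by union.
#'
#' @param positions `n x 2` coordinate matrix.
#' @param k neighbour count, `1 <= k < n`.
#' @return A `mesh` object.
#' @export
build_knn_graph <- function(positions, k) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (k < 1 || k >= n) stop_invalid("k must satisfy 1 <= k < n")
  d <- pdist2(positions)
  diag(d) <- Inf
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    # order() is stable, so equal distances resolve to the lower index
    nb[[i]] <- sort(order(d[i, ])[seq_len(k)])
  }
  # symmetrize by union
  for (i in seq_len(n)) for (j in nb[[i]])
    if (!(i %in% nb[[j]])) nb[[j]] <- sort(c(nb[[j]], i))
  .as_mesh(nb, "knn", k = as.integer(k))
}

#' Resultant mesh strain vectors at a frame
#'
#' For superpixel i with mesh neighbours N_i, the strain vector at frame t
#' is the summed frame-to-frame change of its relative displacement to each
#' neighbour, `sum_j [(r_i(t) - r_j(t)) - (r_i(t-1) - r_j(t-1))]`. It is
#' invariant under global translation and vanishes exactly under rigid
#' collective motion, which makes it a temporally stable direction field
#' for the mesh order parameter. Isolated superpixels get a zero vector.
#'
#' @param tracks `(n, T, 2)` track array.
#' @param mesh a `mesh` built on the same tracks.
#' @param t frame index, `t >= 2` (1-based; the vector uses frames t-1, t).
#' @return `n x 2` matrix of strain vectors, pixels.
#' @export
mesh_strain_vector <- function(tracks, mesh, t) {
  if (t < 2 || t > dim(tracks)[2]) stop_invalid("t must be in [2, n_frames]")
  v <- .frame_positions(tracks, t) - .frame_positions(tracks, t - 1)
  deg <- lengths(mesh$neighbours)
  sum_nb <- t(vapply(mesh$neighbours, function(js) {
    if (!length(js)) c(0, 0) else colSums(v[js, , drop = FALSE])
  }, numeric(2)))
  out <- v * deg - sum_nb
  out[deg == 0L, ] <- 0
  out
}
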