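# Frame-difference division detection in 4D movies. A movie is a T-ordered
# stack of Z-slices of Y-by-X intensity frames. Divisions produce localised
# intensity changes between temporally close frames; contiguous volumes of
# statistically significant voxels in the (robustly standardised) difference
# image become candidate events, and the daughter-separation axis is read off
# the spatial principal axis of the change region.

#' Construct a 4D movie stack
#'
#' @param data Numeric array with dimensions `(Y, X, Z, T)`; intensities are
#'   nonnegative and at least 2 frames are required.
#' @param voxel_size Micrometres per voxel along `(y, x, z)`.
#' @param frame_interval Minutes between frames.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(data, voxel_size = c(1, 1, 1), frame_interval = 3) {
  stopifnot(length(dim(data)) == 4, dim(data)[4] >= 2, all(data >= 0),
            length(voxel_size) == 3, all(voxel_size > 0), frame_interval > 0)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 frame_interval = frame_interval),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("movie_stack: %d frames of %d z x %d y x %d x voxels, %g um voxels (y,x,z), %g min/frame\n",
              d[4], d[3], d[1], d[2], x$voxel_size[1], x$frame_interval))
  invisible(x)
}

#' @rdname movie_io
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie$data)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (t in seq_len(d[4])) for (z in seq_len(d[3])) {
    pages[[k]] <- movie$data[, , z, t]
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read and write movies as multi-page TIFF
#'
#' Pages are ordered frame-major (all z-slices of frame 1, then frame 2,
#' ...). Intensities must lie in `[0, 1]` (32-bit float storage).
#'
#' @param movie A [movie_stack()].
#' @param path TIFF file path.
#' @param n_z Number of z-slices per frame (needed to reshape on read).
#' @param voxel_size,frame_interval Metadata to attach on read.
#' @name movie_io
#' @export
read_movie <- function(path, n_z, voxel_size = c(1, 1, 1), frame_interval = 3) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% n_z != 0) stop("page count is not a multiple of n_z")
  n_t <- length(pages) / n_z
  d <- dim(pages[[1]])
  a <- array(0, c(d[1], d[2], n_z, n_t))
  k <- 1L
  for (t in seq_len(n_t)) for (z in seq_len(n_z)) {
    a[, , z, t] <- pages[[k]]
    k <- k + 1L
  }
  movie_stack(a, voxel_size, frame_interval)
}

# Separable Gaussian smoothing of a 3D array (replicate padding at edges).
.gauss_smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- ceiling(3 * sigma)
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  d <- dim(a)
  for (axis in 1:3) {
    out <- array(0, d)
    n <- d[axis]
    for (k in seq_along(w)) {
      idx <- pmin(pmax(seq_len(n) + (k - r - 1L), 1L), n)
      out <- out + w[k] * switch(axis,
                                 a[idx, , , drop = FALSE],
                                 a[, idx, , drop = FALSE],
                                 a[, , idx, drop = FALSE])
    }
    a <- out
  }
  a
}

#' Significance mask of a frame difference
#'
#' Computes the difference `I(t + gap) - I(t)` (after optional Gaussian
#' pre-smoothing of each frame), standardises it robustly with the median and
#' MAD of the difference image, and marks voxels with `|z| >= threshold`.
#' Constant frames (zero MAD) yield an empty mask.
#'
#' @param movie A [movie_stack()].
#' @param t Frame index; `t + gap` must be within range.
#' @param params [detection_params()].
#' @return List with logical array `mask`, the standardised `z` array and the
#'   smoothed difference `diff`.
#' @export
difference_significance <- function(movie, t, params = detection_params()) {
  stopifnot(inherits(movie, "movie_stack"), inherits(params, "detection_params"))
  nt <- dim(movie$data)[4]
  if (t < 1 || t + params$gap > nt) stop("t and t + gap must be within the movie")
  f1 <- .gauss_smooth3d(movie$data[, , , t, drop = TRUE], params$smooth_sigma)
  f2 <- .gauss_smooth3d(movie$data[, , , t + params$gap, drop = TRUE],
                        params$smooth_sigma)
  if (length(dim(f1)) != 3) {   # single z-slice
    f1 <- array(f1, c(dim(movie$data)[1:2], 1))
    f2 <- array(f2, c(dim(movie$data)[1:2], 1))
  }
  D <- f2 - f1
  med <- stats::median(D)
  s <- stats::mad(D)
  if (s == 0) {
    # noise-free (or near-constant) frames: any material change is
    # infinitely significant; constant frames yield an empty mask
    tol <- 1e-6 * max(abs(D), 1e-12)
    mask <- abs(D - med) > tol
    z <- array(0, dim(D))
    z[mask] <- Inf
    return(list(mask = mask, z = z, diff = D))
  }
  z <- (D - med) / s
  list(mask = abs(z) >= params$threshold, z = z, diff = D)
}

# Connected components of a 3D logical mask (6- or 26-connectivity).
# Returns a list of integer-vector voxel index sets (linear indices).
.mask_components <- function(mask, connectivity = 26) {
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  d <- dim(mask)
  co <- arrayInd(idx, d)
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
    g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
    g[g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
        (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0), , drop = FALSE]
  }
  edges <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    m <- match(nb_lin, idx)
    hit <- !is.na(m)
    if (any(hit))
      edges <- c(edges, rbind(which(ok)[hit], m[hit]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  split(idx, memb)
}

.weighted_principal_axis <- function(coords_um, w) {
  mu <- colSums(coords_um * w) / sum(w)
  cc <- sweep(coords_um, 2, mu)
  S <- crossprod(cc * sqrt(w / sum(w)))
  v <- eigen(S, symmetric = TRUE)$vectors[, 1]
  v / sqrt(sum(v^2))
}

#' Extract division events from a movie
#'
#' Runs [difference_significance()] over all frame pairs, keeps connected
#' components of significant voxels with at least `min_volume` voxels, and
#' turns each into a candidate division event: the position is the
#' `|difference|`-weighted centroid, and the daughter-separation axis is the
#' principal axis of the component's voxel coordinates (the change region of
#' two separating daughters is elongated along the separation axis).
#' Candidates within `merge_radius` micrometres and `merge_frames` frames of
#' a larger candidate are merged into it.
#'
#' @param movie A [movie_stack()].
#' @param params [detection_params()].
#' @return Data frame with columns `t_min`, `frame`, `x_um`, `y_um`, `z_um`,
#'   `ax`, `ay`, `az`, `volume` (possibly 0 rows).
#' @export
extract_events <- function(movie, params = detection_params()) {
  stopifnot(inherits(movie, "movie_stack"))
  nt <- dim(movie$data)[4]
  vs <- movie$voxel_size   # (y, x, z)
  cand <- list()
  for (t in seq_len(nt - params$gap)) {
    ds <- difference_significance(movie, t, params)
    comps <- .mask_components(ds$mask, params$connectivity)
    for (cp in comps) {
      if (length(cp) < params$min_volume) next
      co <- arrayInd(cp, dim(ds$mask))
      um <- cbind(y = (co[, 1] - 1) * vs[1], x = (co[, 2] - 1) * vs[2],
                  z = (co[, 3] - 1) * vs[3])
      w <- abs(ds$diff[cp])
      ctr <- colSums(um * w) / sum(w)
      axis <- if (params$axis_method == "two_centroid") {
        .two_centroid_axis(um, ds$diff[cp])
      } else {
        .weighted_principal_axis(um, w)
      }
      cand[[length(cand) + 1L]] <- data.frame(
        t_min = (t - 1) * movie$frame_interval, frame = t,
        x_um = ctr["x"], y_um = ctr["y"], z_um = ctr["z"],
        ax = axis[2], ay = axis[1], az = axis[3], volume = length(cp))
    }
  }
  empty <- data.frame(t_min = numeric(0), frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0), ax = numeric(0),
                      ay = numeric(0), az = numeric(0), volume = numeric(0))
  if (!length(cand)) return(empty)
  ev <- do.call(rbind, cand)
  rownames(ev) <- NULL
  # merge: greedy by decreasing volume
  ev <- ev[order(-ev$volume), ]
  keep <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    ks <- which(keep)
    dist <- sqrt((ev$x_um[ks] - ev$x_um[i])^2 + (ev$y_um[ks] - ev$y_um[i])^2 +
                   (ev$z_um[ks] - ev$z_um[i])^2)
    dup <- dist <= params$merge_radius &
      abs(ev$frame[ks] - ev$frame[i]) <= params$merge_frames
    if (!any(dup)) keep[i] <- TRUE
  }
  ev <- ev[keep, ]
  ev[order(ev$frame), ]
}

# Alternative axis estimator: split the positive change region (appearing
# daughters) into two clusters and take the inter-centroid axis.
.two_centroid_axis <- function(coords_um, diffvals) {
  pos <- coords_um[diffvals > 0, , drop = FALSE]
  if (nrow(pos) < 4) return(.weighted_principal_axis(coords_um, abs(diffvals)))
  km <- stats::kmeans(pos, centers = 2, nstart = 3)
  v <- km$centers[2, ] - km$centers[1, ]
  n <- sqrt(sum(v^2))
  if (n == 0) return(.weighted_principal_axis(coords_um, abs(diffvals)))
  v / n
}

#' Match detected events against ground truth
#'
#' Greedy nearest-neighbour matching: detected events are paired with planted
#' events within `radius` micrometres and `frame_tol` frames, closest pairs
#' first; each planted event matches at most one detection.
#'
#' @param detected Events data frame from [extract_events()].
#' @param truth Ground-truth events with `x_um`, `y_um`, `z_um`, `frame` and
#'   axis columns `ax`, `ay`, `az`.
#' @param radius Match radius in micrometres (about one cell diameter).
#' @param frame_tol Maximum frame difference.
#' @return List with `precision`, `recall`, `n_matched` and a data frame
#'   `matches` carrying the per-match distance and axis angular error
#'   (degrees).
#' @export
match_events <- function(detected, truth, radius, frame_tol = 1) {
  if (!nrow(detected) || !nrow(truth)) {
    return(list(precision = if (nrow(detected)) 0 else NA_real_,
                recall = if (nrow(truth)) 0 else NA_real_,
                n_matched = 0L, matches = NULL))
  }
  pairs <- expand.grid(i = seq_len(nrow(detected)), j = seq_len(nrow(truth)))
  pairs$dist <- sqrt((detected$x_um[pairs$i] - truth$x_um[pairs$j])^2 +
                       (detected$y_um[pairs$i] - truth$y_um[pairs$j])^2 +
                       (detected$z_um[pairs$i] - truth$z_um[pairs$j])^2)
  pairs$dframe <- abs(detected$frame[pairs$i] - truth$frame[pairs$j])
  pairs <- pairs[pairs$dist <= radius & pairs$dframe <= frame_tol, ]
  pairs <- pairs[order(pairs$dist), ]
  used_i <- used_j <- integer(0)
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    if (pairs$i[r] %in% used_i || pairs$j[r] %in% used_j) next
    keep[r] <- TRUE
    used_i <- c(used_i, pairs$i[r]); used_j <- c(used_j, pairs$j[r])
  }
  m <- pairs[keep, ]
  if (nrow(m)) {
    m$angle_err_deg <- vapply(seq_len(nrow(m)), function(r) {
      a <- c(detected$ax[m$i[r]], detected$ay[m$i[r]], detected$az[m$i[r]])
      b <- c(truth$ax[m$j[r]], truth$ay[m$j[r]], truth$az[m$j[r]])
      axis_angle_error(a, b)
    }, numeric(1))
  }
  list(precision = nrow(m) / nrow(detected), recall = nrow(m) / nrow(truth),
       n_matched = nrow(m), matches = m)
}

#' Angular error between two unoriented axes
#'
#' @param a,b Length-3 vectors (normalised internally).
#' @return Angle in degrees in `[0, 90]`.
#' @export
axis_angle_error <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, abs(sum(a * b)))) * 180 / pi
}
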