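# Annulus geometry of the CMZ: ring assignment from the distance to the
# peripheral edge, division angles against the local tangent of the CMZ
# circle, and per-ring division rates with Poisson intervals.

.project_plane <- function(v, normal) v - sum(v * normal) * normal

#' Assign CMZ rings from 3D positions
#'
#' Positions are projected into the CMZ plane; the distance `d` from the
#' peripheral edge is measured inward (`edge_radius - radial coordinate`,
#' plus any configured `edge_offset`), and the ring is
#' `floor(d / cell_diameter) + 1`. Ring 1 is the most peripheral shell
#' (nearest the lens); positions peripheral to the edge (`d < 0`) are clamped
#' to ring 1 with a warning.
#'
#' @param position Numeric length-3 vector or an n-by-3 matrix of positions
#'   in micrometres.
#' @param geom [cmz_geometry()].
#' @return Integer ring indices (>= 1).
#' @export
assign_ring <- function(position, geom) {
  stopifnot(inherits(geom, "cmz_geometry"))
  p <- if (is.matrix(position)) position else matrix(position, nrow = 1)
  p <- sweep(p, 2, geom$center)
  radial <- sqrt(rowSums((p - outer(p %*% geom$normal, geom$normal)[, 1, ])^2))
  d <- geom$edge_radius - radial + geom$edge_offset
  if (any(d < 0)) {
    warning("position(s) peripheral to the CMZ edge; clamped to ring 1")
    d <- pmax(d, 0)
  }
  as.integer(floor(d / geom$cell_diameter)) + 1L
}

#' Division angle against the local CMZ tangent
#'
#' The daughter-separation axis is projected into the CMZ plane and compared
#' with the tangent to the CMZ circle at the point closest to the division:
#' the returned angle is `acos(|projected axis . tangent|)` in degrees,
#' folded to `[0, 90]` because division axes are unoriented. 0 degrees is
#' circumferential (parallel to the tangent), 90 degrees is radial.
#'
#' @param axis Unit (or unnormalised nonzero) length-3 separation axis.
#' @param position Length-3 division position in micrometres.
#' @param geom [cmz_geometry()].
#' @return Angle in degrees in `[0, 90]`.
#' @export
division_angle <- function(axis, position, geom) {
  stopifnot(inherits(geom, "cmz_geometry"))
  a <- .project_plane(as.numeric(axis), geom$normal)
  na <- sqrt(sum(a^2))
  if (na < 1e-9 * max(1, sqrt(sum(axis^2))))
    stop("axis is perpendicular to the CMZ plane: division angle undefined")
  a <- a / na
  r <- .project_plane(as.numeric(position) - geom$center, geom$normal)
  nr <- sqrt(sum(r^2))
  if (nr < 1e-9) stop("position at the CMZ centre: tangent undefined")
  r <- r / nr
  tg <- c(geom$normal[2] * r[3] - geom$normal[3] * r[2],
          geom$normal[3] * r[1] - geom$normal[1] * r[3],
          geom$normal[1] * r[2] - geom$normal[2] * r[1])
  acos(min(1, abs(sum(a * tg)))) * 180 / pi
}

#' One-sigma Poisson confidence interval for a count
#'
#' Central 68.27% interval for the Poisson mean given an observed count,
#' computed by Garwood-style chi-square inversion:
#' `lower = qchisq(0.15865, 2k) / 2` (0 for k = 0) and
#' `upper = qchisq(0.84135, 2k + 2) / 2`.
#'
#' @param k Nonnegative integer count(s); vectorised.
#' @param conf Interval coverage (default the one-sigma 0.6827).
#' @return A 2-column matrix `lower`, `upper` with one row per count.
#' @export
poisson_onesigma_ci <- function(k, conf = 0.6826895) {
  if (any(k < 0) || any(k != floor(k))) stop("k must be a nonnegative integer")
  a <- (1 - conf) / 2
  lower <- ifelse(k == 0, 0, stats::qchisq(a, 2 * k) / 2)
  upper <- stats::qchisq(1 - a, 2 * (k + 1)) / 2
  cbind(lower = lower, upper = upper)
}

#' Per-ring division rates with one-sigma Poisson intervals
#'
#' Division rate in a ring is the number of divisions observed divided by the
#' number of cells imaged in that ring; the interval is the one-sigma Poisson
#' interval of the count, scaled by the number of cells.
#'
#' @param events Data frame of division events with a `ring` column.
#' @param cells_per_ring Number of cells imaged per ring (index = ring).
#' @return Data frame `ring`, `n_divisions`, `n_cells`, `rate`, `lo`, `hi`.
#'   Rings with 0 imaged cells are omitted with a warning.
#' @export
division_rate_per_ring <- function(events, cells_per_ring) {
  rings <- seq_along(cells_per_ring)
  k <- vapply(rings, function(r) sum(events$ring == r), numeric(1))
  keep <- cells_per_ring > 0
  if (!all(keep)) warning("ring(s) with 0 imaged cells omitted")
  ci <- poisson_onesigma_ci(k[keep])
  data.frame(ring = rings[keep], n_divisions = k[keep],
             n_cells = cells_per_ring[keep],
             rate = k[keep] / cells_per_ring[keep],
             lo = ci[, "lower"] / cells_per_ring[keep],
             hi = ci[, "upper"] / cells_per_ring[keep])
}

#' Ratio of ring-1 to higher-ring cytokinesis counts
#'
#' Summarises oriented-division counts as a `1 : x` ratio, with `x` the
#' nearest-integer ratio of divisions observed in rings >= 2 to divisions in
#' ring 1 over the same imaging interval (e.g. 12 vs 153 rounds to 1:13).
#'
#' @param events Data frame of division events with a `ring` column, or
#'   `NULL` if `n_ring1`/`n_higher` are given directly.
#' @param n_ring1,n_higher Optional explicit counts.
#' @return List with `n_ring1`, `n_higher` and the rounded `ratio`.
#' @export
ring_division_ratio <- function(events = NULL, n_ring1 = NULL, n_higher = NULL) {
  if (!is.null(events)) {
    n_ring1 <- sum(events$ring == 1)
    n_higher <- sum(events$ring >= 2)
  }
  if (n_ring1 <= 0) stop("no ring-1 divisions: ratio undefined")
  list(n_ring1 = n_ring1, n_higher = n_higher,
       ratio = round(n_higher / n_ring1))
}

#' Box-plot statistics of division angles per ring
#'
#' Per-ring quartiles with whiskers extending from the lowest value still
#' within 1.5 interquartile ranges (IQR) of the lower quartile to the highest
#' value still within 1.5 IQR of the upper quartile.
#'
#' @param events Data frame with `ring` and `angle_deg` columns.
#' @return Data frame `ring`, `n`, `q1`, `median`, `q3`, `whisker_lo`,
#'   `whisker_hi`.
#' @export
angle_by_ring_summary <- function(events) {
  rings <- sort(unique(events$ring))
  do.call(rbind, lapply(rings, function(r) {
    x <- events$angle_deg[events$ring == r]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(ring = r, n = length(x), q1 = q[1], median = q[2], q3 = q[3],
               whisker_lo = min(x[x >= q[1] - 1.5 * iqr]),
               whisker_hi = max(x[x <= q[3] + 1.5 * iqr]))
  }))
}

#' Annotate division events with ring and angle
#'
#' Adds/overwrites `ring` and `angle_deg` columns computed from the event
#' positions and axes under a given geometry.
#'
#' @param events Data frame with columns `x_um`, `y_um`, `z_um`, `ax`, `ay`,
#'   `az`.
#' @param geom [cmz_geometry()].
#' @return The annotated events data frame.
#' @export
annotate_events <- function(events, geom) {
  pos <- as.matrix(events[, c("x_um", "y_um", "z_um")])
  events$ring <- assign_ring(pos, geom)
  events$angle_deg <- vapply(seq_len(nrow(events)), function(i)
    division_angle(c(events$ax[i], events$ay[i], events$az[i]), pos[i, ], geom),
    numeric(1))
  events
}

#' @rdname events_io
#' @export
write_events <- function(events, path, header = NULL) {
  .write_tsv(events, path, header)
}

#' Read and write division-event tables
#'
#' TSV with columns `t_min`, `x_um`, `y_um`, `z_um`, `ax`, `ay`, `az` and,
#' when annotated, `ring` and `angle_deg`.
#'
#' @param events Events data frame.
#' @param path File path.
#' @param header Optional provenance comment lines.
#' @name events_io
#' @export
read_events <- function(path) {
  utils::read.delim(path, comment.char = "#")
}
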