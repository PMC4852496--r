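# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth — fate-labelled clone tables, division-event sets on an
# annulus, and noisy 4D movies with planted divisions. All generators are
# deterministic under set.seed().

#' Default marginal fate probabilities
#'
#' A plausible, photoreceptor-dominant retinal fate composition used as the
#' generator default. These proportions are a configuration default for
#' synthetic data, not measured values; analyses that depend on fates should
#' plant their own marginals.
#'
#' @return Named probability vector over [FATES].
#' @export
default_fate_probs <- function() {
  c(RGC = 0.05, AC = 0.15, BC = 0.25, HC = 0.08, PR = 0.45, MG = 0.02)
}

#' Generate a fate-labelled clone table
#'
#' Emulates a photoconversion clone cohort: each clone is maintained (all
#' cells proliferative, rings 1-2) with probability `rsc_fraction`, mixed
#' with probability `mixed_fraction`, and terminated otherwise. Terminated
#' clone sizes are drawn from [simulate_cmz_clone()] and leaf fates i.i.d.
#' from the marginal fate table.
#'
#' @param n_clones Number of clones (default 118).
#' @param rsc_fraction Probability a clone is maintained (default 11/118).
#' @param mixed_fraction Probability a clone is mixed (default 3/118).
#' @param fate_probs Marginal fate probabilities, named over [FATES].
#' @param timepoint_dpf Observation day recorded in the table.
#' @param source Clone source label, `"CMZ"` or `"central"`.
#' @param cycle,schedule,cmz Lineage-model parameters for clone sizes.
#' @return A validated clone table data frame.
#' @export
gen_clone_table <- function(n_clones = 118, rsc_fraction = 11 / 118,
                            mixed_fraction = 3 / 118,
                            fate_probs = default_fate_probs(),
                            timepoint_dpf = 5, source = "CMZ",
                            cycle = cell_cycle_params(),
                            schedule = mode_schedule(),
                            cmz = cmz_params()) {
  stopifnot(rsc_fraction + mixed_fraction <= 1)
  fate_probs <- fate_probs / sum(fate_probs)
  cls <- sample(c("terminated", "maintained", "mixed"), n_clones, replace = TRUE,
                prob = c(1 - rsc_fraction - mixed_fraction, rsc_fraction,
                         mixed_fraction))
  rows <- lapply(seq_len(n_clones), function(i) {
    id <- sprintf("clone%03d", i)
    if (cls[i] == "maintained") {
      n <- sample(2:4, 1)
      data.frame(clone_id = id, cell_id = seq_len(n), fate = "P",
                 ring = sample(1:2, n, replace = TRUE),
                 timepoint_dpf = timepoint_dpf, source = source)
    } else if (cls[i] == "mixed") {
      n <- max(2L, simulate_cmz_clone(cycle, schedule, cmz))
      n_p <- sample.int(n - 1L, 1)
      fate <- c(rep("P", n_p),
                sample(names(fate_probs), n - n_p, replace = TRUE, prob = fate_probs))
      data.frame(clone_id = id, cell_id = seq_len(n), fate = fate,
                 ring = c(sample(3:5, n_p, replace = TRUE), rep(NA, n - n_p)),
                 timepoint_dpf = timepoint_dpf, source = source)
    } else {
      n <- simulate_cmz_clone(cycle, schedule, cmz)
      data.frame(clone_id = id, cell_id = seq_len(n),
                 fate = sample(names(fate_probs), n, replace = TRUE, prob = fate_probs),
                 ring = NA_integer_, timepoint_dpf = timepoint_dpf,
                 source = source)
    }
  })
  out <- do.call(rbind, rows)
  validate_clone_table(out)
  out
}

#' Generate division events on the CMZ annulus
#'
#' Plants division events with per-ring rates (expected events =
#' `rate * cells` per ring, Poisson counts). Ring-1 axes are drawn
#' near-radial: the in-plane deviation from the radial direction is normal
#' with standard deviation `1/sqrt(ring1_concentration)` radians
#' (concentration `Inf` gives exactly radial, i.e. 90-degree, divisions);
#' higher-ring axes are uniformly oriented in the plane. Ground-truth ring
#' and angle are stored with each event.
#'
#' @param geom [cmz_geometry()].
#' @param cells_per_ring Number of cells imaged per ring (index = ring).
#' @param rates_per_ring Planted division rate per ring (events per cell).
#' @param ring1_concentration Concentration of ring-1 axes about the radial
#'   direction.
#' @param t_max Events are placed uniformly in `[0, t_max]` minutes.
#' @return Events data frame with `t_min`, `x_um`, `y_um`, `z_um`, `ax`,
#'   `ay`, `az`, `ring`, `angle_deg` (planted truth).
#' @export
gen_division_events <- function(geom = cmz_geometry(),
                                cells_per_ring = c(60, 80, 80),
                                rates_per_ring = c(0.05, 0.25, 0.10),
                                ring1_concentration = 20, t_max = 180) {
  stopifnot(length(cells_per_ring) == length(rates_per_ring))
  # orthonormal in-plane basis
  n <- geom$normal
  u <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .project_plane(u, n); u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  rows <- list()
  for (r in seq_along(cells_per_ring)) {
    k <- stats::rpois(1, rates_per_ring[r] * cells_per_ring[r])
    if (k == 0) next
    d <- stats::runif(k, (r - 1) * geom$cell_diameter, r * geom$cell_diameter)
    theta <- stats::runif(k, 0, 2 * pi)
    rad <- geom$edge_radius - d
    pos <- t(vapply(seq_len(k), function(i)
      geom$center + rad[i] * (cos(theta[i]) * u + sin(theta[i]) * v),
      numeric(3)))
    # axis: deviation phi from the local radial direction, in-plane
    phi <- if (r == 1) {
      if (is.infinite(ring1_concentration)) rep(0, k)
      else stats::rnorm(k, 0, 1 / sqrt(ring1_concentration))
    } else {
      stats::runif(k, 0, 2 * pi)
    }
    ax <- t(vapply(seq_len(k), function(i) {
      rhat <- cos(theta[i]) * u + sin(theta[i]) * v
      that <- -sin(theta[i]) * u + cos(theta[i]) * v
      cos(phi[i]) * rhat + sin(phi[i]) * that
    }, numeric(3)))
    rows[[r]] <- data.frame(
      t_min = stats::runif(k, 0, t_max),
      x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
      ax = ax[, 1], ay = ax[, 2], az = ax[, 3],
      ring = r, angle_deg = acos(pmin(1, abs(sin(phi)))) * 180 / pi)
  }
  if (!length(rows))
    return(data.frame(t_min = numeric(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), ax = numeric(0), ay = numeric(0),
                      az = numeric(0), ring = integer(0), angle_deg = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$t_min), ]
}

# Gaussian blob as a local patch: index ranges plus intensity values, so
# rendering updates only a small box of the 4D array.
.blob_patch <- function(ctr_vox, sigma_vox, dims3, amp) {
  r <- ceiling(3 * sigma_vox)
  iy <- max(1, round(ctr_vox[1]) - r):min(dims3[1], round(ctr_vox[1]) + r)
  ix <- max(1, round(ctr_vox[2]) - r):min(dims3[2], round(ctr_vox[2]) + r)
  iz <- max(1, round(ctr_vox[3]) - r):min(dims3[3], round(ctr_vox[3]) + r)
  gy <- exp(-(iy - ctr_vox[1])^2 / (2 * sigma_vox^2))
  gx <- exp(-(ix - ctr_vox[2])^2 / (2 * sigma_vox^2))
  gz <- exp(-(iz - ctr_vox[3])^2 / (2 * sigma_vox^2))
  list(iy = iy, ix = ix, iz = iz, val = amp * outer(outer(gy, gx), gz))
}

#' Generate a noisy 4D movie with planted divisions
#'
#' Renders a static annulus background plus, for each planted division, a
#' mother blob that splits into two daughter blobs separating along the
#' planted axis over two frames, then additive Gaussian noise at the target
#' SNR (`SNR = blob amplitude / noise sd`; `Inf` disables noise). Intensities
#' are clipped to `[0, 1]` for 32-bit float TIFF storage.
#'
#' Planted positions respect a minimum pairwise separation of two cell
#' diameters (or more than two frames apart), so ground-truth events are
#' unambiguous.
#'
#' @param n_events Number of planted divisions.
#' @param snr Signal-to-noise ratio (blob amplitude over noise sd).
#' @param dims Movie dimensions, named `(y, x, z, t)` voxels/frames
#'   (default 256 x 256 x 16 x 40).
#' @param voxel_size Micrometres per voxel `(y, x, z)`.
#' @param frame_interval Minutes per frame.
#' @param cell_diameter Cell diameter in micrometres.
#' @param rings Rings on which to plant events.
#' @param ring1_concentration Passed to the axis model (ring-1 near-radial).
#' @return List with `movie` ([movie_stack()]), `truth` (events data frame
#'   with `frame` and planted `ring`/`angle_deg`) and `geom`
#'   ([cmz_geometry()]).
#' @export
gen_movie <- function(n_events = 20, snr = 5,
                      dims = c(y = 256, x = 256, z = 16, t = 40),
                      voxel_size = c(1, 1, 1), frame_interval = 3,
                      cell_diameter = 8, rings = 1:3,
                      ring1_concentration = 20) {
  ny <- dims[["y"]]; nx <- dims[["x"]]; nz <- dims[["z"]]; nt <- dims[["t"]]
  stopifnot(nt >= 8, nz >= 3)
  geom <- cmz_geometry(
    center = c((nx - 1) * voxel_size[2] / 2, (ny - 1) * voxel_size[1] / 2,
               (nz - 1) * voxel_size[3] / 2),
    normal = c(0, 0, 1),
    edge_radius = 0.42 * min((nx - 1) * voxel_size[2], (ny - 1) * voxel_size[1]),
    cell_diameter = cell_diameter)

  # planted events: positions/axes on the annulus, rejection-sampled for
  # separation; frames away from the movie ends
  truth <- NULL
  tries <- 0
  if (n_events == 0)
    truth <- cbind(gen_division_events(geom, cells_per_ring = 0,
                                       rates_per_ring = 0),
                   frame = integer(0))
  while (is.null(truth) || nrow(truth) < n_events) {
    tries <- tries + 1
    if (tries > 200) stop("could not place that many separated events; enlarge the movie")
    cand <- gen_division_events(geom,
                                cells_per_ring = rep(50, max(rings)),
                                rates_per_ring = ifelse(seq_len(max(rings)) %in% rings,
                                                        n_events / length(rings) / 50, 0),
                                ring1_concentration = ring1_concentration,
                                t_max = 1)
    if (!nrow(cand)) next
    cand$frame <- sample(4:(nt - 4), nrow(cand), replace = TRUE)
    pool <- if (is.null(truth)) cand else rbind(truth, cand)
    keep <- logical(nrow(pool))
    for (i in seq_len(nrow(pool))) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      ks <- which(keep)
      dd <- sqrt((pool$x_um[ks] - pool$x_um[i])^2 + (pool$y_um[ks] - pool$y_um[i])^2)
      if (all(dd > 2.5 * cell_diameter | abs(pool$frame[ks] - pool$frame[i]) > 3))
        keep[i] <- TRUE
    }
    truth <- pool[keep, ]
  }
  truth <- truth[seq_len(n_events), ]
  truth$t_min <- (truth$frame - 1) * frame_interval
  rownames(truth) <- NULL

  # static background: annulus band of elevated intensity
  xs <- (seq_len(nx) - 1) * voxel_size[2]
  ys <- (seq_len(ny) - 1) * voxel_size[1]
  rr <- sqrt(outer((ys - geom$center[2])^2, (xs - geom$center[1])^2, "+"))
  band_ctr <- geom$edge_radius - 1.5 * cell_diameter
  bg2d <- 0.15 + 0.2 * exp(-(rr - band_ctr)^2 / (2 * (1.5 * cell_diameter)^2))
  bg <- array(rep(bg2d, nz), c(ny, nx, nz))

  amp <- 0.45
  sigma_blob <- cell_diameter / 4 / voxel_size[1]
  a <- array(0, c(ny, nx, nz, nt))
  for (t in seq_len(nt)) a[, , , t] <- bg
  vox <- function(p) c(p[2] / voxel_size[1] + 1, p[1] / voxel_size[2] + 1,
                       p[3] / voxel_size[3] + 1)   # (y, x, z) voxels
  add <- function(ctr, t) {
    pp <- .blob_patch(vox(ctr), sigma_blob, c(ny, nx, nz), amp)
    a[pp$iy, pp$ix, pp$iz, t] <<- a[pp$iy, pp$ix, pp$iz, t] + pp$val
  }
  for (i in seq_len(nrow(truth))) {
    p <- c(truth$x_um[i], truth$y_um[i], truth$z_um[i])
    axv <- c(truth$ax[i], truth$ay[i], truth$az[i])
    t0 <- truth$frame[i]
    for (t in seq_len(nt)) {
      if (t <= t0) {
        add(p, t)
      } else {
        sep <- min(t - t0, 2) / 2 * cell_diameter
        add(p + sep / 2 * axv, t)
        add(p - sep / 2 * axv, t)
      }
    }
  }
  if (is.finite(snr)) a <- a + stats::rnorm(length(a), 0, amp / snr)
  a <- pmin(pmax(a, 0), 1)
  list(movie = movie_stack(a, voxel_size, frame_interval), truth = truth,
       geom = geom)
}
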