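#' Cell-cycle parameters of the retinal progenitor model
#'
#' Cell-cycle lengths follow a shifted gamma distribution: a fixed refractory
#' period plus a gamma-distributed remainder. The distribution is
#' parameterised by its refractory period, total mean and width (standard
#' deviation); the gamma shape and scale are obtained by moment matching,
#' `shape = ((mean - refractory) / width)^2` and
#' `scale = width^2 / (mean - refractory)`.
#'
#' @param refractory_h Refractory period in hours (shift of the gamma).
#' @param mean_h Mean total cycle length in hours; must exceed `refractory_h`.
#' @param width_h Standard deviation of the cycle length in hours.
#'
#' @return An object of class `cell_cycle_params` with fields
#'   `refractory_h`, `mean_h`, `width_h` and derived `shape`, `scale`.
#' @examples
#' p <- cell_cycle_params()       # refractory 4 h, mean 6 h, width 1 h
#' c(p$shape, p$scale)            # 4, 0.5
#' @export
cell_cycle_params <- function(refractory_h = 4, mean_h = 6, width_h = 1) {
  if (refractory_h < 0) stop("refractory_h must be >= 0")
  if (mean_h <= refractory_h) stop("mean_h must exceed refractory_h")
  if (width_h <= 0) stop("width_h must be > 0")
  mu <- mean_h - refractory_h
  structure(
    list(refractory_h = refractory_h, mean_h = mean_h, width_h = width_h,
         shape = (mu / width_h)^2, scale = width_h^2 / mu),
    class = "cell_cycle_params"
  )
}

#' Division-mode schedule on the lineage's internal clock
#'
#' Progenitor division modes (PP both daughters proliferate, PD one
#' proliferates and one differentiates, DD both differentiate) are drawn from
#' a piecewise-constant schedule over the lineage's internal clock, which
#' starts at the founder's first mitosis. Windows are half-open `[a, b)`:
#' a clock exactly at a boundary belongs to the later window.
#'
#' The default schedule is pure PP in `[0, 8)` h, 20/40/40% PP/PD/DD in
#' `[8, 15)` h, and 20/0/80% PP/PD/DD after 15 h.
#'
#' @param breaks Increasing interior breakpoints in hours; the windows are
#'   `[0, breaks[1])`, ..., `[breaks[k], Inf)`.
#' @param probs Numeric matrix with `length(breaks) + 1` rows and columns
#'   `PP`, `PD`, `DD`; each row sums to 1.
#'
#' @return An object of class `mode_schedule`.
#' @export
mode_schedule <- function(breaks = c(8, 15),
                          probs = rbind(c(1, 0, 0),
                                        c(0.2, 0.4, 0.4),
                                        c(0.2, 0, 0.8))) {
  probs <- as.matrix(probs)
  if (length(breaks) && (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0)))
    stop("breaks must be strictly increasing and positive")
  if (nrow(probs) != length(breaks) + 1L || ncol(probs) != 3L)
    stop("probs must have length(breaks) + 1 rows and 3 columns (PP, PD, DD)")
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-8))
    stop("each row of probs must be a probability vector summing to 1")
  if (probs[nrow(probs), 3] <= 0)
    stop("terminal window must have pDD > 0 so that lineages halt")
  colnames(probs) <- c("PP", "PD", "DD")
  structure(list(breaks = as.numeric(breaks), probs = probs),
            class = "mode_schedule")
}

#' CMZ residence parameters for clone-founder selection
#'
#' Progenitors are eligible founders of a ciliary-marginal-zone (CMZ) clone
#' while they reside in the CMZ, modelled as a limited window after the
#' lineage founder's first mitosis. Single-cell clones are excluded from the
#' analysis by default, mirroring the conditioning used for the experimental
#' clone-size distribution.
#'
#' @param residence_h Length in hours of the residence window on the founder
#'   clock (default 17 h). `0` is the degenerate window containing only the
#'   instant of the first mitosis, when the founder is the only cell alive.
#' @param exclude_singletons If `TRUE`, clones of size 1 are rejected and
#'   redrawn.
#'
#' @return An object of class `cmz_params`.
#' @export
cmz_params <- function(residence_h = 17, exclude_singletons = TRUE) {
  if (residence_h < 0) stop("residence_h must be >= 0")
  structure(list(residence_h = residence_h,
                 exclude_singletons = isTRUE(exclude_singletons)),
            class = "cmz_params")
}

#' Stem-cell niche division parameters
#'
#' Parameters of the retinal stem cell (RSC) / retinal progenitor cell (RPC)
#' niche model: RSCs divide at rate `alpha` (divisions/day) and RPCs at rate
#' `beta`. An RSC division is asymmetric (one RSC stays in the niche, one RPC
#' leaves) with probability `p_asym`; among the non-asymmetric divisions, a
#' fraction `p_loss` removes both daughters from the niche (two RPCs) and the
#' remainder keeps both (two RSCs, subject to optional capacity eviction).
#'
#' `p_asym` may be a single probability or a function of age in days,
#' allowing the asymmetry to increase as the niche stabilises; the default
#' ramps linearly from 0.7 at 5 dpf to 1.0 at 8 dpf.
#'
#' @param alpha RSC division rate, divisions per day.
#' @param beta RPC division rate, divisions per day. `beta >= alpha` is the
#'   biologically expected regime (slow stem cells); a warning is issued
#'   otherwise.
#' @param p_asym Probability that an RSC division is asymmetric; scalar or
#'   `function(day)`.
#' @param p_loss Probability that a non-asymmetric RSC division removes both
#'   daughters from the niche.
#' @param niche_capacity Optional maximum number of RSCs per clone in the
#'   niche (rings 1-2); excess symmetric-renewal daughters are evicted as
#'   RPCs.
#' @param n_rsc0 Initial number of RSCs per labelled clone (default 1: a
#'   maintained clone is assumed to be founded by a single stem cell;
#'   polyclones containing several RSCs can raise this).
#' @param schedule [mode_schedule()] used for the differentiation of RPCs
#'   spawned by the niche.
#' @param censor_prob Per-observation-day probability that the fish dies
#'   (right-censoring); 0 disables censoring.
#'
#' @return An object of class `niche_params`.
#' @export
niche_params <- function(alpha = 0.5, beta = 2,
                         p_asym = function(day) pmin(1, pmax(0.7, 0.7 + 0.1 * (day - 5))),
                         p_loss = 0.5, niche_capacity = NULL, n_rsc0 = 1,
                         schedule = mode_schedule(), censor_prob = 0) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (beta < alpha) warning("beta < alpha: RPCs dividing slower than RSCs is outside the expected regime")
  if (is.numeric(p_asym) && (p_asym < 0 || p_asym > 1)) stop("p_asym must be in [0, 1]")
  if (p_loss < 0 || p_loss > 1) stop("p_loss must be in [0, 1]")
  if (n_rsc0 < 1) stop("n_rsc0 must be >= 1")
  structure(list(alpha = alpha, beta = beta, p_asym = p_asym, p_loss = p_loss,
                 niche_capacity = niche_capacity, n_rsc0 = as.integer(n_rsc0),
                 schedule = schedule, censor_prob = censor_prob),
            class = "niche_params")
}

#' Annulus geometry of the CMZ
#'
#' The CMZ is modelled as an annulus in a plane (the frontal plane of the
#' retina). Rings of cells are counted from the peripheral edge inward: ring
#' 1 is the most peripheral shell (nearest the lens, adjacent to the ring
#' blood vessel), each ring is one cell diameter deep.
#'
#' @param center 3D coordinates (micrometres) of the CMZ circle centre.
#' @param normal Unit normal of the CMZ plane (normalised internally).
#' @param edge_radius Radius in micrometres of the peripheral edge (outer
#'   boundary of ring 1).
#' @param cell_diameter Cell diameter in micrometres (depth of one ring).
#' @param edge_offset Optional offset in micrometres added to the distance
#'   from the edge before ring assignment, accommodating different edge
#'   landmarks (blood-vessel boundary vs last labelled cell).
#'
#' @return An object of class `cmz_geometry`.
#' @export
cmz_geometry <- function(center = c(0, 0, 0), normal = c(0, 0, 1),
                         edge_radius = 100, cell_diameter = 8,
                         edge_offset = 0) {
  if (length(center) != 3 || length(normal) != 3)
    stop("center and normal must be length-3 numeric vectors")
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("normal must be nonzero")
  if (edge_radius <= 0) stop("edge_radius must be > 0")
  if (cell_diameter <= 0) stop("cell_diameter must be > 0")
  structure(list(center = as.numeric(center), normal = as.numeric(normal) / nn,
                 edge_radius = edge_radius, cell_diameter = cell_diameter,
                 edge_offset = edge_offset),
            class = "cmz_geometry")
}

#' Division-detection parameters
#'
#' Parameters of the frame-difference division detector. Each frame is
#' optionally smoothed with an isotropic Gaussian before differencing; the
#' difference image is robustly standardised (median/MAD) and voxels with
#' `|z| >= threshold` form the significance mask. Contiguous significant
#' volumes of at least `min_volume` voxels become candidate events;
#' candidates closer than `merge_radius` micrometres and at most
#' `merge_frames` frames apart are merged.
#'
#' @param threshold Significance threshold on the robust z-score.
#' @param min_volume Minimum connected-component volume in voxels.
#' @param connectivity Voxel connectivity in 3D, 6 or 26.
#' @param gap Frame gap for differencing (1 or 2).
#' @param smooth_sigma Standard deviation in voxels of the Gaussian
#'   pre-smoothing; 0 disables smoothing.
#' @param merge_radius Merge radius in micrometres (about one cell diameter).
#' @param merge_frames Maximum frame separation for merging candidates.
#' @param axis_method Daughter-separation axis estimator: `"pca"` (principal
#'   axis of the significant component) or `"two_centroid"` (axis between the
#'   two halves of the positive change region).
#'
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(threshold = 4, min_volume = 30,
                             connectivity = 26, gap = 1, smooth_sigma = 1,
                             merge_radius = 8, merge_frames = 1,
                             axis_method = c("pca", "two_centroid")) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (min_volume < 1) stop("min_volume must be >= 1")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  if (!gap %in% c(1, 2)) stop("gap must be 1 or 2")
  structure(list(threshold = threshold, min_volume = as.integer(min_volume),
                 connectivity = as.integer(connectivity), gap = as.integer(gap),
                 smooth_sigma = smooth_sigma, merge_radius = merge_radius,
                 merge_frames = as.integer(merge_frames),
                 axis_method = match.arg(axis_method)),
            class = "detection_params")
}

#' @export
print.cell_cycle_params <- function(x, ...) {
  cat(sprintf("Shifted-gamma cell cycle: refractory %g h, mean %g h, sd %g h (shape %g, scale %g)\n",
              x$refractory_h, x$mean_h, x$width_h, x$shape, x$scale))
  invisible(x)
}

#' @export
print.mode_schedule <- function(x, ...) {
  lo <- c(0, x$breaks)
  hi <- c(x$breaks, Inf)
  cat("Division-mode schedule (internal clock, hours):\n")
  for (i in seq_along(lo))
    cat(sprintf("  [%g, %g): PP %.2f  PD %.2f  DD %.2f\n",
                lo[i], hi[i], x$probs[i, 1], x$probs[i, 2], x$probs[i, 3]))
  invisible(x)
}
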