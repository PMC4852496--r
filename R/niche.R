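# Stem-cell niche model: RSCs in rings 1-2 divide at exponential rate alpha
# (divisions/day) with tunable asymmetry; RPCs spawned into ring 3 divide at
# rate beta and differentiate following the lineage-model mode schedule on
# their own internal clock. Clones are sampled at observation days into
# polyclone tracks, the unit of the detachment and niche-count statistics.

TRACK_COLS <- c("clone_id", "day", "ring12_count", "cmz_count",
                "most_peripheral_ring", "status")

.p_asym_at <- function(p_asym, day) {
  if (is.function(p_asym)) p_asym(day) else p_asym
}

#' Simulate one labelled CMZ polyclone
#'
#' Continuous-time simulation of a labelled patch containing `n_rsc0` RSCs.
#' Each RSC divides at rate `alpha`; the division is asymmetric (RSC stays,
#' one RPC leaves to ring 3) with probability `p_asym(day)`; otherwise, with
#' probability `p_loss` both daughters leave the niche as RPCs, and with the
#' remaining probability both stay as RSCs (subject to `niche_capacity`
#' eviction). RPCs divide at rate `beta` and differentiate following the mode
#' schedule on an internal clock started at their first mitosis; each RPC
#' division pushes the daughters one ring centrally, and differentiated cells
#' leave the CMZ.
#'
#' The clone is sampled at `observe_days`: the rings 1-2 count (the RSCs),
#' the total CMZ count, the most peripheral occupied ring (lowest ring
#' number) and the status (`maintained` while rings 1-2 are occupied,
#' `terminated` after, `dead` after censoring).
#'
#' @param params [niche_params()].
#' @param observe_days Strictly increasing observation days (dpf).
#' @param clone_id Identifier recorded in the track.
#' @return A `polyclone_track` data frame with columns `clone_id`, `day`,
#'   `ring12_count`, `cmz_count`, `most_peripheral_ring`, `status`.
#' @export
simulate_polyclone <- function(params = niche_params(),
                               observe_days = c(5, 6, 8, 12, 16),
                               clone_id = "clone1") {
  stopifnot(inherits(params, "niche_params"))
  if (!length(observe_days) || is.unsorted(observe_days, strictly = TRUE))
    stop("observe_days must be nonempty and strictly increasing")
  sched <- params$schedule
  n_rsc <- params$n_rsc0
  rpc_ring <- integer(0)     # current ring per RPC
  rpc_clock0 <- numeric(0)   # day of the RPC lineage's first mitosis (NA before)
  t <- observe_days[1]
  t_end <- observe_days[length(observe_days)]
  obs <- vector("list", length(observe_days))
  next_obs <- 1L
  dead <- FALSE

  snapshot <- function(day) {
    if (dead)
      return(data.frame(clone_id = clone_id, day = day,
                        ring12_count = NA_integer_, cmz_count = NA_integer_,
                        most_peripheral_ring = NA_integer_, status = "dead"))
    mpr <- if (n_rsc > 0) 1L else if (length(rpc_ring)) min(rpc_ring) else NA_integer_
    data.frame(clone_id = clone_id, day = day,
               ring12_count = n_rsc, cmz_count = n_rsc + length(rpc_ring),
               most_peripheral_ring = mpr,
               status = if (n_rsc > 0) "maintained" else "terminated")
  }

  repeat {
    rate <- params$alpha * n_rsc + params$beta * length(rpc_ring)
    t_next <- if (rate > 0) t + stats::rexp(1, rate) else Inf
    # record observations passed before the next event
    while (next_obs <= length(observe_days) && observe_days[next_obs] <= t_next) {
      d <- observe_days[next_obs]
      if (!dead && next_obs > 1L && params$censor_prob > 0 &&
          stats::runif(1) < params$censor_prob)
        dead <- TRUE
      obs[[next_obs]] <- snapshot(d)
      next_obs <- next_obs + 1L
    }
    if (dead) {
      while (next_obs <= length(observe_days)) {
        obs[[next_obs]] <- snapshot(observe_days[next_obs])
        next_obs <- next_obs + 1L
      }
      break
    }
    if (next_obs > length(observe_days) || t_next > t_end) break
    t <- t_next
    if (stats::runif(1) < params$alpha * n_rsc / rate) {
      # RSC division
      pa <- .p_asym_at(params$p_asym, t)
      u <- stats::runif(1)
      if (u < pa) {
        rpc_ring <- c(rpc_ring, 3L); rpc_clock0 <- c(rpc_clock0, NA_real_)
      } else if (stats::runif(1) < params$p_loss) {
        n_rsc <- n_rsc - 1L
        rpc_ring <- c(rpc_ring, 3L, 3L); rpc_clock0 <- c(rpc_clock0, NA, NA)
      } else {
        n_rsc <- n_rsc + 1L
        if (!is.null(params$niche_capacity) && n_rsc > params$niche_capacity) {
          n_rsc <- n_rsc - 1L
          rpc_ring <- c(rpc_ring, 3L); rpc_clock0 <- c(rpc_clock0, NA_real_)
        }
      }
    } else {
      # RPC division
      j <- sample.int(length(rpc_ring), 1L)
      clock0 <- if (is.na(rpc_clock0[j])) t else rpc_clock0[j]
      clock_h <- 24 * (t - clock0)
      m <- choose_mode(clock_h, sched)
      ring <- rpc_ring[j]
      rpc_ring <- rpc_ring[-j]; rpc_clock0 <- rpc_clock0[-j]
      n_new <- switch(m, PP = 2L, PD = 1L, DD = 0L)
      if (n_new > 0) {
        rpc_ring <- c(rpc_ring, rep(ring + 1L, n_new))
        rpc_clock0 <- c(rpc_clock0, rep(clock0, n_new))
      }
    }
  }
  out <- do.call(rbind, obs)
  class(out) <- c("polyclone_track", "data.frame")
  out
}

#' Simulate a cohort of polyclones
#'
#' @param n_clones Number of clones.
#' @param params [niche_params()].
#' @param observe_days Observation days (dpf).
#' @return Row-bound `polyclone_track` for all clones.
#' @export
simulate_polyclone_cohort <- function(n_clones, params = niche_params(),
                                      observe_days = c(5, 6, 8, 12, 16)) {
  out <- do.call(rbind, lapply(seq_len(n_clones), function(i)
    simulate_polyclone(params, observe_days, clone_id = sprintf("clone%03d", i))))
  class(out) <- c("polyclone_track", "data.frame")
  out
}

#' Clonal detachment rate over an observation window
#'
#' The detachment rate is the number of detachment cases (clones that move
#' away from rings 1-2 within the window) divided by the number of clones
#' surviving at the start of the window, divided by the window length in
#' days. Clones censored (dead) before the end of the window are excluded
#' from both numerator and denominator.
#'
#' @param tracks A `polyclone_track` cohort observed at both window
#'   endpoints.
#' @param window Length-2 numeric `(start_day, end_day)`.
#' @return Detachment rate per day (`NA` with a warning when no clone
#'   survives at the window start).
#' @export
detachment_rate <- function(tracks, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  a <- tracks[tracks$day == window[1], ]
  b <- tracks[tracks$day == window[2], ]
  if (!nrow(a) || !nrow(b)) stop("tracks must be observed at both window endpoints")
  surv <- a$clone_id[a$status == "maintained"]
  b <- b[match(surv, b$clone_id), ]
  observed <- surv[!is.na(b$status) & b$status != "dead"]
  if (length(observed) == 0) {
    warning("no surviving clones at window start: detachment rate undefined")
    return(NA_real_)
  }
  detached <- sum(b$status[match(observed, b$clone_id)] == "terminated")
  detached / length(observed) / (window[2] - window[1])
}

#' Mean rings 1-2 cell count of maintained clones per day
#'
#' Averages the rings 1-2 (niche) count over the clones still maintained at
#' each observation day; terminated and dead clones are excluded from that
#' day onward. The interval is the one-sigma Poisson interval of the pooled
#' count, scaled to the per-clone mean.
#'
#' @param tracks A `polyclone_track` cohort.
#' @return Data frame `day`, `n_maintained`, `mean_ring12`, `lo`, `hi`.
#' @export
niche_count_series <- function(tracks) {
  days <- sort(unique(tracks$day))
  do.call(rbind, lapply(days, function(d) {
    x <- tracks[tracks$day == d & tracks$status == "maintained", ]
    if (!nrow(x))
      return(data.frame(day = d, n_maintained = 0L, mean_ring12 = NA_real_,
                        lo = NA_real_, hi = NA_real_))
    tot <- sum(x$ring12_count)
    ci <- poisson_onesigma_ci(tot)
    data.frame(day = d, n_maintained = nrow(x), mean_ring12 = tot / nrow(x),
               lo = ci[, "lower"] / nrow(x), hi = ci[, "upper"] / nrow(x))
  }))
}

#' @rdname track_io
#' @export
write_tracks <- function(tracks, path, header = NULL) {
  .write_tsv(as.data.frame(tracks)[TRACK_COLS], path, header)
}

#' Read and write polyclone tracking tables
#'
#' TSV with columns `clone_id`, `day`, `ring12_count`, `cmz_count`,
#' `most_peripheral_ring`, `status`.
#'
#' @param tracks A `polyclone_track`.
#' @param path File path.
#' @param header Optional provenance comment lines.
#' @name track_io
#' @export
read_tracks <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(TRACK_COLS %in% names(d)))
  class(d) <- c("polyclone_track", "data.frame")
  d
}
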