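# CMZ clone sizes: a CMZ progenitor clone is modelled by simulating a full
# embryonic lineage, picking one progenitor from the pool resident in the
# CMZ during the first residence_h hours of the lineage clock, and counting
# the differentiated descendants of that progenitor.

# Eligible founders on plain core vectors: proliferative nodes whose lifetime
# (birth, division] intersects [0, residence_h]. Cells are considered
# resident from just after their birth mitosis, so the lineage founder (which
# divides at clock 0) is the only cell alive in the limit residence -> 0.
.cmz_candidates <- function(parent, birth, stage, residence_h) {
  prolif <- stage != "D"
  which(prolif & (is.na(parent) | birth < residence_h))
}

.subtree_leaf_count <- function(parent, stage, node) {
  n <- length(parent)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  stack <- node; count <- 0L
  while (length(stack)) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    ch <- kids[[i]]
    if (is.null(ch)) count <- count + 1L else stack <- c(stack, ch)
  }
  count
}

#' Select a CMZ clone founder from a simulated lineage
#'
#' Draws one progenitor uniformly from all proliferative cells resident in
#' the CMZ during the window `[0, residence_h]` on the lineage clock (the
#' clock starts at the lineage founder's first mitosis). The selected cell
#' keeps its inherited clock; it is not reset.
#'
#' @param lineage A completed `lineage` from [simulate_embryonic_lineage()].
#' @param cmz [cmz_params()].
#' @return A one-row `lineage` data frame (the selected node).
#' @export
select_cmz_founder <- function(lineage, cmz = cmz_params()) {
  cand <- .cmz_candidates(lineage$parent_id, lineage$birth_clock_h,
                          lineage$stage, cmz$residence_h)
  if (length(cand) == 0) stop("no eligible CMZ founder in the residence window")
  lineage[cand[sample.int(length(cand), 1L)], , drop = FALSE]
}

#' Simulate the size of one CMZ progenitor clone
#'
#' Simulates an embryonic lineage, selects a CMZ founder via
#' [select_cmz_founder()], and returns the number of differentiated cells in
#' that founder's completed subtree. When `cmz$exclude_singletons` is `TRUE`,
#' sizes of 1 are rejected and the clone is redrawn, matching the
#' conditioning of the experimental distribution on multi-cell clones.
#'
#' @param cycle [cell_cycle_params()].
#' @param schedule [mode_schedule()].
#' @param cmz [cmz_params()].
#' @return Integer clone size.
#' @export
simulate_cmz_clone <- function(cycle = cell_cycle_params(),
                               schedule = mode_schedule(),
                               cmz = cmz_params()) {
  repeat {
    s <- .sim_lineage_core(cycle, schedule)
    cand <- .cmz_candidates(s$parent, s$birth, s$stage, cmz$residence_h)
    node <- cand[sample.int(length(cand), 1L)]
    size <- .subtree_leaf_count(s$parent, s$stage, node)
    if (!cmz$exclude_singletons || size >= 2L) return(size)
  }
}

#' Empirical CMZ clone-size distribution with plausible intervals
#'
#' Simulates `n_replicates` CMZ clones, tabulates the empirical size
#' frequencies and attaches a 95% plausible band reflecting finite sampling:
#' a nonparametric bootstrap (resampling the `n_replicates` clones with
#' replacement, `boot` times) with per-size 2.5/97.5 percentiles.
#'
#' @param n_replicates Number of clones to simulate (>= 100 recommended; a
#'   warning is issued below that, and the band is wide).
#' @param cycle,schedule,cmz Model parameters.
#' @param boot Number of bootstrap resamples for the band.
#' @param conf Band coverage (default 0.95).
#' @return A data frame of class `clone_size_distribution` with columns
#'   `size`, `frequency`, `lo95`, `hi95` and attribute `n_replicates`.
#'   Frequencies sum to 1.
#' @export
clone_size_distribution <- function(n_replicates = 10000,
                                    cycle = cell_cycle_params(),
                                    schedule = mode_schedule(),
                                    cmz = cmz_params(),
                                    boot = 1000, conf = 0.95) {
  if (n_replicates < 100)
    warning("n_replicates < 100: plausible intervals will be unstable")
  sizes <- vapply(seq_len(n_replicates), function(i)
    simulate_cmz_clone(cycle, schedule, cmz), integer(1))
  tab <- table(sizes)
  freq <- as.numeric(tab) / n_replicates
  # bootstrap of iid draws == multinomial resampling of the empirical counts
  bs <- stats::rmultinom(boot, n_replicates, freq) / n_replicates
  a <- (1 - conf) / 2
  qs <- apply(bs, 1, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  out <- data.frame(size = as.integer(names(tab)), frequency = freq,
                    lo95 = qs[1, ], hi95 = qs[2, ])
  attr(out, "n_replicates") <- n_replicates
  class(out) <- c("clone_size_distribution", "data.frame")
  out
}

#' @rdname distribution_io
#' @export
write_distribution <- function(dist, path, header = NULL) {
  d <- as.data.frame(dist)
  d$n_replicates <- attr(dist, "n_replicates")
  .write_tsv(d, path, header)
}

#' Read and write clone-size distributions
#'
#' TSV with columns `size`, `frequency`, `lo95`, `hi95`, `n_replicates`.
#'
#' @param dist A `clone_size_distribution`.
#' @param path File path.
#' @param header Optional provenance comment lines.
#' @name distribution_io
#' @export
read_distribution <- function(path) {
  d <- utils::read.delim(path, comment.char = "#")
  out <- d[c("size", "frequency", "lo95", "hi95")]
  attr(out, "n_replicates") <- d$n_replicates[1]
  class(out) <- c("clone_size_distribution", "data.frame")
  out
}
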