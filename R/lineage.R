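# Lineages are flat node tables (one row per cell) forming a binary tree:
# node_id, parent_id (NA for the founder), birth_clock_h, division_clock_h
# (NA for differentiated leaves), mode at division (PP/PD/DD, NA for leaves),
# stage (I0 initial, I1 primary, I2 secondary, I3 tertiary progenitor, or D
# differentiated) and an optional leaf fate.

LINEAGE_COLS <- c("node_id", "parent_id", "birth_clock_h", "division_clock_h",
                  "mode", "stage", "fate")

#' Fate vocabulary of retinal cell types
#'
#' RGC retinal ganglion cell, AC amacrine, BC bipolar, HC horizontal,
#' PR photoreceptor, MG Mueller glia. `"P"` marks a still-proliferative cell
#' in clone tables.
#' @export
FATES <- c("RGC", "AC", "BC", "HC", "PR", "MG")

.new_lineage <- function(node_id, parent_id, birth, division, mode, stage,
                         fate = rep(NA_character_, length(node_id))) {
  structure(
    data.frame(node_id = as.integer(node_id), parent_id = as.integer(parent_id),
               birth_clock_h = birth, division_clock_h = division,
               mode = mode, stage = stage, fate = fate,
               stringsAsFactors = FALSE),
    class = c("lineage", "data.frame"))
}

# Core simulator on plain vectors (shared by the public wrapper and the CMZ
# clone sampler, which needs many replicates without data.frame overhead).
# The founder's first mitosis defines clock 0; the founder itself divides at
# clock 0 with the mode drawn there.
.sim_lineage_core <- function(cycle, schedule) {
  shape <- cycle$shape; scale <- cycle$scale; refr <- cycle$refractory_h
  breaks <- schedule$breaks; probs <- schedule$probs
  cap <- 64L
  parent <- rep(NA_integer_, cap); birth <- numeric(cap)
  divt <- rep(NA_real_, cap); mode <- rep(NA_character_, cap)
  stage <- rep(NA_character_, cap); gen <- integer(cap)
  birth[1L] <- 0; divt[1L] <- 0; stage[1L] <- "I0"; gen[1L] <- 0L
  n <- 1L
  todo <- integer(64L); todo[1L] <- 1L; head <- 1L; tail <- 1L
  while (head <= tail) {
    i <- todo[head]; head <- head + 1L
    t <- divt[i]
    w <- findInterval(t, breaks) + 1L
    m <- sample.int(3L, 1L, prob = probs[w, ])   # 1 PP, 2 PD, 3 DD
    mode[i] <- c("PP", "PD", "DD")[m]
    n_prolif <- c(2L, 1L, 0L)[m]
    if (n + 2L > cap) {
      cap <- cap * 2L
      parent <- c(parent, rep(NA_integer_, cap)); birth <- c(birth, numeric(cap))
      divt <- c(divt, rep(NA_real_, cap)); mode <- c(mode, rep(NA_character_, cap))
      stage <- c(stage, rep(NA_character_, cap)); gen <- c(gen, integer(cap))
      cap <- length(parent)
    }
    for (k in 1:2) {
      n <- n + 1L
      parent[n] <- i; birth[n] <- t
      if (k <= n_prolif) {
        gen[n] <- gen[i] + 1L
        stage[n] <- paste0("I", min(gen[n], 3L))
        divt[n] <- t + refr + stats::rgamma(1L, shape = shape, scale = scale)
        tail <- tail + 1L
        if (tail > length(todo)) todo <- c(todo, integer(length(todo)))
        todo[tail] <- n
      } else {
        stage[n] <- "D"
      }
    }
  }
  list(parent = parent[seq_len(n)], birth = birth[seq_len(n)],
       divt = divt[seq_len(n)], mode = mode[seq_len(n)],
       stage = stage[seq_len(n)], n = n)
}

#' Simulate an embryonic retinal progenitor lineage
#'
#' Monte Carlo simulation of one clone: the founder progenitor divides at
#' internal clock 0 with a mode drawn from the schedule at clock 0; each
#' proliferative daughter divides one shifted-gamma cycle later with a mode
#' drawn at its own division clock. Daughters fated to differentiate become
#' leaves (stage `D`). The simulation halts when no proliferative cells
#' remain; halting is guaranteed because the terminal schedule window has
#' positive DD probability.
#'
#' @param cycle [cell_cycle_params()].
#' @param schedule [mode_schedule()].
#' @return A `lineage` data frame (see [prototypical_lineage()] for the
#'   column layout).
#' @examples
#' set.seed(7)
#' lin <- simulate_embryonic_lineage()
#' c(leaves = n_leaves(lin), divisions = count_divisions(lin))
#' @export
simulate_embryonic_lineage <- function(cycle = cell_cycle_params(),
                                       schedule = mode_schedule()) {
  stopifnot(inherits(cycle, "cell_cycle_params"),
            inherits(schedule, "mode_schedule"))
  s <- .sim_lineage_core(cycle, schedule)
  .new_lineage(seq_len(s$n), s$parent, s$birth, s$divt, s$mode, s$stage)
}

#' Number of differentiated leaves in a lineage
#'
#' @param lineage A `lineage` data frame.
#' @return Integer leaf count (cells that never divide).
#' @export
n_leaves <- function(lineage) {
  sum(!lineage$node_id %in% lineage$parent_id)
}

#' Count divisions in a lineage
#'
#' Every division creates two daughters from one mother, so a well-formed
#' binary lineage satisfies `leaves = divisions + 1`; a clone of 12
#' differentiated cells is the outcome of 11 divisions.
#'
#' @param lineage A `lineage` data frame.
#' @return Integer number of internal (dividing) nodes.
#' @export
count_divisions <- function(lineage) {
  kids <- table(lineage$parent_id[!is.na(lineage$parent_id)])
  if (any(kids != 2L))
    stop("malformed lineage: every dividing cell must have exactly 2 daughters")
  length(kids)
}

#' The prototypical 12-cell progenitor lineage
#'
#' The deterministic scheme that summarises average proliferative behaviour:
#' the initial progenitor (I0) divides PP into two primary progenitors (I1),
#' which divide PP into four secondary progenitors (I2); each I2 divides PD,
#' giving four tertiary progenitors (I3) and four differentiated cells; each
#' I3 divides DD. Four rounds of mitoses, 11 divisions, 12 differentiated
#' cells. Clocks use the idealised 6 h cycle (rounds at 0, 6, 12, 18 h).
#'
#' @return A `lineage` data frame of 23 nodes.
#' @export
prototypical_lineage <- function() {
  id <- 1L; rows <- list()
  add <- function(parent, birth, divt, mode, stage) {
    r <- list(node_id = id, parent_id = parent, birth = birth, divt = divt,
              mode = mode, stage = stage)
    rows[[length(rows) + 1L]] <<- r
    id <<- id + 1L
    r$node_id
  }
  i0 <- add(NA_integer_, 0, 0, "PP", "I0")
  i1 <- vapply(1:2, function(k) add(i0, 0, 6, "PP", "I1"), integer(1))
  i2 <- unlist(lapply(i1, function(p)
    vapply(1:2, function(k) add(p, 6, 12, "PD", "I2"), integer(1))))
  i3 <- integer(0)
  for (p in i2) {
    i3 <- c(i3, add(p, 12, 18, "DD", "I3"))
    add(p, 12, NA_real_, NA_character_, "D")
  }
  for (p in i3) for (k in 1:2) add(p, 18, NA_real_, NA_character_, "D")
  .new_lineage(vapply(rows, `[[`, integer(1), "node_id"),
               vapply(rows, `[[`, integer(1), "parent_id"),
               vapply(rows, `[[`, numeric(1), "birth"),
               vapply(rows, `[[`, numeric(1), "divt"),
               vapply(rows, `[[`, character(1), "mode"),
               vapply(rows, `[[`, character(1), "stage"))
}

#' Assign fates to the differentiated leaves of a lineage
#'
#' Leaf fates are drawn i.i.d. from a marginal fate table. This is a
#' generative convenience for synthetic data, not a mechanistic fate model.
#'
#' @param lineage A `lineage` data frame.
#' @param fate_probs Named probability vector over [FATES] (normalised
#'   internally).
#' @return The lineage with the `fate` column filled for leaves.
#' @export
assign_fates <- function(lineage, fate_probs = default_fate_probs()) {
  stopifnot(all(names(fate_probs) %in% FATES))
  leaf <- !lineage$node_id %in% lineage$parent_id
  lineage$fate[leaf] <- sample(names(fate_probs), sum(leaf), replace = TRUE,
                               prob = fate_probs)
  lineage
}

#' @rdname lineage_io
#' @export
write_lineage <- function(lineage, path, header = NULL) {
  .write_tsv(as.data.frame(lineage)[LINEAGE_COLS], path, header)
}

#' Read and write lineage tables
#'
#' Lineages are stored as TSV with columns `node_id`, `parent_id`,
#' `birth_clock_h`, `division_clock_h`, `mode`, `stage`, `fate`. Lines
#' starting with `#` are provenance comments.
#'
#' @param lineage A `lineage` data frame.
#' @param path File path.
#' @param header Optional character vector of provenance comment lines.
#' @return `read_lineage` returns a `lineage` data frame; `write_lineage`
#'   returns `path` invisibly.
#' @name lineage_io
#' @export
read_lineage <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(LINEAGE_COLS %in% names(d)))
  .new_lineage(d$node_id, d$parent_id, d$birth_clock_h, d$division_clock_h,
               as.character(d$mode), as.character(d$stage), as.character(d$fate))
}

#' Serialise a lineage as a newick-like tree string
#'
#' Node labels carry the stage and birth clock (`stage_clock`); branch
#' lengths are lifetimes in hours (division or last clock minus birth).
#'
#' @param lineage A `lineage` data frame.
#' @return A single newick string terminated by `;`.
#' @export
as_newick <- function(lineage) {
  kids <- split(lineage$node_id, factor(lineage$parent_id, levels = lineage$node_id))
  end_clock <- ifelse(is.na(lineage$division_clock_h),
                      max(lineage$division_clock_h, na.rm = TRUE),
                      lineage$division_clock_h)
  lab <- sprintf("%s_%g", lineage$stage, lineage$birth_clock_h)
  rec <- function(i) {
    ch <- kids[[i]]
    len <- max(end_clock[i] - lineage$birth_clock_h[i], 0)
    if (length(ch) == 0) return(sprintf("%s:%g", lab[i], len))
    sprintf("(%s,%s)%s:%g", rec(ch[1]), rec(ch[2]), lab[i], len)
  }
  root <- lineage$node_id[is.na(lineage$parent_id)]
  paste0(rec(root), ";")
}
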