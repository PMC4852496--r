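# Clonal statistics over flat clone tables: records of
# (clone_id, cell_id, fate, ring, timepoint_dpf, source) where fate is one of
# RGC/AC/BC/HC/PR/MG or "P" for a still-proliferative cell (which must carry
# a ring), and source distinguishes CMZ clones from central-retina reference
# clones.

CLONE_COLS <- c("clone_id", "cell_id", "fate", "ring", "timepoint_dpf", "source")

#' Validate a clone table
#'
#' Checks the schema used by all clonal statistics: required columns, fates
#' from the fixed vocabulary (plus `"P"`), rings present for proliferative
#' cells, nonempty clone groups.
#'
#' @param tab Clone table data frame.
#' @return `tab`, invisibly; errors on violation.
#' @export
validate_clone_table <- function(tab) {
  miss <- setdiff(CLONE_COLS, names(tab))
  if (length(miss)) stop("clone table missing columns: ", paste(miss, collapse = ", "))
  bad <- !tab$fate %in% c(FATES, "P")
  if (any(bad)) stop("unknown fates: ", paste(unique(tab$fate[bad]), collapse = ", "))
  if (any(tab$fate == "P" & is.na(tab$ring)))
    stop("proliferative (P) cells must carry a ring")
  if (any(!nzchar(as.character(tab$clone_id))))
    stop("clone ids must be nonempty")
  invisible(tab)
}

#' Classify a clone as terminated, maintained or mixed
#'
#' A clone is `terminated` when all its cells are differentiated (no `P`
#' cells), `maintained` when all cells are still proliferative and in the
#' CMZ, and `mixed` otherwise.
#'
#' @param fates Character vector of cell fates for one clone (values in
#'   [FATES] or `"P"`).
#' @return One of `"terminated"`, `"maintained"`, `"mixed"`.
#' @export
classify_clone <- function(fates) {
  if (!length(fates)) stop("empty clone")
  nP <- sum(fates == "P")
  if (nP == 0) "terminated" else if (nP == length(fates)) "maintained" else "mixed"
}

#' Clone-class summary of a clone table
#'
#' Classifies every clone and reports counts and nearest-integer percentages
#' of terminated, maintained and mixed clones.
#'
#' @param tab Clone table.
#' @return List with `class` (named character, per clone), `counts` and
#'   `percent` (named numeric, nearest-integer percentages).
#' @export
clone_class_summary <- function(tab) {
  cls <- vapply(split(as.character(tab$fate), tab$clone_id), classify_clone,
                character(1))
  lv <- c("terminated", "maintained", "mixed")
  counts <- vapply(lv, function(l) sum(cls == l), numeric(1))
  list(class = cls, counts = counts, percent = round(100 * counts / length(cls)))
}

#' Distribution of the most peripheral ring per clone
#'
#' For each clone of the requested class, the most peripheral (lowest) ring
#' occupied at the reference day: the last observed day for maintained
#' clones, the last day with any ringed cell for terminated clones (i.e.
#' before termination). Counts per ring carry one-sigma Poisson intervals.
#'
#' @param tab Clone table with possibly multiple `timepoint_dpf` per clone.
#' @param group `"maintained"` or `"terminated"`.
#' @return Data frame `ring`, `count`, `lo`, `hi`.
#' @export
peripheral_ring_distribution <- function(tab, group = c("maintained", "terminated")) {
  group <- match.arg(group)
  cls <- clone_class_summary(tab)$class
  ids <- names(cls)[cls == group]
  mins <- vapply(ids, function(id) {
    x <- tab[tab$clone_id == id, ]
    ringed <- x[!is.na(x$ring), ]
    if (!nrow(ringed)) return(NA_integer_)
    ref_day <- max(ringed$timepoint_dpf)
    as.integer(min(ringed$ring[ringed$timepoint_dpf == ref_day]))
  }, integer(1))
  mins <- mins[!is.na(mins)]
  rings <- seq_len(max(mins))
  counts <- vapply(rings, function(r) sum(mins == r), numeric(1))
  ci <- poisson_onesigma_ci(counts)
  data.frame(ring = rings, count = counts, lo = ci[, "lower"], hi = ci[, "upper"])
}

#' Fate-pair matrix of two-cell clones
#'
#' Counts the unordered fate pairs of all fully differentiated two-cell
#' clones and normalises the symmetric fate-by-fate matrix to its maximum
#' entry, so the dominant combination is 1 and absent combinations are 0.
#'
#' @param tab Clone table.
#' @return A symmetric `length(FATES)` square matrix, max entry 1 (all zero
#'   if there are no two-cell clones).
#' @export
pair_fate_matrix <- function(tab) {
  m <- matrix(0, length(FATES), length(FATES), dimnames = list(FATES, FATES))
  by_clone <- split(as.character(tab$fate), tab$clone_id)
  for (f in by_clone) {
    if (length(f) != 2 || any(f == "P")) next
    m[f[1], f[2]] <- m[f[1], f[2]] + 1
    if (f[1] != f[2]) m[f[2], f[1]] <- m[f[2], f[1]] + 1
  }
  if (max(m) > 0) m <- m / max(m)
  m
}

#' Conditional fate fraction in three-cell clones
#'
#' Among fully differentiated three-cell clones containing exactly
#' `n_condition` cells of `condition_fate` (default: two photoreceptors), the
#' fraction that also contain at least one cell of a `target_fates` type
#' (default: an amacrine or a ganglion cell).
#'
#' @param tab Clone table.
#' @param condition_fate Fate defining the condition (default `"PR"`).
#' @param n_condition Required count of `condition_fate` cells (default 2).
#' @param target_fates Fates counting as a hit (default `c("AC", "RGC")`).
#' @return Fraction in `[0, 1]`; `NA` with a warning if no clone satisfies
#'   the condition.
#' @export
three_cell_conditional <- function(tab, condition_fate = "PR", n_condition = 2,
                                   target_fates = c("AC", "RGC")) {
  by_clone <- split(as.character(tab$fate), tab$clone_id)
  cond <- Filter(function(f) length(f) == 3 && all(f != "P") &&
                   sum(f == condition_fate) == n_condition, by_clone)
  if (!length(cond)) {
    warning("no three-cell clone satisfies the condition: fraction undefined")
    return(NA_real_)
  }
  mean(vapply(cond, function(f) any(f %in% target_fates), logical(1)))
}

#' Compare the fate composition of large clones between two groups
#'
#' Pools the differentiated cells of all clones with at least `min_size`
#' cells in each group, reports per-fate percentages, and tests each fate for
#' a difference in proportion between groups. The default test is a two-sided
#' two-proportion z-test on pooled cells; `method = "clones"` instead
#' bootstraps clones within groups (respecting the within-clone correlation)
#' and flags fates whose bootstrap interval for the difference excludes 0.
#'
#' @param tab_a,tab_b Clone tables of the two groups (e.g. CMZ clones and
#'   central-retina reference clones).
#' @param min_size Minimum clone size (default 5).
#' @param alpha Significance level (default 0.05).
#' @param method `"cells"` (z-test) or `"clones"` (clone bootstrap).
#' @param boot Bootstrap resamples for `method = "clones"`.
#' @return Data frame `fate`, `pct_a`, `pct_b`, `p_value` (`NA` for the
#'   bootstrap method), `significant`. Fates absent from both groups are
#'   excluded; percentages per group sum to 100.
#' @export
composition_comparison <- function(tab_a, tab_b, min_size = 5, alpha = 0.05,
                                   method = c("cells", "clones"), boot = 2000) {
  method <- match.arg(method)
  pool <- function(tab) {
    by_clone <- split(as.character(tab$fate), tab$clone_id)
    by_clone <- Filter(function(f) sum(f != "P") >= min_size, by_clone)
    lapply(by_clone, function(f) f[f != "P"])
  }
  ca <- pool(tab_a); cb <- pool(tab_b)
  if (!length(ca) || !length(cb)) stop("both groups need clones of >= min_size cells")
  fa <- unlist(ca); fb <- unlist(cb)
  fates <- FATES[FATES %in% c(fa, fb)]
  xa <- vapply(fates, function(f) sum(fa == f), numeric(1))
  xb <- vapply(fates, function(f) sum(fb == f), numeric(1))
  pct_a <- 100 * xa / length(fa)
  pct_b <- 100 * xb / length(fb)
  if (method == "cells") {
    pv <- vapply(seq_along(fates), function(i) {
      suppressWarnings(stats::prop.test(c(xa[i], xb[i]), c(length(fa), length(fb)),
                                        correct = FALSE)$p.value)
    }, numeric(1))
    sig <- pv < alpha
  } else {
    diff_boot <- replicate(boot, {
      ra <- unlist(ca[sample.int(length(ca), replace = TRUE)])
      rb <- unlist(cb[sample.int(length(cb), replace = TRUE)])
      vapply(fates, function(f) mean(ra == f) - mean(rb == f), numeric(1))
    })
    qs <- apply(diff_boot, 1, stats::quantile,
                probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
    sig <- qs[1, ] > 0 | qs[2, ] < 0
    pv <- rep(NA_real_, length(fates))
  }
  data.frame(fate = fates, pct_a = pct_a, pct_b = pct_b, p_value = pv,
             significant = sig, row.names = NULL)
}

#' @rdname clone_table_io
#' @export
write_clone_table <- function(tab, path, header = NULL) {
  validate_clone_table(tab)
  .write_tsv(as.data.frame(tab)[CLONE_COLS], path, header)
}

#' Read and write clone tables
#'
#' TSV with columns `clone_id`, `cell_id`, `fate`, `ring`, `timepoint_dpf`,
#' `source`; validated on read and write.
#'
#' @param tab Clone table.
#' @param path File path.
#' @param header Optional provenance comment lines.
#' @name clone_table_io
#' @export
read_clone_table <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_clone_table(d)
  d
}
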