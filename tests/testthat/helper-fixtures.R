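# Shared fixtures built in code.

# schedule with a single window (used for closed-form checks)
single_window <- function(pp, pd, dd) {
  mode_schedule(breaks = numeric(0), probs = matrix(c(pp, pd, dd), 1))
}

# a minimal hand-built lineage: founder divides once (DD)
tiny_lineage <- function() {
  structure(
    data.frame(node_id = 1:3, parent_id = c(NA, 1L, 1L),
               birth_clock_h = c(0, 0, 0),
               division_clock_h = c(0, NA, NA),
               mode = c("DD", NA, NA), stage = c("I0", "D", "D"),
               fate = NA_character_, stringsAsFactors = FALSE),
    class = c("lineage", "data.frame"))
}

# clone table with exact per-fate cell counts, one clone per `clone_size` cells
clone_table_from_counts <- function(counts, clone_size = 10, source = "CMZ") {
  cells <- rep(names(counts), counts)
  n <- length(cells)
  # round-robin assignment so clones have mixed composition
  data.frame(clone_id = sprintf("%s_%03d", source,
                                rep_len(seq_len(ceiling(n / clone_size)), n)),
             cell_id = seq_len(n), fate = cells, ring = NA_integer_,
             timepoint_dpf = 5, source = source, stringsAsFactors = FALSE)
}

# clone table with the given numbers of terminated/maintained/mixed clones
clone_table_by_class <- function(n_term, n_maint, n_mixed) {
  rows <- list()
  add <- function(id, fates, rings) {
    rows[[length(rows) + 1L]] <<- data.frame(
      clone_id = id, cell_id = seq_along(fates), fate = fates, ring = rings,
      timepoint_dpf = 5, source = "CMZ", stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_term)) add(sprintf("T%03d", i), c("PR", "PR"), NA_integer_)
  for (i in seq_len(n_maint)) add(sprintf("M%03d", i), c("P", "P"), c(1L, 2L))
  for (i in seq_len(n_mixed)) add(sprintf("X%03d", i), c("P", "PR"), c(3L, NA))
  do.call(rbind, rows)
}
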