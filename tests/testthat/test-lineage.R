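test_that("immediate DD schedule gives two leaves and one division", {
  set.seed(21)
  for (i in 1:20) {
    lin <- simulate_embryonic_lineage(schedule = single_window(0, 0, 1))
    expect_equal(n_leaves(lin), 2)
    expect_equal(count_divisions(lin), 1)
  }
})

test_that("leaves = divisions + 1 on random lineages, with consistent clocks", {
  set.seed(22)
  for (i in 1:1000) {
    lin <- simulate_embryonic_lineage()
    # independent traversal oracle: leaves are nodes never seen as a parent
    leaves <- sum(!lin$node_id %in% lin$parent_id)
    internals <- length(unique(lin$parent_id[!is.na(lin$parent_id)]))
    expect_identical(leaves, internals + 1L)
    expect_identical(count_divisions(lin), internals)
  }

  # structural invariants on a smaller instrumented sample
  for (i in 1:50) {
    lin <- simulate_embryonic_lineage()
    par_row <- match(lin$parent_id, lin$node_id)
    kids <- !is.na(lin$parent_id)
    expect_true(all(lin$birth_clock_h[kids] ==
                      lin$division_clock_h[par_row[kids]]))
    # every cycle at least the refractory period (founder divides at clock 0)
    internal <- !is.na(lin$division_clock_h) & !is.na(lin$parent_id)
    expect_true(all(lin$division_clock_h[internal] -
                      lin$birth_clock_h[internal] >= 4))
    # no mode drawn outside its clock window
    div <- !is.na(lin$mode)
    t <- lin$division_clock_h[div]; m <- lin$mode[div]
    expect_true(all(m[t < 8] == "PP"))
    expect_true(all(m[t >= 15] != "PD"))
  }
})

test_that("mean differentiated cells per initial progenitor is about 12", {
  set.seed(23)
  sizes <- vapply(1:2000, function(i) n_leaves(simulate_embryonic_lineage()),
                  integer(1))
  expect_gte(mean(sizes), 10)
  expect_lte(mean(sizes), 14)
})

test_that("idealized fixed 6 h cycles give the closed-form mean clone size 13.33", {
  set.seed(24)
  cyc <- cell_cycle_params(4, 6, 1e-9)
  m <- mean(vapply(1:3000, function(i) n_leaves(simulate_embryonic_lineage(cyc)),
                   integer(1)))
  # closed form: 4 cells divide at 12 h, each yielding 1.2 + 0.8 * 8/3
  expect_equal(m, 4 * (1.2 + 0.8 * 8 / 3), tolerance = 0.025)
})

test_that("division counting matches the binary-tree identity and rejects malformed trees", {
  lone <- tiny_lineage()[1, ]
  lone$division_clock_h <- NA_real_; lone$mode <- NA_character_; lone$stage <- "D"
  expect_equal(count_divisions(lone), 0)
  expect_equal(count_divisions(tiny_lineage()), 1)

  set.seed(25)
  lin <- simulate_embryonic_lineage()
  while (n_leaves(lin) != 12) lin <- simulate_embryonic_lineage()
  expect_equal(count_divisions(lin), 11)

  broken <- tiny_lineage()[1:2, ]   # a parent with a single child
  expect_error(count_divisions(broken), "2 daughters")
})

test_that("the prototypical lineage has 12 cells from 4 rounds and 11 divisions", {
  pl <- prototypical_lineage()
  expect_equal(n_leaves(pl), 12)
  expect_equal(count_divisions(pl), 11)
  expect_equal(length(unique(pl$division_clock_h[!is.na(pl$division_clock_h)])), 4)
  expect_equal(as.vector(table(pl$stage)[c("I0", "I1", "I2", "I3", "D")]),
               c(1, 2, 4, 4, 12))
  # round structure: 1 + 2 + 4 + 4 divisions
  expect_equal(as.vector(table(pl$division_clock_h)), c(1, 2, 4, 4))
})

test_that("lineages round-trip through TSV and export to parseable newick", {
  set.seed(26)
  lin <- simulate_embryonic_lineage()
  f <- tempfile(fileext = ".tsv")
  write_lineage(lin, f, header = "test")
  lin2 <- read_lineage(f)
  expect_equal(as.data.frame(lin2), as.data.frame(lin))

  skip_if_not_installed("ape")
  tr <- ape::read.tree(text = as_newick(lin))
  expect_equal(ape::Ntip(tr), n_leaves(lin))
})
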