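test_that("clone classification partitions the table and matches printed counts", {
  expect_equal(classify_clone(c("PR", "RGC")), "terminated")
  expect_equal(classify_clone(c("P", "P")), "maintained")
  expect_equal(classify_clone(c("P", "PR", "AC")), "mixed")
  expect_error(classify_clone(character(0)), "empty")

  tab <- clone_table_by_class(104, 11, 3)
  s <- clone_class_summary(tab)
  expect_equal(unname(s$counts), c(104, 11, 3))
  expect_equal(unname(s$percent), c(88, 9, 3))
  expect_equal(sum(s$counts), length(unique(tab$clone_id)))
})

test_that("peripheral-ring distributions separate maintained and terminated clones", {
  # maintained clones keep ring 1-2 cells; terminated clones detach first
  mk <- function(id, day, fates, rings) data.frame(
    clone_id = id, cell_id = seq_along(fates), fate = fates, ring = rings,
    timepoint_dpf = day, source = "CMZ")
  tab <- rbind(
    mk("m1", 5, c("P", "P"), c(1, 3)), mk("m1", 8, c("P", "P"), c(1, 4)),
    mk("m2", 8, c("P", "P"), c(2, 2)),
    mk("t1", 5, c("P", "P"), c(4, 5)), mk("t1", 8, c("PR", "PR"), c(NA, NA)),
    mk("t2", 5, c("P", "PR"), c(3, NA)))
  hm <- peripheral_ring_distribution(tab, "maintained")
  expect_equal(hm$count[hm$ring <= 2], c(1, 1))
  expect_equal(sum(hm$count[hm$ring >= 3]), 0)
  # Poisson bars equal the shared one-sigma interval
  expect_equal(cbind(hm$lo, hm$hi), unname(poisson_onesigma_ci(hm$count)))

  single <- peripheral_ring_distribution(mk("m9", 5, c("P", "P"), c(1, 2)),
                                         "maintained")
  expect_equal(single$count, 1)
  expect_equal(single$ring, 1)
})

test_that("fate-pair matrices are symmetric, max-normalised and find the dominant pair", {
  one <- data.frame(clone_id = "c1", cell_id = 1:2, fate = c("PR", "PR"),
                    ring = NA, timepoint_dpf = 5, source = "CMZ")
  m <- pair_fate_matrix(one)
  expect_equal(m["PR", "PR"], 1)
  expect_equal(sum(m), 1)

  set.seed(71)
  probs <- c(RGC = 0.05, AC = 0.1, BC = 0.15, HC = 0.05, PR = 0.6, MG = 0.05)
  tab <- do.call(rbind, lapply(1:300, function(i)
    data.frame(clone_id = paste0("c", i), cell_id = 1:2,
               fate = sample(names(probs), 2, TRUE, probs), ring = NA,
               timepoint_dpf = 5, source = "CMZ")))
  m <- pair_fate_matrix(tab)
  expect_true(isSymmetric(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(max(m), 1)
  expect_equal(which(m == 1), which(rownames(m) == "PR") * (1 + nrow(m)) - nrow(m))
})

test_that("three-cell conditional fractions recover a planted rate", {
  mk3 <- function(i, third) data.frame(
    clone_id = paste0("c", i), cell_id = 1:3, fate = c("PR", "PR", third),
    ring = NA, timepoint_dpf = 5, source = "CMZ")
  all_rgc <- do.call(rbind, lapply(1:10, mk3, third = "RGC"))
  expect_equal(three_cell_conditional(all_rgc), 1.0)

  set.seed(72)
  thirds <- sample(c("AC", "RGC", "BC"), 200, TRUE, c(0.47, 0.47, 0.06))
  tab <- do.call(rbind, lapply(1:200, function(i) mk3(i, thirds[i])))
  est <- three_cell_conditional(tab)
  expect_equal(est, 0.94, tolerance = 3 * sqrt(0.94 * 0.06 / 200) / 0.94)

  # {PR, PR, BC} counts toward the denominator only
  denom_only <- mk3(1, "BC")
  expect_equal(three_cell_conditional(denom_only), 0)
  # and a PR-PR-PR triple does not satisfy the exactly-two-PR condition
  expect_warning(expect_true(is.na(three_cell_conditional(mk3(1, "PR")))),
                 "undefined")
})

test_that("composition comparison flags only a planted ganglion-cell shift", {
  pa <- c(RGC = 0.12, AC = 0.139, BC = 0.232, HC = 0.074, PR = 0.417, MG = 0.018)
  pb <- c(RGC = 0.05, AC = 0.150, BC = 0.250, HC = 0.080, PR = 0.450, MG = 0.020)
  tab_a <- clone_table_from_counts(round(500 * pa), clone_size = 10, source = "CMZ")
  tab_b <- clone_table_from_counts(round(500 * pb), clone_size = 10, source = "central")
  cc <- composition_comparison(tab_a, tab_b)
  expect_equal(cc$fate[cc$significant], "RGC")
  expect_equal(sum(cc$pct_a), 100)
  expect_equal(sum(cc$pct_b), 100)

  same <- composition_comparison(tab_b, tab_b)
  expect_false(any(same$significant))

  # clone-level bootstrap agrees on the planted shift
  set.seed(73)
  cb <- composition_comparison(tab_a, tab_b, method = "clones")
  expect_true(cb$significant[cb$fate == "RGC"])
})

test_that("clone tables validate their schema and round-trip through TSV", {
  tab <- clone_table_by_class(5, 2, 1)
  f <- tempfile(fileext = ".tsv")
  write_clone_table(tab, f, header = "test")
  tab2 <- read_clone_table(f)
  expect_equal(clone_class_summary(tab2)$counts, clone_class_summary(tab)$counts)

  bad <- tab; bad$fate[1] <- "XX"
  expect_error(validate_clone_table(bad), "unknown fates")
  bad2 <- tab; bad2$fate[1] <- "P"; bad2$ring[1] <- NA
  expect_error(validate_clone_table(bad2), "ring")
})
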