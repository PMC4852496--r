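days <- c(5, 6, 8, 12, 16)

test_that("pure asymmetric division keeps the niche count exactly constant", {
  set.seed(41)
  p <- niche_params(p_asym = 1)
  tr <- simulate_polyclone_cohort(60, p, days)
  expect_true(all(tr$ring12_count == p$n_rsc0))
  expect_true(all(tr$status == "maintained"))
  s <- niche_count_series(tr)
  expect_lte(max(s$mean_ring12) / min(s$mean_ring12), 1.2)
  expect_equal(detachment_rate(tr, c(5, 16)), 0)
})

test_that("alpha = 0 freezes the niche with no RPC production", {
  set.seed(42)
  tr <- simulate_polyclone_cohort(20, niche_params(alpha = 0, n_rsc0 = 3), days)
  expect_true(all(tr$ring12_count == 3))
  expect_true(all(tr$cmz_count == 3))
})

test_that("pure symmetric loss detaches clones at the RSC division rate", {
  set.seed(43)
  # single RSC, no asymmetry, every division removes both daughters:
  # survival at day d is exp(-alpha (d - 5))
  p <- suppressWarnings(   # beta = 0 isolates the RSC loss process
    niche_params(alpha = 0.5, beta = 0, p_asym = 0, p_loss = 1, n_rsc0 = 1))
  tr <- simulate_polyclone_cohort(400, p, c(5, 7, 9))
  surv7 <- mean(tr$status[tr$day == 7] == "maintained")
  surv9 <- mean(tr$status[tr$day == 9] == "maintained")
  expect_equal(surv7, exp(-0.5 * 2), tolerance = 0.12)
  expect_equal(surv9, exp(-0.5 * 4), tolerance = 0.25)
})

test_that("detachment rate reproduces the cases/survivors/days arithmetic", {
  mk <- function(id, s5, s7) data.frame(
    clone_id = id, day = c(5, 7), ring12_count = c(3, ifelse(s7 == "maintained", 3, 0)),
    cmz_count = 3, most_peripheral_ring = 1, status = c(s5, s7))
  tr <- do.call(rbind, c(
    lapply(1:3, function(i) mk(paste0("d", i), "maintained", "terminated")),
    lapply(1:27, function(i) mk(paste0("m", i), "maintained", "maintained"))))
  expect_equal(detachment_rate(tr, c(5, 7)), 3 / 30 / 2)   # 0.05 per day
})

test_that("the estimator recovers a planted per-day detachment hazard", {
  set.seed(44)
  q <- 0.10
  n <- 500
  detach_day <- 5 + rgeom(n, q) + 1   # first day whose interval detaches
  tr <- do.call(rbind, lapply(seq_len(n), function(i) {
    dd <- 5:10
    st <- ifelse(dd < detach_day[i], "maintained", "terminated")
    data.frame(clone_id = paste0("c", i), day = dd,
               ring12_count = ifelse(st == "maintained", 2, 0), cmz_count = 2,
               most_peripheral_ring = 1, status = st)
  }))
  est <- detachment_rate(tr, c(5, 6))
  se <- sqrt(q * (1 - q) / n)
  expect_lt(abs(est - q), 2 * se)
})

test_that("the default asymmetry ramp stops detachment after day 8", {
  set.seed(45)
  tr <- simulate_polyclone_cohort(100, niche_params(), days)
  expect_equal(detachment_rate(tr, c(8, 12)), 0)
  expect_equal(detachment_rate(tr, c(12, 16)), 0)
  # before the ramp completes some clones do detach under the defaults
  expect_gt(detachment_rate(tr, c(5, 8)), 0)
})

test_that("partial asymmetry drifts the niche counts of surviving clones", {
  set.seed(46)
  p <- niche_params(p_asym = 0.7, p_loss = 1, n_rsc0 = 3)
  tr <- simulate_polyclone_cohort(200, p, days)
  s <- niche_count_series(tr)
  expect_lt(s$mean_ring12[s$day == 16], s$mean_ring12[s$day == 5])
})

test_that("censoring marks clones dead and excludes them from the statistics", {
  set.seed(47)
  p <- niche_params(p_asym = 1, censor_prob = 0.5)
  tr <- simulate_polyclone_cohort(40, p, days)
  expect_true(any(tr$status == "dead"))
  dead_ids <- unique(tr$clone_id[tr$status == "dead"])
  for (id in dead_ids) {
    x <- tr[tr$clone_id == id, ]
    # once dead, always dead
    d0 <- min(x$day[x$status == "dead"])
    expect_true(all(x$status[x$day >= d0] == "dead"))
  }
  s <- niche_count_series(tr)
  expect_true(all(s$n_maintained <= 40))
})

test_that("tracks round-trip through TSV", {
  set.seed(48)
  tr <- simulate_polyclone_cohort(5, niche_params(), days)
  f <- tempfile(fileext = ".tsv")
  write_tracks(tr, f, header = "test")
  tr2 <- read_tracks(f)
  expect_equal(tr2$ring12_count, tr$ring12_count)
  expect_equal(tr2$status, tr$status)
})
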