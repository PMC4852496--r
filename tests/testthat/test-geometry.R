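geom <- cmz_geometry(center = c(0, 0, 0), normal = c(0, 0, 1),
                     edge_radius = 100, cell_diameter = 8)

test_that("rings are counted inward from the peripheral edge", {
  expect_equal(assign_ring(c(100, 0, 0), geom), 1L)             # d = 0
  expect_equal(assign_ring(c(100 - 12, 0, 0), geom), 2L)        # floor(12/8)+1
  expect_equal(assign_ring(c(0, 100 - 7.9, 5), geom), 1L)       # out of plane z ignored
  expect_warning(r <- assign_ring(c(105, 0, 0), geom), "clamped")
  expect_equal(r, 1L)
})

test_that("ring assignment is invariant under rigid motions of the scene", {
  set.seed(51)
  for (i in 1:20) {
    pos <- c(runif(1, 60, 99), 0, 0)
    pos <- pos[c(sample(1:2), 3)]
    # random rotation + translation applied to both position and geometry
    th <- runif(3, 0, 2 * pi)
    Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0), c(sin(th[1]), cos(th[1]), 0), c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[2]), -sin(th[2])), c(0, sin(th[2]), cos(th[2])))
    R <- Rx %*% Rz
    shift <- runif(3, -50, 50)
    g2 <- cmz_geometry(center = as.vector(R %*% geom$center) + shift,
                       normal = as.vector(R %*% geom$normal),
                       edge_radius = 100, cell_diameter = 8)
    expect_equal(assign_ring(as.vector(R %*% pos) + shift, g2),
                 assign_ring(pos, geom))
  }
})

test_that("division angles hit the tangent/radial/diagonal constructions exactly", {
  pos <- c(80, 0, 0)
  expect_equal(division_angle(c(0, 1, 0), pos, geom), 0)        # tangent
  expect_equal(division_angle(c(1, 0, 0), pos, geom), 90)       # radial
  expect_equal(division_angle(c(1, 1, 0) / sqrt(2), pos, geom), 45)
  # out-of-plane component is projected away
  expect_equal(division_angle(c(1, 0, 3), pos, geom), 90)
  expect_error(division_angle(c(0, 0, 1), pos, geom), "perpendicular")
})

test_that("division angles are invariant to axis sign flips and in-plane rotations", {
  set.seed(52)
  for (i in 1:20) {
    pos <- c(runif(1, 50, 99) * cos(a <- runif(1, 0, 2 * pi)),
             runif(1, 50, 99) * sin(a), runif(1, -5, 5))
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- division_angle(ax, pos, geom)
    expect_equal(division_angle(-ax, pos, geom), ang)
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    expect_equal(division_angle(as.vector(R %*% ax), as.vector(R %*% pos), geom),
                 ang)
  }
})

test_that("uniform in-plane axes give mean division angle near 45 degrees", {
  set.seed(53)
  phi <- runif(1e4, 0, 2 * pi)
  angs <- vapply(seq_along(phi), function(i)
    division_angle(c(cos(phi[i]), sin(phi[i]), 0), c(90, 0, 0), geom), numeric(1))
  expect_equal(mean(angs), 45, tolerance = 0.02)
})

test_that("one-sigma Poisson intervals match CDF inversion and cover the mean", {
  ci0 <- poisson_onesigma_ci(0)
  expect_equal(unname(ci0[, "lower"]), 0)

  # oracle: brute-force root finding on the Poisson CDF tails
  a <- (1 - 0.6826895) / 2
  lo <- uniroot(function(m) ppois(3, m) - (1 - a), c(1e-9, 20), tol = 1e-9)$root
  hi <- uniroot(function(m) ppois(4, m) - a, c(1e-9, 30), tol = 1e-9)$root
  ci4 <- poisson_onesigma_ci(4)
  expect_equal(as.numeric(ci4), c(lo, hi), tolerance = 1e-5)

  expect_error(poisson_onesigma_ci(-1), "nonnegative")

  # coverage at true mean 5: matches exact enumeration (Garwood intervals
  # are conservative for discrete counts: 74% at mean 5, >= the 68% nominal)
  k <- 0:40
  ci <- poisson_onesigma_ci(k)
  exact <- sum(dpois(k, 5) * (ci[, 1] <= 5 & 5 <= ci[, 2]))
  expect_gte(exact, 0.6827)
  set.seed(54)
  draws <- rpois(1e4, 5)
  cid <- poisson_onesigma_ci(draws)
  mc <- mean(cid[, 1] <= 5 & 5 <= cid[, 2])
  expect_equal(mc, exact, tolerance = 0.02)
})

test_that("per-ring division rates and the 1:13 cytokinesis ratio", {
  ev0 <- data.frame(ring = rep(2, 5))
  r <- division_rate_per_ring(ev0, c(10, 50))
  expect_equal(r$rate, c(0, 0.1))
  expect_equal(r$lo[1], 0)

  # printed counts as inputs: 12 ring-1 vs 153 higher-ring events
  ev <- data.frame(ring = c(rep(1, 12), rep(2, 100), rep(3, 53)))
  expect_equal(ring_division_ratio(ev)$ratio, 13)

  expect_warning(division_rate_per_ring(ev0, c(0, 50)), "omitted")
})

test_that("planted per-ring rates are recovered within the Poisson intervals", {
  set.seed(55)
  cells <- c(200, 300, 300)
  rates <- c(0.05, 0.25, 0.10)
  ev <- gen_division_events(geom, cells_per_ring = cells, rates_per_ring = rates)
  r <- division_rate_per_ring(ev, cells)
  halfwidth <- (r$hi - r$lo) / 2
  expect_true(all(abs(r$rate - rates) <= 3 * halfwidth))
})

test_that("angle box statistics match an order-statistics oracle", {
  same <- data.frame(ring = 1, angle_deg = rep(30, 8))
  s <- angle_by_ring_summary(same)
  expect_equal(s$q1, 30); expect_equal(s$q3, 30)
  expect_equal(s$whisker_lo, 30); expect_equal(s$whisker_hi, 30)

  set.seed(56)
  ev <- data.frame(ring = rep(c(1, 3), each = 60),
                   angle_deg = c(pmin(90, pmax(0, rnorm(60, 90, 10))),
                                 runif(60, 0, 90)))
  s <- angle_by_ring_summary(ev)
  expect_gt(s$median[s$ring == 1], s$median[s$ring == 3])

  x <- sort(ev$angle_deg[ev$ring == 3])
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(unlist(s[s$ring == 3, c("q1", "median", "q3")], use.names = FALSE), q)
  iqr <- q[3] - q[1]
  expect_equal(s$whisker_lo[s$ring == 3], min(x[x >= q[1] - 1.5 * iqr]))
  expect_equal(s$whisker_hi[s$ring == 3], max(x[x <= q[3] + 1.5 * iqr]))
})

test_that("events annotate and round-trip through TSV", {
  set.seed(57)
  ev <- gen_division_events(geom)
  ev2 <- annotate_events(ev, geom)
  expect_equal(ev2$ring, ev$ring)                    # planted ring recovered
  expect_equal(ev2$angle_deg, ev$angle_deg, tolerance = 1e-8)
  f <- tempfile(fileext = ".tsv")
  write_events(ev2, f, header = "test")
  ev3 <- read_events(f)
  expect_equal(ev3$angle_deg, ev2$angle_deg, tolerance = 1e-6)
})
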