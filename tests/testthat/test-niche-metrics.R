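unit_square <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))

test_that("convex hull area matches simple geometry and the brute oracle", {
  expect_equal(convex_hull_area(unit_square), 1.0)
  expect_equal(convex_hull_area(rbind(c(0, 0), c(2, 0), c(0, 2))), 2.0)
  expect_warning(a <- convex_hull_area(rbind(c(0, 0), c(1, 1), c(2, 2))),
                 "collinear")
  expect_equal(a, 0)
  expect_error(convex_hull_area(rbind(c(0, 0), c(1, 1))), "3 points")
  set.seed(53)
  for (i in 1:20) {
    p <- matrix(rnorm(2 * sample(5:50, 1)), ncol = 2)
    expect_equal(convex_hull_area(p), brute_hull_area(p), tolerance = 1e-9)
  }
})

test_that("standard ellipse area follows the covariance eigenvalues", {
  # equally spaced points on a circle, radius chosen so sample cov = I
  n <- 24
  theta <- 2 * pi * (seq_len(n) - 1) / n
  r <- sqrt(2 * (n - 1) / n)
  p <- r * cbind(cos(theta), sin(theta))
  se <- standard_ellipse(p)
  expect_equal(unname(se$cov), diag(2), tolerance = 1e-12)
  expect_equal(se$SEA, pi, tolerance = 1e-12)
  expect_equal(se$SEAc, pi * (n - 1) / (n - 2), tolerance = 1e-12)

  # consistency: SEA approaches pi * sqrt(det Sigma) for large samples
  set.seed(59)
  Sigma <- matrix(c(1.2, 0.4, 0.4, 0.8), 2)
  x <- MASS::mvrnorm(1e4, c(0, 0), Sigma)
  se2 <- standard_ellipse(x)
  expect_equal(se2$SEA, pi * sqrt(det(Sigma)), tolerance = 0.02)
  # SEAc/SEA identity holds exactly at any n
  expect_equal(se2$SEAc / se2$SEA, (1e4 - 1) / (1e4 - 2), tolerance = 1e-12)
  expect_gt(se2$SEAc, se2$SEA)
  expect_error(standard_ellipse(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("the standard ellipse contains about 39.3% of Gaussian data", {
  set.seed(61)
  x <- MASS::mvrnorm(2e4, c(-19, 9), matrix(c(0.2, 0.05, 0.05, 0.9), 2))
  se <- standard_ellipse(x)
  coverage <- mean(in_ellipse(se, x))
  expect_equal(coverage, 1 - exp(-0.5), tolerance = 0.02)
})

test_that("Layman metrics match fixtures and the double-loop oracle", {
  lm_sq <- layman_metrics(unit_square)
  expect_equal(unname(lm_sq), c(1, 1, sqrt(2) / 2, 1, 0))
  two <- rbind(c(0, 0), c(3, 4))
  lm_two <- layman_metrics(two)
  expect_equal(unname(lm_two), c(4, 3, 2.5, 5, 0))
  expect_error(layman_metrics(rbind(c(0, 0))), "2 points")
  set.seed(67)
  for (i in 1:20) {
    p <- matrix(rnorm(60), 30, 2)
    expect_equal(layman_metrics(p), brute_layman(p), tolerance = 1e-12)
  }
})

test_that("geometry is invariant under translation and rotation", {
  set.seed(71)
  p <- matrix(rnorm(40), 20, 2)
  shift <- c(5.3, -2.1)
  ps <- sweep(p, 2, shift, "+")
  expect_equal(convex_hull_area(ps), convex_hull_area(p), tolerance = 1e-10)
  expect_equal(standard_ellipse(ps)$SEA, standard_ellipse(p)$SEA,
               tolerance = 1e-10)
  lm0 <- layman_metrics(p); lms <- layman_metrics(ps)
  expect_equal(lms[c("CD", "MNND", "SDNND", "NR", "CR")],
               lm0[c("CD", "MNND", "SDNND", "NR", "CR")], tolerance = 1e-10)
  # delta-13C-only translation leaves NR untouched (and vice versa)
  px <- sweep(p, 2, c(3, 0), "+")
  expect_equal(layman_metrics(px)[["NR"]], lm0[["NR"]])
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  pr <- p %*% R
  expect_equal(convex_hull_area(pr), convex_hull_area(p), tolerance = 1e-9)
  expect_equal(standard_ellipse(pr)$SEA, standard_ellipse(p)$SEA,
               tolerance = 1e-9)
  expect_equal(layman_metrics(pr)[["CD"]], lm0[["CD"]], tolerance = 1e-9)
  expect_equal(layman_metrics(pr)[["MNND"]], lm0[["MNND"]], tolerance = 1e-9)
})

test_that("Bayesian SEA posterior is deterministic and concentrates", {
  set.seed(73)
  x <- MASS::mvrnorm(400, c(0, 0), diag(c(0.3, 1)))
  a <- sea_bayesian(x, n_draws = 2000, seed = 5)
  b <- sea_bayesian(x, n_draws = 2000, seed = 5)
  expect_identical(a$draws, b$draws)
  se <- standard_ellipse(x)
  expect_equal(a$median, se$SEAc, tolerance = 0.05)
  expect_error(sea_bayesian(x, n_draws = 50), "100 draws")
  # minimal n: wide interval, flagged
  small <- sea_bayesian(x[1:4, ], n_draws = 1000, seed = 1)
  expect_true(small$flag_diffuse)
  expect_gt(diff(small$ci) / small$median, diff(a$ci) / a$median)
})

test_that("ellipse overlap handles containment, identity and disjointness", {
  mk <- function(center, cov, n = 1e6) {
    structure(list(center = center, cov = cov, n = n,
                   SEA = pi * sqrt(det(cov)),
                   SEAc = pi * sqrt(det(cov)) * (n - 1) / (n - 2)),
              class = "standard_ellipse")
  }
  circle1 <- mk(c(0, 0), diag(2))
  circle2 <- mk(c(0, 0), 4 * diag(2))
  ov <- ellipse_overlap(circle1, circle2)
  expect_equal(ov$overlap, pi, tolerance = 0.005)
  expect_equal(ov$pct_a, 100, tolerance = 0.5)
  same <- ellipse_overlap(circle1, circle1)
  expect_equal(same$overlap, circle1$SEAc, tolerance = 0.005 * pi)
  expect_equal(same$pct_a, 100, tolerance = 0.5)
  far <- ellipse_overlap(circle1, mk(c(100, 100), diag(2)))
  expect_equal(far$overlap, 0)
})

test_that("the grouped niche table mirrors the component functions", {
  set.seed(79)
  xy <- rbind(MASS::mvrnorm(30, c(-19, 9), diag(c(0.2, 0.8))),
              MASS::mvrnorm(4, c(-18, 10), diag(c(0.1, 0.4))),
              MASS::mvrnorm(2, c(-20, 8), diag(c(0.1, 0.1))))
  g <- rep(c("big", "small", "tiny"), c(30, 4, 2))
  tab <- niche_metric_table(xy, g, n_draws = 500, seed = 3)
  big <- tab[tab$group == "big", ]
  expect_equal(big$TA, convex_hull_area(xy[1:30, ]))
  expect_equal(big$SEAc, standard_ellipse(xy[1:30, ])$SEAc)
  expect_false(big$small_n_flag)
  small <- tab[tab$group == "small", ]
  expect_true(small$small_n_flag)
  expect_false(is.na(small$SEAc))
  tiny <- tab[tab$group == "tiny", ]
  expect_true(is.na(tiny$TA))           # hull suppressed below 3 points
  expect_false(is.na(tiny$NR))          # ranges still reported
})
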