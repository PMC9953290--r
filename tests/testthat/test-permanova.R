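test_that("one-way PERMANOVA on Euclidean univariate data equals ANOVA", {
  set.seed(11)
  for (i in 1:10) {
    y <- rnorm(24, mean = rep(c(0, 0.5, 1), each = 8))
    g <- rep(c("a", "b", "c"), each = 8)
    f_classic <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
    res <- permanova_oneway(euclidean_matrix(y), g, n_perm = 99)
    expect_equal(res$table$pseudoF[1], f_classic, tolerance = 1e-9)
    # df bookkeeping
    expect_equal(res$table$df, c(2, 21, 23))
    expect_equal(sum(res$table$SS[1:2]), res$table$SS[3])
  }
})

test_that("pseudo-F agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(3)
  m <- matrix(rpois(20 * 6, 4), 20, 6)
  g <- rep(c("A", "B"), each = 10)
  mine <- permanova_oneway(bray_curtis_matrix(m), g, n_perm = 99)
  ref <- vegan::adonis2(vegan::vegdist(log1p(m)) ~ g, permutations = 99)
  expect_equal(mine$table$pseudoF[1], ref$F[1], tolerance = 1e-9)
  expect_equal(mine$table$SS[1], ref$SumOfSqs[1], tolerance = 1e-9)
})

test_that("no effect gives large p, strong separation gives minimal p", {
  set.seed(21)
  # the two groups share identical rows: zero between-group signal
  block <- matrix(rpois(30, 4), 5, 6)
  m <- rbind(block, block, block, block)
  g <- rep(c("A", "B"), each = 10)
  res1 <- permanova_oneway(bray_curtis_matrix(m), g, n_perm = 199)
  expect_gt(res1$table$p_perm[1], 0.05)
  # well-separated clouds
  cl <- gaussian_clouds(n = 10, shift = 8)
  res2 <- permanova_oneway(euclidean_matrix(cl$x), cl$groups, n_perm = 999)
  expect_equal(res2$table$p_perm[1], 1 / 1000, tolerance = 1e-12)
  # same distribution: p should not be extreme
  cl0 <- gaussian_clouds(n = 10, shift = 0)
  res0 <- permanova_oneway(euclidean_matrix(cl0$x), cl0$groups, n_perm = 999)
  expect_gt(res0$table$p_perm[1], 0.05)
})

test_that("p-values never reach zero and ties count as exceedances", {
  # identical samples: degenerate, reported as no-test
  m <- matrix(1, 8, 3)
  res <- permanova_oneway(euclidean_matrix(m), rep(c("a", "b"), each = 4),
                          n_perm = 99)
  expect_true(is.na(res$table$pseudoF[1]))
  # general case: p >= 1/(n_perm + 1)
  set.seed(1)
  cl <- gaussian_clouds(n = 5, shift = 1)
  res2 <- permanova_oneway(euclidean_matrix(cl$x), cl$groups, n_perm = 99)
  expect_gte(res2$table$p_perm[1], 1 / 100)
  expect_lte(res2$table$p_perm[1], 1)
})

test_that("degenerate designs are rejected", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(permanova_oneway(euclidean_matrix(x), c("a", "a", "a", "a", "b"),
                                n_perm = 9), "fewer than 2")
  expect_error(permanova_oneway(euclidean_matrix(x), rep("a", 5),
                                n_perm = 9), "2 groups")
})

test_that("tests are invariant to sample order and label names", {
  set.seed(9)
  cl <- gaussian_clouds(n = 8, shift = 2)
  D <- euclidean_matrix(cl$x)
  f1 <- permanova_oneway(D, cl$groups, n_perm = 49)$table$pseudoF[1]
  perm <- sample(16)
  Dp <- euclidean_matrix(cl$x[perm, ])
  f2 <- permanova_oneway(Dp, cl$groups[perm], n_perm = 49)$table$pseudoF[1]
  expect_equal(f1, f2, tolerance = 1e-10)
  renamed <- ifelse(cl$groups == "A", "zebra", "yak")
  f3 <- permanova_oneway(D, renamed, n_perm = 49)$table$pseudoF[1]
  expect_equal(f1, f3, tolerance = 1e-12)
})

test_that("rejection rate grows with effect size", {
  set.seed(33)
  shift <- c(0, 1, 3)
  rates <- vapply(shift, function(s) {
    rej <- vapply(1:40, function(r) {
      cl <- gaussian_clouds(n = 8, shift = s)
      p <- permanova_oneway(euclidean_matrix(cl$x), cl$groups,
                            n_perm = 99, seed = r)$table$p_perm[1]
      p <= 0.05
    }, logical(1))
    mean(rej)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.2)
  expect_gt(rates[3], 0.9)
})

test_that("nested design df match textbook nested ANOVA", {
  set.seed(2)
  # 3 species x 2 areas x 4 replicates, balanced
  fixed <- rep(c("sp1", "sp2", "sp3"), each = 8)
  nested <- rep(rep(c("n", "s"), each = 4), times = 3)
  x <- matrix(rnorm(24 * 2), 24, 2)
  res <- permanova_nested(euclidean_matrix(x), fixed, nested, n_perm = 99)
  expect_equal(res$table$df, c(2, 3, 18, 23))
  expect_equal(sum(res$table$SS[1:3]), res$table$SS[4], tolerance = 1e-9)
  # univariate check against classical nested mixed-model F
  y <- rnorm(24)
  resu <- permanova_nested(euclidean_matrix(y), fixed, nested, n_perm = 99)
  cellf <- factor(paste(fixed, nested))
  a <- stats::anova(stats::lm(y ~ factor(fixed) + cellf))
  ms_sp <- a$`Mean Sq`[1]; ms_cell <- a$`Mean Sq`[2]; ms_res <- a$`Mean Sq`[3]
  expect_equal(resu$table$pseudoF[1], ms_sp / ms_cell, tolerance = 1e-9)
  expect_equal(resu$table$pseudoF[2], ms_cell / ms_res, tolerance = 1e-9)
})

test_that("nested PERMANOVA degenerates gracefully on identical samples", {
  x <- matrix(2, 12, 2)
  fixed <- rep(c("a", "b"), each = 6)
  nested <- rep(rep(c("x", "y"), each = 3), 2)
  res <- permanova_nested(euclidean_matrix(x), fixed, nested, n_perm = 49)
  expect_true(all(is.na(res$table$pseudoF)))
  expect_true(all(is.na(res$table$p_perm)))
})

test_that("nested PERMANOVA detects a species effect against area noise", {
  set.seed(14)
  # species centroids far apart, areas pure noise; enough cells that the
  # cell-reallocation null has resolution below 5%
  fixed <- rep(c("sp1", "sp2", "sp3"), each = 12)
  nested <- rep(rep(c("n", "c", "s"), each = 4), 3)
  x <- matrix(rnorm(36 * 2, sd = 1), 36, 2)
  x[fixed == "sp2", ] <- x[fixed == "sp2", ] + 4
  x[fixed == "sp3", ] <- x[fixed == "sp3", ] + 8
  res <- permanova_nested(euclidean_matrix(x), fixed, nested, n_perm = 199)
  expect_lte(res$table$p_perm[1], 0.05)
})

test_that("pairwise comparisons run per level pair with optional Holm", {
  set.seed(4)
  x <- rbind(matrix(rnorm(20), 10, 2),
             matrix(rnorm(20, 5), 10, 2),
             matrix(rnorm(20, 10), 10, 2))
  g <- rep(c("a", "b", "c"), each = 10)
  pw <- permanova_pairwise(euclidean_matrix(x), g, n_perm = 199)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_perm <= 0.05))
  pw2 <- permanova_pairwise(euclidean_matrix(x), g, n_perm = 199,
                            adjust = "holm")
  expect_true(all(pw2$p_adjusted >= pw2$p_perm))
})
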