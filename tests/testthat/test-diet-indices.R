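test_that("stomach fullness follows the weight ratio and empty threshold", {
  expect_equal(stomach_fullness(1, 100), 1.0)
  expect_equal(stomach_fullness(0, 50), 0.0)
  expect_true(is_empty_stomach(stomach_fullness(0, 50)))
  f <- stomach_fullness(0.2, 45)
  expect_equal(f, 100 * 0.2 / 45)
  expect_true(is_empty_stomach(f))          # 0.444% < 0.5%
  expect_false(is_empty_stomach(stomach_fullness(0.5, 45)))
  expect_error(stomach_fullness(1, 0), "positive")
  expect_error(stomach_fullness(-1, 10), "non-negative")
})

test_that("diet index table matches the hand-computed worked example", {
  # 10 stomachs; taxon A in 5 stomachs (50 ind, 10 g), B in 2 (50 ind, 30 g)
  prey <- rbind(
    data.frame(specimen_id = paste0("s", 1:5), taxon = "A",
               count = 10, weight = 2),
    data.frame(specimen_id = paste0("s", 1:2), taxon = "B",
               count = 25, weight = 15)
  )
  tab <- diet_index_table(prey, n_stomachs = 10)
  tab <- tab[order(tab$taxon), ]
  expect_equal(tab$pF, c(50, 20))
  expect_equal(tab$pN, c(50, 50))
  expect_equal(tab$pW, c(25, 75))
  expect_equal(tab$IRI, c(3750, 2500))
  expect_equal(tab$pIRI, c(60, 40))
})

test_that("single-taxon and empty groups behave", {
  one <- data.frame(specimen_id = "s1", taxon = "A", count = 3, weight = 1)
  expect_equal(diet_index_table(one, n_stomachs = 4)$pIRI, 100)
  none <- one[0, ]
  expect_error(diet_index_table(none, n_stomachs = 4), "empty")
  neg <- transform(one, weight = -1)
  expect_error(diet_index_table(neg, n_stomachs = 4), "negative")
})

test_that("weight-only fragments count as one individual, with a message", {
  prey <- data.frame(specimen_id = c("s1", "s1"), taxon = c("A", "B"),
                     count = c(5L, 0L), weight = c(1, 2))
  expect_message(tab <- diet_index_table(prey, n_stomachs = 2), "zero count")
  expect_equal(tab$count[tab$taxon == "B"], 1)
})

test_that("indices match a brute-force oracle on random small groups", {
  set.seed(101)
  for (rep in 1:50) {
    fx <- random_prey_table()
    mine <- diet_index_table(fx$prey, n_stomachs = fx$n_stomachs)
    oracle <- brute_diet_table(fx$prey, n_stomachs = fx$n_stomachs)
    mine <- mine[order(mine$taxon), ]
    oracle <- oracle[order(oracle$taxon), ]
    expect_equal(mine$pF, oracle$pF)
    expect_equal(mine$pN, oracle$pN)
    expect_equal(mine$pW, oracle$pW)
    expect_equal(mine$IRI, oracle$IRI)
    expect_equal(mine$pIRI, oracle$pIRI)
    expect_equal(sum(mine$pIRI), 100)
    expect_equal(sum(mine$pN), 100)
    expect_equal(sum(mine$pW), 100)
  }
})

test_that("composition percentages are scale- and order-invariant", {
  set.seed(7)
  fx <- random_prey_table()
  base <- diet_index_table(fx$prey, n_stomachs = fx$n_stomachs)
  k <- 13.7
  scaled <- transform(fx$prey, weight = weight * k)
  tab_s <- diet_index_table(scaled, n_stomachs = fx$n_stomachs)
  expect_equal(tab_s$pW, base$pW)
  expect_equal(tab_s$pIRI, base$pIRI)
  counts_scaled <- transform(fx$prey, count = count * 3L)
  tab_c <- diet_index_table(counts_scaled, n_stomachs = fx$n_stomachs)
  expect_equal(tab_c$pN, base$pN)
  shuffled <- fx$prey[sample(nrow(fx$prey)), ]
  tab_p <- diet_index_table(shuffled, n_stomachs = fx$n_stomachs)
  expect_equal(tab_p, base)
})

test_that("'other' material is dropped unless requested", {
  prey <- data.frame(specimen_id = c("s1", "s2"), taxon = c("A", "scales"),
                     count = c(2L, 1L), weight = c(1, 1),
                     is_other = c(FALSE, TRUE))
  tab <- diet_index_table(prey, n_stomachs = 2)
  expect_equal(tab$taxon, "A")
  tab2 <- diet_index_table(prey, n_stomachs = 2, include_other = TRUE)
  expect_equal(sort(tab2$taxon), c("A", "scales"))
})

test_that("Shannon diversity matches direct evaluation", {
  expect_equal(shannon_diversity(c(5, 5)), log(2))
  expect_equal(shannon_diversity(10), 0)
  p <- (1:3) / 6
  expect_equal(shannon_diversity(c(1, 2, 3)), -sum(p * log(p)))
  expect_equal(round(shannon_diversity(c(1, 2, 3)), 4), 1.0114)
  expect_error(shannon_diversity(numeric(0)), "undefined")
  expect_error(shannon_diversity(c(0, 0)), "undefined")
  # bounded by log of taxon count
  set.seed(2)
  for (i in 1:20) {
    x <- rpois(sample(2:6, 1), 4) + 1
    h <- shannon_diversity(x)
    expect_gte(h, 0)
    expect_lte(h, log(length(x)) + 1e-12)
  }
})

test_that("per-stomach diversity supports count and biomass bases", {
  prey <- data.frame(specimen_id = c("s1", "s1", "s2"),
                     taxon = c("A", "B", "A"),
                     count = c(1L, 1L, 4L), weight = c(10, 1, 2))
  hc <- stomach_diversity(prey)
  expect_equal(hc$H[hc$specimen_id == "s1"], log(2))
  expect_equal(hc$H[hc$specimen_id == "s2"], 0)
  hw <- stomach_diversity(prey, basis = "weight")
  p <- c(10, 1) / 11
  expect_equal(hw$H[hw$specimen_id == "s1"], -sum(p * log(p)))
})

test_that("biomass pivot aggregates and zero-fills", {
  prey <- data.frame(specimen_id = c("s1", "s1", "s2"),
                     taxon = c("A", "A", "B"),
                     count = 1L, weight = c(1, 2, 5))
  m <- prey_biomass_matrix(prey)
  expect_equal(m["s1", "A"], 3)
  expect_equal(m["s1", "B"], 0)
  expect_equal(m["s2", "B"], 5)
})
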