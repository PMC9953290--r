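# Compact scenario builders used across tests.

# Single-species, single-area scenario with n specimens.
tiny_scenario <- function(n = 20, species = "T. mediterraneus",
                          area = "North", empty_rate = 0.2,
                          mix = c(0.1, 0.8, 0.1),
                          mu = c(-18.9, 9.8), sigma = diag(c(0.16, 0.64)),
                          slopes = c(0, 0), dirichlet_conc = 5,
                          profile = NULL, seed = 1L) {
  base <- default_scenario(seed)
  cc <- data.frame(species = species, area = area, stratum = "inshore",
                   sex = "ND", n = as.integer(n))
  mixm <- base$size_class_mix
  mixm[species, ] <- mix
  er <- base$empty_rate
  er[species] <- empty_rate
  ip <- base$isotope_params
  ip[[species]][[area]] <- list(mu = mu, sigma = sigma)
  sl <- base$tl_slopes
  sl[[species]] <- slopes
  pp <- base$prey_profiles
  if (!is.null(profile)) pp[[species]][[area]] <- profile
  scenario_config(cell_counts = cc, size_class_mix = mixm,
                  empty_rate = er, prey_catalogue = base$prey_catalogue,
                  prey_profiles = pp, isotope_params = ip, tl_slopes = sl,
                  dirichlet_conc = dirichlet_conc, seed = seed)
}

# Random small prey table (<= max_stomachs stomachs, <= max_taxa taxa).
random_prey_table <- function(max_stomachs = 6, max_taxa = 4) {
  n_st <- sample(2:max_stomachs, 1)
  n_tx <- sample(2:max_taxa, 1)
  taxa <- paste0("tax", seq_len(n_tx))
  rows <- list()
  for (s in seq_len(n_st)) {
    present <- which(stats::runif(n_tx) < 0.7)
    if (length(present) == 0) present <- sample(n_tx, 1)
    for (k in present) {
      rows[[length(rows) + 1]] <- data.frame(
        specimen_id = paste0("s", s), taxon = taxa[k],
        count = sample(1:20, 1),
        weight = round(stats::runif(1, 0.05, 5), 3))
    }
  }
  list(prey = do.call(rbind, rows), n_stomachs = n_st)
}

# Two Gaussian clouds in 2-D as a biomass-free distance fixture.
gaussian_clouds <- function(n = 10, shift = 3, sd = 1) {
  x <- rbind(matrix(stats::rnorm(2 * n, 0, sd), ncol = 2),
             matrix(stats::rnorm(2 * n, shift, sd), ncol = 2))
  list(x = x, groups = rep(c("A", "B"), each = n))
}
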