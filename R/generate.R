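# Synthetic survey data generators. Each stage draws from its own derived
# RNG stream so specimens, stomachs and isotopes can be regenerated
# independently from the same root seed.

size_class_of <- function(tl) {
  ifelse(tl < 12, "small", ifelse(tl < 24, "medium", "large"))
}

#' Generate specimen records for a scenario
#'
#' Draws exactly the configured number of specimens per
#' species x area x stratum x sex cell. Total length is sampled from the
#' species size-class mixture (uniform within each band), wet weight follows
#' the configured length-weight power law, and within each cell the
#' undetermined-sex (juvenile) specimens are matched to the smallest fish.
#'
#' @param config a [scenario_config()].
#' @return data.frame with one row per specimen: `id`, `species`, `area`,
#'   `stratum`, `sex`, `TL` (cm), `WW` (g), `size_class`.
#' @export
generate_specimens <- function(config) {
  validate_scenario(config)
  cc <- config$cell_counts
  if (sum(cc$n) == 0) {
    return(data.frame(id = character(), species = character(),
                      area = character(), stratum = character(),
                      sex = character(), TL = numeric(), WW = numeric(),
                      size_class = character(), stringsAsFactors = FALSE))
  }
  set.seed(derive_seed(config$seed, "specimens"))
  out <- vector("list", 0)
  # group cells by species x area x stratum so ND can be mapped to the
  # smallest fish within the physical cell
  key <- interaction(cc$species, cc$area, cc$stratum, drop = TRUE)
  for (k in levels(key)) {
    sub <- cc[key == k, ]
    sp <- sub$species[1]
    n_tot <- sum(sub$n)
    mix <- config$size_class_mix[sp, ]
    cls <- sample(DN_SIZE_CLASSES, n_tot, replace = TRUE, prob = mix)
    tl <- vapply(cls, function(cl) {
      b <- config$size_bands[[cl]]
      # measured to 0.1 cm; keep the rounded value inside the open upper
      # band edge so the drawn class and the TL-derived class agree
      min(round(stats::runif(1, b[1], b[2]), 1), floor(b[2] * 10 - 1) / 10)
    }, numeric(1))
    # juveniles (ND) take the smallest fish in the cell
    sexes <- rep(sub$sex, sub$n)
    ord <- order(tl)
    assigned <- character(n_tot)
    nd <- sum(sexes == "ND")
    assigned[ord[seq_len(nd)]] <- "ND"
    rest <- sample(sexes[sexes != "ND"])
    assigned[ord[seq.int(nd + 1, length.out = n_tot - nd)]] <- rest
    out[[k]] <- data.frame(
      species = sp, area = sub$area[1], stratum = sub$stratum[1],
      sex = assigned, TL = round(tl, 1), stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, out)
  # stable ordering + ids
  df <- df[order(match(df$species, DN_SPECIES), match(df$area, DN_AREAS),
                 match(df$stratum, DN_STRATA), df$TL), ]
  df$id <- sprintf("F%04d", seq_len(nrow(df)))
  df$WW <- round(config$lw_a * df$TL^config$lw_b, 2)
  df$size_class <- size_class_of(df$TL)
  rownames(df) <- NULL
  df[, c("id", "species", "area", "stratum", "sex", "TL", "WW", "size_class")]
}

# One Dirichlet draw with concentration vector alpha (gamma representation).
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) {               # guard against all-zero draw at tiny alpha
    g[which.max(alpha)] <- 1
  }
  g / sum(g)
}

#' Generate stomach-content records for a set of specimens
#'
#' Each stomach is empty (simulated fullness below the 0.5% threshold) with
#' the species' configured probability; otherwise its prey biomass
#' composition is a Dirichlet draw around the species x area expected
#' profile, scaled to a content weight bounded by the configured fullness
#' cap. Prey counts are derived from per-taxon mean individual weights and
#' digestion grades are uniform on 0-3.
#'
#' @param specimens data.frame from [generate_specimens()].
#' @param config a [scenario_config()].
#' @return list with `stomachs` (one row per specimen: `specimen_id`,
#'   `content_weight`, `fullness`, `empty`) and `prey` (long format, one row
#'   per prey record: `specimen_id`, `taxon`, `count`, `weight`,
#'   `digestion`, `is_other`).
#' @export
generate_stomachs <- function(specimens, config) {
  validate_scenario(config)
  set.seed(derive_seed(config$seed, "stomachs"))
  cat_tab <- config$prey_catalogue
  st <- vector("list", nrow(specimens))
  pr <- vector("list", nrow(specimens))
  for (i in seq_len(nrow(specimens))) {
    sp <- specimens$species[i]
    ar <- specimens$area[i]
    ww <- specimens$WW[i]
    is_empty <- stats::runif(1) < config$empty_rate[[sp]]
    if (is_empty) {
      fullness <- stats::runif(1, 0, 0.45)
      cw <- ww * fullness / 100
      st[[i]] <- data.frame(specimen_id = specimens$id[i],
                            content_weight = cw, fullness = fullness,
                            empty = TRUE)
      next
    }
    profile <- config$prey_profiles[[sp]][[ar]]
    if (is.null(profile))
      stop("configuration error: no prey profile for ", sp, " / ", ar)
    shares <- rdirichlet1(config$dirichlet_conc * profile)
    keep <- shares > 1e-6
    shares <- shares[keep] / sum(shares[keep])
    taxa <- names(profile)[keep]
    fullness <- stats::runif(1, 0.6, config$fullness_cap)
    cw <- ww * fullness / 100
    w <- shares * cw
    miw <- cat_tab$mean_ind_weight[match(taxa, cat_tab$taxon)]
    cnt <- 1L + stats::rpois(length(w), w / miw)
    pr[[i]] <- data.frame(
      specimen_id = specimens$id[i], taxon = taxa, count = cnt,
      weight = round(w, 4),
      digestion = sample(0:3, length(taxa), replace = TRUE),
      is_other = cat_tab$is_other[match(taxa, cat_tab$taxon)],
      stringsAsFactors = FALSE
    )
    st[[i]] <- data.frame(specimen_id = specimens$id[i],
                          content_weight = round(cw, 4),
                          fullness = fullness, empty = FALSE)
  }
  stomachs <- do.call(rbind, st)
  prey <- do.call(rbind, pr[!vapply(pr, is.null, logical(1))])
  if (is.null(prey)) {
    prey <- data.frame(specimen_id = character(), taxon = character(),
                       count = integer(), weight = numeric(),
                       digestion = integer(), is_other = logical())
  }
  rownames(stomachs) <- rownames(prey) <- NULL
  list(stomachs = stomachs, prey = prey)
}

#' Generate stable-isotope records for a set of specimens
#'
#' Per specimen, the lipid-corrected-scale (delta-13C, delta-15N) pair is
#' the species x area bivariate-normal mean plus the species' TL slopes
#' applied to `TL - E[TL]` plus correlated Gaussian noise. The C/N ratio is
#' Gaussian, and the emitted `d13C_raw` is back-transformed so that applying
#' the C/N-gated lipid correction recovers the simulated corrected value.
#'
#' @param specimens data.frame from [generate_specimens()].
#' @param config a [scenario_config()].
#' @return data.frame: `specimen_id`, `d13C_raw`, `d15N`, `CN_ratio`.
#' @export
generate_isotopes <- function(specimens, config) {
  validate_scenario(config)
  set.seed(derive_seed(config$seed, "isotopes"))
  n <- nrow(specimens)
  out <- data.frame(specimen_id = specimens$id,
                    d13C_raw = numeric(n), d15N = numeric(n),
                    CN_ratio = numeric(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sp <- specimens$species[i]
    ar <- specimens$area[i]
    par <- config$isotope_params[[sp]][[ar]]
    if (is.null(par))
      stop("configuration error: no isotope parameters for ", sp, " / ", ar)
    slope <- config$tl_slopes[[sp]]
    mu_tl <- tl_moments(config$size_class_mix[sp, ], config$size_bands)$mean
    mu <- par$mu + slope * (specimens$TL[i] - mu_tl)
    z <- MASS::mvrnorm(1, mu = mu, Sigma = par$sigma)
    cn <- stats::rnorm(1, config$cn_mean, config$cn_sd)
    cn <- max(cn, 0.5)
    # emit raw d13C such that the gated correction reproduces z[1]
    d13c_raw <- if (cn > 3) z[1] + 3.32 - 0.99 * cn else z[1]
    out$d13C_raw[i] <- d13c_raw
    out$d15N[i] <- z[2]
    out$CN_ratio[i] <- cn
  }
  out
}

#' Generate a complete synthetic dataset
#'
#' Runs the three generator stages and bundles their output with the
#' scenario for provenance. Every specimen has exactly one stomach record
#' and one isotope record.
#'
#' @param config a [scenario_config()]; defaults to [default_scenario()].
#' @return object of class `synthetic_dataset`: list with `specimens`,
#'   `stomachs`, `prey`, `isotopes`, `config`.
#' @export
generate_dataset <- function(config = default_scenario()) {
  specimens <- generate_specimens(config)
  guts <- generate_stomachs(specimens, config)
  isotopes <- generate_isotopes(specimens, config)
  structure(list(specimens = specimens, stomachs = guts$stomachs,
                 prey = guts$prey, isotopes = isotopes, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic survey dataset:", nrow(x$specimens), "specimens,",
      sum(!x$stomachs$empty), "non-empty stomachs,",
      nrow(x$prey), "prey records\n")
  invisible(x)
}

#' Write a synthetic dataset to CSV files plus a provenance sidecar
#'
#' Writes `specimens.csv`, `stomachs.csv` (long format, one row per prey
#' record, joined with per-stomach totals), `isotopes.csv` and
#' `provenance.yaml` (root seed and scenario summary) into `dir`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$specimens, file.path(dir, "specimens.csv"),
                   row.names = FALSE)
  long <- merge(dataset$stomachs, dataset$prey, by = "specimen_id",
                all.x = TRUE, sort = FALSE)
  long <- long[order(long$specimen_id, long$taxon), ]
  utils::write.csv(long, file.path(dir, "stomachs.csv"), row.names = FALSE)
  utils::write.csv(dataset$isotopes, file.path(dir, "isotopes.csv"),
                   row.names = FALSE)
  cfg <- dataset$config
  prov <- list(
    generator = "dietniche synthetic_data",
    seed = cfg$seed,
    n_specimens = nrow(dataset$specimens),
    species = as.list(table(dataset$specimens$species)),
    empty_rate = as.list(cfg$empty_rate),
    dirichlet_concentration = cfg$dirichlet_conc,
    length_weight = list(a = cfg$lw_a, b = cfg$lw_b)
  )
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(dir)
}
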