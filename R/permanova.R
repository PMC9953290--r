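# Permutational multivariate analysis of variance on a resemblance matrix.
#
# Sums of squares are partitioned directly from squared inter-point
# distances via the Gower-centered matrix G = -0.5 C D^2 C (C the centering
# matrix): the SS explained by a design X is tr(H G) with H the hat matrix
# of X, and tr(G) is the total SS. Pseudo-F statistics are referred to a
# permutation distribution; p-values use the (b + 1)/(m + 1) convention and
# tied statistics count as exceedances, so p is never exactly zero.

gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  rm <- rowMeans(A)
  A - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(A)
}

hat_matrix <- function(f) {
  X <- stats::model.matrix(~f)
  X %*% solve(crossprod(X), t(X))
}

# tr(H G) for the hat matrix of a factor (with intercept): the projection
# onto group means gives tr(HG) = sum_g 1_g' G 1_g / n_g.
tr_hat_factor <- function(G, f) {
  tot <- 0
  for (g in levels(f)) {
    idx <- which(f == g)
    tot <- tot + sum(G[idx, idx]) / length(idx)
  }
  tot
}

perm_pvalue <- function(obs, perm) {
  (sum(perm >= obs - 1e-12) + 1) / (length(perm) + 1)
}

#' One-way PERMANOVA
#'
#' Tests a single (fixed) factor on a resemblance matrix with unrestricted
#' permutation of raw data: group labels are reallocated freely and the
#' pseudo-F recomputed for each permutation.
#'
#' @param D a `distance_matrix` (see [bray_curtis_matrix()],
#'   [euclidean_matrix()]).
#' @param groups factor (or coercible) of group labels, one per sample;
#'   every group needs at least 2 samples.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @return object of class `permanova_result`: ANOVA-style table with df,
#'   SS, MS, pseudo-F and permutation p per term.
#' @export
permanova_oneway <- function(D, groups, n_perm = 9999, seed = 1L) {
  D <- as_distance_matrix(D)
  groups <- factor(groups)
  n <- nrow(D$D)
  stopifnot(length(groups) == n)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2))
    stop("degenerate design: a group has fewer than 2 samples")
  G <- gower_center(D$D)
  SST <- sum(diag(G))
  if (SST < 1e-12) {
    tab <- data.frame(term = c("Group", "Residual", "Total"),
                      df = c(nlevels(groups) - 1, n - nlevels(groups), n - 1),
                      SS = 0, MS = c(0, 0, NA),
                      pseudoF = c(NA, NA, NA), p_perm = c(NA, NA, NA))
    return(structure(list(table = tab, n_perm = n_perm, seed = seed,
                          permutation_scheme = "raw", metric = D$metric,
                          note = "all samples identical; no test"),
                     class = "permanova_result"))
  }
  # tr(HG) minus the intercept-only part (hat of the grand mean is J/n)
  SSA <- tr_hat_factor(G, groups) - sum(G) / n
  df_a <- nlevels(groups) - 1
  df_r <- n - nlevels(groups)
  SSR <- SST - SSA
  f_obs <- (SSA / df_a) / (SSR / df_r)

  # vectorized permutation of labels: SS within from squared distances,
  # SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2
  D2 <- D$D^2
  set.seed(seed)
  f_perm <- numeric(n_perm)
  tot_pair <- sum(D2) / (2 * n)          # = SST
  block <- 500L
  done <- 0L
  lev <- levels(groups)
  ng <- table(groups)
  while (done < n_perm) {
    m <- min(block, n_perm - done)
    P <- replicate(m, sample.int(n))
    ssw <- numeric(m)
    for (g in lev) {
      idx0 <- which(groups == g)
      Z <- matrix(0, n, m)
      Z[cbind(as.vector(P[idx0, , drop = FALSE]),
              rep(seq_len(m), each = length(idx0)))] <- 1
      ssw <- ssw + colSums(Z * (D2 %*% Z)) / (2 * ng[[g]])
    }
    ssa <- tot_pair - ssw
    f_perm[done + seq_len(m)] <- (ssa / df_a) / ((tot_pair - ssa) / df_r)
    done <- done + m
  }
  p <- perm_pvalue(f_obs, f_perm)
  tab <- data.frame(
    term = c("Group", "Residual", "Total"),
    df = c(df_a, df_r, n - 1),
    SS = c(SSA, SSR, SST),
    MS = c(SSA / df_a, SSR / df_r, NA),
    pseudoF = c(f_obs, NA, NA),
    p_perm = c(p, NA, NA)
  )
  structure(list(table = tab, n_perm = n_perm, seed = seed,
                 permutation_scheme = "raw", metric = D$metric),
            class = "permanova_result")
}

#' Nested two-factor mixed-model PERMANOVA
#'
#' Partition for a fixed factor (e.g. species) with a random factor nested
#' within it (e.g. sampling area within species). Following mixed-model
#' expected mean squares, the fixed factor is tested against the
#' nested-factor mean square and the nested factor against the residual.
#' P-values come from permutation of residuals under the reduced model:
#' for the fixed term, whole nested-factor cells are reallocated across the
#' fixed-factor levels (cells are the exchangeable units); for the nested
#' term, Freedman-Lane-style permutation of the residual Gower matrix under
#' the fixed-factor-only model.
#'
#' @param D a `distance_matrix`.
#' @param fixed fixed-factor labels (one per sample).
#' @param nested nested-factor labels (one per sample); each nested level
#'   must occur under exactly one fixed level.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return a `permanova_result` with terms fixed, nested, residual.
#' @export
permanova_nested <- function(D, fixed, nested, n_perm = 9999, seed = 1L) {
  D <- as_distance_matrix(D)
  fixed <- factor(fixed)
  n <- nrow(D$D)
  stopifnot(length(fixed) == n, length(nested) == n)
  # nested levels sharing a name across fixed levels (area "North" under
  # every species) are distinct units; the fixed:nested interaction makes
  # each cell belong to exactly one fixed level
  cell <- factor(paste(fixed, nested, sep = ":"))
  if (nlevels(fixed) < 2) stop("need at least 2 fixed-factor levels")
  if (nlevels(cell) <= nlevels(fixed))
    stop("design error: no fixed level has 2 or more nested levels")
  G <- gower_center(D$D)
  SST <- sum(diag(G))
  df_f <- nlevels(fixed) - 1
  df_n <- nlevels(cell) - nlevels(fixed)
  df_r <- n - nlevels(cell)
  if (df_r <= 0) stop("no residual degrees of freedom")
  if (SST < 1e-12) {
    tab <- data.frame(term = c("fixed", "nested(fixed)", "Residual", "Total"),
                      df = c(df_f, df_n, df_r, n - 1), SS = 0,
                      MS = c(0, 0, 0, NA), pseudoF = NA_real_,
                      p_perm = NA_real_)
    return(structure(list(table = tab, n_perm = n_perm, seed = seed,
                          permutation_scheme = "residuals_reduced",
                          metric = D$metric,
                          note = "all samples identical; no test"),
                     class = "permanova_result"))
  }

  ss_terms <- function(G, fixed, cell) {
    mean_part <- sum(G) / nrow(G)
    ss1 <- tr_hat_factor(G, fixed) - mean_part
    ss12 <- tr_hat_factor(G, cell) - mean_part
    c(fixed = ss1, nested = ss12 - ss1, resid = sum(diag(G)) - ss12)
  }
  ss <- ss_terms(G, fixed, cell)
  ms <- c(ss[["fixed"]] / df_f, ss[["nested"]] / df_n, ss[["resid"]] / df_r)
  f_fixed <- ms[1] / ms[2]
  f_nested <- ms[2] / ms[3]

  set.seed(seed)
  # fixed term: permute the cell-to-fixed-level allocation, keeping cells
  # intact (whole nested units are the exchangeable objects); tr(H12 G)
  # and the grand-mean part do not change under this permutation
  cells <- levels(cell)
  cell_fixed <- fixed[match(cells, cell)]
  mean_part <- sum(G) / n
  ss12 <- tr_hat_factor(G, cell) - mean_part
  f_fixed_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm_map <- sample(cell_fixed)
    fperm <- factor(perm_map[match(cell, cells)])
    ss1p <- tr_hat_factor(G, fperm) - mean_part
    f_fixed_perm[b] <- (ss1p / df_f) / ((ss12 - ss1p) / df_n)
  }
  p_fixed <- perm_pvalue(f_fixed, f_fixed_perm)

  # nested term: Freedman-Lane permutation of the residual Gower matrix
  # under the fixed-factor-only reduced model
  H1 <- hat_matrix(fixed)
  R1 <- diag(n) - H1
  Gres <- R1 %*% G %*% R1
  f_nested_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    Gp <- Gres[p, p]
    ssb <- ss_terms(Gp, fixed, cell)
    f_nested_perm[b] <- (ssb[["nested"]] / df_n) / (ssb[["resid"]] / df_r)
  }
  p_nested <- perm_pvalue(f_nested, f_nested_perm)

  tab <- data.frame(
    term = c("fixed", "nested(fixed)", "Residual", "Total"),
    df = c(df_f, df_n, df_r, n - 1),
    SS = c(ss[["fixed"]], ss[["nested"]], ss[["resid"]], SST),
    MS = c(ms, NA),
    pseudoF = c(f_fixed, f_nested, NA, NA),
    p_perm = c(p_fixed, p_nested, NA, NA)
  )
  structure(list(table = tab, n_perm = n_perm, seed = seed,
                 permutation_scheme = "residuals_reduced",
                 metric = D$metric),
            class = "permanova_result")
}

#' Pairwise one-way PERMANOVA comparisons
#'
#' Runs [permanova_oneway()] restricted to every pair of group levels, with
#' the same permutation scheme. No multiplicity correction is applied by
#' default; Holm adjustment is available.
#'
#' @param D a `distance_matrix`.
#' @param groups factor of group labels.
#' @param n_perm permutations per pair.
#' @param seed integer seed.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame: `group1`, `group2`, `pseudoF`, `p_perm`
#'   (, `p_adjusted`).
#' @export
permanova_pairwise <- function(D, groups, n_perm = 999, seed = 1L,
                               adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  D <- as_distance_matrix(D)
  groups <- factor(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    sel <- groups %in% pairs[, k]
    if (sum(groups[sel] == pairs[1, k]) < 2 ||
        sum(groups[sel] == pairs[2, k]) < 2) return(NULL)
    Dsub <- new_distance_matrix(D$D[sel, sel, drop = FALSE],
                                D$labels[sel], D$metric)
    res <- permanova_oneway(Dsub, droplevels(groups[sel]),
                            n_perm = n_perm, seed = seed + k)
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               pseudoF = res$table$pseudoF[1], p_perm = res$table$p_perm[1])
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_adjusted <- stats::p.adjust(out$p_perm, "holm")
  rownames(out) <- NULL
  out
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s permutation, %d permutations, metric: %s)\n",
              x$permutation_scheme, x$n_perm, x$metric))
  print(transform(x$table, SS = signif(SS, 5), MS = signif(MS, 5),
                  pseudoF = signif(pseudoF, 5)), row.names = FALSE)
  invisible(x)
}
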