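# Canonical analysis of principal coordinates: constrained ordination that
# maximizes group separation in dissimilarity space.

pcoa_coords <- function(D) {
  G <- gower_center(D)
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-8
  Q <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  list(coords = Q, eigenvalues = e$values)
}

#' Canonical analysis of principal coordinates (CAP)
#'
#' Embeds the samples by principal-coordinate analysis, then fits a linear
#' discriminant on the first `m` axes, choosing `m` to maximize
#' leave-one-out allocation success. Returns the discriminant scores and
#' the per-group and overall allocation success, the standard diagnostics
#' for how well putative groups separate in community space.
#'
#' @param D a `distance_matrix`.
#' @param groups factor of group labels.
#' @param m_max upper bound for the number of PCoA axes screened
#'   (default `min(n - g, embedding rank, 20)`).
#' @return object of class `cap_result`: `m` (axes retained), `scores`
#'   (canonical discriminant scores), `allocation` (per-group LOO success,
#'   percent), `overall_success` (percent), `misclassified` ids.
#' @export
cap <- function(D, groups, m_max = NULL) {
  D <- as_distance_matrix(D)
  groups <- factor(groups)
  n <- nrow(D$D)
  g <- nlevels(groups)
  if (n <= g) stop("design error: need more samples than groups")
  pc <- pcoa_coords(D$D)
  Q <- pc$coords
  rank_q <- ncol(Q)
  if (is.null(m_max)) m_max <- min(n - g, rank_q, 20L)
  m_max <- min(m_max, rank_q, n - g)

  loo_success <- function(m) {
    X <- Q[, seq_len(m), drop = FALSE]
    fit <- tryCatch(MASS::lda(X, grouping = groups, CV = TRUE),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    mean(fit$class == groups)
  }
  succ <- vapply(seq_len(m_max), loo_success, numeric(1))
  if (all(is.na(succ))) stop("discriminant analysis failed on all axis counts")
  m <- which.max(succ)            # first maximum: most parsimonious m
  X <- Q[, seq_len(m), drop = FALSE]
  fit <- MASS::lda(X, grouping = groups)
  cv <- MASS::lda(X, grouping = groups, CV = TRUE)
  scores <- stats::predict(fit, X)$x
  alloc <- 100 * diag(prop.table(table(groups, cv$class), 1))
  structure(list(m = m, scores = scores,
                 allocation = alloc,
                 overall_success = 100 * mean(cv$class == groups),
                 misclassified = D$labels[cv$class != groups],
                 screened = data.frame(m = seq_len(m_max),
                                       loo_success = 100 * succ)),
            class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  cat(sprintf("CAP: %d PCoA axes retained, LOO allocation success %.1f%%\n",
              x$m, x$overall_success))
  print(round(x$allocation, 1))
  invisible(x)
}
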