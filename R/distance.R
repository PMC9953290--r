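# Resemblance matrices feeding the permutation tests.

new_distance_matrix <- function(D, labels, metric) {
  dimnames(D) <- list(labels, labels)
  structure(list(labels = labels, D = D, metric = metric),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("%s distance matrix, %d samples\n", x$metric, nrow(x$D)))
  invisible(x)
}

#' Bray-Curtis resemblance matrix of a biomass matrix
#'
#' \eqn{d_{ij} = \sum_k |y_{ik} - y_{jk}| / \sum_k (y_{ik} + y_{jk})},
#' computed (by default) on log(x + 1)-transformed biomasses, the standard
#' treatment that damps the dominance of heavy prey before community
#' comparison. Rows summing to zero have no defined dissimilarity and are
#' dropped with a warning.
#'
#' @param biomass numeric samples x taxa matrix, non-negative.
#' @param transform `"log1p"` (default) or `"none"`.
#' @return a `distance_matrix` with metric `"bray_curtis"`.
#' @export
bray_curtis_matrix <- function(biomass, transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  biomass <- as.matrix(biomass)
  if (any(biomass < 0)) stop("biomass must be non-negative")
  zero <- rowSums(biomass) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s) dropped: ",
            paste(rownames(biomass)[zero], collapse = ", "))
    biomass <- biomass[!zero, , drop = FALSE]
  }
  if (nrow(biomass) < 2) stop("need at least 2 non-empty samples")
  y <- if (transform == "log1p") log1p(biomass) else biomass
  n <- nrow(y)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    di <- y[i, ]
    num <- colSums(abs(t(y[(i + 1):n, , drop = FALSE]) - di))
    den <- colSums(t(y[(i + 1):n, , drop = FALSE]) + di)
    d <- ifelse(den > 0, num / den, 0)
    D[i, (i + 1):n] <- d
    D[(i + 1):n, i] <- d
  }
  labs <- rownames(y)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  new_distance_matrix(D, labs, "bray_curtis")
}

#' Euclidean resemblance matrix
#'
#' Plain Euclidean distances of untransformed data, used for univariate
#' responses (stomach fullness, diet diversity) and for isotope values.
#'
#' @param x numeric vector or samples x variables matrix.
#' @return a `distance_matrix` with metric `"euclidean"`.
#' @export
euclidean_matrix <- function(x) {
  x <- as.matrix(x)
  D <- as.matrix(stats::dist(x))
  labs <- rownames(x)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(x)))
  new_distance_matrix(unname(D), labs, "euclidean")
}

as_distance_matrix <- function(D) {
  if (inherits(D, "distance_matrix")) return(D)
  if (inherits(D, "dist")) {
    m <- as.matrix(D)
    return(new_distance_matrix(unname(m),
                               labels = attr(D, "Labels") %||%
                                 as.character(seq_len(nrow(m))),
                               metric = "euclidean"))
  }
  stop("not a distance matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
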