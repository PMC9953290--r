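# Stomach-content diet indices: fullness, %F, %N, %W, IRI, %IRI, H'.

#' Stomach fullness
#'
#' Feeding-intensity proxy: stomach content weight as a percentage of body
#' weight. Stomachs with fullness below 0.5% are conventionally treated as
#' empty.
#'
#' @param content_weight stomach content weight (g), non-negative.
#' @param body_weight fish wet weight (g), positive.
#' @return fullness in percent.
#' @export
stomach_fullness <- function(content_weight, body_weight) {
  if (any(body_weight <= 0)) stop("body_weight must be positive")
  if (any(content_weight < 0)) stop("content_weight must be non-negative")
  100 * content_weight / body_weight
}

#' Is a stomach empty under the fullness convention?
#'
#' @param fullness stomach fullness in percent.
#' @param threshold empty threshold in percent (default 0.5).
#' @return logical.
#' @export
is_empty_stomach <- function(fullness, threshold = 0.5) {
  fullness < threshold
}

#' Diet index table (%F, %N, %W, IRI, %IRI)
#'
#' Computes the classical prey-importance indices for a group of stomachs
#' from a long-format prey table:
#' \itemize{
#'   \item \code{pF}: percentage frequency of occurrence,
#'     \eqn{n_i \times 100 / N}, where \eqn{n_i} is the number of stomachs
#'     containing taxon \eqn{i} and \eqn{N} the number of stomachs examined;
#'   \item \code{pN}: numeric composition, prey counts of taxon \eqn{i} as a
#'     percentage of all prey individuals;
#'   \item \code{pW}: gravimetric composition, prey weight of taxon \eqn{i}
#'     as a percentage of total prey weight;
#'   \item \code{IRI}: index of relative importance,
#'     \eqn{(\%N + \%W) \times \%F}, and \code{pIRI}, its percentage of the
#'     group total.
#' }
#'
#' @param prey long-format data.frame with columns `specimen_id`, `taxon`,
#'   `count`, `weight` and optionally `is_other`.
#' @param n_stomachs number of stomachs examined for the group (the
#'   denominator N of %F). By convention this includes empty stomachs;
#'   pass the count of non-empty stomachs to restrict.
#' @param include_other keep records flagged `is_other` (scales, parasites,
#'   undigested material)? Default `FALSE`, dropping them before any index
#'   is computed.
#' @return data.frame, one row per taxon present, columns `taxon`, `n_occ`,
#'   `count`, `weight`, `pF`, `pN`, `pW`, `IRI`, `pIRI`, sorted by
#'   decreasing `pIRI`.
#' @export
diet_index_table <- function(prey, n_stomachs, include_other = FALSE) {
  stopifnot(is.data.frame(prey))
  if (!include_other && "is_other" %in% names(prey)) {
    prey <- prey[!prey$is_other, , drop = FALSE]
  }
  if (nrow(prey) == 0) stop("no prey records in group (all stomachs empty?)")
  if (missing(n_stomachs)) n_stomachs <- length(unique(prey$specimen_id))
  if (any(prey$weight < 0) || any(prey$count < 0))
    stop("negative prey counts or weights")
  # unidentifiable fragments carrying weight but no count enter as one
  # individual
  zero_cnt <- prey$count == 0 & prey$weight > 0
  if (any(zero_cnt)) {
    prey$count[zero_cnt] <- 1L
    message(sum(zero_cnt), " prey record(s) with weight but zero count ",
            "treated as a single individual")
  }
  occ <- tapply(prey$specimen_id, prey$taxon,
                function(x) length(unique(x)))
  cnt <- tapply(prey$count, prey$taxon, sum)
  wgt <- tapply(prey$weight, prey$taxon, sum)
  taxa <- names(occ)
  pF <- 100 * as.numeric(occ) / n_stomachs
  pN <- 100 * as.numeric(cnt) / sum(cnt)
  pW <- 100 * as.numeric(wgt) / sum(wgt)
  iri <- (pN + pW) * pF
  out <- data.frame(taxon = taxa, n_occ = as.integer(occ),
                    count = as.numeric(cnt), weight = as.numeric(wgt),
                    pF = pF, pN = pN, pW = pW, IRI = iri,
                    pIRI = 100 * iri / sum(iri),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pIRI, out$taxon), ]
  rownames(out) <- NULL
  out
}

#' Shannon-Wiener diet diversity
#'
#' \eqn{H' = -\sum p_i \ln p_i} over the prey composition of a single
#' stomach (or any pooled set of prey records). By default \eqn{p_i} is the
#' count share of taxon \eqn{i}; biomass shares are available via `basis`.
#'
#' @param counts numeric vector of prey counts (or weights) per taxon.
#' @return H' (nats); 0 for a single taxon, at most `log(length(counts))`.
#' @export
shannon_diversity <- function(counts) {
  if (length(counts) == 0 || sum(counts) <= 0)
    stop("diet diversity undefined for empty composition")
  if (any(counts < 0)) stop("negative abundances")
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-stomach Shannon diversity for a prey table
#'
#' Computes H' for every stomach that holds at least one prey record, the
#' form in which diet diversity is compared across groups with univariate
#' permutation ANOVA.
#'
#' @param prey long-format prey data.frame (`specimen_id`, `taxon`, `count`,
#'   `weight`, optionally `is_other`).
#' @param basis `"count"` (default) or `"weight"`: which abundance enters
#'   \eqn{p_i}.
#' @param include_other keep `is_other` records? Default `FALSE`.
#' @return data.frame `specimen_id`, `H`.
#' @export
stomach_diversity <- function(prey, basis = c("count", "weight"),
                              include_other = FALSE) {
  basis <- match.arg(basis)
  if (!include_other && "is_other" %in% names(prey)) {
    prey <- prey[!prey$is_other, , drop = FALSE]
  }
  if (nrow(prey) == 0) {
    return(data.frame(specimen_id = character(), H = numeric()))
  }
  ab <- if (basis == "count") prey$count else prey$weight
  h <- tapply(ab, prey$specimen_id, function(x) shannon_diversity(x))
  data.frame(specimen_id = names(h), H = as.numeric(h),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sample-by-taxon biomass matrix from a long prey table
#'
#' Pivot used by all multivariate diet analyses; `is_other` records are
#' dropped by default, matching the convention that scales, parasites and
#' undigested material do not enter resemblance matrices.
#'
#' @param prey long-format prey data.frame.
#' @param value `"weight"` (default) or `"count"`.
#' @param include_other keep `is_other` records?
#' @return numeric matrix, rows = specimen ids, columns = taxa.
#' @export
prey_biomass_matrix <- function(prey, value = c("weight", "count"),
                                include_other = FALSE) {
  value <- match.arg(value)
  if (!include_other && "is_other" %in% names(prey)) {
    prey <- prey[!prey$is_other, , drop = FALSE]
  }
  if (nrow(prey) == 0) stop("no prey records after filtering")
  tab <- tapply(prey[[value]],
                list(prey$specimen_id, prey$taxon), sum, default = 0)
  m <- unclass(tab)
  m[is.na(m)] <- 0
  m
}
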