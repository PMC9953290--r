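# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations they check.

# Diet indices by exhaustive looping over stomachs and taxa.
brute_diet_table <- function(prey, n_stomachs) {
  taxa <- sort(unique(prey$taxon))
  total_count <- 0
  total_weight <- 0
  for (r in seq_len(nrow(prey))) {
    total_count <- total_count + prey$count[r]
    total_weight <- total_weight + prey$weight[r]
  }
  out <- data.frame(taxon = taxa, pF = NA_real_, pN = NA_real_,
                    pW = NA_real_, IRI = NA_real_)
  for (k in seq_along(taxa)) {
    stomachs_with <- character(0)
    cnt <- 0; wgt <- 0
    for (r in seq_len(nrow(prey))) {
      if (prey$taxon[r] == taxa[k]) {
        stomachs_with <- union(stomachs_with, prey$specimen_id[r])
        cnt <- cnt + prey$count[r]
        wgt <- wgt + prey$weight[r]
      }
    }
    out$pF[k] <- length(stomachs_with) * 100 / n_stomachs
    out$pN[k] <- cnt * 100 / total_count
    out$pW[k] <- wgt * 100 / total_weight
    out$IRI[k] <- (out$pN[k] + out$pW[k]) * out$pF[k]
  }
  out$pIRI <- out$IRI / sum(out$IRI) * 100
  out
}

# Bray-Curtis by direct double loop on (optionally transformed) rows.
brute_bray_curtis <- function(y) {
  n <- nrow(y)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- 0; den <- 0
      for (k in seq_len(ncol(y))) {
        num <- num + abs(y[i, k] - y[j, k])
        den <- den + y[i, k] + y[j, k]
      }
      D[i, j] <- if (den > 0) num / den else 0
    }
  }
  D
}

# Layman metrics by explicit double loops.
brute_layman <- function(p) {
  n <- nrow(p)
  cx <- mean(p[, 1]); cy <- mean(p[, 2])
  cd <- 0
  for (i in seq_len(n)) {
    cd <- cd + sqrt((p[i, 1] - cx)^2 + (p[i, 2] - cy)^2)
  }
  nnd <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((p[i, 1] - p[j, 1])^2 + (p[i, 2] - p[j, 2])^2)
      if (d < best) best <- d
    }
    nnd[i] <- best
  }
  c(NR = max(p[, 2]) - min(p[, 2]), CR = max(p[, 1]) - min(p[, 1]),
    CD = cd / n, MNND = mean(nnd),
    SDNND = sqrt(sum((nnd - mean(nnd))^2) / n))
}

# Convex hull area by gift-wrapping (Jarvis march) plus fan triangulation;
# independent of grDevices::chull and the shoelace formula.
brute_hull_area <- function(p) {
  p <- unique(p)
  n <- nrow(p)
  start <- which.min(p[, 2] + 1e-9 * p[, 1])
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- setdiff(seq_len(n), cur)
    best <- cand[1]
    for (j in cand[-1]) {
      cross <- (p[best, 1] - p[cur, 1]) * (p[j, 2] - p[cur, 2]) -
        (p[best, 2] - p[cur, 2]) * (p[j, 1] - p[cur, 1])
      if (cross < 0 ||
          (abs(cross) < 1e-12 &&
           sum((p[j, ] - p[cur, ])^2) > sum((p[best, ] - p[cur, ])^2))) {
        best <- j
      }
    }
    if (best == start) break
    hull <- c(hull, best)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  if (length(hull) < 3) return(0)
  a <- 0
  v0 <- p[hull[1], ]
  for (k in 2:(length(hull) - 1)) {
    v1 <- p[hull[k], ] - v0
    v2 <- p[hull[k + 1], ] - v0
    a <- a + abs(v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  a
}

# Average between-group dissimilarity by direct cross-pair looping.
brute_avg_dissimilarity <- function(y, ia, ib) {
  tot <- 0
  for (i in ia) {
    for (j in ib) {
      num <- sum(abs(y[i, ] - y[j, ]))
      den <- sum(y[i, ] + y[j, ])
      tot <- tot + if (den > 0) 100 * num / den else 0
    }
  }
  tot / (length(ia) * length(ib))
}
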