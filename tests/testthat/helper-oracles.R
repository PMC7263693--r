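# Independent oracles used to pin expected values; these deliberately avoid
# the package's own code paths.

# Exhaustive half-tetrad heterozygosity oracle: enumerate Poisson crossover
# counts (<= max_xo) in the marker-centromere interval and all non-sister
# strand assignments; the retained pair are the sister chromatids (rows 1,2)
# and an exchange swaps the marker-side alleles of the chosen pair.
y_oracle <- function(d_morgan, max_xo = 8) {
  lambda <- 2 * d_morgan
  p_het_given_n <- vapply(0:max_xo, function(n) {
    if (n == 0) return(0)
    combos <- expand.grid(rep(list(1:4), n))
    pair_map <- list(c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L))
    het <- apply(combos, 1L, function(cc) {
      alleles <- c(1L, 1L, 2L, 2L)
      for (k in cc) {
        pr <- pair_map[[k]]
        alleles[pr] <- alleles[rev(pr)]
      }
      alleles[1L] != alleles[2L]
    })
    mean(het)
  }, 0)
  w <- stats::dpois(0:max_xo, lambda)
  sum(w * p_het_given_n) / sum(w)
}

# numeric two-point LOD by direct likelihood maximization over r
lod_numeric <- function(k, n) {
  loglik <- function(r) k * log10(r) + (n - k) * log10(1 - r)
  opt <- stats::optimize(loglik, c(1e-12, 0.5), maximum = TRUE, tol = 1e-12)
  max(n * log10(2) + opt$objective, 0)
}

# brute-force single-position Haley-Knott LOD via lm
hk_lod_bruteforce <- function(pAA, pAB, pBB, y) {
  n <- length(y)
  X <- cbind(a = pBB - pAA, d = pAB)
  rss1 <- sum(stats::resid(stats::lm(y ~ X))^2)
  rss0 <- sum((y - mean(y))^2)
  (n / 2) * log10(rss0 / rss1)
}

# brute-force connected components by breadth-first search
components_bruteforce <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# brute-force count of distinct high peaks in a normalized LOD vector
count_peaks_bruteforce <- function(vn, height, sep) {
  n <- length(vn)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i == 1L) -Inf else vn[i - 1L]
    right <- if (i == n) -Inf else vn[i + 1L]
    vn[i] > left && vn[i] >= right
  }, TRUE)
  peaks <- which(is_max & vn >= height)
  if (length(peaks) <= 1L) return(length(peaks))
  sum(diff(peaks) > sep) + 1L
}
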