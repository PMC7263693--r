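# Single-QTL genome scans: pseudomarker grids, genotype probabilities from
# phase-known flanking markers, expected-relatedness kinship, Haley-Knott
# normal scans (optionally with a kinship random effect), binary-trait
# logistic scans, peak finding with Bayes credible intervals, permutation
# significance, and the LOD-to-PVE conversion.

#' Insert pseudomarkers into a marker map
#'
#' The evaluation grid is the union of marker positions and a regular grid
#' at `step` cM per linkage group, deduplicated within 1e-6 cM.
#'
#' @param map Data frame with `marker`, `chrom` (or `lg`) and `pos` columns.
#' @param step Grid step in cM (> 0).
#' @return Data frame `chrom`, `pos`, `marker` (`NA` at pseudomarkers).
#' @export
insert_pseudomarkers <- function(map, step = 1) {
  if (step <= 0) stop("step must be > 0")
  chrom <- map$chrom %||% map$lg
  out <- do.call(rbind, lapply(unique(chrom), function(ch) {
    mm <- map[chrom == ch, ]
    grid <- seq(min(mm$pos), max(mm$pos), by = step)
    pos <- sort(c(mm$pos, grid))
    keep <- c(TRUE, diff(pos) > 1e-6)
    pos <- pos[keep]
    mrk <- mm$marker[match(round(pos, 6), round(mm$pos, 6))]
    data.frame(chrom = ch, pos = pos, marker = mrk, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Genotype probabilities on an evaluation grid
#'
#' Per parent, the chain of parental-origin calls is interpolated between
#' the flanking informative markers with Haldane transition probabilities;
#' observed non-missing markers are degenerate on their call, and positions
#' with no informative flank fall back to the next informative marker on the
#' other side or to the uniform prior.  Maternal and paternal chains are
#' independent; genotype-class probabilities are their products.
#'
#' @param maternal,paternal Markers x individuals origin-call matrices
#'   (1/2/NA) as produced by [simulate_diploid_family()].
#' @param marker_map Data frame `marker`, `chrom`, `pos` for the rows.
#' @param grid Evaluation grid from [insert_pseudomarkers()] (defaults to a
#'   1 cM grid over `marker_map`).
#' @return A `genoprob` object: `grid`, and `pAA`, `pAB`, `pBB`, `m1`, `p1`
#'   matrices (individuals x grid positions).  `m1`/`p1` are the per-parent
#'   probabilities of origin class 1.
#' @export
calc_genoprob <- function(maternal, paternal, marker_map, grid = NULL) {
  if (is.null(grid)) grid <- insert_pseudomarkers(marker_map, 1)
  n_ind <- ncol(maternal)
  n_pos <- nrow(grid)
  m1 <- p1 <- matrix(NA_real_, n_ind, n_pos)
  for (ch in unique(grid$chrom)) {
    sel_g <- which(grid$chrom == ch)
    sel_m <- which(marker_map$chrom == ch)
    if (!length(sel_m)) {
      warning("no informative markers on ", ch, "; uniform prior used")
      m1[, sel_g] <- 0.5; p1[, sel_g] <- 0.5
      next
    }
    mp <- marker_map$pos[sel_m]
    ord <- order(mp)
    mp <- mp[ord]
    rows <- match(marker_map$marker[sel_m][ord], rownames(maternal))
    qpos <- grid$pos[sel_g]
    m1[, sel_g] <- chain_probs(maternal[rows, , drop = FALSE], mp, qpos)
    p1[, sel_g] <- chain_probs(paternal[rows, , drop = FALSE], mp, qpos)
  }
  pAA <- m1 * p1
  pBB <- (1 - m1) * (1 - p1)
  pAB <- 1 - pAA - pBB
  structure(list(grid = grid, pAA = pAA, pAB = pAB, pBB = pBB,
                 m1 = m1, p1 = p1), class = "genoprob")
}

# one parent chain on one chromosome: P(origin = 1) at each query position
chain_probs <- function(orig, mpos, qpos) {
  n_ind <- ncol(orig)
  out <- matrix(0.5, n_ind, length(qpos))
  for (ind in seq_len(n_ind)) {
    o <- orig[, ind]
    inf <- which(!is.na(o))
    if (!length(inf)) next
    ip <- mpos[inf]
    io <- o[inf]
    left <- findInterval(qpos + 1e-9, ip)       # last informative <= q
    right <- length(ip) - findInterval(-qpos + 1e-9, rev(-ip)) + 1L
    for (k in seq_along(qpos)) {
      li <- left[k]; ri <- right[k]
      if (li >= 1L && abs(ip[li] - qpos[k]) < 1e-6) {
        out[ind, k] <- as.numeric(io[li] == 1L)
        next
      }
      has_l <- li >= 1L
      has_r <- ri <= length(ip)
      if (has_l && has_r) {
        r1 <- haldane_r(qpos[k] - ip[li])
        r2 <- haldane_r(ip[ri] - qpos[k])
        pr_stay1 <- if (io[li] == 1L) 1 - r1 else r1   # P(state 1 | left)
        pr_to_r1 <- if (io[ri] == 1L) 1 - r2 else r2   # P(right | state 1)
        pr_stay2 <- if (io[li] == 2L) 1 - r1 else r1
        pr_to_r2 <- if (io[ri] == 2L) 1 - r2 else r2
        num1 <- pr_stay1 * pr_to_r1
        num2 <- pr_stay2 * pr_to_r2
        out[ind, k] <- num1 / (num1 + num2)
      } else if (has_l) {
        r1 <- haldane_r(qpos[k] - ip[li])
        out[ind, k] <- if (io[li] == 1L) 1 - r1 else r1
      } else if (has_r) {
        r2 <- haldane_r(ip[ri] - qpos[k])
        out[ind, k] <- if (io[ri] == 1L) 1 - r2 else r2
      }
    }
  }
  out
}

#' Expected-relatedness kinship matrix from genotype probabilities
#'
#' `K(i, j)` averages, over a thinned position grid, the probability that
#' individuals `i` and `j` carry the same parental-origin class, then is
#' scaled so that self-kinship equals 1.
#'
#' @param probs A `genoprob` object.
#' @param thin_step Thinning step in cM (positions nearest multiples of the
#'   step are used, mirroring a coarse evaluation grid).
#' @return Individuals x individuals kinship matrix.
#' @export
calc_kinship <- function(probs, thin_step = 3) {
  grid <- probs$grid
  keep <- unlist(lapply(unique(grid$chrom), function(ch) {
    idx <- which(grid$chrom == ch)
    targets <- seq(min(grid$pos[idx]), max(grid$pos[idx]), by = thin_step)
    unique(idx[vapply(targets, function(t)
      which.min(abs(grid$pos[idx] - t)), 1L)])
  }))
  n <- nrow(probs$m1)
  if (n < 2L) stop("need at least 2 individuals")
  K <- matrix(0, n, n)
  for (k in keep) {
    m1 <- probs$m1[, k]; p1 <- probs$p1[, k]
    same_m <- outer(m1, m1) + outer(1 - m1, 1 - m1)
    same_p <- outer(p1, p1) + outer(1 - p1, 1 - p1)
    K <- K + same_m * same_p
  }
  K <- K / length(keep)
  dg <- sqrt(diag(K))
  K / outer(dg, dg)
}

# positions x traits LOD matrix for Haley-Knott normal scans; Y may hold
# many traits/permutations as columns.  With a kinship matrix the model is
# fit by GLS in the eigenspace of K with variance components estimated once
# under the null by maximum likelihood.
scan_normal_engine <- function(probs, Y, kinship = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  n_pos <- nrow(probs$grid)
  a <- probs$pBB - probs$pAA
  dd <- probs$pAB
  lod <- matrix(0, n_pos, ncol(Y))
  if (is.null(kinship)) {
    cY <- scale(Y, center = TRUE, scale = FALSE)
    rss0 <- colSums(cY^2)
    degenerate <- rss0 < 1e-12
    for (p in seq_len(n_pos)) {
      X <- cbind(1, a[, p], dd[, p])
      qr_ <- qr(X)
      Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
      rss1 <- pmax(colSums(Y^2) - colSums(crossprod(Q, Y)^2), 1e-12)
      lod[p, ] <- ifelse(degenerate, 0, (n / 2) * log10(rss0 / rss1))
    }
  } else {
    ed <- eigen(kinship, symmetric = TRUE)
    U <- ed$vectors
    dvals <- pmax(ed$values, 0)
    Ys <- crossprod(U, Y)
    ones <- crossprod(U, rep(1, n))
    h2 <- stats::optimize(function(h) {
      v <- h * dvals + (1 - h)
      w <- 1 / v
      fit <- stats::lm.wfit(x = matrix(ones, ncol = 1), y = Ys[, 1], w = w)
      s2 <- sum(w * fit$residuals^2) / n
      -(-n / 2 * log(s2) - 0.5 * sum(log(v)))
    }, c(0, 0.99))$minimum
    v <- h2 * dvals + (1 - h2)
    sw <- 1 / sqrt(v)
    Yw <- Ys * sw
    Xw0 <- matrix(ones * sw, ncol = 1)
    q0 <- qr.Q(qr(Xw0))
    rss0 <- colSums(Yw^2) - colSums(crossprod(q0, Yw)^2)
    for (p in seq_len(n_pos)) {
      X <- crossprod(U, cbind(1, a[, p], dd[, p])) * sw
      qr_ <- qr(X)
      Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
      rss1 <- pmax(colSums(Yw^2) - colSums(crossprod(Q, Yw)^2), 1e-12)
      lod[p, ] <- (n / 2) * log10(rss0 / rss1)
    }
  }
  pmax(lod, 0)
}

#' Genome scan for an approximately normal trait
#'
#' Haley-Knott regression of the trait on expected additive
#' (`P(hom2) - P(hom1)`) and dominance (`P(het)`) scores at every grid
#' position; `LOD = (n/2) log10(RSS0/RSS1)`.  With `kinship`, a mixed model
#' is used: variance components are estimated once under the null by maximum
#' likelihood and each position is fit by generalized least squares in the
#' rotated space.
#'
#' @param probs A `genoprob` object.
#' @param trait Numeric trait vector (no missing values; drop beforehand,
#'   subsetting `probs` rows to match).
#' @param kinship Optional kinship matrix from [calc_kinship()].
#' @return A `scan_result` data frame: `lg`, `pos`, `lod`, plus fitted
#'   additive/dominance effects per position in attributes.
#' @export
scan_normal <- function(probs, trait, kinship = NULL) {
  stopifnot(!anyNA(trait), length(trait) == nrow(probs$m1))
  lod <- scan_normal_engine(probs, matrix(trait, ncol = 1), kinship)[, 1]
  eff <- position_effects(probs, trait)
  out <- data.frame(lg = probs$grid$chrom, pos = probs$grid$pos, lod = lod)
  attr(out, "effects") <- eff
  attr(out, "model") <- if (is.null(kinship)) "normal" else "normal+kinship"
  class(out) <- c("scan_result", "data.frame")
  out
}

# per-position OLS additive/dominance coefficients (reporting scale)
position_effects <- function(probs, trait) {
  n_pos <- nrow(probs$grid)
  add <- dom <- rep(NA_real_, n_pos)
  for (p in seq_len(n_pos)) {
    X <- cbind(1, probs$pBB[, p] - probs$pAA[, p], probs$pAB[, p])
    fit <- stats::lm.fit(X, trait)
    cf <- fit$coefficients
    add[p] <- cf[2]; dom[p] <- cf[3]
  }
  data.frame(pos = probs$grid$pos, additive = add, dominance = dom)
}

#' Genome scan for a binary trait
#'
#' Per-position logistic regression on the expected additive and dominance
#' scores, fit by iteratively reweighted least squares (max 50 iterations,
#' fitted probabilities clamped to `[1e-8, 1 - 1e-8]`);
#' `LOD = (LL1 - LL0) / ln(10)`.
#'
#' @param probs A `genoprob` object.
#' @param trait01 Trait in 0/1; both classes must be present.
#' @return A `scan_result` data frame (`lg`, `pos`, `lod`).
#' @export
scan_binary <- function(probs, trait01) {
  stopifnot(!anyNA(trait01), all(trait01 %in% c(0, 1)))
  if (length(unique(trait01)) < 2L) stop("both trait classes must be present")
  lod <- scan_binary_engine(probs, matrix(trait01, ncol = 1))[, 1]
  eff <- binary_effects(probs, trait01)
  out <- data.frame(lg = probs$grid$chrom, pos = probs$grid$pos, lod = lod)
  attr(out, "effects") <- eff
  attr(out, "model") <- "binary"
  class(out) <- c("scan_result", "data.frame")
  out
}

scan_binary_engine <- function(probs, Y) {
  n_pos <- nrow(probs$grid)
  lod <- matrix(0, n_pos, ncol(Y))
  for (t in seq_len(ncol(Y))) {
    y <- Y[, t]
    mu0 <- min(max(mean(y), 1e-8), 1 - 1e-8)
    ll0 <- sum(y * log(mu0) + (1 - y) * log(1 - mu0))
    for (p in seq_len(n_pos)) {
      X <- cbind(1, probs$pBB[, p] - probs$pAA[, p], probs$pAB[, p])
      ll1 <- logistic_irls(X, y)$loglik
      lod[p, t] <- max((ll1 - ll0) / log(10), 0)
    }
  }
  lod
}

logistic_irls <- function(X, y, max_iter = 50, clamp = 1e-8) {
  beta <- rep(0, ncol(X))
  loglik_of <- function(b) {
    mu <- pmin(pmax(stats::plogis(drop(X %*% b)), clamp), 1 - clamp)
    sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  ll <- loglik_of(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- pmin(pmax(stats::plogis(eta), clamp), 1 - clamp)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    fit <- tryCatch(suppressWarnings(stats::lm.wfit(X, z, w)),
                    error = function(e) NULL)
    if (is.null(fit)) break
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    ll_new <- loglik_of(beta_new)
    if (!is.finite(ll_new)) break
    beta <- beta_new
    if (abs(ll_new - ll) < 1e-10) { ll <- ll_new; break }
    ll <- ll_new
  }
  list(beta = beta, loglik = ll)
}

binary_effects <- function(probs, y) {
  n_pos <- nrow(probs$grid)
  add <- dom <- rep(NA_real_, n_pos)
  for (p in seq_len(n_pos)) {
    X <- cbind(1, probs$pBB[, p] - probs$pAA[, p], probs$pAB[, p])
    cf <- logistic_irls(X, y)$beta
    add[p] <- cf[2]; dom[p] <- cf[3]
  }
  data.frame(pos = probs$grid$pos, additive = add, dominance = dom)
}

#' Find LOD peaks with Bayes credible intervals
#'
#' Per linkage group: local maxima with `LOD >= threshold`; two maxima are
#' distinct peaks only when the intervening minimum sits at least `peakdrop`
#' below the smaller of the two.  The credible interval is the smallest
#' position set around the peak holding at least `ci_prob` of the normalized
#' `10^LOD` mass of the peak's region, which is truncated where the curve
#' falls `peakdrop` below the peak.
#'
#' @param scan A `scan_result`.
#' @param threshold Minimum peak LOD.
#' @param peakdrop Required valley depth between distinct peaks (and region
#'   truncation drop).
#' @param ci_prob Credible-interval mass.
#' @return Data frame of peaks: `lg`, `pos`, `lod`, `ci_low`, `ci_high`,
#'   plus additive/dominance effects when the scan carries them.
#' @export
find_peaks_ci <- function(scan, threshold = 3, peakdrop = 2, ci_prob = 0.95) {
  eff <- attr(scan, "effects")
  out <- list()
  for (ch in unique(scan$lg)) {
    s <- scan[scan$lg == ch, ]
    s <- s[order(s$pos), ]
    v <- s$lod
    cand <- local_maxima(v)
    cand <- cand[v[cand] >= threshold]
    if (!length(cand)) next
    # merge maxima not separated by a deep enough valley
    keep <- rep(TRUE, length(cand))
    repeat {
      idx <- which(keep)
      if (length(idx) < 2L) break
      merged <- FALSE
      for (q in seq_len(length(idx) - 1L)) {
        i <- cand[idx[q]]; j <- cand[idx[q + 1L]]
        valley <- min(v[i:j])
        if (valley > min(v[i], v[j]) - peakdrop) {
          keep[idx[q:(q + 1L)][which.min(c(v[i], v[j]))]] <- FALSE
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    peaks <- cand[keep]
    for (pk in peaks) {
      other_peaks <- setdiff(peaks, pk)
      lo <- pk
      while (lo > 1L && v[lo - 1L] > v[pk] - peakdrop &&
             !((lo - 1L) %in% other_peaks)) lo <- lo - 1L
      hi <- pk
      nv <- length(v)
      while (hi < nv && v[hi + 1L] > v[pk] - peakdrop &&
             !((hi + 1L) %in% other_peaks)) hi <- hi + 1L
      region <- lo:hi
      w <- 10^(v[region] - max(v[region]))
      w <- w / sum(w)
      ord <- region[order(v[region], decreasing = TRUE)]
      cum <- cumsum(w[match(ord, region)])
      sel <- ord[seq_len(which(cum >= ci_prob)[1])]
      sel <- union(sel, pk)
      row <- data.frame(lg = ch, pos = s$pos[pk], lod = v[pk],
                        ci_low = min(s$pos[sel]), ci_high = max(s$pos[sel]))
      if (!is.null(eff)) {
        m <- which(abs(eff$pos - s$pos[pk]) < 1e-8)[1]
        row$additive <- eff$additive[m]
        row$dominance <- eff$dominance[m]
      }
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out))
    return(data.frame(lg = character(), pos = numeric(), lod = numeric(),
                      ci_low = numeric(), ci_high = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Permutation p-values and genome-wide thresholds
#'
#' Trait values are permuted across individuals (genotypes fixed, preserving
#' LD); the genome-wide maximum LOD of each permutation forms the null.
#' `p = proportion of permuted maxima >= observed LOD`, floored at
#' `1/(n_perm+1)` and flagged `"< 1/(n_perm+1)"` when no permutation reaches
#' the observed score.
#'
#' @param probs A `genoprob` object.
#' @param trait Trait vector (0/1 for `model = "binary"`).
#' @param peaks Peak table from [find_peaks_ci()].
#' @param n_perm Number of permutations.
#' @param model `"normal"` or `"binary"`.
#' @param kinship Optional kinship matrix (normal model only).
#' @param alpha Significance levels for reported thresholds.
#' @return List with `peaks` (p-value and label columns added),
#'   `thresholds` (genome-wide LOD quantiles) and `perm_max`.
#' @export
permutation_pvalues <- function(probs, trait, peaks, n_perm = 1000,
                                model = c("normal", "binary"),
                                kinship = NULL, alpha = 0.05) {
  model <- match.arg(model)
  if (n_perm < 100) warning("n_perm < 100: permutation tail is unstable")
  n <- length(trait)
  P <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  Y <- matrix(trait[P], nrow = n)
  lodmat <- if (model == "normal") scan_normal_engine(probs, Y, kinship)
            else scan_binary_engine(probs, Y)
  perm_max <- apply(lodmat, 2L, max)
  p <- vapply(peaks$lod, function(l) mean(perm_max >= l), 0)
  floor_p <- 1 / (n_perm + 1)
  label <- ifelse(p == 0, sprintf("< %.4g", floor_p), sprintf("%.4g", p))
  peaks$p_value <- pmax(p, floor_p)
  peaks$p_label <- label
  thresholds <- stats::quantile(perm_max, 1 - alpha, names = FALSE)
  list(peaks = peaks,
       thresholds = data.frame(alpha = alpha, lod_threshold = thresholds),
       perm_max = perm_max)
}

#' Proportion of phenotypic variance explained by a QTL
#'
#' `PVE = 1 - 10^(-2 * LOD / n)`, the classical conversion between a LOD
#' score and the model R-squared at sample size `n`.
#'
#' @param lod LOD score(s), >= 0.
#' @param n Sample size (> 0).
#' @param digits Decimal places of the reported value.
#' @return PVE in `[0, 1)`.
#' @export
pve <- function(lod, n, digits = 3) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(lod < 0)) stop("lod must be >= 0")
  round(1 - 10^(-2 * lod / n), digits)
}
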