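# Within-LG marker ordering by SARF (sum of adjacent recombination
# fractions) seriation, sex-specific map positions via the Haldane map
# function, and Table-2-style map summaries.

#' Order markers within a linkage group
#'
#' Seriation minimizing the sum of adjacent recombination fractions: greedy
#' nearest-neighbour paths from random starting markers, each refined by
#' best-improvement 2-opt to local optimality; the best of `n_restarts`
#' solutions is kept.  Orientation is canonicalized so the terminal marker
#' with the lexicographically smaller id comes first.
#'
#' @param gametes Gamete matrix/matrices (see [pairwise_lod()]) restricted to
#'   one linkage group, or a precomputed [pairwise_lod()] result.
#' @param n_restarts Number of random restarts.
#' @return A `marker_order`: `order` (marker ids), `sarf`, and per-adjacent
#'   pair recombination fractions `rf_female`, `rf_male`, `rf_pooled` when
#'   parent-specific matrices were supplied (names `mother` / `father`).
#' @export
order_markers <- function(gametes, n_restarts = 20) {
  pl <- if (is.list(gametes) && !is.null(gametes$rf) && is.matrix(gametes$rf))
    gametes else pairwise_lod(gametes)
  rf <- pl$rf
  m <- nrow(rf)
  if (m < 2L) stop("need at least 2 markers")
  markers <- rownames(rf)
  d <- rf
  d[is.na(d)] <- 0.5   # unscored pairs are treated as unlinked
  diag(d) <- Inf
  if (m == 2L) {
    path <- order(markers)
  } else {
    best_path <- NULL
    best_sarf <- Inf
    for (s in seq_len(n_restarts)) {
      start <- sample.int(m, 1L)
      path <- greedy_path(d, start)
      path <- two_opt(d, path)
      sarf <- path_sarf(d, path)
      if (sarf < best_sarf - 1e-12) {
        best_sarf <- sarf
        best_path <- path
      }
    }
    path <- best_path
  }
  if (markers[path[1L]] > markers[path[length(path)]]) path <- rev(path)
  ord <- markers[path]
  out <- list(order = ord, sarf = path_sarf(d, path),
              rf_pooled = d[cbind(path[-m], path[-1L])])
  if (is.list(gametes) && is.null(gametes$rf)) {
    sex_of <- function(nm) if (!is.null(gametes[[nm]]))
      adjacent_rf(gametes[[nm]], ord) else NULL
    out$rf_female <- sex_of("mother")
    out$rf_male <- sex_of("father")
  }
  structure(out, class = "marker_order")
}

greedy_path <- function(d, start) {
  m <- nrow(d)
  path <- integer(m)
  path[1L] <- start
  used <- rep(FALSE, m); used[start] <- TRUE
  for (i in 2L:m) {
    cand <- d[path[i - 1L], ]
    cand[used] <- Inf
    nxt <- which.min(cand)
    path[i] <- nxt
    used[nxt] <- TRUE
  }
  path
}

path_sarf <- function(d, path)
  sum(d[cbind(path[-length(path)], path[-1L])])

# best-improvement 2-opt on an open path; O(m^2) delta evaluation per pass
# via whole-matrix indexing.
two_opt <- function(d, path) {
  m <- length(path)
  if (m < 4L) return(path)
  repeat {
    # reversal of path[i..j]; ends of the path handled with zero edge cost
    ends_prev <- c(0, d[cbind(path[-m], path[-1L])])  # edge entering i
    improved <- FALSE
    best_delta <- -1e-9
    best_ij <- NULL
    # delta(i,j) = d[p[i-1],p[j]] + d[p[i],p[j+1]] - d[p[i-1],p[i]] - d[p[j],p[j+1]]
    prev_idx <- c(NA, path[-m])   # p[i-1]
    next_idx <- c(path[-1L], NA)  # p[j+1]
    for (i in 1L:(m - 1L)) {
      js <- (i + 1L):m
      a <- if (i == 1L) 0 else d[prev_idx[i], path[js]]
      b <- ifelse(js == m, 0, d[path[i], next_idx[pmin(js, m)]])
      old1 <- if (i == 1L) 0 else d[prev_idx[i], path[i]]
      old2 <- ifelse(js == m, 0, d[cbind(path[js], next_idx[pmin(js, m)])])
      delta <- a + b - old1 - old2
      k <- which.min(delta)
      if (delta[k] < best_delta) {
        best_delta <- delta[k]
        best_ij <- c(i, js[k])
        improved <- TRUE
      }
    }
    if (!improved) break
    i <- best_ij[1L]; j <- best_ij[2L]
    path[i:j] <- rev(path[i:j])
  }
  path
}

adjacent_rf <- function(gam, ord) {
  present <- ord %in% rownames(gam)
  rf <- rep(NA_real_, length(ord) - 1L)
  # fraction between consecutive markers of the order that are informative
  # in this parent; uninformative adjacencies stay NA
  for (i in seq_len(length(ord) - 1L)) {
    if (!present[i] || !present[i + 1L]) next
    a <- gam[ord[i], ]; b <- gam[ord[i + 1L], ]
    okk <- !is.na(a) & !is.na(b)
    if (!any(okk)) next
    rf[i] <- min(sum(a[okk] != b[okk]) / sum(okk), 0.5)
  }
  rf
}

#' Haldane map function and its inverse
#'
#' @param r Recombination fraction(s).
#' @param cap Cap applied to `r` to keep distances finite.
#' @return Distance in cM.
#' @export
haldane_cM <- function(r, cap = 0.49) -50 * log(1 - 2 * pmin(r, cap))

#' @rdname haldane_cM
#' @param d Distance(s) in cM.
#' @export
haldane_r <- function(d) (1 - exp(-2 * d / 100)) / 2

#' Cumulative sex-specific map positions for an ordered linkage group
#'
#' Positions accumulate Haldane distances over adjacent recombination
#' fractions per sex; the sex-averaged position of each marker is the mean
#' of its female and male positions.  Adjacent fractions of exactly 0.5 are
#' flagged and capped.  Uninformative adjacencies (`NA` fractions) contribute
#' zero distance for that sex.
#'
#' @param order A `marker_order` from [order_markers()] (with per-sex
#'   fractions), or a list with `order`, `rf_female`, `rf_male`.
#' @param lg Linkage-group label attached to the output.
#' @return A `linkage_map_table` data frame: marker, lg, female_pos,
#'   male_pos, avg_pos (cM).
#' @export
map_positions <- function(order, lg = "LG1") {
  ord <- order$order
  rf_f <- order$rf_female %||% order$rf_pooled
  rf_m <- order$rf_male %||% order$rf_pooled
  flag <- any(c(rf_f, rf_m) >= 0.5, na.rm = TRUE)
  step_f <- ifelse(is.na(rf_f), 0, haldane_cM(rf_f))
  step_m <- ifelse(is.na(rf_m), 0, haldane_cM(rf_m))
  female <- cumsum(c(0, step_f))
  male <- cumsum(c(0, step_m))
  out <- data.frame(marker = ord, lg = lg, female_pos = female,
                    male_pos = male, avg_pos = (female + male) / 2,
                    stringsAsFactors = FALSE)
  attr(out, "rf_half_flag") <- flag
  class(out) <- c("linkage_map_table", "data.frame")
  out
}

#' Per-LG and overall summary of a linkage map
#'
#' @param map A `linkage_map_table` (rows for one or more LGs).
#' @param digits Decimal places for reported ratios.
#' @return List with `per_lg` (n markers, male/female lengths, female:male
#'   ratio, number of unique female positions) and `overall` (summed lengths
#'   and overall ratio).
#' @export
summarize_map <- function(map, digits = 3) {
  stopifnot(nrow(map) >= 1L)
  per <- do.call(rbind, lapply(split(map, map$lg), function(mm) {
    fl <- max(mm$female_pos) - min(mm$female_pos)
    ml <- max(mm$male_pos) - min(mm$male_pos)
    data.frame(lg = mm$lg[1L], n_markers = nrow(mm),
               male_length = ml, female_length = fl,
               ratio = if (ml > 0) round(fl / ml, digits) else Inf,
               n_unique_pos = length(unique(mm$female_pos)))
  }))
  rownames(per) <- NULL
  tot_f <- sum(per$female_length)
  tot_m <- sum(per$male_length)
  list(per_lg = per,
       overall = data.frame(
         female_total = tot_f, male_total = tot_m,
         ratio = if (tot_m > 0) round(tot_f / tot_m, digits) else Inf,
         male_zero_flag = tot_m == 0))
}
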