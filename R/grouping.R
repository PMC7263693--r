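# Two-point linkage: pairwise LOD matrices, single-linkage grouping at a LOD
# threshold, iterative per-LG threshold splitting toward a target chromosome
# count, and singleton rescue.

#' Two-point LOD and recombination-fraction matrices from gamete matrices
#'
#' For each marker pair with `k` recombinant of `n` jointly scored meioses,
#' `r = min(k/n, 0.5)` and
#' `LOD = n*log10(2) + k*log10(r) + (n-k)*log10(1-r)` (limits taken where
#' `k = 0` or `k = n`).  LODs are summed over informative parents/families;
#' pairs scored in no matrix are `NA`, not zero.
#'
#' @param gametes A single markers x meioses matrix coded 0/1/NA, or a list
#'   of such matrices (one per informative parent per family).  Marker sets
#'   may differ; matrices are aligned by rownames.
#' @return List with `lod` and `rf` (symmetric matrices over the marker
#'   union) and `n` (jointly scored meioses per pair).
#' @export
pairwise_lod <- function(gametes) {
  if (is.matrix(gametes)) gametes <- list(gametes)
  all_mrk <- unique(unlist(lapply(gametes, rownames)))
  if (length(all_mrk) < 2L) stop("need at least 2 markers")
  m <- length(all_mrk)
  lod_sum <- k_sum <- n_sum <- matrix(0, m, m,
                                      dimnames = list(all_mrk, all_mrk))
  for (g in gametes) {
    stopifnot(all(g %in% c(0L, 1L, NA)))
    idx <- match(rownames(g), all_mrk)
    ok <- !is.na(g)
    x <- g; x[!ok] <- 0
    n_pair <- ok %*% t(ok)
    # recombinant meioses: one marker coded 1, the other 0 (NAs masked)
    k_pair <- (x * ok) %*% t((1 - x) * ok) + ((1 - x) * ok) %*% t(x * ok)
    lod_pair <- lod_from_counts(k_pair, n_pair)
    lod_sum[idx, idx] <- lod_sum[idx, idx] + ifelse(n_pair > 0, lod_pair, 0)
    k_sum[idx, idx] <- k_sum[idx, idx] + k_pair
    n_sum[idx, idx] <- n_sum[idx, idx] + n_pair
  }
  lod <- ifelse(n_sum > 0, lod_sum, NA_real_)
  rf <- ifelse(n_sum > 0, pmin(k_sum / pmax(n_sum, 1), 0.5), NA_real_)
  diag(lod) <- NA_real_; diag(rf) <- NA_real_
  list(lod = lod, rf = rf, n = n_sum)
}

# vectorized two-point LOD at the MLE r = min(k/n, 0.5)
lod_from_counts <- function(k, n) {
  r <- pmin(k / pmax(n, 1), 0.5)
  t1 <- ifelse(k > 0, k * log10(r), 0)
  t2 <- ifelse(n - k > 0, (n - k) * log10(1 - r), 0)
  out <- n * log10(2) + t1 + t2
  out[n == 0] <- NA_real_
  pmax(out, 0)
}

#' Assign markers to linkage groups by single-linkage at a LOD threshold
#'
#' Connected components of the graph whose edges join marker pairs with
#' `LOD >= lod_threshold`.  Components smaller than `min_size` dissolve into
#' singletons (label `NA`).  Group labels are `"LG1"`, `"LG2"`, ... in
#' decreasing size order (ties by smallest member id) and are deterministic.
#'
#' @param lods Result of [pairwise_lod()] (or a bare LOD matrix).
#' @param lod_threshold Edge threshold (> 0).
#' @param min_size Minimum linkage-group size.
#' @return A `linkage_grouping`: named `lg` vector, per-LG `sizes`, and an
#'   `audit` data frame of the thresholds that produced each LG.
#' @export
assign_linkage_groups <- function(lods, lod_threshold, min_size = 50) {
  if (lod_threshold <= 0) stop("lod_threshold must be > 0")
  lod <- if (is.list(lods)) lods$lod else lods
  if (length(lod) == 0L)
    return(structure(list(lg = setNames(character(0), character(0)),
                          sizes = integer(0), audit = NULL),
                     class = "linkage_grouping"))
  comp <- lod_components(lod, lod_threshold)
  build_grouping(comp, rownames(lod), min_size,
                 audit_threshold = lod_threshold)
}

# single-linkage components via igraph
lod_components <- function(lod, threshold) {
  adj <- !is.na(lod) & lod >= threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max", diag = FALSE)
  igraph::components(g)$membership
}

build_grouping <- function(membership, markers, min_size, audit_threshold) {
  sizes <- table(membership)
  big <- names(sizes)[sizes >= min_size]
  lg <- rep(NA_character_, length(markers))
  names(lg) <- markers
  if (length(big)) {
    ord <- big[order(-sizes[big],
                     vapply(big, function(b) min(markers[membership == b]), ""))]
    for (i in seq_along(ord))
      lg[membership == ord[i]] <- sprintf("LG%d", i)
  }
  grp_sizes <- table(lg[!is.na(lg)])
  audit <- if (length(grp_sizes))
    data.frame(lg = names(grp_sizes), size = as.integer(grp_sizes),
               threshold = audit_threshold)
  else NULL
  structure(list(lg = lg, sizes = grp_sizes, audit = audit),
            class = "linkage_grouping")
}

#' Split linkage groups toward a target count by raising the LOD threshold
#'
#' Starting from a grouping built at the low end of `threshold_range`, the
#' largest groups are revisited in turn: within each, component assignment is
#' re-run at every (integer) threshold in range, and the maximum threshold
#' that still yields at least two components each larger than `min_size` is
#' adopted.  Splitting stops once `target_n` groups exist or no group can be
#' split further.
#'
#' @param grouping A `linkage_grouping` from [assign_linkage_groups()].
#' @param lods Result of [pairwise_lod()].
#' @param target_n Target number of linkage groups.
#' @param threshold_range Inclusive LOD threshold range scanned.
#' @param min_size Minimum linkage-group size.
#' @return A `linkage_grouping` whose `audit` records each split's threshold.
#' @export
split_to_target <- function(grouping, lods, target_n = 42,
                            threshold_range = c(8, 60), min_size = 50) {
  lod <- if (is.list(lods)) lods$lod else lods
  lg <- grouping$lg
  audit <- list()
  thresholds <- seq(ceiling(threshold_range[1]), floor(threshold_range[2]))
  repeat {
    n_lg <- length(unique(lg[!is.na(lg)]))
    if (n_lg >= target_n) break
    groups <- sort(table(lg[!is.na(lg)]), decreasing = TRUE)
    # ties by label: stable order on name within equal sizes
    groups <- groups[order(-as.integer(groups), names(groups))]
    tried <- attr(lg, "unsplittable") %||% character(0)
    cand <- setdiff(names(groups), tried)
    if (!length(cand)) break
    split_done <- FALSE
    for (g in cand) {
      members <- names(lg)[!is.na(lg) & lg == g]
      sub <- lod[members, members, drop = FALSE]
      best <- NULL
      for (th in rev(thresholds)) {   # maximum workable threshold first
        memb <- lod_components(sub, th)
        sz <- table(memb)
        if (sum(sz > min_size) >= 2L) { best <- list(th = th, memb = memb); break }
      }
      if (is.null(best)) {
        attr(lg, "unsplittable") <- c(tried, g)
        next
      }
      sz <- table(best$memb)
      keep_comps <- names(sz)[sz > min_size]
      new_lab <- paste0(g, letters[seq_along(keep_comps)])
      for (i in seq_along(keep_comps))
        lg[members[best$memb == keep_comps[i]]] <- new_lab[i]
      lg[members[!(best$memb %in% keep_comps)]] <- NA_character_
      audit[[length(audit) + 1L]] <- data.frame(
        parent = g, threshold = best$th, n_new = length(keep_comps))
      split_done <- TRUE
      break
    }
    if (!split_done) break
  }
  n_lg <- length(unique(lg[!is.na(lg)]))
  if (n_lg != target_n)
    warning("target of ", target_n, " linkage groups not reached (", n_lg,
            "); returning best grouping")
  attr(lg, "unsplittable") <- NULL
  relabel_grouping(lg, audit)
}

relabel_grouping <- function(lg, audit = list()) {
  sizes <- sort(table(lg[!is.na(lg)]), decreasing = TRUE)
  sizes <- sizes[order(-as.integer(sizes), names(sizes))]
  map <- setNames(sprintf("LG%d", seq_along(sizes)), names(sizes))
  lg_new <- unname(map[lg])
  names(lg_new) <- names(lg)
  structure(list(lg = lg_new, sizes = table(lg_new[!is.na(lg_new)]),
                 audit = if (length(audit)) do.call(rbind, audit) else NULL),
            class = "linkage_grouping")
}

#' Attach singleton markers to linkage groups
#'
#' Each unassigned marker joins the group holding its best-LOD partner when
#' that best LOD is at least `lod_join` and exceeds the second-best group's
#' LOD by at least `min_lod_diff`.  Passes repeat until no singleton moves,
#' so cascades resolve and the result is independent of scan order.
#'
#' @param grouping A `linkage_grouping`.
#' @param lods Result of [pairwise_lod()].
#' @param lod_join Minimum best-group LOD.
#' @param min_lod_diff Minimum margin over the second-best group.
#' @return The augmented `linkage_grouping`.
#' @export
join_singles <- function(grouping, lods, lod_join = 10, min_lod_diff = 5) {
  lod <- if (is.list(lods)) lods$lod else lods
  lg <- grouping$lg
  repeat {
    singles <- names(lg)[is.na(lg)]
    if (!length(singles)) break
    assigned <- lg[!is.na(lg)]
    groups <- unique(assigned)
    if (!length(groups)) break
    # decide all joins against the current grouping, then apply (order-free)
    decisions <- vapply(singles, function(s) {
      per_group <- vapply(groups, function(g) {
        members <- names(assigned)[assigned == g]
        v <- lod[s, members]
        if (all(is.na(v))) -Inf else max(v, na.rm = TRUE)
      }, 0)
      ord <- order(per_group, decreasing = TRUE)
      best <- per_group[ord[1]]
      second <- if (length(per_group) > 1L) per_group[ord[2]] else -Inf
      if (is.finite(best) && best >= lod_join &&
          (best - max(second, 0)) >= min_lod_diff)
        groups[ord[1]] else NA_character_
    }, "")
    if (all(is.na(decisions))) break
    lg[names(decisions)[!is.na(decisions)]] <- decisions[!is.na(decisions)]
  }
  structure(list(lg = lg, sizes = table(lg[!is.na(lg)]),
                 audit = grouping$audit), class = "linkage_grouping")
}
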