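# Homology assignment between linkage groups and reference chromosomes,
# detection of inverted (anti-collinear) segments in cM-vs-bp scatters, and
# pericentric/paracentric classification against centromere intervals.

#' Assign linkage-group / reference-chromosome homologies
#'
#' A reference chromosome is called homologous to a linkage group when at
#' least `min_loci` of the group's markers align to it with mapping quality
#' at least `mq_min`; smaller counts are reported as suggestive only.
#'
#' @param map A `linkage_map_table`.
#' @param aln Alignment table (`marker`, `chrom`, `bp`, `mq`).
#' @param min_loci Minimum qualifying locus count for an asserted homolog.
#' @param mq_min Minimum mapping quality.
#' @return Data frame: `lg`, `ref_chrom`, `n_loci`, `homolog` (logical),
#'   `suggestive` (logical).
#' @export
assign_homology <- function(map, aln, min_loci = 50, mq_min = 60) {
  aln <- aln[aln$mq >= mq_min, , drop = FALSE]
  mm <- merge(map[, c("marker", "lg")], aln, by = "marker")
  if (nrow(mm) == 0L)
    return(data.frame(lg = character(), ref_chrom = character(),
                      n_loci = integer(), homolog = logical(),
                      suggestive = logical()))
  counts <- as.data.frame(table(lg = mm$lg, ref_chrom = mm$chrom),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, ]
  names(counts)[3] <- "n_loci"
  counts$homolog <- counts$n_loci >= min_loci
  counts$suggestive <- !counts$homolog
  counts <- counts[order(counts$lg, -counts$n_loci), ]
  rownames(counts) <- NULL
  counts
}

#' Detect inverted segments in a map-versus-reference scatter
#'
#' The (cM, bp) scatter of one LG/homolog pair is decomposed greedily (in
#' map order) into maximal runs that stay rank-monotone (|Spearman rho| >=
#' `rho_min` within the run).  Runs whose orientation opposes the
#' chromosome-wide majority and that hold at least `min_segment` markers are
#' candidate inversions; their extent is the run's female-map span.
#'
#' @param cm Female-map positions of the markers (sorted ascending).
#' @param bp Reference physical positions of the same markers.
#' @param min_segment Minimum markers per reported segment.
#' @param rho_min Within-run rank-correlation requirement.
#' @return Data frame of segments: `start`, `end` (cM), `n_markers`,
#'   `orientation` (`"forward"`/`"reversed"`/`"unknown"`), `inversion`
#'   (logical: opposes the majority orientation and is large enough).
#' @export
detect_inversion_segments <- function(cm, bp, min_segment = 10,
                                      rho_min = 0.9) {
  stopifnot(length(cm) == length(bp), length(cm) >= 2L)
  ord <- order(cm)
  cm <- cm[ord]; bp <- bp[ord]
  n <- length(cm)
  if (n < 2 * min_segment)
    stop("need at least 2 * min_segment markers")
  # initial runs: maximal stretches with a consistent direction of travel
  # along the reference (sign runs of diff(bp)), so block boundaries land
  # exactly on direction changes
  d <- sign(diff(bp))
  rl <- rle(d)
  ends <- cumsum(rl$lengths) + 1L   # marker index closing each run
  starts <- c(1L, utils::head(ends, -1L) + 1L)  # turning marker to the left run
  runs <- Map(seq, starts, ends)
  # absorb jitter: runs of <= 2 markers merge into the neighbour with the
  # higher combined rank correlation (a whole-run Spearman criterion would
  # silently swallow genuine minority-orientation blocks)
  while (length(runs) > 1L) {
    len <- lengths(runs)
    small <- which(len <= 2L)
    if (!length(small)) break
    q <- small[which.min(len[small])]
    cand <- c(if (q > 1L) q - 1L, if (q < length(runs)) q + 1L)
    rhos <- vapply(cand, function(nb) {
      idx <- sort(c(runs[[q]], runs[[nb]]))
      r <- run_rho(cm[idx], bp[idx])
      if (is.na(r)) 0 else abs(r)
    }, 0)
    nb <- cand[which.max(rhos)]
    lo <- min(q, nb); hi <- max(q, nb)
    runs[[lo]] <- sort(c(runs[[lo]], runs[[hi]]))
    runs[[hi]] <- NULL
  }
  # merge adjacent runs sharing an orientation
  repeat {
    if (length(runs) == 1L) break
    sgn <- vapply(runs, function(idx) {
      r <- if (length(idx) >= 2L) run_rho(cm[idx], bp[idx]) else NA_real_
      if (is.na(r)) 0 else sign(r)
    }, 0)
    pair <- which(sgn[-1L] == sgn[-length(sgn)] & sgn[-1L] != 0)
    if (!length(pair)) break
    q <- pair[1L]
    runs[[q]] <- sort(c(runs[[q]], runs[[q + 1L]]))
    runs[[q + 1L]] <- NULL
  }
  seg <- do.call(rbind, lapply(runs, function(idx) {
    rho <- if (length(idx) >= 2L) run_rho(cm[idx], bp[idx]) else NA_real_
    data.frame(start = min(cm[idx]), end = max(cm[idx]),
               n_markers = length(idx),
               sign = if (is.na(rho)) 0 else sign(rho))
  }))
  # majority orientation weighted by markers
  wsum <- sum(seg$sign * seg$n_markers)
  if (wsum == 0) {
    seg$orientation <- "unknown"
    seg$inversion <- FALSE
  } else {
    majority <- sign(wsum)
    seg$orientation <- ifelse(seg$sign == 0, "unknown",
                              ifelse(seg$sign == majority, "forward",
                                     "reversed"))
    seg$inversion <- seg$orientation == "reversed" &
      seg$n_markers >= min_segment
  }
  seg$sign <- NULL
  seg
}

run_rho <- function(x, y) {
  if (length(unique(y)) < 2L || length(unique(x)) < 2L) return(NA_real_)
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' Classify an inversion segment as pericentric or paracentric
#'
#' Pericentric when the segment's closed interval intersects the centromere
#' interval (boundary contact counts); paracentric otherwise; `"unknown"`
#' when the centromere is unresolved for the linkage group.
#'
#' @param segment One-row data frame with `start`, `end` (cM) and optional
#'   `lg`.
#' @param centromere A `centromere_interval` row (`lg`, `start`, `end`,
#'   `resolved`).
#' @return The segment with a `centricity` column added.
#' @export
classify_centricity <- function(segment, centromere) {
  if (!is.null(segment$lg) && !is.null(centromere$lg) &&
      !is.na(centromere$lg) && segment$lg != centromere$lg)
    stop("segment and centromere belong to different linkage groups")
  if (!isTRUE(centromere$resolved) || is.na(centromere$start)) {
    segment$centricity <- "unknown"
    return(segment)
  }
  s <- sort(c(segment$start, segment$end))
  c_ <- sort(c(centromere$start, centromere$end))
  overlap <- s[1] <= c_[2] && c_[1] <= s[2]
  segment$centricity <- if (overlap) "pericentric" else "paracentric"
  segment
}
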