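# Marker quality control: segregation distortion, MAF, missingness,
# one-SNP-per-RAD-locus thinning, and the LOD-position-matrix filter used to
# purge markers with ambiguous map positions.

#' Construct a genotype table
#'
#' @param geno Markers x offspring matrix of `"A"`, `"H"`, `"B"`, `NA` calls.
#' @param markers Data frame with at least `marker`; optional `locus` (RAD
#'   locus id) and `offset` (bp from the restriction cut site).
#' @param parents Data frame with `marker`, `mother`, `father` genotype codes
#'   (`"A"`, `"H"`, `"B"` or `NA`).
#' @param family Optional offspring-to-family factor (defaults to one family).
#' @return A `genotype_table`.
#' @export
genotype_table <- function(geno, markers, parents, family = NULL) {
  stopifnot(is.matrix(geno), nrow(geno) == nrow(markers),
            nrow(parents) == nrow(markers))
  if (is.null(markers$locus)) markers$locus <- markers$marker
  if (is.null(markers$offset)) markers$offset <- 0L
  if (any(markers$offset < 0)) stop("offsets must be >= 0")
  if (is.null(family)) family <- rep("F1", ncol(geno))
  structure(list(geno = geno, markers = markers, parents = parents,
                 family = as.character(family)), class = "genotype_table")
}

# Expected segregation given parental genotype codes; NULL when the cross is
# uninformative, NA when a parent genotype is unknown.
cross_expectation <- function(mother, father) {
  if (is.na(mother) || is.na(father)) return(NA)
  key <- paste(sort(c(mother, father)), collapse = "")
  switch(key,
         "HH" = c(A = 0.25, H = 0.5, B = 0.25),
         "AH" = c(A = 0.5, H = 0.5),
         "BH" = c(H = 0.5, B = 0.5),
         NULL)
}

#' Filter markers on segregation distortion, MAF and missingness
#'
#' Segregation is tested per family against the ratio expected from the
#' parental cross type (1:2:1 for het x het, 1:1 for het x hom) with a
#' chi-square test without continuity correction; a marker is removed when
#' any family shows p below `p_distortion`.  Minor allele frequency and
#' missing fraction are computed over all offspring.  Markers informative in
#' zero families are removed.  Markers with an unknown cross type are flagged
#' in the report, not silently tested.
#'
#' @param table A [genotype_table()].
#' @param p_distortion Chi-square p-value threshold.
#' @param maf_min Minimum minor allele frequency.
#' @param missing_max Maximum missing fraction.
#' @return List with `table` (filtered, original marker order kept) and
#'   `report` (per-marker statistics and pass/fail flags).
#' @export
filter_markers <- function(table, p_distortion = 0.01, maf_min = 0.05,
                           missing_max = 0.3) {
  geno <- table$geno
  fam <- table$family
  n_mrk <- nrow(geno)
  p_seg <- rep(NA_real_, n_mrk)
  informative <- logical(n_mrk)
  unknown_cross <- logical(n_mrk)
  for (i in seq_len(n_mrk)) {
    p_fam <- c()
    for (f in unique(fam)) {
      exp_ratio <- cross_expectation(table$parents$mother[i],
                                     table$parents$father[i])
      if (is.null(exp_ratio)) next
      if (anyNA(exp_ratio)) { unknown_cross[i] <- TRUE; next }
      obs <- geno[i, fam == f]
      counts <- vapply(names(exp_ratio), function(g) sum(obs == g, na.rm = TRUE), 0)
      if (sum(counts) == 0L) next
      informative[i] <- TRUE
      stat <- sum((counts - sum(counts) * exp_ratio)^2 /
                    (sum(counts) * exp_ratio))
      p_fam <- c(p_fam, stats::pchisq(stat, df = length(counts) - 1L,
                                      lower.tail = FALSE))
    }
    if (length(p_fam)) p_seg[i] <- min(p_fam)
  }
  n_A <- rowSums(geno == "A", na.rm = TRUE)
  n_H <- rowSums(geno == "H", na.rm = TRUE)
  n_B <- rowSums(geno == "B", na.rm = TRUE)
  n_called <- n_A + n_H + n_B
  af <- ifelse(n_called > 0, (2 * n_B + n_H) / (2 * n_called), NA_real_)
  maf <- pmin(af, 1 - af)
  miss_frac <- rowMeans(is.na(geno))
  pass_seg <- is.na(p_seg) | p_seg >= p_distortion
  pass_maf <- !is.na(maf) & maf >= maf_min
  pass_miss <- miss_frac <= missing_max
  keep <- pass_seg & pass_maf & pass_miss & informative
  report <- data.frame(marker = table$markers$marker,
                       p_segregation = p_seg, maf = maf,
                       missing_fraction = miss_frac,
                       informative = informative,
                       unknown_cross = unknown_cross,
                       pass_segregation = pass_seg, pass_maf = pass_maf,
                       pass_missing = pass_miss, keep = keep)
  list(table = subset_genotype_table(table, keep), report = report)
}

subset_genotype_table <- function(table, keep) {
  structure(list(geno = table$geno[keep, , drop = FALSE],
                 markers = table$markers[keep, , drop = FALSE],
                 parents = table$parents[keep, , drop = FALSE],
                 family = table$family), class = "genotype_table")
}

#' Thin to one SNP per RAD locus
#'
#' Keeps, within each RAD locus, the SNP with the smallest offset from the
#' restriction cut site; offset ties break to the lexicographically smaller
#' marker id.  Marker order is otherwise preserved.
#'
#' @param table A [genotype_table()].
#' @return The thinned `genotype_table`.
#' @export
thin_to_one_snp_per_locus <- function(table) {
  mk <- table$markers
  keep <- logical(nrow(mk))
  for (loc in unique(mk$locus)) {
    idx <- which(mk$locus == loc)
    best <- idx[order(mk$offset[idx], mk$marker[idx])][1L]
    keep[best] <- TRUE
  }
  subset_genotype_table(table, keep)
}

#' Filter markers by the shape of their LOD-position vectors
#'
#' Each marker's vector of LOD scores over candidate map positions is
#' min-max normalized to `[0, 1]`.  A marker is removed when (i) its maximum
#' raw LOD is less than `sd_mult` standard deviations above the mean of its
#' raw vector (an uninformative, flat profile), or (ii) it shows two or more
#' local maxima of normalized height at least `peak_height` separated by
#' more than `min_peak_separation` of the vector length (ambiguous position).
#' Constant vectors are degenerate and removed.
#'
#' @param lod_matrix Markers x candidate-positions matrix of raw LOD scores
#'   (>= 4 columns).
#' @param peak_height Minimum normalized height of a counted peak.
#' @param min_peak_separation Minimum separation between distinct peaks, as a
#'   fraction of the vector length (index units).
#' @param sd_mult Multiplier on the raw vector's SD for the flatness rule.
#' @param use_normalized Apply the SD rule to the normalized rather than the
#'   raw vector.
#' @return Data frame with per-marker `keep` decision and diagnostics.
#' @export
lod_position_filter <- function(lod_matrix, peak_height = 0.95,
                                min_peak_separation = 0.25, sd_mult = 1.0,
                                use_normalized = FALSE) {
  stopifnot(is.matrix(lod_matrix), ncol(lod_matrix) >= 4L)
  if (any(!is.finite(lod_matrix))) stop("LOD matrix entries must be finite")
  n_pos <- ncol(lod_matrix)
  res <- lapply(seq_len(nrow(lod_matrix)), function(i) {
    v <- lod_matrix[i, ]
    rng <- range(v)
    if (rng[1] == rng[2])
      return(data.frame(keep = FALSE, n_peaks = NA_integer_,
                        degenerate = TRUE, flat = NA))
    vn <- (v - rng[1]) / (rng[2] - rng[1])
    test_v <- if (use_normalized) vn else v
    flat <- max(test_v) < mean(test_v) + sd_mult * stats::sd(test_v)
    peaks <- local_maxima(vn)
    peaks <- peaks[vn[peaks] >= peak_height]
    sep <- min_peak_separation * n_pos
    n_distinct <- if (length(peaks) <= 1L) length(peaks) else {
      # peaks closer than `sep` collapse into one peak region
      sum(diff(peaks) > sep) + 1L
    }
    data.frame(keep = !flat && n_distinct < 2L, n_peaks = n_distinct,
               degenerate = FALSE, flat = flat)
  })
  out <- do.call(rbind, res)
  out <- cbind(marker = rownames(lod_matrix) %||%
                 as.character(seq_len(nrow(lod_matrix))), out)
  rownames(out) <- NULL
  out
}

local_maxima <- function(v) {
  n <- length(v)
  if (n == 1L) return(1L)
  which(vapply(seq_len(n), function(i) {
    left <- if (i == 1L) -Inf else v[i - 1L]
    right <- if (i == n) -Inf else v[i + 1L]
    v[i] > left && v[i] >= right
  }, logical(1)))
}

#' Drop RAD loci whose SNPs map to more than one linkage group
#'
#' @param markers Data frame with `marker` and `locus` columns.
#' @param lg Named vector of linkage-group labels (names = marker ids;
#'   `NA` = unassigned singleton, ignored for the multi-LG check).
#' @return Logical keep vector aligned with `markers`.
#' @export
drop_multi_lg_loci <- function(markers, lg) {
  lg_of <- lg[markers$marker]
  n_lg <- tapply(lg_of, markers$locus,
                 function(x) length(unique(x[!is.na(x)])))
  bad_loci <- names(n_lg)[n_lg > 1]
  !(markers$locus %in% bad_loci)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
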