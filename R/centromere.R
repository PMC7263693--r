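# Centromere localization.  Two routes: (i) the half-tetrad route, where the
# observed heterozygosity y of gynogenetic-diploid offspring rises with
# marker-centromere distance (y < 0.1 delineates the centromeric region);
# (ii) the RFm route, where maternal recombination accumulated against a
# terminal reference marker plateaus past the centromere (cutoff 0.45).
# Intervals from the two routes are reconciled and the chromosome classified
# metacentric vs acrocentric/telocentric.

#' Filter half-tetrad variant calls down to informative markers
#'
#' Keeps biallelic SNPs only; genotypes with quality at or below `gq_min`
#' are set missing; markers are dropped when the offspring missing fraction
#' exceeds `missing_max`, minor allele frequency falls below `maf_min`, the
#' mother is not heterozygous, or either homozygote class is unobserved
#' among offspring.  The mother is excluded from all counts.
#'
#' @param calls List with `variants` (data frame: `marker`, `ref`, `alt`;
#'   multi-allelic records carry comma-separated `alt`), `gt` (markers x
#'   individuals matrix coded `"A"`/`"H"`/`"B"`/`NA`), optional `gq`
#'   (numeric matrix, same shape), and `mother` (column name).
#'   See [read_halftetrad_vcf()] for building this from a VCF.
#' @param gq_min Genotype-quality threshold (calls with GQ <= gq_min dropped).
#' @param missing_max Maximum offspring missing fraction.
#' @param maf_min Minimum offspring minor allele frequency.
#' @return List with `states` (offspring matrix of retained markers) and
#'   `report` (per-marker filter outcome).
#' @export
filter_halftetrad_variants <- function(calls, gq_min = 10, missing_max = 0.3,
                                       maf_min = 0.05) {
  if (!calls$mother %in% colnames(calls$gt)) stop("mother absent from calls")
  gt <- calls$gt
  if (!is.null(calls$gq)) gt[!is.na(calls$gq) & calls$gq <= gq_min] <- NA
  v <- calls$variants
  snp <- nchar(v$ref) == 1L & !grepl(",", v$alt) & nchar(v$alt) == 1L
  off <- gt[, setdiff(colnames(gt), calls$mother), drop = FALSE]
  mother_het <- gt[, calls$mother] == "H" & !is.na(gt[, calls$mother])
  miss <- rowMeans(is.na(off))
  nA <- rowSums(off == "A", na.rm = TRUE)
  nH <- rowSums(off == "H", na.rm = TRUE)
  nB <- rowSums(off == "B", na.rm = TRUE)
  called <- nA + nH + nB
  af <- ifelse(called > 0, (2 * nB + nH) / (2 * called), NA_real_)
  maf <- pmin(af, 1 - af)
  both_homs <- nA > 0 & nB > 0
  keep <- snp & mother_het & miss <= missing_max &
    !is.na(maf) & maf >= maf_min & both_homs
  report <- data.frame(marker = v$marker, biallelic_snp = snp,
                       mother_het = mother_het, missing_fraction = miss,
                       maf = maf, both_homozygotes = both_homs, keep = keep)
  rownames(report) <- NULL
  list(states = off[keep, , drop = FALSE], report = report)
}

#' Read gynogenetic half-tetrad calls from a VCF
#'
#' Converts a VCF (via the vcfR package) into the call table consumed by
#' [filter_halftetrad_variants()].  Genotypes are recoded relative to
#' REF/ALT: `0/0` -> `"A"`, heterozygous -> `"H"`, `1/1` -> `"B"`.
#'
#' @param path VCF file path.
#' @param mother Sample name of the mother.
#' @return A calls list (`variants`, `gt`, `gq`, `mother`).
#' @export
read_halftetrad_vcf <- function(path, mother) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF input")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  recode <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_character_, length(g))
    out[g %in% "0/0"] <- "A"
    out[g %in% c("0/1", "1/0")] <- "H"
    out[g %in% "1/1"] <- "B"
    out
  }
  gt <- apply(gt_raw, 2L, recode)
  marker <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  rownames(gt) <- marker
  if (!is.null(gq)) rownames(gq) <- marker
  list(variants = data.frame(marker = marker, ref = fix[, "REF"],
                             alt = fix[, "ALT"], stringsAsFactors = FALSE),
       gt = gt, gq = gq, mother = mother)
}

#' Per-marker offspring heterozygosity (y) profile
#'
#' @param data A `halftetrad_dataset` from [simulate_half_tetrad_family()],
#'   or a bare state matrix (`"H"`/`"A"`/`"B"`/`NA`).
#' @return Data frame with `marker`, `y` (heterozygote fraction among scored
#'   offspring; `NA` when none scored) and `n_scored`.
#' @export
estimate_y <- function(data) {
  states <- if (is.matrix(data)) data else data$states
  n_het <- rowSums(states == "H", na.rm = TRUE)
  n_scored <- rowSums(!is.na(states))
  data.frame(marker = rownames(states),
             y = ifelse(n_scored > 0, n_het / n_scored, NA_real_),
             n_scored = n_scored, stringsAsFactors = FALSE)
}

#' Delineate the centromeric interval from a y profile
#'
#' The interval spans the first to the last marker (in map order) with
#' `y < y_threshold`.  With no qualifying marker the linkage group is
#' reported unresolved.
#'
#' @param profile Data frame with `marker`, `y` and `pos` (cM on the ordered
#'   female map).
#' @param y_threshold Heterozygosity cutoff.
#' @param lg Linkage-group label for the output.
#' @return A `centromere_interval` data frame row (`lg`, `start`, `end`,
#'   `method`, `resolved`).
#' @export
delineate_centromere_y <- function(profile, y_threshold = 0.1, lg = "LG1") {
  stopifnot(all(c("y", "pos") %in% names(profile)))
  profile <- profile[order(profile$pos), ]
  qual <- which(!is.na(profile$y) & profile$y < y_threshold)
  if (!length(qual))
    return(data.frame(lg = lg, start = NA_real_, end = NA_real_,
                      method = "half-tetrad", resolved = FALSE))
  data.frame(lg = lg, start = profile$pos[min(qual)],
             end = profile$pos[max(qual)], method = "half-tetrad",
             resolved = TRUE)
}

#' Maternal recombination (RFm) profile against a terminal reference marker
#'
#' For each marker, recombination relative to the terminal marker of the
#' chosen end, computed across maternal haplotypes either as the mean number
#' of observed crossover events in the spanned interval per haplotype
#' (`method = "count"`, the default) or as the fraction of haplotypes in a
#' recombinant state relative to the terminal marker
#' (`method = "fraction"`).
#'
#' @param gam Maternal gamete matrix (markers x meioses, 0/1/NA) with rows
#'   ordered along the map.
#' @param pos Marker positions (cM), same order as rows.
#' @param from `"left"` or `"right"` reference end.
#' @param method `"count"` or `"fraction"`.
#' @return Data frame with `marker`, `pos`, `rfm`.
#' @export
rfm_profile <- function(gam, pos, from = c("left", "right"),
                        method = c("count", "fraction")) {
  from <- match.arg(from)
  method <- match.arg(method)
  if (from == "right") {
    gam <- gam[rev(seq_len(nrow(gam))), , drop = FALSE]
    pos <- rev(pos)
  }
  m <- nrow(gam)
  # per-haplotype cumulative crossover events from the reference end,
  # counting switches between consecutive informative markers
  events <- matrix(0, m, ncol(gam))
  state <- gam[1L, ]
  for (i in 2L:m) {
    cur <- gam[i, ]
    switch_ <- !is.na(state) & !is.na(cur) & state != cur
    events[i, ] <- events[i - 1L, ] + as.integer(switch_)
    state <- ifelse(is.na(cur), state, cur)
  }
  rfm <- if (method == "count") rowMeans(events)
         else rowMeans(events %% 2L)
  out <- data.frame(marker = rownames(gam), pos = pos, rfm = rfm,
                    stringsAsFactors = FALSE)
  out[order(out$pos), ]
}

#' Centromere interval from RFm profiles
#'
#' Both ends are evaluated.  From each reference end, the candidate
#' centromeric region is the maximal contiguous run of markers with
#' `RFm >= cutoff` that reaches the opposite end of the linkage group
#' (the plateau past the centromere).  When a y profile is available the
#' run(s) containing -- or nearest -- the minimum-y position are selected;
#' if both ends' runs qualify their intersection is taken (the metacentric
#' case).  Without y information, intersecting runs are intersected and
#' disjoint runs leave the group unresolved.
#'
#' @param gam Maternal gamete matrix, rows in map order.
#' @param pos Marker positions (cM), same order.
#' @param y_profile Optional data frame with `pos` and `y`.
#' @param cutoff RFm cutoff.
#' @param method Passed to [rfm_profile()].
#' @param lg Linkage-group label.
#' @return A `centromere_interval` data frame row (`lg`, `start`, `end`,
#'   `method`, `resolved`).
#' @export
rfm_centromere <- function(gam, pos, y_profile = NULL, cutoff = 0.45,
                           method = c("count", "fraction"), lg = "LG1") {
  method <- match.arg(method)
  runs <- list()
  for (end in c("left", "right")) {
    pr <- rfm_profile(gam, pos, from = end, method = method)
    ok <- !is.na(pr$rfm)
    if (sum(ok) < 2L) next
    # the profile is monotone away from the reference end in expectation;
    # enforce that with isotonic regression before thresholding so a single
    # noisy dip cannot shift the run boundary
    v <- pr$rfm[ok]
    fit <- if (end == "left") stats::isoreg(v)$yf
           else rev(stats::isoreg(rev(v))$yf)
    above <- fit >= cutoff
    if (!any(above)) next
    run <- which(ok)[above]
    runs[[end]] <- c(min(pr$pos[run]), max(pr$pos[run]))
  }
  unresolved <- data.frame(lg = lg, start = NA_real_, end = NA_real_,
                           method = "RFm", resolved = FALSE)
  if (!length(runs)) return(unresolved)
  if (!is.null(y_profile) && any(!is.na(y_profile$y))) {
    ymin_pos <- y_profile$pos[which.min(y_profile$y)]
    contains <- vapply(runs, function(r) ymin_pos >= r[1] & ymin_pos <= r[2],
                       TRUE)
    sel <- if (any(contains)) runs[contains] else {
      dist <- vapply(runs, function(r)
        min(abs(r - ymin_pos)), 0)
      runs[which.min(dist)]
    }
  } else sel <- runs
  if (length(sel) == 2L) {
    lo <- max(sel[[1]][1], sel[[2]][1])
    hi <- min(sel[[1]][2], sel[[2]][2])
    if (lo > hi) return(unresolved)
    interval <- c(lo, hi)
  } else interval <- sel[[1]]
  data.frame(lg = lg, start = interval[1], end = interval[2],
             method = "RFm", resolved = TRUE)
}

#' Reconcile half-tetrad and RFm centromere intervals and classify
#'
#' Overlapping intervals intersect; disjoint intervals union with a conflict
#' flag.  The chromosome is called metacentric when the reconciled midpoint
#' lies within the central `central_fraction` of the female map, otherwise
#' acrocentric/telocentric; unresolved groups are class `"unknown"`.
#'
#' @param y_interval,rfm_interval `centromere_interval` rows (either may be
#'   unresolved).
#' @param female_length Female map length of the linkage group (cM).
#' @param central_fraction Width of the central window used for the
#'   metacentric call (default the central 50% of the map).
#' @return A `centromere_interval` row with `method = "reconciled"`,
#'   `chrom_class` and `conflict` columns.
#' @export
reconcile_centromeres <- function(y_interval, rfm_interval, female_length,
                                  central_fraction = 0.5) {
  res_y <- isTRUE(y_interval$resolved)
  res_r <- isTRUE(rfm_interval$resolved)
  lg <- if (res_y) y_interval$lg else rfm_interval$lg
  if (!res_y && !res_r)
    return(data.frame(lg = lg, start = NA_real_, end = NA_real_,
                      method = "reconciled", resolved = FALSE,
                      chrom_class = "unknown", conflict = FALSE))
  if (res_y && res_r) {
    lo <- max(y_interval$start, rfm_interval$start)
    hi <- min(y_interval$end, rfm_interval$end)
    if (lo <= hi) { interval <- c(lo, hi); conflict <- FALSE }
    else {
      interval <- c(min(y_interval$start, rfm_interval$start),
                    max(y_interval$end, rfm_interval$end))
      conflict <- TRUE
    }
  } else if (res_y) { interval <- c(y_interval$start, y_interval$end); conflict <- FALSE }
  else { interval <- c(rfm_interval$start, rfm_interval$end); conflict <- FALSE }
  mid <- mean(interval)
  lohi <- female_length * c((1 - central_fraction) / 2,
                            1 - (1 - central_fraction) / 2)
  cls <- if (mid >= lohi[1] && mid <= lohi[2]) "metacentric"
         else "acrocentric/telocentric"
  data.frame(lg = lg, start = interval[1], end = interval[2],
             method = "reconciled", resolved = TRUE, chrom_class = cls,
             conflict = conflict)
}
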