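# Chromosome-specific recombination rate (cM/Mb) by resampled pairwise
# regression through the origin of genetic against physical distance.

#' Estimate per-LG recombination rates by resampled pairwise regression
#'
#' Markers with mapping quality at least `mq_min` lying on reference
#' chromosomes that hold more than `min_loci` such markers are eligible.
#' Per replicate, `n_pairs` marker pairs (same reference chromosome, same
#' LG) are sampled without replacement from all eligible pairs and
#' `|delta cM|` is regressed on `|delta Mb|` with zero intercept
#' (`slope = sum(xy)/sum(x^2)`).  The mean and SD of the slope over
#' `n_reps` replicates are reported, separately for the female, male and
#' sex-averaged maps.
#'
#' @param map A `linkage_map_table` (marker, lg, female_pos, male_pos,
#'   avg_pos).
#' @param aln Alignment table: `marker`, `chrom` (reference), `bp`, `mq`.
#' @param n_pairs Pairs sampled per replicate.
#' @param n_reps Number of replicates.
#' @param mq_min Minimum mapping quality.
#' @param min_loci Minimum qualifying loci per reference chromosome.
#' @return Data frame: `lg`, `sex`, `mean_slope` (cM/Mb), `sd_slope`,
#'   `n_pairs_available`.
#' @export
estimate_rates <- function(map, aln, n_pairs = 100, n_reps = 100,
                           mq_min = 60, min_loci = 50) {
  aln <- aln[aln$mq >= mq_min & aln$marker %in% map$marker, , drop = FALSE]
  chrom_counts <- table(aln$chrom)
  aln <- aln[aln$chrom %in% names(chrom_counts)[chrom_counts > min_loci], ,
             drop = FALSE]
  out <- list()
  for (lg in unique(map$lg)) {
    mm <- map[map$lg == lg, ]
    mm <- merge(mm, aln, by = "marker")
    # enumerate eligible pairs: same reference chromosome within this LG
    pair_idx <- do.call(rbind, lapply(split(seq_len(nrow(mm)), mm$chrom),
                                      function(idx) {
      if (length(idx) < 2L) return(NULL)
      t(utils::combn(idx, 2L))
    }))
    if (is.null(pair_idx) || nrow(pair_idx) == 0L) next
    n_avail <- nrow(pair_idx)
    if (n_avail < n_pairs)
      warning("LG ", lg, ": only ", n_avail, " eligible pairs; using all")
    for (sex in c("female", "male", "avg")) {
      gen <- mm[[paste0(sex, "_pos")]]
      slopes <- vapply(seq_len(n_reps), function(rep) {
        take <- if (n_avail > n_pairs)
          pair_idx[sample.int(n_avail, n_pairs), , drop = FALSE]
        else pair_idx
        dcm <- abs(gen[take[, 1L]] - gen[take[, 2L]])
        dmb <- abs(mm$bp[take[, 1L]] - mm$bp[take[, 2L]]) / 1e6
        sxx <- sum(dmb^2)
        if (sxx == 0) return(NA_real_)   # zero physical spread
        sum(dcm * dmb) / sxx
      }, 0)
      out[[length(out) + 1L]] <- data.frame(
        lg = lg, sex = sex,
        mean_slope = mean(slopes, na.rm = TRUE),
        sd_slope = stats::sd(slopes),
        n_pairs_available = n_avail)
    }
  }
  if (!length(out))
    return(data.frame(lg = character(), sex = character(),
                      mean_slope = numeric(), sd_slope = numeric(),
                      n_pairs_available = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Convert a SAM alignment of RAD-locus consensus sequences to a table
#'
#' Reads the minimal columns of a (headered or headerless) SAM file and
#' returns one best placement per query: query name, reference, 1-based
#' leftmost position and mapping quality.  Secondary/supplementary records
#' (FLAG 0x100/0x800) and unmapped records are dropped.
#'
#' @param path SAM file path.
#' @return Alignment table (`marker`, `chrom`, `bp`, `mq`).
#' @export
read_alignment_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(marker = character(), chrom = character(),
                      bp = integer(), mq = integer()))
  fields <- strsplit(lines, "\t")
  rec <- do.call(rbind, lapply(fields, function(f)
    data.frame(marker = f[1], flag = as.integer(f[2]), chrom = f[3],
               bp = as.integer(f[4]), mq = as.integer(f[5]),
               stringsAsFactors = FALSE)))
  rec <- rec[bitwAnd(rec$flag, 0x4) == 0 & bitwAnd(rec$flag, 0x100) == 0 &
               bitwAnd(rec$flag, 0x800) == 0, , drop = FALSE]
  # one best placement per marker: highest MQ
  rec <- rec[order(rec$marker, -rec$mq), ]
  rec <- rec[!duplicated(rec$marker), c("marker", "chrom", "bp", "mq")]
  rownames(rec) <- NULL
  rec
}
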