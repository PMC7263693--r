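# Meiosis, family and trait simulator with known truth.
#
# Coordinates: marker positions are cM on the female map of each chromosome.
# Crossovers on the four-chromatid bundle follow a count-location model:
# count ~ Poisson(2 * map length in Morgans), locations uniform, each
# crossover joins one chromatid from each homolog chosen uniformly (no
# chromatid interference).  Male meiosis uses the same process but crossovers
# falling outside the telomeric windows are rejected (dropped), which is what
# makes male map lengths emergent rather than prescribed.

#' Describe one chromosome of a simulated genome
#'
#' @param name Chromosome label.
#' @param female_length Female map length in cM.
#' @param male_length Male map length in cM used for the male crossover rate
#'   before telomeric rejection; defaults to the female length so that the
#'   realized male map shrinks purely through `male_telomere_fraction`.
#' @param physical_length Physical size in bp.
#' @param centromere_pos Centromere position on the female map (cM).
#' @param male_telomere_fraction Proportion of each chromosome end (of the
#'   female map) where male crossovers are permitted; 0 suppresses male
#'   recombination entirely, 0.5 permits it everywhere.
#' @return An object of class `chromosome_model`.
#' @export
chromosome_model <- function(name, female_length, male_length = female_length,
                             physical_length = female_length * 1e6,
                             centromere_pos = 0,
                             male_telomere_fraction = 0.1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (female_length < 0 || male_length < 0)
    stop("map lengths must be non-negative")
  if (centromere_pos < 0 || centromere_pos > female_length)
    stop("centromere_pos must lie in [0, female_length]")
  if (male_telomere_fraction < 0 || male_telomere_fraction > 0.5)
    stop("male_telomere_fraction must lie in [0, 0.5]")
  structure(list(name = name, female_length = female_length,
                 male_length = male_length,
                 physical_length = physical_length,
                 centromere_pos = centromere_pos,
                 male_telomere_fraction = male_telomere_fraction),
            class = "chromosome_model")
}

#' Assemble a genome model from chromosomes and marker positions
#'
#' @param chromosomes List of [chromosome_model()] objects.
#' @param marker_positions Named list (one element per chromosome, same order)
#'   of data frames with columns `marker`, `pos` (cM, female map) and `bp`.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, marker_positions) {
  stopifnot(length(chromosomes) == length(marker_positions))
  names(marker_positions) <- vapply(chromosomes, `[[`, "", "name")
  for (i in seq_along(chromosomes)) {
    chr <- chromosomes[[i]]
    mp <- marker_positions[[i]]
    stopifnot(all(c("marker", "pos", "bp") %in% names(mp)))
    if (nrow(mp) == 0L) stop("chromosome ", chr$name, " has no markers")
    if (any(mp$pos < 0 | mp$pos > chr$female_length))
      stop("marker positions outside [0, female_length] on ", chr$name)
    if (is.unsorted(mp$pos)) stop("marker positions must be sorted")
    if (any(diff(mp$bp[!duplicated(mp$pos)]) <= 0) && nrow(mp) > 1L) {
      # physical coordinates must increase where genetic positions do
      ord <- order(mp$pos)
      if (any(diff(mp$bp[ord])[diff(mp$pos[ord]) > 0] <= 0))
        stop("physical coordinates not increasing with genetic position")
    }
  }
  structure(list(chromosomes = chromosomes,
                 marker_positions = marker_positions),
            class = "genome_model")
}

#' Convenience builder for a regular simulated genome
#'
#' Markers are placed on an evenly spaced grid spanning the full female map
#' (endpoints included) with physical positions proportional to genetic
#' positions, i.e. a uniform cM/Mb landscape.
#'
#' @param n_chrom Number of chromosomes.
#' @param n_markers Markers per chromosome.
#' @param female_length Female map length (cM), recycled across chromosomes.
#' @param centromere_pos Centromere positions (cM), recycled.
#' @param male_telomere_fraction See [chromosome_model()].
#' @param cM_per_Mb Physical scale; bp = pos / cM_per_Mb * 1e6.
#' @return A `genome_model`.
#' @export
sim_genome <- function(n_chrom = 1, n_markers = 100, female_length = 100,
                       centromere_pos = 0, male_telomere_fraction = 0.1,
                       cM_per_Mb = 1) {
  female_length <- rep_len(female_length, n_chrom)
  centromere_pos <- rep_len(centromere_pos, n_chrom)
  n_markers <- rep_len(n_markers, n_chrom)
  chroms <- vector("list", n_chrom)
  mpos <- vector("list", n_chrom)
  for (i in seq_len(n_chrom)) {
    nm <- sprintf("chr%02d", i)
    chroms[[i]] <- chromosome_model(
      nm, female_length[i],
      physical_length = female_length[i] / cM_per_Mb * 1e6,
      centromere_pos = centromere_pos[i],
      male_telomere_fraction = male_telomere_fraction)
    pos <- seq(0, female_length[i], length.out = n_markers[i])
    mpos[[i]] <- data.frame(
      marker = sprintf("%s_m%03d", nm, seq_len(n_markers[i])),
      pos = pos, bp = round(pos / cM_per_Mb * 1e6) + 1)
  }
  genome_model(chroms, mpos)
}

# Simulate the four-chromatid bundle for one meiosis on one chromosome.
# Returns origins (4 x n matrix of 1/2) at positions `pos` plus the kept
# crossover locations.  `eval_pos` may include virtual positions (e.g. the
# centromere) beyond the marker list.
sim_bundle <- function(chrom, eval_pos, sex = c("female", "male"),
                       obligate_chiasma = FALSE) {
  sex <- match.arg(sex)
  if (length(eval_pos) == 0L) stop("empty marker list")
  L <- chrom$female_length
  rate_len <- if (sex == "female") chrom$female_length else chrom$male_length
  if (rate_len < 0) stop("negative map length")
  n_xo <- if (rate_len > 0) stats::rpois(1L, 2 * rate_len / 100) else 0L
  if (obligate_chiasma && rate_len > 0) n_xo <- max(n_xo, 1L)
  xo <- if (n_xo > 0) stats::runif(n_xo, 0, L) else numeric(0)
  if (sex == "male" && length(xo)) {
    f <- chrom$male_telomere_fraction
    keep <- xo <= f * L | xo >= (1 - f) * L
    xo <- xo[keep]
  }
  origins <- matrix(rep(c(1L, 1L, 2L, 2L), length(eval_pos)), nrow = 4L)
  if (length(xo)) {
    cen <- chrom$centromere_pos
    # each chiasma joins one chromatid of each homolog and exchanges the
    # centromere-distal segments, so rows 1,2 and 3,4 remain the sister
    # pairs; working outward from the centromere, the exchanged pair is one
    # strand currently carrying homolog-1 DNA and one carrying homolog-2
    # DNA at that point (uniform among the 2 x 2 choices)
    apply_arm <- function(origins, xs, prefix) {
      s <- c(1L, 1L, 2L, 2L)   # current origin of each row on this arm
      for (x in xs) {
        i <- sample(which(s == 1L), 1L)
        j <- sample(which(s == 2L), 1L)
        distal <- if (prefix) eval_pos < x else eval_pos > x
        if (any(distal)) {
          tmp <- origins[i, distal]
          origins[i, distal] <- origins[j, distal]
          origins[j, distal] <- tmp
        }
        s[c(i, j)] <- s[c(j, i)]
      }
      origins
    }
    origins <- apply_arm(origins, sort(xo[xo >= cen]), prefix = FALSE)
    origins <- apply_arm(origins, sort(xo[xo < cen], decreasing = TRUE),
                         prefix = TRUE)
  }
  list(origins = origins, crossovers = xo)
}

#' Simulate one meiosis and return a single gamete
#'
#' Crossovers arise on the four-chromatid bundle (Poisson count with mean
#' twice the map length in Morgans, uniform locations, uniform non-sister
#' chromatid choice); male crossovers outside the telomeric windows are
#' rejected.  One chromatid is returned uniformly at random.
#'
#' @param chrom A [chromosome_model()].
#' @param positions Marker positions (cM, female map), sorted.
#' @param parent_phase 2 x n matrix of parental haplotype alleles
#'   (row 1 = haplotype 1, row 2 = haplotype 2).
#' @param sex `"female"` or `"male"`.
#' @param obligate_chiasma Force at least one crossover per bundle.
#' @return List with `alleles` (gamete haplotype), `origins` (1/2 vector of
#'   parental haplotype of origin per marker) and `crossovers` (bundle
#'   crossover positions retained after any male telomeric rejection).
#' @export
simulate_meiosis <- function(chrom, positions, parent_phase,
                             sex = c("female", "male"),
                             obligate_chiasma = FALSE) {
  sex <- match.arg(sex)
  if (length(positions) == 0L) stop("empty marker list")
  stopifnot(is.matrix(parent_phase), nrow(parent_phase) == 2L,
            ncol(parent_phase) == length(positions))
  b <- sim_bundle(chrom, positions, sex, obligate_chiasma)
  pick <- sample.int(4L, 1L)
  org <- b$origins[pick, ]
  list(alleles = parent_phase[cbind(org, seq_along(positions))],
       origins = org, crossovers = b$crossovers)
}

geno_code <- function(a1, a2) {
  ifelse(is.na(a1) | is.na(a2), NA_character_,
         ifelse(a1 == a2, ifelse(a1 == "A", "A", "B"), "H"))
}

#' Simulate a phase-known diploid mapping family
#'
#' Each offspring is one maternal meiosis (female recombination model) plus
#' one paternal meiosis (telomere-restricted male model).  Genotyping errors
#' flip transmitted alleles independently; missingness masks whole genotypes.
#' Both parents are heterozygous A/B at every marker (intercross-style
#' informative markers) unless founder phases are supplied.
#'
#' @param genome A [genome_model()].
#' @param n_offspring Number of offspring (>= 1).
#' @param error_rate Per-transmitted-allele flip probability.
#' @param missing_rate Per-genotype missingness probability.
#' @param founders Optional list with elements `mother` and `father`, each a
#'   named list per chromosome of 2 x n allele matrices.
#' @param obligate_chiasma Passed to the bundle simulator.
#' @return A `family_dataset`: marker table, genotype matrix (A/H/B/NA),
#'   maternal/paternal origin-call matrices (1/2/NA, reflecting simulated
#'   errors), truth matrices (error-free origins), crossover log, error log.
#' @export
simulate_diploid_family <- function(genome, n_offspring, error_rate = 0,
                                    missing_rate = 0, founders = NULL,
                                    obligate_chiasma = FALSE) {
  if (n_offspring < 1) stop("n_offspring must be >= 1")
  if (error_rate < 0 || error_rate > 1 || missing_rate < 0 || missing_rate > 1)
    stop("rates must lie in [0, 1]")
  mk <- marker_table(genome)
  n_mrk <- nrow(mk)
  default_phase <- function(n) matrix(c(rep("A", n), rep("B", n)),
                                      nrow = 2L, byrow = TRUE)
  truth_m <- truth_p <- matrix(NA_integer_, n_mrk, n_offspring,
                               dimnames = list(mk$marker, NULL))
  xo_log <- list()
  for (ci in seq_along(genome$chromosomes)) {
    chrom <- genome$chromosomes[[ci]]
    mp <- genome$marker_positions[[ci]]
    rows <- match(mp$marker, mk$marker)
    for (ind in seq_len(n_offspring)) {
      mm <- sim_bundle(chrom, mp$pos, "female", obligate_chiasma)
      pm <- sim_bundle(chrom, mp$pos, "male", obligate_chiasma)
      truth_m[rows, ind] <- mm$origins[sample.int(4L, 1L), ]
      truth_p[rows, ind] <- pm$origins[sample.int(4L, 1L), ]
      n_xo_tot <- length(mm$crossovers) + length(pm$crossovers)
      if (n_xo_tot > 0)
        xo_log[[length(xo_log) + 1L]] <- data.frame(
          chrom = rep(chrom$name, n_xo_tot), ind = rep(ind, n_xo_tot),
          parent = rep(c("mother", "father"),
                       c(length(mm$crossovers), length(pm$crossovers))),
          pos = c(mm$crossovers, pm$crossovers))
    }
  }
  # observed origin calls: allele flips on a het parent flip the origin call
  flip_m <- matrix(stats::runif(n_mrk * n_offspring) < error_rate,
                   n_mrk, n_offspring)
  flip_p <- matrix(stats::runif(n_mrk * n_offspring) < error_rate,
                   n_mrk, n_offspring)
  obs_m <- ifelse(flip_m, 3L - truth_m, truth_m)
  obs_p <- ifelse(flip_p, 3L - truth_p, truth_p)
  phase_of <- function(which_parent, ci) {
    if (is.null(founders)) default_phase(nrow(genome$marker_positions[[ci]]))
    else founders[[which_parent]][[ci]]
  }
  al_m <- al_p <- matrix(NA_character_, n_mrk, n_offspring)
  for (ci in seq_along(genome$chromosomes)) {
    mp <- genome$marker_positions[[ci]]
    rows <- match(mp$marker, mk$marker)
    phm <- phase_of("mother", ci); php <- phase_of("father", ci)
    for (ind in seq_len(n_offspring)) {
      al_m[rows, ind] <- phm[cbind(obs_m[rows, ind], seq_len(nrow(mp)))]
      al_p[rows, ind] <- php[cbind(obs_p[rows, ind], seq_len(nrow(mp)))]
    }
  }
  geno <- matrix(geno_code(al_m, al_p), n_mrk, n_offspring,
                 dimnames = list(mk$marker, sprintf("ind%03d", seq_len(n_offspring))))
  miss <- matrix(stats::runif(n_mrk * n_offspring) < missing_rate,
                 n_mrk, n_offspring)
  geno[miss] <- NA_character_
  obs_m[miss] <- NA_integer_
  obs_p[miss] <- NA_integer_
  dimnames(obs_m) <- dimnames(obs_p) <- dimnames(geno)
  dimnames(truth_m) <- dimnames(truth_p) <- dimnames(geno)
  err_idx <- which((flip_m | flip_p) & !miss, arr.ind = TRUE)
  structure(list(
    markers = mk,
    genotypes = geno,
    maternal = obs_m, paternal = obs_p,
    truth = list(maternal = truth_m, paternal = truth_p,
                 crossovers = do.call(rbind, xo_log)),
    missing_mask = miss,
    error_log = data.frame(marker = mk$marker[err_idx[, 1L]],
                           ind = err_idx[, 2L]),
    parents = data.frame(marker = mk$marker, mother = "H", father = "H",
                         stringsAsFactors = FALSE),
    n_offspring = n_offspring), class = "family_dataset")
}

#' Flatten a genome model's marker positions into one table
#' @param genome A `genome_model`.
#' @return Data frame with marker, chrom, pos, bp, locus, offset columns.
#' @export
marker_table <- function(genome) {
  out <- do.call(rbind, lapply(seq_along(genome$chromosomes), function(ci) {
    mp <- genome$marker_positions[[ci]]
    data.frame(marker = mp$marker, chrom = genome$chromosomes[[ci]]$name,
               pos = mp$pos, bp = mp$bp,
               locus = mp$marker, offset = 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a gynogenetic half-tetrad family
#'
#' Each offspring retains the two sister chromatids of one secondary oocyte
#' (second-polar-body retention).  Sisters are identified by shared parental
#' origin at the centromere after crossing over, so a marker is heterozygous
#' exactly when a crossover has separated it from its centromere on one of
#' the two retained strands.
#'
#' @param genome A [genome_model()]; the mother is heterozygous A/B at all
#'   markers.
#' @param n_offspring Number of gynogenetic offspring (>= 1).
#' @param obligate_chiasma Force one crossover per bundle.
#' @return A `halftetrad_dataset`: marker table, `states` matrix with values
#'   `"H"` (heterozygous), `"A"`, `"B"` (the two homozygotes) and `NA`.
#' @export
simulate_half_tetrad_family <- function(genome, n_offspring,
                                        obligate_chiasma = FALSE) {
  if (n_offspring < 1) stop("n_offspring must be >= 1")
  mk <- marker_table(genome)
  states <- matrix(NA_character_, nrow(mk), n_offspring,
                   dimnames = list(mk$marker,
                                   sprintf("gyn%03d", seq_len(n_offspring))))
  for (ci in seq_along(genome$chromosomes)) {
    chrom <- genome$chromosomes[[ci]]
    mp <- genome$marker_positions[[ci]]
    rows <- match(mp$marker, mk$marker)
    eval_pos <- c(mp$pos, chrom$centromere_pos)
    cen_i <- length(eval_pos)
    for (ind in seq_len(n_offspring)) {
      b <- sim_bundle(chrom, eval_pos, "female", obligate_chiasma)
      cen_origin <- sample.int(2L, 1L)
      pair <- which(b$origins[, cen_i] == cen_origin)
      o1 <- b$origins[pair[1L], -cen_i]
      o2 <- b$origins[pair[2L], -cen_i]
      states[rows, ind] <- ifelse(o1 != o2, "H", ifelse(o1 == 1L, "A", "B"))
    }
  }
  structure(list(markers = mk, states = states, n_offspring = n_offspring,
                 mother = data.frame(marker = mk$marker, genotype = "H")),
            class = "halftetrad_dataset")
}

#' Describe a trait architecture for simulation
#'
#' @param qtl Data frame with columns `chrom`, `pos` (cM), `a` (additive
#'   effect, half the homozygote difference) and `d` (dominance deviation).
#' @param residual_sd Residual standard deviation (trait units).
#' @param type `"normal"` or `"binary"`.
#' @param threshold Liability threshold for binary traits.
#' @return A `trait_model`.
#' @export
trait_model <- function(qtl = NULL, residual_sd = 1,
                        type = c("normal", "binary"), threshold = 0) {
  type <- match.arg(type)
  if (residual_sd < 0) stop("residual_sd must be >= 0")
  if (is.null(qtl)) qtl <- data.frame(chrom = character(), pos = numeric(),
                                      a = numeric(), d = numeric())
  structure(list(qtl = qtl, residual_sd = residual_sd, type = type,
                 threshold = threshold), class = "trait_model")
}

#' Simulate trait values for a diploid family
#'
#' The genetic score of an individual sums, over QTL, `-a` / `d` / `+a` for
#' the hom-1 / het / hom-2 origin class at the marker nearest each QTL (truth
#' origins, error-free).  Normal traits add Gaussian noise; binary traits
#' threshold the same liability.
#'
#' @param trait A [trait_model()].
#' @param family A `family_dataset`.
#' @param genome The `genome_model` the family was simulated from.
#' @return Data frame with `ind` and `value` columns (binary traits in 0/1).
#' @export
simulate_phenotypes <- function(trait, family, genome) {
  n <- family$n_offspring
  score <- numeric(n)
  if (nrow(trait$qtl)) {
    mk <- family$markers
    for (q in seq_len(nrow(trait$qtl))) {
      qq <- trait$qtl[q, ]
      on_chr <- mk$chrom == qq$chrom
      if (!any(on_chr)) stop("QTL chromosome not in genome: ", qq$chrom)
      idx <- which(on_chr)[which.min(abs(mk$pos[on_chr] - qq$pos))]
      gm <- family$truth$maternal[idx, ]
      gp <- family$truth$paternal[idx, ]
      cls <- gm + gp  # 2 = hom1, 3 = het, 4 = hom2
      score <- score + ifelse(cls == 2L, -qq$a, ifelse(cls == 3L, qq$d, qq$a))
    }
  }
  liab <- score + stats::rnorm(n, 0, trait$residual_sd)
  if (trait$type == "binary") {
    if (length(unique(liab)) == 1L)
      stop("degenerate binary trait: all liabilities identical")
    value <- as.integer(liab > trait$threshold)
  } else value <- liab
  data.frame(ind = colnames(family$genotypes), value = value,
             stringsAsFactors = FALSE)
}

#' Extract phase-known gamete matrices from a simulated family
#'
#' @param family A `family_dataset`.
#' @param parent `"mother"`, `"father"` or `"both"`.
#' @param use_truth Use error-free truth origins instead of observed calls.
#' @return Named list of markers x meioses matrices coded 0/1/NA.
#' @export
gamete_matrices <- function(family, parent = c("both", "mother", "father"),
                            use_truth = FALSE) {
  parent <- match.arg(parent)
  src <- if (use_truth) family$truth else family[c("maternal", "paternal")]
  if (use_truth) src <- list(maternal = src$maternal, paternal = src$paternal)
  out <- list()
  if (parent %in% c("both", "mother")) out$mother <- src$maternal - 1L
  if (parent %in% c("both", "father")) out$father <- src$paternal - 1L
  out
}
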