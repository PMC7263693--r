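# File formats, configuration and the end-to-end pipeline driver.
# Conventions: genetic positions are decimal cM; TSV missing sentinel is
# "NA"; VCF input follows its own 1-based standard (see read_halftetrad_vcf).

#' Read and write tab-separated tables
#'
#' Thin wrappers fixing the conventions used throughout the pipeline:
#' header line, tab separator, `"NA"` missing sentinel, no quoting, no row
#' names.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `read_tsv_table` returns a data frame.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a genotype matrix as markers x individuals TSV
#' @param geno Character matrix (A/H/B/NA) with marker rownames.
#' @param path File path.
#' @export
write_genotype_tsv <- function(geno, path) {
  df <- data.frame(marker = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_table(df, path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$marker
  m
}

#' Default pipeline configuration
#'
#' All stage thresholds with their defaults; any subset can be overridden by
#' a YAML file or by the `...` arguments.
#'
#' @param path Optional YAML file whose entries override the defaults.
#' @param ... Named overrides applied after the file.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    # simulation
    n_chrom = 4, n_markers = 60, female_length = 100, centromere_pos = 0,
    male_telomere_fraction = 0.1, n_offspring = 180, n_gynogens = 45,
    error_rate = 0, missing_rate = 0,
    # marker QC
    p_distortion = 0.01, maf_min = 0.05, missing_max = 0.3,
    lod_peak_height = 0.95, lod_min_peak_separation = 0.25,
    # grouping
    lod_range = c(8, 60), target_n = NULL, min_lg_size = 50,
    join_lod = 10, join_min_diff = 5,
    # ordering
    n_restarts = 20,
    # centromere
    y_threshold = 0.1, rfm_cutoff = 0.45, gq_min = 10,
    # QTL scan
    pseudomarker_step = 1, kinship_thin = 3, peak_threshold = 3,
    peakdrop = 2, ci_prob = 0.95, n_perm = 1000,
    # recombination rate
    n_pairs = 100, n_reps = 100, mq_min = 60, min_loci = 50)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run the simulation-to-scan pipeline
#'
#' Deterministic given the seed: simulates a genome and families, runs
#' marker QC, grouping, ordering, centromere mapping and (when a trait model
#' is supplied) the QTL scan, writing each stage's TSV plus a JSON
#' provenance block into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param trait Optional [trait_model()] to simulate and scan.
#' @return Invisibly, a list of stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, trait = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  genome <- sim_genome(n_chrom = config$n_chrom,
                       n_markers = config$n_markers,
                       female_length = config$female_length,
                       centromere_pos = config$centromere_pos,
                       male_telomere_fraction = config$male_telomere_fraction)
  fam <- simulate_diploid_family(genome, config$n_offspring,
                                 error_rate = config$error_rate,
                                 missing_rate = config$missing_rate)
  gyn <- simulate_half_tetrad_family(genome, config$n_gynogens)
  write_genotype_tsv(fam$genotypes, file.path(out_dir, "genotypes.tsv"))
  write_genotype_tsv(gyn$states, file.path(out_dir, "halftetrad.tsv"))

  gt <- genotype_table(fam$genotypes, fam$markers, fam$parents)
  qc <- filter_markers(gt, config$p_distortion, config$maf_min,
                       config$missing_max)
  write_tsv_table(qc$report, file.path(out_dir, "filter_report.tsv"))
  gt <- thin_to_one_snp_per_locus(qc$table)

  gams <- gamete_matrices(fam)
  gams <- lapply(gams, function(g) g[gt$markers$marker, , drop = FALSE])
  pl <- pairwise_lod(gams)
  grouping <- assign_linkage_groups(pl, config$lod_range[1],
                                    config$min_lg_size)
  target <- config$target_n %||% config$n_chrom
  grouping <- split_to_target(grouping, pl, target_n = target,
                              threshold_range = config$lod_range,
                              min_size = config$min_lg_size)
  grouping <- join_singles(grouping, pl, config$join_lod,
                           config$join_min_diff)
  write_tsv_table(data.frame(marker = names(grouping$lg), lg = grouping$lg),
                  file.path(out_dir, "grouping.tsv"))

  maps <- list()
  centro <- list()
  for (lg in sort(unique(grouping$lg[!is.na(grouping$lg)]))) {
    members <- names(grouping$lg)[!is.na(grouping$lg) & grouping$lg == lg]
    sub <- lapply(gams, function(g) g[members, , drop = FALSE])
    mo <- order_markers(sub, n_restarts = config$n_restarts)
    maps[[lg]] <- map_positions(mo, lg = lg)
    # centromere from half-tetrad states of the same markers, mapped onto
    # the estimated order
    states <- gyn$states[intersect(members, rownames(gyn$states)), ,
                         drop = FALSE]
    yp <- estimate_y(states)
    yp$pos <- maps[[lg]]$female_pos[match(yp$marker, maps[[lg]]$marker)]
    y_int <- delineate_centromere_y(yp, config$y_threshold, lg = lg)
    ordm <- sub$mother[maps[[lg]]$marker, , drop = FALSE]
    rfm_int <- rfm_centromere(ordm, maps[[lg]]$female_pos, y_profile = yp,
                              cutoff = config$rfm_cutoff, lg = lg)
    centro[[lg]] <- reconcile_centromeres(y_int, rfm_int,
                                          max(maps[[lg]]$female_pos))
  }
  map_tab <- do.call(rbind, maps)
  rownames(map_tab) <- NULL
  write_tsv_table(map_tab, file.path(out_dir, "map.tsv"))
  summ <- summarize_map(map_tab)
  write_tsv_table(summ$per_lg, file.path(out_dir, "map_summary.tsv"))
  centro_tab <- do.call(rbind, centro)
  rownames(centro_tab) <- NULL
  write_tsv_table(centro_tab, file.path(out_dir, "centromeres.tsv"))

  scan_out <- NULL
  if (!is.null(trait)) {
    phe <- simulate_phenotypes(trait, fam, genome)
    grid <- insert_pseudomarkers(
      data.frame(marker = fam$markers$marker, chrom = fam$markers$chrom,
                 pos = fam$markers$pos), config$pseudomarker_step)
    probs <- calc_genoprob(fam$maternal, fam$paternal,
                           fam$markers[, c("marker", "chrom", "pos")], grid)
    scan <- if (trait$type == "binary") scan_binary(probs, phe$value)
            else scan_normal(probs, phe$value,
                             kinship = calc_kinship(probs,
                                                    config$kinship_thin))
    peaks <- find_peaks_ci(scan, config$peak_threshold, config$peakdrop,
                           config$ci_prob)
    if (nrow(peaks)) {
      perm <- permutation_pvalues(probs, phe$value, peaks,
                                  n_perm = config$n_perm,
                                  model = if (trait$type == "binary")
                                    "binary" else "normal",
                                  kinship = NULL)
      peaks <- perm$peaks
      peaks$pve <- pve(peaks$lod, length(phe$value))
    }
    write_tsv_table(as.data.frame(scan), file.path(out_dir, "scan.tsv"))
    write_tsv_table(peaks, file.path(out_dir, "peaks.tsv"))
    scan_out <- list(scan = scan, peaks = peaks)
  }

  prov <- list(package = "tetramap",
               version = as.character(utils::packageVersion("tetramap")),
               config = unclass(config), config_md5 = config_hash(config),
               n_markers_mapped = sum(!is.na(grouping$lg)),
               n_linkage_groups = length(unique(grouping$lg[!is.na(grouping$lg)])))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "provenance.json"))
  invisible(list(genome = genome, family = fam, gynogens = gyn,
                 grouping = grouping, map = map_tab, summary = summ,
                 centromeres = centro_tab, scan = scan_out))
}
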