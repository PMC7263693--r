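#!/usr/bin/env Rscript
# Stage 1: simulate the study system with known truth.
#
# A small salmonid-style genome: mixed metacentric and acro/telocentric
# chromosomes, strong heterochiasmy (male crossovers confined to telomeric
# windows), one diploid mapping family, one gynogenetic half-tetrad family,
# and two traits (a normal growth-like trait and a binary sex-like locus).
# Everything downstream reads only the files written here.

library(tetramap)

set.seed(20260901)
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- sim_genome(
  n_chrom = 4, n_markers = 80,
  female_length = c(106, 95, 88, 60),
  centromere_pos = c(53, 0, 0, 30),        # one metacentric, two telo, one sub
  male_telomere_fraction = 0.1, cM_per_Mb = 1)

fam <- simulate_diploid_family(genome, n_offspring = 180)
gyn <- simulate_half_tetrad_family(genome, n_offspring = 45)

traits <- data.frame(
  ind = colnames(fam$genotypes),
  growth = simulate_phenotypes(
    trait_model(qtl = data.frame(chrom = "chr01", pos = 30, a = 1, d = 0.2),
                residual_sd = sqrt(0.5 * 0.85 / 0.15)),
    fam, genome)$value,
  sex = simulate_phenotypes(
    trait_model(qtl = data.frame(chrom = "chr02", pos = 65, a = 2.5, d = 0),
                residual_sd = 1, type = "binary"),
    fam, genome)$value)

write_genotype_tsv(fam$genotypes, file.path(out, "genotypes.tsv"))
write_genotype_tsv(gyn$states, file.path(out, "halftetrad.tsv"))
storage_int <- function(m) {
  m2 <- matrix(as.character(m), nrow(m), dimnames = dimnames(m))
  m2
}
write_genotype_tsv(storage_int(fam$maternal),
                   file.path(out, "gametes_maternal.tsv"))
write_genotype_tsv(storage_int(fam$paternal),
                   file.path(out, "gametes_paternal.tsv"))
write_tsv_table(fam$markers, file.path(out, "markers_truth.tsv"))
write_tsv_table(traits, file.path(out, "traits.tsv"))
write_tsv_table(data.frame(marker = fam$markers$marker, chrom = "ref_chr",
                           bp = fam$markers$bp, mq = 60L),
                file.path(out, "alignment.tsv"))
truth <- list(
  chromosomes = lapply(genome$chromosomes, unclass),
  qtl = list(growth = list(chrom = "chr01", pos = 30),
             sex = list(chrom = "chr02", pos = 65)))
writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, pretty = TRUE,
                            digits = NA),
           file.path(out, "truth.json"))

message("simulated ", nrow(fam$markers), " markers on ",
        length(genome$chromosomes), " chromosomes; ",
        ncol(fam$genotypes), " diploid offspring, ",
        ncol(gyn$states), " gynogens; sex ratio ",
        round(mean(traits$sex), 2))
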