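#!/usr/bin/env Rscript
# Stage 2: marker quality control.
#
# Segregation-distortion, MAF and missingness filters against the expected
# intercross ratios, then thinning to one SNP per RAD locus.  On the
# error-free simulation nearly everything should survive; the filter report
# is the artifact of record.

library(tetramap)

sim <- "results/sim"
out <- "results/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

geno <- read_genotype_tsv(file.path(sim, "genotypes.tsv"))
markers <- read_tsv_table(file.path(sim, "markers_truth.tsv"))
tab <- genotype_table(geno, markers,
                      parents = data.frame(marker = markers$marker,
                                           mother = "H", father = "H"))

qc <- filter_markers(tab, p_distortion = 0.01, maf_min = 0.05,
                     missing_max = 0.3)
thinned <- thin_to_one_snp_per_locus(qc$table)

write_tsv_table(qc$report, file.path(out, "filter_report.tsv"))
write_tsv_table(thinned$markers, file.path(out, "markers_kept.tsv"))

message(sum(qc$report$keep), " of ", nrow(qc$report),
        " markers pass QC; ", nrow(thinned$markers),
        " after one-SNP-per-locus thinning")
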