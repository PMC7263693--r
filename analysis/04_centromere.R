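#!/usr/bin/env Rscript
# Stage 4: centromere mapping.
#
# Per linkage group: the half-tetrad y profile (heterozygosity of
# gynogenetic offspring) delineated at y < 0.1, the maternal RFm profile
# thresholded at 0.45 and disambiguated by the y minimum, then
# reconciliation and metacentric vs acro/telocentric classification.

library(tetramap)

out <- "results/centromere"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

map <- read_tsv_table("results/map/map.tsv")
states <- read_genotype_tsv("results/sim/halftetrad.tsv")
gm <- read_genotype_tsv("results/sim/gametes_maternal.tsv")
mode(gm) <- "integer"

rows <- lapply(sort(unique(map$lg)), function(lg) {
  mm <- map[map$lg == lg, ]
  yp <- estimate_y(states[mm$marker, , drop = FALSE])
  yp$pos <- mm$female_pos
  y_int <- delineate_centromere_y(yp, y_threshold = 0.1, lg = lg)
  rfm_int <- rfm_centromere(gm[mm$marker, , drop = FALSE] - 1L, mm$female_pos,
                            y_profile = yp, cutoff = 0.45, lg = lg)
  cbind(reconcile_centromeres(y_int, rfm_int, max(mm$female_pos)),
        y_resolved = y_int$resolved, rfm_resolved = rfm_int$resolved)
})
centro <- do.call(rbind, rows)
write_tsv_table(centro, file.path(out, "centromeres.tsv"))

message(sum(centro$resolved), " of ", nrow(centro),
        " linkage groups have a reconciled centromere (",
        sum(centro$chrom_class == "metacentric"), " metacentric)")
print(centro)
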