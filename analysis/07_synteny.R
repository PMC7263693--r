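#!/usr/bin/env Rscript
# Stage 7: homology and inversion centricity.
#
# Homology calls against the reference alignment (>= 50 loci at MQ >= 60),
# then a constructed divergent reference: the 0-30 cM block of the first
# linkage group is reversed in physical coordinates to emulate an inversion
# differentiating the mapped genome from the reference.  Detected reversed
# segments are classified pericentric/paracentric against the stage-4
# centromere intervals.

library(tetramap)

out <- "results/synteny"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

map <- read_tsv_table("results/map/map.tsv")
aln <- read_tsv_table("results/sim/alignment.tsv")
centro <- read_tsv_table("results/centromere/centromeres.tsv")

hom <- assign_homology(map, aln, min_loci = 50, mq_min = 60)
write_tsv_table(hom, file.path(out, "homology.tsv"))

# divergent reference: reverse the physical block spanning 0-30 cM of LG1
lg1 <- map[map$lg == "LG1", ]
aln1 <- aln[match(lg1$marker, aln$marker), ]
block <- lg1$female_pos <= 30
aln1$bp[block] <- rev(aln1$bp[block])

seg <- detect_inversion_segments(lg1$female_pos, aln1$bp, min_segment = 10)
seg$lg <- "LG1"
cen1 <- centro[centro$lg == "LG1", ]
seg <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i)
  classify_centricity(seg[i, ], cen1)))
write_tsv_table(seg, file.path(out, "inversions.tsv"))

inv <- seg[seg$inversion, ]
message(nrow(inv), " inverted segment(s) on LG1: ",
        paste(sprintf("%.0f-%.0f cM (%s)", inv$start, inv$end,
                      inv$centricity), collapse = "; "))
print(seg)
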