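# Half-tetrad variant filtering, y profiles, y/RFm centromere delineation
# and reconciliation.

toy_calls <- function() {
  gt <- rbind(
    snp_ok   = c("H", "H", "A", "B", "H", "A", "B", "H", "A"),
    triallel = c("H", "H", "A", "B", "H", "A", "B", "H", "A"),
    mom_hom  = c("A", "H", "A", "B", "H", "A", "B", "H", "A"),
    one_hom  = c("H", "H", "A", "A", "H", "A", "A", "H", "A"),
    missing_ = c("H", "H", NA, NA, NA, "A", "B", "H", "A"))
  colnames(gt) <- c("mom", paste0("o", 1:8))
  variants <- data.frame(
    marker = rownames(gt),
    ref = "A",
    alt = c("T", "T,G", "T", "T", "T"))
  list(variants = variants, gt = gt, gq = NULL, mother = "mom")
}

test_that("half-tetrad variant filter applies the full rule chain", {
  res <- filter_halftetrad_variants(toy_calls(), missing_max = 0.3,
                                    maf_min = 0.05)
  rep_ <- res$report
  expect_false(rep_$keep[rep_$marker == "triallel"])   # >2 alleles
  expect_false(rep_$keep[rep_$marker == "mom_hom"])    # mother not het
  expect_false(rep_$keep[rep_$marker == "one_hom"])    # hom-B unobserved
  expect_false(rep_$keep[rep_$marker == "missing_"])   # 3/8 missing
  expect_true(rep_$keep[rep_$marker == "snp_ok"])
  expect_identical(rownames(res$states), "snp_ok")
  # mother removed from downstream counts
  expect_false("mom" %in% colnames(res$states))
  calls2 <- toy_calls(); calls2$mother <- "nope"
  expect_error(filter_halftetrad_variants(calls2), "mother absent")
})

test_that("low-MAF markers fail the frequency rule", {
  gt <- rbind(rare = c("H", rep("A", 19), "H"))
  colnames(gt) <- c("mom", paste0("o", 1:20))
  calls <- list(variants = data.frame(marker = "rare", ref = "A", alt = "T"),
                gt = gt, gq = NULL, mother = "mom")
  res <- filter_halftetrad_variants(calls)
  expect_equal(res$report$maf[1], 1 / 40)
  expect_false(res$report$keep[1])
})

test_that("genotype-quality masking feeds the missingness rule", {
  calls <- toy_calls()
  gq <- matrix(99, nrow(calls$gt), ncol(calls$gt),
               dimnames = dimnames(calls$gt))
  gq["snp_ok", c("o1", "o2", "o3")] <- 5       # <= 10 -> missing
  calls$gq <- gq
  res <- filter_halftetrad_variants(calls)
  expect_false(res$report$keep[res$report$marker == "snp_ok"])
  expect_gt(res$report$missing_fraction[res$report$marker == "snp_ok"], 0.3)
})

test_that("VCF round trip produces the expected A/H/B coding", {
  skip_if_not_installed("vcfR")
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tmom\to1\to2",
    "loc1\t10\t.\tA\tT\t50\tPASS\t.\tGT:GQ\t0/1:60\t0/0:60\t1/1:60",
    "loc2\t20\t.\tG\tC\t50\tPASS\t.\tGT:GQ\t0/1:60\t0/1:5\t./.:.")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines, path)
  calls <- read_halftetrad_vcf(path, mother = "mom")
  expect_identical(unname(calls$gt["loc1:10", ]), c("H", "A", "B"))
  expect_identical(unname(calls$gt["loc2:20", c("mom", "o1")]), c("H", "H"))
  expect_true(is.na(calls$gt["loc2:20", "o2"]))
  expect_equal(unname(calls$gq["loc2:20", "o1"]), 5)
})

test_that("y estimation is simple arithmetic with missing-safe behavior", {
  states <- matrix("A", 3, 45, dimnames = list(c("m1", "m2", "m3"), NULL))
  states["m1", 1:10] <- "H"
  states["m2", ] <- "B"
  states["m3", ] <- NA
  yp <- estimate_y(states)
  expect_equal(yp$y[1], 10 / 45, tolerance = 1e-12)
  expect_equal(round(yp$y[1], 4), 0.2222)
  expect_equal(yp$y[2], 0)
  expect_true(is.na(yp$y[3]))
  expect_equal(yp$n_scored[3], 0)
})

test_that("y-based delineation takes the first-to-last sub-threshold span", {
  prof <- data.frame(marker = paste0("m", 1:7),
                     pos = c(0, 10, 20, 40, 45, 60, 80),
                     y = c(0.5, 0.3, 0.2, 0.05, 0.08, 0.3, 0.5))
  ci <- delineate_centromere_y(prof, 0.1)
  expect_true(ci$resolved)
  expect_equal(c(ci$start, ci$end), c(40, 45))
  prof$y <- pmax(prof$y, 0.2)
  ci2 <- delineate_centromere_y(prof, 0.1)
  expect_false(ci2$resolved)
  expect_true(is.na(ci2$start))
})

test_that("RFm profiles accumulate maternal crossover events from either
           end", {
  # 4 markers, 4 gametes with hand-countable switch patterns
  gam <- rbind(m1 = c(0L, 0L, 1L, 1L),
               m2 = c(0L, 1L, 1L, 1L),
               m3 = c(1L, 1L, 1L, 0L),
               m4 = c(1L, 1L, 0L, 0L))
  pos <- c(0, 10, 20, 30)
  pr <- rfm_profile(gam, pos, from = "left", method = "count")
  # per-gamete switch positions reading m1 -> m4:
  # g1 (0,0,1,1): m3; g2 (0,1,1,1): m2; g3 (1,1,1,0): m4; g4 (1,1,0,0): m3
  # cumulative means: m1 0; m2 1/4; m3 3/4; m4 4/4
  expect_equal(pr$rfm, c(0, 1 / 4, 3 / 4, 4 / 4))
  pr_r <- rfm_profile(gam, pos, from = "right", method = "count")
  expect_equal(pr_r$rfm[pr_r$marker == "m4"], 0)
  expect_equal(pr_r$rfm[pr_r$marker == "m1"], 1)
  # fraction method coincides here (all per-gamete counts are 0/1)
  prf <- rfm_profile(gam, pos, from = "left", method = "fraction")
  expect_equal(prf$rfm, c(0, 1 / 4, 3 / 4, 4 / 4))
})

test_that("RFm centromere intervals recover simulated telocentric and
           metacentric centromeres", {
  set.seed(41)
  # telocentric: centromere at 0 of a 100 cM chromosome; maternal gametes
  # pooled to the four-diploid-family scale (~360 meioses)
  gen_t <- sim_genome(1, 60, 100, centromere_pos = 0)
  fam_t <- simulate_diploid_family(gen_t, 360)
  gm_t <- gamete_matrices(fam_t)$mother
  pos_t <- gen_t$marker_positions[[1]]$pos
  yp_t <- estimate_y(simulate_half_tetrad_family(gen_t, 45))
  yp_t$pos <- pos_t
  ci_t <- rfm_centromere(gm_t, pos_t, y_profile = yp_t, cutoff = 0.45)
  expect_true(ci_t$resolved)
  expect_equal(ci_t$start, 0)          # interval abuts the telomere
  expect_lt(ci_t$start, 5)
  # metacentric: centromere at 50
  gen_m <- sim_genome(1, 60, 100, centromere_pos = 50)
  fam_m <- simulate_diploid_family(gen_m, 360)
  gm_m <- gamete_matrices(fam_m)$mother
  pos_m <- gen_m$marker_positions[[1]]$pos
  yp_m <- estimate_y(simulate_half_tetrad_family(gen_m, 45))
  yp_m$pos <- pos_m
  ci_m <- rfm_centromere(gm_m, pos_m, y_profile = yp_m, cutoff = 0.45)
  expect_true(ci_m$resolved)
  # both-end runs intersect near the centromere; boundary noise at n = 200
  # gametes is a few cM, so check the midpoint and overlap with the y dip
  expect_gt(mean(c(ci_m$start, ci_m$end)), 40)
  expect_lt(mean(c(ci_m$start, ci_m$end)), 60)
  y_int <- delineate_centromere_y(yp_m, 0.1)
  expect_true(ci_m$start <= y_int$end && y_int$start <= ci_m$end)
})

test_that("two-marker groups stay unresolved below the cutoff", {
  gam <- rbind(m1 = rep(0L, 50), m2 = c(rep(1L, 5), rep(0L, 45)))
  ci <- rfm_centromere(gam, c(0, 10), cutoff = 0.45)
  expect_false(ci$resolved)
})

test_that("reconciliation intersects, unions with conflict, and classifies", {
  y_i <- data.frame(lg = "LG1", start = 40, end = 45, method = "half-tetrad",
                    resolved = TRUE)
  r_i <- data.frame(lg = "LG1", start = 42, end = 50, method = "RFm",
                    resolved = TRUE)
  rec <- reconcile_centromeres(y_i, r_i, female_length = 100)
  expect_equal(c(rec$start, rec$end), c(42, 45))
  expect_false(rec$conflict)
  expect_equal(rec$chrom_class, "metacentric")

  r_d <- data.frame(lg = "LG1", start = 30, end = 35, method = "RFm",
                    resolved = TRUE)
  y_d <- data.frame(lg = "LG1", start = 5, end = 10, method = "half-tetrad",
                    resolved = TRUE)
  rec2 <- reconcile_centromeres(y_d, r_d, female_length = 100)
  expect_equal(c(rec2$start, rec2$end), c(5, 35))
  expect_true(rec2$conflict)

  y_a <- data.frame(lg = "LG2", start = 0, end = 8, method = "half-tetrad",
                    resolved = TRUE)
  r_u <- data.frame(lg = "LG2", start = NA_real_, end = NA_real_,
                    method = "RFm", resolved = FALSE)
  rec3 <- reconcile_centromeres(y_a, r_u, female_length = 100)
  expect_equal(rec3$chrom_class, "acrocentric/telocentric")

  rec4 <- reconcile_centromeres(
    data.frame(lg = "LG3", start = NA_real_, end = NA_real_,
               method = "half-tetrad", resolved = FALSE), r_u, 100)
  expect_false(rec4$resolved)
  expect_equal(rec4$chrom_class, "unknown")
})

test_that("a map with one data-starved group mirrors the 41-of-42 outcome", {
  set.seed(42)
  n_lg <- 3
  res <- lapply(seq_len(n_lg), function(i) {
    if (i < n_lg) {
      gen <- sim_genome(1, 40, 100, centromere_pos = 0)
    } else {
      # the starved group: markers only on a short centromere-distal stub,
      # so no marker can show y < 0.1 and RFm cannot reach the cutoff
      gen <- genome_model(
        list(chromosome_model("chr01", 100, centromere_pos = 0)),
        list(data.frame(marker = sprintf("s%d", 1:5),
                        pos = seq(60, 80, 5), bp = seq(60e6, 80e6, 5e6))))
    }
    yp <- estimate_y(simulate_half_tetrad_family(gen, 45))
    yp$pos <- gen$marker_positions[[1]]$pos
    fam <- simulate_diploid_family(gen, 150)
    gm <- gamete_matrices(fam)$mother
    y_i <- delineate_centromere_y(yp, 0.1, lg = paste0("LG", i))
    r_i <- rfm_centromere(gm, yp$pos, y_profile = yp,
                          lg = paste0("LG", i))
    reconcile_centromeres(y_i, r_i, 100)
  })
  resolved <- vapply(res, function(r) r$resolved, TRUE)
  expect_equal(sum(resolved), n_lg - 1)
  expect_equal(res[[n_lg]]$chrom_class, "unknown")
})
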