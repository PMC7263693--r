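# Marker QC: segregation-distortion / MAF / missingness filters, RAD-locus
# thinning, and the LOD-position-matrix filter.

make_table <- function(counts_list, mother = "H", father = "A") {
  # counts_list: per marker, named counts of A/H/B (+ NAs via `miss`)
  geno <- do.call(rbind, lapply(counts_list, function(cc) {
    g <- rep(names(cc), cc)
    c(g, rep(NA_character_, attr(cc, "miss") %||% 0))
  }))
  rownames(geno) <- sprintf("m%02d", seq_along(counts_list))
  n <- nrow(geno)
  genotype_table(geno,
                 markers = data.frame(marker = rownames(geno)),
                 parents = data.frame(marker = rownames(geno),
                                      mother = rep(mother, n),
                                      father = rep(father, n)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("segregation-distortion filter matches the chi-square tail", {
  tab <- make_table(list(c(A = 45, H = 45), c(A = 60, H = 30)))
  res <- filter_markers(tab)
  expect_equal(res$report$p_segregation[1], 1)
  # 60:30 on a 1:1 expectation: chi-square 10 on 1 df
  expect_equal(res$report$p_segregation[2],
               pchisq(10, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(res$report$p_segregation[2], 0.01)
  expect_identical(res$report$keep, c(TRUE, FALSE))
  expect_identical(res$table$markers$marker, "m01")
})

test_that("het-x-het markers are tested against 1:2:1", {
  tab <- make_table(list(c(A = 25, H = 50, B = 25), c(A = 50, H = 25, B = 25)),
                    mother = "H", father = "H")
  res <- filter_markers(tab)
  expect_equal(res$report$p_segregation[1], 1)
  stat <- sum((c(50, 25, 25) - 100 * c(.25, .5, .25))^2 / (100 * c(.25, .5, .25)))
  expect_equal(res$report$p_segregation[2],
               pchisq(stat, df = 2, lower.tail = FALSE))
})

test_that("low-MAF and high-missingness markers are removed; unknown cross
           types are flagged", {
  cc <- c(A = 92, H = 8)          # allele freq of B = 0.04
  tab <- make_table(list(cc))
  res <- filter_markers(tab)
  expect_false(res$report$pass_maf[1])
  expect_false(res$report$keep[1])
  cc2 <- c(A = 30, H = 30); attr(cc2, "miss") <- 40   # 40% missing
  tab2 <- make_table(list(cc2))
  res2 <- filter_markers(tab2)
  expect_false(res2$report$pass_missing[1])
  tab3 <- make_table(list(c(A = 45, H = 45)), mother = NA)
  res3 <- filter_markers(tab3)
  expect_true(res3$report$unknown_cross[1])
  expect_false(res3$report$informative[1])
})

test_that("filters act as independent predicates (order invariance)", {
  set.seed(11)
  gen <- sim_genome(1, 40, 60)
  fam <- simulate_diploid_family(gen, 90, missing_rate = 0.1)
  tab <- genotype_table(fam$genotypes, fam$markers, fam$parents)
  res <- filter_markers(tab)
  joint <- res$report$keep
  manual <- res$report$pass_segregation & res$report$pass_maf &
    res$report$pass_missing & res$report$informative
  expect_identical(joint, manual)
})

test_that("distortion filter type-I rate on balanced data is near nominal", {
  set.seed(12)
  gen <- sim_genome(1, 200, 400)
  fam <- simulate_diploid_family(gen, 200)
  tab <- genotype_table(fam$genotypes, fam$markers, fam$parents)
  res <- filter_markers(tab, p_distortion = 0.05)
  rate <- mean(!res$report$pass_segregation)
  ci <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(rate, ci[1]); expect_lte(rate, ci[2])
})

test_that("RAD-locus thinning keeps the cut-site-proximal SNP with
           lexicographic ties", {
  geno <- matrix("H", 5, 4,
                 dimnames = list(c("b_88", "a_12", "c_30", "a_30", "solo"),
                                 NULL))
  mk <- data.frame(marker = rownames(geno),
                   locus = c("L1", "L1", "L2", "L2", "L3"),
                   offset = c(88L, 12L, 30L, 30L, 5L))
  tab <- genotype_table(geno, mk,
                        parents = data.frame(marker = mk$marker,
                                             mother = "H", father = "H"))
  thin <- thin_to_one_snp_per_locus(tab)
  expect_setequal(thin$markers$marker, c("a_12", "a_30", "solo"))
  # invariant under input row permutation
  for (i in 1:5) {
    perm <- sample(nrow(mk))
    tabp <- genotype_table(geno[perm, , drop = FALSE], mk[perm, ],
                           parents = data.frame(marker = mk$marker[perm],
                                                mother = "H", father = "H"))
    expect_setequal(thin_to_one_snp_per_locus(tabp)$markers$marker,
                    c("a_12", "a_30", "solo"))
  }
})

test_that("LOD-position filter keeps sharp single peaks and drops ambiguous
           or flat profiles", {
  n_pos <- 40
  sharp <- c(rep(0.2, 19), 5, rep(0.2, 20))                # one clear peak
  two_far <- rep(0.2, n_pos); two_far[1] <- 2; two_far[32] <- 1.95
  # normalized heights 1.0 and ~0.97, separated by 31 > 25% of 40
  two_near <- rep(0.2, n_pos); two_near[18] <- 2; two_near[22] <- 1.98
  flat <- rep(c(0, 1), 20)      # max below mean + sd: uninformative profile
  const <- rep(0.5, n_pos)
  m <- rbind(sharp = sharp, two_far = two_far, two_near = two_near,
             flat = flat, const = const)
  res <- lod_position_filter(m)
  expect_true(res$keep[res$marker == "sharp"])
  expect_false(res$keep[res$marker == "two_far"])
  expect_true(res$keep[res$marker == "two_near"])
  expect_false(res$keep[res$marker == "flat"])
  expect_false(res$keep[res$marker == "const"])
  expect_true(res$degenerate[res$marker == "const"])
  # peak counting agrees with the brute-force scan
  for (nm in c("sharp", "two_far", "two_near")) {
    v <- m[nm, ]
    vn <- (v - min(v)) / (max(v) - min(v))
    expect_equal(res$n_peaks[res$marker == nm],
                 count_peaks_bruteforce(vn, 0.95, 0.25 * n_pos))
  }
})

test_that("loci spanning multiple linkage groups are dropped entirely", {
  mk <- data.frame(marker = c("a1", "a2", "b1", "c1"),
                   locus = c("LA", "LA", "LB", "LC"))
  lg <- c(a1 = "LG1", a2 = "LG2", b1 = "LG1", c1 = NA)
  keep <- drop_multi_lg_loci(mk, lg)
  expect_identical(keep, c(FALSE, FALSE, TRUE, TRUE))
})
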