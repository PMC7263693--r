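# Pseudomarker grids, genotype probabilities, kinship, normal/binary scans,
# peak finding with credible intervals, permutations and PVE.

# small helper: probs object from a simulated family on its true map
family_probs <- function(gen, fam, step = 1) {
  mm <- data.frame(marker = fam$markers$marker, chrom = fam$markers$chrom,
                   pos = fam$markers$pos)
  calc_genoprob(fam$maternal, fam$paternal, mm,
                insert_pseudomarkers(mm, step))
}

test_that("pseudomarker insertion unions marker and grid positions", {
  map <- data.frame(marker = c("a", "b"), chrom = "c1", pos = c(0, 5))
  expect_equal(insert_pseudomarkers(map, 1)$pos, 0:5)
  map2 <- data.frame(marker = c("a", "b"), chrom = "c1", pos = c(0, 0.4))
  expect_equal(insert_pseudomarkers(map2, 1)$pos, c(0, 0.4))
  map3 <- data.frame(marker = c("a", "b"), chrom = "c1", pos = c(0, 2.5))
  expect_equal(insert_pseudomarkers(map3, 1)$pos, c(0, 1, 2, 2.5))
  expect_error(insert_pseudomarkers(map, 0), "step")
})

test_that("genotype probabilities are degenerate at observed markers and
           follow the two-flank formula at pseudomarkers", {
  mm <- data.frame(marker = c("a", "b"), chrom = "c1", pos = c(0, 10))
  maternal <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("a", "b"), "i1"))
  paternal <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("a", "b"), "i1"))
  grid <- insert_pseudomarkers(mm, 1)
  pr <- calc_genoprob(maternal, paternal, mm, grid)
  expect_equal(pr$pAA[1, grid$pos == 0], 1)
  expect_equal(pr$pAA[1, grid$pos == 10], 1)
  # midway: per-chain stay probability (1-r)^2 / ((1-r)^2 + r^2) with
  # r = Haldane(5 cM); genotype class is the product of the two chains
  r <- (1 - exp(-2 * 5 / 100)) / 2
  chain <- (1 - r)^2 / ((1 - r)^2 + r^2)
  expect_equal(pr$m1[1, grid$pos == 5], chain, tolerance = 1e-12)
  expect_equal(pr$pAA[1, grid$pos == 5], chain^2, tolerance = 1e-12)
  expect_equal(round(chain^2, 5), 0.99503)
  # missing both flanks: uniform
  maternal2 <- matrix(NA_integer_, 2, 1, dimnames = list(c("a", "b"), "i1"))
  pr2 <- calc_genoprob(maternal2, maternal2, mm, grid)
  expect_true(all(pr2$m1 == 0.5))
  expect_equal(pr2$pAB[1, 1], 0.5)
})

test_that("genotype probabilities are proper at every position", {
  set.seed(51)
  gen <- sim_genome(2, 12, 50)
  fam <- simulate_diploid_family(gen, 30, missing_rate = 0.2)
  pr <- family_probs(gen, fam)
  expect_true(all(pr$m1 >= 0 & pr$m1 <= 1))
  expect_true(all(pr$pAA >= 0 & pr$pAB >= 0 & pr$pBB >= 0))
  expect_equal(pr$pAA + pr$pAB + pr$pBB,
               matrix(1, nrow(pr$pAA), ncol(pr$pAA)))
})

test_that("kinship is 1 on the diagonal and for clone pairs, and matches a
           Monte-Carlo expectation for full sibs", {
  set.seed(52)
  gen <- sim_genome(2, 30, 80)
  fam <- simulate_diploid_family(gen, 60)
  pr <- family_probs(gen, fam)
  K <- calc_kinship(pr, thin_step = 3)
  expect_equal(unname(diag(K)), rep(1, 60))
  expect_true(all(K <= 1 + 1e-8))
  # clone pair: duplicate one individual's origin calls
  fam2 <- fam
  fam2$maternal[, 2] <- fam2$maternal[, 1]
  fam2$paternal[, 2] <- fam2$paternal[, 1]
  pr2 <- family_probs(gen, fam2)
  K2 <- calc_kinship(pr2, 3)
  expect_equal(K2[1, 2], 1, tolerance = 1e-8)
  # full sibs share a parental-origin class with probability 1/4 + ... ;
  # Monte-Carlo oracle: mean over many independent positions of the
  # same-class indicator for random sib pairs
  set.seed(53)
  mc <- replicate(20000, {
    g1 <- c(sample(2, 1), sample(2, 1))
    g2 <- c(sample(2, 1), sample(2, 1))
    all(g1 == g2)
  })
  off <- K[upper.tri(K)]
  expect_equal(mean(off), mean(mc), tolerance = 0.05)
})

test_that("normal scans equal brute-force per-position regression", {
  set.seed(54)
  gen <- sim_genome(1, 15, 60)
  fam <- simulate_diploid_family(gen, 80)
  pr <- family_probs(gen, fam)
  tm <- trait_model(qtl = data.frame(chrom = "chr01", pos = 30, a = 1, d = 0.3),
                    residual_sd = 1)
  y <- simulate_phenotypes(tm, fam, gen)$value
  scan <- scan_normal(pr, y)
  for (p in sample(nrow(scan), 12)) {
    expect_equal(scan$lod[p],
                 hk_lod_bruteforce(pr$pAA[, p], pr$pAB[, p], pr$pBB[, p], y),
                 tolerance = 1e-8)
  }
  expect_true(all(scan$lod >= 0))
  # constant trait: identically zero
  scan0 <- scan_normal(pr, rep(2, 80))
  expect_true(all(scan0$lod == 0))
})

test_that("kinship-adjusted scans stay close to OLS on independent data and
           recover a simulated QTL", {
  set.seed(55)
  gen <- sim_genome(2, 25, 80)
  fam <- simulate_diploid_family(gen, 150)
  pr <- family_probs(gen, fam)
  a <- 1; target <- 0.15
  res_sd <- sqrt((a^2 / 2) * (1 - target) / target)
  tm <- trait_model(qtl = data.frame(chrom = "chr01", pos = 40, a = a, d = 0),
                    residual_sd = res_sd)
  y <- simulate_phenotypes(tm, fam, gen)$value
  K <- calc_kinship(pr, 3)
  scan_o <- scan_normal(pr, y)
  scan_k <- scan_normal(pr, y, kinship = K)
  peak_o <- scan_o[which.max(scan_o$lod), ]
  peak_k <- scan_k[which.max(scan_k$lod), ]
  expect_equal(peak_o$lg, "chr01")
  expect_lt(abs(peak_o$pos - 40), 10)
  expect_gt(peak_o$lod, 3)
  # the whole-genome kinship absorbs part of the QTL variance (no
  # leave-one-chromosome-out), so the mixed-model peak is attenuated but
  # stays at the same location
  expect_equal(peak_k$lg, "chr01")
  expect_lt(abs(peak_k$pos - 40), 10)
  expect_lte(peak_k$lod, peak_o$lod)
  expect_gt(peak_k$lod, 1)
})

test_that("binary scans reach the saturated-model bound under perfect
           separation and stay near zero under the null", {
  set.seed(56)
  gen <- sim_genome(1, 9, 40)
  fam <- simulate_diploid_family(gen, 100)
  pr <- family_probs(gen, fam)
  # perfect separation by genotype class (hom-2 vs rest) at marker 5
  idx <- which(pr$grid$marker == "chr01_m005")
  y_sep <- as.integer(pr$pBB[, idx] > 0.5)
  p1 <- mean(y_sep)
  # saturated model: LOD approaches the full null deviance in log10 units
  bound <- -(sum(y_sep) * log10(p1) + (100 - sum(y_sep)) * log10(1 - p1))
  scan <- scan_binary(pr, y_sep)
  expect_gt(max(scan$lod), 0.95 * bound)
  y_null <- rbinom(100, 1, 0.5)
  scan_n <- scan_binary(pr, y_null)
  expect_lt(max(scan_n$lod), 3)
  expect_error(scan_binary(pr, rep(1, 100)), "both")
})

test_that("balanced perfect separation attains the 30.10 LOD clamp", {
  # direct engine check with hand-built degenerate probabilities
  n <- 100
  m1 <- matrix(rep(c(1, 0), each = n / 2), n, 1)
  probs <- list(grid = data.frame(chrom = "c", pos = 0, marker = "m"),
                m1 = m1, p1 = m1, pAA = m1 * m1, pAB = m1 * 0,
                pBB = (1 - m1)^2)
  probs$pAB <- 1 - probs$pAA - probs$pBB
  y <- rep(c(1, 0), each = 50)
  scan <- scan_binary(probs, y)
  expect_equal(scan$lod, 100 * log10(2), tolerance = 1e-4)
})

test_that("peak finding merges shallow valleys and bounds credible
           intervals", {
  pos <- 0:100
  lod <- pmax(6.5 - abs(pos - 3) * 1.5, 0.2)
  scan <- structure(data.frame(lg = "LG1", pos = pos, lod = lod),
                    class = c("scan_result", "data.frame"))
  pk <- find_peaks_ci(scan)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$pos, 3)
  expect_true(pk$ci_low <= 3 & pk$ci_high >= 3)

  # two maxima LOD 5 and 4.5 with a valley at 4: shallower than peakdrop 2
  lod2 <- rep(0.2, 101)
  lod2[21] <- 5; lod2[22:40] <- 4; lod2[41] <- 4.5
  lod2[22:40] <- 4
  scan2 <- structure(data.frame(lg = "LG1", pos = pos, lod = lod2),
                     class = c("scan_result", "data.frame"))
  pk2 <- find_peaks_ci(scan2)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$pos, 20)

  # deep valley: two distinct peaks
  lod3 <- rep(0.2, 101)
  lod3[21] <- 5; lod3[61] <- 4.5
  scan3 <- structure(data.frame(lg = "LG1", pos = pos, lod = lod3),
                     class = c("scan_result", "data.frame"))
  expect_equal(nrow(find_peaks_ci(scan3)), 2)

  # flat profile at 3.5: one peak, CI spans ~95% of the group
  scan4 <- structure(data.frame(lg = "LG1", pos = pos, lod = rep(3.5, 101)),
                     class = c("scan_result", "data.frame"))
  pk4 <- find_peaks_ci(scan4)
  expect_equal(nrow(pk4), 1)
  expect_gte(pk4$ci_high - pk4$ci_low, 0.9 * 100)
})

test_that("permutation p-values behave under null and extreme peaks", {
  set.seed(57)
  gen <- sim_genome(1, 10, 50)
  fam <- simulate_diploid_family(gen, 60)
  pr <- family_probs(gen, fam, step = 5)
  y <- rnorm(60)
  peaks <- data.frame(lg = "chr01", pos = 25,
                      lod = c(0.5, 50))
  res <- permutation_pvalues(pr, y, peaks, n_perm = 200, model = "normal")
  expect_gt(res$peaks$p_value[1], 0.2)   # unremarkable score
  expect_equal(res$peaks$p_value[2], 1 / 201)
  expect_match(res$peaks$p_label[2], "^< ")
  expect_length(res$perm_max, 200)
  expect_warning(
    permutation_pvalues(pr, y, peaks[1, ], n_perm = 50, model = "normal"),
    "unstable")
})

test_that("PVE reproduces published conversions and is monotone", {
  expect_equal(pve(8.538, 323), 0.115)
  expect_equal(pve(8.04, 323), 0.108)
  expect_equal(pve(6.563, 143), 0.191)
  expect_equal(pve(4.855, 143), 0.145)
  expect_equal(pve(4.401, 179), 0.107)
  expect_equal(pve(3.796, 179), 0.093)
  expect_equal(pve(0, 100), 0)
  lods <- seq(0, 20, 0.5)
  expect_true(all(diff(pve(lods, 100, digits = 10)) > 0))
  ns <- seq(50, 500, 50)
  expect_true(all(diff(pve(5, ns, digits = 10)) < 0))
  expect_error(pve(3, 0), "positive")
  expect_error(pve(-1, 10), ">= 0")
})
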