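test_that("bootstrap resamples are balanced with exactly one imputed observation", {
  sim <- simulateVirome(syntheticConfig(nPhyla = 3, samplesPerPhylum = 18, seed = 31L))
  counts <- t(viromeCounts(sim$experiment))
  phylum <- sampleData(sim$experiment)$phylum
  set.seed(1)
  for (r in 1:25) {
    rs <- bootstrapResample(counts, phylum, groupSize = 15)
    expect_true(all(table(rs$meta$phylum) == 15))
    # the shuffled observation appears only under the imputed label
    labs <- unique(rs$meta$phylum[rs$meta$origId == rs$shuffled])
    expect_identical(labs, rs$imputedPhylum)
    expect_true(rs$imputedPhylum != rs$originalPhylum)
    # resampled rows are rows of the input matrix
    expect_true(all(rs$meta$origId %in% rownames(counts)))
  }
  # determinism under a fixed RNG state
  set.seed(99); a <- bootstrapResample(counts, phylum)
  set.seed(99); b <- bootstrapResample(counts, phylum)
  expect_identical(a, b)
  expect_error(bootstrapResample(counts, rep("onlyone", nrow(counts))), "2 phyla")
})

test_that("pairwise tests cover n(n-1)/2 pairs with valid p-values", {
  sim <- simulateVirome(syntheticConfig(nPhyla = 4, samplesPerPhylum = 6, seed = 32L))
  counts <- t(viromeCounts(sim$experiment))
  phylum <- sampleData(sim$experiment)$phylum
  set.seed(2)
  pw <- pairwisePhylumTests(counts, phylum, nPerm = 49)
  expect_equal(nrow(pw), 6L)      # 4*(4-1)/2
  expect_true(all(pw$p_permanova > 0 & pw$p_permanova <= 1))
  expect_true(all(pw$p_permdisp > 0 & pw$p_permdisp <= 1))

  # a pair of phyla holding identical duplicated samples: PERMANOVA accepts
  base <- counts[phylum == "Phylum01", ][1:6, ]
  dup <- rbind(base, base)
  set.seed(3)
  pwDup <- pairwisePhylumTests(dup, rep(c("X", "Y"), each = 6), nPerm = 199)
  expect_gt(pwDup$p_permanova, 0.5)
})

test_that("outcome coding follows the four-level FDR rule", {
  mk <- function(pa, pd) data.frame(phylum_a = "A", phylum_b = "B",
                                    p_permanova = pa, p_permdisp = pd)
  expect_identical(as.character(encodeOutcomes(mk(0.01, 0.30))$code), "LOC_DIFF")
  expect_identical(as.character(encodeOutcomes(mk(0.50, 0.50))$code), "NEITHER")
  expect_identical(as.character(encodeOutcomes(mk(0.01, 0.01))$code), "BOTH_REJECT")
  expect_identical(as.character(encodeOutcomes(mk(0.90, 0.001))$code), "DISP_ONLY")
  # pooled family: PERMANOVA p adjusted over both families jointly
  two <- rbind(mk(0.04, 0.9), mk(0.9, 0.9))
  pooled <- encodeOutcomes(two)
  expect_equal(pooled$fdr_permanova[1], 0.04 * 4, tolerance = 1e-12)
  separate <- encodeOutcomes(two, fdrFamily = "separate")
  expect_equal(separate$fdr_permanova[1], 0.08, tolerance = 1e-12)
})

test_that("network edges require support strictly above the threshold", {
  oc <- data.frame(iteration = rep(1:10, each = 2),
                   phylum_a = rep(c("A", "A"), 10),
                   phylum_b = rep(c("B", "C"), 10),
                   code = c(rbind(rep("LOC_DIFF", 10),
                                  rep(c("NEITHER", "LOC_DIFF"), each = 5))))
  net <- buildEquivalenceNetwork(oc, supportThreshold = 0.2)
  sup <- setNames(net$support$support, net$support$phylum_b)
  expect_equal(sup[["B"]], 0)
  expect_equal(sup[["C"]], 0.5)
  expect_identical(net$edges$phylum_b, "C")
  # support exactly at the threshold draws no edge
  netHalf <- buildEquivalenceNetwork(oc, supportThreshold = 0.5)
  expect_equal(nrow(netHalf$edges), 0L)
  # raising the threshold can only remove edges
  for (thr in c(0.1, 0.3, 0.6)) {
    eLow <- buildEquivalenceNetwork(oc, thr)$edges
    eHigh <- buildEquivalenceNetwork(oc, min(1, thr + 0.2))$edges
    expect_true(all(paste(eHigh$phylum_a, eHigh$phylum_b) %in%
                    paste(eLow$phylum_a, eLow$phylum_b)))
  }
})

test_that("the full loop is reproducible and shaped by nIter", {
  sim <- simulateVirome(syntheticConfig(nPhyla = 3, samplesPerPhylum = 8, seed = 33L))
  cfg <- bootstrapConfig(groupSize = 8, nIter = 1, nPerm = 19, seed = 4L)
  bs <- runBootstrap(sim$experiment, config = cfg, minSamples = 8)
  expect_equal(nrow(bs$outcomes), 3L)           # 1 iteration x 3 pairs
  bs2 <- runBootstrap(sim$experiment, config = cfg, minSamples = 8)
  expect_identical(bs$outcomes, bs2$outcomes)
  expect_error(runBootstrap(sim$experiment, config = cfg, minSamples = 100),
               "fewer than 2 phyla")
  expect_error(bootstrapConfig(groupSize = 1), "groupSize")
  expect_error(bootstrapConfig(alpha = 2), "alpha")
})
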