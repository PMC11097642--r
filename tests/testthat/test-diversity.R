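test_that("richness counts families with positive reads", {
  expect_identical(familyRichness(c(5, 0, 3, 0, 2)), 3L)
  expect_identical(familyRichness(rep(0, 4)), 0L)
  expect_identical(familyRichness(rep(1, 37)), 37L)
  expect_error(familyRichness(c(1, -1)), "non-negative")
})

test_that("Shannon index matches hand evaluations and its bounds", {
  expect_equal(shannonIndex(c(1, 1, 1, 1)), log(4), tolerance = 1e-12)
  expect_equal(shannonIndex(c(10, 0, 0)), 0)
  expect_equal(shannonIndex(c(2, 1, 1)), 1.0397208, tolerance = 1e-6)
  expect_error(shannonIndex(c(0, 0)), "all-zero")
  # permutation invariance and H <= ln(richness) on random vectors
  set.seed(1)
  for (i in 1:20) {
    v <- rpois(12, 3)
    if (sum(v) == 0) v[1] <- 1
    expect_equal(shannonIndex(v), shannonIndex(sample(v)), tolerance = 1e-12)
    expect_lte(shannonIndex(v), log(max(1, familyRichness(v))) + 1e-12)
  }
})

test_that("accumulation curves pool richness and fit a log-linear model", {
  set.seed(3)
  m <- matrix(rpois(20 * 12, 1.2), nrow = 20)
  colnames(m) <- paste0("f", 1:12)
  ac <- accumulationCurve(m, sizes = c(1, 5, 10, 20), nIter = 30, seed = 2,
                          minGroupSize = 15)
  # full-group subsample equals the pooled richness exactly
  expect_equal(ac$table$meanRichness[4], sum(colSums(m) > 0))
  # singleton pooling equals mean per-sample richness within MC error
  expect_lt(abs(ac$table$meanRichness[1] - mean(familyRichness(m))), 1.5)
  # pooled support grows monotonically with subsample size
  expect_true(all(diff(ac$table$meanRichness) >= -1e-9))
  # identical family support in every sample gives a flat curve
  flat <- matrix(1, nrow = 16, ncol = 5)
  acFlat <- accumulationCurve(flat, sizes = c(1, 4, 8, 16), nIter = 10, seed = 1)
  expect_equal(unname(acFlat$fit["slope"]), 0, tolerance = 1e-10)
  expect_error(accumulationCurve(m, sizes = 50), "sizes")
  expect_error(accumulationCurve(m[1:5, ]), "samples")
})

test_that("Box-Cox transform matches the closed form and round-trips", {
  expect_equal(boxcoxTransform(1, 0.7), 0)
  expect_equal(boxcoxTransform(2, 2.5), (2^2.5 - 1) / 2.5, tolerance = 1e-12)
  expect_equal(boxcoxTransform(2, 2.5), 1.8627417, tolerance = 1e-6)
  y <- c(0.4, 1.1, 2.4)
  expect_equal(boxcoxTransform(boxcoxTransform(y, 2.5), 2.5, "inverse"), y,
               tolerance = 1e-12)
  expect_equal(boxcoxTransform(boxcoxTransform(y, 0), 0, "inverse"), y,
               tolerance = 1e-12)
  expect_error(boxcoxTransform(c(1, -2), 2.5), "indices: 2")
  expect_error(boxcoxTransform(-10, 2.5, "inverse"), "domain")
})

test_that("Levene test matches a direct ANOVA-on-deviations oracle", {
  # identical within-group deviation patterns: F = 0, p = 1
  same <- leveneHomogeneity(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_equal(same$F, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # variances 1 vs 100 at n = 50: near-certain rejection
  set.seed(7)
  y <- c(rnorm(50, sd = 1), rnorm(50, sd = 10))
  g <- rep(c("a", "b"), each = 50)
  expect_lt(leveneHomogeneity(y, g)$p, 0.01)
  # oracle: one-way ANOVA on absolute deviations from the group median
  dev <- abs(y - ave(y, g, FUN = median))
  oracle <- anova(lm(dev ~ g))
  ours <- leveneHomogeneity(y, g)
  expect_equal(ours$F, oracle$`F value`[1], tolerance = 1e-10)
  expect_equal(ours$p, oracle$`Pr(>F)`[1], tolerance = 1e-10)
  expect_error(leveneHomogeneity(c(1, 2, 3), c("a", "a", "b")), "singleton")
})

test_that("AIC model selection recovers a pure phylum effect and flat nulls", {
  set.seed(21)
  n <- 60
  meta <- data.frame(phylum = rep(paste0("P", 1:4), each = 15),
                     habitat = rep(c("marine", "terrestrial"), 30))
  y <- rnorm(n, mean = rep(c(0, 2, 4, 6), each = 15), sd = 0.5)
  fit <- fitAnovaSelect(y, meta)
  expect_true(grepl("^\\.y ~ phylum", fit$formula))
  expect_lt(fit$candidates["phylum"], fit$candidates["habitat"])
  expect_gt(fit$r2, 0.8)
  # identical values in every group: F = 0 for every term
  flat <- fitAnovaSelect(rep(c(1, 2, 3), 20), meta)
  expect_equal(flat$anova$F[seq_len(nrow(flat$anova) - 1L)],
               rep(0, nrow(flat$anova) - 1L), tolerance = 1e-12)
  # levels below the minimum group size are dropped before fitting
  meta2 <- rbind(meta, data.frame(phylum = "Rare", habitat = "brackish"))
  fit2 <- fitAnovaSelect(c(y, 100), meta2, minGroupSize = 5)
  expect_false("Rare" %in% levels(fit2$data$phylum))
  expect_equal(nrow(fit2$data), 60L)
})

test_that("Tukey letters reflect exactly the non-rejected pairs", {
  base <- c(-1.2, -0.6, 0, 0.6, 1.2)
  y <- c(base, base + 1.1, base + 2.2)
  g <- rep(c("A", "B", "C"), each = 5)
  fit <- fitAnovaSelect(y, data.frame(phylum = g), factors = "phylum",
                        minGroupSize = 2)
  tk <- tukeyHsdLetters(fit, "phylum")
  # oracle: adjusted p from the studentized range distribution
  mse <- sum((y - ave(y, g))^2) / 12
  pCA <- 1 - ptukey(2.2 / sqrt(mse / 5), nmeans = 3, df = 12)
  expect_equal(tk$pairs$p_adj[tk$pairs$comparison == "C-A"], pCA, tolerance = 1e-10)
  expect_identical(unname(tk$letters), c("a", "ab", "b"))

  # two groups, huge separation: distinct letters
  y2 <- c(base, base + 50)
  fit2 <- fitAnovaSelect(y2, data.frame(phylum = rep(c("A", "B"), each = 5)),
                         factors = "phylum", minGroupSize = 2)
  expect_identical(unname(tukeyHsdLetters(fit2, "phylum")$letters), c("a", "b"))

  # equal means: everyone shares one letter
  y3 <- c(base, base, base)
  fit3 <- fitAnovaSelect(y3, data.frame(phylum = g), factors = "phylum",
                         minGroupSize = 2)
  expect_identical(unname(tukeyHsdLetters(fit3, "phylum")$letters),
                   c("a", "a", "a"))
})
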