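test_that("bipartite construction supports abundance and presence modes", {
  m <- matrix(0, 15, 2, dimnames = list(paste0("s", 1:15), c("f1", "f2")))
  m[1:3, 1] <- 0.5; m[, 2] <- 0.5; m[1:3, 2] <- 0.5
  pf <- buildBipartite(m, mode = "presence_fraction", group = rep("PhA", 15))
  expect_equal(pf["PhA", "f1"], 0.2)   # present in 3 of 15 samples
  one <- matrix(c(0.25, 0.75), 1, dimnames = list("s1", c("f1", "f2")))
  expect_equal(buildBipartite(one)[1, ], c(f1 = 0.25, f2 = 0.75))
  # presence filter: a family in 4/20 samples of one phylum is kept at 20%
  m2 <- matrix(0, 40, 2, dimnames = list(paste0("s", 1:40), c("keep", "drop")))
  m2[1:4, "keep"] <- 1; m2[21:40, "drop"] <- 0.03; m2[, "drop"][1:40] <- 0.03
  m2[5:40, "keep"] <- 0
  m2[1:20, "drop"] <- 0.03
  grp <- rep(c("P1", "P2"), each = 20)
  kept <- buildBipartite(m2, group = grp, minPresence = 0.2)
  expect_true("keep" %in% colnames(kept))
  m3 <- m2; m3[1:4, "keep"] <- 0; m3[1:3, "keep"] <- 1   # 3/20 = 15% max
  expect_false("keep" %in% colnames(buildBipartite(m3, group = grp,
                                                   minPresence = 0.2)))
  expect_error(buildBipartite(matrix(0, 2, 2)), "empty")
})

test_that("weighted linkage density equals the effective-partner mean", {
  expect_equal(linkageDensity(matrix(1)), 1)
  expect_equal(linkageDensity(diag(2)), 1)
  expect_equal(linkageDensity(matrix(1, 2, 2)), 2)
  # marginal weighting: a dominant specialist row pulls the mean down
  m <- rbind(c(100, 0), c(1, 1))
  expect_lt(linkageDensity(m), linkageDensity(matrix(1, 2, 2)))
})

test_that("H2' spans its extremes and is scale invariant", {
  expect_equal(h2Prime(diag(2)), 1)
  expect_equal(h2Prime(outer(c(1, 2), c(3, 4))), 0)
  set.seed(41)
  for (i in 1:20) {
    m <- matrix(rgamma(20, 1), 4, 5)
    v <- h2Prime(m)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, h2Prime(m * 7.3), tolerance = 1e-10)
  }
  expect_warning(h2Prime(matrix(5)), "single-cell")
})

test_that("NODF matches hand cases and a brute-force oracle", {
  expect_equal(nodf(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))), 100)
  expect_equal(nodf(diag(3)), 0)
  # equal fills contribute zero regardless of overlap
  expect_equal(nodf(rbind(c(1, 1, 0), c(0, 1, 1))), 50)

  bruteNodf <- function(b) {
    sc <- c()
    for (mm in list(b, t(b))) {
      fills <- rowSums(mm)
      n <- nrow(mm)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        lo <- min(fills[i], fills[j]); hi <- max(fills[i], fills[j])
        shared <- sum(mm[i, ] & mm[j, ])
        sc <- c(sc, if (hi > lo && lo > 0) 100 * shared / lo else 0)
      }
    }
    mean(sc)
  }
  set.seed(42)
  for (i in 1:100) {
    b <- matrix(rbinom(25, 1, 0.45), 5, 5)
    if (sum(b) == 0) b[1, 1] <- 1
    expect_equal(nodf(b), bruteNodf(b), tolerance = 1e-12)
    expect_equal(nodf(b, "NODF"), bruteNodf(b), tolerance = 1e-12)
  }
})

test_that("Barber modularity finds block structure and is seed-stable", {
  blocks <- rbind(cbind(matrix(1, 2, 2), matrix(0, 2, 2)),
                  cbind(matrix(0, 2, 2), matrix(1, 2, 2)))
  q <- qModularity(blocks, seed = 1)
  expect_equal(q$Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(q$rowModules[1:2])), 1L)
  expect_false(q$rowModules[1] == q$rowModules[3])
  # uniform matrix has no structure
  expect_lte(qModularity(matrix(1, 3, 3), seed = 1)$Q, 1e-12)
  # never below the one-module baseline; identical under the same seed
  set.seed(43)
  for (i in 1:10) {
    m <- matrix(rgamma(30, 1), 5, 6)
    a <- qModularity(m, seed = i)
    b <- qModularity(m, seed = i)
    expect_gte(a$Q, 0)
    expect_identical(a, b)
  }
})

test_that("d' is 0 for availability-matched nodes and 1 for extreme packing", {
  # interactions exactly proportional to partner marginals
  m <- outer(c(2, 3), c(1, 4))
  expect_equal(unname(dPrime(m)), c(0, 0), tolerance = 1e-12)
  # all weight on the rarest partner, which its marginal can absorb
  m2 <- rbind(c(10, 0), c(0, 1))
  expect_equal(unname(dPrime(m2)[2]), 1, tolerance = 1e-12)
  set.seed(44)
  for (i in 1:20) {
    m <- matrix(rgamma(24, 1), 4, 6)
    v <- dPrime(m)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(v, dPrime(m * 3.7), tolerance = 1e-10)
  }
  expect_warning(v0 <- dPrime(rbind(c(1, 1), c(0, 0))), "zero-weight")
  expect_true(is.na(v0[2]))
})

test_that("Patefield draws preserve marginals and the 2x2 hypergeometric law", {
  m <- matrix(c(3, 1, 2, 4, 0, 5), 2, 3)
  set.seed(45)
  for (i in 1:50) {
    nl <- patefieldNull(m)
    expect_equal(rowSums(nl), rowSums(m))
    expect_equal(colSums(nl), colSums(m))
    expect_true(all(nl >= 0))
  }
  # non-integer weights: integer-rounded marginals preserved after scaling
  w <- m / sum(m)
  nlw <- patefieldNull(w, scale = 1e4)
  expect_equal(rowSums(round(nlw * 1e4)), rowSums(round(w * 1e4)))
  # 1 x n: margins force the table
  expect_identical(patefieldNull(matrix(1:3, 1)), matrix(1:3, 1))
  # cell means approach the independence table (3 SE over 2000 draws)
  set.seed(46)
  draws <- replicate(2000, patefieldNull(m))
  indep <- outer(rowSums(m), colSums(m)) / sum(m)
  mns <- apply(draws, c(1, 2), mean)
  ses <- apply(draws, c(1, 2), sd) / sqrt(2000)
  expect_true(all(abs(mns - indep) <= 3 * pmax(ses, 1e-9)))
})

test_that("null-model z-tests behave at the mean, the quantile and the boundary", {
  set.seed(47)
  nulls <- rnorm(1000, 0.5, 0.05)
  zt <- nullZtest(mean(nulls), nulls)
  expect_equal(zt$z, 0, tolerance = 1e-12)
  expect_equal(zt$p, 1, tolerance = 1e-12)
  zt2 <- nullZtest(mean(nulls) + 1.96 * sd(nulls), nulls)
  expect_equal(zt2$p, 0.05, tolerance = 1e-3)
  expect_warning(nullZtest(0.999, rnorm(100, 0.95, 0.03), range = c(0, 1)),
                 "boundary")
  expect_error(nullZtest(1, rep(0.5, 100)), "standard deviation")
  expect_error(nullZtest(1, rnorm(10)), "at least 30")
})

test_that("d' ANOVA delegates to the diversity module's model selection", {
  set.seed(48)
  dp <- c(rnorm(10, 0.2, 0.01), rnorm(10, 0.8, 0.01))
  ph <- rep(c("A", "B"), each = 10)
  fit <- dprimeAnova(dp, ph)
  direct <- fitAnovaSelect(dp, data.frame(phylum = ph), factors = "phylum")
  expect_equal(fit$anova$F, direct$anova$F, tolerance = 1e-12)
  expect_equal(fit$aic, direct$aic)
  # all-equal d' values: F = 0
  flat <- dprimeAnova(rep(c(0.1, 0.2), 10), ph)
  expect_equal(flat$anova$F[1], 0, tolerance = 1e-12)
  # a strongly shifted phylum is isolated by the letters
  tk <- tukeyHsdLetters(fit, "phylum")
  expect_identical(unname(tk$letters), c("a", "b"))
})
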