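test_that("relative abundance projects rows onto the simplex", {
  expect_equal(as.vector(toRelativeAbundance(matrix(c(2, 2, 4), nrow = 1))),
               c(0.25, 0.25, 0.5))
  expect_equal(as.vector(toRelativeAbundance(matrix(c(0, 7, 0), nrow = 1))),
               c(0, 1, 0))
  set.seed(4)
  m <- matrix(rpois(60, 5) + 1, nrow = 6)
  expect_equal(rowSums(toRelativeAbundance(m)), rep(1, 6), tolerance = 1e-12)
  bad <- rbind(m, 0)
  rownames(bad) <- paste0("s", 1:7)
  expect_error(toRelativeAbundance(bad), "s7")
})

test_that("family filter thresholds the column mean inclusively", {
  ra <- rbind(c(0.99982, 0.00009, 0.00009),
              c(0.99971, 0.00009, 0.00020))
  colnames(ra) <- c("big", "below", "edge")   # means: ~1, 9e-5, 1.45e-4
  out <- filterFamilies(ra)
  expect_identical(attr(out, "dropped"), "below")
  expect_identical(colnames(out), c("big", "edge"))
  expect_equal(rowSums(out), rep(1, 2), tolerance = 1e-12)
  # a family whose mean is exactly the threshold is retained
  ra2 <- cbind(exact = rep(1e-4, 2), rest = rep(1 - 1e-4, 2))
  expect_true("exact" %in% colnames(filterFamilies(ra2)))
  expect_error(filterFamilies(ra * 0 + 1e-9, minMean = 1), "all families")
})

test_that("CZM replacement preserves the simplex and nonzero ratios", {
  row <- matrix(c(0.5, 0.5, 0), nrow = 1)
  out <- czmReplaceZeros(row, depths = 99)
  expect_equal(as.vector(out), c(0.49675, 0.49675, 0.0065), tolerance = 1e-12)
  expect_equal(rowSums(out), 1, tolerance = 1e-12)

  # zero-free rows are unchanged
  clean <- matrix(c(0.2, 0.3, 0.5), nrow = 1)
  expect_identical(czmReplaceZeros(clean, depths = 100), clean)

  set.seed(5)
  m <- matrix(rpois(80, 2), nrow = 8) + 0
  m[1, ] <- m[1, ] + 1
  ra <- m / rowSums(m)
  depths <- rowSums(m)
  imp <- suppressWarnings(czmReplaceZeros(ra, depths))
  expect_true(all(imp > 0))
  expect_equal(rowSums(imp), rep(1, 8), tolerance = 1e-12)
  for (i in 1:8) {                       # nonzero-part ratios unchanged
    nz <- which(ra[i, ] > 0)
    if (length(nz) >= 2)
      expect_equal(imp[i, nz] / imp[i, nz[1]], ra[i, nz] / ra[i, nz[1]],
                   tolerance = 1e-12)
  }
  # imputation above the detection limit warns
  expect_warning(czmReplaceZeros(matrix(c(0.999, 0.001, 0), 1), depths = 2),
                 "smallest nonzero")
})

test_that("clr rows sum to zero and match the geometric-mean form", {
  expect_equal(as.vector(clrTransform(matrix(1 / 3, 1, 3))), rep(0, 3))
  expect_equal(as.vector(clrTransform(matrix(c(1, 2, 4) / 7, nrow = 1))),
               c(-log(2), 0, log(2)), tolerance = 1e-12)
  set.seed(6)
  m <- matrix(rgamma(100, 2), nrow = 10)
  ra <- m / rowSums(m)
  clr <- clrTransform(ra)
  expect_lt(max(abs(rowSums(clr))), 1e-10)
  # scale invariance: multiplying a count row by a constant changes nothing
  expect_equal(clrTransform(ra), clrTransform(ra * 37), tolerance = 1e-12)
  expect_error(clrTransform(matrix(c(1, 0), 1)), "positive")
})

test_that("Aitchison distances are Euclidean on clr rows and perturbation-invariant", {
  clr <- rbind(c(0, 0), c(3, -3))
  expect_equal(as.vector(aitchisonDistances(clr)), sqrt(18), tolerance = 1e-12)
  expect_equal(as.matrix(aitchisonDistances(rbind(c(1, 2), c(1, 2))))[1, 2], 0)
  set.seed(8)
  m <- matrix(rgamma(50, 2), nrow = 5)
  ra <- m / rowSums(m)
  p <- rgamma(10, 2)
  pert <- sweep(ra, 2, p, `*`)
  pert <- pert / rowSums(pert)
  d1 <- as.matrix(aitchisonDistances(clrTransform(ra)))
  d2 <- as.matrix(aitchisonDistances(clrTransform(pert)))
  expect_lt(max(abs(d1 - d2)), 1e-10)
  expect_equal(d1, t(d1))
  expect_equal(unname(diag(d1)), rep(0, 5))
})

test_that("centroid distances match a brute-force oracle", {
  clr <- matrix(c(1, 1, 1, 1, 3, 3, 3, 3), nrow = 4, byrow = FALSE)
  cd <- centroidDistances(clr, rep("g", 4), minGroupSize = 1)
  expect_equal(cd$distance, rep(0, 4))
  two <- rbind(c(0, 0), c(2, 2))
  cd2 <- centroidDistances(two, c("g", "g"), minGroupSize = 1)
  expect_equal(cd2$distance, rep(sqrt(8) / 2, 2), tolerance = 1e-12)

  set.seed(9)
  X <- matrix(rnorm(50), 10, 5)
  g <- rep(c("a", "b"), each = 5)
  cd3 <- centroidDistances(X, g, minGroupSize = 1)
  oracle <- vapply(1:10, function(i) {
    ctr <- colMeans(X[g == g[i], , drop = FALSE])
    sqrt(sum((X[i, ] - ctr)^2))
  }, numeric(1))
  expect_equal(cd3$distance, oracle, tolerance = 1e-12)
  # default admits only groups of >= 15
  expect_equal(nrow(centroidDistances(X, g)), 0L)
})

test_that("equal-weight aggregation and Ward2 clustering behave as stated", {
  ra <- matrix(rep(c(0.2, 0.3, 0.5), 3), nrow = 3, byrow = TRUE)
  agg <- aggregateByGroup(ra, rep("g", 3))
  expect_equal(as.vector(agg$profiles), as.vector(clrTransform(ra[1, , drop = FALSE])),
               tolerance = 1e-12)

  # duplicating a sample changes the equal-weight mean ...
  ra2 <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.2, 0.7))
  p1 <- aggregateByGroup(ra2, c("g", "g"))$profiles
  p2 <- aggregateByGroup(ra2[c(1, 1, 2), ], rep("g", 3))$profiles
  expect_gt(max(abs(p1 - p2)), 1e-6)
  # ... but adding a sample equal to the current mean does not
  mid <- colMeans(ra2)
  p3 <- aggregateByGroup(rbind(ra2, mid), rep("g", 3))$profiles
  expect_equal(p1, p3, tolerance = 1e-12)

  # groups with disjoint dominant families merge last
  ra3 <- rbind(A1 = c(0.80, 0.16, 0.02, 0.02),
               A2 = c(0.76, 0.20, 0.02, 0.02),
               B1 = c(0.16, 0.80, 0.02, 0.02),
               B2 = c(0.20, 0.76, 0.02, 0.02),
               C1 = c(0.02, 0.02, 0.80, 0.16),
               C2 = c(0.02, 0.02, 0.76, 0.20))
  agg3 <- aggregateByGroup(ra3, c("A", "A", "B", "B", "C", "C"))
  grpOfC <- cutree(agg3$groupTree, k = 2)["C"]
  expect_true(sum(cutree(agg3$groupTree, k = 2) == grpOfC) == 1)
  # newick export round-trips through ape
  dir <- withr::local_tempdir()
  f <- file.path(dir, "t.nwk")
  writeDendrogramNewick(agg3$groupTree, f)
  expect_identical(sort(ape::read.tree(f)$tip.label), c("A", "B", "C"))
})

test_that("countsToClr applies filter, imputation and clr in the stated order", {
  set.seed(10)
  m <- matrix(rpois(200, 3) + 1, nrow = 10)
  colnames(m) <- paste0("f", 1:20)
  m[, 20] <- 0                        # all-zero family: filtered, never imputed
  m[3, 5] <- 0                        # a real zero for CZM to replace
  clr <- countsToClr(m)
  expect_false("f20" %in% colnames(clr))
  expect_equal(ncol(clr), 19L)
  expect_lt(max(abs(rowSums(clr))), 1e-10)
  expect_true(all(is.finite(clr)))
})
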