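# Distance-matrix PERMANOVA and PERMDISP.
#
# The sums of squares follow Anderson's partitioning of the Gower-centered
# matrix G = (I - 11'/n) (-D^2/2) (I - 11'/n): the SS explained by a design
# projection H is tr(HG), total SS is tr(G), and permuting sample labels is
# equivalent to permuting rows/columns of G under fixed H.

.gowerCenter <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A)
}

.checkDistMatrix <- function(d) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  D
}

# all permutations of 1:n (n! rows); used for exhaustive enumeration
.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L), drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the sum of squares of a distance matrix among sequential
#' (Type I) model terms and tests each term's pseudo-F statistic by
#' permutation of sample labels. Monte-Carlo p-values use the
#' \eqn{(1 + b)/(1 + m)} convention and therefore never return 0; with
#' \code{exhaustive = TRUE} (small n) all \eqn{n!} label permutations are
#' enumerated and the p-value is the exact fraction with
#' \eqn{F_{perm} \ge F_{obs}} (the identity included).
#'
#' @param d \code{dist} object or symmetric distance matrix.
#' @param design data.frame of factors aligned to the samples of \code{d}.
#' @param formula Model formula (e.g. \code{~ phylum + habitat}) or character
#'   vector of term labels, fitted sequentially in the given order.
#' @param nPerm Number of Monte-Carlo permutations. Default 999.
#' @param seed Integer seed for the permutations.
#' @param exhaustive Enumerate all permutations (requires n <= 8).
#' @return Object of class \code{"PermanovaResult"}: list with \code{table}
#'   (per-term df, SS, R2, pseudo-F, p plus residual and total rows),
#'   \code{aic} (pseudo-AIC, see \code{\link{permanovaAIC}}), \code{nPerm},
#'   \code{seed}.
#' @export
#' @examples
#' pts <- c(0, 1, 3, 4)
#' d <- dist(pts)
#' permanova(d, data.frame(g = c("A", "A", "B", "B")), ~ g, exhaustive = TRUE)
permanova <- function(d, design, formula, nPerm = 999, seed = NULL,
                      exhaustive = FALSE) {
  D <- .checkDistMatrix(d)
  n <- nrow(D)
  stopifnot(is.data.frame(design), nrow(design) == n)
  termLabels <- if (inherits(formula, "formula"))
    attr(terms(formula), "term.labels") else as.character(formula)
  if (!length(termLabels)) stop("at least one model term is required")
  for (v in all.vars(stats::reformulate(termLabels))) {
    design[[v]] <- droplevels(factor(design[[v]]))
    if (nlevels(design[[v]]) < 2L)
      stop("factor '", v, "' has fewer than 2 levels")
  }
  G <- .gowerCenter(D)
  ssTotal <- sum(diag(G))

  hats <- list(); ranks <- integer(length(termLabels))
  for (j in seq_along(termLabels)) {
    X <- model.matrix(stats::reformulate(termLabels[seq_len(j)]), design)
    qx <- qr(X)
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    hats[[j]] <- tcrossprod(Q)
    ranks[j] <- qx$rank
  }
  ssCum <- vapply(hats, function(H) sum(H * G), numeric(1L))
  ssTerm <- diff(c(0, ssCum))
  dfTerm <- diff(c(1L, ranks))
  if (any(dfTerm < 1L)) stop("aliased model term(s); check the design")
  dfRes <- n - ranks[length(ranks)]
  ssRes <- ssTotal - ssCum[length(ssCum)]
  if (dfRes < 1L) stop("no residual degrees of freedom; model is saturated")
  Fobs <- (ssTerm / dfTerm) / (ssRes / dfRes)

  statFor <- function(perm) {
    Gp <- G[perm, perm]
    cum <- vapply(hats, function(H) sum(H * Gp), numeric(1L))
    st <- diff(c(0, cum))
    (st / dfTerm) / ((ssTotal - cum[length(cum)]) / dfRes)
  }
  if (exhaustive) {
    if (n > 8L) stop("exhaustive enumeration supported only for n <= 8")
    perms <- .allPermutations(n)
    Fperm <- apply(perms, 1L, statFor)
    Fperm <- matrix(Fperm, nrow = length(termLabels))
    pvals <- rowMeans(Fperm >= Fobs - 1e-12)
    nPermUsed <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(deriveSeed(seed, 41L))
    exceed <- integer(length(termLabels))
    for (b in seq_len(nPerm)) {
      Fp <- statFor(sample.int(n))
      exceed <- exceed + (Fp >= Fobs - 1e-12)
    }
    pvals <- (1 + exceed) / (1 + nPerm)
    nPermUsed <- nPerm
  }
  tab <- data.frame(
    term = c(termLabels, "Residual", "Total"),
    df = c(dfTerm, dfRes, n - 1L),
    sumsq = c(ssTerm, ssRes, ssTotal),
    r2 = c(ssTerm, ssRes, ssTotal) / ssTotal,
    pseudoF = c(Fobs, NA, NA),
    p = c(pvals, NA, NA))
  res <- list(table = tab, nPerm = nPermUsed, seed = seed,
              exhaustive = exhaustive,
              modelDf = ranks[length(ranks)] - 1L, n = n, ssRes = ssRes)
  res$aic <- permanovaAIC(res)
  class(res) <- "PermanovaResult"
  res
}

#' @export
print.PermanovaResult <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s, %d permutations)\n",
              if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$nPerm))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("pseudo-AIC = %.3f\n", x$aic))
  invisible(x)
}

#' Pseudo-AIC of a fitted PERMANOVA model
#'
#' An AIC-style score \eqn{n \ln(SS_{res}/n) + 2k} with \eqn{k} = model
#' degrees of freedom + 1, comparable only across models fitted to the same
#' distance matrix. This is the package's own definition: neither the
#' distance-based ANOVA literature nor its reference implementations define
#' an AIC, so treat the score as a relative model-ranking device, not a
#' likelihood-based quantity.
#'
#' @param result A \code{"PermanovaResult"}.
#' @return Numeric pseudo-AIC.
#' @export
permanovaAIC <- function(result) {
  if (result$ssRes <= 0) stop("residual SS must be positive")
  result$n * log(result$ssRes / result$n) + 2 * (result$modelDf + 1)
}

#' Permutation test for homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the distance matrix by principal coordinates analysis, keeping
#' negative-eigenvalue axes on the imaginary dimension (a sample's squared
#' distance to its group center is the real part minus the imaginary part,
#' truncated at zero), computes each sample's distance to its own-group
#' center, and tests the one-way ANOVA F statistic on those distances by
#' permuting group labels.
#'
#' @param d \code{dist} or symmetric distance matrix.
#' @param groups Group labels (>= 2 groups, each >= 2 samples).
#' @param nPerm Number of permutations. Default 999.
#' @param center \code{"centroid"} (default) or \code{"spatial_median"}
#'   (Weiszfeld L1-median computed separately on the real and imaginary
#'   axis sets).
#' @param seed Integer seed.
#' @return Object of class \code{"PermdispResult"}: list with
#'   \code{dispersions} (group mean distance-to-center), \code{distances}
#'   (per sample), \code{F}, \code{p}, \code{nPerm}, \code{center}.
#' @export
permdisp <- function(d, groups, nPerm = 999,
                     center = c("centroid", "spatial_median"), seed = NULL) {
  center <- match.arg(center)
  D <- .checkDistMatrix(d)
  n <- nrow(D)
  groups <- factor(groups)
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop("at least 2 groups are required")
  if (any(sizes < 2L))
    stop("group(s) of size 1: ", paste(names(sizes)[sizes < 2L], collapse = ", "))

  G <- .gowerCenter(D)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  Upos <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  Uneg <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))

  centerOf <- function(M, idx) {
    if (ncol(M) == 0L) return(numeric(0))
    if (center == "centroid") colMeans(M[idx, , drop = FALSE])
    else .weiszfeld(M[idx, , drop = FALSE])
  }
  z <- numeric(n)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cp <- centerOf(Upos, idx)
    cn <- centerOf(Uneg, idx)
    d2 <- if (ncol(Upos)) colSums((t(Upos[idx, , drop = FALSE]) - cp)^2) else 0
    if (ncol(Uneg)) d2 <- d2 - colSums((t(Uneg[idx, , drop = FALSE]) - cn)^2)
    z[idx] <- sqrt(pmax(d2, 0))
  }
  fStat <- function(z, g) {
    m <- tapply(z, g, mean)
    nn <- tapply(z, g, length)
    ssb <- sum(nn * (m - mean(z))^2)
    ssw <- sum((z - m[g])^2)
    (ssb / (nlevels(g) - 1L)) / (ssw / (length(z) - nlevels(g)))
  }
  Fobs <- fStat(z, groups)
  if (!is.null(seed)) set.seed(deriveSeed(seed, 42L))
  exceed <- 0L
  for (b in seq_len(nPerm))
    exceed <- exceed + (fStat(z, groups[sample.int(n)]) >= Fobs - 1e-12)
  res <- list(dispersions = tapply(z, groups, mean), distances = z,
              F = Fobs, p = (1 + exceed) / (1 + nPerm),
              nPerm = nPerm, center = center, groups = groups)
  class(res) <- "PermdispResult"
  res
}

# Weiszfeld iteration for the geometric (L1) median
.weiszfeld <- function(M, maxIter = 100, tol = 1e-10) {
  x <- colMeans(M)
  for (it in seq_len(maxIter)) {
    dd <- sqrt(colSums((t(M) - x)^2))
    if (any(dd < tol)) return(x)
    w <- 1 / dd
    xNew <- colSums(M * w) / sum(w)
    if (sqrt(sum((xNew - x)^2)) < tol) return(xNew)
    x <- xNew
  }
  x
}

#' @export
print.PermdispResult <- function(x, ...) {
  cat(sprintf("PERMDISP (%s center, %d permutations): F = %.4f, p = %.4g\n",
              x$center, x$nPerm, x$F, x$p))
  print(round(x$dispersions, 4))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values (delegates to
#' \code{stats::p.adjust}), with input validation.
#'
#' @param pvalues Numeric p-values in [0, 1].
#' @return Adjusted p-values (same length/order).
#' @export
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03))
fdrAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}
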