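# Quantitative bipartite virus-host network structure: linkage density,
# H2' specialization, NODF nestedness, Barber modularity, d' specialization,
# and Patefield r2d null-model z-tests.

#' Build a quantitative host x viral-family interaction matrix
#'
#' In \code{"abundance"} mode the weights are relative abundances (per
#' sample, or the equal-weight per-group mean when \code{group} is given);
#' in \code{"presence_fraction"} mode (requires \code{group}) the weight is
#' the fraction of the group's samples in which the family has a positive
#' count. All-zero rows and columns are dropped. An optional
#' \code{minPresence} retains only families present in at least that
#' fraction of the samples of at least one group.
#'
#' @param relabund Relative-abundance (or count, for presence mode) matrix,
#'   samples as rows.
#' @param mode \code{"abundance"} or \code{"presence_fraction"}.
#' @param group Optional group (phylum) label per sample for aggregation.
#' @param minPresence Optional presence-fraction filter (e.g. 0.2).
#' @return Numeric weight matrix, hosts as rows, families as columns.
#' @export
buildBipartite <- function(relabund, mode = c("abundance", "presence_fraction"),
                           group = NULL, minPresence = NULL) {
  mode <- match.arg(mode)
  m <- as.matrix(relabund)
  if (!length(m) || all(m == 0)) stop("empty interaction matrix")
  if (!is.null(minPresence)) {
    stopifnot(!is.null(group))
    pres <- rowsum((m > 0) + 0, as.character(group))
    pres <- pres / as.vector(table(as.character(group))[rownames(pres)])
    m <- m[, apply(pres, 2L, max) >= minPresence, drop = FALSE]
  }
  if (mode == "presence_fraction") {
    if (is.null(group)) stop("presence_fraction mode requires 'group'")
    out <- rowsum((m > 0) + 0, as.character(group))
    out <- out / as.vector(table(as.character(group))[rownames(out)])
  } else if (!is.null(group)) {
    out <- rowsum(m, as.character(group))
    out <- out / as.vector(table(as.character(group))[rownames(out)])
  } else out <- m
  out <- out[rowSums(out) > 0, colSums(out) > 0, drop = FALSE]
  if (!length(out)) stop("empty interaction matrix after dropping zero margins")
  out
}

#' Quantitative (weighted) linkage density
#'
#' Mean effective number of partners per node, weighted by node marginal
#' totals: each node's effective partner count is the exponential of the
#' Shannon entropy of its interaction weights, and the linkage density is
#' half the sum of the marginal-weighted means over rows and columns.
#'
#' @param m Non-negative weight matrix.
#' @return Numeric linkage density.
#' @export
#' @examples
#' linkageDensity(matrix(1))            # 1
#' linkageDensity(matrix(1, 2, 2))      # 2
linkageDensity <- function(m) {
  m <- as.matrix(m)
  F_ <- sum(m)
  if (F_ <= 0) stop("total weight must be positive")
  effPartners <- function(w) {
    w <- w[w > 0] / sum(w)
    exp(-sum(w * log(w)))
  }
  nRow <- apply(m, 1L, effPartners)   # effective families per host
  nCol <- apply(m, 2L, effPartners)   # effective hosts per family
  0.5 * (sum(rowSums(m) / F_ * nRow) + sum(colSums(m) / F_ * nCol))
}

# Shannon entropy of a (possibly unnormalized) non-negative table
.tableEntropy <- function(m) {
  p <- m[m > 0] / sum(m)
  -sum(p * log(p))
}

# Greedy minimum-entropy table under fixed marginals: repeatedly place
# min(largest remaining row total, largest remaining column total).
.minEntropyTable <- function(r, c) {
  out <- matrix(0, length(r), length(c))
  repeat {
    i <- which.max(r); j <- which.max(c)
    a <- min(r[i], c[j])
    if (a <= 1e-15) break
    out[i, j] <- out[i, j] + a
    r[i] <- r[i] - a; c[j] <- c[j] - a
  }
  out
}

#' H2' network-level specialization index
#'
#' Standardizes the Shannon entropy \eqn{H_2} of the normalized interaction
#' matrix between the extremes attainable under its fixed marginal totals:
#' \eqn{H_2' = (H_{2,max} - H_2)/(H_{2,max} - H_{2,min})}, where the maximum
#' is the entropy of the independence (marginal outer-product) table and the
#' minimum comes from a greedy marginal-packing heuristic. Clipped to
#' [0, 1]; 0 = fully generalized, 1 = fully specialized. Invariant to
#' multiplying the matrix by a positive constant.
#'
#' @param m Non-negative weight matrix with positive total.
#' @return Numeric H2' in [0, 1].
#' @export
#' @examples
#' h2Prime(diag(2))                         # 1
#' h2Prime(outer(c(1, 2), c(3, 4)))         # 0
h2Prime <- function(m) {
  m <- as.matrix(m)
  if (sum(m) <= 0) stop("total weight must be positive")
  if (nrow(m) == 1L && ncol(m) == 1L) {
    warning("single-cell matrix: no specialization freedom, H2' defined as 0")
    return(0)
  }
  p <- m / sum(m)
  r <- rowSums(p); cc <- colSums(p)
  h2 <- .tableEntropy(p)
  h2max <- .tableEntropy(outer(r, cc))
  h2min <- .tableEntropy(.minEntropyTable(r, cc))
  if (h2max - h2min < 1e-12) return(0)
  min(1, max(0, (h2max - h2) / (h2max - h2min)))
}

#' NODF nestedness (paired overlap with decreasing fill)
#'
#' The matrix is binarized (weight > 0). For every ordered pair of rows (and
#' of columns) the pair contributes the percentage of the poorer node's
#' links shared with the richer node, but only when the richer node's fill
#' strictly exceeds the poorer node's (equal fills contribute 0). NODF is
#' the mean contribution over all row pairs and column pairs, in [0, 100].
#' The \code{"NODF2"} variant sorts rows and columns by decreasing fill
#' before computing; since the decreasing-fill condition is evaluated on the
#' fills themselves, the sorted and unsorted values coincide.
#'
#' @param m Weight or incidence matrix.
#' @param variant \code{"NODF2"} (sorted; default) or \code{"NODF"}.
#' @return Numeric NODF in [0, 100].
#' @export
#' @examples
#' nodf(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0)))  # 100
#' nodf(diag(3))                                    # 0
nodf <- function(m, variant = c("NODF2", "NODF")) {
  variant <- match.arg(variant)
  b <- (as.matrix(m) > 0) + 0
  if (!sum(b)) stop("matrix is empty after binarization")
  if (variant == "NODF2")
    b <- b[order(rowSums(b), decreasing = TRUE),
           order(colSums(b), decreasing = TRUE), drop = FALSE]
  pairScore <- function(x) {        # x: n x k incidence, pairs along rows
    fills <- rowSums(x)
    n <- nrow(x)
    if (n < 2L) return(numeric(0))
    sh <- tcrossprod(x)             # shared links
    s <- numeric(0)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      hi <- max(fills[i], fills[j]); lo <- min(fills[i], fills[j])
      s <- c(s, if (hi > lo && lo > 0) 100 * sh[i, j] / lo else 0)
    }
    s
  }
  scores <- c(pairScore(b), pairScore(t(b)))
  if (!length(scores)) stop("need at least two rows or two columns")
  mean(scores)
}

# Barber bipartite modularity of a given module assignment.
# rowMod/colMod: integer labels for row and column nodes.
.barberQ <- function(m, rowMod, colMod) {
  F_ <- sum(m)
  k <- rowSums(m); d <- colSums(m)
  same <- outer(rowMod, colMod, "==")
  sum((m - outer(k, d) / F_)[same]) / F_
}

#' Barber bipartite modularity via label propagation
#'
#' Maximizes \eqn{Q = \frac{1}{F}\sum_{ij}(A_{ij} - k_i d_j / F)\,
#' \delta(g_i, g_j)} over joint module assignments of row and column nodes
#' by label propagation with random restarts and a final local-move
#' refinement. The one-module baseline (\eqn{Q = 0}) is always admissible,
#' so the returned Q is never negative. Deterministic under \code{seed}.
#'
#' @param m Non-negative weight matrix with positive total.
#' @param nRestarts Number of random restarts. Default 10.
#' @param seed Integer seed.
#' @return List with \code{Q}, \code{rowModules}, \code{colModules}
#'   (integer labels named by dimnames when present).
#' @export
#' @examples
#' blocks <- rbind(cbind(matrix(1, 2, 2), 0 * diag(2)),
#'                 cbind(0 * diag(2), matrix(1, 2, 2)))
#' qModularity(blocks, seed = 1)$Q   # 0.5
qModularity <- function(m, nRestarts = 10, seed = 1L) {
  m <- as.matrix(m)
  F_ <- sum(m)
  if (F_ <= 0) stop("total weight must be positive")
  nr <- nrow(m); nc <- ncol(m)
  k <- rowSums(m); d <- colSums(m)
  B <- m - outer(k, d) / F_          # modularity matrix
  set.seed(deriveSeed(seed, 61L))

  gain <- function(vec, mods, lab) {  # score of joining label 'lab'
    sum(vec[mods == lab])
  }
  oneRun <- function(rowMod) {
    colMod <- integer(nc)
    repeat {
      changed <- FALSE
      for (j in seq_len(nc)) {
        sc <- vapply(unique(rowMod), function(l) gain(B[, j], rowMod, l), 0)
        best <- unique(rowMod)[which.max(sc)]
        if (max(sc) <= 0) best <- 0L   # own singleton module
        if (!identical(best, colMod[j])) { colMod[j] <- best; changed <- TRUE }
      }
      for (i in seq_len(nr)) {
        labs <- unique(colMod[colMod != 0L])
        if (!length(labs)) break
        sc <- vapply(labs, function(l) gain(B[i, ], colMod, l), 0)
        best <- labs[which.max(sc)]
        if (!identical(best, rowMod[i])) { rowMod[i] <- best; changed <- TRUE }
      }
      if (!changed) break
    }
    # local refinement: move single nodes while Q improves
    repeat {
      improved <- FALSE
      labs <- unique(c(rowMod, colMod[colMod != 0L]))
      for (i in seq_len(nr)) {
        sc <- vapply(labs, function(l) gain(B[i, ], colMod, l), 0)
        best <- labs[which.max(sc)]
        if (sc[which.max(sc)] > gain(B[i, ], colMod, rowMod[i]) + 1e-12) {
          rowMod[i] <- best; improved <- TRUE
        }
      }
      for (j in seq_len(nc)) {
        sc <- vapply(labs, function(l) gain(B[, j], rowMod, l), 0)
        best <- labs[which.max(sc)]
        cur <- if (colMod[j] == 0L) 0 else gain(B[, j], rowMod, colMod[j])
        if (sc[which.max(sc)] > cur + 1e-12) { colMod[j] <- best; improved <- TRUE }
      }
      if (!improved) break
    }
    list(Q = .barberQ(m, rowMod, colMod), rowMod = rowMod, colMod = colMod)
  }

  best <- list(Q = 0, rowMod = rep(1L, nr), colMod = rep(1L, nc))  # one-module baseline
  starts <- c(list(seq_len(nr)),                                   # all-singleton start
              lapply(seq_len(max(0L, nRestarts - 1L)), function(s)
                sample.int(max(2L, min(nr, nc)), nr, replace = TRUE)))
  for (st in starts) {
    run <- oneRun(as.integer(st))
    if (run$Q > best$Q + 1e-12) best <- run
  }
  list(Q = best$Q,
       rowModules = setNames(best$rowMod, rownames(m)),
       colModules = setNames(best$colMod, colnames(m)))
}

#' d' node-level specialization index
#'
#' For each node on the chosen margin, d is the Kullback-Leibler divergence
#' of the node's normalized interaction vector from the partner marginal
#' distribution; d' standardizes it between 0 (interactions proportional to
#' partner availability) and the maximum attainable by greedily packing the
#' node's total onto the scarcest partners without exceeding their marginal
#' totals.
#'
#' @param m Non-negative weight matrix.
#' @param margin \code{"rows"} or \code{"columns"}.
#' @return Named numeric vector of d' values in [0, 1] (NA, with a warning,
#'   for zero-weight nodes).
#' @export
dPrime <- function(m, margin = c("rows", "columns")) {
  margin <- match.arg(margin)
  m <- as.matrix(m)
  if (margin == "columns") m <- t(m)
  F_ <- sum(m)
  q <- colSums(m) / F_                 # partner availability
  colTot <- colSums(m)
  out <- setNames(rep(NA_real_, nrow(m)), rownames(m))
  for (i in seq_len(nrow(m))) {
    Ai <- sum(m[i, ])
    if (Ai <= 0) next
    p <- m[i, ] / Ai
    dObs <- sum(p[p > 0] * log(p[p > 0] / q[p > 0]))
    # greedy packing of Ai onto the rarest partners, capped by column totals
    ord <- order(q)
    rem <- Ai; alloc <- numeric(length(q))
    for (j in ord) {
      a <- min(rem, colTot[j])
      alloc[j] <- a; rem <- rem - a
      if (rem <= 1e-15) break
    }
    pm <- alloc / Ai
    dMax <- sum(pm[pm > 0] * log(pm[pm > 0] / q[pm > 0]))
    out[i] <- if (dMax <= 1e-12) 0 else min(1, max(0, dObs / dMax))
  }
  if (anyNA(out)) warning("zero-weight node(s): d' undefined, returned NA")
  out
}

#' Patefield (r2d) null draw with fixed marginals
#'
#' Draws a random integer table with exactly the observed row and column
#' totals via Patefield's algorithm (\code{stats::r2dtable}). Non-integer
#' weight matrices are scaled by \code{scale}, rounded to integers, sampled,
#' and rescaled, so the null preserves the integer-rounded marginals.
#'
#' @param m Non-negative weight matrix.
#' @param scale Scaling factor applied before rounding non-integer weights.
#'   Default \code{1e4}.
#' @return A null matrix of the same dimension (same dimnames).
#' @export
patefieldNull <- function(m, scale = 1e4) {
  m <- as.matrix(m)
  if (any(!is.finite(m)) || any(m < 0)) stop("weights must be finite and non-negative")
  isInt <- all(m == round(m))
  mi <- if (isInt) round(m) else round(m * scale)
  if (nrow(mi) == 1L || ncol(mi) == 1L) return(m)  # margins force the table
  draw <- r2dtable(1L, rowSums(mi), colSums(mi))[[1L]]
  dimnames(draw) <- dimnames(m)
  if (isInt) draw else draw / scale
}

#' Null-model ensemble of a network index
#'
#' Evaluates an index function over \code{nNull} Patefield r2d null draws.
#'
#' @param m Observed weight matrix.
#' @param indexFun Function taking a matrix and returning a scalar index.
#' @param nNull Number of null matrices. Default 1000.
#' @param seed Integer seed.
#' @param scale Passed to \code{\link{patefieldNull}}.
#' @return Numeric vector of null index values (class \code{"NullEnsemble"},
#'   with attribute \code{method = "r2d"}).
#' @export
nullEnsemble <- function(m, indexFun, nNull = 1000, seed = 1L, scale = 1e4) {
  set.seed(deriveSeed(seed, 62L))
  vals <- vapply(seq_len(nNull), function(b) indexFun(patefieldNull(m, scale = scale)),
                 numeric(1L))
  structure(vals, class = c("NullEnsemble", "numeric"), method = "r2d")
}

#' z-test of an observed index against its null ensemble
#'
#' \eqn{z = (obs - \bar{x}_{null}) / sd_{null}} with a two-sided normal
#' p-value. When the index has a closed range, a warning is issued if the
#' observed value or the null mean lies within 2 null standard deviations of
#' a boundary (the normal approximation is then doubtful).
#'
#' @param observed Observed index value.
#' @param nulls Numeric vector of null index values (>= 30).
#' @param range Optional closed range of the index, e.g. \code{c(0, 1)}.
#' @return List with \code{z}, \code{p}, \code{nullMean}, \code{nullSd}.
#' @export
nullZtest <- function(observed, nulls, range = NULL) {
  if (length(nulls) < 30L) stop("at least 30 null values are required")
  mu <- mean(nulls); s <- sd(nulls)
  if (s <= 0) stop("null standard deviation is zero")
  if (!is.null(range)) {
    nearBoundary <- function(v) any(abs(v - range) < 2 * s)
    if (nearBoundary(observed) || nearBoundary(mu))
      warning("observed value or null mean within 2 null SD of a range boundary; ",
              "normal approximation may be invalid")
  }
  z <- (observed - mu) / s
  list(z = z, p = 2 * pnorm(-abs(z)), nullMean = mu, nullSd = s)
}

#' ANOVA of per-host d' values grouped by phylum
#'
#' Delegates to the diversity module's AIC-selected ANOVA with the single
#' factor \code{phylum} (the same minimum-group-size exclusion applies).
#'
#' @param dprimes Named numeric vector of per-host d' values.
#' @param phylum Phylum label per host.
#' @param minGroupSize Minimum group size. Default 5.
#' @return An \code{"AnovaFit"} (see \code{\link{fitAnovaSelect}}).
#' @export
dprimeAnova <- function(dprimes, phylum, minGroupSize = 5) {
  fitAnovaSelect(as.numeric(dprimes),
                 data.frame(phylum = as.character(phylum)),
                 factors = "phylum", minGroupSize = minGroupSize)
}
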