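#' Relative abundances of viral families
#'
#' Row-normalizes a sample x family count (or weight) matrix onto the unit
#' simplex. Input may be a \linkS4class{ViromeExperiment} (its eukaryotic
#' counts are used transposed to samples-as-rows) or a plain matrix with
#' samples as rows.
#'
#' @param x \code{ViromeExperiment} or numeric matrix (samples as rows).
#' @return Numeric matrix, samples as rows, every row summing to 1.
#' @export
#' @examples
#' toRelativeAbundance(matrix(c(2, 2, 4), nrow = 1))
toRelativeAbundance <- function(x) {
  m <- if (is(x, "ViromeExperiment")) t(viromeCounts(x)) else as.matrix(x)
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero))
    stop("sample(s) with zero total reads: ",
         paste(rownames(m)[zero], collapse = ", "))
  m / rs
}

#' Drop families below a mean relative-abundance threshold
#'
#' Families whose column mean relative abundance is below \code{minMean}
#' (default 1e-4, i.e. 0.01\%) are removed and rows are renormalized. The
#' boundary is inclusive: a family whose mean exactly reaches the threshold
#' is retained.
#'
#' @param relabund Relative-abundance matrix (samples as rows).
#' @param minMean Column-mean threshold. Default \code{1e-4}.
#' @return Filtered, renormalized matrix with attributes \code{"retained"}
#'   and \code{"dropped"} (family names).
#' @export
filterFamilies <- function(relabund, minMean = 1e-4) {
  relabund <- as.matrix(relabund)
  mu <- colMeans(relabund)
  keep <- mu >= minMean
  if (!any(keep)) stop("all families fall below the mean-abundance threshold")
  out <- relabund[, keep, drop = FALSE]
  out <- out / rowSums(out)
  attr(out, "retained") <- colnames(relabund)[keep]
  attr(out, "dropped") <- colnames(relabund)[!keep]
  out
}

#' Count-zero multiplicative (CZM) replacement of zeros
#'
#' Imputes zeros in compositional rows below a count-based detection limit:
#' in sample \eqn{i} with sequencing depth \eqn{n_i}, each zero becomes
#' \eqn{\delta_i = label / (n_i + 1)} and the nonzero parts are multiplied by
#' \eqn{1 - z_i \delta_i} (with \eqn{z_i} the number of zeros in the row), so
#' rows stay on the unit simplex and the ratios between nonzero parts are
#' preserved exactly. Zero-free rows are returned unchanged.
#'
#' @param relabund Relative-abundance matrix (samples as rows, rows sum to 1).
#' @param depths Positive per-sample total read counts (recycled scalar ok).
#' @param label Multiplicative label in (0, 1). Default 0.65.
#' @return Strictly positive matrix with unchanged dimnames.
#' @export
#' @examples
#' czmReplaceZeros(matrix(c(0.5, 0.5, 0), nrow = 1), depths = 99)
czmReplaceZeros <- function(relabund, depths, label = 0.65) {
  relabund <- as.matrix(relabund)
  if (any(depths <= 0)) stop("'depths' must be positive")
  label <- .assertPos(label, "label")
  if (label >= 1) stop("'label' must be in (0, 1)")
  depths <- rep_len(depths, nrow(relabund))
  delta <- label / (depths + 1)
  out <- relabund
  for (i in seq_len(nrow(out))) {
    z <- out[i, ] == 0
    if (!any(z)) next
    nz <- out[i, !z]
    if (delta[i] >= min(nz))
      warning(sprintf("row %d: imputed value %.3g exceeds the smallest nonzero part",
                      i, delta[i]))
    out[i, z] <- delta[i]
    out[i, !z] <- nz * (1 - sum(z) * delta[i])
  }
  out
}

#' Centered log-ratio (clr) transform
#'
#' Maps strictly positive compositional rows to clr coordinates:
#' \eqn{clr(x)_j = \ln(x_j / g(x))} with \eqn{g(x)} the row geometric mean.
#' Every output row sums to zero; the transform is invariant to positive
#' rescaling of a row.
#'
#' @param relabund Strictly positive matrix, samples as rows.
#' @return Matrix of clr coordinates with the input's dimnames.
#' @export
#' @examples
#' clrTransform(matrix(c(1, 2, 4) / 7, nrow = 1))
clrTransform <- function(relabund) {
  m <- as.matrix(relabund)
  if (any(m <= 0)) stop("clr requires strictly positive entries; impute zeros first")
  lg <- log(m)
  lg - rowMeans(lg)
}

#' Aitchison (clr-Euclidean) distance matrix
#'
#' Pairwise Euclidean distances between clr-transformed compositions.
#'
#' @param clr Matrix of clr coordinates (samples as rows).
#' @return A \code{dist} object over the samples.
#' @export
aitchisonDistances <- function(clr) {
  dist(as.matrix(clr), method = "euclidean")
}

#' Full counts-to-clr preparation
#'
#' Convenience wrapper running the pipeline's stated order on a eukaryotic
#' count matrix: relative abundance, mean-abundance family filter, CZM zero
#' replacement (using the original per-sample eukaryotic read depths), clr.
#'
#' @param counts Count matrix, samples as rows (or a
#'   \linkS4class{ViromeExperiment}, transposed internally).
#' @param minMean Family filter threshold. Default \code{1e-4}.
#' @param label CZM label. Default 0.65.
#' @return clr coordinate matrix (samples as rows).
#' @export
countsToClr <- function(counts, minMean = 1e-4, label = 0.65) {
  m <- if (is(counts, "ViromeExperiment")) t(viromeCounts(counts)) else as.matrix(counts)
  depths <- rowSums(m)
  ra <- toRelativeAbundance(m)
  ra <- filterFamilies(ra, minMean = minMean)
  ra <- suppressWarnings(czmReplaceZeros(ra, depths = depths, label = label))
  clrTransform(ra)
}

#' Distances of samples to their own group centroid in clr space
#'
#' The group centroid is the arithmetic mean of the group's clr rows; each
#' sample's Euclidean distance to its own-group centroid is returned. These
#' distances feed the diversity module's ANOVA/Tukey workflow. By default the
#' analysis is restricted to groups with at least \code{minGroupSize} samples.
#'
#' @param clr clr coordinate matrix (samples as rows).
#' @param groups Group (phylum) label per sample.
#' @param minGroupSize Minimum group size admitted. Default 15; set to 1 to
#'   keep every group.
#' @return data.frame with \code{sample}, \code{group}, \code{distance}.
#' @export
centroidDistances <- function(clr, groups, minGroupSize = 15) {
  clr <- as.matrix(clr)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(clr))
  keepG <- names(which(table(groups) >= minGroupSize))
  idx <- groups %in% keepG
  clr <- clr[idx, , drop = FALSE]
  groups <- groups[idx]
  d <- numeric(nrow(clr))
  for (g in unique(groups)) {
    rows <- which(groups == g)
    ctr <- colMeans(clr[rows, , drop = FALSE])
    d[rows] <- sqrt(colSums((t(clr[rows, , drop = FALSE]) - ctr)^2))
  }
  data.frame(sample = rownames(clr) %||% as.character(seq_len(nrow(clr))),
             group = groups, distance = d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Equal-weight group aggregation with Ward2 clustering
#'
#' Aggregates sample relative-abundance vectors by group with equal weight
#' per sample (arithmetic mean of compositions), clr-transforms the group
#' profiles, and clusters both groups and families by agglomerative
#' clustering with the Ward.D2 criterion on Euclidean distances.
#'
#' @param relabund Strictly positive relative-abundance matrix (samples as
#'   rows; run \code{\link{czmReplaceZeros}} first).
#' @param groups Group label per sample.
#' @return List with \code{profiles} (group x family clr matrix),
#'   \code{groupTree} and \code{familyTree} (\code{hclust} objects, the
#'   latter \code{NULL} when fewer than 2 groups/families).
#' @export
aggregateByGroup <- function(relabund, groups) {
  m <- as.matrix(relabund)
  if (any(m <= 0)) stop("aggregation requires strictly positive compositions")
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  prof <- rowsum(m, groups) / as.vector(table(groups)[sort(unique(groups))])
  prof <- prof / rowSums(prof)
  clrProf <- clrTransform(prof)
  gTree <- if (nrow(clrProf) >= 2L)
    hclust(dist(clrProf), method = "ward.D2") else NULL
  fTree <- if (ncol(clrProf) >= 2L)
    hclust(dist(t(clrProf)), method = "ward.D2") else NULL
  list(profiles = clrProf, groupTree = gTree, familyTree = fTree)
}

#' Write an hclust dendrogram as Newick
#'
#' @param tree An \code{hclust} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeDendrogramNewick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
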