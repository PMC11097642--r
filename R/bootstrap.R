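# Bootstrap-balanced pairwise PERMANOVA/PERMDISP and the centroid
# equivalence network.

#' Configuration of the bootstrap equivalence procedure
#'
#' @param groupSize Bootstrap group size per phylum. Default 15.
#' @param nIter Number of bootstrap iterations. Default 1500.
#' @param alpha FDR significance level for the four-level coding. Default 0.05.
#' @param supportThreshold Strict lower bound on edge support. Default 0.2.
#' @param nPerm Permutations per within-iteration test. Default 199 (the main
#'   runtime knob: each iteration runs 2 tests for each of n(n-1)/2 pairs).
#' @param minMean Family filter threshold applied within each iteration.
#' @param label CZM label applied within each iteration.
#' @param fdrFamily \code{"pooled"} (default; PERMANOVA and PERMDISP p-values
#'   of one iteration adjusted as one Benjamini-Hochberg family of
#'   \eqn{2 \cdot n(n-1)/2} tests) or \code{"separate"} (one family per test
#'   type).
#' @param seed Integer master seed of the whole loop.
#' @return Validated list of class \code{"BootstrapConfig"}.
#' @export
bootstrapConfig <- function(groupSize = 15, nIter = 1500, alpha = 0.05,
                            supportThreshold = 0.2, nPerm = 199,
                            minMean = 1e-4, label = 0.65,
                            fdrFamily = c("pooled", "separate"), seed = 1L) {
  cfg <- list(groupSize = .assertCount(groupSize, "groupSize", min = 2L),
              nIter = .assertCount(nIter, "nIter", min = 1L),
              alpha = .assertProb(alpha, "alpha"),
              supportThreshold = .assertProb(supportThreshold, "supportThreshold"),
              nPerm = .assertCount(nPerm, "nPerm", min = 1L),
              minMean = .assertNonNeg(minMean, "minMean"),
              label = .assertPos(label, "label"),
              fdrFamily = match.arg(fdrFamily),
              seed = .assertCount(seed, "seed", min = 0L))
  class(cfg) <- "BootstrapConfig"
  cfg
}

#' One balanced bootstrap resample with a single imputed phylum label
#'
#' Implements the resampling steps of the pairwise testing loop:
#' (i) draw \code{groupSize} observations per phylum with replacement;
#' (ii) pick one drawn observation at random and impute a new phylum for it
#' (uniform over the other phyla), relabeling all its bootstrap duplicates;
#' (iii) randomly drop original members of the imputed phylum until its group
#' size is back to \code{groupSize}, keeping the shuffled observation;
#' (iv) redraw replacements for the shuffled observation's old phylum,
#' excluding the shuffled observation itself. The output is exactly
#' \code{groupSize} observations per phylum label, and the shuffled
#' observation appears only under its imputed label. Uses the current RNG
#' state (seed the loop, not the iteration).
#'
#' @param counts Count matrix, samples as rows (or a
#'   \linkS4class{ViromeExperiment}).
#' @param phylum Phylum label per sample (ignored for a
#'   \code{ViromeExperiment} carrying its own).
#' @param groupSize Target group size. Default 15.
#' @return List with \code{counts} (resampled matrix, unique row ids of the
#'   form \code{origId.k}), \code{meta} (data.frame \code{origId},
#'   \code{phylum}), \code{shuffled} (the shuffled observation's id),
#'   \code{imputedPhylum}, \code{originalPhylum}.
#' @export
bootstrapResample <- function(counts, phylum = NULL, groupSize = 15) {
  if (is(counts, "ViromeExperiment")) {
    phylum <- sampleData(counts)$phylum
    counts <- t(viromeCounts(counts))
  }
  counts <- as.matrix(counts)
  phylum <- as.character(phylum)
  stopifnot(length(phylum) == nrow(counts))
  phyla <- sort(unique(phylum))
  if (length(phyla) < 2L) stop("at least 2 phyla are required")
  ids <- rownames(counts) %||% as.character(seq_len(nrow(counts)))

  pool <- split(ids, phylum)
  draw <- lapply(phyla, function(ph)
    sample(pool[[ph]], groupSize, replace = TRUE))
  sel <- data.frame(origId = unlist(draw),
                    phylum = rep(phyla, each = groupSize),
                    stringsAsFactors = FALSE)

  j <- sample.int(nrow(sel), 1L)
  shuffled <- sel$origId[j]
  pOld <- sel$phylum[j]
  pNew <- if (length(phyla) == 2L) setdiff(phyla, pOld) else
    sample(setdiff(phyla, pOld), 1L)
  dupRows <- which(sel$origId == shuffled)   # all duplicates relabeled
  nDup <- length(dupRows)
  sel$phylum[dupRows] <- pNew

  # (iii) trim the imputed phylum back to groupSize, keeping the shuffled obs
  newRows <- which(sel$phylum == pNew)
  removable <- setdiff(newRows, dupRows)
  nDrop <- length(newRows) - groupSize
  drop <- removable[sample.int(length(removable), nDrop)]
  if (length(drop)) sel <- sel[-drop, , drop = FALSE]

  # (iv) refill the old phylum, never re-drawing the shuffled observation
  refillPool <- setdiff(pool[[pOld]], shuffled)
  if (!length(refillPool))
    stop("phylum '", pOld, "' has no observation other than the shuffled one")
  sel <- rbind(sel, data.frame(origId = sample(refillPool, nDup, replace = TRUE),
                               phylum = pOld, stringsAsFactors = FALSE))

  sel <- sel[order(sel$phylum), , drop = FALSE]
  out <- counts[sel$origId, , drop = FALSE]
  rownames(out) <- sprintf("%s.%d", sel$origId, seq_len(nrow(sel)))
  rownames(sel) <- rownames(out)
  list(counts = out, meta = sel, shuffled = shuffled,
       imputedPhylum = pNew, originalPhylum = pOld)
}

#' Pairwise PERMANOVA and PERMDISP p-values for one bootstrap resample
#'
#' Re-runs the compositional preparation (family filter, CZM imputation,
#' clr) on the resampled absolute-abundance matrix, then performs a one-way
#' PERMANOVA and a PERMDISP for every unordered pair of phyla on the
#' Euclidean distances of the pair's clr rows.
#'
#' @param counts Resampled count matrix (samples as rows).
#' @param phylum Phylum label per resampled row.
#' @param nPerm Permutations per test.
#' @param minMean,label Compositional preparation parameters.
#' @return data.frame with one row per pair: \code{phylum_a},
#'   \code{phylum_b}, \code{p_permanova}, \code{p_permdisp}.
#' @export
pairwisePhylumTests <- function(counts, phylum, nPerm = 199,
                                minMean = 1e-4, label = 0.65) {
  phylum <- as.character(phylum)
  clr <- countsToClr(as.matrix(counts), minMean = minMean, label = label)
  phyla <- sort(unique(phylum))
  prs <- combn(phyla, 2L)
  res <- data.frame(phylum_a = prs[1L, ], phylum_b = prs[2L, ],
                    p_permanova = NA_real_, p_permdisp = NA_real_)
  for (k in seq_len(ncol(prs))) {
    idx <- phylum %in% prs[, k]
    d <- dist(clr[idx, , drop = FALSE])
    g <- phylum[idx]
    pm <- permanova(d, data.frame(g = g), ~ g, nPerm = nPerm)
    pd <- permdisp(d, g, nPerm = nPerm)
    res$p_permanova[k] <- pm$table$p[1L]
    res$p_permdisp[k] <- pd$p
  }
  res
}

#' Four-level coding of pairwise test outcomes after FDR adjustment
#'
#' Adjusts the PERMANOVA and PERMDISP p-values of one iteration by
#' Benjamini-Hochberg (by default both test families pooled into a single
#' family of \eqn{2 \cdot n(n-1)/2} tests) and discretizes each pair:
#' \code{LOC_DIFF} (PERMANOVA rejected, PERMDISP accepted -- the only code
#' counted as a significant centroid difference), \code{BOTH_REJECT},
#' \code{DISP_ONLY}, \code{NEITHER}.
#'
#' @param pairs data.frame from \code{\link{pairwisePhylumTests}}.
#' @param alpha Significance level on the FDR scale. Default 0.05.
#' @param fdrFamily \code{"pooled"} or \code{"separate"}.
#' @return The input with added columns \code{fdr_permanova},
#'   \code{fdr_permdisp}, \code{code}.
#' @export
encodeOutcomes <- function(pairs, alpha = 0.05,
                           fdrFamily = c("pooled", "separate")) {
  fdrFamily <- match.arg(fdrFamily)
  if (fdrFamily == "pooled") {
    adj <- fdrAdjust(c(pairs$p_permanova, pairs$p_permdisp))
    pairs$fdr_permanova <- adj[seq_len(nrow(pairs))]
    pairs$fdr_permdisp <- adj[nrow(pairs) + seq_len(nrow(pairs))]
  } else {
    pairs$fdr_permanova <- fdrAdjust(pairs$p_permanova)
    pairs$fdr_permdisp <- fdrAdjust(pairs$p_permdisp)
  }
  rejA <- pairs$fdr_permanova < alpha
  rejD <- pairs$fdr_permdisp < alpha
  pairs$code <- factor(ifelse(rejA & !rejD, "LOC_DIFF",
                       ifelse(rejA & rejD, "BOTH_REJECT",
                       ifelse(!rejA & rejD, "DISP_ONLY", "NEITHER"))),
                       levels = c("LOC_DIFF", "BOTH_REJECT", "DISP_ONLY", "NEITHER"))
  pairs
}

#' Build the centroid equivalence network from the outcome array
#'
#' A pair's support is the fraction of iterations whose code was anything
#' other than \code{LOC_DIFF} (i.e. the pair was \emph{not} significantly
#' different in centroid location). An edge connects two phyla iff support
#' strictly exceeds \code{supportThreshold}.
#'
#' @param outcomes Long data.frame with columns \code{iteration},
#'   \code{phylum_a}, \code{phylum_b}, \code{code}.
#' @param supportThreshold Strict support bound. Default 0.2.
#' @return Object of class \code{"EquivalenceNetwork"}: list with
#'   \code{nodes}, \code{support} (all pairs with their support) and
#'   \code{edges} (the supported subset).
#' @export
buildEquivalenceNetwork <- function(outcomes, supportThreshold = 0.2) {
  key <- paste(outcomes$phylum_a, outcomes$phylum_b, sep = "\r")
  supp <- tapply(outcomes$code != "LOC_DIFF", key, mean)
  parts <- strsplit(names(supp), "\r", fixed = TRUE)
  support <- data.frame(phylum_a = vapply(parts, `[`, "", 1L),
                        phylum_b = vapply(parts, `[`, "", 2L),
                        support = as.numeric(supp), row.names = NULL)
  net <- list(nodes = sort(unique(c(support$phylum_a, support$phylum_b))),
              support = support,
              edges = support[support$support > supportThreshold, , drop = FALSE],
              supportThreshold = supportThreshold)
  class(net) <- "EquivalenceNetwork"
  net
}

#' @export
print.EquivalenceNetwork <- function(x, ...) {
  cat(sprintf("Equivalence network: %d phyla, %d edge(s) with support > %.2f\n",
              length(x$nodes), nrow(x$edges), x$supportThreshold))
  if (nrow(x$edges)) print(x$edges, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the full bootstrap equivalence procedure
#'
#' Loops \code{config$nIter} balanced resamples
#' (\code{\link{bootstrapResample}}), re-derives the clr matrix per
#' iteration, runs all pairwise PERMANOVA/PERMDISP tests
#' (\code{\link{pairwisePhylumTests}}), applies the per-iteration FDR coding
#' (\code{\link{encodeOutcomes}}) and condenses the outcome array into the
#' equivalence network (\code{\link{buildEquivalenceNetwork}}).
#' Only phyla with at least \code{minSamples} samples enter the analysis.
#' Reproducible under \code{config$seed}.
#'
#' @param counts Count matrix (samples as rows) or
#'   \linkS4class{ViromeExperiment}.
#' @param phylum Phylum label per sample (taken from the experiment's
#'   \code{colData} when omitted).
#' @param config \code{\link{bootstrapConfig}} object.
#' @param minSamples Minimum samples per admitted phylum. Default 15; lower
#'   it for reduced-scale runs.
#' @param verbose Log progress every 50 iterations.
#' @return List with \code{outcomes} (long data.frame: iteration, pair,
#'   p-values, FDR values, code) and \code{network}
#'   (\code{"EquivalenceNetwork"}).
#' @export
runBootstrap <- function(counts, phylum = NULL, config = bootstrapConfig(),
                         minSamples = 15, verbose = FALSE) {
  if (is(counts, "ViromeExperiment")) {
    phylum <- sampleData(counts)$phylum
    counts <- t(viromeCounts(counts))
  }
  counts <- as.matrix(counts)
  phylum <- as.character(phylum)
  keep <- phylum %in% names(which(table(phylum) >= minSamples))
  counts <- counts[keep, , drop = FALSE]
  phylum <- phylum[keep]
  if (length(unique(phylum)) < 2L)
    stop("fewer than 2 phyla with >= ", minSamples, " samples")
  set.seed(deriveSeed(config$seed, 51L))
  out <- vector("list", config$nIter)
  for (it in seq_len(config$nIter)) {
    rs <- bootstrapResample(counts, phylum, groupSize = config$groupSize)
    pw <- pairwisePhylumTests(rs$counts, rs$meta$phylum, nPerm = config$nPerm,
                              minMean = config$minMean, label = config$label)
    pw <- encodeOutcomes(pw, alpha = config$alpha, fdrFamily = config$fdrFamily)
    pw$iteration <- it
    out[[it]] <- pw
    if (verbose && it %% 50L == 0L)
      message(sprintf("bootstrap iteration %d/%d", it, config$nIter))
  }
  outcomes <- do.call(rbind, out)
  list(outcomes = outcomes,
       network = buildEquivalenceNetwork(outcomes, config$supportThreshold))
}
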