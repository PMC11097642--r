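#' @importFrom methods new validObject is as setValidity show
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats aov anova aggregate as.dist dist lm AIC TukeyHSD
#'   p.adjust pnorm ptukey rnorm rlnorm rmultinom rgamma runif cutree hclust
#'   model.matrix qtukey terms sd var r2dtable setNames coef residuals
#' @importFrom utils read.delim write.table combn head
NULL

#' Derive a stage seed from a master seed
#'
#' Deterministic splitting of one master integer seed into per-stage
#' sub-seeds, used throughout the package so that a single seed governs all
#' randomness. The result is always a valid 32-bit R integer seed.
#'
#' @param seed Master integer seed.
#' @param offset Integer stage offset.
#' @return An integer seed.
#' @export
#' @examples
#' deriveSeed(1, 1)
deriveSeed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + 104729 * as.numeric(offset)) %% 2147483629)
}

# shared validators ---------------------------------------------------------

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.assertProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}

.assertNonNeg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative number", name), call. = FALSE)
  as.numeric(x)
}

.assertPos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  as.numeric(x)
}

#' Habitat category labels
#'
#' The closed five-category habitat vocabulary used for sample annotation.
#'
#' @return Character vector of the five admissible habitat labels.
#' @export
#' @examples
#' habitatLevels()
habitatLevels <- function() {
  c("brackish", "freshwater", "intertidal zone", "marine", "terrestrial")
}

#' Host-domain categories for viral families
#'
#' @return Character vector of admissible host-domain labels.
#' @export
hostDomainLevels <- function() {
  c("eukaryote", "prokaryote_archaea", "uncertain")
}

# Reserved family receiving reads without a family-level classification.
UNCERTAIN_FAMILY <- "UNCERTAIN_FAMILY"
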