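#' Family richness (alpha-diversity)
#'
#' Number of viral families with strictly positive read counts.
#'
#' @param counts Non-negative count vector, or a matrix with samples as rows
#'   (per-sample richness is returned).
#' @return Integer (or integer vector for matrix input).
#' @export
#' @examples
#' familyRichness(c(5, 0, 3, 0, 2))
familyRichness <- function(counts) {
  if (is.matrix(counts)) return(apply(counts, 1L, familyRichness))
  if (any(counts < 0)) stop("counts must be non-negative")
  sum(counts > 0)
}

#' Shannon diversity index (natural log)
#'
#' \eqn{H' = -\sum_j p_j \ln p_j} over the families with positive counts,
#' where \eqn{p_j} is the within-sample proportion of reads in family
#' \eqn{j}. Bounded by \eqn{0 \le H' \le \ln(\mathrm{richness})}.
#'
#' @param counts Count vector with at least one positive entry, or a matrix
#'   with samples as rows.
#' @param base Logarithm base; default \code{exp(1)} (natural log).
#' @return Numeric H' (or vector for matrix input).
#' @export
#' @examples
#' shannonIndex(c(1, 1, 1, 1))   # ln 4
shannonIndex <- function(counts, base = exp(1)) {
  if (is.matrix(counts)) return(apply(counts, 1L, shannonIndex, base = base))
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot == 0) stop("Shannon index undefined for an all-zero vector")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Per-sample diversity table
#'
#' Computes richness and Shannon H' for every sample of a eukaryotic count
#' matrix and attaches the sample metadata.
#'
#' @param x \linkS4class{ViromeExperiment} (eukaryotic families) or count
#'   matrix with samples as rows.
#' @param meta Optional data.frame of sample metadata (ignored for a
#'   \code{ViromeExperiment}, whose own \code{colData} is used).
#' @return data.frame with \code{sample}, \code{richness}, \code{shannon}
#'   and any metadata columns.
#' @export
diversityTable <- function(x, meta = NULL) {
  if (is(x, "ViromeExperiment")) {
    meta <- sampleData(x)
    m <- t(viromeCounts(x))
  } else m <- as.matrix(x)
  out <- data.frame(sample = rownames(m) %||% as.character(seq_len(nrow(m))),
                    richness = familyRichness(m),
                    shannon = shannonIndex(m))
  if (!is.null(meta)) out <- cbind(out, meta[rownames(m), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Family accumulation curve by repeated subsampling
#'
#' For each subsample size, draws \code{nIter} random sample subsets without
#' replacement from one group, records the pooled richness (number of
#' families with a positive count in the union), and averages. An ordinary
#' least-squares line of mean richness on the natural log of the subsample
#' size summarizes the curve.
#'
#' @param counts Count matrix, samples as rows (already restricted to the
#'   group of interest, or use \code{groups}/\code{group}).
#' @param groups Optional group label per sample.
#' @param group Which group to use when \code{groups} is given.
#' @param sizes Integer subsample sizes; default \code{1:n}.
#' @param nIter Iterations per size. Default 50.
#' @param seed Integer seed.
#' @param minGroupSize Groups below this size are rejected. Default 15.
#' @return List with \code{table} (data.frame \code{size},
#'   \code{meanRichness}) and \code{fit} (named vector: intercept, slope of
#'   richness on ln size).
#' @export
accumulationCurve <- function(counts, groups = NULL, group = NULL, sizes = NULL,
                              nIter = 50, seed = 1L, minGroupSize = 15) {
  m <- if (is(counts, "ViromeExperiment")) t(viromeCounts(counts)) else as.matrix(counts)
  if (!is.null(groups)) {
    stopifnot(!is.null(group))
    m <- m[as.character(groups) == group, , drop = FALSE]
  }
  n <- nrow(m)
  if (n < minGroupSize)
    stop(sprintf("group has %d samples; %d or more required", n, minGroupSize))
  if (is.null(sizes)) sizes <- seq_len(n)
  if (any(sizes < 1 | sizes > n)) stop("subsample sizes must be in [1, group size]")
  set.seed(deriveSeed(seed, 31L))
  meanRich <- vapply(sizes, function(s) {
    mean(vapply(seq_len(nIter), function(it) {
      idx <- sample.int(n, s)
      sum(colSums(m[idx, , drop = FALSE]) > 0)
    }, numeric(1L)))
  }, numeric(1L))
  tab <- data.frame(size = sizes, meanRichness = meanRich)
  fit <- lm(meanRichness ~ log(size), data = tab)
  list(table = tab, fit = c(intercept = unname(coef(fit)[1L]),
                            slope = unname(coef(fit)[2L])))
}

#' Box-Cox transform (forward and inverse)
#'
#' Forward: \eqn{y \mapsto (y^\lambda - 1)/\lambda} (log for
#' \eqn{\lambda = 0}); inverse: \eqn{z \mapsto (\lambda z + 1)^{1/\lambda}}
#' (exp for \eqn{\lambda = 0}). Both are monotone increasing and round-trip
#' to identity.
#'
#' @param values Numeric vector. Forward requires positive values; inverse
#'   requires \eqn{\lambda z + 1 > 0}.
#' @param lambda Transformation parameter.
#' @param direction \code{"forward"} or \code{"inverse"}.
#' @return Transformed numeric vector.
#' @export
#' @examples
#' boxcoxTransform(2, lambda = 2.5)                      # (2^2.5 - 1)/2.5
#' boxcoxTransform(boxcoxTransform(3, 2.5), 2.5, "inverse")
boxcoxTransform <- function(values, lambda, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (direction == "forward") {
    bad <- which(values <= 0)
    if (length(bad))
      stop("forward Box-Cox requires positive values; offending indices: ",
           paste(bad, collapse = ", "))
    if (lambda == 0) log(values) else (values^lambda - 1) / lambda
  } else {
    if (lambda == 0) return(exp(values))
    bad <- which(lambda * values + 1 <= 0)
    if (length(bad))
      stop("inverse Box-Cox domain violation (lambda*z + 1 <= 0) at indices: ",
           paste(bad, collapse = ", "))
    (lambda * values + 1)^(1 / lambda)
  }
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on absolute deviations from the group center (median by
#' default, the Brown-Forsythe variant; mean available). Delegates to
#' \code{car::leveneTest}.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, each with >= 2 observations).
#' @param center \code{"median"} (default) or \code{"mean"}.
#' @return List with \code{F}, \code{p}, \code{df}.
#' @export
leveneHomogeneity <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- factor(groups)
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop("at least 2 groups are required")
  if (any(sizes < 2L)) stop("singleton group(s): ",
                            paste(names(sizes)[sizes < 2L], collapse = ", "))
  res <- car::leveneTest(values, groups,
                         center = if (center == "median") stats::median else mean)
  list(F = res[1L, "F value"], p = res[1L, "Pr(>F)"],
       df = c(res[1L, "Df"], res[2L, "Df"]))
}

# AIC with the fixed in-package convention n*ln(RSS/n) + 2k, k = params + 1.
# Only differences between models on the same response are meaningful.
.aicFromRSS <- function(rss, n, nParams) {
  if (rss <= 0) stop("residual sum of squares must be positive for AIC")
  n * log(rss / n) + 2 * (nParams + 1)
}

#' Fit candidate ANOVA models and select by AIC
#'
#' Considers the one-way models for each factor and the additive model of
#' all factors, after dropping observations belonging to factor levels with
#' fewer than \code{minGroupSize} observations, and returns the fit that
#' minimizes the AIC (convention \eqn{n \ln(RSS/n) + 2k}, \eqn{k} = number
#' of coefficients + 1). An optional Box-Cox transform (the pipeline default
#' for Shannon H' is the inverse transform with \eqn{\lambda = 2.5}) is
#' applied to the response before fitting.
#'
#' @param values Numeric response per sample.
#' @param data data.frame holding the factor columns.
#' @param factors Character vector of factor column names (candidate set =
#'   every single factor plus the additive combination). Default
#'   \code{c("phylum", "habitat")}.
#' @param minGroupSize Factor levels below this size are dropped before
#'   fitting. Default 5.
#' @param transform \code{"none"}, \code{"boxcox-inverse"} or
#'   \code{"boxcox-forward"}.
#' @param lambda Box-Cox parameter. Default 2.5.
#' @return Object of class \code{"AnovaFit"}: list with \code{formula},
#'   \code{fit} (the \code{lm}), \code{anova} (per-term df, SS, F, p),
#'   \code{aic}, \code{r2}, \code{transformation}, \code{lambda},
#'   \code{candidates} (AIC of every candidate), \code{data}.
#' @export
fitAnovaSelect <- function(values, data, factors = c("phylum", "habitat"),
                           minGroupSize = 5,
                           transform = c("none", "boxcox-inverse", "boxcox-forward"),
                           lambda = 2.5) {
  transform <- match.arg(transform)
  stopifnot(length(values) == nrow(data), all(factors %in% colnames(data)))
  y <- switch(transform,
              none = values,
              `boxcox-inverse` = boxcoxTransform(values, lambda, "inverse"),
              `boxcox-forward` = boxcoxTransform(values, lambda, "forward"))
  df <- data.frame(.y = y, data[, factors, drop = FALSE])
  keep <- rep(TRUE, nrow(df))
  for (f in factors) {
    tab <- table(df[[f]])
    keep <- keep & df[[f]] %in% names(tab)[tab >= minGroupSize]
  }
  df <- df[keep, , drop = FALSE]
  for (f in factors) df[[f]] <- droplevels(factor(df[[f]]))

  cand <- c(as.list(factors), if (length(factors) > 1L) list(factors))
  fits <- list()
  aics <- numeric(0)
  for (cc in cand) {
    usable <- vapply(cc, function(f) nlevels(df[[f]]) >= 2L, logical(1L))
    if (!all(usable)) {
      warning("candidate {", paste(cc, collapse = "+"),
              "} skipped: factor(s) with < 2 levels after filtering")
      next
    }
    fo <- stats::as.formula(paste(".y ~", paste(cc, collapse = " + ")))
    fit <- lm(fo, data = df)
    rss <- sum(residuals(fit)^2)
    key <- paste(cc, collapse = "+")
    fits[[key]] <- fit
    aics[key] <- .aicFromRSS(rss, nrow(df), length(coef(fit)))
  }
  if (!length(fits)) stop("no fittable candidate model")
  best <- names(which.min(aics))
  fit <- fits[[best]]
  atab <- anova(fit)
  res <- list(formula = paste(".y ~", best),
              fit = fit,
              anova = data.frame(term = rownames(atab), df = atab$Df,
                                 sumsq = atab$`Sum Sq`, F = atab$`F value`,
                                 p = atab$`Pr(>F)`),
              aic = unname(aics[best]),
              r2 = summary(fit)$r.squared,
              transformation = transform, lambda = lambda,
              candidates = aics, data = df)
  class(res) <- "AnovaFit"
  res
}

#' @export
print.AnovaFit <- function(x, ...) {
  cat("ANOVA model selected by AIC:", x$formula, "\n")
  cat(sprintf("  AIC = %.2f, R^2 = %.3f, transformation = %s\n",
              x$aic, x$r2, x$transformation))
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD post hoc test with compact letter display
#'
#' Runs Tukey's honestly-significant-difference test (Tukey-Kramer for
#' unbalanced groups) on one categorical term of a selected ANOVA model and
#' derives the compact letter display by the insert-and-absorb algorithm:
#' groups sharing a letter are exactly the pairs not rejected at
#' \code{alpha}. Ties in letter assignment are resolved by group (factor
#' level) order.
#'
#' @param fit An \code{"AnovaFit"} from \code{\link{fitAnovaSelect}}, or a
#'   fitted \code{aov}/\code{lm} with the term's data accessible.
#' @param term Name of the categorical term (default: first factor term).
#' @param alpha Significance level. Default 0.05.
#' @return Object of class \code{"TukeyResult"}: list with \code{pairs}
#'   (data.frame: comparison, diff, lwr, upr, p_adj) and \code{letters}
#'   (named character vector per group).
#' @export
tukeyHsdLetters <- function(fit, term = NULL, alpha = 0.05) {
  if (inherits(fit, "AnovaFit")) {
    df <- fit$data
    terms_ <- attr(terms(fit$fit), "term.labels")
    if (is.null(term)) term <- terms_[1L]
    av <- aov(stats::as.formula(paste(".y ~", paste(terms_, collapse = "+"))),
              data = df)
  } else {
    av <- if (inherits(fit, "aov")) fit else aov(fit)
    if (is.null(term)) term <- attr(terms(av), "term.labels")[1L]
    df <- stats::model.frame(av)
  }
  lev <- levels(factor(df[[term]]))
  if (length(lev) < 2L) stop("term must have at least 2 levels")
  if (any(table(df[[term]]) < 2L)) stop("singleton group in term '", term, "'")
  tk <- TukeyHSD(av, which = term)[[term]]
  pairs <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  sig <- pairs$comparison[pairs$p_adj < alpha]
  sigPairs <- strsplit(sig, "-", fixed = TRUE)
  letters_ <- .compactLetters(lev, sigPairs)
  structure(list(pairs = pairs, letters = letters_, alpha = alpha, term = term),
            class = "TukeyResult")
}

# Insert-and-absorb compact letter display. 'sigPairs' is a list of
# length-2 character vectors naming significantly different group pairs.
.compactLetters <- function(groups, sigPairs) {
  sets <- list(groups)
  for (pr in sigPairs) {
    newSets <- list()
    for (S in sets) {
      if (all(pr %in% S)) {
        newSets <- c(newSets, list(setdiff(S, pr[1L])), list(setdiff(S, pr[2L])))
      } else newSets <- c(newSets, list(S))
    }
    # absorb sets contained in another set
    keep <- rep(TRUE, length(newSets))
    for (i in seq_along(newSets))
      for (j in seq_along(newSets))
        if (i != j && keep[i] && keep[j] &&
            all(newSets[[i]] %in% newSets[[j]]) &&
            !(length(newSets[[i]]) == length(newSets[[j]]) && i < j))
          keep[i] <- FALSE
    sets <- newSets[keep]
  }
  ord <- order(vapply(sets, function(S) min(match(S, groups)), numeric(1L)))
  sets <- sets[ord]
  lab <- setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets))
    lab[sets[[k]]] <- paste0(lab[sets[[k]]], letters[k])
  lab
}

#' @export
print.TukeyResult <- function(x, ...) {
  cat("Tukey HSD on term '", x$term, "' (alpha = ", x$alpha, ")\n", sep = "")
  print(x$pairs, row.names = FALSE)
  cat("letters:\n")
  print(x$letters)
  invisible(x)
}
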