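# End-to-end orchestration: counts -> diversity -> composition ->
# multivariate -> bootstrap -> bipartite, with one master seed.

#' Pipeline configuration
#'
#' Collects every input path and threshold of the full analysis in one
#' validated, serializable object. Defaults mirror the pipeline's canonical
#' settings: read length >= 75, > 3 Gbases, 20 species per phylum, 0.01\%
#' mean-abundance family filter, groups of >= 5 for univariate ANOVA, phyla
#' of >= 15 samples for the clr/PERMANOVA subset, 1000 bipartite null
#' models, Box-Cox \eqn{\lambda = 2.5}.
#'
#' @param countsPath,annotationPath,samplePath Input TSVs (counts: samples
#'   as rows; see \code{\link{readCountMatrix}}). Leave \code{countsPath}
#'   NULL to run on a simulated dataset from \code{simulateConfig}.
#' @param simulateConfig Optional \code{\link{syntheticConfig}} used when no
#'   counts path is given.
#' @param minMean Family filter threshold. Default 1e-4.
#' @param czmLabel CZM label. Default 0.65.
#' @param minGroupSize Univariate ANOVA group-size bound. Default 5.
#' @param minSamplesClr Phylum-size bound for the multivariate subset.
#'   Default 15.
#' @param lambda Box-Cox parameter for Shannon H'. Default 2.5.
#' @param nPerm Permutations for the global PERMANOVA/PERMDISP. Default 999.
#' @param bootstrap A \code{\link{bootstrapConfig}}.
#' @param nNull Bipartite null-model count. Default 1000.
#' @param accumulationIter Accumulation-curve iterations. Default 50.
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @return Validated list of class \code{"ViromePipelineConfig"}.
#' @export
viromePipelineConfig <- function(countsPath = NULL, annotationPath = NULL,
                                 samplePath = NULL, simulateConfig = NULL,
                                 minMean = 1e-4, czmLabel = 0.65,
                                 minGroupSize = 5, minSamplesClr = 15,
                                 lambda = 2.5, nPerm = 999,
                                 bootstrap = bootstrapConfig(),
                                 nNull = 1000, accumulationIter = 50,
                                 seed = 1L) {
  for (p in c(countsPath, annotationPath, samplePath))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  if (is.null(countsPath) && is.null(simulateConfig))
    stop("either 'countsPath' or 'simulateConfig' is required")
  cfg <- list(countsPath = countsPath, annotationPath = annotationPath,
              samplePath = samplePath, simulateConfig = simulateConfig,
              minMean = .assertNonNeg(minMean, "minMean"),
              czmLabel = .assertPos(czmLabel, "czmLabel"),
              minGroupSize = .assertCount(minGroupSize, "minGroupSize"),
              minSamplesClr = .assertCount(minSamplesClr, "minSamplesClr"),
              lambda = .assertPos(lambda, "lambda"),
              nPerm = .assertCount(nPerm, "nPerm"),
              bootstrap = bootstrap,
              nNull = .assertCount(nNull, "nNull"),
              accumulationIter = .assertCount(accumulationIter, "accumulationIter"),
              seed = .assertCount(seed, "seed", min = 0L))
  class(cfg) <- "ViromePipelineConfig"
  cfg
}

.configHash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "simulateConfig")]), collapse = "")
  if (!is.null(cfg$simulateConfig))
    s <- paste0(s, paste(deparse(unclass(cfg$simulateConfig)), collapse = ""))
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

.writeArtifact <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config=%s seed=%d", hash, seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full virome analysis pipeline
#'
#' Executes every stage in order and writes all result tables as TSV into
#' \code{outDir}. Each artifact carries the config hash and master seed in
#' a leading comment line; identical config + seed give byte-identical
#' outputs. A failing stage aborts with the stage name and leaves a
#' \code{FAILED} marker next to the partial outputs.
#'
#' @param config A \code{\link{viromePipelineConfig}}.
#' @param outDir Output directory (created if needed).
#' @param verbose Log stage progress. Default TRUE.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
runViromePipeline <- function(config, outDir, verbose = TRUE) {
  stopifnot(inherits(config, "ViromePipelineConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  hash <- .configHash(config)
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "setup"
  res <- list()
  wa <- function(df, name) .writeArtifact(df, file.path(outDir, name), hash, seed)

  runStage <- function(name, expr) {
    stage <<- name
    say("stage: %s", name)
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
                 file.path(outDir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  res$counts <- runStage("counts", {
    if (!is.null(config$countsPath))
      readCountMatrix(config$countsPath, config$annotationPath, config$samplePath)
    else simulateVirome(config$simulateConfig)$experiment
  })

  res$partition <- runStage("host_domain_partition", {
    part <- suppressWarnings(partitionByHostDomain(res$counts))
    wa(data.frame(sample = rownames(part$fractions), part$fractions),
       "host_domain_fractions.tsv")
    part
  })
  euk <- res$partition$eukaryotic
  meta <- sampleData(euk)
  eukCounts <- t(viromeCounts(euk))

  res$diversity <- runStage("diversity", {
    dt <- diversityTable(euk)
    wa(dt, "diversity.tsv")
    fits <- list()
    factors <- intersect(c("phylum", "habitat"), colnames(meta))
    fits$richness <- fitAnovaSelect(dt$richness, meta, factors = factors,
                                    minGroupSize = config$minGroupSize)
    fits$shannon <- fitAnovaSelect(dt$shannon, meta, factors = factors,
                                   minGroupSize = config$minGroupSize,
                                   transform = "boxcox-inverse",
                                   lambda = config$lambda)
    anovaRows <- do.call(rbind, lapply(names(fits), function(nm)
      cbind(metric = nm, model = fits[[nm]]$formula, aic = fits[[nm]]$aic,
            r2 = fits[[nm]]$r2, fits[[nm]]$anova)))
    wa(anovaRows, "diversity_anova.tsv")
    letters_ <- lapply(fits, function(f)
      if ("phylum" %in% attr(terms(f$fit), "term.labels"))
        tukeyHsdLetters(f, term = "phylum")$letters else NULL)
    lt <- do.call(rbind, lapply(names(letters_), function(nm)
      if (!is.null(letters_[[nm]]))
        data.frame(metric = nm, group = names(letters_[[nm]]),
                   letters = unname(letters_[[nm]]))))
    if (!is.null(lt)) wa(lt, "tukey_letters.tsv")
    list(table = dt, fits = fits, letters = letters_)
  })

  res$accumulation <- runStage("accumulation_curves", {
    phyla <- names(which(table(meta$phylum) >= config$minSamplesClr))
    curves <- lapply(phyla, function(ph)
      accumulationCurve(eukCounts, groups = meta$phylum, group = ph,
                        nIter = config$accumulationIter,
                        seed = deriveSeed(seed, 71L),
                        minGroupSize = config$minSamplesClr))
    names(curves) <- phyla
    if (length(curves)) {
      tab <- do.call(rbind, lapply(phyla, function(ph)
        cbind(phylum = ph, curves[[ph]]$table)))
      wa(tab, "accumulation_curves.tsv")
    }
    curves
  })

  res$composition <- runStage("composition", {
    keep <- meta$phylum %in% names(which(table(meta$phylum) >= config$minSamplesClr))
    sub <- eukCounts[keep, , drop = FALSE]
    subMeta <- meta[keep, , drop = FALSE]
    clr <- countsToClr(sub, minMean = config$minMean, label = config$czmLabel)
    wa(data.frame(sample = rownames(clr), clr, check.names = FALSE), "clr.tsv")
    cd <- centroidDistances(clr, subMeta$phylum, minGroupSize = config$minSamplesClr)
    wa(cd, "centroid_distances.tsv")
    cdFit <- fitAnovaSelect(cd$distance, data.frame(phylum = cd$group),
                            factors = "phylum", minGroupSize = config$minGroupSize)
    ra <- toRelativeAbundance(sub)
    ra <- filterFamilies(ra, minMean = config$minMean)
    raPos <- suppressWarnings(czmReplaceZeros(ra, depths = rowSums(sub),
                                              label = config$czmLabel))
    agg <- aggregateByGroup(raPos, subMeta$phylum)
    wa(data.frame(phylum = rownames(agg$profiles), agg$profiles,
                  check.names = FALSE), "phylum_clr_profiles.tsv")
    if (!is.null(agg$groupTree))
      writeDendrogramNewick(agg$groupTree, file.path(outDir, "phylum_dendrogram.nwk"))
    if (!is.null(agg$familyTree))
      writeDendrogramNewick(agg$familyTree, file.path(outDir, "family_dendrogram.nwk"))
    list(clr = clr, meta = subMeta, centroid = cd, centroidFit = cdFit,
         relabund = ra, relabundPositive = raPos, aggregate = agg)
  })

  res$multivariate <- runStage("multivariate", {
    clr <- res$composition$clr
    subMeta <- res$composition$meta
    d <- aitchisonDistances(clr)
    factors <- intersect(c("phylum", "habitat"), colnames(subMeta))
    candidates <- c(as.list(factors),
                    if (length(factors) > 1L)
                      list(factors, c(factors, paste(factors, collapse = ":"))))
    fits <- list()
    for (cc in candidates) {
      key <- paste(cc, collapse = "+")
      fit <- try(permanova(d, subMeta, cc, nPerm = config$nPerm,
                           seed = deriveSeed(seed, 72L)), silent = TRUE)
      if (!inherits(fit, "try-error")) fits[[key]] <- fit
    }
    aics <- vapply(fits, `[[`, 0, "aic")
    best <- names(which.min(aics))
    tab <- do.call(rbind, lapply(names(fits), function(nm)
      cbind(model = nm, aic = fits[[nm]]$aic, fits[[nm]]$table)))
    wa(tab, "permanova.tsv")
    pd <- permdisp(d, subMeta$phylum, nPerm = config$nPerm,
                   seed = deriveSeed(seed, 73L))
    wa(data.frame(group = names(pd$dispersions),
                  dispersion = as.numeric(pd$dispersions),
                  F = pd$F, p = pd$p), "permdisp.tsv")
    list(fits = fits, bestModel = best, permdisp = pd)
  })

  res$bootstrap <- runStage("bootstrap_equivalence", {
    bs <- runBootstrap(eukCounts, meta$phylum, config = config$bootstrap,
                       minSamples = config$minSamplesClr, verbose = verbose)
    wa(bs$outcomes[, c("iteration", "phylum_a", "phylum_b", "code")],
       "bootstrap_outcomes.tsv")
    wa(bs$network$support, "equivalence_support.tsv")
    wa(bs$network$edges, "equivalence_edges.tsv")
    bs
  })

  res$bipartite <- runStage("bipartite_network", {
    bp <- buildBipartite(res$composition$relabund)
    idx <- c(linkage_density = linkageDensity(bp), h2_prime = h2Prime(bp),
             nodf = nodf(bp),
             q_modularity = qModularity(bp, seed = deriveSeed(seed, 74L))$Q)
    ranges <- list(linkage_density = NULL, h2_prime = c(0, 1),
                   nodf = c(0, 100), q_modularity = c(0, 1))
    funs <- list(linkage_density = linkageDensity, h2_prime = h2Prime,
                 nodf = nodf,
                 q_modularity = function(x) qModularity(x, nRestarts = 3,
                                                        seed = deriveSeed(seed, 75L))$Q)
    # one shared ensemble of null matrices; every index evaluated on it
    set.seed(deriveSeed(seed, 76L))
    draws <- lapply(seq_len(config$nNull), function(b) patefieldNull(bp))
    zrows <- lapply(names(idx), function(nm) {
      nulls <- vapply(draws, funs[[nm]], numeric(1L))
      # a degenerate (constant) null ensemble leaves the z-test undefined
      zt <- tryCatch(suppressWarnings(nullZtest(idx[[nm]], nulls,
                                                range = ranges[[nm]])),
                     error = function(e) list(nullMean = mean(nulls),
                                              nullSd = sd(nulls),
                                              z = NA_real_, p = NA_real_))
      data.frame(index = nm, observed = idx[[nm]], null_mean = zt$nullMean,
                 null_sd = zt$nullSd, z = zt$z, p = zt$p)
    })
    wa(do.call(rbind, zrows), "bipartite_indices.tsv")
    dp <- suppressWarnings(dPrime(bp, "rows"))
    dpFam <- suppressWarnings(dPrime(bp, "columns"))
    wa(data.frame(node = c(names(dp), names(dpFam)),
                  side = rep(c("host", "family"), c(length(dp), length(dpFam))),
                  d_prime = c(dp, dpFam)), "d_prime.tsv")
    dpFit <- dprimeAnova(dp, res$composition$meta[names(dp), "phylum"],
                         minGroupSize = config$minGroupSize)
    list(matrix = bp, indices = idx, ztests = do.call(rbind, zrows),
         dPrimeHosts = dp, dPrimeFamilies = dpFam, dPrimeFit = dpFit)
  })

  cfgLines <- c(sprintf("config_hash=%s", hash), sprintf("seed=%d", seed),
                sprintf("minMean=%g", config$minMean),
                sprintf("minSamplesClr=%d", config$minSamplesClr),
                sprintf("lambda=%g", config$lambda),
                sprintf("bootstrap_nIter=%d", config$bootstrap$nIter))
  writeLines(cfgLines, file.path(outDir, "run_config.txt"))
  say("pipeline complete: %s", outDir)
  invisible(res)
}
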