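#' Configuration of the synthetic virome generator
#'
#' Builds and validates the parameter set of the grouped compositional count
#' simulator. Per-phylum base compositions are drawn from a shared Dirichlet
#' center and perturbed in log-ratio space with magnitude
#' \code{phylumEffect} (0 = all phyla share one composition, so samples are
#' exchangeable across phyla); a habitat-linked additive log-ratio shift of
#' magnitude \code{habitatEffect} acts on a fixed random subset of families;
#' per-sample sequencing depths are log-normal and counts multinomial.
#'
#' @param nPhyla Number of host phyla.
#' @param samplesPerPhylum Samples simulated per phylum.
#' @param nFamilies Number of (eukaryote-virus) families.
#' @param habitatsPerPhylum Optional named list mapping each phylum to the
#'   habitat labels its samples cycle through; default: every phylum
#'   alternates \code{"marine"} and \code{"terrestrial"}.
#' @param concentration Positive Dirichlet concentration of the shared base
#'   composition (smaller = more uneven family abundances).
#' @param phylumEffect Non-negative between-phylum divergence (sd of the
#'   per-family log-ratio perturbation).
#' @param habitatEffect Non-negative magnitude of the habitat log-ratio shift.
#' @param depthLogMean,depthLogSd Log-normal sequencing-depth model on the
#'   natural-log scale (defaults: meanlog 10, sdlog 0.5, i.e. a median depth
#'   of about 22,000 classified eukaryote-virus reads per sample).
#' @param zeroInflation Probability in [0, 1] that a family is structurally
#'   absent from a given sample.
#' @param seed Integer master seed; all randomness of
#'   \code{\link{simulateVirome}} derives from it.
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @export
#' @examples
#' cfg <- syntheticConfig(nPhyla = 4, samplesPerPhylum = 15, seed = 1)
syntheticConfig <- function(nPhyla = 4, samplesPerPhylum = 15, nFamilies = 40,
                            habitatsPerPhylum = NULL, concentration = 5,
                            phylumEffect = 0, habitatEffect = 0,
                            depthLogMean = 10, depthLogSd = 0.5,
                            zeroInflation = 0.2, seed = 1L) {
  cfg <- list(
    nPhyla = .assertCount(nPhyla, "nPhyla", min = 1L),
    samplesPerPhylum = .assertCount(samplesPerPhylum, "samplesPerPhylum", min = 1L),
    nFamilies = .assertCount(nFamilies, "nFamilies", min = 2L),
    concentration = .assertPos(concentration, "concentration"),
    phylumEffect = .assertNonNeg(phylumEffect, "phylumEffect"),
    habitatEffect = .assertNonNeg(habitatEffect, "habitatEffect"),
    depthLogMean = .assertNonNeg(depthLogMean, "depthLogMean"),
    depthLogSd = .assertNonNeg(depthLogSd, "depthLogSd"),
    zeroInflation = .assertProb(zeroInflation, "zeroInflation"),
    seed = .assertCount(seed, "seed", min = 0L))
  phyla <- sprintf("Phylum%02d", seq_len(cfg$nPhyla))
  if (is.null(habitatsPerPhylum)) {
    habitatsPerPhylum <- setNames(rep(list(c("marine", "terrestrial")), cfg$nPhyla), phyla)
  } else {
    if (is.null(names(habitatsPerPhylum)) || length(habitatsPerPhylum) != cfg$nPhyla)
      stop("'habitatsPerPhylum' must be a named list with one entry per phylum")
    phyla <- names(habitatsPerPhylum)
    bad <- setdiff(unlist(habitatsPerPhylum), habitatLevels())
    if (length(bad))
      stop("'habitatsPerPhylum' contains invalid habitat(s): ",
           paste(bad, collapse = ", "))
  }
  cfg$phyla <- phyla
  cfg$habitatsPerPhylum <- habitatsPerPhylum
  class(cfg) <- "SyntheticConfig"
  cfg
}

.softmax <- function(logp) {
  p <- exp(logp - max(logp))
  p / sum(p)
}

#' Simulate a grouped compositional virome dataset
#'
#' Draws a sample x viral-family count matrix with known group structure:
#' Dirichlet base composition, logistic-normal phylum divergence, additive
#' habitat shift in log-ratio space, optional structural zeros, log-normal
#' depths and multinomial counts. Row (sample) totals equal the drawn depths
#' exactly. Identical configs (including seed) give bit-identical output.
#'
#' @param config A \code{\link{syntheticConfig}} object.
#' @return A list with \code{experiment} (a \linkS4class{ViromeExperiment},
#'   all families annotated \code{eukaryote}), and \code{truth} (class
#'   \code{"ViromeGroundTruth"}: per-phylum \code{baseCompositions} rows
#'   summing to 1, the injected-effect flags \code{phylumEffectActive} /
#'   \code{habitatEffectActive}, and the shifted family subset).
#' @export
#' @examples
#' sim <- simulateVirome(syntheticConfig(nPhyla = 2, samplesPerPhylum = 3, seed = 7))
#' sim$experiment
simulateVirome <- function(config) {
  if (!inherits(config, "SyntheticConfig"))
    stop("'config' must be built with syntheticConfig()")
  fams <- sprintf("vf%02d", seq_len(config$nFamilies))
  phyla <- config$phyla

  # stream 1: compositional structure
  set.seed(deriveSeed(config$seed, 1L))
  center <- rgamma(config$nFamilies, shape = config$concentration)
  center <- pmax(center, 1e-12) / sum(pmax(center, 1e-12))
  logBase <- matrix(rep(log(center), each = length(phyla)),
                    nrow = length(phyla), dimnames = list(phyla, fams))
  if (config$phylumEffect > 0)
    logBase <- logBase + config$phylumEffect *
      matrix(rnorm(length(phyla) * config$nFamilies), nrow = length(phyla))
  base <- t(apply(logBase, 1L, .softmax))
  dimnames(base) <- list(phyla, fams)

  habitats <- sort(unique(unlist(config$habitatsPerPhylum)))
  nShift <- max(1L, ceiling(0.25 * config$nFamilies))
  shiftFams <- sort(sample.int(config$nFamilies, nShift))
  habShift <- matrix(0, nrow = length(habitats), ncol = config$nFamilies,
                     dimnames = list(habitats, fams))
  if (config$habitatEffect > 0)
    habShift[, shiftFams] <- config$habitatEffect *
      matrix(rnorm(length(habitats) * nShift), nrow = length(habitats))

  # stream 2: per-sample draws
  set.seed(deriveSeed(config$seed, 2L))
  n <- length(phyla) * config$samplesPerPhylum
  counts <- matrix(0L, nrow = config$nFamilies, ncol = n,
                   dimnames = list(fams, NULL))
  sampIds <- character(n)
  sampPhylum <- character(n)
  sampHabitat <- character(n)
  k <- 0L
  for (ph in phyla) {
    habs <- config$habitatsPerPhylum[[ph]]
    for (i in seq_len(config$samplesPerPhylum)) {
      k <- k + 1L
      hab <- habs[((i - 1L) %% length(habs)) + 1L]
      logp <- log(base[ph, ]) + habShift[hab, ]
      p <- .softmax(logp)
      if (config$zeroInflation > 0) {
        absent <- runif(config$nFamilies) < config$zeroInflation
        if (all(absent)) absent[which.max(p)] <- FALSE
        p[absent] <- 0
        p <- p / sum(p)
      }
      depth <- max(1L, round(rlnorm(1L, config$depthLogMean, config$depthLogSd)))
      counts[, k] <- rmultinom(1L, size = depth, prob = p)[, 1L]
      sampIds[k] <- sprintf("%s_s%02d", ph, i)
      sampPhylum[k] <- ph
      sampHabitat[k] <- hab
    }
  }
  colnames(counts) <- sampIds
  meta <- data.frame(species = sprintf("Genus%s sp%02d",
                                       sub("Phylum", "", sampPhylum),
                                       rep(seq_len(config$samplesPerPhylum), length(phyla))),
                     phylum = sampPhylum, habitat = sampHabitat,
                     row.names = sampIds)
  ve <- ViromeExperiment(counts,
                         hostDomain = setNames(rep("eukaryote", length(fams)), fams),
                         sampleData = meta)
  truth <- structure(list(baseCompositions = base,
                          phylumEffectActive = config$phylumEffect > 0,
                          habitatEffectActive = config$habitatEffect > 0,
                          shiftedFamilies = fams[shiftFams],
                          config = config),
                     class = "ViromeGroundTruth")
  list(experiment = ve, truth = truth)
}

#' Write a simulated dataset to a directory
#'
#' Serializes the count matrix (\code{counts.tsv}, samples as rows), the
#' sample table (\code{samples.tsv}), the family annotation
#' (\code{families.tsv}) and the ground truth (\code{ground_truth.txt}, flat
#' key=value with the base-composition matrix as TSV alongside).
#'
#' @param sim Result of \code{\link{simulateVirome}}.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
writeSyntheticDataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeCountMatrix(sim$experiment, file.path(dir, "counts.tsv"),
                   annotationPath = file.path(dir, "families.tsv"))
  sd <- data.frame(sample_id = colnames(sim$experiment), sampleData(sim$experiment))
  write.table(sd, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  kv <- c(sprintf("phylum_effect_active=%s", tr$phylumEffectActive),
          sprintf("habitat_effect_active=%s", tr$habitatEffectActive),
          sprintf("shifted_families=%s", paste(tr$shiftedFamilies, collapse = ",")),
          sprintf("seed=%d", tr$config$seed))
  writeLines(kv, file.path(dir, "ground_truth.txt"))
  write.table(data.frame(phylum = rownames(tr$baseCompositions),
                         tr$baseCompositions, check.names = FALSE),
              file.path(dir, "base_compositions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate an SRA-style run-metadata table
#'
#' Generates \code{n} records with randomized library strategy, layout, read
#' length, base counts and species/phylum labels, spanning both eligible and
#' ineligible cases for \code{\link{filterEligible}}. For \code{n >= 20} the
#' first three records are constructed to fail, respectively, the library
#' strategy, read length and total-bases criterion, so every filter branch is
#' exercised.
#'
#' @param n Number of records (>= 1).
#' @param seed Integer seed; the table is a pure function of \code{n, seed}.
#' @return A data.frame of run records (one row per run accession).
#' @export
#' @examples
#' head(simulateRunRecords(10, seed = 1))
simulateRunRecords <- function(n, seed = 1L) {
  n <- .assertCount(n, "n", min = 1L)
  set.seed(deriveSeed(seed, 11L))
  phyla <- c("Arthropoda", "Mollusca", "Annelida", "Porifera", "Rotifera")
  genera <- c("Aedes", "Mytilus", "Hirudo", "Spongilla", "Brachionus",
              "Daphnia", "Octopus", "Nereis")
  suffix <- c("", "", "", " strain X1", " cf. minor", "")
  nSpecies <- max(3L, ceiling(n / 2))
  speciesPool <- sprintf("%s %s%s",
                         sample(genera, nSpecies, replace = TRUE),
                         sample(c("albopictus", "edulis", "communis", "lacustris",
                                  "plicatilis", "pulex", "vulgaris", "virens"),
                                nSpecies, replace = TRUE),
                         sample(suffix, nSpecies, replace = TRUE))
  spIdx <- sample.int(nSpecies, n, replace = TRUE)
  rec <- data.frame(
    run_accession = sprintf("SRR%07d", sample.int(9999999L, n)),
    biosample = sprintf("SAMN%08d", sample.int(99999999L, n)),
    taxid = 100000L + spIdx,
    species_name = speciesPool[spIdx],
    phylum = sample(phyla, n, replace = TRUE),
    library_strategy = sample(c("RNA-Seq", "RNA-Seq", "RNA-Seq", "WGS", "AMPLICON"),
                              n, replace = TRUE),
    library_layout = sample(c("PAIRED", "SINGLE"), n, replace = TRUE, prob = c(.9, .1)),
    avg_read_length = round(runif(n, 50, 250)),
    total_bases = round(rlnorm(n, meanlog = log(8e9), sdlog = 0.9)),
    isolation_source = sample(c("sea water", "soil", "river sediment", NA),
                              n, replace = TRUE),
    stringsAsFactors = FALSE)
  if (n >= 20L) {  # constructed coverage of the three eligibility criteria
    rec$library_strategy[1L] <- "WGS"
    rec$library_strategy[2:3] <- "RNA-Seq"
    rec$avg_read_length[2L] <- 60
    rec$avg_read_length[3L] <- 150
    rec$total_bases[2L] <- 1e10
    rec$total_bases[3L] <- 2e9
  }
  rec
}
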