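#' Harmonize a species name to binomial form
#'
#' Database species names often carry subspecies, strain or qualifier tokens.
#' Harmonization keeps the first two rank-bearing words when the name is at
#' least binomial, and appends \code{" sp."} to a bare genus (or other single
#' lowest-certain taxon). Names already of the form \code{"Genus sp."} /
#' \code{"Genus spp."} are returned unchanged; the operation is idempotent.
#'
#' @param rawName Non-empty character vector of raw names.
#' @return Character vector of harmonized binomial names.
#' @export
#' @examples
#' harmonizeSpeciesName("Drosophila melanogaster strain OregonR")
#' harmonizeSpeciesName("Rhynchomesostoma")
harmonizeSpeciesName <- function(rawName) {
  if (!is.character(rawName) || any(!nzchar(trimws(rawName))) || anyNA(rawName))
    stop("'rawName' must be non-empty character")
  vapply(trimws(rawName), function(nm) {
    words <- strsplit(nm, "\\s+")[[1L]]
    if (length(words) == 1L) return(paste(words, "sp."))
    if (words[2L] %in% c("sp.", "spp.", "sp", "spp"))
      return(paste(words[1L], sub("([^.])$", "\\1.", words[2L])))
    # qualifiers meaning species-level identity is uncertain
    if (words[2L] %in% c("cf.", "aff.", "cf", "aff")) return(paste(words[1L], "sp."))
    paste(words[1L], words[2L])
  }, character(1L), USE.NAMES = FALSE)
}

.requiredRunFields <- c("run_accession", "species_name", "phylum",
                        "library_strategy", "avg_read_length", "total_bases")

#' Filter run records on the three eligibility criteria
#'
#' Retains exactly the records with (i) library strategy \code{RNA-Seq},
#' (ii) average read length >= 75 bases (inclusive) and (iii) total sequenced
#' bases > 3 Gbases (strict), preserving input order. Records with missing
#' required fields are excluded and reported in the \code{"errors"} attribute.
#'
#' @param records data.frame of run records (see
#'   \code{\link{simulateRunRecords}} for the expected columns).
#' @param minReadLength Inclusive read-length bound (bases). Default 75.
#' @param minBases Strict total-bases bound. Default 3e9.
#' @return The eligible subset of \code{records}; attribute \code{"errors"}
#'   names excluded records with missing fields.
#' @export
filterEligible <- function(records, minReadLength = 75, minBases = 3e9) {
  stopifnot(is.data.frame(records))
  missingCols <- setdiff(.requiredRunFields, colnames(records))
  if (length(missingCols))
    stop("records table lacks required column(s): ", paste(missingCols, collapse = ", "))
  bad <- !stats::complete.cases(records[, .requiredRunFields])
  errs <- character(0)
  if (any(bad)) {
    errs <- sprintf("record %s: missing required field(s)",
                    records$run_accession[bad])
    warning(sprintf("excluded %d record(s) with missing required fields", sum(bad)))
  }
  ok <- !bad &
    records$library_strategy == "RNA-Seq" &
    records$avg_read_length >= minReadLength &
    records$total_bases > minBases
  out <- records[which(ok), , drop = FALSE]
  attr(out, "errors") <- errs
  out
}

#' Balanced one-run-per-species sampling with per-phylum caps
#'
#' From an eligibility-filtered run table, selects at most one run per
#' harmonized species and at most \code{maxPerPhylum} species per phylum
#' (per-phylum overrides honored). Species and runs are chosen uniformly at
#' random under the size-priority constraint: runs below
#' \code{sizePriorityThreshold} bases are exhausted before any larger run is
#' chosen, both when filling a phylum (species with at least one small run
#' first) and when picking the run within a species. Deterministic under a
#' fixed seed.
#'
#' @param records Eligible run records (see \code{\link{filterEligible}}).
#' @param maxPerPhylum Cap on species per phylum. Default 20.
#' @param sizePriorityThreshold Size-priority bound in bases. Default 30e9.
#' @param overrides Named integer vector of per-phylum cap overrides, e.g.
#'   \code{c(Mollusca = 39)}.
#' @param seed Integer seed.
#' @return A subset of \code{records}: one row per selected species, with an
#'   added \code{species} column holding the harmonized name.
#' @export
sampleSelection <- function(records, maxPerPhylum = 20,
                            sizePriorityThreshold = 30e9,
                            overrides = integer(0), seed = 1L) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    records$species <- character(0)
    return(records)
  }
  set.seed(deriveSeed(seed, 21L))
  records$species <- harmonizeSpeciesName(records$species_name)
  records$.small <- records$total_bases < sizePriorityThreshold
  picked <- integer(0)
  for (ph in sort(unique(records$phylum))) {
    cap <- if (ph %in% names(overrides)) overrides[[ph]] else maxPerPhylum
    sub <- records[records$phylum == ph, , drop = FALSE]
    hasSmall <- tapply(sub$.small, sub$species, any)
    species <- names(hasSmall)
    # species with at least one sub-threshold run fill the phylum first
    chosen <- character(0)
    for (tier in c(TRUE, FALSE)) {
      pool <- setdiff(species[hasSmall == tier], chosen)
      room <- cap - length(chosen)
      if (room <= 0L || !length(pool)) next
      chosen <- c(chosen, if (length(pool) <= room) pool else
        sample(pool, room))
    }
    for (sp in chosen) {
      runs <- which(records$phylum == ph & records$species == sp)
      small <- runs[records$.small[runs]]
      pool <- if (length(small)) small else runs
      picked <- c(picked, if (length(pool) == 1L) pool else sample(pool, 1L))
    }
  }
  out <- records[sort(picked), setdiff(colnames(records), ".small"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign habitat labels from a user-supplied ecology table
#'
#' Looks species up in an ecology table mapping species names to one of the
#' five habitat categories (\code{\link{habitatLevels}}). Species absent from
#' the table are labeled \code{NA} with a warning; labels outside the closed
#' category set are a validation error.
#'
#' @param species Character vector of (harmonized) species names.
#' @param ecologyTable Named character vector or 2-column data.frame
#'   (\code{species}, \code{habitat}).
#' @return Character vector of habitat labels (\code{NA} = missing), with a
#'   \code{"missing"} attribute listing unmatched species.
#' @export
assignHabitat <- function(species, ecologyTable) {
  if (is.data.frame(ecologyTable))
    ecologyTable <- setNames(as.character(ecologyTable[[2L]]),
                             as.character(ecologyTable[[1L]]))
  bad <- setdiff(unique(unname(ecologyTable)), habitatLevels())
  if (length(bad))
    stop("habitat label(s) outside the five-category set: ",
         paste(bad, collapse = ", "))
  lab <- unname(ecologyTable[species])
  miss <- unique(species[is.na(lab)])
  if (length(miss))
    warning("no habitat entry for species: ", paste(miss, collapse = ", "))
  attr(lab, "missing") <- miss
  lab
}
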