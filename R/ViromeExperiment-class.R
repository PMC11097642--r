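#' ViromeExperiment: sample x viral-family read counts with annotation
#'
#' An S4 container for virome profiles derived from read-based taxonomic
#' classification. It extends \linkS4class{SummarizedExperiment} with viral
#' families as rows and samples as columns. The single assay \code{"counts"}
#' holds non-negative integer read counts; \code{rowData} carries the
#' host-domain annotation of each family (\code{eukaryote},
#' \code{prokaryote_archaea} or \code{uncertain}); \code{colData} carries the
#' per-sample \code{species}, \code{phylum} and \code{habitat} labels.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no extra slots are added.
#'
#' @seealso \code{\link{ViromeExperiment}} (constructor),
#'   \code{\link{viromeCounts}}, \code{\link{partitionByHostDomain}},
#'   \code{\link{readCountMatrix}}
#' @export
setClass("ViromeExperiment", contains = "SummarizedExperiment")

.validViromeExperiment <- function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(cnt)))
      msg <- c(msg, "counts contain NA")
    else {
      if (any(cnt < 0)) msg <- c(msg, "counts contain negative entries")
      if (any(cnt != round(cnt))) msg <- c(msg, "counts contain non-integer entries")
    }
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "family names (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (!"host_domain" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData column 'host_domain' is required")
  else {
    hd <- SummarizedExperiment::rowData(object)$host_domain
    bad <- setdiff(unique(as.character(hd)), hostDomainLevels())
    if (length(bad))
      msg <- c(msg, sprintf("invalid host_domain value(s): %s",
                            paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}

setValidity("ViromeExperiment", .validViromeExperiment)

#' Construct a ViromeExperiment
#'
#' @param counts Integer matrix of read counts, viral families as rows and
#'   samples as columns, with complete unique dimnames. (The on-disk TSV
#'   interchange format keeps samples as rows; \code{\link{readCountMatrix}}
#'   transposes on input.)
#' @param hostDomain Character vector (or factor) along the rows of
#'   \code{counts} giving each family's host domain; one of
#'   \code{hostDomainLevels()}. A named vector is matched by family name.
#' @param sampleData \code{data.frame} of per-sample metadata aligned to the
#'   columns of \code{counts} (matched by rownames when present). Typical
#'   columns: \code{species}, \code{phylum}, \code{habitat}.
#'
#' @return A \linkS4class{ViromeExperiment}.
#' @export
#' @examples
#' cnt <- matrix(c(5L, 0L, 2L, 3L), nrow = 2,
#'               dimnames = list(c("Retroviridae", "UNCERTAIN_FAMILY"),
#'                               c("s1", "s2")))
#' ve <- ViromeExperiment(cnt, hostDomain = c("eukaryote", "uncertain"),
#'                        sampleData = data.frame(phylum = c("Mollusca", "Annelida"),
#'                                                row.names = c("s1", "s2")))
#' ve
ViromeExperiment <- function(counts, hostDomain,
                             sampleData = data.frame(row.names = colnames(counts))) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (!is.null(names(hostDomain)))
    hostDomain <- hostDomain[rownames(counts)]
  if (length(hostDomain) != nrow(counts))
    stop("'hostDomain' must have one entry per family (row of 'counts')")
  if (!is.null(rownames(sampleData)) &&
      !identical(rownames(sampleData), as.character(seq_len(nrow(sampleData))))) {
    missing <- setdiff(colnames(counts), rownames(sampleData))
    if (length(missing))
      stop("sampleData lacks rows for sample(s): ", paste(missing, collapse = ", "))
    sampleData <- sampleData[colnames(counts), , drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(host_domain = as.character(hostDomain),
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(sampleData))
  new("ViromeExperiment", se)
}

#' @describeIn ViromeExperiment compact display
#' @param object A \code{ViromeExperiment}.
#' @export
setMethod("show", "ViromeExperiment", function(object) {
  hd <- table(factor(SummarizedExperiment::rowData(object)$host_domain,
                     levels = hostDomainLevels()))
  cat(sprintf("ViromeExperiment: %d viral families x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  host domains: %s\n",
              paste(sprintf("%s (%d)", names(hd), hd), collapse = ", ")))
  cd <- colnames(SummarizedExperiment::colData(object))
  if (length(cd)) cat("  sample annotation:", paste(cd, collapse = ", "), "\n")
  invisible(NULL)
})

#' Accessors for ViromeExperiment
#'
#' \code{viromeCounts} returns the integer count matrix (families x samples);
#' \code{hostDomain} the per-family host-domain annotation;
#' \code{sampleData} the sample metadata as a plain \code{data.frame}.
#'
#' @param x A \linkS4class{ViromeExperiment}.
#' @return See individual descriptions.
#' @name virome-accessors
#' @export
viromeCounts <- function(x) {
  stopifnot(is(x, "ViromeExperiment"))
  SummarizedExperiment::assay(x, "counts")
}

#' @rdname virome-accessors
#' @export
hostDomain <- function(x) {
  stopifnot(is(x, "ViromeExperiment"))
  setNames(as.character(SummarizedExperiment::rowData(x)$host_domain), rownames(x))
}

#' @rdname virome-accessors
#' @export
sampleData <- function(x) {
  stopifnot(is(x, "ViromeExperiment"))
  as.data.frame(SummarizedExperiment::colData(x))
}

#' Partition a virome by the host domain of its viral families
#'
#' Splits the classified virome into eukaryote-virus, phage (prokaryote +
#' archaea) and uncertain-family fractions, and extracts the eukaryotic
#' submatrix on which all downstream diversity and compositional analyses
#' operate. The uncertain bucket and non-eukaryote families are dropped from
#' the submatrix.
#'
#' @param x A \linkS4class{ViromeExperiment}.
#' @param dropEmpty Logical; drop zero-total-read samples from the eukaryotic
#'   submatrix (they are always flagged). Default \code{TRUE}.
#' @return A list with \code{eukaryotic} (a \code{ViromeExperiment} restricted
#'   to eukaryote-virus families), \code{fractions} (data.frame with one row
#'   per sample: \code{eukaryote}, \code{phage}, \code{uncertain}, summing to
#'   1; \code{NA} for zero-read samples) and \code{flagged} (character vector
#'   of zero-read sample ids).
#' @export
partitionByHostDomain <- function(x, dropEmpty = TRUE) {
  stopifnot(is(x, "ViromeExperiment"))
  cnt <- viromeCounts(x)
  hd <- hostDomain(x)
  tot <- colSums(cnt)
  sums <- vapply(c(eukaryote = "eukaryote", phage = "prokaryote_archaea",
                   uncertain = "uncertain"),
                 function(d) colSums(cnt[hd == d, , drop = FALSE]),
                 numeric(ncol(cnt)))
  if (ncol(cnt) == 1L) sums <- matrix(sums, nrow = 1L,
                                      dimnames = list(colnames(cnt), names(sums)))
  frac <- sums / tot
  frac[tot == 0, ] <- NA_real_
  flagged <- colnames(cnt)[tot == 0]
  if (length(flagged))
    warning("sample(s) with zero classified viral reads: ",
            paste(flagged, collapse = ", "))
  euk <- x[hd == "eukaryote", , drop = FALSE]
  if (dropEmpty && length(flagged))
    euk <- euk[, setdiff(colnames(euk), flagged), drop = FALSE]
  list(eukaryotic = euk,
       fractions = as.data.frame(frac),
       flagged = flagged)
}
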