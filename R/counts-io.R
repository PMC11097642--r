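#' Aggregate per-read classifier calls into a family count vector
#'
#' Consumes classifier output in the common three-column dialect
#' (status \code{C}/\code{U}, read id, taxon id) and tallies classified reads
#' into viral-family counts via a taxon-id to family map. Reads whose taxon id
#' maps to no family-level rank -- and, with a warning, reads with taxon ids
#' absent from the map -- are tallied into the reserved
#' \code{"UNCERTAIN_FAMILY"} bucket. Unclassified (\code{U}) reads contribute
#' nothing.
#'
#' @param lines A data.frame with columns \code{status}, \code{read_id},
#'   \code{taxon_id}, or a path to a headerless 3-column TSV in that order.
#' @param taxmap Named character vector or 2-column data.frame
#'   (\code{taxon_id}, \code{family}) mapping taxon ids to family names; use
#'   \code{"UNCERTAIN_FAMILY"} for ids without a family-level rank.
#' @param maxMalformed Maximum tolerated fraction of malformed lines (skipped
#'   with a warning) before a hard error. Default 0.01.
#' @return Named integer vector of read counts over all families in
#'   \code{taxmap} plus \code{UNCERTAIN_FAMILY}.
#' @export
#' @examples
#' lines <- data.frame(status = c("C", "C", "U"),
#'                     read_id = c("r1", "r2", "r3"),
#'                     taxon_id = c(11646L, 11646L, NA))
#' aggregateHits(lines, c("11646" = "Retroviridae"))
aggregateHits <- function(lines, taxmap, maxMalformed = 0.01) {
  if (is.character(lines) && length(lines) == 1L) {
    lines <- read.delim(lines, header = FALSE, col.names = c("status", "read_id", "taxon_id"),
                        colClasses = c("character", "character", "character"))
  }
  if (is.data.frame(taxmap)) {
    taxmap <- setNames(as.character(taxmap[[2L]]), as.character(taxmap[[1L]]))
  }
  families <- unique(c(unname(taxmap), UNCERTAIN_FAMILY))
  counts <- setNames(integer(length(families)), families)
  if (nrow(lines) == 0L) return(counts)

  status <- as.character(lines$status)
  taxid <- suppressWarnings(as.integer(as.character(lines$taxon_id)))
  malformed <- !(status %in% c("C", "U")) | (status == "C" & is.na(taxid))
  if (any(malformed)) {
    frac <- mean(malformed)
    if (frac > maxMalformed)
      stop(sprintf("%.1f%% of classifier lines are malformed (limit %.1f%%)",
                   100 * frac, 100 * maxMalformed))
    warning(sprintf("skipped %d malformed classifier line(s)", sum(malformed)))
  }
  keep <- status == "C" & !malformed
  if (!any(keep)) return(counts)
  fam <- taxmap[as.character(taxid[keep])]
  if (anyNA(fam)) {
    warning(sprintf("%d classified read(s) with taxon ids absent from the map routed to %s",
                    sum(is.na(fam)), UNCERTAIN_FAMILY))
    fam[is.na(fam)] <- UNCERTAIN_FAMILY
  }
  tab <- table(factor(fam, levels = families))
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Read / write a virome count matrix as TSV
#'
#' The interchange format is a TSV with samples as rows and viral families as
#' columns; the first column (\code{sample_id}) holds sample ids. An optional
#' two-column annotation TSV (\code{family}, \code{host_domain}) supplies the
#' host-domain labels; families not listed default to \code{"uncertain"}.
#' The round trip \code{writeCountMatrix} then \code{readCountMatrix} is
#' lossless.
#'
#' @param path Path of the count TSV.
#' @param annotationPath Optional path of the family annotation TSV.
#' @param sampleDataPath Optional path of a sample metadata TSV (first column
#'   \code{sample_id}).
#' @return \code{readCountMatrix}: a \linkS4class{ViromeExperiment}.
#' @export
readCountMatrix <- function(path, annotationPath = NULL, sampleDataPath = NULL) {
  raw <- read.delim(path, header = TRUE, check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2L) stop("count matrix must have a sample-id column and >= 1 family")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  fams <- colnames(raw)[-1L]
  if (anyDuplicated(fams))
    stop("duplicate family id(s): ", paste(unique(fams[duplicated(fams)]), collapse = ", "))
  mat <- matrix(NA_real_, nrow = length(ids), ncol = length(fams),
                dimnames = list(ids, fams))
  for (j in seq_along(fams)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf("invalid count '%s' at row %d (sample %s), column %s",
                   raw[[j + 1L]][bad[1L]], bad[1L], ids[bad[1L]], fams[j]))
    mat[, j] <- v
  }
  counts <- t(mat)  # families x samples internally
  hd <- setNames(rep("uncertain", length(fams)), fams)
  if (!is.null(annotationPath)) {
    ann <- read.delim(annotationPath, header = TRUE, colClasses = "character")
    hd[ann[[1L]][ann[[1L]] %in% fams]] <- ann[[2L]][ann[[1L]] %in% fams]
  }
  sd <- data.frame(row.names = colnames(counts))
  if (!is.null(sampleDataPath)) {
    sd <- read.delim(sampleDataPath, header = TRUE, colClasses = "character")
    rownames(sd) <- sd[[1L]]
    sd <- sd[, -1L, drop = FALSE]
  }
  ViromeExperiment(counts, hostDomain = hd, sampleData = sd)
}

#' @rdname readCountMatrix
#' @param x A \linkS4class{ViromeExperiment} to serialize.
#' @param annotationPath For the writer: if non-NULL, also write the family
#'   host-domain annotation there.
#' @export
writeCountMatrix <- function(x, path, annotationPath = NULL) {
  stopifnot(is(x, "ViromeExperiment"))
  out <- data.frame(sample_id = colnames(x), t(viromeCounts(x)),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotationPath)) {
    ann <- data.frame(family = rownames(x), host_domain = hostDomain(x))
    write.table(ann, annotationPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
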