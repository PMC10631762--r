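#' Read a sequence family from FASTA
#'
#' Parses a FASTA file (plain or gzip) or in-memory FASTA text into a
#' data frame of sequence records. Headers are expected to carry an
#' identifier as the first token; an IMGT-style functionality tag
#' ("F" = functional/productive, "ORF", "P" = pseudogene) is picked up from
#' any later |- or whitespace-separated token. Records without a tag default
#' to productive.
#'
#' @param file Path to a FASTA file, or a character vector of FASTA text
#'   lines (anything containing a ">" is treated as text).
#' @param family Family label attached to every record, e.g. "TRAV",
#'   "TRBV", "HLA-I".
#' @param functionality_regex Named list of regular expressions used to
#'   recognise functionality tokens in the header; defaults to IMGT-style
#'   "F", "ORF", "P" tokens.
#' @return A data frame of class \code{seq_records} with columns
#'   \code{id}, \code{family}, \code{functionality}, \code{sequence},
#'   in order of first appearance.
#' @export
read_family_fasta <- function(file, family = "other",
                              functionality_regex = list(
                                productive = "^F$|^functional$",
                                ORF        = "^ORF$",
                                pseudogene = "^P$|^pseudogene$")) {
  is_text <- length(file) > 1L || any(grepl(">", file, fixed = TRUE))
  if (is_text) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(file, path)
  } else {
    if (!file.exists(file)) stop("FASTA file not found: ", file)
    path <- file
  }
  .validate_fasta_lines(path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA: no sequence records found")
  headers <- names(aa)
  ids <- vapply(strsplit(headers, "[|[:space:]]+"), `[`, "", 1L)
  func <- vapply(strsplit(headers, "[|[:space:]]+"), function(tok) {
    tok <- tok[-1L]
    for (lab in names(functionality_regex)) {
      if (any(grepl(functionality_regex[[lab]], tok))) return(lab)
    }
    "productive"
  }, "")
  seqs <- toupper(as.character(aa))
  bad <- grepl("[^A-Z*.]", seqs)
  if (any(bad)) {
    stop("invalid residue characters in record '", ids[which(bad)[1L]], "'")
  }
  seqs <- gsub("[*.]", "", seqs)  # strip IMGT gap/stop marks
  out <- data.frame(id = ids, family = family, functionality = func,
                    sequence = seqs, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("seq_records", "data.frame")
  out
}

# minimal structural check so that malformed input fails with a line number
.validate_fasta_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA: ", path)
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA at line ", first,
         ": expected a '>' header, got: ", substr(lines[first], 1, 40))
  }
  hdr <- startsWith(lines, ">")
  runs <- rle(hdr[nonblank])
  if (any(runs$values & runs$lengths > 1L)) {
    dup <- nonblank[cumsum(runs$lengths)[which(runs$values & runs$lengths > 1L)[1L]]]
    stop("malformed FASTA at line ", dup, ": header without sequence")
  }
  invisible(TRUE)
}

#' Filter records to unique productive sequences
#'
#' Keeps only records whose functionality is \code{"productive"} (dropping
#' open reading frames and pseudogenes), then deduplicates on the
#' concatenation of the extracted region segments when region columns are
#' present, else on the full sequence; the first record of each duplicate
#' set is kept.
#'
#' @param records A \code{seq_records} data frame.
#' @param regions Optional character vector naming the region columns to
#'   judge uniqueness on; defaults to all region columns present (any column
#'   other than id/family/functionality/sequence), falling back to
#'   \code{sequence}.
#' @return Filtered \code{seq_records}.
#' @export
filter_productive_unique <- function(records, regions = NULL) {
  stopifnot(is.data.frame(records))
  keep <- records$functionality == "productive"
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) {
    rownames(records) <- NULL
    return(records)
  }
  meta <- c("id", "family", "functionality", "sequence")
  if (is.null(regions)) {
    regions <- setdiff(names(records), meta)
    if (length(regions) == 0L) regions <- "sequence"
  }
  key <- do.call(paste, c(records[regions], sep = "|"))
  records <- records[!duplicated(key), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Region definition for a sequence family
#'
#' A region definition names, for one family, the 1-based residue positions
#' (in the family's reference numbering) making up each structurally
#' conserved region (CDR loops, TCR-exposed helix residues, peptide
#' contacts).
#'
#' @param family Family label.
#' @param regions Named list of strictly increasing 1-based integer position
#'   vectors, one per region label.
#' @return An object of class \code{region_definition}.
#' @export
region_definition <- function(family, regions) {
  stopifnot(is.list(regions), length(regions) > 0L,
            !is.null(names(regions)), all(nzchar(names(regions))))
  if (anyDuplicated(names(regions)))
    stop("region labels must be unique within a definition")
  regions <- lapply(regions, function(p) {
    p <- as.integer(p)
    if (length(p) == 0L) stop("empty position list in region definition")
    if (any(p < 1L) || is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing and >= 1")
    p
  })
  structure(list(family = family, regions = regions),
            class = "region_definition")
}

#' Read region definitions from a YAML or JSON config
#'
#' The config maps family -> region -> list of 1-based positions.
#'
#' @param path Path to a .yaml/.yml or .json file.
#' @return Named list of \code{region_definition} objects, one per family.
#' @export
read_region_definitions <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- lapply(names(cfg), function(fam) region_definition(fam, cfg[[fam]]))
  names(out) <- names(cfg)
  out
}

#' Extract region segments from one sequence
#'
#' @param sequence Amino-acid string.
#' @param definition A \code{region_definition}.
#' @param id Record identifier used in error messages.
#' @return Named character vector of segments, one per region, each the
#'   concatenation of the residues at the listed positions in list order.
#' @export
extract_regions <- function(sequence, definition, id = "<sequence>") {
  stopifnot(inherits(definition, "region_definition"))
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  vapply(names(definition$regions), function(lab) {
    pos <- definition$regions[[lab]]
    if (max(pos) > n) {
      stop("record '", id, "': region ", lab, " position ", max(pos),
           " beyond sequence end (length ", n, ")")
    }
    paste(chars[pos], collapse = "")
  }, "")
}

#' Extract regions for every record of a family
#'
#' Adds one column per region label to the records, holding the extracted
#' segment.
#'
#' @param records A \code{seq_records} data frame with a \code{sequence}
#'   column.
#' @param definition A \code{region_definition} for the records' family.
#' @return The records with region columns appended.
#' @export
extract_family_regions <- function(records, definition) {
  stopifnot(is.data.frame(records), inherits(definition, "region_definition"))
  k <- length(definition$regions)
  segs <- vapply(seq_len(nrow(records)), function(i) {
    extract_regions(records$sequence[i], definition, id = records$id[i])
  }, character(k))
  segs <- if (k == 1L) matrix(segs, ncol = 1L) else t(segs)
  segs <- as.data.frame(segs, stringsAsFactors = FALSE)
  names(segs) <- names(definition$regions)
  out <- cbind(records, segs)
  class(out) <- class(records)
  out
}

#' Build sequence records directly from segments
#'
#' Convenience constructor used by the synthetic generator and tests:
#' builds a \code{seq_records} data frame from explicit per-region segment
#' vectors.
#'
#' @param id Character vector of record ids.
#' @param segments Named list of character vectors (one per region), each of
#'   the same length as \code{id}.
#' @param family Family label.
#' @param functionality Functionality labels (recycled).
#' @return A \code{seq_records} data frame with region columns.
#' @export
seq_records <- function(id, segments, family = "other",
                        functionality = "productive") {
  stopifnot(is.list(segments), !is.null(names(segments)))
  out <- data.frame(id = id, family = family,
                    functionality = rep_len(functionality, length(id)),
                    sequence = do.call(paste0, segments),
                    stringsAsFactors = FALSE)
  for (lab in names(segments)) out[[lab]] <- segments[[lab]]
  class(out) <- c("seq_records", "data.frame")
  out
}
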