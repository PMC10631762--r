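#' Canonical amino-acid alphabet used for integer encoding
#'
#' Residues are coded 1-20 in alphabetical one-letter order (A = 1 ... Y = 20),
#' code 21 is reserved for 'X'/nonstandard residues and code 0 for structural
#' gap/pad cells.
#'
#' @return Character vector of the 20 canonical one-letter codes in coding
#'   order.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# code for unknown/nonstandard residue
.AA_X_CODE <- 21L

#' Convert residues to integer codes
#'
#' @param x Character vector of single residues, or a single string that is
#'   split into residues.
#' @return Integer vector of codes in \code{[1, 21]}.
#' @keywords internal
aa_to_code <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  idx <- match(toupper(x), aa_alphabet())
  idx[is.na(idx)] <- .AA_X_CODE
  as.integer(idx)
}

#' Convert integer codes back to residues
#'
#' @param codes Integer vector with values in \code{[0, 21]}; 0 maps to
#'   \code{NA} (pad), 21 to \code{"X"}.
#' @return Character vector of residues.
#' @keywords internal
code_to_aa <- function(codes) {
  out <- rep(NA_character_, length(codes))
  canonical <- codes >= 1L & codes <= 20L
  out[canonical] <- aa_alphabet()[codes[canonical]]
  out[codes == .AA_X_CODE] <- "X"
  out
}
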