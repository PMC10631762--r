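#' Built-in amino-acid property tables
#'
#' \code{charge_table()}: side-chain charge at physiological pH — K, R = +1;
#' D, E = -1; H = +0.1 (partial protonation); all others 0.
#' \code{hydropathy_table()}: the Kyte-Doolittle hydropathy index.
#' Both are returned raw; use \code{\link{normalize_table}} for the
#' z-scored form used in position profiles.
#'
#' @return Named numeric vector over the 20 canonical amino acids, in
#'   coding order, with a \code{"property"} attribute.
#' @export
charge_table <- function() {
  v <- stats::setNames(numeric(20), aa_alphabet())
  v[c("K", "R")] <- 1
  v[c("D", "E")] <- -1
  v["H"] <- 0.1
  attr(v, "property") <- "charge"
  v
}

#' @rdname charge_table
#' @export
hydropathy_table <- function() {
  v <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
         H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
         P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
         W = -0.9, Y = -1.3)
  v <- v[aa_alphabet()]
  attr(v, "property") <- "hydropathy"
  v
}

#' Read a property table from CSV
#'
#' Expects two columns, \code{aa} (one-letter code) and \code{value}, one
#' row per canonical amino acid.
#'
#' @param path CSV path.
#' @param name Property name to attach.
#' @return Named numeric vector in coding order.
#' @export
read_property_table <- function(path, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("aa", "value") %in% names(df)))
  v <- stats::setNames(df$value, toupper(df$aa))[aa_alphabet()]
  if (anyNA(v)) stop("property table must cover all 20 canonical amino acids")
  attr(v, "property") <- name
  v
}

#' z-normalize a property table
#'
#' Centers and scales the 20 values to mean 0 and (sample) standard
#' deviation 1, as used for the position-sensitive charge and hydropathy
#' profiles. Order is preserved; idempotent on already-normalized tables.
#'
#' @param table Named numeric vector of 20 values.
#' @return Normalized table with \code{normalization = "zscore"} attribute.
#' @export
normalize_table <- function(table) {
  stopifnot(length(table) == 20L)
  s <- stats::sd(table)
  if (s == 0) stop("cannot normalize a constant property table")
  out <- (table - mean(table)) / s
  attr(out, "property") <- attr(table, "property")
  attr(out, "normalization") <- "zscore"
  out
}

#' Position-sensitive property profile of an encoded repertoire
#'
#' For each alignment column, the mean and standard deviation (over
#' sequences) of the property values of the residues observed there. Pad
#' cells (code 0) and unknown residues (code 21) never contribute; columns
#' with no canonical residues are reported as \code{NA}.
#'
#' @param x An \code{aims_matrix} or integer code matrix.
#' @param table Property table covering the 20 canonical amino acids
#'   (raw or normalized).
#' @return Data frame of class \code{property_profile} with \code{column},
#'   \code{region}, \code{mean}, \code{std}, \code{n}.
#' @export
position_property_profile <- function(x, table) {
  codes <- if (inherits(x, "aims_matrix")) x$codes else x
  stopifnot(length(table) == 20L)
  vals <- unname(table)[aa_to_code(names(table))]  # align to coding order
  per_col <- function(col) {
    col <- col[col >= 1L & col <= 20L]
    if (length(col) == 0L) return(c(NA_real_, NA_real_, 0))
    v <- vals[col]
    c(mean(v), if (length(v) > 1L) stats::sd(v) else 0, length(v))
  }
  m <- t(apply(codes, 2L, per_col))
  region <- if (inherits(x, "aims_matrix")) x$column_regions
            else rep(NA_character_, ncol(codes))
  out <- data.frame(column = seq_len(ncol(codes)), region = region,
                    mean = m[, 1L], std = m[, 2L], n = as.integer(m[, 3L]))
  attr(out, "property") <- attr(table, "property")
  class(out) <- c("property_profile", "data.frame")
  out
}
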