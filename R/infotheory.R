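#' Shannon entropy of one alignment column
#'
#' Entropy H = -sum p(x) log2 p(x) over the amino acids observed in the
#' column. Pad cells (code 0) mark structural gaps, not residues, and are
#' excluded from the distribution; code 21 ('X') is kept as a symbol.
#' Columns with at most one effective observation have zero entropy. The
#' theoretical maximum for 20 equiprobable amino acids is log2(20) = 4.32
#' bits.
#'
#' @param codes Integer vector of column codes in \code{[0, 21]}, or —
#'   with \code{counts = TRUE} — a pre-tabulated count vector over codes.
#' @param counts Interpret \code{codes} as tabulated counts rather than
#'   raw codes.
#' @return Entropy in bits.
#' @export
column_entropy <- function(codes, counts = FALSE) {
  counts <- if (counts) codes[codes > 0] else {
    codes <- codes[codes != 0L]
    if (length(codes) == 0L) return(0)
    tabulate(codes, nbins = 21L)
  }
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n <= 1) return(0)
  p <- counts / n
  -sum(p * log2(p))
}

#' Position-sensitive entropy of an encoded repertoire
#'
#' @param x An \code{aims_matrix} or integer code matrix.
#' @return Numeric vector of per-column entropies in bits.
#' @export
entropy_profile <- function(x) {
  codes <- if (inherits(x, "aims_matrix")) x$codes else x
  apply(codes, 2L, column_entropy)
}

#' Subsampling-averaged entropy profile
#'
#' Repeatedly draws \code{n_subsample} sequences without replacement and
#' computes the per-column entropy of each draw; reports the mean and
#' standard deviation over repetitions, putting differently sized sequence
#' sets on a common footing.
#'
#' @param x An \code{aims_matrix} or integer code matrix.
#' @param n_subsample Number of rows per draw; must not exceed the number
#'   of rows.
#' @param n_repetitions Number of subsampling repetitions (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @return An object of class \code{entropy_profile}: data frame with
#'   \code{column}, \code{region}, \code{mean_bits}, \code{std_bits} plus
#'   metadata attributes.
#' @export
subsampled_entropy_profile <- function(x, n_subsample,
                                       n_repetitions = 1000L, seed) {
  codes <- if (inherits(x, "aims_matrix")) x$codes else x
  n <- nrow(codes)
  if (n_subsample > n) {
    stop("n_subsample (", n_subsample, ") exceeds number of sequences (",
         n, ")")
  }
  stopifnot(n_repetitions >= 1L)
  rng <- .seeded_rng(seed)
  H <- matrix(0, nrow = n_repetitions, ncol = ncol(codes))
  for (r in seq_len(n_repetitions)) {
    idx <- rng$sample(n, n_subsample)
    H[r, ] <- apply(codes[idx, , drop = FALSE], 2L, column_entropy)
  }
  region <- if (inherits(x, "aims_matrix")) x$column_regions
            else rep(NA_character_, ncol(codes))
  out <- data.frame(column = seq_len(ncol(codes)), region = region,
                    mean_bits = colMeans(H),
                    std_bits = apply(H, 2L, stats::sd))
  if (n_repetitions == 1L) out$std_bits <- 0
  attr(out, "n_subsample") <- n_subsample
  attr(out, "n_repetitions") <- n_repetitions
  attr(out, "seed") <- seed
  class(out) <- c("entropy_profile", "data.frame")
  out
}

# joint-count mutual information in bits for paired code vectors;
# pairs with a pad on either side are excluded
.pair_mi <- function(xc, yc) {
  keep <- xc != 0L & yc != 0L
  xc <- xc[keep]; yc <- yc[keep]
  n <- length(xc)
  if (n <= 1L) return(0)
  joint <- table(xc, yc)
  pj <- joint / n
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / outer(px, py)[nz]))
}

#' Mutual information between TCR and MHC alignment columns
#'
#' Treats each TCR sequence as the input and an MHC sequence as the output
#' of a communication channel: per repetition every TCR row is paired with
#' one MHC row, and for every (TCR column, MHC column) pair the mutual
#' information I(X;Y) = H(X) - H(X|Y) is computed on the paired sample from
#' joint amino-acid counts. The mean and standard deviation over
#' repetitions are reported.
#'
#' @param tcr,mhc \code{aims_matrix} objects (or integer code matrices).
#' @param pairing \code{"random"} (default): each TCR row draws one MHC row
#'   uniformly with replacement per repetition. \code{"identity"}: rows are
#'   paired by index (requires equal row counts) — deterministic, so a
#'   single repetition is performed. \code{"grouped"}: like random but each
#'   TCR row draws only from MHC rows with the same group label (pairing
#'   within an organismal source).
#' @param tcr_groups,mhc_groups Group labels per row, required for
#'   \code{pairing = "grouped"}.
#' @param n_repetitions Number of pairing repetitions (default 1000).
#' @param seed Integer seed (required unless pairing is identity).
#' @param correction \code{"none"} (default, raw averages) or
#'   \code{"miller_madow"} to subtract the first-order finite-sample bias
#'   (K-1)(L-1)/(2 n ln 2) per column pair.
#' @return An object of class \code{mi_matrix}: list with \code{mean} and
#'   \code{std} matrices (rows = TCR columns, cols = MHC columns) and
#'   pairing metadata.
#' @export
mutual_information <- function(tcr, mhc,
                               pairing = c("random", "identity", "grouped"),
                               tcr_groups = NULL, mhc_groups = NULL,
                               n_repetitions = 1000L, seed = NULL,
                               correction = c("none", "miller_madow")) {
  pairing <- match.arg(pairing)
  correction <- match.arg(correction)
  xm <- if (inherits(tcr, "aims_matrix")) tcr$codes else tcr
  ym <- if (inherits(mhc, "aims_matrix")) mhc$codes else mhc
  if (nrow(xm) == 0L || nrow(ym) == 0L) stop("empty input matrix")
  if (pairing == "identity") {
    if (nrow(xm) != nrow(ym))
      stop("identity pairing requires equal row counts")
    n_repetitions <- 1L
  }
  if (pairing == "grouped") {
    stopifnot(length(tcr_groups) == nrow(xm),
              length(mhc_groups) == nrow(ym))
    missing <- setdiff(unique(tcr_groups), unique(mhc_groups))
    if (length(missing) > 0L) {
      stop("group(s) present in TCR but absent in MHC: ",
           paste(missing, collapse = ", "))
    }
    group_idx <- lapply(unique(tcr_groups), function(g) which(mhc_groups == g))
    names(group_idx) <- unique(tcr_groups)
  }
  if (pairing != "identity" && is.null(seed))
    stop("seed is required for stochastic pairing")
  rng <- if (!is.null(seed)) .seeded_rng(seed)
  nx <- ncol(xm); ny <- ncol(ym)
  acc <- matrix(0, nx, ny); acc2 <- matrix(0, nx, ny)
  for (r in seq_len(n_repetitions)) {
    partner <- switch(pairing,
      identity = seq_len(nrow(xm)),
      random = rng$sample(nrow(ym), nrow(xm), replace = TRUE),
      grouped = {
        p <- integer(nrow(xm))
        for (g in names(group_idx)) {
          rows <- which(tcr_groups == g)
          pool <- group_idx[[g]]
          p[rows] <- pool[rng$sample(length(pool), length(rows),
                                     replace = TRUE)]
        }
        p
      })
    yp <- ym[partner, , drop = FALSE]
    I <- matrix(0, nx, ny)
    for (i in seq_len(nx)) {
      for (j in seq_len(ny)) {
        I[i, j] <- .pair_mi(xm[, i], yp[, j])
      }
    }
    if (correction == "miller_madow") {
      for (i in seq_len(nx)) {
        for (j in seq_len(ny)) {
          keep <- xm[, i] != 0L & yp[, j] != 0L
          n <- sum(keep)
          if (n > 1L) {
            K <- length(unique(xm[keep, i]))
            L <- length(unique(yp[keep, j]))
            I[i, j] <- max(0, I[i, j] - (K - 1) * (L - 1) / (2 * n * log(2)))
          }
        }
      }
    }
    acc <- acc + I
    acc2 <- acc2 + I * I
  }
  mean_mi <- acc / n_repetitions
  var_mi <- pmax(0, acc2 / n_repetitions - mean_mi^2)
  dimnames(mean_mi) <- list(colnames(xm), colnames(ym))
  structure(list(mean = mean_mi,
                 std = sqrt(var_mi),
                 pairing = pairing,
                 n_repetitions = n_repetitions,
                 seed = seed,
                 correction = correction),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat("Mutual information:", nrow(x$mean), "TCR x", ncol(x$mean),
      "MHC columns |", x$pairing, "pairing,", x$n_repetitions,
      "repetition(s)\n")
  cat("max I =", round(max(x$mean), 4), "bits\n")
  invisible(x)
}

#' Chi-square finite-sample bias bound for mutual information
#'
#' Under independence, 2 n ln(2) I is asymptotically chi-square with
#' (K-1)(L-1) degrees of freedom; the bound is the \code{q} quantile of
#' that null converted back to bits — an upper band on the MI expected from
#' finite sampling alone.
#'
#' @param n Paired sample size.
#' @param k,l Alphabet sizes on the two sides.
#' @param q Quantile (default 0.999).
#' @return Bound in bits.
#' @export
mi_bias_bound <- function(n, k, l, q = 0.999) {
  stats::qchisq(q, df = (k - 1) * (l - 1)) / (2 * n * log(2))
}

# Local RNG wrapper: isolates package randomness from the global stream.
.seeded_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(as.integer(seed))
    st <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    st
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
    f()
  }
  list(
    sample = function(n, size, replace = FALSE)
      with_state(function() sample.int(n, size, replace = replace)),
    runif = function(n) with_state(function() stats::runif(n)),
    rnorm = function(n, mean = 0, sd = 1)
      with_state(function() stats::rnorm(n, mean, sd))
  )
}
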