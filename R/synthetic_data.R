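# Seeded generators producing every input the pipeline needs with known
# ground truth: repertoires with controlled per-column amino-acid
# distributions and planted TCR<->MHC covariation, and toy two-chain
# coordinate files with atoms placed at prescribed distances.

#' Specify a synthetic repertoire
#'
#' Each region is a list of column specifications; a column is either a
#' fixed residue (one-letter code), a residue class name (drawn uniformly
#' within the class as mapped by \code{\link{residue_classes}}), or a named
#' probability vector over amino acids. An optional per-region
#' \code{length_range} makes loop lengths vary: each sequence keeps the
#' first ceiling(L/2) and last floor(L/2) columns of the region (apex
#' deletion, matching the central pad rule of the encoder).
#'
#' @param n_sequences Number of sequences to generate.
#' @param regions Named list: region label -> list of column specs, or
#'   \code{list(columns = ..., length_range = c(min, max))}.
#' @param family Family label for the generated records.
#' @return An object of class \code{repertoire_spec} carrying the resolved
#'   per-column probability tables (the ground truth).
#' @export
repertoire_spec <- function(n_sequences, regions, family = "synthetic") {
  stopifnot(n_sequences >= 1L, is.list(regions), !is.null(names(regions)))
  classes <- residue_classes()
  resolve_col <- function(spec) {
    if (is.character(spec) && length(spec) == 1L && nchar(spec) == 1L) {
      p <- stats::setNames(numeric(20), aa_alphabet())
      if (!spec %in% aa_alphabet()) stop("unknown residue '", spec, "'")
      p[spec] <- 1
      return(p)
    }
    if (is.character(spec) && length(spec) == 1L) {
      members <- names(classes)[classes == spec]
      if (length(members) == 0L) {
        stop("column spec '", spec,
             "' is neither a residue nor a residue class")
      }
      p <- stats::setNames(numeric(20), aa_alphabet())
      p[members] <- 1 / length(members)
      return(p)
    }
    if (is.numeric(spec)) {
      p <- stats::setNames(numeric(20), aa_alphabet())
      if (is.null(names(spec)) && length(spec) == 20L) names(spec) <- aa_alphabet()
      if (is.null(names(spec))) stop("probability columns must be named")
      p[names(spec)] <- spec
      if (abs(sum(p) - 1) > 1e-8) stop("column probabilities must sum to 1")
      return(p)
    }
    stop("unsupported column spec")
  }
  resolved <- lapply(regions, function(r) {
    cols <- if (!is.null(r$columns)) r$columns else r
    lr <- r$length_range
    probs <- lapply(cols, resolve_col)
    if (!is.null(lr)) {
      lr <- as.integer(lr)
      if (length(lr) != 2L || lr[1L] > lr[2L] || lr[2L] > length(probs) ||
          lr[1L] < 1L) {
        stop("invalid length_range")
      }
    }
    list(probs = probs, length_range = lr)
  })
  structure(list(n_sequences = as.integer(n_sequences),
                 regions = resolved, family = family),
            class = "repertoire_spec")
}

#' Generate a synthetic repertoire
#'
#' Draws each column independently from the spec's per-column
#' distributions; byte-identical output for the same seed. The returned
#' records carry the spec (including the resolved probabilities) as the
#' \code{"ground_truth"} attribute, so expected entropies and property
#' profiles are computable in closed form.
#'
#' @param spec A \code{repertoire_spec}.
#' @param seed Integer seed.
#' @param id_prefix Prefix for generated record ids.
#' @return A \code{seq_records} data frame with one column per region.
#' @export
generate_repertoire <- function(spec, seed, id_prefix = "syn") {
  stopifnot(inherits(spec, "repertoire_spec"))
  rng <- .seeded_rng(seed)
  n <- spec$n_sequences
  segments <- lapply(spec$regions, function(r) {
    # inverse-CDF draw per column so every column consumes exactly n
    # uniforms regardless of its distribution
    full <- matrix("", nrow = n, ncol = length(r$probs))
    for (j in seq_along(r$probs)) {
      p <- r$probs[[j]]
      u <- rng$runif(n)
      full[, j] <- aa_alphabet()[findInterval(u, cumsum(p),
                                              rightmost.closed = TRUE) + 1L]
    }
    lens <- if (is.null(r$length_range)) rep(ncol(full), n)
            else r$length_range[1L] - 1L +
              rng$sample(r$length_range[2L] - r$length_range[1L] + 1L, n,
                         replace = TRUE)
    vapply(seq_len(n), function(i) {
      L <- lens[i]
      keep <- .pad_positions(L, ncol(full), "central")
      paste(full[i, keep], collapse = "")
    }, "")
  })
  names(segments) <- names(spec$regions)
  rec <- seq_records(sprintf("%s%04d", id_prefix, seq_len(n)), segments,
                     family = spec$family)
  attr(rec, "ground_truth") <- spec
  rec
}

#' Expected per-column entropy of a repertoire spec
#'
#' Closed-form Shannon entropy of each resolved column distribution of a
#' fixed-length region.
#'
#' @param spec A \code{repertoire_spec}.
#' @param region Region label.
#' @return Numeric vector of entropies in bits, one per column.
#' @export
expected_entropy <- function(spec, region) {
  probs <- spec$regions[[region]]$probs
  vapply(probs, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }, 0)
}

#' Generate paired TCR/MHC repertoires with planted covariation
#'
#' Generates two repertoires of equal size and then rewrites selected MHC
#' columns as a (possibly noisy) function of TCR columns: with probability
#' \code{obedience} the MHC residue at the target column is set to
#' \code{map[tcr residue]}, otherwise it keeps its independent draw. Under
#' identity pairing, an obeyed k-symbol uniform bijection has mutual
#' information log2(k) bits; at obedience 0 the ground truth is 0 (up to
#' finite-sample bias).
#'
#' @param tcr_spec,mhc_spec \code{repertoire_spec}s with equal
#'   \code{n_sequences}; covariation columns must sit in fixed-length
#'   regions.
#' @param covariation List of plans:
#'   \code{list(tcr_region=, tcr_column=, mhc_region=, mhc_column=,
#'   map=, obedience=)} with \code{map} a named character vector
#'   (TCR residue -> MHC residue).
#' @param seed Integer seed.
#' @return List with \code{tcr} and \code{mhc} \code{seq_records}; the
#'   covariation plan is attached as attribute \code{"covariation"}.
#' @export
generate_paired_repertoires <- function(tcr_spec, mhc_spec,
                                        covariation = list(), seed) {
  stopifnot(tcr_spec$n_sequences == mhc_spec$n_sequences)
  tcr <- generate_repertoire(tcr_spec, seed, id_prefix = "tcr")
  mhc <- generate_repertoire(mhc_spec, seed + 1L, id_prefix = "mhc")
  rng <- .seeded_rng(seed + 2L)
  for (plan in covariation) {
    stopifnot(plan$obedience >= 0, plan$obedience <= 1)
    if (!is.null(tcr_spec$regions[[plan$tcr_region]]$length_range) ||
        !is.null(mhc_spec$regions[[plan$mhc_region]]$length_range)) {
      stop("covariation columns must sit in fixed-length regions")
    }
    tcol <- substr(tcr[[plan$tcr_region]], plan$tcr_column, plan$tcr_column)
    obey <- rng$runif(nrow(mhc)) < plan$obedience
    target <- unname(plan$map[tcol])
    if (anyNA(target[obey])) {
      stop("covariation map does not cover all TCR residues drawn")
    }
    seg <- mhc[[plan$mhc_region]]
    substr(seg, plan$mhc_column, plan$mhc_column) <-
      ifelse(obey, target, substr(seg, plan$mhc_column, plan$mhc_column))
    mhc[[plan$mhc_region]] <- seg
    mhc$sequence <- do.call(paste0, mhc[setdiff(names(mhc),
      c("id", "family", "functionality", "sequence"))])
  }
  out <- list(tcr = tcr, mhc = mhc)
  attr(out, "covariation") <- covariation
  out
}

#' Specify a toy two-chain complex with planted contacts
#'
#' Each planted (or decoy) entry places one TCR atom and one MHC atom at an
#' exact prescribed distance, on residues of the requested amino acids.
#' Residue pairs are laid out 40 Angstrom apart along the chain axis so
#' only the planted atom pairs can fall within contact cutoffs; the
#' remaining backbone atoms of each residue are parked behind the
#' interface.
#'
#' @param planted List of entries \code{list(tcr_aa=, tcr_atom=, mhc_aa=,
#'   mhc_atom=, distance=)} intended to qualify as contacts.
#' @param decoys Like \code{planted} but at distances beyond the cutoffs.
#' @return An object of class \code{toy_complex_spec}.
#' @export
toy_complex_spec <- function(planted, decoys = list()) {
  chk <- function(e) {
    stopifnot(all(c("tcr_aa", "tcr_atom", "mhc_aa", "mhc_atom",
                    "distance") %in% names(e)))
    if (e$distance <= 0) stop("planted distance must be positive")
    e
  }
  structure(list(planted = lapply(planted, chk),
                 decoys = lapply(decoys, chk)),
            class = "toy_complex_spec")
}

# expected contact records for one planted entry, applying the distance /
# chemistry rules analytically (generator-side ground truth)
.expected_for_entry <- function(e, resno, vdw_cutoff = 4.5,
                                elec_cutoff = 6.0) {
  t_side <- if (toupper(e$tcr_atom) %in% .BACKBONE_ATOMS) "Back" else "SC"
  m_side <- if (toupper(e$mhc_atom) %in% .BACKBONE_ATOMS) "Back" else "SC"
  cls <- paste0(t_side, "-", m_side)
  te <- substr(toupper(e$tcr_atom), 1L, 1L)
  me <- substr(toupper(e$mhc_atom), 1L, 1L)
  sty <- e$tcr_aa %in% c("S", "T", "Y") || e$mhc_aa %in% c("S", "T", "Y")
  his <- e$tcr_aa == "H" || e$mhc_aa == "H"
  elec_pair <- (te == "N" && me == "O") || (te == "O" && me == "N") ||
    (te == "O" && me == "O" && sty) || (te == "N" && me == "N" && his)
  types <- c(if (e$distance <= vdw_cutoff) "vdw",
             if (e$distance <= elec_cutoff && elec_pair) "electrostatic")
  if (length(types) == 0L) return(NULL)
  data.frame(tcr_resno = resno, tcr_aa = e$tcr_aa, mhc_resno = resno,
             mhc_aa = e$mhc_aa, tcr_atom = toupper(e$tcr_atom),
             mhc_atom = toupper(e$mhc_atom), distance = e$distance,
             bond_type = types, contact_class = cls,
             stringsAsFactors = FALSE)
}

#' Generate a toy complex PDB with planted contacts
#'
#' Writes a minimal two-chain PDB (chain A = TCR, chain B = MHC) realizing
#' the spec's planted distances exactly, together with the matching
#' annotation and the exact expected contact list. An optional rigid-body
#' transform is applied to all coordinates (contact detection must be
#' invariant under it).
#'
#' @param spec A \code{toy_complex_spec}.
#' @param pdb_file Output PDB path.
#' @param rotation Optional 3 x 3 rotation matrix.
#' @param translation Optional length-3 translation vector.
#' @param annotation_file Optional path; if given, the annotation is also
#'   written there as JSON.
#' @return List with \code{pdb_file}, \code{annotation}
#'   (a \code{complex_annotation}) and \code{expected} (data frame of
#'   ground-truth contacts: residue numbers, amino acids, atoms, distance,
#'   bond type, contact class).
#' @export
generate_toy_complex <- function(spec, pdb_file = tempfile(fileext = ".pdb"),
                                 rotation = NULL, translation = NULL,
                                 annotation_file = NULL) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  entries <- c(spec$planted, spec$decoys)
  n <- length(entries)
  if (n == 0L) stop("toy complex spec has no entries")
  aa3 <- stats::setNames(names(.AA3_TO_1), .AA3_TO_1)
  atoms <- list()
  add_atom <- function(chain, resno, resid1, elety, x, y, z) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      chain = chain, resno = resno, resid = aa3[[resid1]],
      elety = elety, x = x, y = y, z = z, stringsAsFactors = FALSE)
  }
  for (k in seq_len(n)) {
    e <- entries[[k]]
    x0 <- 40 * k
    d <- e$distance
    t_atom <- toupper(e$tcr_atom); m_atom <- toupper(e$mhc_atom)
    # TCR residue (chain A): planted atom on the interface at y = 10,
    # remaining backbone atoms parked behind it (smaller y)
    t_back_y <- if (t_atom %in% .BACKBONE_ATOMS) 4 else 2
    bb <- setdiff(c("N", "CA", "C", "O"), t_atom)
    add_atom("A", k, e$tcr_aa, t_atom, x0, 10, 0)
    for (i in seq_along(bb)) {
      add_atom("A", k, e$tcr_aa, bb[i], x0 + 0.7 * i, t_back_y, 0)
    }
    # MHC residue (chain B): planted atom exactly d away along y
    m_back_y <- 10 + d + (if (m_atom %in% .BACKBONE_ATOMS) 6 else 8)
    bb <- setdiff(c("N", "CA", "C", "O"), m_atom)
    add_atom("B", k, e$mhc_aa, m_atom, x0, 10 + d, 0)
    for (i in seq_along(bb)) {
      add_atom("B", k, e$mhc_aa, bb[i], x0 + 0.7 * i, m_back_y, 0)
    }
  }
  at <- do.call(rbind, atoms)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (!is.null(rotation)) xyz <- xyz %*% t(rotation)
  if (!is.null(translation)) xyz <- sweep(xyz, 2L, -translation)
  ord <- order(at$chain, at$resno)
  at <- at[ord, , drop = FALSE]
  xyz <- xyz[ord, , drop = FALSE]
  elesy <- substr(at$elety, 1L, 1L)
  bio3d::write.pdb(file = pdb_file,
                   xyz = as.numeric(t(xyz)),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   elety = at$elety, eleno = seq_len(nrow(at)),
                   elesy = elesy, o = rep(1, nrow(at)),
                   b = rep(0, nrow(at)))
  ann <- complex_annotation(
    tcr = data.frame(chain = "A", loop = "CDR1", start = 1L, end = n,
                     stringsAsFactors = FALSE),
    mhc = data.frame(chain = "B", helix = "helix1", start = 1L, end = n,
                     stringsAsFactors = FALSE))
  expected <- do.call(rbind, lapply(seq_along(entries), function(k) {
    .expected_for_entry(entries[[k]], k)
  }))
  if (!is.null(expected)) {
    expected <- expected[order(expected$tcr_resno, expected$contact_class,
                               expected$bond_type), , drop = FALSE]
    rownames(expected) <- NULL
  } else {
    expected <- data.frame()
  }
  if (!is.null(annotation_file)) {
    jsonlite::write_json(list(
      tcr = list(list(chain = "A", loop = "CDR1", start = 1, end = n)),
      mhc = list(list(chain = "B", helix = "helix1", start = 1, end = n))),
      annotation_file, auto_unbox = TRUE)
  }
  list(pdb_file = pdb_file, annotation = ann, expected = expected)
}
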