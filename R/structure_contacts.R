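# Quantification of germline-CDR <-> MHC-helix contacts in solved
# TCR-pMHC complexes: distance/chemistry rules, contact classes, 20x20
# count matrices and permutation-test group comparisons.

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.AA3_TO_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
               GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
               LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
               SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Classify an atom as sidechain or backbone
#'
#' Backbone is the standard peptide unit \{N, CA, C, O, OXT\}; every other
#' heavy atom belongs to the sidechain. Glycine thus has no sidechain
#' atoms. Atom names not following standard PDB nomenclature raise a
#' warning and are treated as sidechain.
#'
#' @param residue Three- or one-letter residue name (used only for the
#'   warning message).
#' @param atom Atom name, e.g. "CA", "NZ", "OE1".
#' @return \code{"backbone"} or \code{"sidechain"}.
#' @export
classify_atom <- function(residue, atom) {
  atom <- toupper(trimws(atom))
  if (atom %in% .BACKBONE_ATOMS) return("backbone")
  if (!grepl("^[CNOS]", atom)) {
    warning("unrecognized atom name '", atom, "' in residue ", residue,
            "; treated as sidechain")
  }
  "sidechain"
}

#' Annotation of a TCR-pMHC complex
#'
#' Names the chains and residue ranges the contact scan should consider:
#' the CDR1/CDR2 ranges on the TCR chains and the helix ranges on the MHC
#' chain(s), plus optional gene assignments for grouping.
#'
#' @param tcr Data frame with columns \code{chain}, \code{loop},
#'   \code{start}, \code{end} (residue numbers, inclusive).
#' @param mhc Data frame with columns \code{chain}, \code{helix},
#'   \code{start}, \code{end}.
#' @param genes Optional named character vector (e.g.
#'   \code{c(alpha = "TRAV19", beta = "TRBV6-1")}).
#' @return An object of class \code{complex_annotation}.
#' @export
complex_annotation <- function(tcr, mhc, genes = NULL) {
  stopifnot(all(c("chain", "loop", "start", "end") %in% names(tcr)),
            all(c("chain", "helix", "start", "end") %in% names(mhc)))
  for (df in list(tcr, mhc)) {
    by_chain <- split(df, df$chain)
    for (d in by_chain) {
      d <- d[order(d$start), ]
      if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
        stop("overlapping residue ranges within chain ", d$chain[1L])
      }
    }
  }
  structure(list(tcr = tcr, mhc = mhc, genes = genes),
            class = "complex_annotation")
}

#' Read a complex annotation from YAML or JSON
#'
#' @param path File with top-level keys \code{tcr}, \code{mhc} (lists of
#'   chain/loop-or-helix/start/end entries) and optional \code{genes}.
#' @return A \code{complex_annotation}.
#' @export
read_complex_annotation <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = FALSE)
  to_df <- function(lst) {
    do.call(rbind, lapply(lst, function(e)
      as.data.frame(e, stringsAsFactors = FALSE)))
  }
  complex_annotation(tcr = to_df(cfg$tcr), mhc = to_df(cfg$mhc),
                     genes = if (!is.null(cfg$genes)) unlist(cfg$genes))
}

# atom table (one row per heavy atom, altloc-resolved) for the residues of
# one annotation side
.atoms_for_ranges <- function(atoms, ranges, label_col) {
  out <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    sel <- atoms$chain == r$chain & atoms$resno >= r$start &
      atoms$resno <= r$end
    if (!any(sel)) {
      stop("annotation references chain ", r$chain, " residues ",
           r$start, "-", r$end, " absent from the structure")
    }
    a <- atoms[sel, , drop = FALSE]
    a$region <- r[[label_col]]
    a
  })
  do.call(rbind, out)
}

# read + tidy a PDB into a heavy-atom table with altlocs resolved to the
# highest-occupancy conformer per (chain, resno, icode, atom)
.pdb_atom_table <- function(pdb) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  a <- pdb$atom
  a <- a[a$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  elt <- toupper(trimws(ifelse(is.na(a$elesy) | a$elesy == "",
                               substr(trimws(a$elety), 1L, 1L), a$elesy)))
  a$element <- elt
  a <- a[a$element != "H", , drop = FALSE]
  a$icode <- ifelse(is.na(a$insert), "", a$insert)
  key <- paste(a$chain, a$resno, a$icode, a$elety)
  occ <- ifelse(is.na(a$o), 1, a$o)
  keep <- unlist(lapply(split(seq_along(key), key), function(idx) {
    idx[which.max(occ[idx])]
  }), use.names = FALSE)
  a <- a[sort(keep), , drop = FALSE]
  a$aa1 <- unname(.AA3_TO_1[toupper(a$resid)])
  a
}

#' Find germline-CDR to MHC-helix contacts in a complex
#'
#' Scans every CDR-residue x helix-residue heavy-atom pair. A van der
#' Waals contact requires a distance of at most \code{vdw_cutoff}
#' (4.5 A default); an electrostatic contact requires a distance of at most
#' \code{elec_cutoff} (6.0 A default) and a nitrogen-oxygen atom pair — or
#' an O-O pair with Ser/Thr/Tyr involved, or an N-N pair with His involved
#' (hydroxyl/imidazole donor exceptions). Contacts are recorded once per
#' (TCR residue, MHC residue, contact class, bond type), keeping the
#' closest qualifying atom pair. The contact class reflects which atoms
#' touch: SC-SC, SC-Back (TCR sidechain to MHC backbone), Back-SC,
#' Back-Back.
#'
#' @param pdb Path to a PDB file or a \code{bio3d} pdb object.
#' @param annotation A \code{complex_annotation}.
#' @param vdw_cutoff,elec_cutoff Distance cutoffs in Angstrom.
#' @return Data frame of class \code{contact_records}, one row per
#'   contact: TCR/MHC chain, residue number, amino acid, region, atom
#'   names, distance, \code{bond_type}, \code{contact_class}.
#' @export
find_contacts <- function(pdb, annotation, vdw_cutoff = 4.5,
                          elec_cutoff = 6.0) {
  stopifnot(inherits(annotation, "complex_annotation"))
  atoms <- .pdb_atom_table(pdb)
  ta <- .atoms_for_ranges(atoms, annotation$tcr, "loop")
  ma <- .atoms_for_ranges(atoms, annotation$mhc, "helix")
  d <- sqrt(outer(ta$x, ma$x, "-")^2 + outer(ta$y, ma$y, "-")^2 +
              outer(ta$z, ma$z, "-")^2)
  hits <- which(d <= max(vdw_cutoff, elec_cutoff), arr.ind = TRUE)
  if (nrow(hits) == 0L) return(.empty_contacts())
  ti <- hits[, 1L]; mi <- hits[, 2L]
  dist <- d[hits]
  t_side <- vapply(seq_along(ti), function(k)
    classify_atom(ta$resid[ti[k]], ta$elety[ti[k]]), "")
  m_side <- vapply(seq_along(mi), function(k)
    classify_atom(ma$resid[mi[k]], ma$elety[mi[k]]), "")
  cls <- paste0(ifelse(t_side == "sidechain", "SC", "Back"), "-",
                ifelse(m_side == "sidechain", "SC", "Back"))
  te <- ta$element[ti]; me <- ma$element[mi]
  sty <- ta$aa1[ti] %in% c("S", "T", "Y") | ma$aa1[mi] %in% c("S", "T", "Y")
  his <- ta$aa1[ti] == "H" | ma$aa1[mi] == "H"
  elec_pair <- (te == "N" & me == "O") | (te == "O" & me == "N") |
    (te == "O" & me == "O" & sty) | (te == "N" & me == "N" & his)
  rows <- list()
  add <- function(sel, type) {
    if (!any(sel)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      tcr_chain = ta$chain[ti[sel]], tcr_resno = ta$resno[ti[sel]],
      tcr_aa = ta$aa1[ti[sel]], loop = ta$region[ti[sel]],
      mhc_chain = ma$chain[mi[sel]], mhc_resno = ma$resno[mi[sel]],
      mhc_aa = ma$aa1[mi[sel]], helix = ma$region[mi[sel]],
      tcr_atom = ta$elety[ti[sel]], mhc_atom = ma$elety[mi[sel]],
      distance = dist[sel], bond_type = type,
      contact_class = cls[sel], stringsAsFactors = FALSE)
  }
  add(dist <= vdw_cutoff, "vdw")
  add(dist <= elec_cutoff & elec_pair, "electrostatic")
  rec <- do.call(rbind, rows)
  if (is.null(rec) || nrow(rec) == 0L) return(.empty_contacts())
  # one record per residue pair x class x bond type, closest atoms kept
  key <- paste(rec$tcr_chain, rec$tcr_resno, rec$mhc_chain, rec$mhc_resno,
               rec$contact_class, rec$bond_type)
  ord <- order(key, rec$distance)
  rec <- rec[ord, , drop = FALSE]
  rec <- rec[!duplicated(key[ord]), , drop = FALSE]
  rec <- rec[order(rec$tcr_chain, rec$tcr_resno, rec$mhc_chain,
                   rec$mhc_resno, rec$contact_class, rec$bond_type), ,
             drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("contact_records", "data.frame")
  rec
}

.empty_contacts <- function() {
  rec <- data.frame(tcr_chain = character(0), tcr_resno = integer(0),
                    tcr_aa = character(0), loop = character(0),
                    mhc_chain = character(0), mhc_resno = integer(0),
                    mhc_aa = character(0), helix = character(0),
                    tcr_atom = character(0), mhc_atom = character(0),
                    distance = numeric(0), bond_type = character(0),
                    contact_class = character(0), stringsAsFactors = FALSE)
  class(rec) <- c("contact_records", "data.frame")
  rec
}

#' Tabulate contacts into a 20 x 20 residue-pair count matrix
#'
#' Rows index the MHC amino acid, columns the TCR amino acid. The
#' symmetrized variant is M + t(M), so its total is twice the raw record
#' count.
#'
#' @param records \code{contact_records}.
#' @param classes Contact classes to keep (default \code{"SC-SC"}, the
#'   sidechain-sidechain contacts the interaction potential models); use
#'   \code{NULL} for all.
#' @param bond_types Bond types to keep (default both).
#' @return List with \code{raw} and \code{symmetrized} 20 x 20 integer
#'   matrices (amino-acid dimnames) and \code{n_records}.
#' @export
contact_count_matrix <- function(records, classes = "SC-SC",
                                 bond_types = c("vdw", "electrostatic")) {
  if (!is.null(classes)) {
    records <- records[records$contact_class %in% classes, , drop = FALSE]
  }
  records <- records[records$bond_type %in% bond_types, , drop = FALSE]
  aas <- aa_alphabet()
  m <- matrix(0L, 20L, 20L, dimnames = list(mhc = aas, tcr = aas))
  if (nrow(records) > 0L) {
    keep <- records$mhc_aa %in% aas & records$tcr_aa %in% aas
    tab <- table(factor(records$mhc_aa[keep], levels = aas),
                 factor(records$tcr_aa[keep], levels = aas))
    m[] <- as.integer(tab)
  }
  list(raw = m, symmetrized = m + t(m), n_records = nrow(records))
}

#' Contact counts per helix alignment column
#'
#' Maps each contacted MHC residue to its alignment column and totals the
#' CDR contacts there, for comparison against the per-residue interaction
#' potential breakdown. Residues missing from the map are totalled under
#' \code{"unmapped"}.
#'
#' @param records \code{contact_records}.
#' @param alignment_map Data frame with \code{chain}, \code{resno},
#'   \code{column} mapping MHC residues to alignment columns.
#' @param classes Contact classes to count (default the TCR-sidechain
#'   classes \code{"SC-SC"}).
#' @return Data frame with \code{column} (character; "unmapped" collects
#'   unmapped residues) and \code{count}.
#' @export
per_residue_contact_counts <- function(records, alignment_map,
                                       classes = "SC-SC") {
  stopifnot(all(c("chain", "resno", "column") %in% names(alignment_map)))
  if (!is.null(classes)) {
    records <- records[records$contact_class %in% classes, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    return(data.frame(column = character(0), count = integer(0)))
  }
  idx <- match(paste(records$mhc_chain, records$mhc_resno),
               paste(alignment_map$chain, alignment_map$resno))
  col <- ifelse(is.na(idx), "unmapped",
                as.character(alignment_map$column[idx]))
  agg <- as.data.frame(table(col), stringsAsFactors = FALSE)
  names(agg) <- c("column", "count")
  agg$count <- as.integer(agg$count)
  agg[order(suppressWarnings(as.numeric(agg$column)), agg$column), ,
      drop = FALSE]
}

#' Bin per-gene potentials into weak/moderate/strong
#'
#' Default thresholds are the tertiles of the potential distribution.
#'
#' @param potentials Named numeric vector of per-gene potentials.
#' @param breaks Optional explicit two inner break points.
#' @return Factor with levels weak, moderate, strong.
#' @export
potential_bins <- function(potentials, breaks = NULL) {
  if (is.null(breaks)) {
    breaks <- stats::quantile(potentials, c(1 / 3, 2 / 3), names = FALSE)
  }
  cut(potentials, c(-Inf, breaks, Inf),
      labels = c("weak", "moderate", "strong"), right = TRUE)
}

#' Permutation-test comparison of contact counts across potential bins
#'
#' For every pair of bins, a two-sided nonparametric permutation test on
#' the difference of mean contact counts: group labels are shuffled
#' \code{n_perm} times and p = (1 + #\{|d_perm| >= |d_obs|\}) /
#' (1 + n_perm). Bins with fewer than two members are skipped with a
#' warning.
#'
#' @param values Numeric vector of per-complex (or per-gene) contact
#'   counts.
#' @param bins Factor or character vector of bin labels, same length.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return Data frame with \code{group1}, \code{group2}, \code{n1},
#'   \code{n2}, \code{mean1}, \code{mean2}, \code{delta}, \code{p_value}.
#' @export
group_comparison <- function(values, bins, n_perm = 10000L, seed) {
  stopifnot(length(values) == length(bins))
  bins <- as.factor(bins)
  counts <- table(bins)
  usable <- names(counts)[counts >= 2L]
  skipped <- setdiff(names(counts)[counts > 0L], usable)
  if (length(skipped) > 0L) {
    warning("bin(s) with < 2 members skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (length(usable) < 2L) stop("need at least two bins with >= 2 members")
  rng <- .seeded_rng(seed)
  pairs <- utils::combn(usable, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    x <- values[bins == g1]; y <- values[bins == g2]
    z <- c(x, y); n1 <- length(x); n <- length(z)
    obs <- mean(x) - mean(y)
    S <- sum(z)
    perm_delta <- vapply(seq_len(n_perm), function(i) {
      s1 <- sum(z[rng$sample(n, n1)])
      s1 / n1 - (S - s1) / (n - n1)
    }, 0)
    p <- (1 + sum(abs(perm_delta) >= abs(obs))) / (1 + n_perm)
    data.frame(group1 = g1, group2 = g2, n1 = n1, n2 = length(y),
               mean1 = mean(x), mean2 = mean(y), delta = obs, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}
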