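#' Residue interaction classes
#'
#' The five-way biophysical classification underlying the pairwise
#' interaction matrix: positive (K, R, H), negative (D, E), hydrophilic
#' (S, T, N, Q, Y, C, W), hydrophobic (F, L, I, M, V) and noninteracting
#' (G, A, P — small residues whose side chains contribute no specific
#' contact).
#'
#' @return Named character vector mapping each canonical amino acid to its
#'   class.
#' @export
residue_classes <- function() {
  cls <- c(positive = "K R H", negative = "D E",
           hydrophilic = "S T N Q Y C W", hydrophobic = "F L I M V",
           noninteracting = "G A P")
  out <- character(0)
  for (nm in names(cls)) {
    aas <- strsplit(cls[[nm]], " ")[[1]]
    out[aas] <- nm
  }
  out[aa_alphabet()]
}

#' Default class-pair rule scores
#'
#' Productive interactions (salt bridges, hydrogen-bond donor/acceptor
#' pairings) score positively, destructive ones (like-charge clashes,
#' hydrophilic-hydrophobic mismatch) negatively; anything involving a
#' noninteracting residue scores zero.
#'
#' @return Data frame with columns \code{class1}, \code{class2},
#'   \code{score} covering all 15 unordered class pairs.
#' @export
interaction_rules <- function() {
  rules <- rbind(
    c("positive",    "negative",       2),
    c("positive",    "positive",      -2),
    c("negative",    "negative",      -2),
    c("positive",    "hydrophilic",    1),
    c("negative",    "hydrophilic",    1),
    c("hydrophilic", "hydrophilic",    1),
    c("hydrophobic", "hydrophobic",    1),
    c("hydrophobic", "hydrophilic",   -1),
    c("hydrophobic", "positive",      -1),
    c("hydrophobic", "negative",      -1),
    c("noninteracting", "positive",    0),
    c("noninteracting", "negative",    0),
    c("noninteracting", "hydrophilic", 0),
    c("noninteracting", "hydrophobic", 0),
    c("noninteracting", "noninteracting", 0))
  data.frame(class1 = rules[, 1], class2 = rules[, 2],
             score = as.integer(rules[, 3]), stringsAsFactors = FALSE)
}

#' Build a 20 x 20 pairwise interaction matrix from class rules
#'
#' Every residue pair scores by the rule for its unordered class pair, so
#' the matrix is symmetric by construction. By default the result is
#' checked against two anchored scoring cases (NNK/EDQ all +1 and valid;
#' KEL/RKA = (-2, +2, 0) and rejected) so that any configured class map or
#' rule set that breaks the scoring contract fails fast.
#'
#' @param classes Named character vector as from
#'   \code{\link{residue_classes}}.
#' @param rules Data frame of class-pair scores as from
#'   \code{\link{interaction_rules}}; must cover all unordered pairs of the
#'   classes in use.
#' @param check Run the worked-example self-check (default TRUE).
#' @return Integer matrix with amino-acid dimnames, class
#'   \code{interaction_matrix}.
#' @export
build_interaction_matrix <- function(classes = residue_classes(),
                                     rules = interaction_rules(),
                                     check = TRUE) {
  aas <- aa_alphabet()
  stopifnot(all(aas %in% names(classes)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  lut <- stats::setNames(rules$score, key(rules$class1, rules$class2))
  used <- unique(classes[aas])
  need <- outer(used, used, key)
  missing <- setdiff(unique(as.vector(need)), names(lut))
  if (length(missing) > 0L) {
    stop("rule table missing class pair(s): ", paste(missing, collapse = "; "))
  }
  m <- matrix(0L, 20L, 20L, dimnames = list(aas, aas))
  for (a in aas) for (b in aas) {
    m[a, b] <- as.integer(lut[[key(classes[[a]], classes[[b]])]])
  }
  class(m) <- c("interaction_matrix", class(m))
  if (check) check_interaction_matrix(m)
  m
}

#' Read a 20 x 20 interaction matrix override from CSV
#'
#' @param path CSV with amino-acid row names and column headers.
#' @param check Run the worked-example self-check (default TRUE).
#' @return An \code{interaction_matrix}.
#' @export
read_interaction_matrix <- function(path, check = TRUE) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)[aa_alphabet(), aa_alphabet()]
  storage.mode(m) <- "integer"
  if (max(abs(m - t(m))) != 0L) stop("interaction matrix must be symmetric")
  class(m) <- c("interaction_matrix", class(m))
  if (check) check_interaction_matrix(m)
  m
}

#' Self-check an interaction matrix against the anchored scoring cases
#'
#' Asserts that NNK vs EDQ scores (+1, +1, +1) and forms a valid triad, and
#' that KEL vs RKA scores (-2, +2, 0) and is rejected. Called on any
#' configured matrix at build/load time.
#'
#' @param matrix An \code{interaction_matrix}.
#' @return Invisibly TRUE; stops on failure.
#' @export
check_interaction_matrix <- function(matrix) {
  a <- score_trigram_pair("NNK", "EDQ", matrix)
  b <- score_trigram_pair("KEL", "RKA", matrix)
  ok <- identical(a$pair_scores, c(1L, 1L, 1L)) && a$valid &&
    identical(b$pair_scores, c(-2L, 2L, 0L)) && !b$valid && b$total == 0L
  if (!ok) {
    stop("interaction matrix fails the anchored scoring cases ",
         "(NNK/EDQ -> +1,+1,+1 valid; KEL/RKA -> -2,+2,0 rejected)")
  }
  invisible(TRUE)
}

# default matrix, built once per session
.default_matrix_cache <- new.env(parent = emptyenv())

#' The default interaction matrix
#'
#' @return The \code{interaction_matrix} built from
#'   \code{\link{residue_classes}} and \code{\link{interaction_rules}}.
#' @export
default_interaction_matrix <- function() {
  if (is.null(.default_matrix_cache$m)) {
    .default_matrix_cache$m <- build_interaction_matrix()
  }
  .default_matrix_cache$m
}

#' Score one TCR trigram against one MHC trigram
#'
#' Positions are scored pairwise through the interaction matrix. A triad is
#' valid only if it consists throughout of at least weakly interacting
#' residues — under the default rule, all three pair scores >= +1; the
#' alternative \code{"no_negative"} rule rejects only triads containing a
#' clash. Invalid triads contribute a total of 0. Nonstandard residues
#' score 0 at their position.
#'
#' @param tcr,mhc Three-letter amino-acid strings.
#' @param matrix An \code{interaction_matrix} (default matrix if omitted).
#' @param validity \code{"all_weak"} (default) or \code{"no_negative"}.
#' @return List of class \code{triad_score}: \code{tcr}, \code{mhc},
#'   \code{pair_scores} (integer 3-vector), \code{valid}, \code{total}.
#' @export
score_trigram_pair <- function(tcr, mhc, matrix = default_interaction_matrix(),
                               validity = c("all_weak", "no_negative")) {
  validity <- match.arg(validity)
  if (nchar(tcr) != 3L || nchar(mhc) != 3L) stop("trigrams must have length 3")
  tc <- aa_to_code(tcr); mc <- aa_to_code(mhc)
  ps <- integer(3L)
  for (i in 1:3) {
    ps[i] <- if (tc[i] > 20L || mc[i] > 20L) 0L
             else matrix[tc[i], mc[i]]
  }
  valid <- if (validity == "all_weak") all(ps >= 1L) else all(ps >= 0L)
  structure(list(tcr = tcr, mhc = mhc, pair_scores = ps, valid = valid,
                 total = if (valid) sum(ps) else 0L),
            class = "triad_score")
}

#' @export
print.triad_score <- function(x, ...) {
  cat(sprintf("TCR:%s vs MHC:%s -> [%+d,%+d,%+d] %s (total %d)\n",
              x$tcr, x$mhc, x$pair_scores[1], x$pair_scores[2],
              x$pair_scores[3], if (x$valid) "valid" else "rejected",
              x$total))
  invisible(x)
}

# integer-coded trigram scoring core shared by the potential routines.
# Returns total potential and per-helix-position attribution for one
# loop/helix pair.
.potential_core <- function(loop_codes, helix_codes, matrix, validity) {
  Lt <- length(loop_codes); Lm <- length(helix_codes)
  attribution <- numeric(Lm)
  total <- 0L
  if (Lt < 3L || Lm < 3L) {
    return(list(score = 0L, attribution = attribution, n_valid = 0L))
  }
  # scores for every aligned residue pair, X/nonstandard scoring 0
  sc <- matrix
  n_valid <- 0L
  for (i in seq_len(Lt - 2L)) {
    t3 <- loop_codes[i:(i + 2L)]
    for (j in seq_len(Lm - 2L)) {
      m3 <- helix_codes[j:(j + 2L)]
      ps <- integer(3L)
      for (k in 1:3) {
        ps[k] <- if (t3[k] > 20L || m3[k] > 20L) 0L else sc[t3[k], m3[k]]
      }
      ok <- if (validity == "all_weak") all(ps >= 1L) else all(ps >= 0L)
      if (ok) {
        total <- total + sum(ps)
        n_valid <- n_valid + 1L
        attribution[j:(j + 2L)] <- attribution[j:(j + 2L)] + ps
      }
    }
  }
  list(score = total, attribution = attribution, n_valid = n_valid)
}

#' Interaction potential between a CDR loop and an MHC helix
#'
#' Slides a length-3 window over both sequences and scores every
#' combination of loop trigram x helix trigram through
#' \code{\link{score_trigram_pair}}; the potential is the sum of the totals
#' of all valid triads, so it is nonnegative under the default validity
#' rule and enumerates (Lt-2)(Lm-2) trigram pairs without any assumed
#' binding orientation. Per-position attribution credits each helix
#' position with its own pair score within every valid triad, so the
#' attribution sums to the potential.
#'
#' @param loop,helix Amino-acid strings (lengths >= 3; shorter input scores
#'   0 with a warning).
#' @param matrix An \code{interaction_matrix}.
#' @param validity Triad validity rule, see
#'   \code{\link{score_trigram_pair}}.
#' @param normalize If TRUE, divide the potential and attribution by the
#'   number of trigram pairs (Lt-2)(Lm-2) for cross-length comparison;
#'   default off (raw sum).
#' @return List of class \code{loop_helix_potential}: \code{score},
#'   \code{attribution} (numeric, one entry per helix position),
#'   \code{n_valid} triad count.
#' @export
loop_helix_potential <- function(loop, helix,
                                 matrix = default_interaction_matrix(),
                                 validity = c("all_weak", "no_negative"),
                                 normalize = FALSE) {
  validity <- match.arg(validity)
  lc <- aa_to_code(loop); hc <- aa_to_code(helix)
  if (length(lc) < 3L || length(hc) < 3L) {
    warning("loop/helix shorter than a trigram; potential is 0")
  }
  res <- .potential_core(lc, hc, matrix, validity)
  if (normalize && length(lc) >= 3L && length(hc) >= 3L) {
    np <- (length(lc) - 2L) * (length(hc) - 2L)
    res$score <- res$score / np
    res$attribution <- res$attribution / np
  }
  structure(res, class = "loop_helix_potential")
}

#' Interaction potentials for every gene x allele combination
#'
#' Computes the loop/helix interaction potential for the complete
#' cross-product of (TCR gene, CDR loop) and (HLA allele, helix).
#'
#' @param tcr_records \code{seq_records} with the loop segment columns.
#' @param mhc_records \code{seq_records} with the helix segment columns.
#' @param matrix An \code{interaction_matrix}.
#' @param loops,helices Segment column names to score (defaults CDR1/CDR2
#'   and helix1/helix2).
#' @param validity,normalize Passed to \code{\link{loop_helix_potential}}.
#' @return Data frame of class \code{score_table} with columns
#'   \code{tcr_gene}, \code{loop}, \code{hla_allele}, \code{helix},
#'   \code{score}.
#' @export
gene_allele_scores <- function(tcr_records, mhc_records,
                               matrix = default_interaction_matrix(),
                               loops = c("CDR1", "CDR2"),
                               helices = c("helix1", "helix2"),
                               validity = "all_weak", normalize = FALSE) {
  if (nrow(tcr_records) == 0L || nrow(mhc_records) == 0L)
    stop("empty record set")
  stopifnot(all(loops %in% names(tcr_records)),
            all(helices %in% names(mhc_records)))
  grid <- expand.grid(ti = seq_len(nrow(tcr_records)), loop = loops,
                      mi = seq_len(nrow(mhc_records)), helix = helices,
                      stringsAsFactors = FALSE)
  # cache potentials per unique (loop string, helix string) pair
  lp <- mapply(function(i, l) tcr_records[[l]][i], grid$ti, grid$loop)
  hp <- mapply(function(i, h) mhc_records[[h]][i], grid$mi, grid$helix)
  key <- paste(lp, hp)
  uniq <- !duplicated(key)
  uscores <- vapply(which(uniq), function(i) {
    loop_helix_potential(lp[i], hp[i], matrix, validity,
                         normalize = normalize)$score
  }, 0)
  scores <- uscores[match(key, key[uniq])]
  out <- data.frame(tcr_gene = tcr_records$id[grid$ti], loop = grid$loop,
                    hla_allele = mhc_records$id[grid$mi], helix = grid$helix,
                    score = scores, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Mean potential per gene x allele over loops
#'
#' @param table A \code{score_table}.
#' @return Data frame with \code{tcr_gene}, \code{hla_allele},
#'   \code{helix}, \code{mean_score} (mean over CDR loops).
#' @export
mean_loop_scores <- function(table) {
  agg <- stats::aggregate(score ~ tcr_gene + hla_allele + helix,
                          data = table, FUN = mean)
  names(agg)[names(agg) == "score"] <- "mean_score"
  agg
}

#' Per-helix score distributions by HLA group
#'
#' For each (HLA group, helix) the distribution of per-(gene, allele)
#' potentials averaged over both CDR loops — one value per gene x allele
#' combination, as used to compare helix engagement across allele groups.
#'
#' @param table A \code{score_table}.
#' @param hla_groups Named character vector mapping every allele in the
#'   table to a group label (e.g. "HLA-A", "HLA-B", "HLA-C").
#' @return List with \code{distributions} (data frame: \code{group},
#'   \code{helix}, \code{tcr_gene}, \code{hla_allele}, \code{mean_score})
#'   and \code{summary} (quartiles and n per group x helix).
#' @export
helix_distributions <- function(table, hla_groups) {
  alleles <- unique(table$hla_allele)
  unknown <- setdiff(alleles, names(hla_groups))
  if (length(unknown) > 0L) {
    stop("no group label for allele(s): ", paste(unknown, collapse = ", "))
  }
  means <- mean_loop_scores(table)
  means$group <- unname(hla_groups[means$hla_allele])
  sum_one <- function(d) {
    q <- stats::quantile(d$mean_score, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = d$group[1L], helix = d$helix[1L], n = nrow(d),
               q1 = q[1L], median = q[2L], q3 = q[3L])
  }
  pieces <- split(means, list(means$group, means$helix), drop = TRUE)
  summary <- do.call(rbind, lapply(pieces, sum_one))
  rownames(summary) <- NULL
  list(distributions = means[, c("group", "helix", "tcr_gene",
                                 "hla_allele", "mean_score")],
       summary = summary)
}

#' Per-residue breakdown of the interaction potential on MHC helices
#'
#' Attributes the interaction potential to individual helix positions:
#' for every (gene, loop, allele) combination the per-position attribution
#' of \code{\link{loop_helix_potential}} is computed and averaged over
#' genes and loops (and alleles, when several are given). Helix segments of
#' one label must share a common length across alleles. Conserved
#' noninteracting positions come out exactly 0.
#'
#' @param tcr_records \code{seq_records} with loop columns.
#' @param mhc_records \code{seq_records} with helix columns (one or more
#'   alleles).
#' @param matrix An \code{interaction_matrix}.
#' @param loops,helices Segment columns to use.
#' @param validity Triad validity rule.
#' @return Data frame with \code{helix}, \code{position},
#'   \code{mean_score}: the mean attributed potential per helix alignment
#'   column.
#' @export
per_residue_breakdown <- function(tcr_records, mhc_records,
                                  matrix = default_interaction_matrix(),
                                  loops = c("CDR1", "CDR2"),
                                  helices = c("helix1", "helix2"),
                                  validity = "all_weak") {
  if (nrow(tcr_records) == 0L || nrow(mhc_records) == 0L)
    stop("empty record set")
  out <- lapply(helices, function(h) {
    lens <- nchar(mhc_records[[h]])
    if (length(unique(lens)) != 1L) {
      stop("helix '", h, "' segments must share one alignment length ",
           "across alleles")
    }
    acc <- numeric(lens[1L])
    n <- 0L
    for (mi in seq_len(nrow(mhc_records))) {
      for (loop in loops) {
        for (ti in seq_len(nrow(tcr_records))) {
          p <- loop_helix_potential(tcr_records[[loop]][ti],
                                    mhc_records[[h]][mi], matrix, validity)
          acc <- acc + p$attribution
          n <- n + 1L
        }
      }
    }
    data.frame(helix = h, position = seq_along(acc), mean_score = acc / n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Map negative values to zero
#'
#' Normalization used when comparing potentials to empirical contact
#' counts, where negative counts cannot occur: elementwise max(0, x).
#' Idempotent; shape and dimnames preserved.
#'
#' @param x Numeric vector, matrix, or data frame column(s).
#' @return Same shape as \code{x}.
#' @export
relu_normalize <- function(x) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, TRUE)
    x[num] <- lapply(x[num], function(v) pmax(0, v))
    return(x)
  }
  out <- pmax(0, x)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Enumerate productive gene pairings
#'
#' @param trav_records,trbv_records \code{seq_records} for the two chains
#'   (assumed already filtered to unique productive genes).
#' @return Data frame with one row per TRAV x TRBV pairing.
#' @export
gene_pairings <- function(trav_records, trbv_records) {
  out <- expand.grid(trav = trav_records$id, trbv = trbv_records$id,
                     stringsAsFactors = FALSE)
  class(out) <- c("gene_pairings", "data.frame")
  out
}
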