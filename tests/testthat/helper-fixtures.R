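# Shared fixtures built in code.

fasta_text <- function(headers, seqs) {
  as.vector(rbind(paste0(">", headers), seqs))
}

# tiny TCR/MHC families with CDR and helix segments
toy_tcr_records <- function() {
  seq_records(
    id = c("TRBVX-1", "TRBVX-2"),
    segments = list(CDR1 = c("YNNKEL", "KRSTQ"),
                    CDR2 = c("SNQTY", "FLIMV")),
    family = "TRBV")
}

toy_mhc_records <- function() {
  seq_records(
    id = c("HLA-X*01:01", "HLA-X*02:01"),
    segments = list(helix1 = c("EDQRKA", "QNESTK"),
                    helix2 = c("ASTQNE", "GSTQNE")),
    family = "HLA-I")
}

# exhaustive double-loop oracle for the trigram interaction potential,
# independent of the package's sliding-window implementation
oracle_potential <- function(loop, helix, matrix = default_interaction_matrix(),
                             validity = "all_weak") {
  lt <- nchar(loop); lm <- nchar(helix)
  if (lt < 3 || lm < 3) return(0)
  total <- 0
  for (i in 1:(lt - 2)) {
    for (j in 1:(lm - 2)) {
      ts <- score_trigram_pair(substr(loop, i, i + 2),
                               substr(helix, j, j + 2),
                               matrix, validity = validity)
      total <- total + ts$total
    }
  }
  total
}

random_aa_string <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}
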