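# tcrmhc

Antigen-independent analysis of germline-encoded TCR–MHC compatibility.

T cell receptors (TCRs) dock onto peptide-MHC complexes in a narrowly
conserved orientation, yet the hypervariable CDR3 loops and the peptide —
the parts most studied — differ in every complex. The only interface
components shared across all receptor–ligand combinations are the
germline-encoded CDR1/CDR2 loops (fixed by the TRAV/TRBV gene) and the MHC
α-helices. Fewer than 0.01% of the possible gene × allele combinations have
been crystallized, so `tcrmhc` characterizes this space computationally,
for immunologists and computational biologists studying TCR repertoires,
HLA polymorphism, or TCR-pMHC structure:

- **Encoding** — CDR loops and TCR-exposed MHC helix residues become an
  integer alignment matrix (codes 1–21, zeros padding gaps), built from
  FASTA inputs and editable region-position configs.
- **Diversity** — position-sensitive Shannon entropy
  *H = −Σ p(x) log₂ p(x)* (bits; 0 = conserved, 4.32 = 20-letter maximum)
  with subsampling-averaged profiles, and mutual information
  *I(X;Y) = H(X) − H(X|Y)* between TCR and MHC positions under repeated
  random pairing of sequences.
- **Biophysics** — position-sensitive charge and Kyte–Doolittle hydropathy
  profiles, z-normalized over the 20 amino acids.
- **Interaction potential** — a pairwise residue scoring matrix (salt
  bridges and hydrogen-bond pairings positive, clashes negative,
  G/A/P inert) applied to every trigram of a CDR loop against every
  trigram of an MHC helix; a triad counts only if all three pairwise
  scores are at least weakly productive (≥ +1). Summing valid triads gives
  a nonnegative, orientation-free potential for every (gene, loop, allele,
  helix) combination, with per-helix-residue attribution.
- **Structural validation** — atom-level CDR↔helix contact extraction from
  PDB files (4.5 Å van der Waals, 6.0 Å electrostatic with O–O admitted
  only via Ser/Thr/Tyr and N–N only via His), sidechain/backbone contact
  classes, 20×20 contact-count matrices, and seeded permutation tests
  comparing contact counts across potential bins.
- **Synthetic data** — seeded generators for repertoires with controlled
  per-column distributions and planted TCR↔MHC covariation, and for toy
  two-chain PDB files with contacts known by construction.

## Worked example

Score two TRBV genes against an HLA allele and break the potential down by
helix position:

```r
library(tcrmhc)

score_trigram_pair("NNK", "EDQ")
#> TCR:NNK vs MHC:EDQ -> [+1,+1,+1] valid (total 3)

tcr <- seq_records(c("TRBV6-5", "TRBV7-2"),
                   list(CDR1 = c("SGHNS", "SGDLS"),
                        CDR2 = c("YNNKEL", "YEEEEL")))
mhc <- seq_records("HLA-A*02:01",
                   list(helix1 = "EDQRKA", helix2 = "QASTEN"))

gene_allele_scores(tcr, mhc)
#>   tcr_gene loop  hla_allele  helix score
#> 1  TRBV6-5 CDR1 HLA-A*02:01 helix1    11
#> 2  TRBV7-2 CDR1 HLA-A*02:01 helix1     0
#> 3  TRBV6-5 CDR2 HLA-A*02:01 helix1    20
#> 4  TRBV7-2 CDR2 HLA-A*02:01 helix1    19
#> 5  TRBV6-5 CDR1 HLA-A*02:01 helix2     6
#> 6  TRBV7-2 CDR1 HLA-A*02:01 helix2     0
#> 7  TRBV6-5 CDR2 HLA-A*02:01 helix2    17
#> 8  TRBV7-2 CDR2 HLA-A*02:01 helix2     0
```

The trigram `NNK` against `EDQ` pairs asparagine with glutamate/aspartate
(hydrogen-bond capable, +1 each) and lysine with glutamine (+1): a valid
triad totalling +3. In the table, each score sums all valid triads between
one CDR loop and one helix: TRBV6-5 is broadly compatible with this
allele, while the glutamate-rich CDR2 of TRBV7-2 clashes with the acidic
helix1 everywhere except one register (score 19 vs 0 on helix2) and its
CDR1 makes no productive triads at all — the kind of gene-dependent
recognition strategy the potential is designed to expose.

```r
subset(per_residue_breakdown(tcr, mhc), helix == "helix1")
#>    helix position mean_score
#> 1 helix1        1       1.25
#> 2 helix1        2       2.50
#> 3 helix1        3       3.25
#> 4 helix1        4       3.50
#> 5 helix1        5       2.00
#> 6 helix1        6       0.00
```

Position 6 of the helix — the inert alanine — attributes exactly zero:
conserved G/A positions form the low-potential bands that constrain where
TCRs can productively engage.

Inputs normally come from FASTA files
(`read_family_fasta()` → `extract_family_regions()` →
`filter_productive_unique()` → `encode_repertoire()`), with region
positions taken from `inst/extdata/region_definitions.yaml`; `run_pipeline()`
drives the full encode → entropy → MI → biophysics → potential →
contacts → comparison chain from one config and writes CSVs plus a hashed
manifest.

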