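test_that("atoms classify into backbone and sidechain", {
  expect_equal(classify_atom("LYS", "CA"), "backbone")
  expect_equal(classify_atom("LYS", "NZ"), "sidechain")
  expect_equal(classify_atom("GLU", "OXT"), "backbone")
  expect_warning(cls <- classify_atom("LYS", "ZZ9"), "unrecognized")
  expect_equal(cls, "sidechain")
})

test_that("annotations validate ranges and file round-trip", {
  expect_error(complex_annotation(
    tcr = data.frame(chain = "A", loop = c("CDR1", "CDR2"),
                     start = c(1, 3), end = c(5, 8)),
    mhc = data.frame(chain = "B", helix = "helix1", start = 1, end = 9)),
    "overlapping")
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    tcr = list(list(chain = "A", loop = "CDR1", start = 1, end = 4)),
    mhc = list(list(chain = "B", helix = "helix1", start = 1, end = 4))),
    f, auto_unbox = TRUE)
  ann <- read_complex_annotation(f)
  expect_s3_class(ann, "complex_annotation")
  expect_equal(ann$tcr$end, 4L)
})

make_fixture <- function() {
  toy_complex_spec(
    planted = list(
      # electrostatic SC-SC (N-O at 5.0, beyond vdw)
      list(tcr_aa = "K", tcr_atom = "NZ", mhc_aa = "E", mhc_atom = "OE1",
           distance = 5.0),
      # O-O without S/T/Y: vdw only even at 3.0
      list(tcr_aa = "D", tcr_atom = "OD1", mhc_aa = "E", mhc_atom = "OE1",
           distance = 3.0),
      # O-O with Ser involved: electrostatic at 5.5
      list(tcr_aa = "S", tcr_atom = "OG", mhc_aa = "E", mhc_atom = "OE1",
           distance = 5.5),
      # N-N with His involved: electrostatic
      list(tcr_aa = "H", tcr_atom = "ND1", mhc_aa = "Q", mhc_atom = "NE2",
           distance = 5.8),
      # N-N without His: nothing beyond vdw range, vdw inside
      list(tcr_aa = "K", tcr_atom = "NZ", mhc_aa = "Q", mhc_atom = "NE2",
           distance = 4.0),
      # backbone-backbone vdw+electrostatic
      list(tcr_aa = "G", tcr_atom = "O", mhc_aa = "Q", mhc_atom = "N",
           distance = 4.2),
      # sidechain-backbone carbon pair: vdw only
      list(tcr_aa = "L", tcr_atom = "CD1", mhc_aa = "A", mhc_atom = "CA",
           distance = 4.4)),
    decoys = list(
      list(tcr_aa = "K", tcr_atom = "NZ", mhc_aa = "E", mhc_atom = "OE1",
           distance = 6.1),
      list(tcr_aa = "G", tcr_atom = "O", mhc_aa = "Q", mhc_atom = "N",
           distance = 6.5),
      list(tcr_aa = "S", tcr_atom = "OG", mhc_aa = "T", mhc_atom = "OG1",
           distance = 7.0)))
}

# identity of a contact set; distances checked separately because PDB
# coordinates are written at 3-decimal precision
contact_key <- function(d) {
  d <- d[order(d$tcr_resno, d$mhc_resno, d$contact_class, d$bond_type), ]
  paste(d$tcr_resno, d$mhc_resno, d$tcr_aa, d$mhc_aa, d$contact_class,
        d$bond_type)
}

contact_dists <- function(d) {
  d <- d[order(d$tcr_resno, d$mhc_resno, d$contact_class, d$bond_type), ]
  d$distance
}

test_that("toy fixtures reproduce planted contacts exactly", {
  tc <- generate_toy_complex(make_fixture())
  found <- find_contacts(tc$pdb_file, tc$annotation)
  expect_equal(contact_key(found), contact_key(tc$expected))
  expect_equal(contact_dists(found), contact_dists(tc$expected),
               tolerance = 0.01)
  # chemistry rules, spot checks
  expect_true(any(found$tcr_aa == "K" & found$mhc_aa == "E" &
                    found$bond_type == "electrostatic"))
  dd <- found[found$tcr_aa == "D", ]
  expect_equal(dd$bond_type, "vdw")  # O-O without S/T/Y never electrostatic
  expect_true(any(found$tcr_aa == "S" & found$bond_type == "electrostatic"))
  expect_true(any(found$tcr_aa == "H" & found$bond_type == "electrostatic"))
  kq <- found[found$tcr_aa == "K" & found$mhc_aa == "Q", ]
  expect_equal(kq$bond_type, "vdw")  # N-N without His
})

test_that("contact detection is invariant under rigid motion", {
  spec <- make_fixture()
  plain <- generate_toy_complex(spec)
  theta <- 0.7; phi <- 1.2
  rz <- matrix(c(cos(theta), -sin(theta), 0,
                 sin(theta), cos(theta), 0, 0, 0, 1), 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(phi), -sin(phi),
                 0, sin(phi), cos(phi)), 3, byrow = TRUE)
  moved <- generate_toy_complex(spec, rotation = rz %*% rx,
                                translation = c(15.5, -30.2, 7.7))
  a <- find_contacts(plain$pdb_file, plain$annotation)
  b <- find_contacts(moved$pdb_file, moved$annotation)
  expect_equal(contact_key(a), contact_key(b))
  expect_equal(contact_dists(a), contact_dists(b), tolerance = 0.01)
})

test_that("tightening cutoffs never increases contact counts", {
  tc <- generate_toy_complex(make_fixture())
  n_at <- function(vdw, elec) {
    nrow(find_contacts(tc$pdb_file, tc$annotation, vdw_cutoff = vdw,
                       elec_cutoff = elec))
  }
  vdws <- c(5.5, 4.5, 3.5, 2.5)
  elecs <- c(7.0, 6.0, 5.0, 4.0)
  counts <- mapply(n_at, vdws, elecs)
  expect_true(all(diff(counts) <= 0))
  # loosened cutoffs pick up the decoys
  expect_gt(n_at(4.5, 7.5), n_at(4.5, 6.0))
})

test_that("missing chains or residues are reported", {
  tc <- generate_toy_complex(make_fixture())
  bad <- complex_annotation(
    tcr = data.frame(chain = "Z", loop = "CDR1", start = 1, end = 5),
    mhc = data.frame(chain = "B", helix = "helix1", start = 1, end = 5))
  expect_error(find_contacts(tc$pdb_file, bad), "absent")
})

test_that("count matrices tabulate residue pairs and symmetrize as M + t(M)", {
  tc <- generate_toy_complex(make_fixture())
  rec <- find_contacts(tc$pdb_file, tc$annotation)
  cm <- contact_count_matrix(rec, classes = NULL)
  expect_equal(sum(cm$raw), nrow(rec))
  expect_equal(sum(cm$symmetrized), 2L * nrow(rec))
  expect_equal(cm$symmetrized, cm$raw + t(cm$raw))
  # SC-SC filter matches the fixture's sidechain-sidechain records
  sc <- contact_count_matrix(rec, classes = "SC-SC")
  expect_equal(sum(sc$raw), sum(rec$contact_class == "SC-SC"))
  expect_equal(sc$raw["E", "K"],
               sum(rec$tcr_aa == "K" & rec$mhc_aa == "E" &
                     rec$contact_class == "SC-SC"))
  empty <- contact_count_matrix(rec[0, ])
  expect_equal(sum(empty$raw), 0L)
})

test_that("per-column counts follow the alignment map, unmapped reported", {
  tc <- generate_toy_complex(make_fixture())
  rec <- find_contacts(tc$pdb_file, tc$annotation)
  sc <- rec[rec$contact_class == "SC-SC", ]
  map <- data.frame(chain = "B", resno = sort(unique(sc$mhc_resno))[1],
                    column = 10L)
  out <- per_residue_contact_counts(rec, map)
  expect_true("unmapped" %in% out$column)
  expect_equal(out$count[out$column == "10"],
               sum(sc$mhc_resno == map$resno))
  expect_equal(sum(out$count), nrow(sc))
})

test_that("potential binning defaults to tertiles", {
  x <- c(1, 2, 3, 10, 11, 12, 100, 110, 120)
  b <- potential_bins(x)
  expect_equal(as.vector(table(b)), c(3, 3, 3))
  expect_equal(levels(b), c("weak", "moderate", "strong"))
})

test_that("permutation test separates disjoint groups and not identical ones", {
  set.seed(51)
  same <- c(rep(5, 12), rep(5, 12))
  bins <- rep(c("weak", "strong"), each = 12)
  res_same <- group_comparison(same, bins, n_perm = 500, seed = 1)
  expect_gt(res_same$p_value, 0.9)

  apart <- c(rnorm(20, 0, 0.1), rnorm(20, 50, 0.1))
  res_apart <- group_comparison(apart, rep(c("weak", "strong"), each = 20),
                                n_perm = 2000, seed = 2)
  expect_lte(res_apart$p_value, 0.01)
})

test_that("permutation p-values are seeded and small bins are skipped", {
  set.seed(52)
  v <- rnorm(25)
  bins <- c(rep("weak", 12), rep("moderate", 12), "strong")
  expect_warning(res <- group_comparison(v, bins, n_perm = 200, seed = 3),
                 "skipped")
  expect_equal(nrow(res), 1L)  # only weak vs moderate survives
  res2 <- suppressWarnings(group_comparison(v, bins, n_perm = 200, seed = 3))
  expect_equal(res$p_value, res2$p_value)
  expect_error(suppressWarnings(
    group_comparison(v[1:3], c("a", "a", "b"), 100, seed = 1)),
    "at least two bins")
})
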