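test_that("residue classes partition the 20 amino acids", {
  cls <- residue_classes()
  expect_equal(sort(names(cls)), sort(aa_alphabet()))
  expect_equal(length(cls), 20L)
  expect_setequal(unique(cls), c("positive", "negative", "hydrophilic",
                                 "hydrophobic", "noninteracting"))
})

test_that("the default matrix applies the class-pair rules symmetrically", {
  m <- default_interaction_matrix()
  expect_equal(m["K", "E"], 2L)       # salt bridge
  expect_equal(m["E", "K"], 2L)
  expect_equal(max(abs(m - t(m))), 0L)
  expect_true(all(m[c("G", "A", "P"), ] == 0L))  # noninteracting rows
  # sign structure: pos x neg > 0, like charge < 0, phil x phob < 0
  expect_gt(m["K", "D"], 0)
  expect_lt(m["K", "R"], 0)
  expect_lt(m["D", "E"], 0)
  expect_lt(m["S", "L"], 0)
  # ordering sanity across rule magnitudes
  expect_gt(m["K", "E"], m["S", "T"])
  expect_gt(m["S", "T"], 0)
  expect_gt(0, m["S", "F"])
  expect_gt(m["S", "F"], m["K", "R"])
})

test_that("building with incomplete rules fails", {
  rules <- interaction_rules()
  expect_error(build_interaction_matrix(rules = rules[-1, ]),
               "missing class pair")
})

test_that("the anchored trigram cases score as printed", {
  a <- score_trigram_pair("NNK", "EDQ")
  expect_equal(a$pair_scores, c(1L, 1L, 1L))
  expect_true(a$valid)
  expect_equal(a$total, 3L)

  b <- score_trigram_pair("KEL", "RKA")
  expect_equal(b$pair_scores, c(-2L, 2L, 0L))
  expect_false(b$valid)
  expect_equal(b$total, 0L)

  g <- score_trigram_pair("GGG", "GGG")
  expect_equal(g$pair_scores, c(0L, 0L, 0L))
  expect_false(g$valid)
  expect_equal(g$total, 0L)
})

test_that("the matrix self-check rejects a rule set breaking the anchors", {
  rules <- interaction_rules()
  rules$score[rules$class1 == "positive" & rules$class2 == "negative"] <- 1L
  expect_error(build_interaction_matrix(rules = rules), "anchored")
  expect_silent(build_interaction_matrix())
})

test_that("nonstandard residues score zero without raising", {
  s <- score_trigram_pair("NXK", "EDQ")
  expect_equal(s$pair_scores[2], 0L)
  expect_false(s$valid)
  expect_error(score_trigram_pair("NK", "EDQ"), "length 3")
})

test_that("the alternative no-negative validity reproduces the anchors", {
  a <- score_trigram_pair("NNK", "EDQ", validity = "no_negative")
  expect_true(a$valid)
  b <- score_trigram_pair("KEL", "RKA", validity = "no_negative")
  expect_false(b$valid)
})

test_that("loop/helix potential equals exhaustive enumeration", {
  p <- loop_helix_potential("YNNKEL", "EDQRKA")
  expect_equal(p$score, oracle_potential("YNNKEL", "EDQRKA"))
  # attribution conserves the total
  expect_equal(sum(p$attribution), p$score)
})

test_that("potential matches the brute-force oracle on random pairs", {
  set.seed(41)
  for (k in 1:200) {
    loop <- random_aa_string(sample(3:10, 1))
    helix <- random_aa_string(sample(3:10, 1))
    p <- loop_helix_potential(loop, helix)
    expect_equal(p$score, oracle_potential(loop, helix))
    expect_equal(sum(p$attribution), p$score)
  }
})

test_that("potential is symmetric in roles and monotone in loop length", {
  set.seed(42)
  for (k in 1:25) {
    loop <- random_aa_string(sample(3:8, 1))
    helix <- random_aa_string(sample(3:8, 1))
    expect_equal(loop_helix_potential(loop, helix)$score,
                 loop_helix_potential(helix, loop)$score)
    longer <- paste0(loop, random_aa_string(2))
    expect_gte(loop_helix_potential(longer, helix)$score,
               loop_helix_potential(loop, helix)$score)
  }
})

test_that("degenerate and noninteracting inputs give zero potential", {
  expect_warning(p <- loop_helix_potential("NK", "EDQRKA"), "trigram")
  expect_equal(p$score, 0L)
  expect_equal(loop_helix_potential("YNNKEL", "AAAAAA")$score, 0L)
})

test_that("per-pair normalization divides by the trigram-pair count", {
  raw <- loop_helix_potential("YNNKEL", "EDQRKA")
  norm <- loop_helix_potential("YNNKEL", "EDQRKA", normalize = TRUE)
  expect_equal(norm$score, raw$score / 16)
})

test_that("gene/allele score tables cover the full cross-product", {
  tab <- gene_allele_scores(toy_tcr_records(), toy_mhc_records())
  expect_equal(nrow(tab), 2 * 2 * 2 * 2)
  one <- gene_allele_scores(toy_tcr_records()[1, ], toy_mhc_records()[1, ])
  expect_equal(nrow(one), 4L)  # 2 loops x 2 helices
  expect_true(all(tab$score >= 0))
  # invariant to record order
  tab2 <- gene_allele_scores(toy_tcr_records()[2:1, ],
                             toy_mhc_records()[2:1, ])
  key <- function(d) d[order(d$tcr_gene, d$loop, d$hla_allele, d$helix), ]
  expect_equal(key(tab2)$score, key(tab)$score)
  expect_error(gene_allele_scores(toy_tcr_records()[0, ],
                                  toy_mhc_records()), "empty")
})

test_that("45 x 48 productive genes enumerate 2160 pairings", {
  trav <- seq_records(sprintf("TRAV%d", 1:45), list(CDR1 = rep("AAA", 45)),
                      family = "TRAV")
  trbv <- seq_records(sprintf("TRBV%d", 1:48), list(CDR1 = rep("AAA", 48)),
                      family = "TRBV")
  expect_equal(nrow(gene_pairings(trav, trbv)), 2160L)
})

test_that("helix distributions aggregate per gene x allele means", {
  tab <- gene_allele_scores(toy_tcr_records(), toy_mhc_records())
  groups <- c("HLA-X*01:01" = "HLA-A", "HLA-X*02:01" = "HLA-A")
  hd <- helix_distributions(tab, groups)
  # one value per gene x allele per helix
  expect_equal(nrow(hd$distributions), 2 * 2 * 2)
  expect_equal(unique(hd$summary$n), 4L)
  # single gene, single allele: distribution of size 1 = loop mean
  hd1 <- helix_distributions(
    gene_allele_scores(toy_tcr_records()[1, ], toy_mhc_records()[1, ]),
    groups)
  expect_equal(nrow(hd1$distributions), 2L)
  sub <- tab[tab$tcr_gene == "TRBVX-1" & tab$hla_allele == "HLA-X*01:01" &
               tab$helix == "helix1", ]
  expect_equal(
    hd1$distributions$mean_score[hd1$distributions$helix == "helix1"],
    mean(sub$score))
  expect_error(helix_distributions(tab, c("HLA-X*01:01" = "HLA-A")),
               "no group")
})

test_that("planted class-composition shift orders group medians", {
  set.seed(43)
  tcr <- seq_records(paste0("g", 1:6),
                     list(CDR1 = replicate(6, random_aa_string(5)),
                          CDR2 = replicate(6, random_aa_string(5))))
  # strong group: hydrophilic helices (productive vs most loops);
  # weak group: noninteracting helices
  strong <- seq_records(paste0("s", 1:4),
                        list(helix1 = rep("SNQTSN", 4),
                             helix2 = rep("TQNSTQ", 4)))
  weak <- seq_records(paste0("w", 1:4),
                      list(helix1 = rep("AGAGAG", 4),
                           helix2 = rep("GAPAGA", 4)))
  mhc <- rbind(strong, weak)
  class(mhc) <- class(strong)
  tab <- gene_allele_scores(tcr, mhc)
  groups <- setNames(rep(c("strong", "weak"), each = 4), mhc$id)
  hd <- helix_distributions(tab, groups)
  med <- tapply(hd$distributions$mean_score, hd$distributions$group,
                median)
  expect_gt(med["strong"], med["weak"])
})

test_that("per-residue breakdown conserves the mean potential", {
  tcr <- toy_tcr_records()
  mhc <- toy_mhc_records()[1, ]
  bd <- per_residue_breakdown(tcr, mhc)
  for (h in c("helix1", "helix2")) {
    pots <- c(loop_helix_potential(tcr$CDR1[1], mhc[[h]][1])$score,
              loop_helix_potential(tcr$CDR1[2], mhc[[h]][1])$score,
              loop_helix_potential(tcr$CDR2[1], mhc[[h]][1])$score,
              loop_helix_potential(tcr$CDR2[2], mhc[[h]][1])$score)
    expect_equal(sum(bd$mean_score[bd$helix == h]), mean(pots))
  }
})

test_that("per-residue breakdown equals a hand-enumerated toy case", {
  # 2 genes, 1 loop, 1 helix of width 4: attribute by hand
  tcr <- seq_records(c("g1", "g2"), list(CDR1 = c("KDS", "NNK")))
  mhc <- seq_records("a1", list(helix1 = "EDQR"))
  m <- default_interaction_matrix()
  manual <- numeric(4)
  n <- 0
  for (loop in tcr$CDR1) {
    for (j in 1:2) {
      tri_m <- substr("EDQR", j, j + 2)
      ts <- score_trigram_pair(loop, tri_m, m)
      if (ts$valid) manual[j:(j + 2)] <- manual[j:(j + 2)] + ts$pair_scores
    }
    n <- n + 1
  }
  bd <- per_residue_breakdown(tcr, mhc, loops = "CDR1",
                              helices = "helix1")
  expect_equal(bd$mean_score, manual / n)
})

test_that("conserved noninteracting helix columns attribute exactly zero", {
  tcr <- toy_tcr_records()
  mhc <- seq_records(c("a1", "a2"), list(helix1 = c("EDQAKE", "QNEAST")))
  bd <- per_residue_breakdown(tcr, mhc, helices = "helix1")
  expect_equal(bd$mean_score[bd$position == 4], 0)  # A/A column
})

test_that("relu normalization clamps negatives and is idempotent", {
  expect_equal(relu_normalize(c(-2, 2, 0)), c(0, 2, 0))
  m <- matrix(c(-1, 3, 0, -5), 2, dimnames = list(c("a", "b"), NULL))
  r <- relu_normalize(m)
  expect_equal(r, relu_normalize(r))
  expect_equal(dimnames(r), dimnames(m))
  allpos <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(relu_normalize(allpos), allpos)
})
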