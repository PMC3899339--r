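test_that("CAI is the geometric mean of included codon weights", {
  w <- c(AAA = 1, GAA = 0.25, GAT = 0.5)
  expect_equal(compute_cai(c("AAA", "AAA"), c(AAA = 1)), 1.0)
  expect_equal(compute_cai(c("AAA", "GAA"), w), 0.5)       # sqrt(1 * 0.25)
  expect_equal(compute_cai("GAT", w), 0.5)                  # single codon
  # order invariance (geometric mean symmetry)
  cds <- c("AAA", "GAA", "GAT", "GAA")
  expect_equal(compute_cai(cds, w), compute_cai(rev(cds), w))
  # stop codons and single-codon families are excluded
  expect_equal(compute_cai(c("AAA", "TAA", "ATG", "TGG"), w), 1.0)
  expect_error(compute_cai(c("TAA", "ATG"), w), "no codons")
  expect_error(compute_cai("CCC", w), "CCC")
})

test_that("reference-set weights are relative adaptiveness within synonymous families", {
  # Lys family AAA/AAG: 3 vs 1 usage -> weights 1 and 1/3
  seqs <- c(g1 = "AAAAAAAAGAAA")
  w <- cai_weights(seqs)
  expect_equal(unname(w["AAA"]), 1)
  expect_equal(unname(w["AAG"]), 1 / 3)
  expect_true(all(w > 0 & w <= 1))
})

test_that("DoC aggregates score over length and DoT takes the top-scoring domain", {
  one <- data.frame(domain_id = "D1", bit_score = 100, domain_length = 200)
  expect_equal(compute_doc(one), 0.5)
  two <- data.frame(domain_id = c("D1", "D2"), bit_score = c(50, 30),
                    domain_length = c(100, 60))
  expect_equal(compute_doc(two), 0.5)  # 80 / 160
  none <- two[0, ]
  expect_true(is.na(compute_doc(none)))
  expect_true(is.na(compute_dot(none)))
  expect_equal(compute_dot(data.frame(domain_id = c("D2", "D1"),
                                      bit_score = c(40, 90),
                                      domain_length = c(10, 10))), "D1")
  # tie broken lexicographically
  expect_equal(compute_dot(data.frame(domain_id = c("D2", "D1"),
                                      bit_score = c(50, 50),
                                      domain_length = c(10, 10))), "D1")
  expect_error(compute_doc(data.frame(domain_id = "D1", bit_score = 5,
                                      domain_length = 0)), "domain_length")
  # scale consistency: doubling scores doubles DoC
  expect_equal(compute_doc(transform(two, bit_score = 2 * bit_score)),
               2 * compute_doc(two))
  # best-hit reading of the score/length ratio
  mixed <- data.frame(domain_id = c("D1", "D2"), bit_score = c(90, 10),
                      domain_length = c(100, 100))
  expect_equal(compute_doc(mixed), 0.5)
  expect_equal(compute_doc(mixed, method = "best"), 0.9)
})

test_that("the curated rule-based selections ship as a loadable reference table", {
  path <- system.file("extdata", "rule_selected_training_sets.tsv",
                      package = "essTransfer")
  ref <- read_tsv(path)
  expect_equal(dim(ref), c(20L, 5L))
  expect_equal(unlist(ref[ref$test_species == "ECO", -1], use.names = FALSE),
               c("STY", "PAU", "BSU", "CCS"))
  expect_false(any(vapply(seq_len(nrow(ref)),
                          function(i) ref$test_species[i] %in% unlist(ref[i, -1]),
                          logical(1))))
})

test_that("centralities match hand-derived values on canonical graphs", {
  k3 <- graph_centralities(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")),
                           nodes = c("A", "B", "C"))
  expect_equal(k3$DC, rep(1, 3))
  expect_equal(k3$CCo, rep(1, 3))
  expect_equal(k3$CC, rep(1, 3))
  expect_equal(k3$BC, rep(0, 3))

  path <- graph_centralities(data.frame(a = c("A", "B"), b = c("B", "C")),
                             nodes = c("A", "B", "C"))
  b <- path[path$gene_id == "B", ]
  expect_equal(unlist(b[c("DC", "CCo", "CC", "BC")]),
               c(DC = 1, CCo = 0, CC = 1, BC = 1))

  iso <- graph_centralities(data.frame(a = "A", b = "B"), nodes = c("A", "B", "X"))
  expect_equal(unlist(iso[iso$gene_id == "X", c("DC", "CCo", "CC", "BC")]),
               c(DC = 0, CCo = 0, CC = 0, BC = 0))

  expect_error(graph_centralities(data.frame(a = "A", b = "Z"), nodes = c("A", "B")),
               "absent")
  expect_message(graph_centralities(data.frame(a = c("A", "A", "A"),
                                               b = c("B", "B", "A")),
                                    nodes = c("A", "B")), "dropped")
})

test_that("paralog counts deduplicate edges and ignore self-hits", {
  edges <- data.frame(a = c("g1", "g1", "g1", "g2", "g3"),
                      b = c("g2", "g3", "g4", "g1", "g3"))
  expect_equal(unname(paralog_count(edges, "g1")), 3L)
  expect_equal(unname(paralog_count(edges, "g5")), 0L)
  dup <- data.frame(a = c("g1", "g2"), b = c("g2", "g1"))
  expect_equal(unname(paralog_count(dup, "g1")), 1L)
})

test_that("cross-species homology counts respect labels and species exclusion", {
  gene_species <- c(t1 = "A", e1 = "B", e2 = "B", e3 = "C", u1 = "D", p1 = "A")
  omap <- data.frame(a = c("t1", "t1", "t1", "t1", "t1"),
                     b = c("e1", "e2", "e3", "u1", "p1"))
  labels <- list(B = c(e1 = 1L, e2 = 0L), C = c(e3 = 1L))
  cnt <- cross_species_homology_counts(omap, gene_species, labels, "t1")
  expect_equal(cnt, c(NS = 3L, NEH = 2L, NNH = 1L))  # own-species p1 excluded
  expect_equal(cross_species_homology_counts(omap[0, ], gene_species, labels, "t1"),
               c(NS = 0L, NEH = 0L, NNH = 0L))
  # removing a species never increases any count (monotonicity)
  cnt2 <- cross_species_homology_counts(omap, gene_species, labels["C"], "t1")
  expect_true(all(cnt2 <= cnt))
  omap2 <- omap[!(omap$b %in% c("e1", "e2")), ]
  gs2 <- gene_species[setdiff(names(gene_species), c("e1", "e2"))]
  cnt3 <- cross_species_homology_counts(omap2, gs2, labels, "t1")
  expect_true(all(cnt3 <= cnt))
})

test_that("phyletic age is the outermost clade with a homolog", {
  clades <- c("species typical", "Ascomycota", "Opisthokonta", "Eukaryota",
              "cellular organisms")
  expect_equal(phyletic_age(c(TRUE, FALSE, FALSE, FALSE, FALSE), clades), 1L)
  expect_equal(phyletic_age(rep(TRUE, 5), clades), 5L)
  # gaps don't matter: outermost positive clade wins
  expect_equal(phyletic_age(c(TRUE, FALSE, FALSE, FALSE, TRUE), clades), 5L)
  expect_equal(phyletic_age(rep(FALSE, 5), clades), 1L)
  expect_equal(phyletic_age(c("Ascomycota"), clades), 2L)
  expect_error(phyletic_age(TRUE, character(0)), "clade_order")
})

test_that("expression stats use the n-1 coefficient of variation", {
  expect_equal(expression_stats(c(5, 5, 5)), c(mE = 5, mEF = 0))
  expect_equal(expression_stats(c(2, 4)), c(mE = 3, mEF = sqrt(2) / 3))
  expect_equal(expression_stats(7), c(mE = 7, mEF = NA_real_))
  expect_equal(expression_stats(c(NA_real_, NA_real_)),
               c(mE = NA_real_, mEF = NA_real_))
  expect_true(is.na(expression_stats(c(-2, 0, 2))[["mEF"]]))  # mean <= 0
})

test_that("the assembled feature table has the full 15-feature schema", {
  genes <- sprintf("g%02d", 1:20)
  cdna <- setNames(rep("ATGAAAGAAGATTAA", 20), genes)  # 5 codons incl stop
  expr <- matrix(rexp(40, 1 / 50), nrow = 20, dimnames = list(genes, c("c1", "c2")))
  hits <- data.frame(gene_id = c("g01", "g01", "g02"),
                     domain_id = c("PF1", "PF2", "PF1"),
                     bit_score = c(50, 30, 80), domain_length = c(100, 60, 100))
  ppi <- data.frame(a = c("g01", "g02"), b = c("g02", "g03"))
  tab <- build_feature_table("SPX", genes,
                             domain_hits = hits,
                             ppi_edges = ppi, ppi_nodes = genes[1:10],
                             cdna = cdna, expression = expr,
                             paralog_edges = data.frame(a = "g01", b = "g04"),
                             clade_presence = matrix(TRUE, 20, 2,
                                                     dimnames = list(genes, c("inner", "outer"))),
                             clade_order = c("inner", "outer"))
  expect_equal(ncol(tab), 17L)
  expect_equal(names(tab)[1:2], c("gene_id", "species_id"))
  expect_setequal(setdiff(names(tab), c("gene_id", "species_id")),
                  c("mE", "mEF", "Age", "DoT", "DoC", "DC", "CCo", "CC", "BC",
                    "PL", "CAI", "NP", "NS", "NEH", "NNH"))
  expect_equal(tab$DoC[tab$gene_id == "g01"], 0.5)
  expect_equal(tab$PL[1], 4)  # 15 nt / 3 - 1
  # inside the PPI node universe but unconnected -> centralities 0
  expect_equal(tab$DC[tab$gene_id == "g05"], 0)
  # outside the node universe -> missing
  expect_true(is.na(tab$DC[tab$gene_id == "g15"]))
  expect_error(build_feature_table("SPX", c("g1", "g1")), "duplicated")

  # empty expression input leaves mE/mEF missing but the table valid
  tab2 <- build_feature_table("SPX", genes, expression = NULL)
  expect_true(all(is.na(tab2$mE)))
  expect_equal(nrow(tab2), 20L)
})
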