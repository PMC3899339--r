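test_that("integrated-set enumeration matches binomial coefficients", {
  pool19 <- sprintf("S%02d", 1:19)
  expect_length(enumerate_integrated_sets(pool19, 2), 171)
  expect_length(enumerate_integrated_sets(pool19, 3), 969)
  expect_length(enumerate_integrated_sets(letters[1:3], 3), 1)
  expect_error(enumerate_integrated_sets(letters[1:3], 4), "pool size")
  expect_error(enumerate_integrated_sets(letters[1:3], 0), "pool size")
  for (case in list(c(7, 3), c(12, 5), c(20, 4), c(5, 1))) {
    pool <- sprintf("x%02d", seq_len(case[1]))
    combos <- enumerate_integrated_sets(pool, case[2])
    expect_length(combos, choose(case[1], case[2]))
    expect_false(anyDuplicated(vapply(combos, paste, character(1), collapse = "+")) > 0)
  }
  # deterministic lexicographic order
  expect_identical(enumerate_integrated_sets(c("b", "a", "c"), 2),
                   list(c("a", "b"), c("a", "c"), c("b", "c")))
})

test_that("incomplete-training curves are reproducible and improve with size", {
  corpus <- make_corpus(2, 600, seed = 91, essential_fraction = 0.2)$datasets
  cur1 <- incomplete_training_curve(corpus$S01, fractions = c(0.05, 0.4),
                                    reps = 10, seed = 5)
  cur2 <- incomplete_training_curve(corpus$S01, fractions = c(0.05, 0.4),
                                    reps = 10, seed = 5)
  expect_identical(cur1, cur2)
  expect_equal(cur1$reps, c(10, 10))
  # more training data should not hurt on average
  expect_gte(cur1$mean_auc[2], cur1$mean_auc[1] - 0.01)
  expect_error(incomplete_training_curve(corpus$S01, fractions = c(0.5, 0.9)),
               "fraction")
  expect_error(incomplete_training_curve(corpus$S01, fractions = c(0.4, 0.2)),
               "increasing")
})

test_that("HASTS/LASTS split generalizes the 9-of-19 top share", {
  set.seed(2)
  a19 <- setNames(runif(19, 0.5, 1), sprintf("S%02d", 1:19))
  sp19 <- hasts_lasts_split(a19)
  expect_length(sp19$hasts, 9)
  expect_length(sp19$lasts, 10)
  expect_true(min(a19[sp19$hasts]) > max(a19[sp19$lasts]))
  expect_true(sp19$threshold > max(a19[sp19$lasts]) &&
              sp19$threshold < min(a19[sp19$hasts]))
  sp4 <- hasts_lasts_split(c(w = 0.9, x = 0.8, y = 0.7, z = 0.6))
  expect_identical(sp4$hasts, c("w", "x"))  # ceiling(4 * 9/19) = 2
  # all-equal scores: deterministic id tie-break
  eq <- hasts_lasts_split(setNames(rep(0.8, 4), c("d", "b", "a", "c")))
  expect_identical(eq$hasts, c("a", "b"))
})

test_that("integration of a single species reduces to the matrix entry", {
  corpus <- make_corpus(3, 300, seed = 101)$datasets
  M <- cross_species_matrix(corpus)
  res <- integrated_performance(corpus, list("S02"), "S01")
  expect_equal(res$auc, unname(M["S02", "S01"]), tolerance = 1e-12)
  expect_error(integrated_performance(corpus, list(c("S01", "S02")), "S01"),
               "contains the testing species")
})

test_that("integrating a dataset with its own duplicate changes little", {
  corpus <- make_corpus(3, 400, seed = 111, missing_rate = 0)$datasets
  dup <- corpus$S02
  dup$species_id <- "S02b"
  dup$features$species_id <- "S02b"
  corpus$S02b <- dup
  single <- integrated_performance(corpus, list("S02"), "S01", alpha = 0)$auc
  doubled <- integrated_performance(corpus, list(c("S02", "S02b")), "S01",
                                    alpha = 0)$auc
  expect_lt(abs(single - doubled), 0.01)
})

test_that("group comparison partitions all k-subsets into high/low/mixed", {
  corpus <- make_corpus(9, 150, seed = 121,
                        label_noise = c(0, 0, 0, 0, 0.05, 0.2, 0.3, 0.3, 0.3))$datasets
  singles <- integrated_performance(
    corpus, as.list(setdiff(names(corpus), "S01")), "S01")
  aucs <- setNames(singles$auc, singles$combo)
  spl <- hasts_lasts_split(aucs)
  gc <- group_comparison(corpus, spl$hasts, spl$lasts, k = 3, "S01")
  expect_length(gc$high, choose(length(spl$hasts), 3))
  expect_length(gc$low, choose(length(spl$lasts), 3))
  expect_length(gc$mixed, choose(8, 3) - length(gc$high) - length(gc$low))
  expect_true(all(c(gc$high, gc$low, gc$mixed) >= 0 &
                  c(gc$high, gc$low, gc$mixed) <= 1))
  # canonical pool arithmetic: 9/10 split at k = 4
  expect_equal(choose(9, 4), 126)
  h <- enumerate_integrated_sets(sprintf("h%d", 1:9), 4)
  l <- enumerate_integrated_sets(sprintf("l%d", 1:10), 4)
  all19 <- enumerate_integrated_sets(c(sprintf("h%d", 1:9), sprintf("l%d", 1:10)), 4)
  expect_length(h, 126)
  expect_length(l, 210)
  expect_length(all19, 3876)
  expect_equal(length(all19) - length(h) - length(l), 3540)
})

test_that("integration rescues a noisy training set", {
  corpus <- make_corpus(5, 400, seed = 131, drift_sigma = 0,
                        label_noise = c(0.35, 0, 0, 0, 0))$datasets
  noisy_alone <- integrated_performance(corpus, list("S01"), "S05")$auc
  rescued <- integrated_performance(corpus, list(c("S01", "S02", "S03", "S04")),
                                    "S05")$auc
  expect_gt(rescued, noisy_alone)
})

test_that("permutation p-values match exceedance proportions at the extremes", {
  corpus <- make_corpus(5, 150, seed = 141)$datasets
  rule <- c("S02", "S03", "S04")
  lo <- random_integration_pvalue(corpus, "S01", rule, n_sims = 50,
                                  mode = "sampled", seed = 1,
                                  null_scores = rep(0, 25))
  expect_equal(lo$p_value, 0)
  hi <- random_integration_pvalue(corpus, "S01", rule, n_sims = 50,
                                  mode = "sampled", seed = 1,
                                  null_scores = rep(1, 25))
  expect_equal(hi$p_value, 1)
  ex <- random_integration_pvalue(corpus, "S01", rule, mode = "exact")
  expect_equal(ex$n_sims, choose(4, 3))
  expect_equal(ex$p_value, mean(ex$sims > ex$threshold))
  expect_error(random_integration_pvalue(corpus, "S01", rule, n_sims = 0),
               "n_sims")
  expect_error(random_integration_pvalue(corpus, "S01", c("S01", "S02", "S03")),
               "exclude")
})

test_that("rule-based selection ranks by the four weighted criteria", {
  md <- data.frame(
    species_id = c("TGT", "TWIN", "FAR", "LOWQ", "DIFF", "COND"),
    quality_tier = c("deletion", "deletion", "deletion", "inferred",
                     "deletion", "deletion"),
    growth_condition = c("rich", "rich", "rich", "rich", "rich", "minimal"),
    gram = c("neg", "neg", "neg", "neg", "pos", "neg"),
    oxygen = c("aerobe", "aerobe", "aerobe", "aerobe", "anaerobe", "aerobe"),
    shape = c("rod", "rod", "rod", "rod", "coccus", "rod"),
    stringsAsFactors = FALSE)
  sp <- md$species_id
  D <- matrix(2000, 6, 6, dimnames = list(sp, sp))
  diag(D) <- 0
  D["TGT", "TWIN"] <- D["TWIN", "TGT"] <- 1e-9
  sel <- rule_based_select(md, D, "TGT", n = 2)
  expect_equal(sel$selected[1], "TWIN")  # dominates every criterion

  # hand-computed weighted scores (equal weights, dmax = 2000):
  # TWIN: (1 + 1 + 1 + 1)/4 = 1;  FAR: (1 + 1 + 0 + 1)/4 = 0.75
  # LOWQ: (0 + 1 + 0 + 1)/4 = 0.5; COND: (1 + 0 + 0 + 1)/4 = 0.5
  # DIFF: (1 + 1 + 0 + 0)/4 = 0.5
  r <- sel$ranking
  expect_equal(r$score[r$species_id == "TWIN"], 1, tolerance = 1e-6)
  expect_equal(r$score[r$species_id == "FAR"], 0.75)
  expect_equal(r$score[r$species_id == "LOWQ"], 0.5)
  # ties broken by ascending id: COND < DIFF < LOWQ
  expect_identical(r$species_id, c("TWIN", "FAR", "COND", "DIFF", "LOWQ"))

  # single-criterion monotonicity: only quality differs
  md2 <- md[md$species_id %in% c("TGT", "FAR", "LOWQ"), ]
  sel2 <- rule_based_select(md2, D, "TGT", n = 1)
  expect_equal(sel2$selected, "FAR")

  # candidates with missing metadata are excluded with a warning
  md3 <- md
  md3$gram[md3$species_id == "FAR"] <- NA
  expect_warning(sel3 <- rule_based_select(md3, D, "TGT", n = 2), "FAR")
  expect_false("FAR" %in% sel3$ranking$species_id)
})

test_that("Welch comparison of AUC groups returns a standard htest", {
  t <- welch_auc_test(c(0.9, 0.92, 0.91), c(0.8, 0.82, 0.81))
  expect_s3_class(t, "htest")
  expect_lt(t$p.value, 0.05)
})
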