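# pre-normalize every dataset once so repeated fits skip the rank transform
prenormalize_corpus <- function(datasets, normalize) {
  lapply(datasets, function(d) {
    d$features <- normalize_features(d$features, normalize)
    d
  })
}

#' Incomplete-training-set learning curve
#'
#' Within one species, measures predictive accuracy as a function of
#' training-set size. Each replicate draws a stratified 20% testing set,
#' then for every requested fraction draws a training subset of that
#' fraction *of the total genes* from the remaining 80%, fits the
#' classifier, and records AUC and PPV at k on the testing set. Replicates
#' are seeded independently and reproducibly. A training draw that happens
#' to be single-class is redrawn (up to 100 attempts).
#'
#' @param dataset a `species_dataset` with both classes present.
#' @param fractions strictly increasing training fractions of total genes,
#'   each at most `1 - test_fraction`.
#' @param reps number of replicates.
#' @param test_fraction held-out share (default 0.2).
#' @param ppv_k top-k cutoff for PPV; default `min(200, testing-set size)`.
#' @param seed integer seed.
#' @param normalize,alpha,var_floor classifier settings, see [fit_nb()].
#' @return data frame with one row per fraction: `fraction`, `mean_auc`,
#'   `sd_auc`, `mean_ppv`, `sd_ppv`, `reps`.
#' @export
incomplete_training_curve <- function(dataset,
                                      fractions = c(seq(0.01, 0.10, by = 0.01),
                                                    0.15, seq(0.2, 0.8, by = 0.1)),
                                      reps = 1000, test_fraction = 0.2,
                                      ppv_k = NULL, seed = 1,
                                      normalize = "rank", alpha = 1,
                                      var_floor = 1e-9) {
  stopifnot(inherits(dataset, "species_dataset"))
  if (any(diff(fractions) <= 0)) stop_invalid("`fractions` must be strictly increasing")
  if (any(fractions <= 0) || any(fractions > 1 - test_fraction + 1e-12)) {
    stop_invalid("each fraction must be in (0, 1 - test_fraction]")
  }
  y <- dataset$labels$essential
  if (length(unique(y)) < 2L) stop_invalid("dataset has a single class")
  n <- length(y)
  feats <- normalize_features(dataset$features, normalize)
  pos <- which(y == 1L); neg <- which(y == 0L)
  n_test_pos <- round(test_fraction * length(pos))
  n_test_neg <- round(test_fraction * length(neg))
  if (n_test_pos < 1L || n_test_neg < 1L) {
    stop_invalid("testing fraction leaves no genes of one class")
  }

  auc_mat <- matrix(NA_real_, reps, length(fractions))
  ppv_mat <- matrix(NA_real_, reps, length(fractions))
  for (r in seq_len(reps)) {
    draws <- with_seed(seed_stream(seed, "curve-rep", r), {
      test_idx <- c(sample(pos, n_test_pos), sample(neg, n_test_neg))
      pool <- setdiff(seq_len(n), test_idx)
      train_sets <- vector("list", length(fractions))
      for (fi in seq_along(fractions)) {
        m <- min(round(fractions[fi] * n), length(pool))
        for (attempt in seq_len(100L)) {
          idx <- sample(pool, m)
          if (length(unique(y[idx])) == 2L) break
          idx <- NULL
        }
        if (is.null(idx)) {
          stop_invalid("could not draw a two-class training set at fraction %.3f",
                       fractions[fi])
        }
        train_sets[[fi]] <- idx
      }
      list(test = test_idx, train = train_sets)
    })
    test_feats <- feats[draws$test, , drop = FALSE]
    y_test <- y[draws$test]
    k <- ppv_k %||% min(200L, length(draws$test))
    for (fi in seq_along(fractions)) {
      idx <- draws$train[[fi]]
      ds <- species_dataset(dataset$species_id,
                            feats[idx, , drop = FALSE],
                            dataset$labels[idx, , drop = FALSE])
      fit <- fit_nb(ds, alpha = alpha, var_floor = var_floor, normalize = "none")
      s <- score_genes(fit, test_feats)
      auc_mat[r, fi] <- auc(s, y_test)
      ppv_mat[r, fi] <- ppv_at_k(s, y_test, k)
    }
  }
  data.frame(fraction = fractions,
             mean_auc = colMeans(auc_mat), sd_auc = apply(auc_mat, 2, stats::sd),
             mean_ppv = colMeans(ppv_mat), sd_ppv = apply(ppv_mat, 2, stats::sd),
             reps = reps)
}

#' Enumerate integrated training sets
#'
#' All k-subsets of a species pool, in deterministic lexicographic order of
#' the sorted pool.
#'
#' @param pool character vector of species ids.
#' @param k subset size, `1 <= k <= length(pool)`.
#' @return list of character vectors, `choose(length(pool), k)` of them.
#' @examples
#' length(enumerate_integrated_sets(paste0("S", 1:10), 4))  # 210
#' @export
enumerate_integrated_sets <- function(pool, k) {
  if (k < 1 || k > length(pool)) {
    stop_invalid("`k` must be between 1 and the pool size (%d)", length(pool))
  }
  utils::combn(sort(pool), k, simplify = FALSE)
}

combo_key <- function(combo) paste(sort(combo), collapse = "+")

#' Performance of integrated training sets
#'
#' For each combination of species, pools their (per-species normalized)
#' feature tables and labels into one training set, fits the classifier,
#' scores the testing species, and records the transfer AUC.
#'
#' @param datasets named list of `species_dataset` objects.
#' @param combos list of character vectors (e.g. from
#'   [enumerate_integrated_sets()]); a length-1 combo reduces to the
#'   non-integrated case.
#' @param test_species species to predict; must not appear in any combo.
#' @param normalize,alpha,var_floor classifier settings.
#' @return data frame with `combo` (ids joined by `+`), `k`, and `auc`.
#' @export
integrated_performance <- function(datasets, combos, test_species,
                                   normalize = "rank", alpha = 1,
                                   var_floor = 1e-9) {
  if (!test_species %in% names(datasets)) stop_invalid("unknown test species %s", test_species)
  if (any(vapply(combos, function(cb) test_species %in% cb, logical(1)))) {
    stop_invalid("a combo contains the testing species %s", test_species)
  }
  missing_sp <- setdiff(unique(unlist(combos)), names(datasets))
  if (length(missing_sp)) stop_invalid("unknown species in combos: %s",
                                       paste(missing_sp, collapse = ", "))
  norm <- prenormalize_corpus(datasets, normalize)
  test_feats <- norm[[test_species]]$features
  y_test <- norm[[test_species]]$labels$essential
  aucs <- vapply(combos, function(cb) {
    fit <- fit_nb(norm[cb], alpha = alpha, var_floor = var_floor, normalize = "none")
    auc(score_genes(fit, test_feats), y_test)
  }, numeric(1))
  data.frame(combo = vapply(combos, combo_key, character(1)),
             k = lengths(combos), auc = aucs, stringsAsFactors = FALSE)
}

#' Split single-species training sets into HASTS and LASTS
#'
#' Sorts training sets by their transfer AUC for one testing species and
#' splits off the top ceiling(n * 9/19) as the high-AUC training sets
#' (HASTS) — exactly 9 of 19 at the canonical pool size — leaving the rest
#' as LASTS. The threshold is the midpoint between the boundary scores;
#' ties are broken by ascending species id.
#'
#' @param single_set_aucs named numeric vector: per-training-species AUC for
#'   one testing species.
#' @return list with `hasts`, `lasts` (character vectors) and `threshold`.
#' @export
hasts_lasts_split <- function(single_set_aucs) {
  n <- length(single_set_aucs)
  if (n < 2L) stop_invalid("need at least 2 training sets")
  if (is.null(names(single_set_aucs))) stop_invalid("`single_set_aucs` must be named by species")
  ord <- order(-single_set_aucs, names(single_set_aucs))
  n_high <- ceiling(n * 9 / 19)
  hasts <- names(single_set_aucs)[ord[seq_len(n_high)]]
  lasts <- names(single_set_aucs)[ord[(n_high + 1L):n]]
  threshold <- mean(c(single_set_aucs[ord[n_high]], single_set_aucs[ord[n_high + 1L]]))
  list(hasts = hasts, lasts = lasts, threshold = unname(threshold))
}

#' Compare high / low / mixed integrated groups
#'
#' Scores every k-subset drawn entirely from HASTS (high group), entirely
#' from LASTS (low group), or straddling both (mixed group) on one testing
#' species. All `choose(n, k)` subsets of the pooled 19-set union are
#' evaluated once and partitioned by membership.
#'
#' @param datasets named list of `species_dataset` objects.
#' @param hasts,lasts character vectors partitioning the training pool.
#' @param k species per integrated set (default 4).
#' @param test_species the testing species.
#' @param ... classifier settings passed to [integrated_performance()].
#' @return list with numeric vectors `high`, `low`, `mixed` (named by combo)
#'   and the full `table`. A group smaller than `k` yields an empty vector.
#' @export
group_comparison <- function(datasets, hasts, lasts, k = 4, test_species, ...) {
  if (length(intersect(hasts, lasts))) stop_invalid("hasts and lasts overlap")
  pool <- c(hasts, lasts)
  combos <- enumerate_integrated_sets(pool, k)
  res <- integrated_performance(datasets, combos, test_species, ...)
  in_high <- vapply(combos, function(cb) all(cb %in% hasts), logical(1))
  in_low <- vapply(combos, function(cb) all(cb %in% lasts), logical(1))
  res$group <- ifelse(in_high, "high", ifelse(in_low, "low", "mixed"))
  pick <- function(g) stats::setNames(res$auc[res$group == g], res$combo[res$group == g])
  list(high = pick("high"), low = pick("low"), mixed = pick("mixed"), table = res)
}

#' Random-integration permutation null for a rule-selected training set
#'
#' The rule-selected k-species integrated training set yields a threshold
#' AUC on the testing species. The null distribution integrates k species
#' drawn at random from the remaining pool; the p-value is the proportion
#' of simulated AUCs strictly exceeding the threshold. `mode = "sampled"`
#' draws combinations uniformly with replacement (the classical 10,000
#' computer replications); `mode = "exact"` enumerates every combination
#' and returns the exact exceedance proportion.
#'
#' @param datasets named list of `species_dataset` objects.
#' @param test_species the testing species.
#' @param rule_set character vector of k species (excluding `test_species`).
#' @param k integration size (default 4; taken from `rule_set` if absent).
#' @param n_sims number of sampled replications.
#' @param mode `"sampled"` or `"exact"`.
#' @param seed integer seed for the sampled mode.
#' @param null_scores optional precomputed numeric vector of integrated
#'   AUCs for every k-combination of the pool (e.g. the `auc` column of
#'   [integrated_performance()] over [enumerate_integrated_sets()]); when
#'   supplied, both modes reuse it instead of refitting.
#' @param ... classifier settings passed to [integrated_performance()].
#' @return list with `threshold`, `sims`, `p_value`, `n_sims`, `mode`.
#' @export
random_integration_pvalue <- function(datasets, test_species, rule_set,
                                      k = length(rule_set), n_sims = 10000,
                                      mode = c("sampled", "exact"), seed = 1,
                                      null_scores = NULL, ...) {
  mode <- match.arg(mode)
  if (n_sims < 1) stop_invalid("`n_sims` must be >= 1")
  if (test_species %in% rule_set) stop_invalid("rule set must exclude the testing species")
  if (length(rule_set) != k) stop_invalid("rule set size differs from k")
  threshold <- integrated_performance(datasets, list(rule_set), test_species, ...)$auc
  pool <- setdiff(names(datasets), test_species)

  if (is.null(null_scores)) {
    if (mode == "exact") {
      null_scores <- integrated_performance(datasets,
                                            enumerate_integrated_sets(pool, k),
                                            test_species, ...)$auc
    } else {
      cache <- new.env(parent = emptyenv())
      norm_call <- function(cb) {
        key <- combo_key(cb)
        if (is.null(cache[[key]])) {
          cache[[key]] <- integrated_performance(datasets, list(cb),
                                                 test_species, ...)$auc
        }
        cache[[key]]
      }
      draws <- with_seed(seed, replicate(n_sims, sort(sample(pool, k)), simplify = FALSE))
      sims <- vapply(draws, norm_call, numeric(1))
      return(list(threshold = threshold, sims = sims,
                  p_value = mean(sims > threshold), n_sims = n_sims,
                  mode = mode))
    }
  }
  if (mode == "exact") {
    return(list(threshold = threshold, sims = null_scores,
                p_value = mean(null_scores > threshold),
                n_sims = length(null_scores), mode = mode))
  }
  sims <- with_seed(seed, sample(null_scores, n_sims, replace = TRUE))
  list(threshold = threshold, sims = sims, p_value = mean(sims > threshold),
       n_sims = n_sims, mode = mode)
}

#' Rule-based training-set selection
#'
#' Ranks candidate training species for a target by a weighted sum of the
#' four selection criteria: label quality (systematic deletion beats
#' transposon mutagenesis beats inferred sets), growth-condition match,
#' phylogenetic closeness (negative normalized divergence), and lifestyle
#' similarity (fraction of matching Gram/oxygen/shape tags). Candidates
#' missing metadata are excluded with a warning; ties break by ascending
#' species id.
#'
#' @param metadata data frame as from [corpus_metadata()]: `species_id`,
#'   `quality_tier` (`deletion`/`transposon`/`inferred`),
#'   `growth_condition`, `gram`, `oxygen`, `shape`.
#' @param divergence a `divergence_matrix` (or plain matrix) with entries
#'   for the target and candidates.
#' @param target target species id.
#' @param n how many species to select.
#' @param weights named numeric weights for `quality`, `condition`,
#'   `distance`, `lifestyle` (default equal).
#' @return list with `selected` (top-n ids) and `ranking` (data frame with
#'   per-criterion subscores and the weighted total).
#' @export
rule_based_select <- function(metadata, divergence, target, n = 4,
                              weights = c(quality = 1, condition = 1,
                                          distance = 1, lifestyle = 1)) {
  D <- if (inherits(divergence, "divergence_matrix")) divergence$D else divergence
  if (!target %in% metadata$species_id) stop_invalid("target %s has no metadata", target)
  if (!target %in% rownames(D)) stop_invalid("target %s missing from divergence matrix", target)
  tgt <- metadata[metadata$species_id == target, ]
  cand <- metadata[metadata$species_id != target, ]
  need <- c("quality_tier", "growth_condition", "gram", "oxygen", "shape")
  complete <- stats::complete.cases(cand[need]) & cand$species_id %in% rownames(D)
  if (any(!complete)) {
    warning(sprintf("excluding candidates with missing metadata/divergence: %s",
                    paste(cand$species_id[!complete], collapse = ", ")))
    cand <- cand[complete, ]
  }
  if (!nrow(cand)) stop_invalid("no candidates with complete metadata")
  tier_score <- c(deletion = 1, transposon = 0.5, inferred = 0)
  quality <- unname(tier_score[cand$quality_tier])
  if (anyNA(quality)) stop_invalid("unknown quality tier(s): %s",
                                   paste(unique(cand$quality_tier[is.na(quality)]), collapse = ", "))
  condition <- as.numeric(cand$growth_condition == tgt$growth_condition)
  d <- D[cand$species_id, target]
  dmax <- max(d)
  distance <- if (dmax > 0) 1 - d / dmax else rep(1, length(d))
  lifestyle <- (as.numeric(cand$gram == tgt$gram) +
                as.numeric(cand$oxygen == tgt$oxygen) +
                as.numeric(cand$shape == tgt$shape)) / 3
  w <- weights[c("quality", "condition", "distance", "lifestyle")]
  if (anyNA(w)) stop_invalid("`weights` must name quality, condition, distance, lifestyle")
  score <- (w[["quality"]] * quality + w[["condition"]] * condition +
            w[["distance"]] * distance + w[["lifestyle"]] * lifestyle) / sum(w)
  ranking <- data.frame(species_id = cand$species_id, quality = quality,
                        condition = condition, distance = unname(distance),
                        lifestyle = lifestyle, score = unname(score),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$score, ranking$species_id), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  list(selected = utils::head(ranking$species_id, n), ranking = ranking)
}

#' Welch two-sample comparison of AUC groups
#'
#' Thin wrapper over the Welch t-test for comparing two distributions of
#' integrated-training-set AUC scores (e.g. the high vs low groups of
#' [group_comparison()]).
#'
#' @param x,y numeric vectors of AUC scores.
#' @return an `htest` object.
#' @export
welch_auc_test <- function(x, y) {
  stats::t.test(x, y, var.equal = FALSE)
}
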