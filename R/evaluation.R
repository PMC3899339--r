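#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' essential gene outranks a randomly chosen non-essential one, with tied
#' score pairs contributing 1/2.
#'
#' @param scores numeric scores, higher = more essential.
#' @param labels 0/1 labels, same length.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0))
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_invalid("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop_invalid("scores/labels must not contain NA")
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop_invalid("labels must be 0/1")
  P <- sum(y == 1L); N <- sum(y == 0L)
  if (P == 0L || N == 0L) {
    stop_invalid("AUC needs at least one positive and one negative label")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - P * (P + 1) / 2) / (P * N)
}

# deterministic ranking used by top-k metrics: descending score, ties broken
# by ascending gene id (names of `scores`), then position
topk_order <- function(scores) {
  ids <- names(scores) %||% sprintf("g%09d", seq_along(scores))
  order(-scores, ids)
}

#' Positive predictive value among the top-k genes
#'
#' Fraction of truly essential genes among the `k` genes with the highest
#' essentiality scores (default k = 200). Ties at the k-th score are broken
#' deterministically: descending score, then ascending gene id.
#'
#' @param scores numeric scores (named by gene id for the tie-break).
#' @param labels 0/1 labels.
#' @param k cutoff; must not exceed the number of genes.
#' @return PPV in \[0, 1\].
#' @export
ppv_at_k <- function(scores, labels, k = 200) {
  if (length(scores) != length(labels)) stop_invalid("scores and labels differ in length")
  if (k < 1 || k > length(scores)) {
    stop_invalid("`k` (%s) must be between 1 and the number of genes (%d)",
                 format(k), length(scores))
  }
  y <- as.integer(labels)
  top <- topk_order(scores)[seq_len(k)]
  mean(y[top] == 1L)
}

#' True positive rate at prevalence
#'
#' With P positives, the fraction of positives recovered among the top-P
#' scored genes (the precision = recall operating point). Tie handling as in
#' [ppv_at_k()].
#'
#' @inheritParams ppv_at_k
#' @return TPR in \[0, 1\].
#' @export
tpr_at_prevalence <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_invalid("scores and labels differ in length")
  y <- as.integer(labels)
  P <- sum(y == 1L)
  if (P == 0L) stop_invalid("TPR needs at least one positive label")
  top <- topk_order(scores)[seq_len(P)]
  sum(y[top] == 1L) / P
}

#' Reciprocal cross-species transfer matrix
#'
#' Fits the classifier on each species in turn and evaluates it on every
#' species (including itself), giving the n x n matrix M = (m_ij) with
#' species i as the training set (rows) and species j as the testing set
#' (columns). A species whose labels are single-class yields missing
#' entries with a warning rather than an error.
#'
#' @param datasets named list of `species_dataset` objects (>= 2).
#' @param metric `"auc"` or `"ppv"` (PPV at `k`).
#' @param k top-k cutoff for the PPV metric.
#' @param normalize,alpha,var_floor classifier settings, see [fit_nb()].
#' @return numeric matrix with `metric` attribute; rows = training species,
#'   columns = testing species.
#' @export
cross_species_matrix <- function(datasets, metric = c("auc", "ppv"), k = 200,
                                 normalize = "rank", alpha = 1, var_floor = 1e-9) {
  metric <- match.arg(metric)
  sp <- names(datasets)
  if (length(sp) < 2L) stop_invalid("need at least 2 species")
  norm <- lapply(datasets, function(d) {
    d$features <- normalize_features(d$features, normalize)
    d
  })
  M <- matrix(NA_real_, length(sp), length(sp), dimnames = list(train = sp, test = sp))
  for (i in sp) {
    fit <- tryCatch(fit_nb(norm[[i]], alpha = alpha, var_floor = var_floor,
                           normalize = "none"),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("species %s has single-class labels; row left missing", i))
      next
    }
    for (j in sp) {
      s <- score_genes(fit, norm[[j]]$features)
      y <- norm[[j]]$labels$essential
      M[i, j] <- tryCatch(
        if (metric == "auc") auc(s, y) else ppv_at_k(s, y, k),
        error = function(e) {
          warning(sprintf("entry %s -> %s left missing: %s", i, j, conditionMessage(e)))
          NA_real_
        })
    }
  }
  attr(M, "metric") <- if (metric == "ppv") paste0("ppv@", k) else "auc"
  M
}

#' Per-testing-species dispersion of a transfer matrix
#'
#' For each testing species (column), the interquartile range of the scores
#' obtained from the different training sets, with outlier training sets
#' flagged by the 1.5 IQR whisker rule. Quantiles use linear interpolation
#' (R type 7). Self-prediction (the diagonal) is excluded by default.
#'
#' @param matrix transfer matrix from [cross_species_matrix()].
#' @param exclude_diagonal drop the self-prediction entry of each column?
#' @return list with `stats` (data frame: `test_species`, `q1`, `q3`, `iqr`,
#'   `n`) and `outliers` (named list of flagged training species).
#' @export
column_dispersion <- function(matrix, exclude_diagonal = TRUE) {
  sp <- colnames(matrix)
  stats_rows <- vector("list", length(sp))
  outliers <- stats::setNames(vector("list", length(sp)), sp)
  for (j in seq_along(sp)) {
    v <- matrix[, j]
    if (exclude_diagonal) v <- v[setdiff(rownames(matrix), sp[j])]
    v <- v[!is.na(v)]
    if (length(v) < 4L) {
      stop_invalid("column %s has %d entries; need >= 4 training sets", sp[j], length(v))
    }
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[2] + 1.5 * iqr
    outliers[[j]] <- names(v)[v < lo | v > hi]
    stats_rows[[j]] <- data.frame(test_species = sp[j], q1 = q[1], q3 = q[2],
                                  iqr = iqr, n = length(v),
                                  stringsAsFactors = FALSE)
  }
  list(stats = do.call(rbind, c(stats_rows, list(make.row.names = FALSE))),
       outliers = outliers)
}

pearson_pairs <- function(x, y, labels, outlier_z) {
  discarded <- character(0)
  keep <- rep(TRUE, length(x))
  if (!is.null(outlier_z) && is.finite(outlier_z)) {
    fit0 <- stats::lm(y ~ x)
    r <- stats::resid(fit0)
    z <- r / stats::sd(r)
    keep <- abs(z) <= outlier_z
    discarded <- labels[!keep]
  }
  if (sum(keep) < 3L) stop_invalid("fewer than 3 pairs remain after outlier removal")
  ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
  fit <- stats::lm(y[keep] ~ x[keep])
  list(R = unname(ct$estimate), p_value = ct$p.value, n_used = sum(keep),
       discarded = discarded,
       slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]))
}

#' Correlation between transfer accuracy and divergence time
#'
#' Pairs every ordered cross-species entry m_ij (i != j) of a transfer
#' matrix with the divergence time d(i, j) and computes the Pearson
#' correlation with its two-sided p-value, after optionally discarding
#' pairs whose standardized OLS residual exceeds `outlier_z`. `mode =
#' "per_test"` repeats the analysis within each testing-set column.
#'
#' @param matrix transfer matrix from [cross_species_matrix()].
#' @param divergence a `divergence_matrix` (or plain symmetric matrix)
#'   covering the matrix's species.
#' @param mode `"pooled"` (all ordered pairs) or `"per_test"` (one result
#'   per testing species).
#' @param outlier_z discard threshold on |standardized residual|; `NULL`
#'   keeps every pair.
#' @return for `"pooled"`, a list with `R`, `p_value`, `n_used`,
#'   `discarded`, `slope`, `intercept`; for `"per_test"`, a data frame with
#'   one row per testing species.
#' @export
divergence_correlation <- function(matrix, divergence,
                                   mode = c("pooled", "per_test"),
                                   outlier_z = 3) {
  mode <- match.arg(mode)
  D <- if (inherits(divergence, "divergence_matrix")) divergence$D else divergence
  sp <- rownames(matrix)
  if (!all(sp %in% rownames(D))) {
    stop_invalid("divergence matrix does not cover all species of the transfer matrix")
  }
  D <- D[sp, sp]
  if (mode == "pooled") {
    ij <- which(row(matrix) != col(matrix) & !is.na(matrix), arr.ind = TRUE)
    labels <- paste0(sp[ij[, 1]], "->", sp[ij[, 2]])
    return(pearson_pairs(D[ij], matrix[ij], labels, outlier_z))
  }
  rows <- lapply(seq_along(sp), function(j) {
    i <- setdiff(seq_along(sp), j)
    ok <- i[!is.na(matrix[i, j])]
    res <- pearson_pairs(D[ok, j], matrix[ok, j], sp[ok], outlier_z)
    data.frame(test_species = sp[j], R = res$R, p_value = res$p_value,
               n_used = res$n_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
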