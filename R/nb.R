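#' Feature schema of a table
#'
#' Splits the feature columns of a table into continuous and categorical
#' sets. Numeric columns are continuous and character/factor columns are
#' categorical, except that `DoT` (domain type) and `Age` (phyletic age) are
#' always treated as categorical, matching how they enter the classifier.
#'
#' @param table feature data frame (`gene_id`, `species_id`, features).
#' @return list with character vectors `continuous` and `categorical`.
#' @export
feature_schema <- function(table) {
  feats <- setdiff(names(table), c("gene_id", "species_id"))
  is_cat <- vapply(table[feats],
                   function(x) is.character(x) || is.factor(x), logical(1))
  forced <- intersect(c("DoT", "Age"), feats)
  categorical <- union(feats[is_cat], forced)
  list(continuous = setdiff(feats, categorical), categorical = categorical)
}

#' Normalize continuous features within species
#'
#' Cross-species transfer compares features measured on incommensurable
#' scales (expression platforms, network sizes), so continuous features are
#' put on a common scale per species before pooling. `rank` maps each value
#' to rank/(n+1) in (0, 1) (average ranks for ties, so a constant column
#' becomes all 0.5); `zscore` standardizes (constant columns become 0);
#' `none` is the identity. Categorical columns and missing values are left
#' untouched.
#'
#' @param table feature data frame with a `species_id` column.
#' @param method one of `"rank"`, `"zscore"`, `"none"`.
#' @return the table with continuous columns transformed.
#' @examples
#' tb <- data.frame(gene_id = c("a", "b", "c"), species_id = "S",
#'                  x = c(10, 20, 30))
#' normalize_features(tb, "rank")$x
#' @export
normalize_features <- function(table, method = c("rank", "zscore", "none")) {
  method <- match.arg(method)
  if (method == "none") return(table)
  sch <- feature_schema(table)
  cont <- setdiff(sch$continuous, c("Age"))
  if (!length(cont)) return(table)
  for (sp in unique(table$species_id)) {
    rows <- which(table$species_id == sp)
    for (f in cont) {
      x <- table[[f]][rows]
      ok <- !is.na(x)
      if (!any(ok)) next
      if (method == "rank") {
        x[ok] <- rank(x[ok], ties.method = "average") / (sum(ok) + 1)
      } else {
        s <- stats::sd(x[ok])
        x[ok] <- if (!is.finite(s) || s == 0) 0 else (x[ok] - mean(x[ok])) / s
      }
      table[[f]][rows] <- x
    }
  }
  table
}

# pooled feature table + labels from one or a list of species_dataset
pool_datasets <- function(train) {
  if (inherits(train, "species_dataset")) train <- list(train)
  if (!length(train) || !all(vapply(train, inherits, logical(1), "species_dataset"))) {
    stop_invalid("`train` must be a species_dataset or a list of them")
  }
  feats <- lapply(train, `[[`, "features")
  cols <- names(feats[[1]])
  if (!all(vapply(feats, function(f) identical(names(f), cols), logical(1)))) {
    stop_invalid("training species have inconsistent feature columns")
  }
  list(features = do.call(rbind, c(feats, list(make.row.names = FALSE))),
       labels = unlist(lapply(train, function(d) d$labels$essential), use.names = FALSE),
       species = vapply(train, `[[`, character(1), "species_id"))
}

#' Fit a naive Bayes essentiality classifier
#'
#' Fits class priors and per-feature class-conditional models on one or
#' several pooled species datasets: Gaussian per continuous feature
#' (sample mean and n-1 variance from non-missing values, floored at
#' `var_floor`), and Laplace-smoothed multinomial per categorical feature.
#' Continuous features are normalized per species with
#' [normalize_features()] before pooling; the recipe is stored and re-applied
#' at scoring time. A feature with no observed values in one class is
#' flagged unusable and skipped when scoring.
#'
#' @param train a `species_dataset` or list of them; pooling several species
#'   is exactly concatenation of their (normalized) tables.
#' @param alpha Laplace smoothing pseudo-count for categorical levels.
#' @param var_floor lower bound on Gaussian variances (on the normalized
#'   scale), guarding against degenerate spikes.
#' @param normalize normalization recipe, see [normalize_features()].
#' @return an object of class `nb_model`.
#' @examples
#' tr <- simulate_divergence_tree(2, seed = 1)
#' corpus <- simulate_multispecies(sim_config(2, 200, seed = 1), tr)
#' m <- fit_nb(corpus[[1]])
#' m
#' @export
fit_nb <- function(train, alpha = 1, var_floor = 1e-9,
                   normalize = c("rank", "zscore", "none")) {
  normalize <- match.arg(normalize)
  pooled <- pool_datasets(train)
  y <- pooled$labels
  if (length(unique(y)) < 2L) {
    stop_invalid("training data contains a single class; need both essential and non-essential genes")
  }
  tab <- normalize_features(pooled$features, normalize)
  sch <- feature_schema(tab)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  priors <- c(`0` = n0, `1` = n1) / (n0 + n1)

  cont <- list()
  for (f in sch$continuous) {
    x <- tab[[f]]
    p <- list()
    for (cl in c("0", "1")) {
      v <- x[y == as.integer(cl) & !is.na(x)]
      if (!length(v)) {
        p[[cl]] <- NULL
      } else {
        vr <- if (length(v) >= 2L) stats::var(v) else 0
        p[[cl]] <- c(mean = mean(v), var = max(vr, var_floor))
      }
    }
    cont[[f]] <- list(params = p, usable = length(p) == 2L)
  }

  cat_ <- list()
  for (f in sch$categorical) {
    x <- as.character(tab[[f]])
    levels <- sort(unique(x[!is.na(x)]))
    K <- length(levels)
    p <- list()
    for (cl in c("0", "1")) {
      v <- x[y == as.integer(cl) & !is.na(x)]
      if (!length(v) || K == 0L) {
        p[[cl]] <- NULL
      } else {
        cnt <- table(factor(v, levels = levels))
        prob <- (as.numeric(cnt) + alpha) / (length(v) + alpha * K)
        unseen <- alpha / (length(v) + alpha * K)
        p[[cl]] <- list(prob = stats::setNames(prob, levels), unseen = unseen)
      }
    }
    cat_[[f]] <- list(levels = levels, params = p, usable = length(p) == 2L)
  }

  structure(list(
    schema_version = "1",
    priors = priors,
    continuous = cont,
    categorical = cat_,
    alpha = alpha,
    var_floor = var_floor,
    normalize = normalize,
    training = list(species = pooled$species,
                    n_genes = length(y), n_essential = n1)
  ), class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf(
    "nb_model: %d continuous + %d categorical features, prior P(essential) = %.3f\n",
    length(x$continuous), length(x$categorical), x$priors[["1"]]))
  cat(sprintf("trained on %s (%d genes), normalization: %s\n",
              paste(x$training$species, collapse = "+"),
              x$training$n_genes, x$normalize))
  invisible(x)
}

#' Score genes for essentiality
#'
#' Computes the posterior probability of essentiality for each gene by the
#' naive factorization, evaluated in log space. Missing features contribute
#' nothing (they are marginalized out), unseen categorical levels receive
#' the smoothed pseudo-count mass, and a gene with every feature missing
#' scores at the class prior.
#'
#' @param model an `nb_model`.
#' @param table feature data frame (or a `species_dataset`, whose features
#'   are used); the model's normalization recipe is applied per species.
#' @return numeric vector of scores in \[0, 1\], named by `gene_id`.
#' @export
score_genes <- function(model, table) {
  stopifnot(inherits(model, "nb_model"))
  if (inherits(table, "species_dataset")) table <- table$features
  tab <- normalize_features(table, model$normalize)
  n <- nrow(tab)
  llr <- rep(log(model$priors[["1"]]) - log(model$priors[["0"]]), n)

  for (f in names(model$continuous)) {
    spec <- model$continuous[[f]]
    if (!spec$usable || is.null(tab[[f]])) next
    x <- tab[[f]]
    ok <- !is.na(x)
    if (!any(ok)) next
    p0 <- spec$params[["0"]]; p1 <- spec$params[["1"]]
    llr[ok] <- llr[ok] +
      stats::dnorm(x[ok], p1[["mean"]], sqrt(p1[["var"]]), log = TRUE) -
      stats::dnorm(x[ok], p0[["mean"]], sqrt(p0[["var"]]), log = TRUE)
  }

  for (f in names(model$categorical)) {
    spec <- model$categorical[[f]]
    if (!spec$usable || is.null(tab[[f]])) next
    x <- as.character(tab[[f]])
    ok <- !is.na(x)
    if (!any(ok)) next
    p0 <- spec$params[["0"]]; p1 <- spec$params[["1"]]
    l1 <- p1$prob[x[ok]]
    l0 <- p0$prob[x[ok]]
    unseen <- is.na(l1)
    l1[unseen] <- p1$unseen
    l0[unseen] <- p0$unseen
    contrib <- log(l1) - log(l0)
    contrib[l1 == 0 & l0 == 0] <- 0      # alpha = 0 and unseen level: skip
    llr[ok] <- llr[ok] + contrib
  }

  stats::setNames(stats::plogis(llr), tab$gene_id)
}

#' Write / read a naive Bayes model
#'
#' Serializes an `nb_model` to structured JSON text (17 significant digits,
#' which round-trips IEEE doubles exactly) and reads it back.
#'
#' @param model an `nb_model`.
#' @param path file path.
#' @return `nb_write` returns `path` invisibly; `nb_read` returns the model.
#' @export
nb_write <- function(model, path) {
  stopifnot(inherits(model, "nb_model"))
  obj <- unclass(model)
  obj$priors <- as.list(obj$priors)                 # keep names as JSON keys
  obj$continuous <- lapply(obj$continuous, function(spec) {
    spec$params <- lapply(spec$params, as.list)
    spec
  })
  obj$categorical <- lapply(obj$categorical, function(spec) {
    spec$params <- lapply(spec$params, function(p) {
      p$prob <- as.list(p$prob)
      p
    })
    spec
  })
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                           pretty = TRUE, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname nb_write
#' @export
nb_read <- function(path) {
  raw <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  raw$priors <- unlist(raw$priors)[c("0", "1")]
  raw$continuous <- lapply(raw$continuous, function(spec) {
    spec$params <- lapply(spec$params, function(p) unlist(p)[c("mean", "var")])
    spec
  })
  raw$categorical <- lapply(raw$categorical, function(spec) {
    spec$levels <- as.character(unlist(spec$levels))
    spec$params <- lapply(spec$params, function(p) {
      list(prob = unlist(p$prob), unseen = p$unseen)
    })
    spec
  })
  structure(raw, class = "nb_model")
}
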