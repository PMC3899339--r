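# All on-disk tables are UTF-8, tab-separated, Unix newlines, header row,
# missing values encoded as "NA"; numbers printed with %.15g so that a
# read -> write cycle is byte-stable.

fmt_cell <- function(x) {
  if (is.numeric(x)) {
    out <- ifelse(is.na(x), "NA",
                  ifelse(x == round(x) & abs(x) < 1e15,
                         sprintf("%.0f", x), sprintf("%.15g", x)))
    out
  } else {
    ifelse(is.na(x), "NA", as.character(x))
  }
}

#' Write / read a tab-separated table
#'
#' Deterministic TSV writer/reader used for every tabular format in the
#' package (labels, features, edge lists, expression, metadata).
#'
#' @param df data frame.
#' @param path file path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv` a data frame.
#' @export
write_tsv <- function(df, path) {
  cols <- lapply(df, fmt_cell)
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(cols, sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  first <- readLines(path, n = 1L)
  nfield <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  counts <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  bad <- which(counts != nfield)
  if (length(bad)) {
    stop_invalid("malformed TSV row(s) in %s at line(s): %s", path,
                 paste(utils::head(bad, 5), collapse = ", "))
  }
  utils::read.delim(path, sep = "\t", quote = "", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA)
}

#' Read / write FASTA sequences
#'
#' cDNA sequences as a named character vector, via Biostrings.
#'
#' @param path FASTA file path.
#' @param sequences named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Write / read a square species matrix
#'
#' TSV with species ids as header row and first column, used for
#' divergence-time and transfer-accuracy matrices.
#'
#' @param m square numeric matrix with dimnames.
#' @param path file path.
#' @return `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(species_id = rownames(m), as.data.frame(m, check.names = FALSE),
                   stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

CORPUS_SCHEMA_VERSION <- "1"

#' Write a corpus to disk
#'
#' Writes per-species label and feature TSVs, the divergence matrix, the
#' species metadata table, and a JSON manifest tying them together, in the
#' same formats the readers consume (synthetic and real corpora are
#' interchangeable).
#'
#' @param datasets named list of `species_dataset` objects.
#' @param divergence a `divergence_matrix` (or plain matrix) covering the
#'   species.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_corpus <- function(datasets, divergence, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  D <- if (inherits(divergence, "divergence_matrix")) divergence$D else divergence
  species <- names(datasets)
  entries <- vector("list", length(species))
  for (i in seq_along(species)) {
    sp <- species[i]
    lf <- file.path(dir, sprintf("%s_labels.tsv", sp))
    ff <- file.path(dir, sprintf("%s_features.tsv", sp))
    write_tsv(datasets[[sp]]$labels, lf)
    write_tsv(datasets[[sp]]$features, ff)
    entries[[i]] <- list(species_id = sp, labels = basename(lf),
                         features = basename(ff))
  }
  write_matrix_tsv(D, file.path(dir, "divergence.tsv"))
  write_tsv(corpus_metadata(datasets), file.path(dir, "metadata.tsv"))
  manifest <- list(schema_version = CORPUS_SCHEMA_VERSION,
                   species = entries,
                   divergence = "divergence.tsv",
                   metadata = "metadata.tsv")
  manifest_path <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             manifest_path, useBytes = TRUE)
  invisible(manifest_path)
}

#' Read a corpus from a manifest
#'
#' Loads and validates a corpus written by [write_corpus()]: every
#' referenced file must exist, species ids must be unique, labels must be
#' 0/1, gene ids must agree between the label and feature files, and the
#' divergence matrix must cover every species.
#'
#' @param manifest_path path to `manifest.json`.
#' @return list with `datasets` (named list of `species_dataset`),
#'   `divergence` (matrix), and `metadata` (data frame).
#' @export
read_corpus <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop_invalid("manifest not found: %s", manifest_path)
  manifest <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = FALSE)
  if (!identical(manifest$schema_version, CORPUS_SCHEMA_VERSION)) {
    stop_invalid("unsupported corpus schema version: %s",
                 manifest$schema_version %||% "<missing>")
  }
  dir <- dirname(manifest_path)
  ids <- vapply(manifest$species, `[[`, character(1), "species_id")
  if (anyDuplicated(ids)) stop_invalid("duplicate species in manifest: %s",
                                       paste(unique(ids[duplicated(ids)]), collapse = ", "))
  datasets <- stats::setNames(vector("list", length(ids)), ids)
  meta_path <- file.path(dir, manifest$metadata)
  metadata <- if (file.exists(meta_path)) read_tsv(meta_path) else NULL
  for (e in manifest$species) {
    lf <- file.path(dir, e$labels)
    ff <- file.path(dir, e$features)
    for (p in c(lf, ff)) if (!file.exists(p)) stop_invalid("missing file: %s", p)
    labels <- read_tsv(lf)
    features <- read_tsv(ff)
    if (!all(labels$essential %in% c(0L, 1L))) {
      stop_invalid("labels outside {0,1} in %s", lf)
    }
    if (!setequal(labels$gene_id, features$gene_id)) {
      stop_invalid("gene ids disagree between %s and %s", lf, ff)
    }
    meta <- list()
    if (!is.null(metadata) && e$species_id %in% metadata$species_id) {
      meta <- as.list(metadata[metadata$species_id == e$species_id, ])
    }
    datasets[[e$species_id]] <- species_dataset(e$species_id, features, labels, meta)
  }
  D <- read_matrix_tsv(file.path(dir, manifest$divergence))
  if (!all(ids %in% rownames(D))) {
    stop_invalid("divergence matrix does not cover species: %s",
                 paste(setdiff(ids, rownames(D)), collapse = ", "))
  }
  list(datasets = datasets, divergence = D, metadata = metadata)
}

PIPELINE_EXPERIMENTS <- c("matrix", "dispersion", "correlate", "incomplete",
                          "integrate", "null", "select")

#' Run the full analysis pipeline
#'
#' Orchestrates the reciprocal-prediction workflow on a simulated or loaded
#' corpus: transfer matrix, per-testing-set dispersion, divergence
#' correlation, incomplete-training-set curve, integrated-set comparison,
#' random-integration null, and rule-based selection, writing a
#' deterministic directory of TSV/JSON outputs plus a run log (config hash,
#' seed, per-stage runtimes).
#'
#' @param config path to a JSON configuration file or an equivalent list.
#'   Fields: `seed`; either `corpus` (manifest path) or `simulate` (a list
#'   of [sim_config()] arguments); `experiments` (subset of
#'   `r paste0('"', PIPELINE_EXPERIMENTS, '"', collapse = ", ")`); and
#'   optional per-experiment parameter lists (`incomplete`, `integrate`,
#'   `null`, `select`).
#' @param outdir output directory.
#' @return invisibly, a named list of the experiment results.
#' @export
run_pipeline <- function(config, outdir) {
  t_start <- proc.time()[["elapsed"]]
  config_json <- NULL
  if (is.character(config)) {
    if (!file.exists(config)) stop_invalid("config not found: %s", config)
    config_json <- config
    config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  experiments <- unlist(config$experiments %||% c("matrix", "dispersion", "correlate"))
  unknown <- setdiff(experiments, PIPELINE_EXPERIMENTS)
  if (length(unknown)) {
    stop_invalid("unknown experiment(s): %s (valid: %s)",
                 paste(unknown, collapse = ", "),
                 paste(PIPELINE_EXPERIMENTS, collapse = ", "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$corpus)) {
    corpus <- read_corpus(config$corpus)
    datasets <- corpus$datasets
    D <- corpus$divergence
  } else if (!is.null(config$simulate)) {
    args <- config$simulate
    args$seed <- args$seed %||% seed
    cfg <- do.call(sim_config, args)
    tree <- simulate_divergence_tree(cfg$n_species, cfg$max_depth_my,
                                     seed = seed_stream(cfg$seed, "tree"))
    datasets <- simulate_multispecies(cfg, tree)
    D <- tree$D
    write_corpus(datasets, tree, file.path(outdir, "corpus"))
  } else {
    stop_invalid("config must provide either `corpus` or `simulate`")
  }

  results <- list()
  timings <- list()
  errors <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", name, conditionMessage(e)))
      NULL
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  M <- NULL
  if (length(intersect(c("matrix", "dispersion", "correlate", "null"), experiments))) {
    M <- stage("matrix", {
      m <- cross_species_matrix(datasets)
      write_matrix_tsv(m, file.path(outdir, "auc_matrix.tsv"))
      m
    })
    results$matrix <- M
  }
  if ("dispersion" %in% experiments && !is.null(M)) {
    results$dispersion <- stage("dispersion", {
      d <- column_dispersion(M)
      write_tsv(d$stats, file.path(outdir, "dispersion.tsv"))
      d
    })
  }
  if ("correlate" %in% experiments && !is.null(M)) {
    results$correlate <- stage("correlate", {
      cr <- divergence_correlation(M, D)
      writeLines(jsonlite::toJSON(cr, auto_unbox = TRUE, digits = I(17), pretty = TRUE),
                 file.path(outdir, "correlation.json"), useBytes = TRUE)
      cr
    })
  }
  if ("incomplete" %in% experiments) {
    results$incomplete <- stage("incomplete", {
      p <- config$incomplete %||% list()
      sp <- p$species %||% names(datasets)[1]
      cur <- incomplete_training_curve(
        datasets[[sp]],
        fractions = unlist(p$fractions %||% c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8)),
        reps = p$reps %||% 100, seed = seed)
      write_tsv(cur, file.path(outdir, "incomplete_curve.tsv"))
      cur
    })
  }
  if ("integrate" %in% experiments) {
    results$integrate <- stage("integrate", {
      p <- config$integrate %||% list()
      test_sp <- p$test_species %||% names(datasets)[1]
      k <- p$k %||% min(4, length(datasets) - 1L)
      combos <- enumerate_integrated_sets(setdiff(names(datasets), test_sp), k)
      res <- integrated_performance(datasets, combos, test_sp)
      write_tsv(res, file.path(outdir, "integration.tsv"))
      res
    })
  }
  if ("null" %in% experiments && !is.null(M)) {
    results$null <- stage("null", {
      p <- config$null %||% list()
      test_sp <- p$test_species %||% names(datasets)[1]
      n_rule <- p$k %||% min(4, length(datasets) - 1L)
      sel <- rule_based_select(corpus_metadata(datasets), D, test_sp, n = n_rule)
      nr <- random_integration_pvalue(datasets, test_sp, sel$selected,
                                      k = n_rule, n_sims = p$n_sims %||% 1000,
                                      mode = p$mode %||% "sampled", seed = seed)
      out <- list(test_species = test_sp, rule_set = sel$selected,
                  threshold = nr$threshold, p_value = nr$p_value,
                  n_sims = nr$n_sims, mode = nr$mode)
      writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(17), pretty = TRUE),
                 file.path(outdir, "null.json"), useBytes = TRUE)
      nr
    })
  }
  if ("select" %in% experiments) {
    results$select <- stage("select", {
      p <- config$select %||% list()
      test_sp <- p$target %||% names(datasets)[1]
      sel <- rule_based_select(corpus_metadata(datasets), D, test_sp,
                               n = p$n %||% 4)
      write_tsv(sel$ranking, file.path(outdir, "selection.tsv"))
      sel
    })
  }

  log <- list(
    package_version = as.character(utils::packageVersion("essTransfer")),
    seed = seed,
    config_hash = local({
      src <- config_json
      if (is.null(src)) {
        src <- tempfile(fileext = ".json")
        on.exit(unlink(src), add = TRUE)
        writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = I(17)), src)
      }
      unname(tools::md5sum(src))
    }),
    experiments = experiments,
    stage_runtimes_sec = timings,
    errors = errors,
    total_runtime_sec = round(proc.time()[["elapsed"]] - t_start, 3)
  )
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, pretty = TRUE, null = "null"),
             file.path(outdir, "run_log.json"), useBytes = TRUE)
  if (length(errors)) {
    stop_invalid("pipeline finished with failures:\n%s", paste(errors, collapse = "\n"))
  }
  invisible(results)
}
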