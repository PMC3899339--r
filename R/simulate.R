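#' Simulate a divergence-time tree
#'
#' Draws a Yule (pure-birth) tree on `n_species` tips and rescales branch
#' lengths so the root depth equals `max_depth_my` million years. The
#' pairwise divergence time of two species is the time back to their most
#' recent common ancestor, so the returned matrix is symmetric, has a zero
#' diagonal, and is ultrametric.
#'
#' @param n_species number of species (tips), at least 2.
#' @param max_depth_my tree depth (root to tip) in millions of years.
#' @param seed integer RNG seed.
#' @return an object of class `divergence_matrix`: a list with `species`
#'   (tip labels), `D` (symmetric divergence-time matrix in My), and
#'   `phylo` (the `ape::phylo` tree, kept for trait simulation).
#' @examples
#' tr <- simulate_divergence_tree(5, max_depth_my = 3500, seed = 1)
#' tr$D
#' @export
simulate_divergence_tree <- function(n_species, max_depth_my = 3500, seed = 1) {
  if (!is.numeric(n_species) || length(n_species) != 1L || n_species < 2) {
    stop_invalid("`n_species` must be a single integer >= 2")
  }
  if (!is.numeric(max_depth_my) || max_depth_my <= 0) {
    stop_invalid("`max_depth_my` must be a positive number")
  }
  phy <- with_seed(seed, ape::rphylo(as.integer(n_species), birth = 1, death = 0))
  phy$tip.label <- sprintf("S%02d", seq_len(as.integer(n_species)))
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * (max_depth_my / depth)
  divergence_from_tree(phy)
}

#' Divergence-time matrix from an ultrametric tree
#'
#' Converts an ultrametric `ape::phylo` tree (branch lengths in millions of
#' years) into a `divergence_matrix`: divergence(i, j) is the time since the
#' most recent common ancestor of tips i and j (half the patristic
#' distance).
#'
#' @param phylo an ultrametric `ape::phylo` object with branch lengths.
#' @return a `divergence_matrix` (see [simulate_divergence_tree()]).
#' @export
divergence_from_tree <- function(phylo) {
  if (!inherits(phylo, "phylo")) stop_invalid("`phylo` must be an ape phylo object")
  if (is.null(phylo$edge.length)) stop_invalid("tree has no branch lengths")
  if (!ape::is.ultrametric(phylo, tol = 1e-6)) {
    stop_invalid("tree must be ultrametric (a time tree)")
  }
  D <- ape::cophenetic.phylo(phylo) / 2
  tips <- phylo$tip.label
  D <- D[tips, tips, drop = FALSE]
  diag(D) <- 0
  structure(list(species = tips, D = D, phylo = phylo),
            class = "divergence_matrix")
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("divergence_matrix: %d species, depth %.1f My\n",
              length(x$species), max(x$D) ))
  invisible(x)
}

#' Configuration for the multi-species simulator
#'
#' Collects every tunable parameter of the synthetic corpus generator. The
#' defaults describe a moderately diverged set of microbial genomes:
#' 500-gene genomes, a 15% essential fraction, ten continuous and two
#' categorical features with a per-feature class separation of 0.7 latent
#' standard deviations, and Brownian drift of both family importance and the
#' class-separation direction at rate `drift_sigma` per square-root million
#' years along a 3500-My-deep tree.
#'
#' @param n_species number of species; must match the tree it is used with.
#' @param n_genes_per_species genes per genome.
#' @param essential_fraction target essential-gene share per species,
#'   strictly in (0, 1); scalar or per-species vector.
#' @param n_features_cont,n_features_cat number of continuous and
#'   categorical features.
#' @param n_cat_levels levels per categorical feature (default 5, the usual
#'   number of phyletic-age groups).
#' @param feature_effect absolute class-mean separation of each continuous
#'   feature, in units of its unit noise standard deviation.
#' @param drift_sigma Brownian-motion rate (per sqrt(My)) of family
#'   importance and of the class-separation direction; 0 freezes evolution
#'   so all species share one generative model.
#' @param label_noise per-species probability in \[0, 0.5\] of flipping each
#'   reported label (training-set "quality"); scalar or per-species.
#' @param condition per-species growth condition, `"rich"` or `"minimal"`.
#' @param gram,oxygen,shape per-species lifestyle tags: `"pos"`/`"neg"`,
#'   `"aerobe"`/`"anaerobe"`/`"facultative"`, and a free-text shape.
#' @param condition_effect_size latent shift (+ under minimal, - under rich)
#'   applied to the designated biosynthesis gene subset.
#' @param lifestyle_effect_size latent shift applied to the designated
#'   energy-metabolism subset (+ aerobe, - anaerobe, 0 facultative).
#' @param conditional_gene_fraction,energy_gene_fraction shares of the
#'   genome designated as condition-dependent biosynthesis genes and as
#'   oxygen-keyed energy genes.
#' @param missing_rate missing-completely-at-random rate applied to feature
#'   cells.
#' @param max_depth_my tree depth in millions of years (documentation of
#'   the scale `drift_sigma` acts on).
#' @param seed master integer seed; identical configurations (including
#'   the seed) give bit-identical corpora.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_species,
                       n_genes_per_species = 500,
                       essential_fraction = 0.15,
                       n_features_cont = 10,
                       n_features_cat = 2,
                       n_cat_levels = 5,
                       feature_effect = 0.7,
                       drift_sigma = 0.02,
                       label_noise = 0,
                       condition = "rich",
                       gram = "neg",
                       oxygen = "facultative",
                       shape = "rod",
                       condition_effect_size = 2,
                       lifestyle_effect_size = 1.5,
                       conditional_gene_fraction = 0.10,
                       energy_gene_fraction = 0.10,
                       missing_rate = 0.05,
                       max_depth_my = 3500,
                       seed = 1) {
  if (!is.numeric(n_species) || n_species < 2) stop_invalid("`n_species` must be >= 2")
  if (any(essential_fraction <= 0) || any(essential_fraction >= 1)) {
    stop_invalid("`essential_fraction` must be strictly in (0, 1)")
  }
  if (any(label_noise < 0) || any(label_noise > 0.5)) {
    stop_invalid("`label_noise` must be in [0, 0.5]")
  }
  if (drift_sigma < 0) stop_invalid("`drift_sigma` must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stop_invalid("`missing_rate` must be in [0, 1)")
  if (n_features_cont < 1) stop_invalid("at least one continuous feature is required")
  if (n_features_cat < 0) stop_invalid("`n_features_cat` must be >= 0")
  if (n_cat_levels < 2) stop_invalid("`n_cat_levels` must be >= 2")
  if (conditional_gene_fraction < 0 || energy_gene_fraction < 0 ||
      conditional_gene_fraction + energy_gene_fraction > 0.5) {
    stop_invalid("designated gene fractions must be nonnegative and sum to <= 0.5")
  }
  bad_cond <- setdiff(condition, c("rich", "minimal"))
  if (length(bad_cond)) stop_invalid("unknown condition tag(s): %s", paste(bad_cond, collapse = ", "))
  bad_oxy <- setdiff(oxygen, c("aerobe", "anaerobe", "facultative"))
  if (length(bad_oxy)) stop_invalid("unknown oxygen tag(s): %s", paste(bad_oxy, collapse = ", "))
  structure(list(
    n_species = as.integer(n_species),
    n_genes_per_species = as.integer(n_genes_per_species),
    essential_fraction = essential_fraction,
    n_features_cont = as.integer(n_features_cont),
    n_features_cat = as.integer(n_features_cat),
    n_cat_levels = as.integer(n_cat_levels),
    feature_effect = feature_effect,
    drift_sigma = drift_sigma,
    label_noise = label_noise,
    condition = condition,
    gram = gram,
    oxygen = oxygen,
    shape = shape,
    condition_effect_size = condition_effect_size,
    lifestyle_effect_size = lifestyle_effect_size,
    conditional_gene_fraction = conditional_gene_fraction,
    energy_gene_fraction = energy_gene_fraction,
    missing_rate = missing_rate,
    max_depth_my = max_depth_my,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Brownian motion of m traits down a phylo tree: each edge adds independent
# N(0, sigma^2 * branch length) increments.  Returns tips x traits.
bm_tips <- function(phy, root_values, sigma) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  m <- length(root_values)
  vals <- matrix(NA_real_, nnode, m)
  vals[ntip + 1L, ] <- root_values
  po <- ape::reorder.phylo(phy, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  for (k in rev(seq_len(nrow(edge)))) {       # reverse postorder: parents first
    parent <- edge[k, 1L]
    child <- edge[k, 2L]
    if (sigma > 0 && elen[k] > 0) {
      vals[child, ] <- vals[parent, ] + stats::rnorm(m, 0, sigma * sqrt(elen[k]))
    } else {
      vals[child, ] <- vals[parent, ]
    }
  }
  out <- vals[seq_len(ntip), , drop = FALSE]
  rownames(out) <- phy$tip.label
  out
}

#' Construct a per-species dataset
#'
#' Bundles one species' feature table, essentiality labels, and metadata.
#'
#' @param species_id species identifier.
#' @param features data frame with columns `gene_id`, `species_id`, then one
#'   column per feature (numeric = continuous, character = categorical).
#' @param labels data frame with columns `gene_id` and `essential` (0/1).
#' @param meta named list of species metadata (quality tier, condition,
#'   lifestyle tags).
#' @return an object of class `species_dataset`.
#' @export
species_dataset <- function(species_id, features, labels, meta = list()) {
  stopifnot(is.data.frame(features), is.data.frame(labels))
  if (!all(c("gene_id", "species_id") %in% names(features))) {
    stop_invalid("`features` must have gene_id and species_id columns")
  }
  if (!all(c("gene_id", "essential") %in% names(labels))) {
    stop_invalid("`labels` must have gene_id and essential columns")
  }
  if (anyDuplicated(features$gene_id)) stop_invalid("duplicated gene_id in features")
  if (!all(labels$essential %in% c(0L, 1L))) {
    stop_invalid("labels must be 0/1")
  }
  if (!setequal(features$gene_id, labels$gene_id)) {
    stop_invalid("feature and label gene ids disagree for species %s", species_id)
  }
  labels <- labels[match(features$gene_id, labels$gene_id), , drop = FALSE]
  rownames(labels) <- NULL
  structure(list(species_id = species_id, features = features,
                 labels = labels, meta = meta),
            class = "species_dataset")
}

#' @export
print.species_dataset <- function(x, ...) {
  cat(sprintf("species_dataset %s: %d genes, %d features, %.1f%% essential\n",
              x$species_id, nrow(x$features), ncol(x$features) - 2L,
              100 * mean(x$labels$essential)))
  invisible(x)
}

#' Flip binary labels with a fixed error probability
#'
#' Models training-set quality: each label is independently flipped with
#' probability `q`, emulating the systematic error of, e.g., transposon
#' mutagenesis screens relative to systematic gene deletion.
#'
#' @param labels integer 0/1 vector.
#' @param q flip probability in \[0, 0.5\].
#' @param seed integer RNG seed.
#' @return integer 0/1 vector of the same length.
#' @examples
#' apply_label_noise(c(1L, 0L, 1L, 1L), q = 0.5, seed = 42)
#' @export
apply_label_noise <- function(labels, q, seed = 1) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 0.5) {
    stop_invalid("`q` must be a single value in [0, 0.5]")
  }
  if (!all(labels %in% c(0L, 1L))) stop_invalid("`labels` must be 0/1")
  if (q == 0) return(as.integer(labels))
  flip <- with_seed(seed, stats::runif(length(labels)) < q)
  as.integer(ifelse(flip, 1L - as.integer(labels), as.integer(labels)))
}

#' Simulate a multi-species essentiality corpus
#'
#' Generates one labeled dataset per tip of `tree`, sharing a single set of
#' ortholog families. A latent importance score per family evolves by
#' Brownian motion along the tree, as does the class-separation direction of
#' the continuous features, so the feature-label association decays with
#' divergence time. Designated "biosynthesis" genes are essential only under
#' minimal medium and designated "energy" genes are keyed to the oxygen tag;
#' each species' essentiality threshold is solved so the realized essential
#' fraction matches its target. Reported labels are then flipped with the
#' per-species `label_noise`, and a missing-completely-at-random mask is
#' applied to feature cells.
#'
#' Continuous features are class-conditional Gaussians (unit noise) around
#' the drifted class means of the species' *intrinsic* class (thresholded
#' latent importance without the condition/lifestyle terms); the first
#' categorical feature carries a functional-category marker (level `"B"` for
#' biosynthesis, `"E"` for energy genes) and all other categorical levels
#' bin a noisy copy of the latent importance.
#'
#' @param config a [sim_config()].
#' @param tree a `divergence_matrix` from [simulate_divergence_tree()] or
#'   [divergence_from_tree()]; its species count must match `config`.
#' @return named list of [species_dataset()] objects, one per species, with
#'   the designated gene subsets attached as attributes `biosynthesis_genes`
#'   and `energy_genes` (family indices) and the config as `config`.
#' @examples
#' tr <- simulate_divergence_tree(3, seed = 1)
#' cfg <- sim_config(n_species = 3, n_genes_per_species = 100,
#'                   essential_fraction = 0.2, seed = 1)
#' corpus <- simulate_multispecies(cfg, tr)
#' corpus[[1]]
#' @export
simulate_multispecies <- function(config, tree) {
  stopifnot(inherits(config, "sim_config"), inherits(tree, "divergence_matrix"))
  species <- tree$species
  if (length(species) != config$n_species) {
    stop_invalid("tree has %d species but config expects %d",
                 length(species), config$n_species)
  }
  n <- config$n_genes_per_species
  seed <- config$seed
  pi_s <- per_species(config$essential_fraction, species, "essential_fraction")
  q_s <- per_species(config$label_noise, species, "label_noise")
  cond_s <- per_species(config$condition, species, "condition")
  gram_s <- per_species(config$gram, species, "gram")
  oxy_s <- per_species(config$oxygen, species, "oxygen")
  shape_s <- per_species(config$shape, species, "shape")

  # family-level designations, shared across species
  subsets <- with_seed(seed_stream(seed, "families"), {
    idx <- sample.int(n)
    nb <- round(config$conditional_gene_fraction * n)
    ne <- round(config$energy_gene_fraction * n)
    list(bio = sort(idx[seq_len(nb)]),
         energy = sort(idx[nb + seq_len(ne)]))
  })

  # latent family importance and class-separation direction, both Brownian
  z_root <- with_seed(seed_stream(seed, "z-root"), stats::rnorm(n))
  Z <- with_seed(seed_stream(seed, "z-bm"),
                 bm_tips(tree$phylo, z_root, config$drift_sigma))
  b_root <- config$feature_effect * rep_len(c(1, -1), config$n_features_cont)
  B <- with_seed(seed_stream(seed, "b-bm"),
                 bm_tips(tree$phylo, b_root, config$drift_sigma))

  out <- vector("list", length(species))
  names(out) <- species
  for (i in seq_along(species)) {
    sp <- species[i]
    z <- Z[sp, ]
    k_target <- round(n * pi_s[sp])
    if (k_target < 1 || k_target > n - 1 || abs(k_target / n - pi_s[sp]) > 0.02) {
      stop_invalid("essential fraction %.3f unattainable with %d genes in %s",
                   pi_s[sp], n, sp)
    }

    # intrinsic class: top-pi share of raw importance (features condition on it)
    intrinsic <- logical(n)
    intrinsic[order(z, decreasing = TRUE)[seq_len(k_target)]] <- TRUE

    # reported essentiality: importance shifted by condition and lifestyle,
    # thresholded at the order statistic that realizes the target fraction
    shift <- numeric(n)
    shift[subsets$bio] <- if (cond_s[sp] == "minimal") config$condition_effect_size else -config$condition_effect_size
    shift[subsets$energy] <- switch(oxy_s[sp],
                                    aerobe = config$lifestyle_effect_size,
                                    anaerobe = -config$lifestyle_effect_size,
                                    facultative = 0)
    latent <- z + shift
    y_true <- logical(n)
    y_true[order(latent, decreasing = TRUE)[seq_len(k_target)]] <- TRUE
    realized <- mean(y_true)
    if (abs(realized - pi_s[sp]) > 0.02) {
      stop_invalid("realized essential fraction %.3f misses target %.3f in %s",
                   realized, pi_s[sp], sp)
    }

    # continuous features: class-conditional Gaussian, drifted means
    Xc <- with_seed(seed_stream(seed, "xcont", i), {
      noise <- matrix(stats::rnorm(n * config$n_features_cont), n)
      noise + outer(ifelse(intrinsic, 0.5, -0.5), B[sp, ])
    })
    colnames(Xc) <- sprintf("cont%02d", seq_len(config$n_features_cont))

    # categorical features: functional marker + quantile bins of noisy z
    Xk <- NULL
    if (config$n_features_cat > 0) {
      Xk <- with_seed(seed_stream(seed, "xcat", i), {
        m <- matrix(NA_character_, n, config$n_features_cat)
        for (f in seq_len(config$n_features_cat)) {
          zc <- z + stats::rnorm(n)
          nlev <- if (f == 1L) max(config$n_cat_levels - 2L, 2L) else config$n_cat_levels
          br <- stats::quantile(zc, probs = seq(0, 1, length.out = nlev + 1L),
                                type = 7, names = FALSE)
          br[1] <- -Inf; br[length(br)] <- Inf
          br <- unique(br)
          lev <- as.integer(cut(zc, breaks = br, include.lowest = TRUE))
          m[, f] <- sprintf("L%d", lev)
          if (f == 1L) {
            m[subsets$bio, f] <- "B"
            m[subsets$energy, f] <- "E"
          }
        }
        colnames(m) <- sprintf("cat%02d", seq_len(config$n_features_cat))
        m
      })
    }

    y <- apply_label_noise(as.integer(y_true), q_s[sp],
                           seed_stream(seed, "noise", i))

    gene_id <- sprintf("%s_g%04d", sp, seq_len(n))
    features <- data.frame(gene_id = gene_id, species_id = sp, Xc,
                           stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(Xk)) {
      features <- cbind(features,
                        as.data.frame(Xk, stringsAsFactors = FALSE))
    }

    if (config$missing_rate > 0) {
      feat_cols <- setdiff(names(features), c("gene_id", "species_id"))
      features[feat_cols] <- with_seed(seed_stream(seed, "missing", i), {
        lapply(features[feat_cols], function(col) {
          col[stats::runif(n) < config$missing_rate] <- NA
          col
        })
      })
    }

    tier <- if (q_s[sp] <= 0.02) "deletion" else if (q_s[sp] <= 0.15) "transposon" else "inferred"
    meta <- list(species_id = sp, quality_tier = tier,
                 growth_condition = unname(cond_s[sp]), gram = unname(gram_s[sp]),
                 oxygen = unname(oxy_s[sp]), shape = unname(shape_s[sp]),
                 label_noise = unname(q_s[sp]),
                 essential_fraction = unname(pi_s[sp]))
    out[[sp]] <- species_dataset(sp, features,
                                 data.frame(gene_id = gene_id, essential = y,
                                            stringsAsFactors = FALSE),
                                 meta)
  }
  attr(out, "biosynthesis_genes") <- subsets$bio
  attr(out, "energy_genes") <- subsets$energy
  attr(out, "config") <- config
  out
}

#' Species metadata table of a corpus
#'
#' Collects the per-species metadata of a simulated (or loaded) corpus into
#' the data frame consumed by [rule_based_select()].
#'
#' @param datasets named list of `species_dataset` objects.
#' @return data frame with columns `species_id`, `quality_tier`,
#'   `growth_condition`, `gram`, `oxygen`, `shape`.
#' @export
corpus_metadata <- function(datasets) {
  rows <- lapply(datasets, function(d) {
    m <- d$meta
    data.frame(species_id = d$species_id,
               quality_tier = m$quality_tier %||% NA_character_,
               growth_condition = m$growth_condition %||% NA_character_,
               gram = m$gram %||% NA_character_,
               oxygen = m$oxygen %||% NA_character_,
               shape = m$shape %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
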