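# shared fixture factories (all data built in code at test time)

make_corpus <- function(n_species = 4, n_genes = 500, seed = 1, ...) {
  tr <- simulate_divergence_tree(n_species, seed = seed)
  cfg <- sim_config(n_species, n_genes_per_species = n_genes, seed = seed, ...)
  list(tree = tr, datasets = simulate_multispecies(cfg, tr))
}

# balanced 3-taxon tree: A and B exactly equidistant from T
equidistant_tree <- function(depth = 3500) {
  phy <- ape::read.tree(text = sprintf("((A:%f,B:%f):0.000001,T:%f);",
                                       depth, depth, depth + 0.000001))
  divergence_from_tree(phy)
}

# minimal hand-built species dataset from plain vectors
toy_dataset <- function(species_id, x, y, categorical = NULL) {
  gene_id <- sprintf("%s_g%03d", species_id, seq_along(y))
  feats <- data.frame(gene_id = gene_id, species_id = species_id,
                      stringsAsFactors = FALSE)
  if (!is.null(x)) feats <- cbind(feats, as.data.frame(x))
  if (!is.null(categorical)) feats <- cbind(feats, as.data.frame(categorical,
                                                                 stringsAsFactors = FALSE))
  species_dataset(species_id, feats,
                  data.frame(gene_id = gene_id, essential = as.integer(y),
                             stringsAsFactors = FALSE))
}
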