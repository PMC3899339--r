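# codons excluded from CAI: stops plus the single-codon families Met/Trp
# (no synonymous variation), standard CAI practice
CAI_EXCLUDED <- c("TAA", "TAG", "TGA", "ATG", "TGG")

# synonymous families of the standard genetic code, stops removed
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

split_codons <- function(sequence) {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) %% 3 != 0) {
    stop_invalid("sequence length (%d) is not divisible by 3", nchar(sequence))
  }
  substring(sequence, seq(1, nchar(sequence), by = 3), seq(3, nchar(sequence), by = 3))
}

#' Relative adaptiveness weights for CAI
#'
#' Computes per-codon relative adaptiveness from a reference gene set:
#' within each synonymous family, codon frequency divided by the frequency
#' of the most-used synonym. Codons never observed in the reference receive
#' a small floor weight (0.01) so the geometric mean stays defined.
#'
#' @param sequences named character vector of cDNA sequences (or a
#'   `Biostrings::DNAStringSet`), lengths divisible by 3.
#' @param ref_ids optional names of the reference genes; default all.
#' @return named numeric weights in (0, 1\] for all non-stop codons.
#' @export
cai_weights <- function(sequences, ref_ids = NULL) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (!is.null(ref_ids)) {
    missing_ids <- setdiff(ref_ids, names(sequences))
    if (length(missing_ids)) stop_invalid("reference genes not found: %s",
                                          paste(missing_ids, collapse = ", "))
    sequences <- sequences[ref_ids]
  }
  if (!length(sequences)) stop_invalid("empty reference set")
  codons <- unlist(lapply(sequences, split_codons), use.names = FALSE)
  counts <- table(factor(codons, levels = names(Biostrings::GENETIC_CODE)))
  fams <- codon_families()
  w <- c()
  for (fam in fams) {
    cnt <- as.numeric(counts[fam])
    mx <- max(cnt)
    wf <- if (mx > 0) cnt / mx else rep(1, length(cnt))
    wf[wf == 0] <- 0.01
    w[fam] <- wf
  }
  w
}

#' Codon adaptation index
#'
#' Geometric mean of relative adaptiveness over the codons of a gene,
#' excluding stop codons and the single-codon families ATG and TGG (no
#' synonymous variation).
#'
#' @param codons character vector of codons, or a single cDNA sequence whose
#'   length is divisible by 3.
#' @param weights named codon weights in (0, 1\], e.g. from [cai_weights()].
#' @return CAI in (0, 1\].
#' @examples
#' compute_cai(c("AAA", "GAA"), c(AAA = 1, GAA = 0.25))
#' @export
compute_cai <- function(codons, weights) {
  if (length(codons) == 1L && nchar(codons) > 3L) codons <- split_codons(codons)
  codons <- toupper(codons)
  keep <- !(codons %in% CAI_EXCLUDED)
  codons <- codons[keep]
  if (!length(codons)) stop_invalid("no codons remain after excluding stops and single-codon families")
  unknown <- setdiff(unique(codons), names(weights))
  if (length(unknown)) stop_invalid("no weight for codon(s): %s", paste(unknown, collapse = ", "))
  w <- weights[codons]
  if (any(w <= 0) || any(w > 1)) stop_invalid("weights must be in (0, 1]")
  exp(mean(log(w)))
}

validate_hits <- function(hits) {
  if (is.null(hits) || !nrow(hits)) return(hits)
  need <- c("domain_id", "bit_score", "domain_length")
  if (!all(need %in% names(hits))) {
    stop_invalid("domain hits need columns: %s", paste(need, collapse = ", "))
  }
  if (any(hits$domain_length < 1)) stop_invalid("domain_length must be >= 1")
  if (any(hits$bit_score < 0)) stop_invalid("bit_score must be >= 0")
  hits
}

#' Domain conservation score (DoC)
#'
#' Ratio of conserved-domain bit score to domain length for one gene;
#' `NA` when the gene has no hits. The default `"aggregate"` method pools
#' all hits (sum of scores over sum of lengths, using all evidence);
#' `"best"` uses only the highest-scoring hit.
#'
#' @param hits data frame of the gene's hits with columns `domain_id`,
#'   `bit_score`, `domain_length`.
#' @param method `"aggregate"` (default) or `"best"`.
#' @return score-per-length ratio, or `NA_real_` without hits.
#' @export
compute_doc <- function(hits, method = c("aggregate", "best")) {
  method <- match.arg(method)
  hits <- validate_hits(hits)
  if (is.null(hits) || !nrow(hits)) return(NA_real_)
  if (method == "best") {
    hits <- hits[order(-hits$bit_score, hits$domain_id)[1], , drop = FALSE]
  }
  sum(hits$bit_score) / sum(hits$domain_length)
}

#' Domain type (DoT)
#'
#' The domain id of the gene's highest-scoring hit; ties break
#' lexicographically by domain id. `NA` without hits.
#'
#' @inheritParams compute_doc
#' @return character domain id or `NA_character_`.
#' @export
compute_dot <- function(hits) {
  hits <- validate_hits(hits)
  if (is.null(hits) || !nrow(hits)) return(NA_character_)
  hits$domain_id[order(-hits$bit_score, hits$domain_id)][1]
}

#' PPI network centralities
#'
#' Degree (DC), local clustering coefficient (CCo), closeness (CC), and
#' betweenness (BC) centrality of every node in a protein-protein
#' interaction network, all normalized to \[0, 1\]. Self-loops and duplicate
#' edges are dropped (with a message). Closeness uses the
#' disconnected-graph correction: within-component closeness scaled by
#' (component size - 1)/(n - 1). Isolated nodes get all four = 0; nodes
#' with degree < 2 get CCo = 0.
#'
#' @param edges two-column data frame or matrix of undirected edges.
#' @param nodes gene id universe; every edge endpoint must be in it.
#' @return data frame: `gene_id`, `DC`, `CCo`, `CC`, `BC`.
#' @export
graph_centralities <- function(edges, nodes) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) && ncol(edges) < 2L) stop_invalid("`edges` needs two columns")
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_invalid("duplicated node ids")
  if (nrow(edges)) {
    ends <- unique(c(as.character(edges[[1]]), as.character(edges[[2]])))
    bad <- setdiff(ends, nodes)
    if (length(bad)) stop_invalid("edge endpoints absent from node universe: %s",
                                  paste(utils::head(bad, 5), collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = nodes))
  before <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  dropped <- before - igraph::ecount(g)
  if (dropped > 0) message(sprintf("dropped %d self-loop/duplicate edge(s)", dropped))

  n <- length(nodes)
  deg <- igraph::degree(g)
  DC <- if (n > 1) deg / (n - 1) else rep(0, n)
  CCo <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  BC <- if (n > 2) {
    igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  } else rep(0, n)

  # closeness with the disconnected-graph correction
  comp <- igraph::components(g)
  dists <- igraph::distances(g)
  CC <- numeric(n)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    csize <- length(members)
    if (csize == 1L) { CC[members] <- 0; next }
    S <- rowSums(dists[members, members, drop = FALSE])
    CC[members] <- ((csize - 1) / S) * ((csize - 1) / (n - 1))
  }
  data.frame(gene_id = nodes, DC = unname(DC[nodes]), CCo = unname(CCo[match(nodes, igraph::V(g)$name)]),
             CC = unname(CC[match(nodes, igraph::V(g)$name)]),
             BC = unname(BC[nodes]), stringsAsFactors = FALSE)
}

# undirected de-duplicated edge list with self-edges removed
clean_pairs <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(edges)) return(data.frame(a = character(0), b = character(0)))
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dedup <- !duplicated(paste(lo, hi, sep = "\r"))
  data.frame(a = lo[dedup], b = hi[dedup], stringsAsFactors = FALSE)
}

#' Number of paralogs (NP)
#'
#' Distinct within-species homology partners of a gene, from an
#' already-thresholded all-against-all map. Duplicate and self edges are
#' ignored.
#'
#' @param within_species_homology two-column edge list of homologous pairs.
#' @param gene gene id (vectorized).
#' @return integer count(s).
#' @export
paralog_count <- function(within_species_homology, gene) {
  pairs <- clean_pairs(within_species_homology)
  cnt <- table(c(pairs$a, pairs$b))
  out <- as.integer(cnt[gene])
  out[is.na(out)] <- 0L
  stats::setNames(out, gene)
}

#' Cross-species homology counts (NS, NEH, NNH)
#'
#' For a target gene: the number of *other* species with at least one
#' homolog (NS), and the numbers of essential (NEH) and non-essential (NNH)
#' homologous genes in those species. Homologs in species without labels
#' count toward NS but toward neither NEH nor NNH; the target's own species
#' is excluded from all three counts.
#'
#' @param ortholog_map two-column cross-species edge list of homologous
#'   gene pairs.
#' @param gene_species named character vector mapping gene id to species id.
#' @param labels_by_species named list: species id -> named 0/1 vector of
#'   essentiality labels (omit a species to leave it unlabeled).
#' @param target target gene id.
#' @return named integer vector `c(NS, NEH, NNH)`.
#' @export
cross_species_homology_counts <- function(ortholog_map, gene_species,
                                          labels_by_species, target) {
  if (!target %in% names(gene_species)) stop_invalid("unknown target gene %s", target)
  pairs <- clean_pairs(ortholog_map)
  partners <- unique(c(pairs$b[pairs$a == target], pairs$a[pairs$b == target]))
  own <- gene_species[[target]]
  psp <- gene_species[partners]
  if (anyNA(psp)) stop_invalid("ortholog map names genes without a species: %s",
                               paste(partners[is.na(psp)], collapse = ", "))
  keep <- psp != own
  partners <- partners[keep]; psp <- psp[keep]
  NS <- length(unique(psp))
  lab <- rep(NA_integer_, length(partners))
  for (i in seq_along(partners)) {
    ls <- labels_by_species[[psp[i]]]
    if (!is.null(ls) && partners[i] %in% names(ls)) lab[i] <- ls[[partners[i]]]
  }
  c(NS = NS, NEH = sum(lab == 1L, na.rm = TRUE), NNH = sum(lab == 0L, na.rm = TRUE))
}

#' Phyletic gene age
#'
#' Ordinal age of a gene: the index of the outermost clade (in an
#' innermost-to-outermost nested ordering, e.g. species typical,
#' Ascomycota, Opisthokonta, Eukaryota, cellular organisms) in which the
#' gene has a homolog. Presence is taken at the outermost positive clade
#' regardless of gaps; a gene with no homolog beyond itself has age 1.
#'
#' @param presence_by_clade logical vector of homolog presence per clade,
#'   in `clade_order`, or a character vector of clade names with presence.
#' @param clade_order ordered clade names, innermost first.
#' @return integer age in 1..length(clade_order).
#' @export
phyletic_age <- function(presence_by_clade, clade_order) {
  if (!length(clade_order)) stop_invalid("`clade_order` must not be empty")
  if (is.character(presence_by_clade)) {
    bad <- setdiff(presence_by_clade, clade_order)
    if (length(bad)) stop_invalid("unknown clade(s): %s", paste(bad, collapse = ", "))
    presence_by_clade <- clade_order %in% presence_by_clade
  }
  if (length(presence_by_clade) != length(clade_order)) {
    stop_invalid("presence flags and clade_order differ in length")
  }
  if (!any(presence_by_clade)) return(1L)
  max(which(presence_by_clade))
}

#' Expression mean and fluctuation
#'
#' Arithmetic mean (mE) and coefficient of variation (mEF; sample standard
#' deviation with the n-1 denominator over the mean) of a gene's expression
#' across conditions. mEF is missing with fewer than two values or a
#' non-positive mean.
#'
#' @param expression_row numeric expression values across conditions.
#' @return named numeric vector `c(mE, mEF)` (either may be `NA`).
#' @examples
#' expression_stats(c(2, 4))  # mE = 3, mEF = sqrt(2)/3
#' @export
expression_stats <- function(expression_row) {
  x <- expression_row[!is.na(expression_row)]
  if (!length(x)) return(c(mE = NA_real_, mEF = NA_real_))
  mE <- mean(x)
  mEF <- if (length(x) >= 2L && mE > 0) stats::sd(x) / mE else NA_real_
  c(mE = mE, mEF = mEF)
}

#' Assemble the 15-feature table of one species
#'
#' Combines the per-feature extractors into the canonical feature table
#' (one row per gene, 15 feature columns). Any input left `NULL` yields
#' missing values for its features; genes in the id universe but absent
#' from an input are missing for that feature (except PPI centralities,
#' which are 0 for any gene inside the supplied node universe). Reports
#' per-feature missingness as the `missingness` attribute.
#'
#' @param species_id species identifier.
#' @param gene_ids gene id universe (duplicates are an error).
#' @param domain_hits data frame `gene_id`, `domain_id`, `bit_score`,
#'   `domain_length`.
#' @param ppi_edges,ppi_nodes PPI edge list and node universe.
#' @param cdna named character vector (or `DNAStringSet`) of cDNA
#'   sequences, lengths divisible by 3 (codon frames taken as given).
#' @param cai_ref optional reference gene ids for [cai_weights()].
#' @param expression numeric matrix/data frame, rows named by gene id,
#'   columns = conditions.
#' @param paralog_edges within-species homology edge list.
#' @param ortholog_edges,gene_species,labels_by_species cross-species
#'   homology inputs, see [cross_species_homology_counts()].
#' @param clade_presence data frame/matrix of logical presence flags, rows
#'   named by gene id, columns = clades in `clade_order`.
#' @param clade_order ordered clade names, innermost first.
#' @param protein_lengths named numeric vector of protein lengths (amino
#'   acids); derived as cDNA length / 3 - 1 when absent but cDNA is given.
#' @return data frame with columns `gene_id`, `species_id`, `mE`, `mEF`,
#'   `Age`, `DoT`, `DoC`, `DC`, `CCo`, `CC`, `BC`, `PL`, `CAI`, `NP`, `NS`,
#'   `NEH`, `NNH`.
#' @export
build_feature_table <- function(species_id, gene_ids,
                                domain_hits = NULL,
                                ppi_edges = NULL, ppi_nodes = NULL,
                                cdna = NULL, cai_ref = NULL,
                                expression = NULL,
                                paralog_edges = NULL,
                                ortholog_edges = NULL, gene_species = NULL,
                                labels_by_species = NULL,
                                clade_presence = NULL, clade_order = NULL,
                                protein_lengths = NULL) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop_invalid("duplicated gene_id in universe")
  n <- length(gene_ids)
  tab <- data.frame(gene_id = gene_ids, species_id = species_id,
                    mE = NA_real_, mEF = NA_real_, Age = NA_integer_,
                    DoT = NA_character_, DoC = NA_real_,
                    DC = NA_real_, CCo = NA_real_, CC = NA_real_, BC = NA_real_,
                    PL = NA_real_, CAI = NA_real_,
                    NP = NA_integer_, NS = NA_integer_,
                    NEH = NA_integer_, NNH = NA_integer_,
                    stringsAsFactors = FALSE)

  if (!is.null(expression) && nrow(as.data.frame(expression))) {
    em <- as.matrix(expression)
    for (g in intersect(gene_ids, rownames(em))) {
      st <- expression_stats(as.numeric(em[g, ]))
      tab[tab$gene_id == g, c("mE", "mEF")] <- as.list(st)
    }
  }

  if (!is.null(domain_hits) && nrow(domain_hits)) {
    validate_hits(domain_hits)
    for (g in intersect(gene_ids, unique(domain_hits$gene_id))) {
      h <- domain_hits[domain_hits$gene_id == g, , drop = FALSE]
      tab$DoC[tab$gene_id == g] <- compute_doc(h)
      tab$DoT[tab$gene_id == g] <- compute_dot(h)
    }
  }

  if (!is.null(ppi_nodes)) {
    cent <- graph_centralities(ppi_edges %||% data.frame(a = character(0), b = character(0)),
                               ppi_nodes)
    idx <- match(tab$gene_id, cent$gene_id)
    hit <- !is.na(idx)
    tab[hit, c("DC", "CCo", "CC", "BC")] <- cent[idx[hit], c("DC", "CCo", "CC", "BC")]
  }

  if (!is.null(cdna)) {
    if (inherits(cdna, "DNAStringSet")) {
      cdna <- stats::setNames(as.character(cdna), names(cdna))
    }
    w <- cai_weights(cdna, ref_ids = cai_ref)
    for (g in intersect(gene_ids, names(cdna))) {
      tab$CAI[tab$gene_id == g] <- compute_cai(cdna[[g]], w)
    }
    if (is.null(protein_lengths)) {
      pl <- nchar(cdna) / 3 - 1
      idx <- match(names(cdna), tab$gene_id)
      tab$PL[idx[!is.na(idx)]] <- pl[!is.na(idx)]
    }
  }
  if (!is.null(protein_lengths)) {
    idx <- match(names(protein_lengths), tab$gene_id)
    tab$PL[idx[!is.na(idx)]] <- protein_lengths[!is.na(idx)]
  }

  if (!is.null(paralog_edges)) {
    tab$NP <- unname(paralog_count(paralog_edges, gene_ids))
  }

  if (!is.null(ortholog_edges)) {
    if (is.null(gene_species)) stop_invalid("`gene_species` is required with `ortholog_edges`")
    for (g in gene_ids) {
      cnt <- cross_species_homology_counts(ortholog_edges, gene_species,
                                           labels_by_species %||% list(), g)
      tab[tab$gene_id == g, c("NS", "NEH", "NNH")] <- as.list(as.integer(cnt))
    }
  }

  if (!is.null(clade_presence)) {
    if (is.null(clade_order)) stop_invalid("`clade_order` is required with `clade_presence`")
    cp <- as.matrix(clade_presence)
    for (g in intersect(gene_ids, rownames(cp))) {
      tab$Age[tab$gene_id == g] <- phyletic_age(as.logical(cp[g, clade_order]), clade_order)
    }
  }

  feat_cols <- setdiff(names(tab), c("gene_id", "species_id"))
  attr(tab, "missingness") <- vapply(tab[feat_cols], function(x) sum(is.na(x)), integer(1))
  tab
}
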