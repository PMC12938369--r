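#' Generate miRNA-like sequences with planted similarity clusters
#'
#' Cluster ancestors are drawn uniformly over `{A,C,G,U}` with lengths in
#' `length_range` (19-25 nt, the mature-miRNA range); members are
#' point-mutated copies of their ancestor, so same-cluster pairs have higher
#' expected alignment identity than cross-cluster pairs. With
#' `mutation_rate = 0` all within-cluster identities are 100%; with
#' `n_clusters = n` there is no planted structure.
#'
#' @param n number of sequences.
#' @param length_range integer range of sequence lengths.
#' @param n_clusters number of ancestor clusters (`1 <= n_clusters <= n`).
#' @param mutation_rate per-position substitution probability in `[0,1]`.
#' @param seed integer seed.
#' @return list with `sequences` (named character vector, ids
#'   `syn-mir-0001`, ...) and `clusters` (integer cluster label per
#'   sequence).
#' @export
generate_sequences <- function(n, length_range = c(19, 25), n_clusters = 8,
                               mutation_rate = 0.05, seed = 1) {
  stopifnot(n >= 1, n_clusters >= 1, n >= n_clusters)
  if (mutation_rate < 0 || mutation_rate > 1)
    stopf("mutation_rate must lie in [0,1]")
  bases <- c("A", "C", "G", "U")
  set.seed(substream_seed(seed, "sequences"))
  anc_len <- sample(length_range[1L]:length_range[2L], n_clusters,
                    replace = TRUE)
  ancestors <- lapply(anc_len, function(l) sample(bases, l, replace = TRUE))
  clusters <- sort(rep_len(seq_len(n_clusters), n))
  seqs <- vapply(seq_len(n), function(i) {
    s <- ancestors[[clusters[i]]]
    mut <- stats::runif(length(s)) < mutation_rate
    if (any(mut)) {
      s[mut] <- vapply(s[mut],
                       function(b) sample(setdiff(bases, b), 1L), "")
    }
    paste(s, collapse = "")
  }, "")
  ids <- sprintf("syn-mir-%04d", seq_len(n))
  list(sequences = stats::setNames(seqs, ids),
       clusters = stats::setNames(clusters, ids))
}

# calibrate an additive offset so that mean(plogis(logits + offset)) = target
calibrate_offset <- function(logits, target) {
  if (target <= 0 || target >= 1)
    stopf("infeasible density: %.3f (must be in (0,1))", target)
  f <- function(o) mean(logistic(logits + o)) - target
  stats::uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root
}

#' Generate a full synthetic dataset with known latent structure
#'
#' Emulates the statistical regime the method assumes: a low-rank
#' miRNA-disease association matrix at ~1-3% density, disease-gene edges
#' correlated with the disease factors, and sequence clusters aligned with
#' the miRNA factors so that every sequence-derived relation genuinely
#' carries association signal. miRNA factors are the cluster centroid plus
#' per-miRNA jitter; association probabilities are
#' `logistic(scale * (1 - noise) * <m, d>/sqrt(latent_dim) + offset)` with
#' the offset calibrated to the target density, so `noise = 1` degenerates
#' to a constant probability (no signal). All edges are independent
#' Bernoulli draws; everything is reproducible from the seed via named
#' substreams.
#'
#' @param n_mirna,n_disease,n_gene entity counts.
#' @param latent_dim latent factor dimension.
#' @param target_density target MDA density in percent.
#' @param noise signal attenuation in `[0,1]` (0 = full signal, 1 = none).
#' @param seed master seed.
#' @param n_clusters sequence/factor clusters (default 8).
#' @param mutation_rate within-cluster sequence divergence (default 0.05).
#' @param factor_jitter sd of per-miRNA factor jitter around the cluster
#'   centroid (default 0.3).
#' @param affinity_scale logit scale of the association signal (default 3).
#' @param dg_density disease-gene edge density in percent (default 5).
#' @param dg_scale logit scale of the disease-gene affinity (default 3).
#' @return list with `inputs` (list: `sequences`, `mirna_disease` and
#'   `disease_gene` association tables) and `truth` (a `synthetic_truth`:
#'   factors, association probability matrix, clusters, seed).
#' @export
generate_dataset <- function(n_mirna = 200, n_disease = 100, n_gene = 300,
                             latent_dim = 4, target_density = 2, noise = 0.1,
                             seed = 1, n_clusters = 8, mutation_rate = 0.05,
                             factor_jitter = 0.3, affinity_scale = 3,
                             dg_density = 5, dg_scale = 3) {
  stopifnot(n_mirna >= latent_dim, n_disease >= latent_dim,
            n_gene >= latent_dim, noise >= 0, noise <= 1)
  sq <- generate_sequences(n_mirna, n_clusters = n_clusters,
                           mutation_rate = mutation_rate, seed = seed)

  set.seed(substream_seed(seed, "factors"))
  centroids <- matrix(stats::rnorm(n_clusters * latent_dim), n_clusters)
  mirna_factors <- centroids[sq$clusters, , drop = FALSE] +
    factor_jitter * matrix(stats::rnorm(n_mirna * latent_dim), n_mirna)
  disease_factors <- matrix(stats::rnorm(n_disease * latent_dim), n_disease)
  gene_factors <- matrix(stats::rnorm(n_gene * latent_dim), n_gene)

  disease_ids <- sprintf("disease-%03d", seq_len(n_disease))
  gene_ids <- sprintf("gene-%04d", seq_len(n_gene))
  rownames(mirna_factors) <- names(sq$sequences)
  rownames(disease_factors) <- disease_ids
  rownames(gene_factors) <- gene_ids

  raw <- tcrossprod(mirna_factors, disease_factors) / sqrt(latent_dim)
  logits <- affinity_scale * (1 - noise) * raw
  offset <- calibrate_offset(logits, target_density / 100)
  association_prob <- logistic(logits + offset)

  set.seed(substream_seed(seed, "edges"))
  mda <- matrix(stats::rbinom(length(association_prob), 1,
                              association_prob),
                n_mirna, dimnames = dimnames(association_prob))
  idx <- which(mda == 1, arr.ind = TRUE)
  mirna_disease <- association_table("mirna_disease",
                                     rownames(mda)[idx[, 1L]],
                                     disease_ids[idx[, 2L]])

  raw_g <- tcrossprod(disease_factors, gene_factors) / sqrt(latent_dim)
  logits_g <- dg_scale * raw_g
  offset_g <- calibrate_offset(logits_g, dg_density / 100)
  set.seed(substream_seed(seed, "dg_edges"))
  dg <- matrix(stats::rbinom(length(logits_g), 1,
                             logistic(logits_g + offset_g)),
               n_disease)
  idx_g <- which(dg == 1, arr.ind = TRUE)
  disease_gene <- association_table("disease_gene",
                                    disease_ids[idx_g[, 1L]],
                                    gene_ids[idx_g[, 2L]])

  truth <- structure(list(seed = seed, n_mirna = n_mirna,
                          n_disease = n_disease, n_gene = n_gene,
                          latent_dim = latent_dim,
                          mirna_factors = mirna_factors,
                          disease_factors = disease_factors,
                          gene_factors = gene_factors,
                          association_prob = association_prob,
                          clusters = sq$clusters,
                          sequences = sq$sequences,
                          target_density = target_density, noise = noise),
                     class = "synthetic_truth")
  list(inputs = list(sequences = sq$sequences,
                     mirna_disease = mirna_disease,
                     disease_gene = disease_gene),
       truth = truth)
}

#' Bayes-oracle scores for miRNA-disease pairs
#'
#' Returns the true association probability for each pair — ranking by these
#' is Bayes-optimal on the generated edges and upper-bounds (in expectation)
#' any trained model's ranking performance.
#'
#' @param truth a `synthetic_truth`.
#' @param pairs data.frame with columns `mirna`, `disease` (ids).
#' @return numeric vector of probabilities in `[0,1]`.
#' @export
oracle_scores <- function(truth, pairs) {
  stopifnot(inherits(truth, "synthetic_truth"))
  mi <- match(pairs$mirna, rownames(truth$association_prob))
  di <- match(pairs$disease, colnames(truth$association_prob))
  if (anyNA(mi) || anyNA(di)) stopf("pair(s) outside the generated entities")
  truth$association_prob[cbind(mi, di)]
}

#' Assemble the heterogeneous graph from generated inputs
#'
#' Convenience wrapper: computes the similarity graph and pattern incidence
#' from the generated sequences and assembles the full graph.
#'
#' @param inputs the `inputs` element of [generate_dataset()].
#' @param threshold_pct similarity threshold (default 60).
#' @param scheme a [scoring_scheme()].
#' @return a `hetero_graph`.
#' @export
build_synthetic_graph <- function(inputs, threshold_pct = 60,
                                  scheme = scoring_scheme()) {
  sim <- build_similarity_graph(inputs$sequences, scheme, threshold_pct)
  pat <- motif_incidence(inputs$sequences, k = 4)
  assemble_graph(inputs$mirna_disease, inputs$disease_gene, sim, pat)
}

#' Gene-dominant synthetic benchmark
#'
#' Builds a structured dataset in which the disease-gene relation carries
#' the dominant predictive signal for cold-start miRNA evaluation, while the
#' two miRNA-side relations are individually dispensable. Diseases come in
#' groups; each group owns a disjoint pair of sequence clusters and a
#' group-exclusive gene set, and every disease has exactly two associations:
#' one miRNA in each of its group's clusters. When a fold hides one of the
#' two, the disease's remaining training edge points at the *other* cluster,
#' so only the shared genes -- via sibling diseases whose edges into the
#' evaluated cluster stay in training -- can route the group-level signal to
#' the scored pair. Within-cluster sequences are identical, so k-mer input
#' features (or either similarity-derived relation) suffice to place a cold
#' miRNA in its cluster.
#'
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param n_groups number of disease groups (uses `2 * n_groups` clusters).
#' @param per_cluster miRNAs per sequence cluster.
#' @param diseases_per_group diseases sharing each group's gene set.
#' @param genes_per_group group-exclusive genes.
#' @return list with `graph` (a `hetero_graph`) and `sequences` (named
#'   character vector, one per miRNA) for building k-mer input features.
#' @export
gene_dominant_fixture <- function(seed = 1, n_groups = 8, per_cluster = 10,
                                  diseases_per_group = 30,
                                  genes_per_group = 6) {
  stopifnot(n_groups >= 1, per_cluster >= 1, diseases_per_group >= 1,
            genes_per_group >= 1)
  n_clusters <- 2L * n_groups
  n_mirna <- n_clusters * per_cluster
  sq <- generate_sequences(n_mirna, n_clusters = n_clusters,
                           mutation_rate = 0, seed = seed)
  set.seed(substream_seed(seed, "gene_fixture"))
  n_disease <- n_groups * diseases_per_group
  disease_ids <- sprintf("disease-%03d", seq_len(n_disease))
  d_group <- rep(seq_len(n_groups), each = diseases_per_group)
  partner_a <- vapply(d_group, function(g)
    sample(names(sq$sequences)[sq$clusters == 2L * g - 1L], 1L), "")
  partner_b <- vapply(d_group, function(g)
    sample(names(sq$sequences)[sq$clusters == 2L * g], 1L), "")
  mirna_disease <- association_table(
    "mirna_disease", c(partner_a, partner_b), rep(disease_ids, 2L))
  gene_ids <- sprintf("gene-%04d", seq_len(n_groups * genes_per_group))
  g_group <- rep(seq_len(n_groups), each = genes_per_group)
  dg_dst <- unlist(lapply(d_group, function(g) gene_ids[g_group == g]))
  disease_gene <- association_table(
    "disease_gene", rep(disease_ids, each = genes_per_group), dg_dst)
  list(graph = build_synthetic_graph(list(sequences = sq$sequences,
                                          mirna_disease = mirna_disease,
                                          disease_gene = disease_gene)),
       sequences = sq$sequences)
}
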