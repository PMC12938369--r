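# Independent oracles and small fixture builders shared across tests.

# exhaustive enumeration of all global alignments (no DP): max score over
# every way of interleaving the two sequences with gaps
enum_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# sliding-window k-mer tally independent of the package implementation
tally_kmers <- function(seq, k) {
  kmers <- substring(seq, 1:(nchar(seq) - k + 1), k:nchar(seq))
  bases <- c("A", "C", "G", "U")
  all_k <- sort(apply(do.call(expand.grid, rep(list(bases), k)), 1,
                      paste, collapse = ""))
  counts <- table(factor(kmers, levels = all_k))
  as.numeric(counts)
}

random_rna <- function(n, len = 20) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    "")
}

# brute-force AUC: fraction of correctly ordered (pos, neg) pairs, ties 1/2
brute_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

# dense triple-loop message-passing oracle: loops over every (target node,
# directed relation, neighbor) explicitly, per-relation neighbor mean
dense_layer_oracle <- function(H, graph, params, layer) {
  lay <- params$layers[[layer]]
  rels <- canonical_relations()
  out <- list()
  for (t in c("mirna", "disease", "gene", "pattern")) {
    n_t <- length(graph$nodes[[t]])
    Z <- matrix(0, n_t, ncol(lay$W0))
    for (v in seq_len(n_t)) {
      z <- as.numeric(H[[t]][v, ] %*% lay$W0)
      for (dr in directed_relations()) {
        if (dr$dst != t) next
        e <- graph$edges[[dr$canonical]]
        if (dr$canonical == "mirna_mirna") {
          nbr <- c(e[e[, 1] == v, 2], e[e[, 2] == v, 1])
        } else if (endsWith(dr$name, "__fwd")) {
          nbr <- e[e[, 2] == v, 1]
        } else {
          nbr <- e[e[, 1] == v, 2]
        }
        if (length(nbr) == 0) next
        msg <- 0
        for (u in nbr) msg <- msg + as.numeric(H[[dr$src]][u, ] %*% lay$We[[dr$name]])
        z <- z + msg / length(nbr)
      }
      Z[v, ] <- z
    }
    out[[t]] <- pmax(Z, 0)
  }
  out
}

# a small random heterogeneous graph built directly from random matrices
# (no sequence alignment involved), for fast property sweeps
random_toy_graph <- function(seed, n_m = 8, n_d = 5, n_g = 4, n_pat_k = 2,
                             density = 0.3) {
  set.seed(seed)
  m_ids <- sprintf("m%02d", seq_len(n_m))
  d_ids <- sprintf("d%02d", seq_len(n_d))
  g_ids <- sprintf("g%02d", seq_len(n_g))
  pats <- sort(apply(do.call(expand.grid,
                             rep(list(c("A", "C", "G", "U")), n_pat_k)), 1,
                     paste, collapse = ""))
  md <- which(matrix(runif(n_m * n_d) < density, n_m), arr.ind = TRUE)
  if (nrow(md) == 0) md <- cbind(1, 1)
  dg <- which(matrix(runif(n_d * n_g) < 0.3, n_d), arr.ind = TRUE)
  if (nrow(dg) == 0) dg <- cbind(1, 1)
  sim <- matrix(0, n_m, n_m, dimnames = list(m_ids, m_ids))
  up <- which(upper.tri(sim) & matrix(runif(n_m^2) < 0.3, n_m), arr.ind = TRUE)
  sim[up] <- 1; sim <- sim + t(sim)
  pat <- matrix(as.integer(runif(n_m * length(pats)) < 0.4), n_m,
                dimnames = list(m_ids, pats))
  pat[, 1] <- 1  # every miRNA carries at least one pattern
  assemble_graph(
    association_table("mirna_disease", m_ids[md[, 1]], d_ids[md[, 2]]),
    association_table("disease_gene", d_ids[dg[, 1]], g_ids[dg[, 2]]),
    sim, pat)
}

# cheap training configuration for protocol tests (overridable defaults)
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(dims = c(16, 16, 16), max_epochs = 60,
                                 patience = 10, seed = seed), list(...))
  do.call(train_config, args)
}

# small planted-signal dataset + graph used by several training tests.
# affinity_scale 6 / noise 0.05 plant a STRONG signal (Bayes-oracle AUC on a
# held-out fold ~0.99), so the trained-model bar tests generalization, not
# the fixture's ceiling.
small_signal_graph <- function(seed = 21, n_mirna = 50, n_disease = 25,
                               n_gene = 40, density = 8, noise = 0.05) {
  ds <- generate_dataset(n_mirna = n_mirna, n_disease = n_disease,
                         n_gene = n_gene, latent_dim = 3,
                         target_density = density, noise = noise,
                         seed = seed, n_clusters = 5, affinity_scale = 6)
  list(graph = build_synthetic_graph(ds$inputs), truth = ds$truth,
       inputs = ds$inputs)
}
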