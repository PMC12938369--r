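#' Canonical relation schema of the heterogeneous graph
#'
#' Five relations over four node types: experimentally supported
#' miRNA-disease associations, sequence-similarity edges between miRNAs,
#' curated disease-gene links, miRNA-pattern incidence (which 4-mers occur in
#' which miRNA), and derived pattern-disease edges (a pattern touches a
#' disease iff some miRNA carries the pattern and is associated with the
#' disease).
#'
#' @return named list: for each relation, `c(source_type, target_type)`.
#' @export
canonical_relations <- function() {
  list(mirna_disease   = c("mirna",   "disease"),
       mirna_mirna     = c("mirna",   "mirna"),
       disease_gene    = c("disease", "gene"),
       mirna_pattern   = c("mirna",   "pattern"),
       pattern_disease = c("pattern", "disease"))
}

#' Node types of the heterogeneous graph
#'
#' @return character vector of the four node types.
#' @export
node_types <- function() c("mirna", "disease", "gene", "pattern")

new_hetero_graph <- function(nodes, edges, features = NULL) {
  structure(list(nodes = nodes, edges = edges, features = features),
            class = "hetero_graph")
}

# pairs: 2-col integer index matrix into the source/target node vectors
edge_index <- function(src_ids, dst_ids, src_nodes, dst_nodes, relation) {
  si <- match(src_ids, src_nodes)
  di <- match(dst_ids, dst_nodes)
  bad <- unique(c(src_ids[is.na(si)], dst_ids[is.na(di)]))
  if (length(bad)) {
    stopf("%s: edge(s) reference unknown node(s): %s", relation,
          paste(utils::head(bad, 10L), collapse = ", "))
  }
  m <- cbind(src = si, dst = di)
  m <- m[!duplicated(m), , drop = FALSE]
  # canonical row order: the edge set is order-free, so store it sorted
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Assemble the heterogeneous graph
#'
#' Combines the miRNA-disease and disease-gene association tables with the
#' sequence-derived miRNA-miRNA similarity adjacency and miRNA-pattern
#' incidence into a single typed graph. Pattern-disease edges are derived
#' from the full miRNA-disease set via [derive_pattern_disease_edges()].
#' Node orderings are deterministic (lexicographically sorted ids). miRNAs
#' appearing in association tables but lacking a sequence (no row in
#' `similarity`/`patterns`) are dropped with a warning, since three of the
#' five relations require sequence-derived features.
#'
#' @param mirna_disease an `association_table` with relation `mirna_disease`.
#' @param disease_gene an `association_table` with relation `disease_gene`.
#' @param similarity symmetric binary adjacency from
#'   [build_similarity_graph()], rownames = miRNA ids.
#' @param patterns binary incidence matrix from [motif_incidence()].
#' @param features optional named list of per-type feature matrices.
#' @return a `hetero_graph`: node id vectors per type, edge index matrices
#'   per relation, optional features.
#' @export
assemble_graph <- function(mirna_disease, disease_gene, similarity, patterns,
                           features = NULL) {
  stopifnot(inherits(mirna_disease, "association_table"),
            mirna_disease$relation_name == "mirna_disease",
            inherits(disease_gene, "association_table"),
            disease_gene$relation_name == "disease_gene",
            is.matrix(similarity), is.matrix(patterns))
  if (!setequal(rownames(similarity), rownames(patterns)))
    stopf("similarity and pattern matrices cover different miRNA sets")

  mirnas <- sort(norm_id(rownames(patterns)))
  md <- mirna_disease$pairs
  missing_m <- setdiff(unique(md$source), mirnas)
  if (length(missing_m)) {
    warnf("dropping %d miRNA(s) without sequences from associations: %s",
          length(missing_m), paste(utils::head(missing_m, 5L), collapse = ", "))
    md <- md[md$source %in% mirnas, , drop = FALSE]
  }
  diseases <- sort(unique(c(md$target, disease_gene$pairs$source)))
  genes <- sort(unique(disease_gene$pairs$target))
  pats <- sort(colnames(patterns))
  nodes <- list(mirna = mirnas, disease = diseases, gene = genes,
                pattern = pats)

  sim <- similarity[mirnas, mirnas, drop = FALSE]
  if (!isTRUE(all.equal(sim, t(sim))))
    stopf("similarity adjacency must be symmetric")
  canon <- function(m) m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  ut <- which(upper.tri(sim) & sim > 0, arr.ind = TRUE)
  mm <- canon(cbind(src = ut[, 1L], dst = ut[, 2L]))

  pat <- patterns[mirnas, pats, drop = FALSE]
  mp_idx <- which(pat > 0, arr.ind = TRUE)
  mp <- canon(cbind(src = mp_idx[, 1L], dst = mp_idx[, 2L]))

  pd <- derive_pattern_disease_edges(pat, md, md)

  edges <- list(
    mirna_disease = edge_index(md$source, md$target, mirnas, diseases,
                               "mirna_disease"),
    mirna_mirna = mm[!duplicated(mm), , drop = FALSE],
    disease_gene = edge_index(disease_gene$pairs$source,
                              disease_gene$pairs$target, diseases, genes,
                              "disease_gene"),
    mirna_pattern = mp,
    pattern_disease = edge_index(pd$pattern, pd$disease, pats, diseases,
                                 "pattern_disease"))
  g <- new_hetero_graph(nodes, edges, features)
  hetmda_log("graph_builder", "assembled graph: %s",
             paste(sprintf("%s=%d", names(nodes), lengths(nodes)),
                   collapse = " "))
  g
}

#' Derive pattern-disease edges through miRNA-disease associations
#'
#' A pattern p is linked to disease d iff there exists a miRNA m such that m
#' contains p and the pair (m, d) belongs to `allowed_mda`. Restricting
#' `allowed_mda` to one side of a train/validation split is exactly the
#' leakage-masking rule applied when building per-fold graphs; passing the
#' full association set yields the full-graph relation.
#'
#' @param mirna_pattern binary incidence matrix (rownames = miRNA ids).
#' @param mirna_disease data.frame of all known (source = miRNA, target =
#'   disease) pairs, or an `association_table`.
#' @param allowed_mda subset of `mirna_disease` defining which associations
#'   may support a derived edge (defaults to all of them).
#' @return data.frame with columns `pattern`, `disease` (unique pairs).
#' @export
derive_pattern_disease_edges <- function(mirna_pattern, mirna_disease,
                                         allowed_mda = mirna_disease) {
  md <- if (inherits(mirna_disease, "association_table"))
    mirna_disease$pairs else mirna_disease
  am <- if (inherits(allowed_mda, "association_table"))
    allowed_mda$pairs else allowed_mda
  key <- function(d) paste(d$source, d$target, sep = "\r")
  if (!all(key(am) %in% key(md)))
    stopf("allowed_mda must be a subset of mirna_disease")
  if (nrow(am) == 0L)
    return(data.frame(pattern = character(0), disease = character(0)))
  am <- am[am$source %in% rownames(mirna_pattern), , drop = FALSE]
  diseases <- sort(unique(am$target))
  # (pattern x miRNA) %*% (miRNA x disease) > 0 realizes the existential rule
  A <- Matrix::sparseMatrix(i = match(am$source, rownames(mirna_pattern)),
                            j = match(am$target, diseases),
                            x = 1,
                            dims = c(nrow(mirna_pattern), length(diseases)))
  P <- as.matrix(Matrix::crossprod(Matrix::Matrix(mirna_pattern, sparse = TRUE), A))
  idx <- which(P > 0, arr.ind = TRUE)
  data.frame(pattern = colnames(mirna_pattern)[idx[, 1L]],
             disease = diseases[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Edge density as a percentage
#'
#' `100 * n_edges / (n_rows * n_cols)` — the percentage of observed
#' associations over all possible ordered pairs.
#'
#' @param n_edges,n_rows,n_cols non-negative counts (`n_rows`, `n_cols` > 0).
#' @return density percentage.
#' @export
edge_density <- function(n_edges, n_rows, n_cols) {
  if (any(c(n_edges, n_rows, n_cols) < 0)) stopf("counts must be non-negative")
  if (n_rows == 0 || n_cols == 0) stopf("n_rows and n_cols must be positive")
  if (n_edges > n_rows * n_cols) stopf("n_edges exceeds n_rows * n_cols")
  100 * n_edges / (n_rows * n_cols)
}

#' Per-relation edge counts and densities
#'
#' Reports a summary table of the graph: nodes per type, edges and density
#' per relation. The miRNA-miRNA relation is stored undirected without
#' self-loops but reported as directed edge count over n^2 ordered pairs
#' (each undirected edge counts twice), matching the usual adjacency-matrix
#' entry-count convention for similarity graphs.
#'
#' @param graph a `hetero_graph`.
#' @return data.frame with columns `relation`, `n_src`, `n_dst`, `n_edges`,
#'   `density_pct`.
#' @export
graph_stats <- function(graph) {
  stopifnot(inherits(graph, "hetero_graph"))
  rels <- canonical_relations()
  rows <- lapply(names(rels), function(r) {
    st <- rels[[r]]
    n_src <- length(graph$nodes[[st[1L]]])
    n_dst <- length(graph$nodes[[st[2L]]])
    ne <- nrow(graph$edges[[r]])
    if (r == "mirna_mirna") ne <- 2L * ne
    data.frame(relation = r, n_src = n_src, n_dst = n_dst, n_edges = ne,
               density_pct = if (n_src > 0 && n_dst > 0)
                 edge_density(ne, n_src, n_dst) else NA_real_)
  })
  do.call(rbind, rows)
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat("<hetero_graph>\n nodes:",
      paste(sprintf("%s=%d", names(x$nodes), lengths(x$nodes)),
            collapse = " "), "\n")
  s <- graph_stats(x)
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-16s %7d edges (%.2f%%)\n", s$relation[i], s$n_edges[i],
                s$density_pct[i]))
  invisible(x)
}

#' Remove all edges of one relation
#'
#' Returns a copy of the graph with the named relation's edge set empty;
#' nodes (including now-isolated ones) are retained and the input graph is
#' unchanged.
#'
#' @param graph a `hetero_graph`.
#' @param relation canonical relation name.
#' @return the ablated `hetero_graph`.
#' @export
ablate_edge_type <- function(graph, relation) {
  stopifnot(inherits(graph, "hetero_graph"))
  if (!relation %in% names(graph$edges))
    stopf("unknown relation: %s", relation)
  graph$edges[[relation]] <- graph$edges[[relation]][0L, , drop = FALSE]
  graph
}

# replace one relation's edges by id pairs (used when masking MDA folds)
set_relation_edges <- function(graph, relation, src_ids, dst_ids) {
  st <- canonical_relations()[[relation]]
  graph$edges[[relation]] <- edge_index(src_ids, dst_ids,
                                        graph$nodes[[st[1L]]],
                                        graph$nodes[[st[2L]]], relation)
  graph
}

# id-level view of one relation's edges
relation_pairs <- function(graph, relation) {
  st <- canonical_relations()[[relation]]
  e <- graph$edges[[relation]]
  data.frame(source = graph$nodes[[st[1L]]][e[, 1L]],
             target = graph$nodes[[st[2L]]][e[, 2L]],
             stringsAsFactors = FALSE)
}

#' Serialize a graph to a directory of TSV edge lists
#'
#' Writes one `<relation>.tsv` per relation (`source<TAB>target` with header)
#' plus a `manifest.json` with node ids and counts.
#'
#' @param graph a `hetero_graph`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_graph_dir <- function(graph, dir) {
  stopifnot(inherits(graph, "hetero_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in names(graph$edges)) {
    utils::write.table(relation_pairs(graph, r),
                       file.path(dir, paste0(r, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(nodes = graph$nodes,
                   counts = as.list(lengths(graph$nodes)),
                   relations = names(graph$edges))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a graph serialized by [write_graph_dir()]
#'
#' @param dir the graph directory.
#' @return a `hetero_graph`.
#' @export
read_graph_dir <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stopf("not a graph directory (no manifest.json): %s", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  nodes <- lapply(manifest$nodes, as.character)
  edges <- lapply(stats::setNames(nm = names(canonical_relations())),
                  function(r) {
    st <- canonical_relations()[[r]]
    df <- utils::read.delim(file.path(dir, paste0(r, ".tsv")),
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    edge_index(df$source, df$target, nodes[[st[1L]]], nodes[[st[2L]]], r)
  })
  new_hetero_graph(nodes, edges)
}
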