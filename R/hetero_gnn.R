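#' Directed edge types of the model
#'
#' Every canonical (undirected biological) relation is expanded into two
#' directed edge types with independent transformation matrices: `__fwd`
#' carries messages source-type -> target-type, `__rev` the reverse. The
#' symmetric miRNA-miRNA similarity relation likewise yields two directed
#' types sharing the same adjacency but separate weights.
#'
#' @return list of lists with fields `name`, `canonical`, `src`, `dst`.
#' @export
directed_relations <- function() {
  out <- list()
  for (r in names(canonical_relations())) {
    st <- canonical_relations()[[r]]
    out[[paste0(r, "__fwd")]] <- list(name = paste0(r, "__fwd"),
                                      canonical = r, src = st[1L], dst = st[2L])
    out[[paste0(r, "__rev")]] <- list(name = paste0(r, "__rev"),
                                      canonical = r, src = st[2L], dst = st[1L])
  }
  out
}

# Row-normalized adjacency per directed edge type: M[e] is n_dst x n_src with
# row v equal to 1/|N(v,e)| on v's e-neighbors (zero row if none), so
# M[e] %*% H_src is the per-relation neighbor mean of Eq.-style message
# passing. norm = "global" divides instead by the node's total neighbor count
# across all relations.
build_norm_adj <- function(graph, norm = c("relation", "global")) {
  norm <- match.arg(norm)
  n <- lengths(graph$nodes)
  raw <- list()
  for (dr in directed_relations()) {
    e <- graph$edges[[dr$canonical]]
    dims <- c(n[[dr$dst]], n[[dr$src]])
    if (dr$canonical == "mirna_mirna") {
      i <- c(e[, 1L], e[, 2L]); j <- c(e[, 2L], e[, 1L])
    } else if (endsWith(dr$name, "__fwd")) {
      i <- e[, 2L]; j <- e[, 1L]
    } else {
      i <- e[, 1L]; j <- e[, 2L]
    }
    raw[[dr$name]] <- Matrix::sparseMatrix(i = i, j = j, x = rep(1, length(i)),
                                           dims = dims)
  }
  drs <- directed_relations()
  if (norm == "relation") {
    lapply(raw, function(A) {
      rs <- Matrix::rowSums(A)
      Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% A
    })
  } else {
    tot <- lapply(stats::setNames(nm = node_types()),
                  function(t) rep(0, n[[t]]))
    for (dr in drs) tot[[dr$dst]] <- tot[[dr$dst]] + Matrix::rowSums(raw[[dr$name]])
    lapply(stats::setNames(nm = names(raw)), function(nm) {
      d <- tot[[drs[[nm]]$dst]]
      Matrix::Diagonal(x = ifelse(d > 0, 1 / d, 0)) %*% raw[[nm]]
    })
  }
}

glorot <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

#' Initialize model parameters
#'
#' Each node type gets a learnable input embedding table: under
#' `feature_mode = "one-hot"` (the default) this is the identity matrix, one
#' one-hot row per node, followed by a node-type-specific linear projection to
#' the first hidden width. Under `"kmer"` the miRNA table is replaced by the
#' supplied 80-dimensional k-mer profile matrix; `"custom"` takes any
#' per-type matrices from `features`. Each message-passing layer holds a
#' self-transform `W0` plus one transform `We` per directed edge type. All
#' weights are Glorot-uniform initialized from the seed and fully
#' reproducible.
#'
#' @param graph a `hetero_graph` (defines the schema: node counts and edge
#'   types).
#' @param dims integer vector of layer widths `c(w0, w1, ..., wL)`: `w0` is
#'   the projection width and each of the `L = length(dims) - 1`
#'   message-passing layers maps `w_(l-1) -> w_l`. Default `c(64, 64, 64)`
#'   (two layers of width 64).
#' @param feature_mode `"one-hot"`, `"kmer"` or `"custom"`.
#' @param features named list of per-type input feature matrices (required
#'   for `"kmer"`: `features$mirna`, rows ordered like `graph$nodes$mirna`).
#' @param seed integer seed.
#' @param norm neighbor normalization: `"relation"` (mean within each
#'   relation, then sum across relations) or `"global"` (single mean over all
#'   typed neighbors).
#' @return an object of class `model_params`.
#' @export
init_parameters <- function(graph, dims = c(64, 64, 64),
                            feature_mode = c("one-hot", "kmer", "custom"),
                            features = NULL, seed = 1,
                            norm = c("relation", "global")) {
  feature_mode <- match.arg(feature_mode)
  norm <- match.arg(norm)
  stopifnot(length(dims) >= 1L, all(dims >= 1L))
  n <- lengths(graph$nodes)
  if (feature_mode == "kmer" && is.null(features$mirna))
    stopf("feature_mode 'kmer' requires features$mirna (k-mer profile matrix)")
  X <- lapply(stats::setNames(nm = node_types()), function(t) {
    custom <- !is.null(features[[t]]) && feature_mode %in% c("kmer", "custom")
    use_custom <- custom && (feature_mode == "custom" || t == "mirna")
    if (use_custom) {
      f <- features[[t]]
      stopifnot(nrow(f) == n[[t]])
      unname(as.matrix(f))
    } else diag(n[[t]])
  })
  set.seed(substream_seed(seed, "init"))
  P <- lapply(stats::setNames(nm = node_types()),
              function(t) glorot(ncol(X[[t]]), dims[1L]))
  L <- length(dims) - 1L
  layers <- if (L > 0L) lapply(seq_len(L), function(l) {
    W0 <- glorot(dims[l], dims[l + 1L])
    We <- lapply(stats::setNames(nm = names(directed_relations())),
                 function(nm) glorot(dims[l], dims[l + 1L]))
    list(W0 = W0, We = We)
  }) else list()
  structure(list(dims = dims, L = L, feature_mode = feature_mode,
                 norm = norm, seed = seed,
                 n_nodes = as.list(n), X = X, P = P, layers = layers),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> L=%d dims=%s feature_mode=%s seed=%d\n", x$L,
              paste(x$dims, collapse = "-"), x$feature_mode, x$seed))
  invisible(x)
}

# projected input embeddings H^0
embed_inputs <- function(params) {
  lapply(stats::setNames(nm = node_types()),
         function(t) params$X[[t]] %*% params$P[[t]])
}

#' Initial embedding state (projected input embeddings, layer 0)
#'
#' @param graph a `hetero_graph`.
#' @param params a `model_params`.
#' @return an embedding state suitable for [message_pass_layer()].
#' @export
initial_state <- function(graph, params) {
  H <- embed_inputs(params)
  for (t in node_types()) rownames(H[[t]]) <- graph$nodes[[t]]
  list(H = H, layer = 0L, adj = build_norm_adj(graph, params$norm))
}

#' One relation-specific message-passing layer
#'
#' For every node v of every type, the pre-activation is
#' `W0' h_v + sum_e mean_{u in N(v,e)} We' h_u` — its own embedding through
#' the self-transform plus, for each directed edge type, the mean of its
#' neighbors' embeddings through that relation's transform (relations with no
#' neighbors contribute zero). The output is the ReLU of the pre-activation.
#'
#' @param state an embedding state: list with `H` (per-type embedding
#'   matrices) and `layer` (0-based layer index).
#' @param graph a `hetero_graph`.
#' @param params a `model_params`.
#' @param layer 1-based index of the layer to apply (must equal
#'   `state$layer + 1`).
#' @return the updated state, with `Z` holding the pre-activations.
#' @export
message_pass_layer <- function(state, graph, params, layer) {
  stopifnot(layer >= 1L, layer <= params$L)
  if (!is.null(state$layer) && state$layer != layer - 1L)
    stopf("state is at layer %d; cannot apply layer %d", state$layer, layer)
  adj <- state$adj %||% build_norm_adj(graph, params$norm)
  lay <- params$layers[[layer]]
  drs <- directed_relations()
  Z <- lapply(stats::setNames(nm = node_types()), function(t) {
    if (ncol(state$H[[t]]) != nrow(lay$W0))
      stopf("dimension mismatch at layer %d for type %s", layer, t)
    acc <- state$H[[t]] %*% lay$W0
    for (dr in drs) {
      if (dr$dst != t) next
      M <- adj[[dr$name]]
      if (Matrix::nnzero(M) == 0L) next
      acc <- acc + as.matrix(M %*% state$H[[dr$src]]) %*% lay$We[[dr$name]]
    }
    acc
  })
  list(H = lapply(Z, relu), Z = Z, layer = layer, adj = adj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full forward pass with cached intermediates for backprop
gnn_forward <- function(adj, params) {
  H0 <- embed_inputs(params)
  cache <- list(H0 = H0, layers = vector("list", params$L))
  H <- H0
  drs <- directed_relations()
  for (l in seq_len(params$L)) {
    lay <- params$layers[[l]]
    Msg <- list()
    Z <- lapply(stats::setNames(nm = node_types()), function(t) H[[t]] %*% lay$W0)
    for (dr in drs) {
      M <- adj[[dr$name]]
      if (Matrix::nnzero(M) == 0L) next
      msg <- as.matrix(M %*% H[[dr$src]])
      Msg[[dr$name]] <- msg
      Z[[dr$dst]] <- Z[[dr$dst]] + msg %*% lay$We[[dr$name]]
    }
    H <- lapply(Z, relu)
    cache$layers[[l]] <- list(Msg = Msg, Z = Z, H = H)
  }
  cache$H_final <- H
  cache
}

#' Encode a graph into node embeddings
#'
#' Applies the projected input embeddings and all `L` message-passing layers;
#' with `L = 0` the final embeddings are the projected input embeddings.
#'
#' @inheritParams message_pass_layer
#' @return an embedding state at the final layer: list with `H` (per-type
#'   matrices with node ids as rownames) and `layer = L`.
#' @export
encode <- function(graph, params) {
  adj <- build_norm_adj(graph, params$norm)
  cache <- gnn_forward(adj, params)
  H <- cache$H_final
  for (t in node_types()) rownames(H[[t]]) <- graph$nodes[[t]]
  list(H = H, layer = params$L, adj = adj)
}

#' Construct a pair-scores object
#'
#' @param mirna,disease character vectors of ids.
#' @param logit numeric vector of decoder logits.
#' @return a `pair_scores` data.frame with `probability = logistic(logit)`.
#' @export
pair_scores <- function(mirna, disease, logit) {
  stopifnot(length(mirna) == length(disease), length(mirna) == length(logit))
  structure(data.frame(mirna = as.character(mirna),
                       disease = as.character(disease),
                       logit = as.numeric(logit),
                       probability = logistic(as.numeric(logit)),
                       stringsAsFactors = FALSE),
            class = c("pair_scores", "data.frame"))
}

#' Score miRNA-disease pairs with the dot-product decoder
#'
#' The association logit of a pair is the dot product of the final-layer
#' miRNA and disease embeddings; the reported probability is its logistic.
#' The sigmoid is applied exactly once end-to-end (training consumes the raw
#' logits through a with-logits cross-entropy).
#'
#' @param state an embedding state from [encode()] (embeddings carry node ids
#'   as rownames).
#' @param pairs data.frame with columns `mirna` and `disease` (ids).
#' @return a `pair_scores` data.frame.
#' @export
score_pairs <- function(state, pairs) {
  Hm <- state$H$mirna; Hd <- state$H$disease
  mi <- match(pairs$mirna, rownames(Hm))
  di <- match(pairs$disease, rownames(Hd))
  bad <- unique(c(pairs$mirna[is.na(mi)], pairs$disease[is.na(di)]))
  if (length(bad)) stopf("unknown id(s) in pairs: %s",
                         paste(utils::head(bad, 10L), collapse = ", "))
  logits <- rowSums(Hm[mi, , drop = FALSE] * Hd[di, , drop = FALSE])
  pair_scores(pairs$mirna, pairs$disease, logits)
}

#' Binary cross-entropy with logits
#'
#' Mean over the batch of `-(y log s + (1-y) log(1-s))` with
#' `s = logistic(logit)`, computed in the numerically stable with-logits form
#' `max(l,0) - l y + log(1 + exp(-|l|))`.
#'
#' @param logits numeric vector.
#' @param labels 0/1 vector of the same length.
#' @return non-negative scalar loss.
#' @export
bce_loss <- function(logits, labels) {
  if (length(logits) == 0L) stopf("empty batch")
  stopifnot(length(logits) == length(labels), all(labels %in% c(0, 1)))
  mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
}

# ---- backward pass -------------------------------------------------------

# loss + gradients for BCE on MDA pairs given a cached forward pass.
# pair_idx: 2-col integer matrix (mirna index, disease index).
gnn_loss_grads <- function(params, adj, cache, pair_idx, labels) {
  np <- nrow(pair_idx)
  Hm <- cache$H_final$mirna; Hd <- cache$H_final$disease
  logits <- rowSums(Hm[pair_idx[, 1L], , drop = FALSE] *
                    Hd[pair_idx[, 2L], , drop = FALSE])
  loss <- bce_loss(logits, labels)
  g <- (logistic(logits) - labels) / np

  Sm <- Matrix::sparseMatrix(i = seq_len(np), j = pair_idx[, 1L], x = g,
                             dims = c(np, nrow(Hm)))
  Sd <- Matrix::sparseMatrix(i = seq_len(np), j = pair_idx[, 2L], x = g,
                             dims = c(np, nrow(Hd)))
  G <- lapply(stats::setNames(nm = node_types()),
              function(t) matrix(0, nrow(cache$H_final[[t]]),
                                 ncol(cache$H_final[[t]])))
  G$mirna <- as.matrix(Matrix::crossprod(Sm, Hd[pair_idx[, 2L], , drop = FALSE]))
  G$disease <- as.matrix(Matrix::crossprod(Sd, Hm[pair_idx[, 1L], , drop = FALSE]))

  grads <- list()
  drs <- directed_relations()
  for (l in rev(seq_len(params$L))) {
    lay <- params$layers[[l]]
    lc <- cache$layers[[l]]
    Hprev <- if (l == 1L) cache$H0 else cache$layers[[l - 1L]]$H
    dZ <- lapply(stats::setNames(nm = node_types()),
                 function(t) G[[t]] * (lc$Z[[t]] > 0))
    gW0 <- matrix(0, nrow(lay$W0), ncol(lay$W0))
    Gprev <- lapply(stats::setNames(nm = node_types()),
                    function(t) dZ[[t]] %*% t(lay$W0))
    for (t in node_types()) gW0 <- gW0 + crossprod(Hprev[[t]], dZ[[t]])
    for (dr in drs) {
      nm <- dr$name
      M <- adj[[nm]]
      if (Matrix::nnzero(M) == 0L) {
        grads[[sprintf("layers.%d.We.%s", l, nm)]] <-
          matrix(0, nrow(lay$We[[nm]]), ncol(lay$We[[nm]]))
        next
      }
      grads[[sprintf("layers.%d.We.%s", l, nm)]] <-
        crossprod(lc$Msg[[nm]], dZ[[dr$dst]])
      Gprev[[dr$src]] <- Gprev[[dr$src]] +
        as.matrix(Matrix::crossprod(M, dZ[[dr$dst]])) %*% t(lay$We[[nm]])
    }
    grads[[sprintf("layers.%d.W0", l)]] <- gW0
    G <- Gprev
  }
  for (t in node_types()) {
    grads[[paste0("P.", t)]] <- crossprod(params$X[[t]], G[[t]])
    grads[[paste0("X.", t)]] <- G[[t]] %*% t(params$P[[t]])
  }
  list(loss = loss, logits = logits, grads = grads)
}

# ---- parameter flattening + Adam -----------------------------------------

param_list <- function(params) {
  out <- list()
  for (t in node_types()) {
    out[[paste0("X.", t)]] <- params$X[[t]]
    out[[paste0("P.", t)]] <- params$P[[t]]
  }
  for (l in seq_len(params$L)) {
    out[[sprintf("layers.%d.W0", l)]] <- params$layers[[l]]$W0
    for (nm in names(params$layers[[l]]$We))
      out[[sprintf("layers.%d.We.%s", l, nm)]] <- params$layers[[l]]$We[[nm]]
  }
  out
}

assign_params <- function(params, plist) {
  for (t in node_types()) {
    params$X[[t]] <- plist[[paste0("X.", t)]]
    params$P[[t]] <- plist[[paste0("P.", t)]]
  }
  for (l in seq_len(params$L)) {
    params$layers[[l]]$W0 <- plist[[sprintf("layers.%d.W0", l)]]
    for (nm in names(params$layers[[l]]$We))
      params$layers[[l]]$We[[nm]] <- plist[[sprintf("layers.%d.We.%s", l, nm)]]
  }
  params
}

adam_init <- function(plist) {
  list(m = lapply(plist, function(p) p * 0),
       v = lapply(plist, function(p) p * 0), t = 0L)
}

adam_step <- function(plist, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (k in names(plist)) {
    gk <- grads[[k]]
    if (is.null(gk)) next
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * gk
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * gk^2
    mhat <- st$m[[k]] / (1 - beta1^st$t)
    vhat <- st$v[[k]] / (1 - beta2^st$t)
    plist[[k]] <- plist[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(plist = plist, state = st)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a directory with a JSON manifest (schema, dims, seed)
#' and the weight arrays.
#'
#' @param params a `model_params`.
#' @param dir checkpoint directory.
#' @return invisibly, `dir` (or the loaded `model_params` for
#'   `load_model()`).
#' @export
save_model <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(dims = params$dims, L = params$L,
                   feature_mode = params$feature_mode, norm = params$norm,
                   seed = params$seed, n_nodes = params$n_nodes,
                   version = as.character(utils::packageVersion("hetmda")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(params, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  f <- file.path(dir, "weights.rds")
  if (!file.exists(f)) stopf("not a checkpoint directory: %s", dir)
  readRDS(f)
}
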