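#' Training configuration
#'
#' Defaults (learning rate 1e-3, full-batch loss over all miRNA-disease
#' pairs per epoch, up to 500 epochs, patience 20, 1:1 negative sampling) are
#' the package's own choices for desk-scale graphs; all are configurable.
#' `monitor = "inner"` carves an inner fraction of training miRNAs out as an
#' early-stopping set so that stopping never consults the evaluation fold;
#' `monitor = "outer"` stops on the evaluation fold's loss instead.
#'
#' @param dims layer widths `c(w0, ..., wL)` (see [init_parameters()]).
#' @param learning_rate Adam learning rate.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without early-stopping-loss improvement before
#'   stopping (0 = stop at the first non-improving epoch).
#' @param negative_ratio negatives sampled per positive.
#' @param feature_mode input embedding mode (see [init_parameters()]).
#' @param features optional per-type feature matrices for
#'   `feature_mode != "one-hot"`.
#' @param seed master seed for this run.
#' @param batch_size reserved; `NULL` means full-batch (the default and only
#'   implemented mode at desk scale).
#' @param monitor early-stopping monitor: `"inner"` (carve-out), `"outer"`
#'   (validation fold), or `"train"` (training loss itself -- fixed-length
#'   training up to a plateau, no held-out-based epoch selection).
#' @param inner_frac fraction of training miRNAs carved out as the inner
#'   early-stopping set.
#' @param norm neighbor normalization (see [init_parameters()]).
#' @param threshold probability threshold for precision/recall/F1 reporting.
#' @return an object of class `train_config`.
#' @export
train_config <- function(dims = c(64, 64, 64), learning_rate = 1e-3,
                         max_epochs = 500L, patience = 20L,
                         negative_ratio = 1, feature_mode = "one-hot",
                         features = NULL, seed = 1, batch_size = NULL,
                         monitor = c("inner", "outer", "train"),
                         inner_frac = 0.1,
                         norm = "relation", threshold = 0.5) {
  monitor <- match.arg(monitor)
  stopifnot(learning_rate > 0, max_epochs >= 1, patience >= 0,
            negative_ratio > 0, inner_frac > 0, inner_frac < 1,
            threshold > 0, threshold < 1)
  if (!is.null(batch_size)) stopifnot(batch_size > 0)
  structure(list(dims = dims, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 negative_ratio = negative_ratio,
                 feature_mode = feature_mode, features = features,
                 seed = as.integer(seed), batch_size = batch_size,
                 monitor = monitor, inner_frac = inner_frac, norm = norm,
                 threshold = threshold),
            class = "train_config")
}

#' Partition miRNAs into cross-validation folds
#'
#' Balanced random partition (fold sizes differ by at most one),
#' reproducible from the repetition seed. Diseases are never split: the
#' protocol cold-starts miRNAs only.
#'
#' @param mirnas character vector of miRNA ids.
#' @param k number of folds (>= 2).
#' @param repetition_seed integer seed for this repetition's partition.
#' @param repetition repetition label stored in the plan.
#' @return a `fold_plan`: list with `k`, `repetition`, `seed` and `fold_of`
#'   (named integer vector, values in `0:(k-1)`).
#' @export
make_folds <- function(mirnas, k, repetition_seed, repetition = 1L) {
  stopifnot(k >= 2)
  if (k > length(mirnas))
    stopf("k = %d exceeds the number of miRNAs (%d)", k, length(mirnas))
  set.seed(as.integer(repetition_seed))
  shuffled <- sample(mirnas)
  fold_of <- stats::setNames(rep_len(seq_len(k) - 1L, length(mirnas)),
                             shuffled)[mirnas]
  structure(list(k = as.integer(k), repetition = as.integer(repetition),
                 seed = as.integer(repetition_seed), fold_of = fold_of),
            class = "fold_plan")
}

# sample n pairs uniformly from (side miRNAs x all diseases) \ known
# positives; ids returned as a data.frame
sample_negatives <- function(mirnas, diseases, known_pos, n, seed,
                             exclude_diseases = character(0)) {
  diseases_ok <- setdiff(diseases, exclude_diseases)
  if (n == 0L) return(data.frame(mirna = character(0), disease = character(0)))
  grid_keys <- as.vector(outer(seq_along(mirnas),
                               (match(diseases_ok, diseases) - 1L) * length(mirnas),
                               "+"))
  pos_keys <- match(known_pos$source, mirnas) +
    (match(known_pos$target, diseases) - 1L) * length(mirnas)
  pos_keys <- pos_keys[!is.na(pos_keys)]
  cand <- setdiff(grid_keys, pos_keys)
  if (length(cand) < n)
    stopf("insufficient negative candidates: need %d, have %d (shortfall %d)",
          n, length(cand), n - length(cand))
  set.seed(as.integer(seed))
  keys <- sample(cand, n)
  mi <- ((keys - 1L) %% length(mirnas)) + 1L
  di <- ((keys - 1L) %/% length(mirnas)) + 1L
  data.frame(mirna = mirnas[mi], disease = diseases[di],
             stringsAsFactors = FALSE)
}

# incidence matrix (mirna x pattern) reconstructed from the graph's edges
graph_incidence <- function(graph) {
  e <- graph$edges$mirna_pattern
  inc <- matrix(0, length(graph$nodes$mirna), length(graph$nodes$pattern),
                dimnames = list(graph$nodes$mirna, graph$nodes$pattern))
  inc[e] <- 1
  inc
}

# graph view with the MDA relation restricted to `pos` and pattern-disease
# edges re-derived from those positives only
mask_graph <- function(graph, pos, full_pos) {
  g <- set_relation_edges(graph, "mirna_disease", pos$source, pos$target)
  pd <- derive_pattern_disease_edges(graph_incidence(graph), full_pos, pos)
  set_relation_edges(g, "pattern_disease", pd$pattern, pd$disease)
}

#' Build the train/validation edge split for one fold
#'
#' Realizes the leakage-control protocol: the validation fold's miRNAs are
#' completely unseen during training — all their miRNA-disease edges are
#' removed from the training graph (and symmetrically for the validation
#' graph); negatives are sampled among the side's miRNAs over all diseases,
#' excluding every known positive; and pattern-disease edges in each graph
#' view are re-derived from that side's positives only, so no association
#' can leak through a sequence pattern.
#'
#' @param graph the full `hetero_graph`.
#' @param plan a `fold_plan`.
#' @param fold fold index in `0:(k-1)`.
#' @param negative_ratio negatives per positive.
#' @param seed seed for negative sampling.
#' @return an `edge_split`: `train_pos`, `val_pos`, `train_neg`, `val_neg`
#'   (data.frames with columns `mirna`, `disease`), `train_graph`,
#'   `val_graph`, `train_mirnas`, `val_mirnas`. `val_graph` is the symmetric
#'   masked view used for leakage assertions ([validate_split()]); training,
#'   monitoring and evaluation all encode `train_graph` only, so validation
#'   associations never enter message passing.
#' @export
make_split <- function(graph, plan, fold, negative_ratio = 1, seed = 1) {
  stopifnot(inherits(plan, "fold_plan"))
  if (!fold %in% 0:(plan$k - 1L)) stopf("fold %s not in plan", fold)
  pos <- relation_pairs(graph, "mirna_disease")
  val_m <- names(plan$fold_of)[plan$fold_of == fold]
  train_m <- setdiff(graph$nodes$mirna, val_m)
  train_pos <- pos[pos$source %in% train_m, , drop = FALSE]
  val_pos <- pos[pos$source %in% val_m, , drop = FALSE]
  diseases <- graph$nodes$disease
  train_neg <- sample_negatives(train_m, diseases, pos,
                                round(negative_ratio * nrow(train_pos)),
                                substream_seed(seed, "train_neg"))
  val_neg <- sample_negatives(val_m, diseases, pos,
                              round(negative_ratio * nrow(val_pos)),
                              substream_seed(seed, "val_neg"))
  as_md <- function(d) data.frame(mirna = d$source, disease = d$target,
                                  stringsAsFactors = FALSE)
  structure(list(train_pos = as_md(train_pos), val_pos = as_md(val_pos),
                 train_neg = train_neg, val_neg = val_neg,
                 train_graph = mask_graph(graph, train_pos, pos),
                 val_graph = mask_graph(graph, val_pos, pos),
                 train_mirnas = train_m, val_mirnas = val_m,
                 fold = as.integer(fold), repetition = plan$repetition),
            class = "edge_split")
}

# split with everything on the training side (used for final-model training
# and disease holdout). exclude_diseases: their MDA edges are dropped from
# training and no negatives are generated for them.
make_full_split <- function(graph, negative_ratio = 1, seed = 1,
                            exclude_diseases = character(0)) {
  pos <- relation_pairs(graph, "mirna_disease")
  train_pos <- pos[!pos$target %in% exclude_diseases, , drop = FALSE]
  train_neg <- sample_negatives(graph$nodes$mirna, graph$nodes$disease, pos,
                                round(negative_ratio * nrow(train_pos)),
                                substream_seed(seed, "train_neg"),
                                exclude_diseases = exclude_diseases)
  as_md <- function(d) data.frame(mirna = d$source, disease = d$target,
                                  stringsAsFactors = FALSE)
  empty <- data.frame(mirna = character(0), disease = character(0))
  tg <- mask_graph(graph, train_pos, pos)
  structure(list(train_pos = as_md(train_pos), val_pos = empty,
                 train_neg = train_neg, val_neg = empty,
                 train_graph = tg, val_graph = tg,
                 train_mirnas = graph$nodes$mirna, val_mirnas = character(0),
                 fold = NA_integer_, repetition = NA_integer_),
            class = "edge_split")
}

#' Assert every leakage invariant of an edge split
#'
#' Checks positive/negative disjointness, fold membership of every pair,
#' that no sampled negative is a known positive, and that each graph view's
#' pattern-disease edges are supported exclusively by that side's positives.
#' Errors on the first violation.
#'
#' @param split an `edge_split`.
#' @param graph the full graph the split was derived from.
#' @return invisibly `TRUE`.
#' @export
validate_split <- function(split, graph) {
  key <- function(d) paste(d[[1L]], d[[2L]], sep = "\r")
  pos <- relation_pairs(graph, "mirna_disease")
  if (length(intersect(key(split$train_pos), key(split$val_pos))))
    stopf("train and validation positives overlap")
  if (!all(split$val_pos$mirna %in% split$val_mirnas))
    stopf("validation positive involves a training miRNA")
  if (!all(split$train_pos$mirna %in% split$train_mirnas))
    stopf("training positive involves a validation miRNA")
  negs <- rbind(split$train_neg, split$val_neg)
  if (any(key(negs) %in% key(data.frame(pos$source, pos$target))))
    stopf("sampled negative coincides with a known positive")
  if (!all(split$train_neg$mirna %in% split$train_mirnas) ||
      !all(split$val_neg$mirna %in% split$val_mirnas))
    stopf("negative sampled from the wrong fold's miRNAs")
  inc <- graph_incidence(graph)
  for (side in c("train", "val")) {
    g <- split[[paste0(side, "_graph")]]
    p <- split[[paste0(side, "_pos")]]
    expected <- derive_pattern_disease_edges(
      inc, pos, data.frame(source = p$mirna, target = p$disease))
    got <- relation_pairs(g, "pattern_disease")
    if (!setequal(key(expected), key(data.frame(got$source, got$target))))
      stopf("%s graph pattern-disease edges not supported by %s positives",
            side, side)
    md <- relation_pairs(g, "mirna_disease")
    if (!setequal(key(md), key(data.frame(p$mirna, p$disease))))
      stopf("%s graph MDA edges differ from %s positives", side, side)
  }
  invisible(TRUE)
}

pair_index <- function(graph, pairs) {
  cbind(match(pairs$mirna, graph$nodes$mirna),
        match(pairs$disease, graph$nodes$disease))
}

#' Train the model on one edge split
#'
#' Full-batch Adam on the binary cross-entropy over miRNA-disease pairs only
#' (positives plus sampled negatives); all other relations shape the
#' embeddings through message passing but never enter the loss. Early
#' stopping monitors either an inner carve-out of training miRNAs (default;
#' their MDA edges are additionally masked from the optimization graph, so
#' they are genuinely unseen), the outer validation fold, or the training
#' loss itself (`monitor = "train"`: fixed-length training to a plateau).
#' Returns the parameters of the best monitored epoch.
#'
#' @param split an `edge_split` from [make_split()].
#' @param config a [train_config()].
#' @return a `trained_model`: list with `params` (best-epoch
#'   `model_params`), `history` (per-epoch losses), `best_epoch`, `config`.
#' @export
train_model <- function(split, config) {
  stopifnot(inherits(split, "edge_split"), inherits(config, "train_config"))
  full_pos <- rbind(split$train_pos, split$val_pos)
  full_pos_df <- data.frame(source = full_pos$mirna, target = full_pos$disease)

  if (config$monitor == "inner") {
    train_m_assoc <- sort(unique(split$train_pos$mirna))
    set.seed(substream_seed(config$seed, "inner"))
    n_inner <- max(1L, floor(config$inner_frac * length(train_m_assoc)))
    inner_m <- if (length(train_m_assoc) > 1L)
      sample(train_m_assoc, n_inner) else character(0)
    opt_pos <- split$train_pos[!split$train_pos$mirna %in% inner_m, ,
                               drop = FALSE]
    mon_pos <- split$train_pos[split$train_pos$mirna %in% inner_m, ,
                               drop = FALSE]
    opt_neg <- split$train_neg[!split$train_neg$mirna %in% inner_m, ,
                               drop = FALSE]
    mon_neg <- split$train_neg[split$train_neg$mirna %in% inner_m, ,
                               drop = FALSE]
    opt_graph <- mask_graph(split$train_graph,
                            data.frame(source = opt_pos$mirna,
                                       target = opt_pos$disease),
                            full_pos_df)
    mon_graph <- NULL  # monitored on the optimization graph itself
    if (nrow(mon_pos) == 0L) {
      hetmda_log("training_cv",
                 "inner monitor empty; falling back to training loss",
                 level = "WARN")
      mon_pos <- opt_pos; mon_neg <- opt_neg
    }
  } else if (config$monitor == "outer") {
    opt_pos <- split$train_pos; opt_neg <- split$train_neg
    mon_pos <- split$val_pos; mon_neg <- split$val_neg
    opt_graph <- split$train_graph
    # monitored on the training graph: the fold's MDA edges must never
    # enter message passing, only the monitored loss
    mon_graph <- NULL
    if (nrow(mon_pos) == 0L && nrow(mon_neg) == 0L) {
      mon_pos <- opt_pos; mon_neg <- opt_neg
    }
  } else {
    # "train": the optimized loss is its own monitor, so the run trains to a
    # plateau and keeps the lowest-training-loss parameters
    opt_pos <- split$train_pos; opt_neg <- split$train_neg
    mon_pos <- opt_pos; mon_neg <- opt_neg
    opt_graph <- split$train_graph
    mon_graph <- NULL
  }
  if (nrow(opt_pos) == 0L) stopf("no training positives to learn from")

  g <- opt_graph
  opt_idx <- pair_index(g, rbind(opt_pos, opt_neg))
  opt_y <- rep(c(1, 0), c(nrow(opt_pos), nrow(opt_neg)))
  mon_idx <- pair_index(g, rbind(mon_pos, mon_neg))
  mon_y <- rep(c(1, 0), c(nrow(mon_pos), nrow(mon_neg)))

  params <- init_parameters(g, dims = config$dims,
                            feature_mode = config$feature_mode,
                            features = config$features,
                            seed = substream_seed(config$seed, "params"),
                            norm = config$norm)
  adj_opt <- build_norm_adj(g, params$norm)
  adj_mon <- if (is.null(mon_graph)) NULL else
    build_norm_adj(mon_graph, params$norm)

  plist <- param_list(params)
  astate <- adam_init(plist)
  best <- list(loss = Inf, epoch = 0L, plist = plist)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     monitor_loss = numeric(0))

  for (epoch in seq_len(config$max_epochs)) {
    params <- assign_params(params, plist)
    cache <- gnn_forward(adj_opt, params)
    lg <- gnn_loss_grads(params, adj_opt, cache, opt_idx, opt_y)
    if (!is.finite(lg$loss))
      stopf("training diverged (non-finite loss) at epoch %d", epoch)
    mon_loss <- if (is.null(adj_mon)) {
      Hm <- cache$H_final$mirna; Hd <- cache$H_final$disease
      bce_loss(rowSums(Hm[mon_idx[, 1L], , drop = FALSE] *
                       Hd[mon_idx[, 2L], , drop = FALSE]), mon_y)
    } else {
      mc <- gnn_forward(adj_mon, params)
      bce_loss(rowSums(mc$H_final$mirna[mon_idx[, 1L], , drop = FALSE] *
                       mc$H_final$disease[mon_idx[, 2L], , drop = FALSE]),
               mon_y)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = lg$loss,
                                   monitor_loss = mon_loss))
    if (mon_loss < best$loss) {
      best <- list(loss = mon_loss, epoch = epoch, plist = plist)
    } else if (epoch - best$epoch > config$patience) {
      break
    }
    upd <- adam_step(plist, lg$grads, astate, lr = config$learning_rate)
    plist <- upd$plist; astate <- upd$state
  }
  params <- assign_params(params, best$plist)
  hetmda_log("training_cv", "trained %d epochs, best epoch %d (loss %.4f)",
             nrow(hist), best$epoch, best$loss)
  structure(list(params = params, history = hist, best_epoch = best$epoch,
                 best_loss = best$loss, config = config),
            class = "trained_model")
}

#' Evaluate a trained model on its validation fold
#'
#' Encodes the training graph — the only graph whose edges the model may
#' legitimately see: the fold's miRNAs are present but carry no MDA edges
#' there, so the scored associations never participate in message passing —
#' and scores the fold's positives against its sampled negatives.
#'
#' @param model a `trained_model`.
#' @param split the `edge_split` it was trained on.
#' @param threshold probability threshold for precision/recall/F1.
#' @return a `metrics_report` (see [ranking_metrics()]).
#' @export
evaluate_model <- function(model, split, threshold = model$config$threshold) {
  state <- encode(split$train_graph, model$params)
  pairs <- rbind(split$val_pos, split$val_neg)
  labels <- rep(c(1, 0), c(nrow(split$val_pos), nrow(split$val_neg)))
  scores <- score_pairs(state, pairs)
  rep <- ranking_metrics(scores, labels, threshold)
  rep$fold <- split$fold
  rep$repetition <- split$repetition
  rep
}

#' k-fold x repeated cross-validation at the miRNA level
#'
#' @param graph the full `hetero_graph`.
#' @param config a [train_config()]; `config$seed` drives every substream
#'   (partitions, negative sampling, initialization).
#' @param k folds per repetition.
#' @param repetitions independent repetitions with fresh partitions.
#' @return a `cv_result`: list with `reports` (per-fold `metrics_report`s),
#'   `per_fold` (data.frame) and `aggregate` (mean and sd per metric).
#' @export
cross_validate <- function(graph, config, k = 10, repetitions = 1) {
  pos <- relation_pairs(graph, "mirna_disease")
  n_assoc <- length(unique(pos$source))
  if (n_assoc < k)
    stopf("graph has %d miRNAs with associations; need >= k = %d", n_assoc, k)
  reports <- list()
  for (r in seq_len(repetitions)) {
    plan <- make_folds(graph$nodes$mirna, k,
                       substream_seed(config$seed, paste0("folds.rep", r)),
                       repetition = r)
    for (f in 0:(k - 1L)) {
      split <- make_split(graph, plan, f, config$negative_ratio,
                          seed = substream_seed(config$seed,
                                                sprintf("split.r%d.f%d", r, f)))
      if (nrow(split$val_pos) == 0L) {
        hetmda_log("training_cv", "rep %d fold %d has no positives; skipped",
                   r, f, level = "WARN")
        next
      }
      cfg <- config
      cfg$seed <- substream_seed(config$seed, sprintf("train.r%d.f%d", r, f))
      model <- train_model(split, cfg)
      reports[[length(reports) + 1L]] <- evaluate_model(model, split)
    }
  }
  per_fold <- do.call(rbind, lapply(reports, as.data.frame))
  metrics <- c("auc_roc", "aupr", "precision", "recall", "f1")
  aggregate <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_fold[[m]]), 0),
    sd = vapply(metrics, function(m) stats::sd(per_fold[[m]]), 0))
  structure(list(reports = reports, per_fold = per_fold,
                 aggregate = aggregate, k = k, repetitions = repetitions),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold x %d repetition(s), %d fold reports\n",
              x$k, x$repetitions, length(x$reports)))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}
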