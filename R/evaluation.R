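#' Ranking metrics for link prediction
#'
#' AUC-ROC via the rank (Mann-Whitney) formulation with midrank tie
#' handling; AUPR by step integration of the precision-recall curve
#' (precision evaluated at each distinct score cut, weighted by the recall
#' increment); precision, recall and F1 at a probability threshold (default
#' 0.5 — the threshold used is always carried in the report).
#'
#' @param scores a `pair_scores` object or a numeric vector of
#'   scores/probabilities.
#' @param labels binary 0/1 vector, same length.
#' @param threshold probability threshold for the thresholded metrics.
#' @return a `metrics_report`: list with `auc_roc`, `aupr`, `precision`,
#'   `recall`, `f1`, `threshold`, `n_pos`, `n_neg`.
#' @export
ranking_metrics <- function(scores, labels, threshold = 0.5) {
  s <- if (inherits(scores, "pair_scores")) scores$probability
       else as.numeric(scores)
  stopifnot(length(s) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stopf("ranking metrics need both classes (got %d pos, %d neg)",
          n_pos, n_neg)
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(s, decreasing = TRUE)
  y <- labels[ord]; sv <- s[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(sv[-1] != sv[-length(sv)], TRUE)  # evaluate at distinct cuts only
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  aupr <- sum(diff(c(0, rec)) * prec)

  pred <- as.integer(s >= threshold)
  tp_t <- sum(pred == 1 & labels == 1)
  fp_t <- sum(pred == 1 & labels == 0)
  fn_t <- sum(pred == 0 & labels == 1)
  precision <- if (tp_t + fp_t > 0) tp_t / (tp_t + fp_t) else NA_real_
  recall <- tp_t / (tp_t + fn_t)
  f1 <- if (!is.na(precision) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(auc_roc = auc, aupr = aupr, precision = precision,
                 recall = recall, f1 = f1, threshold = threshold,
                 n_pos = n_pos, n_neg = n_neg,
                 fold = NA_integer_, repetition = NA_integer_),
            class = "metrics_report")
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(auc_roc = x$auc_roc, aupr = x$aupr, precision = x$precision,
             recall = x$recall, f1 = x$f1, threshold = x$threshold,
             n_pos = x$n_pos, n_neg = x$n_neg, fold = x$fold,
             repetition = x$repetition)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> AUC %.4f AUPR %.4f P %.3f R %.3f F1 %.3f (t=%.2f, %d+/%d-)\n",
    x$auc_roc, x$aupr, x$precision, x$recall, x$f1, x$threshold,
    x$n_pos, x$n_neg))
  invisible(x)
}

# train + evaluate a single shared fold of `graph`; the plan/seeds are fixed
# by the caller so baseline and ablated runs are directly comparable
eval_one_fold <- function(graph, config, plan, fold, split_seed) {
  split <- make_split(graph, plan, fold, config$negative_ratio,
                      seed = split_seed)
  model <- train_model(split, config)
  list(model = model, split = split, metrics = evaluate_model(model, split))
}

#' Edge-type ablation study
#'
#' `mode = "pre"` removes a relation's edges before training and retrains
#' from scratch (same fold plan, same seeds as the baseline), measuring how
#' much relational information the embeddings needed during learning.
#' `mode = "post"` trains once on the full graph and perturbs the relation
#' only at inference (random deletion of `perturb_frac` of its edges in the
#' validation graph), measuring the trained model's robustness to missing
#' context.
#'
#' @param graph the full `hetero_graph`.
#' @param config a [train_config()].
#' @param relations relations to ablate (defaults to the three non-MDA
#'   informative relations; the derived pattern-disease relation follows the
#'   MDA edges and is not ablated on its own).
#' @param mode `"pre"` or `"post"`.
#' @param k folds in the shared plan.
#' @param folds fold indices scored and averaged (default all `k` folds;
#'   fewer folds trade variance for speed).
#' @param perturb_frac fraction of edges deleted in `"post"` mode.
#' @return data.frame with columns `relation`, `mode`, `auc_base`,
#'   `auc_ablated`, `decrease`; AUCs are means over the scored folds.
#' @export
ablation_study <- function(graph, config,
                           relations = c("mirna_mirna", "disease_gene",
                                         "mirna_pattern"),
                           mode = c("pre", "post"), k = 5,
                           folds = seq_len(k) - 1L, perturb_frac = 0.1) {
  mode <- match.arg(mode)
  stopifnot(all(relations %in% names(canonical_relations())),
            all(folds %in% (seq_len(k) - 1L)))
  plan <- make_folds(graph$nodes$mirna, k,
                     substream_seed(config$seed, "ablation.folds"))
  split_seed <- function(f) substream_seed(config$seed,
                                           paste0("ablation.split.f", f))
  base <- lapply(folds, function(f)
    eval_one_fold(graph, config, plan, f, split_seed(f)))
  auc_base <- mean(vapply(base, function(b) b$metrics$auc_roc, 0))
  rows <- lapply(relations, function(rel) {
    per_fold <- vapply(seq_along(folds), function(i) {
      f <- folds[[i]]
      if (mode == "pre") {
        abl <- eval_one_fold(ablate_edge_type(graph, rel), config, plan, f,
                             split_seed(f))
        abl$metrics$auc_roc
      } else {
        b <- base[[i]]
        vg <- perturb_relation(b$split$train_graph, rel, perturb_frac,
                               substream_seed(config$seed,
                                              sprintf("perturb.%s.f%d",
                                                      rel, f)))
        state <- encode(vg, b$model$params)
        pairs <- rbind(b$split$val_pos, b$split$val_neg)
        labels <- rep(c(1, 0), c(nrow(b$split$val_pos),
                                 nrow(b$split$val_neg)))
        ranking_metrics(score_pairs(state, pairs), labels,
                        config$threshold)$auc_roc
      }
    }, 0)
    data.frame(relation = rel, mode = mode, auc_base = auc_base,
               auc_ablated = mean(per_fold),
               decrease = auc_base - mean(per_fold))
  })
  do.call(rbind, rows)
}

#' Randomly delete a fraction of one relation's edges
#'
#' @param graph a `hetero_graph`.
#' @param relation canonical relation name.
#' @param frac fraction of edges to delete in `[0,1]`.
#' @param seed sampling seed.
#' @return the perturbed graph.
#' @export
perturb_relation <- function(graph, relation, frac, seed = 1) {
  if (!relation %in% names(graph$edges)) stopf("unknown relation: %s", relation)
  stopifnot(frac >= 0, frac <= 1)
  e <- graph$edges[[relation]]
  n_drop <- round(frac * nrow(e))
  if (n_drop > 0L) {
    set.seed(as.integer(seed))
    drop <- sample(nrow(e), n_drop)
    graph$edges[[relation]] <- e[-drop, , drop = FALSE]
  }
  graph
}

#' Disease-level holdout analysis
#'
#' For each listed disease: the baseline model is trained on the full graph;
#' the drop model is retrained with every MDA edge of that disease removed
#' and with no negatives sampled for it. Both are evaluated on the same
#' pairs — the disease's known positives against an equal number of sampled
#' negative miRNAs for that disease — and the cost of removal is
#' `delta_auc = auc_base - auc_drop`.
#'
#' @param graph the full `hetero_graph`.
#' @param config a [train_config()].
#' @param diseases disease ids to hold out.
#' @return data.frame with columns `disease`, `n_pos`, `auc_base`,
#'   `auc_drop`, `delta_auc`; diseases with fewer than 2 positives are
#'   skipped with a warning.
#' @export
disease_holdout <- function(graph, config, diseases) {
  unknown <- setdiff(diseases, graph$nodes$disease)
  if (length(unknown))
    stopf("disease(s) not in graph: %s", paste(unknown, collapse = ", "))
  pos <- relation_pairs(graph, "mirna_disease")
  counts <- table(pos$target)
  usable <- diseases[diseases %in% names(counts)[counts >= 2]]
  skipped <- setdiff(diseases, usable)
  if (length(skipped))
    warnf("skipping disease(s) with < 2 positives: %s",
          paste(skipped, collapse = ", "))
  if (!length(usable)) stopf("no evaluable diseases")

  base_cfg <- config
  base_cfg$seed <- substream_seed(config$seed, "holdout.base")
  base_split <- make_full_split(graph, config$negative_ratio, base_cfg$seed)
  base_model <- train_model(base_split, base_cfg)
  base_state <- encode(graph, base_model$params)

  rows <- lapply(usable, function(d) {
    d_pos <- pos[pos$target == d, , drop = FALSE]
    set.seed(substream_seed(config$seed, paste0("holdout.eval.", d)))
    cand <- setdiff(graph$nodes$mirna, d_pos$source)
    if (length(cand) < nrow(d_pos))
      stopf("not enough negative miRNAs for disease %s", d)
    neg_m <- sample(cand, nrow(d_pos))
    pairs <- data.frame(mirna = c(d_pos$source, neg_m),
                        disease = d, stringsAsFactors = FALSE)
    labels <- rep(c(1, 0), c(nrow(d_pos), length(neg_m)))

    drop_cfg <- config
    drop_cfg$seed <- substream_seed(config$seed, paste0("holdout.drop.", d))
    drop_split <- make_full_split(graph, config$negative_ratio, drop_cfg$seed,
                                  exclude_diseases = d)
    drop_model <- train_model(drop_split, drop_cfg)
    drop_state <- encode(drop_split$train_graph, drop_model$params)

    auc_base <- ranking_metrics(score_pairs(base_state, pairs),
                                labels)$auc_roc
    auc_drop <- ranking_metrics(score_pairs(drop_state, pairs),
                                labels)$auc_roc
    data.frame(disease = d, n_pos = nrow(d_pos), auc_base = auc_base,
               auc_drop = auc_drop, delta_auc = auc_base - auc_drop)
  })
  do.call(rbind, rows)
}

#' Cross-version score-transfer analysis
#'
#' Compares a model trained on an earlier dataset release with one trained
#' on a later release, over the "new" pairs: positives present in the new
#' graph but absent from the old graph's MDA set (restricted to miRNAs and
#' diseases the old model knows). Reports the Pearson correlation between
#' the two models' probabilities on those pairs, the old model's AUC on new
#' positives versus sampled negatives, and the fraction of pairs whose
#' absolute probability difference exceeds `divergence_threshold`.
#'
#' @param model_old,model_new `model_params` or `trained_model` objects.
#' @param graph_old,graph_new the graphs each model was trained on.
#' @param seed seed for negative sampling.
#' @param divergence_threshold probability-difference cut for the divergent
#'   fraction (default 0.5).
#' @return list with `pearson_r`, `auc_new_positives`, `divergent_fraction`,
#'   `n_new_pos`, and the scored pairs.
#' @export
version_transfer <- function(model_old, graph_old, model_new, graph_new,
                             seed = 1, divergence_threshold = 0.5) {
  p_old <- if (inherits(model_old, "trained_model")) model_old$params else model_old
  p_new <- if (inherits(model_new, "trained_model")) model_new$params else model_new
  shared_m <- intersect(graph_old$nodes$mirna, graph_new$nodes$mirna)
  shared_d <- intersect(graph_old$nodes$disease, graph_new$nodes$disease)
  key <- function(d) paste(d[[1L]], d[[2L]], sep = "\r")
  old_pos <- relation_pairs(graph_old, "mirna_disease")
  new_pos <- relation_pairs(graph_new, "mirna_disease")
  new_pos <- new_pos[new_pos$source %in% shared_m &
                     new_pos$target %in% shared_d &
                     !key(new_pos) %in% key(old_pos), , drop = FALSE]
  if (nrow(new_pos) == 0L) stopf("no new positive pairs to transfer onto")

  state_old <- encode(graph_old, p_old)
  state_new <- encode(graph_new, p_new)
  pairs <- data.frame(mirna = new_pos$source, disease = new_pos$target,
                      stringsAsFactors = FALSE)
  s_old <- score_pairs(state_old, pairs)
  s_new <- score_pairs(state_new, pairs)
  if (stats::sd(s_old$probability) == 0 || stats::sd(s_new$probability) == 0)
    stopf("constant score vector; correlation undefined")
  r <- stats::cor(s_old$probability, s_new$probability)

  all_pos <- rbind(old_pos, relation_pairs(graph_new, "mirna_disease"))
  neg <- sample_negatives(shared_m, shared_d, all_pos, nrow(new_pos),
                          substream_seed(seed, "transfer_neg"))
  s_neg <- score_pairs(state_old, neg)
  auc <- ranking_metrics(c(s_old$probability, s_neg$probability),
                         rep(c(1, 0), c(nrow(new_pos), nrow(neg))))$auc_roc
  div <- mean(abs(s_old$probability - s_new$probability) >
              divergence_threshold)
  list(pearson_r = r, auc_new_positives = auc, divergent_fraction = div,
       n_new_pos = nrow(new_pos),
       scores = data.frame(pairs, prob_old = s_old$probability,
                           prob_new = s_new$probability))
}
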