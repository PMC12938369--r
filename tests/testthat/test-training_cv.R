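test_that("make_folds is a balanced reproducible partition", {
  m <- sprintf("m%03d", 1:23)
  plan <- make_folds(m, 5, repetition_seed = 99)
  expect_setequal(names(plan$fold_of), m)
  expect_setequal(unique(plan$fold_of), 0:4)
  sizes <- table(plan$fold_of)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(plan$fold_of, make_folds(m, 5, 99)$fold_of)
  expect_false(identical(plan$fold_of, make_folds(m, 5, 100)$fold_of))
  expect_error(make_folds(m[1:3], 5, 1), "exceeds")
})

test_that("sample_negatives avoids positives, respects sides, errors on shortfall", {
  sample_negatives <- hetmda:::sample_negatives
  m <- c("m1", "m2"); d <- c("d1", "d2", "d3")
  pos <- data.frame(source = c("m1", "m2"), target = c("d1", "d2"))
  neg <- sample_negatives(m, d, pos, 4, seed = 1)
  expect_equal(nrow(neg), 4)
  expect_false(any(paste(neg$mirna, neg$disease) %in%
                   paste(pos$source, pos$target)))
  expect_true(all(neg$mirna %in% m))
  # full complement requested -> exactly the 4 non-positive cells
  expect_setequal(paste(neg$mirna, neg$disease),
                  c("m1 d2", "m1 d3", "m2 d1", "m2 d3"))
  expect_error(sample_negatives(m, d, pos, 5, seed = 1), "insufficient")
  ex <- sample_negatives(m, d, pos, 2, seed = 1, exclude_diseases = "d3")
  expect_setequal(paste(ex$mirna, ex$disease), c("m1 d2", "m2 d1"))
  expect_identical(sample_negatives(m, d, pos, 3, seed = 7),
                   sample_negatives(m, d, pos, 3, seed = 7))
})

test_that("edge splits satisfy every leakage invariant across a seed sweep", {
  for (seed in 1:12) {
    g <- random_toy_graph(seed, n_m = 12, n_d = 6)
    plan <- make_folds(g$nodes$mirna, 3, repetition_seed = seed)
    for (f in 0:2) {
      split <- make_split(g, plan, f, negative_ratio = 1, seed = seed)
      expect_true(validate_split(split, g), info = paste(seed, f))
      # the fold's miRNAs carry no MDA edge in the training graph
      tr_md <- hetmda:::relation_pairs(split$train_graph, "mirna_disease")
      expect_false(any(tr_md$source %in% split$val_mirnas))
      va_md <- hetmda:::relation_pairs(split$val_graph, "mirna_disease")
      expect_false(any(va_md$source %in% split$train_mirnas))
    }
  }
  # validate_split rejects a corrupted split
  g <- random_toy_graph(1, n_m = 12, n_d = 6)
  plan <- make_folds(g$nodes$mirna, 3, repetition_seed = 1)
  split <- make_split(g, plan, 0, seed = 1)
  bad <- split
  # a validation-side pair that is NOT a known positive, planted as train_neg
  pos_keys <- paste(hetmda:::relation_pairs(g, "mirna_disease")$source,
                    hetmda:::relation_pairs(g, "mirna_disease")$target)
  cand <- expand.grid(mirna = split$val_mirnas, disease = g$nodes$disease,
                      stringsAsFactors = FALSE)
  cand <- cand[!paste(cand$mirna, cand$disease) %in% pos_keys, ]
  bad$train_neg <- rbind(bad$train_neg, cand[1, ])
  expect_error(validate_split(bad, g), "wrong fold")
  bad2 <- split
  bad2$val_pos <- rbind(bad2$val_pos, split$train_pos[1, ])
  expect_error(validate_split(bad2, g), "miRNA|overlap")
})

test_that("pattern-disease edges never leak validation associations", {
  # a disease connected ONLY to a validation miRNA must lose all of its
  # pattern-disease support in the training graph
  for (seed in 31:35) {
    g <- random_toy_graph(seed, n_m = 10, n_d = 8)
    plan <- make_folds(g$nodes$mirna, 2, repetition_seed = seed)
    split <- make_split(g, plan, 0, seed = seed)
    val_only_d <- setdiff(unique(split$val_pos$disease),
                          unique(split$train_pos$disease))
    pd <- hetmda:::relation_pairs(split$train_graph, "pattern_disease")
    expect_false(any(pd$target %in% val_only_d), info = seed)
  }
})

test_that("training is deterministic and patience semantics hold", {
  g <- random_toy_graph(41, n_m = 15, n_d = 8)
  plan <- make_folds(g$nodes$mirna, 3, repetition_seed = 41)
  split <- make_split(g, plan, 0, seed = 41)
  cfg <- train_config(dims = c(8, 8), max_epochs = 15, patience = 3, seed = 2)
  m1 <- train_model(split, cfg)
  m2 <- train_model(split, cfg)
  expect_identical(hetmda:::param_list(m1$params),
                   hetmda:::param_list(m2$params))
  expect_identical(m1$history, m2$history)
  expect_equal(m1$history$epoch, seq_len(nrow(m1$history)))
  expect_true(all(is.finite(m1$history$train_loss)))
  # best epoch realizes the monitor minimum, and training stops within
  # patience epochs of it
  expect_equal(m1$best_epoch, which.min(m1$history$monitor_loss))
  expect_lte(nrow(m1$history) - m1$best_epoch, cfg$patience + 1)

  cfg0 <- train_config(dims = c(8, 8), max_epochs = 15, patience = 0, seed = 2)
  m0 <- train_model(split, cfg0)
  expect_lte(nrow(m0$history), 15)
  expect_equal(m0$best_epoch, which.min(m0$history$monitor_loss))
  # patience 0: the epoch after the best is the last one evaluated
  if (nrow(m0$history) < 15)
    expect_equal(nrow(m0$history), m0$best_epoch + 1)
})

test_that("outer monitor consults the validation fold, inner does not", {
  g <- random_toy_graph(43, n_m = 15, n_d = 8)
  plan <- make_folds(g$nodes$mirna, 3, repetition_seed = 43)
  split <- make_split(g, plan, 0, seed = 43)
  cfg_in <- train_config(dims = c(8, 8), max_epochs = 10, patience = 10,
                         seed = 3, monitor = "inner")
  cfg_out <- train_config(dims = c(8, 8), max_epochs = 10, patience = 10,
                          seed = 3, monitor = "outer")
  m_in <- train_model(split, cfg_in)
  m_out <- train_model(split, cfg_out)
  expect_false(identical(m_in$history$monitor_loss,
                         m_out$history$monitor_loss))
  # identical optimization trajectory when the same pairs are optimized is
  # not required (inner masks a carve-out), but both must produce finite
  # monitored losses
  expect_true(all(is.finite(m_out$history$monitor_loss)))
})

test_that("train monitor tracks the optimized loss itself", {
  g <- random_toy_graph(44, n_m = 15, n_d = 8)
  plan <- make_folds(g$nodes$mirna, 3, repetition_seed = 44)
  split <- make_split(g, plan, 0, seed = 44)
  cfg <- train_config(dims = c(8, 8), max_epochs = 20, patience = 20,
                      seed = 2, monitor = "train")
  m <- train_model(split, cfg)
  # the monitored loss IS the training loss, so best epoch is its minimum
  expect_equal(m$history$monitor_loss, m$history$train_loss)
  expect_equal(m$best_epoch, which.min(m$history$train_loss))
  expect_identical(m$history, train_model(split, cfg)$history)
})

test_that("training learns a planted signal well above chance", {
  sg <- small_signal_graph()
  plan <- make_folds(sg$graph$nodes$mirna, 5, repetition_seed = 77)
  split <- make_split(sg$graph, plan, 0, seed = 77)
  model <- train_model(split, train_config(dims = c(32, 32, 32),
                                           max_epochs = 200, patience = 15,
                                           seed = 7))
  rep <- evaluate_model(model, split)
  expect_gt(rep$auc_roc, 0.8)
  expect_gt(rep$aupr, 0.6)
  # the same fold scored with an untrained model should be much weaker
  virgin <- init_parameters(split$train_graph, dims = c(32, 32, 32), seed = 7)
  st <- encode(split$val_graph, virgin)
  pairs <- rbind(split$val_pos, split$val_neg)
  labels <- rep(c(1, 0), c(nrow(split$val_pos), nrow(split$val_neg)))
  auc0 <- ranking_metrics(score_pairs(st, pairs), labels)$auc_roc
  expect_gt(rep$auc_roc, auc0 + 0.1)
})

test_that("fold AUC is stable under negative resampling", {
  sg <- small_signal_graph()
  plan <- make_folds(sg$graph$nodes$mirna, 5, repetition_seed = 78)
  aucs <- vapply(c(101, 202), function(s) {
    split <- make_split(sg$graph, plan, 0, seed = s)
    model <- train_model(split, train_config(dims = c(32, 32, 32),
                                             max_epochs = 150, patience = 15,
                                             seed = 7))
    evaluate_model(model, split)$auc_roc
  }, 0)
  expect_lt(abs(aucs[1] - aucs[2]), 0.05)
})

test_that("cross_validate aggregates per-fold reports correctly", {
  g <- random_toy_graph(51, n_m = 16, n_d = 8)
  cv <- cross_validate(g, tiny_config(seed = 5, max_epochs = 8), k = 3)
  expect_s3_class(cv, "cv_result")
  expect_equal(nrow(cv$per_fold), 3)
  expect_setequal(cv$per_fold$fold, 0:2)
  agg <- cv$aggregate
  expect_equal(agg$mean[agg$metric == "auc_roc"], mean(cv$per_fold$auc_roc))
  expect_equal(agg$sd[agg$metric == "aupr"], sd(cv$per_fold$aupr))
  expect_true(all(cv$per_fold$auc_roc >= 0 & cv$per_fold$auc_roc <= 1))
  # reproducible end to end
  cv2 <- cross_validate(g, tiny_config(seed = 5, max_epochs = 8), k = 3)
  expect_equal(cv$per_fold, cv2$per_fold)
  expect_error(cross_validate(g, tiny_config(), k = 50), "miRNAs")
})
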