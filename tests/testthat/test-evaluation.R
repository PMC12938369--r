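test_that("ranking metrics reproduce hand-computed examples", {
  # scores (pos: .9 .8 .4 | neg: .7 .3): 4 of 6 pos>neg orderings + 2 more
  s <- c(0.9, 0.8, 0.4, 0.7, 0.3)
  y <- c(1, 1, 1, 0, 0)
  rep <- ranking_metrics(s, y)
  expect_equal(rep$auc_roc, 5 / 6)
  # threshold 0.5: predicted pos {.9 .8 .7}, so TP=2 FP=1 FN=1
  expect_equal(rep$precision, 2 / 3)
  expect_equal(rep$recall, 2 / 3)
  expect_equal(rep$f1, 2 / 3)
  expect_equal(rep$n_pos, 3); expect_equal(rep$n_neg, 2)

  # TP=3 FP=1 FN=1 -> P=0.75 R=0.75 F1=0.75
  rep2 <- ranking_metrics(c(0.9, 0.8, 0.7, 0.6, 0.3, 0.2, 0.1, 0.4),
                          c(1,   1,   1,   0,   1,   0,   0,   0))
  expect_equal(rep2$precision, 0.75)
  expect_equal(rep2$recall, 0.75)
  expect_equal(rep2$f1, 0.75)

  # perfect and inverted separations
  expect_equal(ranking_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0))$auc_roc, 1)
  expect_equal(ranking_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0))$aupr, 1)
  expect_equal(ranking_metrics(c(0.1, 0.2, 0.9), c(1, 1, 0))$auc_roc, 0)
  # all-tied scores: AUC 1/2, AUPR = prevalence
  expect_equal(ranking_metrics(rep(0.5, 6), c(1, 0, 1, 0, 0, 0))$auc_roc, 0.5)
  expect_equal(ranking_metrics(rep(0.5, 6), c(1, 0, 1, 0, 0, 0))$aupr, 1 / 3)
  expect_error(ranking_metrics(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC matches brute-force pair counting (with ties)", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    s <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    expect_equal(ranking_metrics(s, y)$auc_roc, brute_auc(s, y),
                 tolerance = 1e-12)
  }
})

test_that("AUC and AUPR agree with pROC / baseline bounds", {
  set.seed(29)
  y <- rbinom(400, 1, 0.3)
  s <- plogis(2 * y + rnorm(400))
  rep <- ranking_metrics(s, y)
  proc_auc <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                             direction = "<")))
  expect_equal(rep$auc_roc, proc_auc, tolerance = 1e-10)
  expect_gte(rep$aupr, mean(y))  # AUPR of an informative scorer >= prevalence
  # random scores: AUC in a narrow band around 1/2 at n = 1000
  set.seed(31)
  y2 <- rep(c(1, 0), 500)
  s2 <- runif(1000)
  rep2 <- ranking_metrics(s2, y2)
  expect_gt(rep2$auc_roc, 0.4); expect_lt(rep2$auc_roc, 0.6)
  expect_gt(rep2$aupr, 0.4); expect_lt(rep2$aupr, 0.65)
})

test_that("perturb_relation removes the requested fraction reproducibly", {
  g <- random_toy_graph(61, n_m = 12, n_d = 8)
  n0 <- nrow(g$edges$mirna_disease)
  p <- perturb_relation(g, "mirna_disease", 0.5, seed = 3)
  expect_equal(nrow(p$edges$mirna_disease), n0 - round(0.5 * n0))
  expect_true(all(apply(p$edges$mirna_disease, 1, paste, collapse = ",") %in%
                  apply(g$edges$mirna_disease, 1, paste, collapse = ",")))
  expect_identical(perturb_relation(g, "mirna_disease", 0.5, seed = 3),
                   p)
  expect_identical(perturb_relation(g, "mirna_disease", 0), g)
  expect_error(perturb_relation(g, "bogus", 0.1), "unknown")
})

test_that("ablation study compares like with like and degrades the signal", {
  sg <- small_signal_graph(seed = 63, n_mirna = 40, n_disease = 20,
                           n_gene = 30)
  cfg <- tiny_config(seed = 11, max_epochs = 40)
  pre <- ablation_study(sg$graph, cfg, relations = "disease_gene",
                        mode = "pre", k = 4)
  expect_equal(nrow(pre), 1)
  expect_equal(pre$decrease, pre$auc_base - pre$auc_ablated)
  expect_equal(pre$mode, "pre")
  # baseline AUC identical across calls (shared plan and seeds)
  pre2 <- ablation_study(sg$graph, cfg, relations = "mirna_mirna",
                         mode = "pre", k = 4)
  expect_equal(pre$auc_base, pre2$auc_base)

  post <- ablation_study(sg$graph, cfg,
                         relations = c("mirna_mirna", "disease_gene"),
                         mode = "post", k = 4, perturb_frac = 0.3)
  expect_equal(nrow(post), 2)
  expect_equal(post$auc_base[1], post$auc_base[2])
  expect_true(all(abs(post$decrease) <= 1))
})

test_that("disease holdout reports the removal cost per disease", {
  sg <- small_signal_graph(seed = 65, n_mirna = 40, n_disease = 20,
                           n_gene = 30)
  pos <- hetmda:::relation_pairs(sg$graph, "mirna_disease")
  counts <- sort(table(pos$target), decreasing = TRUE)
  ds <- names(counts)[1:2]
  res <- disease_holdout(sg$graph, tiny_config(seed = 13, max_epochs = 40),
                         ds)
  expect_equal(res$disease, ds)
  expect_equal(res$n_pos, as.integer(counts[ds]), ignore_attr = TRUE)
  expect_equal(res$delta_auc, res$auc_base - res$auc_drop)
  expect_true(all(res$auc_base >= 0 & res$auc_base <= 1))
  expect_true(all(res$auc_drop >= 0 & res$auc_drop <= 1))
  expect_error(disease_holdout(sg$graph, tiny_config(), "no-such-disease"),
               "not in graph")
})

test_that("disease holdout skips diseases with fewer than 2 positives", {
  m_ids <- sprintf("m%02d", 1:8)
  sim <- matrix(0, 8, 8, dimnames = list(m_ids, m_ids))
  sim["m01", "m02"] <- sim["m02", "m01"] <- 1
  pat <- matrix(0, 8, 2, dimnames = list(m_ids, c("AA", "AC")))
  pat[, 1] <- 1; pat[1:4, 2] <- 1
  md <- association_table("mirna_disease",
                          c("m01", "m02", "m03", "m04"),
                          c("d1", "d1", "d1", "d2"))
  dg <- association_table("disease_gene", c("d1", "d2"), c("g1", "g2"))
  g <- assemble_graph(md, dg, sim, pat)
  cfg <- train_config(dims = c(4, 4), max_epochs = 3, patience = 5, seed = 1)
  expect_warning(res <- disease_holdout(g, cfg, c("d1", "d2")), "d2")
  expect_equal(res$disease, "d1")
  expect_equal(res$n_pos, 3L)
  expect_error(suppressWarnings(disease_holdout(g, cfg, "d2")),
               "no evaluable")
})

test_that("version_transfer is exact on self-comparison and counts divergence", {
  g_old <- random_toy_graph(71, n_m = 14, n_d = 8)
  # new release: same entities, extra MDA edges
  e <- g_old$edges$mirna_disease
  all_cells <- expand.grid(m = seq_along(g_old$nodes$mirna),
                           d = seq_along(g_old$nodes$disease))
  have <- paste(e[, 1], e[, 2])
  missing <- all_cells[!paste(all_cells$m, all_cells$d) %in% have, ]
  add <- missing[1:6, ]
  g_new <- g_old
  g_new$edges$mirna_disease <- rbind(e, as.matrix(unname(add)))

  params <- init_parameters(g_old, dims = c(8, 6), seed = 71)
  tr <- version_transfer(params, g_old, params, g_new, seed = 5)
  expect_equal(tr$n_new_pos, 6)
  expect_equal(tr$divergent_fraction,
               mean(abs(tr$scores$prob_old - tr$scores$prob_new) > 0.5))
  expect_true(tr$pearson_r >= -1 && tr$pearson_r <= 1)
  expect_true(tr$auc_new_positives >= 0 && tr$auc_new_positives <= 1)
  # the scored pairs are exactly the new positives (old pairs excluded)
  old_keys <- paste(g_old$nodes$mirna[e[, 1]], g_old$nodes$disease[e[, 2]])
  got_keys <- paste(tr$scores$mirna, tr$scores$disease)
  expect_false(any(got_keys %in% old_keys))
  expect_setequal(got_keys, paste(g_old$nodes$mirna[add$m],
                                  g_old$nodes$disease[add$d]))
  # scores against the old model are reproducible from the seed
  tr_b <- version_transfer(params, g_old, params, g_new, seed = 5)
  expect_equal(tr_b$auc_new_positives, tr$auc_new_positives)
})

test_that("version_transfer errors when there are no new pairs", {
  g <- random_toy_graph(73, n_m = 10, n_d = 6)
  params <- init_parameters(g, dims = c(6, 4), seed = 73)
  expect_error(version_transfer(params, g, params, g), "no new positive")
})
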