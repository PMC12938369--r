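test_that("directed relation schema expands every canonical relation twice", {
  drs <- directed_relations()
  expect_length(drs, 10)
  expect_setequal(vapply(drs, `[[`, "", "canonical"),
                  names(canonical_relations()))
  for (dr in drs) {
    st <- canonical_relations()[[dr$canonical]]
    if (endsWith(dr$name, "__fwd")) {
      expect_equal(c(dr$src, dr$dst), unname(st))
    } else {
      expect_equal(c(dr$dst, dr$src), unname(st))
    }
  }
})

test_that("normalized adjacency rows are neighbor means", {
  g <- random_toy_graph(101)
  adj <- hetmda:::build_norm_adj(g, "relation")
  for (nm in names(adj)) {
    rs <- Matrix::rowSums(adj[[nm]])
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-12), info = nm)
  }
  # fwd/rev share the same support, transposed
  expect_equal(as.matrix(adj$mirna_disease__fwd > 0) * 1,
               t(as.matrix(adj$mirna_disease__rev > 0) * 1))
  # global norm: per node, total mass across relations is 1 (if any neighbor)
  adjg <- hetmda:::build_norm_adj(g, "global")
  for (t in node_types()) {
    tot <- rep(0, length(g$nodes[[t]]))
    for (dr in directed_relations())
      if (dr$dst == t) tot <- tot + Matrix::rowSums(adjg[[dr$name]])
    expect_true(all(abs(tot[tot > 0] - 1) < 1e-12), info = t)
  }
})

test_that("one message-passing layer matches the dense triple-loop oracle", {
  for (seed in c(2, 3, 4)) {
    g <- random_toy_graph(seed)
    params <- init_parameters(g, dims = c(6, 5, 4), seed = seed)
    st0 <- initial_state(g, params)
    st1 <- message_pass_layer(st0, g, params, 1)
    want1 <- dense_layer_oracle(lapply(st0$H, unname), g, params, 1)
    for (t in node_types())
      expect_equal(unname(st1$H[[t]]), want1[[t]], tolerance = 1e-10,
                   info = paste(seed, t, "layer1"))
    st2 <- message_pass_layer(st1, g, params, 2)
    want2 <- dense_layer_oracle(want1, g, params, 2)
    for (t in node_types())
      expect_equal(unname(st2$H[[t]]), want2[[t]], tolerance = 1e-10,
                   info = paste(seed, t, "layer2"))
    # composition of layers == encode()
    enc <- encode(g, params)
    for (t in node_types())
      expect_equal(unname(enc$H[[t]]), unname(st2$H[[t]]), tolerance = 1e-12)
  }
  g <- random_toy_graph(2)
  params <- init_parameters(g, dims = c(6, 5, 4), seed = 2)
  st0 <- initial_state(g, params)
  expect_error(message_pass_layer(st0, g, params, 2), "layer")
})

test_that("with all relations ablated the network reduces to self-transforms", {
  g <- random_toy_graph(7)
  for (r in names(canonical_relations())) g <- ablate_edge_type(g, r)
  params <- init_parameters(g, dims = c(6, 5, 4), seed = 7)
  enc <- encode(g, params)
  for (t in node_types()) {
    h <- params$X[[t]] %*% params$P[[t]]
    h <- relu(h %*% params$layers[[1]]$W0)
    h <- relu(h %*% params$layers[[2]]$W0)
    expect_equal(unname(enc$H[[t]]), h, tolerance = 1e-12, info = t)
  }
})

test_that("zero-layer model scores are projected-embedding dot products", {
  g <- random_toy_graph(11)
  params <- init_parameters(g, dims = 8, seed = 11)
  expect_equal(params$L, 0)
  enc <- encode(g, params)
  pairs <- data.frame(mirna = g$nodes$mirna[c(1, 3)],
                      disease = g$nodes$disease[c(2, 2)])
  sc <- score_pairs(enc, pairs)
  for (i in 1:2) {
    hm <- params$P$mirna[match(pairs$mirna[i], g$nodes$mirna), ]
    hd <- params$P$disease[match(pairs$disease[i], g$nodes$disease), ]
    expect_equal(sc$logit[i], sum(hm * hd), tolerance = 1e-12)
  }
  expect_equal(sc$probability, plogis(sc$logit))
  expect_error(score_pairs(enc, data.frame(mirna = "nope", disease = "d01")),
               "unknown")
})

test_that("bce_loss matches the naive formula and stays finite at extremes", {
  expect_equal(bce_loss(0, 1), log(2))
  expect_equal(bce_loss(0, 0), log(2))
  set.seed(17)
  l <- rnorm(200, sd = 3); y <- rbinom(200, 1, 0.5)
  p <- plogis(l)
  naive <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(bce_loss(l, y), naive, tolerance = 1e-12)
  expect_true(is.finite(bce_loss(c(1000, -1000), c(1, 0))))
  expect_equal(bce_loss(c(1000, -1000), c(1, 0)), 0, tolerance = 1e-10)
  expect_gt(bce_loss(1000, 0), 100)
  expect_error(bce_loss(numeric(0), numeric(0)), "empty")
})

test_that("analytic gradients match central finite differences", {
  g <- random_toy_graph(5)
  params <- init_parameters(g, dims = c(5, 4, 3), seed = 5)
  adj <- hetmda:::build_norm_adj(g, params$norm)
  pos <- hetmda:::relation_pairs(g, "mirna_disease")
  pair_idx <- cbind(match(pos$source, g$nodes$mirna),
                    match(pos$target, g$nodes$disease))
  set.seed(6)
  neg <- cbind(sample(length(g$nodes$mirna), 6, TRUE),
               sample(length(g$nodes$disease), 6, TRUE))
  pair_idx <- rbind(pair_idx, neg)
  labels <- rep(c(1, 0), c(nrow(pos), 6))

  loss_at <- function(plist) {
    p <- hetmda:::assign_params(params, plist)
    cache <- hetmda:::gnn_forward(adj, p)
    hetmda:::gnn_loss_grads(p, adj, cache, pair_idx, labels)$loss
  }
  plist <- hetmda:::param_list(params)
  cache <- hetmda:::gnn_forward(adj, params)
  grads <- hetmda:::gnn_loss_grads(params, adj, cache, pair_idx, labels)$grads

  eps <- 1e-5
  set.seed(8)
  worst <- 0
  for (k in names(plist)) {
    entries <- sample(length(plist[[k]]), min(4, length(plist[[k]])))
    for (e in entries) {
      up <- plist; up[[k]][e] <- up[[k]][e] + eps
      dn <- plist; dn[[k]][e] <- dn[[k]][e] - eps
      fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      an <- grads[[k]][e]
      err <- abs(fd - an) / max(1, abs(fd), abs(an))
      worst <- max(worst, err)
      expect_lt(err, 1e-4)
    }
  }
  expect_lt(worst, 1e-5)  # hand-written backprop should be near machine-exact
})

test_that("Adam drives a known quadratic to its minimum", {
  plist <- list(a = matrix(c(10, -4), 1))
  st <- hetmda:::adam_init(plist)
  for (i in 1:2000) {
    grads <- list(a = 2 * (plist$a - 3))
    upd <- hetmda:::adam_step(plist, grads, st, lr = 0.05)
    plist <- upd$plist; st <- upd$state
  }
  expect_equal(unname(plist$a), matrix(c(3, 3), 1), tolerance = 1e-4)
})

test_that("parameter init is reproducible and parameter list round-trips", {
  g <- random_toy_graph(9)
  p1 <- init_parameters(g, dims = c(6, 4), seed = 42)
  p2 <- init_parameters(g, dims = c(6, 4), seed = 42)
  p3 <- init_parameters(g, dims = c(6, 4), seed = 43)
  expect_identical(hetmda:::param_list(p1), hetmda:::param_list(p2))
  expect_false(identical(p1$P$mirna, p3$P$mirna))
  back <- hetmda:::assign_params(p1, hetmda:::param_list(p1))
  expect_identical(hetmda:::param_list(back), hetmda:::param_list(p1))
})

test_that("kmer feature mode uses the supplied miRNA features", {
  g <- random_toy_graph(12)
  seqs <- setNames(random_rna(length(g$nodes$mirna), 20), g$nodes$mirna)
  feats <- kmer_profiles(seqs[g$nodes$mirna])
  p <- init_parameters(g, dims = c(6, 4), feature_mode = "kmer",
                       features = list(mirna = feats), seed = 1)
  expect_equal(p$X$mirna, unname(as.matrix(feats)))
  expect_equal(dim(p$P$mirna), c(80, 6))
  expect_equal(p$X$disease, diag(length(g$nodes$disease)))
  expect_error(init_parameters(g, feature_mode = "kmer"), "features")
  enc <- encode(g, p)  # forward pass works with non-square inputs
  expect_equal(nrow(enc$H$mirna), length(g$nodes$mirna))
})

test_that("model checkpoints round-trip through save/load", {
  g <- random_toy_graph(14)
  params <- init_parameters(g, dims = c(5, 4), seed = 14)
  dir <- withr::local_tempdir()
  save_model(params, file.path(dir, "ckpt"))
  expect_true(file.exists(file.path(dir, "ckpt", "manifest.json")))
  back <- load_model(file.path(dir, "ckpt"))
  expect_identical(hetmda:::param_list(back), hetmda:::param_list(params))
  enc1 <- encode(g, params); enc2 <- encode(g, back)
  expect_equal(enc1$H, enc2$H)
  expect_error(load_model(dir), "checkpoint")
})
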