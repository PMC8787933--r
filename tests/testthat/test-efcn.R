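test_that("network construction is seed-deterministic with a closed-form parameter count", {
  sch <- small_schema()
  arch <- quick_arch()
  n1 <- build_efcn(sch, arch, "decision", seed = 7)
  n2 <- build_efcn(sch, arch, "decision", seed = 7)
  expect_identical(n1$params, n2$params)
  expect_false(identical(n1$params,
                         build_efcn(sch, arch, "decision", seed = 8)$params))

  # embeddings + conv (k*c_in*c_out + c_out) + batch norm (2*c_out) + head
  L <- lengths(sch$features[sch$decision_inputs])
  d <- pmin(16, ceiling((L + 1) / 2))
  d_max <- max(d)
  expected <- sum(L * d)
  c_in <- d_max
  for (b in seq_along(arch$conv_filters)) {
    k <- arch$kernel_widths[b]; c_out <- arch$conv_filters[b]
    expected <- expected + k * c_in * c_out + c_out + 2 * c_out
    c_in <- c_out
  }
  expected <- expected + c_in + 1
  expect_identical(efcn_param_count(n1), as.integer(expected))
})

test_that("decision and survival networks differ by exactly one embedding table", {
  sch <- small_schema()
  dec <- build_efcn(sch, quick_arch(), "decision", seed = 1)
  sur <- build_efcn(sch, quick_arch(), "survival", seed = 1)
  emb <- function(n) grep("^emb\\.", names(n$params), value = TRUE)
  expect_identical(setdiff(emb(sur), emb(dec)),
                   "emb.coronary_angiography")
  expect_length(sur$features, length(dec$features) + 1L)
})

test_that("backpropagation matches numerical gradients", {
  sch <- small_schema()
  net <- build_efcn(sch, quick_arch(), "decision", seed = 4)
  set.seed(9)
  X1 <- matrix(sapply(net$n_levels, function(L) sample.int(L, 6, TRUE)), 6)
  y <- c(1, 0, 1, 0, 1, 0)
  loss <- function(net) {
    p <- pmin(pmax(efcn_forward(net, X1, "train")$p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  cache <- efcn_forward(net, X1, "train")
  gr <- efcn_backward(net, cache, y)
  eps <- 1e-5
  for (nm in names(net$params)) {
    take <- seq_len(min(4, length(net$params[[nm]])))
    for (i in take) {
      np <- net
      np$params[[nm]][i] <- net$params[[nm]][i] + eps
      up <- loss(np)
      np$params[[nm]][i] <- net$params[[nm]][i] - eps
      dn <- loss(np)
      num <- (up - dn) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-3,
                   label = sprintf("analytic grad %s[%d]", nm, i))
    }
  }
})

test_that("a separable toy task is learned to perfect discrimination", {
  sch <- small_schema()
  reg <- small_registry(400, seed = 2)
  xi <- index_encode(reg, sch, "decision")
  sub <- function(x, i) { x$matrix <- x$matrix[i, , drop = FALSE]; x }
  net <- build_efcn(sch, quick_arch(), "decision", seed = 1)
  net <- train_efcn(net, sub(xi, 1:300), reg$ca_performed[1:300],
                    sub(xi, 301:400), reg$ca_performed[301:400],
                    list(max_epochs = 50, patience = 50, seed = 3))
  expect_gte(max(net$history$val_auroc), 0.99)
  scores <- predict(net, sub(xi, 301:400))
  pos <- reg$ca_performed[301:400] == 1
  expect_gt(min(scores[pos]), max(scores[!pos]))
})

test_that("training rejects single-class labels and overlapping usage is caught upstream", {
  sch <- small_schema()
  reg <- small_registry(50, seed = 2)
  xi <- index_encode(reg, sch, "decision")
  net <- build_efcn(sch, quick_arch(), "decision", seed = 1)
  expect_error(train_efcn(net, xi, rep(1L, 50), xi, reg$ca_performed),
               "single-class")
  expect_error(train_efcn_pair(reg, sch, 1:30, 25:50), "overlap")
})

test_that("prediction is deterministic, duplicate-consistent and order-invariant", {
  sch <- small_schema()
  reg <- small_registry(120, seed = 5, noise = 0.2)
  xi <- index_encode(reg, sch, "decision")
  sub <- function(x, i) { x$matrix <- x$matrix[i, , drop = FALSE]; x }
  net <- build_efcn(sch, quick_arch(), "decision", seed = 2)
  net <- train_efcn(net, sub(xi, 1:80), reg$ca_performed[1:80],
                    sub(xi, 81:120), reg$ca_performed[81:120],
                    list(max_epochs = 5, patience = 5, seed = 1))
  s <- predict(net, xi)
  expect_true(all(s > 0 & s < 1))
  dup <- xi; dup$matrix <- xi$matrix[c(1, 1, 2), , drop = FALSE]
  sd <- predict(net, dup)
  expect_equal(sd[1], sd[2])
  perm <- sample(nrow(xi$matrix))
  shuffled <- xi; shuffled$matrix <- xi$matrix[perm, , drop = FALSE]
  expect_equal(predict(net, shuffled), s[perm])
  expect_error(predict(net, xi$matrix[, 1:3]), "width")
})

test_that("embedding transfer copies shared tables verbatim and leaves CA fresh", {
  sch <- small_schema()
  reg <- small_registry(200, seed = 6, noise = 0.1)
  xi <- index_encode(reg, sch, "decision")
  sub <- function(x, i) { x$matrix <- x$matrix[i, , drop = FALSE]; x }
  dec <- build_efcn(sch, quick_arch(), "decision", seed = 1)
  dec <- train_efcn(dec, sub(xi, 1:150), reg$ca_performed[1:150],
                    sub(xi, 151:200), reg$ca_performed[151:200],
                    list(max_epochs = 8, patience = 8, seed = 2))
  sur <- transfer_embeddings(dec, seed = 9)
  for (f in dec$features)
    expect_identical(sur$params[[paste0("emb.", f)]],
                     dec$params[[paste0("emb.", f)]])
  expect_identical(
    sur$transfer_manifest$initialization[
      sur$transfer_manifest$feature == "coronary_angiography"],
    "randomly_initialized")
  expect_identical(sum(sur$transfer_manifest$initialization ==
                         "randomly_initialized"), 1L)
  expect_error(transfer_embeddings(sur), "decision-input")

  # after survival training the shared tables move, and the stored
  # decision model is untouched
  dec_snapshot <- dec$params
  xs <- index_encode(reg, sch, "survival")
  sur2 <- train_efcn(sur, sub(xs, 1:150), reg$outcome_class[1:150],
                     sub(xs, 151:200), reg$outcome_class[151:200],
                     list(max_epochs = 8, patience = 8, seed = 3))
  moved <- vapply(dec$features, function(f)
    sum(abs(sur2$params[[paste0("emb.", f)]] -
              dec$params[[paste0("emb.", f)]])), numeric(1))
  expect_true(all(moved > 0))
  expect_identical(dec$params, dec_snapshot)
})

test_that("the full pair run is reproducible seed-for-seed", {
  sch <- small_schema()
  reg <- small_registry(200, seed = 8, noise = 0.25)
  h <- list(max_epochs = 6, patience = 6)
  b1 <- train_efcn_pair(reg, sch, 1:140, 141:200, quick_arch(), h, seed = 5)
  b2 <- train_efcn_pair(reg, sch, 1:140, 141:200, quick_arch(), h, seed = 5)
  expect_identical(b1$decision_model$history, b2$decision_model$history)
  expect_identical(b1$survival_model$params, b2$survival_model$params)
  expect_identical(predict(b1$survival_model, reg),
                   predict(b2$survival_model, reg))
})
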