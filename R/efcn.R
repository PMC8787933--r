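#' Embedded fully convolutional network architecture
#'
#' The EFCN treats a patient record as a length-F sequence (one position
#' per categorical feature).  Each feature owns an embedding table; the
#' embedded features are concatenated along the feature axis and passed
#' through same-padded 1-D convolution blocks (convolution, batch
#' normalization, rectifier), global average pooling over positions, and
#' a single logistic output.  Features whose embedding dimension is
#' below the widest one are zero-padded in the channel dimension.
#'
#' Default sizes target registry-scale data (thousands of rows, a few
#' dozen features); every element is configurable.
#'
#' @param conv_filters integer vector, output channels per conv block.
#' @param kernel_widths integer vector, same length, kernel width per block.
#' @param use_batch_norm include batch normalization in each block.
#' @param dropout_rate inverted dropout on the pooled representation
#'   during training (0 disables).
#' @param embedding_dim_rule function mapping a feature's level count to
#'   its embedding dimension.  Default `min(16, ceiling((levels+1)/2))`:
#'   small vocabularies get small embeddings.
#' @return object of class `efcn_architecture`.
#' @export
efcn_architecture <- function(conv_filters = c(32L, 64L, 32L),
                              kernel_widths = c(8L, 5L, 3L),
                              use_batch_norm = TRUE,
                              dropout_rate = 0,
                              embedding_dim_rule = function(n_levels)
                                min(16L, as.integer(ceiling((n_levels + 1) / 2)))) {
  stopifnot(length(conv_filters) >= 1,
            length(conv_filters) == length(kernel_widths),
            all(conv_filters >= 1), all(kernel_widths >= 1),
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_widths = as.integer(kernel_widths),
                 use_batch_norm = isTRUE(use_batch_norm),
                 dropout_rate = dropout_rate,
                 embedding_dim_rule = embedding_dim_rule),
            class = "efcn_architecture")
}

#' Build an untrained EFCN
#'
#' Instantiates embedding tables (one per input feature), convolution
#' stacks and the logistic head with seed-deterministic initialization
#' (embeddings ~ N(0, 0.05); conv and head weights He-scaled normal).
#'
#' @param schema a [feature_schema()].
#' @param arch an [efcn_architecture()].
#' @param input_set `"decision"` or `"survival"` (decision inputs + CA).
#' @param seed initialization seed.
#' @return object of class `efcn` (untrained).
#' @export
build_efcn <- function(schema, arch = efcn_architecture(),
                       input_set = c("decision", "survival"), seed = 1L) {
  input_set <- match.arg(input_set)
  feats <- schema_inputs(schema, input_set)
  n_levels <- vapply(schema$features[feats], length, integer(1))
  if (any(n_levels < 2)) stop("every feature needs >= 2 levels")
  d <- vapply(n_levels, function(L) as.integer(arch$embedding_dim_rule(L)),
              integer(1))
  if (any(d < 1)) stop("embedding dimensions must be >= 1")
  d_max <- max(d)
  params <- withr_seed(seed, {
    p <- list()
    for (j in seq_along(feats))
      p[[paste0("emb.", feats[j])]] <-
        matrix(stats::rnorm(n_levels[j] * d[j], 0, 0.05), n_levels[j], d[j])
    c_in <- d_max
    for (b in seq_along(arch$conv_filters)) {
      k <- arch$kernel_widths[b]; c_out <- arch$conv_filters[b]
      p[[paste0("conv", b, ".W")]] <-
        matrix(stats::rnorm(k * c_in * c_out, 0, sqrt(2 / (k * c_in))),
               k * c_in, c_out)
      p[[paste0("conv", b, ".b")]] <- numeric(c_out)
      if (arch$use_batch_norm) {
        p[[paste0("bn", b, ".gamma")]] <- rep(1, c_out)
        p[[paste0("bn", b, ".beta")]] <- numeric(c_out)
      }
      c_in <- c_out
    }
    p[["head.w"]] <- matrix(stats::rnorm(c_in, 0, sqrt(2 / c_in)), c_in, 1)
    p[["head.b"]] <- 0
    p
  })
  bn_state <- lapply(seq_along(arch$conv_filters), function(b)
    list(mean = numeric(arch$conv_filters[b]),
         var = rep(1, arch$conv_filters[b])))
  structure(list(schema = schema, arch = arch, input_set = input_set,
                 features = feats, n_levels = n_levels, emb_dims = d,
                 d_max = d_max, params = params, bn_state = bn_state,
                 seed = as.integer(seed), trained = FALSE,
                 history = NULL), class = "efcn")
}

#' @export
print.efcn <- function(x, ...) {
  cat(sprintf("<efcn> %s model: %d features, conv (%s), %s\n",
              x$input_set, length(x$features),
              paste(x$arch$conv_filters, collapse = ", "),
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  %d trainable parameters\n", efcn_param_count(x)))
  if (!is.null(x$history))
    cat(sprintf("  best validation AUROC %.4f at epoch %d of %d\n",
                max(x$history$val_auroc), which.max(x$history$val_auroc),
                nrow(x$history)))
  invisible(x)
}

#' Trainable parameter count of an EFCN
#' @param net an `efcn`.
#' @return integer parameter count.
#' @export
efcn_param_count <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

# --- forward / backward -----------------------------------------------------

# Activations are held as a flat (n * positions) x channels matrix with
# row index i + (t - 1) * n: padding and im2col then reduce to
# contiguous row-block copies, and convolution to one BLAS matmul.
cadd <- function(M, v) M + rep(v, rep.int(nrow(M), length(v)))
cmul <- function(M, v) M * rep(v, rep.int(nrow(M), length(v)))

# X1: n x F matrix of 1-based level indices.
# mode "train" computes batch statistics and caches for backward;
# "eval" uses running batch-norm statistics.
efcn_forward <- function(net, X1, mode = c("eval", "train"),
                         dropout_mask = NULL) {
  mode <- match.arg(mode)
  arch <- net$arch
  n <- nrow(X1); Fn <- ncol(X1); d_max <- net$d_max
  M <- matrix(0, n * Fn, d_max)
  for (j in seq_len(Fn)) {
    E <- net$params[[paste0("emb.", net$features[j])]]
    M[(j - 1L) * n + seq_len(n), seq_len(ncol(E))] <- E[X1[, j], , drop = FALSE]
  }
  cache <- list(X1 = X1, n = n, Fn = Fn, blocks = list())
  mid <- seq_len(n * Fn)
  c_in <- d_max
  for (b in seq_along(arch$conv_filters)) {
    k <- arch$kernel_widths[b]; c_out <- arch$conv_filters[b]
    left <- (k - 1L) %/% 2L
    Mpad <- matrix(0, (Fn + k - 1L) * n, c_in)
    Mpad[left * n + mid, ] <- M
    Xcol <- matrix(0, n * Fn, k * c_in)
    for (j in seq_len(k))
      Xcol[, ((j - 1L) * c_in + 1L):(j * c_in)] <-
        Mpad[(j - 1L) * n + mid, , drop = FALSE]
    Z <- cadd(Xcol %*% net$params[[paste0("conv", b, ".W")]],
              net$params[[paste0("conv", b, ".b")]])
    blk <- list(Xcol = Xcol, k = k, c_in = c_in, left = left)
    if (arch$use_batch_norm) {
      g <- net$params[[paste0("bn", b, ".gamma")]]
      be <- net$params[[paste0("bn", b, ".beta")]]
      if (mode == "train") {
        mu <- colMeans(Z)
        v <- colMeans(Z^2) - mu^2
        blk$mu <- mu; blk$v <- v
      } else {
        mu <- net$bn_state[[b]]$mean
        v <- net$bn_state[[b]]$var
      }
      inv_std <- 1 / sqrt(v + 1e-5)
      xhat <- cmul(cadd(Z, -mu), inv_std)
      Z <- cadd(cmul(xhat, g), be)
      blk$xhat <- xhat; blk$inv_std <- inv_std
    }
    relu_mask <- Z > 0
    Z <- Z * relu_mask
    blk$relu_mask <- relu_mask
    cache$blocks[[b]] <- blk
    M <- Z
    c_in <- c_out
  }
  G <- M[seq_len(n), , drop = FALSE]
  for (t in 2:Fn) G <- G + M[(t - 1L) * n + seq_len(n), , drop = FALSE]
  G <- G / Fn
  if (mode == "train" && arch$dropout_rate > 0 && !is.null(dropout_mask))
    G <- G * dropout_mask / (1 - arch$dropout_rate)
  cache$G <- G
  logits <- drop(G %*% net$params[["head.w"]]) + net$params[["head.b"]]
  cache$p <- stats::plogis(logits)
  cache
}

# Gradient of mean binary cross-entropy; returns named list matching params.
efcn_backward <- function(net, cache, y, dropout_mask = NULL) {
  arch <- net$arch
  n <- cache$n; Fn <- cache$Fn
  mid <- seq_len(n * Fn)
  grads <- list()
  dlogit <- matrix((cache$p - y) / n, n, 1)
  grads[["head.w"]] <- crossprod(cache$G, dlogit)
  grads[["head.b"]] <- sum(dlogit)
  dG <- dlogit %*% t(net$params[["head.w"]])
  if (arch$dropout_rate > 0 && !is.null(dropout_mask))
    dG <- dG * dropout_mask / (1 - arch$dropout_rate)
  # GAP spreads each pooled gradient uniformly over the F positions
  dZ <- dG[rep(seq_len(n), times = Fn), , drop = FALSE] / Fn
  for (b in rev(seq_along(arch$conv_filters))) {
    blk <- cache$blocks[[b]]
    dZ <- dZ * blk$relu_mask
    if (arch$use_batch_norm) {
      g <- net$params[[paste0("bn", b, ".gamma")]]
      grads[[paste0("bn", b, ".gamma")]] <- colSums(dZ * blk$xhat)
      grads[[paste0("bn", b, ".beta")]] <- colSums(dZ)
      m <- nrow(dZ)
      dxhat <- cmul(dZ, g)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * blk$xhat)
      dZ <- cmul(cadd(dxhat, -s1 / m) - cmul(blk$xhat, s2 / m), blk$inv_std)
    }
    W <- net$params[[paste0("conv", b, ".W")]]
    grads[[paste0("conv", b, ".W")]] <- crossprod(blk$Xcol, dZ)
    grads[[paste0("conv", b, ".b")]] <- colSums(dZ)
    dXcol <- dZ %*% t(W)
    k <- blk$k; c_in <- blk$c_in; left <- blk$left
    dMpad <- matrix(0, (Fn + k - 1L) * n, c_in)
    for (j in seq_len(k)) {
      rows <- (j - 1L) * n + mid
      dMpad[rows, ] <- dMpad[rows, , drop = FALSE] +
        dXcol[, ((j - 1L) * c_in + 1L):(j * c_in), drop = FALSE]
    }
    dZ <- dMpad[left * n + mid, , drop = FALSE]
  }
  for (j in seq_len(Fn)) {
    f <- net$features[j]
    d_f <- net$emb_dims[j]
    dmat <- dZ[(j - 1L) * n + seq_len(n), seq_len(d_f), drop = FALSE]
    acc <- rowsum(dmat, group = cache$X1[, j])
    gE <- matrix(0, net$n_levels[j], d_f)
    gE[as.integer(rownames(acc)), ] <- acc
    grads[[paste0("emb.", f)]] <- gE
  }
  grads
}

#' Train an EFCN with early stopping on validation AUROC
#'
#' Minimizes mean binary cross-entropy by mini-batch adaptive-moment
#' gradient descent.  After every epoch the network is scored on the
#' validation set (using running batch-norm statistics); the weights
#' from the best validation-AUROC epoch are returned.  Fully
#' deterministic given the seed under single-threaded execution.
#'
#' @param net an untrained (or warm-started) `efcn`.
#' @param x_train,x_val `index_matrix` objects (or 0-based integer
#'   matrices) for disjoint training and validation sets.
#' @param y_train,y_val binary labels.
#' @param hyper list overriding any of: `lr` (1e-3), `batch_size` (64),
#'   `max_epochs` (200), `patience` (20), `seed` (1).
#' @return the trained `efcn`, with a `history` data frame (epoch,
#'   train_loss, val_auroc) attached.
#' @export
train_efcn <- function(net, x_train, y_train, x_val, y_val, hyper = list()) {
  stopifnot(inherits(net, "efcn"))
  h <- utils::modifyList(list(lr = 1e-3, batch_size = 64L, max_epochs = 200L,
                              patience = 20L, seed = 1L), hyper)
  X <- as_index_1(x_train, net)
  Xv <- as_index_1(x_val, net)
  y <- as.integer(y_train); yv <- as.integer(y_val)
  if (length(unique(y)) < 2) stop("training labels are single-class")
  if (length(unique(yv)) < 2) stop("validation labels are single-class")
  n <- nrow(X)
  adam <- list(m = lapply(net$params, function(p) p * 0),
               v = lapply(net$params, function(p) p * 0), t = 0)
  # seeded with the incoming weights so zero-epoch training is the identity
  best <- list(auroc = -Inf, params = net$params, bn = net$bn_state,
               epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auroc = numeric(0))
  bn_momentum <- 0.9
  withr_seed(h$seed, {
    for (epoch in seq_len(h$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = h$batch_size)) {
        idx <- ord[start:min(start + h$batch_size - 1L, n)]
        if (length(idx) < 2) next  # batch norm needs > 1 row
        mask <- if (net$arch$dropout_rate > 0)
          matrix(stats::rbinom(length(idx) * utils::tail(net$arch$conv_filters, 1),
                               1, 1 - net$arch$dropout_rate),
                 length(idx)) else NULL
        cache <- efcn_forward(net, X[idx, , drop = FALSE], "train", mask)
        p <- pmin(pmax(cache$p, 1e-12), 1 - 1e-12)
        losses <- c(losses, -mean(y[idx] * log(p) + (1 - y[idx]) * log(1 - p)))
        if (net$arch$use_batch_norm)
          for (b in seq_along(net$bn_state)) {
            net$bn_state[[b]]$mean <- bn_momentum * net$bn_state[[b]]$mean +
              (1 - bn_momentum) * cache$blocks[[b]]$mu
            net$bn_state[[b]]$var <- bn_momentum * net$bn_state[[b]]$var +
              (1 - bn_momentum) * cache$blocks[[b]]$v
          }
        grads <- efcn_backward(net, cache, y[idx], mask)
        adam$t <- adam$t + 1
        bc1 <- 1 - 0.9^adam$t; bc2 <- 1 - 0.999^adam$t
        for (nm in names(net$params)) {
          g <- grads[[nm]]
          if (is.null(g)) next
          adam$m[[nm]] <- 0.9 * adam$m[[nm]] + 0.1 * g
          adam$v[[nm]] <- 0.999 * adam$v[[nm]] + 0.001 * g^2
          net$params[[nm]] <- net$params[[nm]] -
            h$lr * (adam$m[[nm]] / bc1) / (sqrt(adam$v[[nm]] / bc2) + 1e-8)
        }
      }
      val_scores <- efcn_score(net, Xv)
      va <- auroc(val_scores, yv)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(losses),
                                           val_auroc = va))
      if (va > best$auroc) {
        best <- list(auroc = va, params = net$params, bn = net$bn_state,
                     epoch = epoch)
      } else if (epoch - best$epoch >= h$patience) break
    }
  })
  net$params <- best$params
  net$bn_state <- best$bn
  net$trained <- TRUE
  net$history <- history
  net$hyper <- h
  net
}

# Accept an index_matrix, a 0-based integer matrix, or a registry data
# frame; return 1-based indices in the net's feature order.
as_index_1 <- function(x, net) {
  if (inherits(x, "index_matrix")) {
    if (!identical(colnames(x$matrix), net$features))
      stop("index matrix features do not match the network's input set")
    return(x$matrix + 1L)
  }
  if (is.data.frame(x))
    return(index_encode(x, net$schema, net$input_set)$matrix + 1L)
  if (is.matrix(x)) {
    if (ncol(x) != length(net$features))
      stop(sprintf("input width %d does not match network width %d",
                   ncol(x), length(net$features)))
    return(x + 1L)
  }
  stop("unsupported input type")
}

# Batched eval-mode scoring on 1-based indices.
efcn_score <- function(net, X1, batch = 2048L) {
  n <- nrow(X1)
  out <- numeric(n)
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    out[idx] <- efcn_forward(net, X1[idx, , drop = FALSE], "eval")$p
  }
  out
}

#' Predict positive-class probabilities from a trained EFCN
#'
#' @param object a trained `efcn`.
#' @param newdata an `index_matrix`, a 0-based integer index matrix, or a
#'   registry data frame (encoded internally against the model's schema).
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.efcn <- function(object, newdata, ...) {
  if (!object$trained) warning("scoring an untrained network")
  efcn_score(object, as_index_1(newdata, object))
}

#' Transfer decision-model embeddings into a fresh survival network
#'
#' Builds an untrained survival-input network and copies every shared
#' feature's embedding table verbatim from the trained decision model.
#' The CA feature's embedding — the only input the survival task adds —
#' stays randomly initialized, as do the convolution stack and head
#' unless `transfer_all` is set (which warm-starts those layers from the
#' decision model too).  The transfer manifest records the provenance of
#' every embedding table.
#'
#' @param decision_model a trained decision-input `efcn`.
#' @param seed initialization seed for the non-transferred weights.
#' @param transfer_all also copy convolution, batch-norm and head weights.
#' @return an untrained survival `efcn` with `transfer_manifest` attached.
#' @export
transfer_embeddings <- function(decision_model, seed = 1L,
                                transfer_all = FALSE) {
  stopifnot(inherits(decision_model, "efcn"))
  if (decision_model$input_set != "decision")
    stop("transfer source must be a decision-input model")
  net <- build_efcn(decision_model$schema, decision_model$arch,
                    "survival", seed = seed)
  shared <- decision_model$features
  if (!all(shared %in% net$features))
    stop("schema mismatch between decision and survival networks")
  for (f in shared)
    net$params[[paste0("emb.", f)]] <- decision_model$params[[paste0("emb.", f)]]
  if (transfer_all) {
    for (nm in names(net$params))
      if (!startsWith(nm, "emb.") && !is.null(decision_model$params[[nm]]))
        net$params[[nm]] <- decision_model$params[[nm]]
    net$bn_state <- decision_model$bn_state
  }
  net$transfer_manifest <- data.frame(
    feature = net$features,
    initialization = ifelse(net$features %in% shared,
                            "transferred", "randomly_initialized"),
    stringsAsFactors = FALSE)
  net
}

#' Train the sequential EFCN pair with embedding transfer
#'
#' The decision (CA) network is trained first; its embedding tables are
#' then transferred into the survival (CPC-class) network, which is
#' trained on the same splits.  Training the survival model never
#' mutates the stored decision model.
#'
#' @param registry registry data frame.
#' @param schema a [feature_schema()].
#' @param train_idx,val_idx integer row indices of the training and
#'   validation subsets (disjoint).
#' @param arch an [efcn_architecture()].
#' @param hyper hyperparameter overrides, see [train_efcn()].
#' @param seed base seed; decision and survival seeds are derived from it.
#' @param transfer disable to train the survival model from scratch.
#' @param transfer_all see [transfer_embeddings()].
#' @return object of class `efcn_bundle`: `decision_model`,
#'   `survival_model`, `transfer_manifest`, `seeds`.
#' @export
train_efcn_pair <- function(registry, schema, train_idx, val_idx,
                            arch = efcn_architecture(), hyper = list(),
                            seed = 1L, transfer = TRUE,
                            transfer_all = FALSE) {
  if (length(intersect(train_idx, val_idx)))
    stop("training and validation indices overlap")
  y_ca <- registry$ca_performed
  y_out <- registry[[schema$outcome_field]]
  x_dec <- index_encode(registry, schema, "decision")
  x_sur <- index_encode(registry, schema, "survival")
  sub <- function(x, idx) {
    x$matrix <- x$matrix[idx, , drop = FALSE]; x
  }
  seeds <- c(decision = seed + 11L, survival = seed + 23L)
  dec <- build_efcn(schema, arch, "decision", seed = seeds[["decision"]])
  dec <- train_efcn(dec, sub(x_dec, train_idx), y_ca[train_idx],
                    sub(x_dec, val_idx), y_ca[val_idx],
                    utils::modifyList(hyper, list(seed = seeds[["decision"]])))
  sur <- if (transfer)
    transfer_embeddings(dec, seed = seeds[["survival"]],
                        transfer_all = transfer_all)
  else build_efcn(schema, arch, "survival", seed = seeds[["survival"]])
  manifest <- sur$transfer_manifest
  sur <- train_efcn(sur, sub(x_sur, train_idx), y_out[train_idx],
                    sub(x_sur, val_idx), y_out[val_idx],
                    utils::modifyList(hyper, list(seed = seeds[["survival"]])))
  structure(list(decision_model = dec, survival_model = sur,
                 transfer_manifest = manifest, seeds = seeds),
            class = "efcn_bundle")
}

#' @export
print.efcn_bundle <- function(x, ...) {
  cat("<efcn_bundle>\n decision: ")
  print(x$decision_model)
  cat(" survival: ")
  print(x$survival_model)
  if (!is.null(x$transfer_manifest)) {
    fresh <- x$transfer_manifest$feature[
      x$transfer_manifest$initialization == "randomly_initialized"]
    cat(" transferred embeddings for all features except:",
        paste(fresh, collapse = ", "), "\n")
  }
  invisible(x)
}
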