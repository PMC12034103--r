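#' Configuration for the GIN graph classifier
#'
#' Three message-passing layers update node representations by the graph
#' isomorphism network rule h_v' = MLP((1 + eps) h_v + sum_{u in N(v)} m(h_u,
#' e_uv)), with eps fixed at 0 by default. The neighborhood N(v) is the
#' in-neighbors over the complete directed graph, i.e. every other node.
#' `edge_mode` controls the edge message m: `"project_add"` (default) adds a
#' learned linear projection of the 23-element edge feature to the neighbor
#' representation; `"ignore"` uses the neighbor representation alone (the
#' plain GIN update). Readout is per-layer global average pooling, layer
#' means summed, LeakyReLU, then a linear projection to `embed_dim` — the
#' 128-dimensional per-graph feature vector used downstream.
#'
#' @param num_layers number of message-passing layers (default 3).
#' @param hidden_dim width of the per-layer perceptrons (default 128).
#' @param embed_dim width of the graph embedding (default 128).
#' @param epsilon the GIN eps (default 0).
#' @param learnable_epsilon if `TRUE`, eps is trained; default fixed.
#' @param edge_mode `"project_add"` or `"ignore"`.
#' @param epochs,learning_rate,batch_size Adam training hyperparameters.
#' @param leaky_slope negative slope of the LeakyReLU activation.
#' @param seed integer seed controlling initialization and shuffling.
#' @return a list of class `gin_config`.
#' @export
gin_config <- function(num_layers = 3L, hidden_dim = 128L, embed_dim = 128L,
                       epsilon = 0, learnable_epsilon = FALSE,
                       edge_mode = c("project_add", "ignore"),
                       epochs = 200L, learning_rate = 1e-3, batch_size = 32L,
                       leaky_slope = 0.01, seed = 0L) {
  edge_mode <- match.arg(edge_mode)
  stopifnot(num_layers >= 1L, embed_dim >= 1L, hidden_dim >= 1L)
  structure(list(num_layers = as.integer(num_layers),
                 hidden_dim = as.integer(hidden_dim),
                 embed_dim = as.integer(embed_dim),
                 epsilon = epsilon, learnable_epsilon = learnable_epsilon,
                 edge_mode = edge_mode, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 leaky_slope = leaky_slope, seed = as.integer(seed)),
            class = "gin_config")
}

lrelu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)

#' One GIN message-passing layer
#'
#' Exposed primarily for verification: with an identity MLP, eps = 0 and
#' `edge_mode = "ignore"` this is plain sum-aggregation over the complete
#' directed graph and can be checked by hand.
#'
#' @param h_prev numeric matrix, one row per node.
#' @param graph a `loop_graph`, or an integer node count (complete graph
#'   with no edge features).
#' @param epsilon the GIN eps.
#' @param mlp a function applied row-wise to the aggregated matrix
#'   (default identity).
#' @param edge_mode `"ignore"` or `"project_add"`.
#' @param edge_proj d x 23 projection matrix (required for `"project_add"`).
#' @return updated node representation matrix.
#' @export
gin_layer <- function(h_prev, graph, epsilon = 0, mlp = identity,
                      edge_mode = c("ignore", "project_add"), edge_proj = NULL) {
  edge_mode <- match.arg(edge_mode)
  h_prev <- as.matrix(h_prev)
  n <- if (is.numeric(graph) && length(graph) == 1L) as.integer(graph)
       else nrow(graph$node_features)
  if (nrow(h_prev) != n)
    stop("h_prev has ", nrow(h_prev), " rows for a ", n, "-node graph")
  agg <- matrix(colSums(h_prev), n, ncol(h_prev), byrow = TRUE) - h_prev
  if (edge_mode == "project_add") {
    if (is.null(edge_proj)) stop("edge_proj required for project_add")
    Ein <- edge_feature_sums(graph)
    agg <- agg + Ein %*% t(edge_proj)
  }
  mlp((1 + epsilon) * h_prev + agg)
}

# N x 23 matrix: for each node v, the sum of edge features over in-edges u->v
edge_feature_sums <- function(graph) {
  n <- nrow(graph$node_features)
  Ein <- matrix(0, n, ncol(graph$edge_features))
  to <- graph$edges[, 2]
  for (v in seq_len(n)) {
    rows <- which(to == v)
    if (length(rows)) Ein[v, ] <- colSums(graph$edge_features[rows, , drop = FALSE])
  }
  Ein
}

#' Graph readout: per-layer mean pooling, summed, activated, projected
#'
#' @param per_layer_node_reps list of node-representation matrices (equal
#'   widths), one per message-passing layer.
#' @param proj optional projection matrix (width x embed_dim); identity if
#'   `NULL`.
#' @param bias optional bias vector for the projection.
#' @param leaky_slope LeakyReLU negative slope.
#' @return numeric vector: the graph feature.
#' @export
readout <- function(per_layer_node_reps, proj = NULL, bias = NULL,
                    leaky_slope = 0.01) {
  means <- lapply(per_layer_node_reps, function(H) colMeans(as.matrix(H)))
  r <- Reduce(`+`, means)
  a <- lrelu(r, leaky_slope)
  if (is.null(proj)) return(a)
  out <- as.numeric(a %*% proj)
  if (!is.null(bias)) out <- out + bias
  out
}

# ---- internal: parameters, forward, backward ----

gin_init_params <- function(config, node_dim, edge_dim, num_classes) {
  h <- config$hidden_dim; e <- config$embed_dim
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  p <- list()
  d_in <- node_dim
  for (k in seq_len(config$num_layers)) {
    p[[paste0("We", k)]] <- glorot(d_in, edge_dim) * 0.1
    p[[paste0("W", k)]] <- glorot(d_in, h)
    p[[paste0("b", k)]] <- rep(0, h)
    d_in <- h
  }
  p$Wr <- glorot(h, e); p$br <- rep(0, e)
  p$Wc <- glorot(e, num_classes); p$bc <- rep(0, num_classes)
  p$eps <- config$epsilon
  p
}

# forward pass for one pre-processed graph (list with H0, Ein);
# returns cache for backprop
gin_forward <- function(pre, params, config) {
  H <- pre$H0; n <- nrow(H)
  sl <- config$leaky_slope
  cache <- list(H = list(), Z = list(), P = list())
  for (k in seq_len(config$num_layers)) {
    agg <- matrix(colSums(H), n, ncol(H), byrow = TRUE) - H
    if (config$edge_mode == "project_add")
      agg <- agg + pre$Ein %*% t(params[[paste0("We", k)]])
    z <- (1 + params$eps) * H + agg
    a <- sweep(z %*% params[[paste0("W", k)]], 2, params[[paste0("b", k)]], `+`)
    Hk <- lrelu(a, sl)
    cache$Hprev[[k]] <- H; cache$Z[[k]] <- z; cache$P[[k]] <- a
    cache$H[[k]] <- Hk
    H <- Hk
  }
  r <- Reduce(`+`, lapply(cache$H, colMeans))
  ar <- lrelu(r, sl)
  emb <- as.numeric(ar %*% params$Wr) + params$br
  logits <- as.numeric(emb %*% params$Wc) + params$bc
  mx <- max(logits)
  p <- exp(logits - mx); p <- p / sum(p)
  cache$r <- r; cache$ar <- ar; cache$emb <- emb; cache$prob <- p
  cache
}

# accumulate gradients for one graph into grads (same shapes as params)
gin_backward <- function(pre, params, config, cache, y_onehot, grads) {
  sl <- config$leaky_slope
  n <- nrow(pre$H0)
  dlogits <- cache$prob - y_onehot
  grads$Wc <- grads$Wc + outer(cache$emb, dlogits)
  grads$bc <- grads$bc + dlogits
  demb <- as.numeric(params$Wc %*% dlogits)
  grads$Wr <- grads$Wr + outer(cache$ar, demb)
  grads$br <- grads$br + demb
  dar <- as.numeric(params$Wr %*% demb)
  dr <- dar * lrelu_grad(cache$r, sl)
  dH_next <- NULL
  for (k in rev(seq_len(config$num_layers))) {
    dH <- matrix(dr / n, n, length(dr), byrow = TRUE)
    if (!is.null(dH_next)) dH <- dH + dH_next
    dpre <- dH * lrelu_grad(cache$P[[k]], sl)
    grads[[paste0("W", k)]] <- grads[[paste0("W", k)]] +
      crossprod(cache$Z[[k]], dpre)
    grads[[paste0("b", k)]] <- grads[[paste0("b", k)]] + colSums(dpre)
    dz <- tcrossprod(dpre, params[[paste0("W", k)]])
    if (config$edge_mode == "project_add")
      grads[[paste0("We", k)]] <- grads[[paste0("We", k)]] +
        crossprod(dz, pre$Ein)
    if (config$learnable_epsilon)
      grads$eps <- grads$eps + sum(dz * cache$Hprev[[k]])
    dH_next <- params$eps * dz +
      matrix(colSums(dz), n, ncol(dz), byrow = TRUE)
  }
  grads
}

zero_like <- function(params) lapply(params, function(p) p * 0)

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, skip = character(0)) {
  for (nm in names(params)) {
    if (nm %in% skip) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# pre-process graphs once: node features + summed in-edge features
gin_preprocess <- function(graphs, config) {
  lapply(graphs, function(g) {
    list(H0 = g$node_features,
         Ein = if (config$edge_mode == "project_add") edge_feature_sums(g)
               else NULL)
  })
}

#' Train a GIN graph classifier on labelled loop graphs
#'
#' Trains with categorical cross-entropy over a softmax head using Adam,
#' evaluating validation accuracy each epoch and retaining the weights of
#' the best-validation-accuracy epoch. Fully deterministic given
#' `config$seed`.
#'
#' @param graphs list of labelled `loop_graph` objects (labels must not be
#'   `NA` for graphs referenced by the split).
#' @param split list with integer index vectors `train`, `val`, `test`.
#' @param config a [gin_config()].
#' @return an object of class `gin_model`: weights, config, label
#'   vocabulary, `best_val_accuracy`, per-epoch training `log`, and test
#'   accuracy (`test_accuracy`, `NA` if the test split is empty).
#' @export
gin_train <- function(graphs, split, config = gin_config()) {
  stopifnot(inherits(config, "gin_config"))
  if (!all(c("train", "val") %in% names(split)))
    stop("split must contain at least 'train' and 'val' index vectors")
  if (length(split$train) == 0L || length(split$val) == 0L)
    stop("empty train or validation split")
  labels <- vapply(graphs, function(g) as.character(g$label), character(1))
  if (anyNA(labels[unlist(split)])) stop("all split graphs must be labelled")
  vocab <- sort(unique(labels[split$train]))
  if (length(vocab) < 2L) stop("need at least 2 classes to train, got ", length(vocab))
  y <- match(labels, vocab)
  node_dim <- ncol(graphs[[1]]$node_features)
  edge_dim <- ncol(graphs[[1]]$edge_features)

  set.seed(config$seed)
  params <- gin_init_params(config, node_dim, edge_dim, length(vocab))
  state <- list(m = zero_like(params), v = zero_like(params))
  skip <- if (config$learnable_epsilon) character(0) else "eps"
  pre <- gin_preprocess(graphs, config)

  acc_of <- function(idx) {
    if (length(idx) == 0L) return(NA_real_)
    hit <- vapply(idx, function(i) {
      p <- gin_forward(pre[[i]], params, config)$prob
      which.max(p) == y[i]
    }, logical(1))
    mean(hit)
  }

  best <- list(acc = -Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(), loss = numeric(),
                    train_accuracy = numeric(), val_accuracy = numeric())
  t_adam <- 0L
  for (epoch in seq_len(config$epochs)) {
    idx <- sample(split$train)
    nb <- ceiling(length(idx) / config$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      bidx <- idx[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size,
                                                          length(idx))]
      grads <- zero_like(params)
      for (i in bidx) {
        cache <- gin_forward(pre[[i]], params, config)
        yv <- rep(0, length(vocab)); yv[y[i]] <- 1
        ep_loss <- ep_loss - log(max(cache$prob[y[i]], 1e-12))
        grads <- gin_backward(pre[[i]], params, config, cache, yv, grads)
      }
      grads <- lapply(grads, function(g) g / length(bidx))
      t_adam <- t_adam + 1L
      st <- adam_step(params, grads, state, config$learning_rate, t_adam,
                      skip = skip)
      params <- st$params; state <- st$state
    }
    tr_acc <- acc_of(split$train)
    val_acc <- acc_of(split$val)
    log <- rbind(log, data.frame(epoch = epoch,
                                 loss = ep_loss / length(idx),
                                 train_accuracy = tr_acc,
                                 val_accuracy = val_acc))
    if (val_acc > best$acc) best <- list(acc = val_acc, params = params,
                                         epoch = epoch)
  }
  params <- best$params
  model <- structure(list(weights = params, config = config,
                          label_vocabulary = vocab,
                          best_val_accuracy = best$acc,
                          best_epoch = best$epoch, log = log,
                          schema = list(node_dim = node_dim,
                                        edge_dim = edge_dim)),
                     class = "gin_model")
  model$test_accuracy <- if (length(split$test))
    gin_accuracy(model, graphs[split$test]) else NA_real_
  model
}

#' @export
print.gin_model <- function(x, ...) {
  cat("<gin_model> ", x$config$num_layers, " GIN layers, hidden ",
      x$config$hidden_dim, ", embedding ", x$config$embed_dim,
      ", edge_mode=", x$config$edge_mode, "\n",
      "  classes: ", paste(x$label_vocabulary, collapse = ", "), "\n",
      "  best validation accuracy ", sprintf("%.3f", x$best_val_accuracy),
      " (epoch ", x$best_epoch, ")",
      if (!is.na(x$test_accuracy))
        paste0(", test accuracy ", sprintf("%.3f", x$test_accuracy)) else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.gin_model <- function(object, ...) {
  print(object)
  cat("training log (last 5 epochs):\n")
  print(utils::tail(object$log, 5), row.names = FALSE)
  invisible(object)
}

check_schema <- function(model, graphs) {
  nd <- ncol(graphs[[1]]$node_features); ed <- ncol(graphs[[1]]$edge_features)
  if (nd != model$schema$node_dim || ed != model$schema$edge_dim)
    stop("graph feature dimensions (", nd, ", ", ed,
         ") do not match the training schema (", model$schema$node_dim, ", ",
         model$schema$edge_dim, ")")
}

#' Predict motif family labels and class probabilities
#'
#' @param object a `gin_model`.
#' @param graphs list of `loop_graph` objects encoded with the training
#'   schema.
#' @param ... unused.
#' @return a list with `labels` (character), `prob` (k x num_classes matrix,
#'   rows summing to 1).
#' @export
predict.gin_model <- function(object, graphs, ...) {
  check_schema(object, graphs)
  pre <- gin_preprocess(graphs, object$config)
  prob <- t(vapply(pre, function(g)
    gin_forward(g, object$weights, object$config)$prob,
    numeric(length(object$label_vocabulary))))
  colnames(prob) <- object$label_vocabulary
  rownames(prob) <- vapply(graphs, `[[`, character(1), "loop_id")
  list(labels = object$label_vocabulary[max.col(prob, ties.method = "first")],
       prob = prob)
}

#' Classification accuracy of a model on labelled graphs
#' @param model a `gin_model`.
#' @param graphs labelled `loop_graph` list.
#' @return accuracy in \[0, 1\].
#' @export
gin_accuracy <- function(model, graphs) {
  truth <- vapply(graphs, function(g) as.character(g$label), character(1))
  mean(predict(model, graphs)$labels == truth)
}

#' Graph embeddings from a trained GIN model
#'
#' The 128-dimensional (by default) graph feature vector taken immediately
#' before the softmax head; one row per input graph, in input order.
#'
#' @param model a `gin_model`.
#' @param graphs list of `loop_graph` objects.
#' @return numeric matrix k x embed_dim, rownames = loop ids.
#' @export
gin_embed <- function(model, graphs) {
  check_schema(model, graphs)
  pre <- gin_preprocess(graphs, model$config)
  emb <- t(vapply(pre, function(g)
    gin_forward(g, model$weights, model$config)$emb,
    numeric(model$config$embed_dim)))
  rownames(emb) <- vapply(graphs, `[[`, character(1), "loop_id")
  colnames(emb) <- paste0("f", seq_len(ncol(emb)) - 1L)
  emb
}

#' Write / read an embedding matrix as CSV
#'
#' Layout `loop_id, f0..f127`.
#'
#' @param emb matrix from [gin_embed()].
#' @param path CSV path.
#' @export
write_embeddings <- function(emb, path) {
  df <- data.frame(loop_id = rownames(emb), emb, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  emb <- as.matrix(df[, -1, drop = FALSE])
  rownames(emb) <- df$loop_id
  emb
}
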