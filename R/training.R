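## Training: f-nat regression with MSE under Adam, per-epoch model selection
## on validation loss, complex-disjoint cross-validation splits, and the
## user-facing grank_fit() entry point.

#' Training configuration
#'
#' Defaults reproduce the reference protocol: minibatches of 64 models,
#' learning rate 1e-4, Adam, mean-squared-error loss on f-nat, 50 epochs with
#' the lowest-validation-loss epoch retained.
#'
#' @param batch_size models per minibatch.
#' @param learning_rate Adam step size.
#' @param n_epochs training epochs.
#' @param seed seed controlling shuffling and dropout.
#' @param beta1,beta2,epsilon Adam moment decays and stabilizer (canonical
#'   defaults; weight decay is not used).
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 1e-4,
                         n_epochs = 50L, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  stopifnot(batch_size >= 1L, learning_rate > 0, n_epochs >= 1L)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 n_epochs = as.integer(n_epochs), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "train_config")
}

## recursive walks over parameter structures (numeric leaves) --------------

params_zero <- function(p) {
  if (is.list(p)) {
    out <- lapply(p, params_zero)
    attributes(out) <- attributes(p)
    out
  } else p * 0
}

params_add <- function(a, b) {
  if (is.list(a)) {
    keys <- if (is.null(names(a))) seq_along(a) else names(a)
    for (nm in keys) a[[nm]] <- params_add(a[[nm]], b[[nm]])
    a
  } else a + b
}

params_scale <- function(a, k) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- params_scale(a[[nm]], k)
    a
  } else a * k
}

adam_step <- function(p, g, m, v, t, cfg) {
  if (is.list(p)) {
    ## match children by name where available: gradient lists may order
    ## their elements differently from the parameter lists
    keys <- if (is.null(names(p))) seq_along(p) else names(p)
    for (nm in keys) {
      st <- adam_step(p[[nm]], g[[nm]], m[[nm]], v[[nm]], t, cfg)
      p[[nm]] <- st$p; m[[nm]] <- st$m; v[[nm]] <- st$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- cfg$beta1 * m + (1 - cfg$beta1) * g
  v <- cfg$beta2 * v + (1 - cfg$beta2) * g * g
  mhat <- m / (1 - cfg$beta1^t)
  vhat <- v / (1 - cfg$beta2^t)
  list(p = p - cfg$learning_rate * mhat / (sqrt(vhat) + cfg$epsilon),
       m = m, v = v)
}

#' Complex-disjoint cross-validation splits
#'
#' Holds out `n_test` complexes as a fixed test set, then partitions the
#' remaining complexes into `n_folds` validation groups; fold k trains on all
#' non-test complexes outside group k. All models of a complex always land in
#' the same split, so no decoy of a test complex is ever seen in training.
#'
#' @param complex_ids character vector of complex identifiers.
#' @param n_folds number of folds.
#' @param seed shuffling seed (same seed, same splits).
#' @param n_test complexes held out as the common test set (default ~10%).
#' @return list of `fold_split` lists (fold_id, train, validation, test).
#' @export
make_splits <- function(complex_ids, n_folds, seed,
                        n_test = max(1L, round(0.1 * length(complex_ids)))) {
  ids <- unique(complex_ids)
  if (length(ids) < n_folds + n_test)
    grank_stop("too few complexes for the requested folds and test size",
               "grank_config_error")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- sample(ids)
  test <- sort(ids[seq_len(n_test)])
  rest <- ids[-seq_len(n_test)]
  groups <- split(rest, rep_len(seq_len(n_folds), length(rest)))
  lapply(seq_len(n_folds), function(k) {
    structure(list(fold_id = k,
                   train = sort(unlist(groups[-k], use.names = FALSE)),
                   validation = sort(groups[[k]]),
                   test = test),
              class = "fold_split")
  })
}

batch_mse_grad <- function(batch, y, state) {
  fw <- grank_forward(batch, state, training = TRUE, keep_cache = TRUE)
  resid <- fw$scores - y
  loss <- mean(resid^2)
  grads <- grank_backward(2 * resid / length(y), state, fw$cache)
  list(loss = loss, grads = grads)
}

eval_mse <- function(graphs, y, state, chunk = 256L) {
  tot <- 0
  for (i in seq(1L, length(graphs), by = chunk)) {
    j <- min(i + chunk - 1L, length(graphs))
    sc <- grank_forward(build_batch(graphs[i:j]), state)$scores
    tot <- tot + sum((sc - y[i:j])^2)
  }
  tot / length(graphs)
}

#' Train one fold
#'
#' Minimizes the mean squared error between predicted scores and f-nat labels
#' with Adam; examples are reshuffled every epoch with a fold-and-epoch
#' derived seed; validation loss is computed in eval mode after each epoch and
#' the parameters of the lowest-validation-loss epoch are returned.
#'
#' @param train_graphs,val_graphs lists of `interface_graph` objects.
#' @param train_y,val_y f-nat labels aligned with the graphs.
#' @param model_cfg a `grank_config`; `train_cfg` a [train_config()].
#' @param fold_id integer tag entering the shuffle seed.
#' @param verbose print per-epoch losses.
#' @return list(state, history) where `history` is a data frame of per-epoch
#'   train/validation loss with attribute `selected_epoch`.
#' @export
train_fold <- function(train_graphs, train_y, val_graphs, val_y,
                       model_cfg, train_cfg = train_config(),
                       fold_id = 1L, verbose = FALSE) {
  stopifnot(length(train_graphs) == length(train_y),
            length(val_graphs) == length(val_y),
            length(train_graphs) > 0L, length(val_graphs) > 0L)
  model_cfg$seed <- derive_seed(train_cfg$seed, fold_id)
  state <- grank_init(model_cfg)
  m <- params_zero(state$params); v <- params_zero(state$params)
  t_step <- 0L
  nb <- length(train_y)
  hist_tr <- numeric(train_cfg$n_epochs)
  hist_va <- numeric(train_cfg$n_epochs)
  best <- list(loss = Inf, params = NULL, epoch = NA_integer_)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (epoch in seq_len(train_cfg$n_epochs)) {
    set.seed(derive_seed(train_cfg$seed, fold_id * 1000L + epoch))
    ord <- sample.int(nb)
    ep_loss <- 0
    for (i in seq(1L, nb, by = train_cfg$batch_size)) {
      j <- min(i + train_cfg$batch_size - 1L, nb)
      sel <- ord[i:j]
      bg <- batch_mse_grad(build_batch(train_graphs[sel]), train_y[sel], state)
      if (!is.finite(bg$loss))
        grank_stop(sprintf(
          "non-finite training loss at epoch %d (batch starting %d)",
          epoch, i), "grank_training_error")
      t_step <- t_step + 1L
      st <- adam_step(state$params, bg$grads, m, v, t_step, train_cfg)
      state$params <- st$p; m <- st$m; v <- st$v
      ep_loss <- ep_loss + bg$loss * length(sel)
    }
    hist_tr[epoch] <- ep_loss / nb
    hist_va[epoch] <- eval_mse(val_graphs, val_y, state)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f",
                      epoch, hist_tr[epoch], hist_va[epoch]))
    if (hist_va[epoch] < best$loss)
      best <- list(loss = hist_va[epoch], params = state$params,
                   epoch = epoch)
  }
  state$params <- best$params
  history <- data.frame(epoch = seq_len(train_cfg$n_epochs),
                        train_loss = hist_tr, val_loss = hist_va)
  attr(history, "selected_epoch") <- best$epoch
  list(state = state, history = history)
}

#' Epoch selected by the lowest validation loss
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @return 1-based index of the minimum (first on ties).
#' @export
select_epoch <- function(val_losses) which.min(val_losses)

## ---------------------------------------------------------------------------

#' Fit the docking-model scoring network
#'
#' The main fitting entry point: takes a featurized dataset (graphs plus
#' f-nat labels), builds complex-disjoint folds, trains one network per fold
#' and returns the fold ensemble, whose prediction for a graph is the mean of
#' the member models' scores.
#'
#' @param graphs list of `interface_graph` objects.
#' @param labels data frame with at least `complex_id`, `model_id`, `fnat`
#'   (as produced by [label_models()] or [make_dataset()]), aligned with
#'   `graphs` by (complex_id, model_id).
#' @param n_folds number of cross-validation folds (1 trains a single model
#'   on a simple train/validation split).
#' @param model_config a [grank_config()].
#' @param train_cfg a [train_config()].
#' @param splits optional precomputed list from [make_splits()]; when NULL,
#'   splits are generated from `train_cfg$seed`.
#' @param verbose print per-epoch losses.
#' @return an object of class `grank_fit` with elements `states` (one
#'   `grank_state` per fold), `histories`, `splits`, `labels` and the configs.
#' @seealso [predict.grank_fit()], [plot.grank_fit()]
#' @export
grank_fit <- function(graphs, labels, n_folds = 10L,
                      model_config = grank_config(),
                      train_cfg = train_config(), splits = NULL,
                      verbose = FALSE) {
  stopifnot(length(graphs) == nrow(labels))
  cid <- labels$complex_id
  if (is.null(splits))
    splits <- make_splits(unique(cid), n_folds, seed = train_cfg$seed)
  states <- vector("list", length(splits))
  histories <- vector("list", length(splits))
  for (k in seq_along(splits)) {
    sp <- splits[[k]]
    tr <- which(cid %in% sp$train)
    va <- which(cid %in% sp$validation)
    res <- train_fold(graphs[tr], labels$fnat[tr], graphs[va],
                      labels$fnat[va], model_config, train_cfg,
                      fold_id = sp$fold_id, verbose = verbose)
    states[[k]] <- res$state
    histories[[k]] <- res$history
  }
  structure(list(states = states, histories = histories, splits = splits,
                 labels = labels, model_config = model_config,
                 train_config = train_cfg),
            class = "grank_fit")
}

#' @export
print.grank_fit <- function(x, ...) {
  sel <- vapply(x$histories, function(h) attr(h, "selected_epoch"), integer(1L))
  vl <- vapply(x$histories, function(h) min(h$val_loss), numeric(1L))
  cat(sprintf(
    "grank fit: %d fold model(s), %d GVPConv block(s), node dims (%d, %d)\n",
    length(x$states), x$model_config$n_blocks,
    x$model_config$node_dims[1L], x$model_config$node_dims[2L]))
  cat(sprintf("  selected epochs: %s\n", paste(sel, collapse = ", ")))
  cat(sprintf("  best validation MSE per fold: %s\n",
              paste(sprintf("%.4f", vl), collapse = ", ")))
  invisible(x)
}

#' @export
summary.grank_fit <- function(object, ...) {
  h <- do.call(rbind, Map(function(hh, k) {
    data.frame(fold = k, epoch = hh$epoch, train_loss = hh$train_loss,
               val_loss = hh$val_loss)
  }, object$histories, seq_along(object$histories)))
  sel <- vapply(object$histories, function(hh) attr(hh, "selected_epoch"),
                integer(1L))
  out <- list(history = h, selected_epochs = sel,
              test_complexes = object$splits[[1L]]$test,
              n_folds = length(object$states))
  class(out) <- "summary.grank_fit"
  out
}

#' @export
print.summary.grank_fit <- function(x, ...) {
  cat(sprintf("grank fit over %d fold(s); test complexes: %s\n",
              x$n_folds, paste(x$test_complexes, collapse = ", ")))
  last <- x$history[x$history$epoch == max(x$history$epoch), ]
  cat("final-epoch losses:\n")
  print(last, row.names = FALSE)
  invisible(x)
}

#' Ensemble predictions from a fitted model
#'
#' @param object a `grank_fit`.
#' @param graphs list of `interface_graph` objects (or a single graph).
#' @param ... unused.
#' @return data frame with complex_id, model_id and the ensemble `score`.
#' @export
predict.grank_fit <- function(object, graphs, ...) {
  if (inherits(graphs, "interface_graph")) graphs <- list(graphs)
  batch <- build_batch(graphs)
  data.frame(complex_id = batch$complex_id, model_id = batch$model_id,
             score = ensemble_predict(object$states, batch),
             stringsAsFactors = FALSE)
}

#' Training curves of a fitted model
#'
#' Plots per-epoch training and validation loss for every fold; the selected
#' epoch of each fold is marked.
#'
#' @param x a `grank_fit`; `...` passed to [graphics::matplot()].
#' @export
plot.grank_fit <- function(x, ...) {
  tr <- sapply(x$histories, `[[`, "train_loss")
  va <- sapply(x$histories, `[[`, "val_loss")
  ep <- x$histories[[1L]]$epoch
  graphics::matplot(ep, cbind(tr, va), type = "l",
                    lty = c(rep(1L, ncol(tr)), rep(2L, ncol(va))),
                    col = rep(seq_len(ncol(tr)), 2L),
                    xlab = "epoch", ylab = "MSE loss", ...)
  sel <- vapply(x$histories, function(h) attr(h, "selected_epoch"), integer(1L))
  graphics::points(sel, mapply(function(h, s) h$val_loss[s], x$histories, sel),
                   pch = 19L)
  graphics::legend("topright", legend = c("train", "validation"),
                   lty = c(1L, 2L), bty = "n")
  invisible(x)
}
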