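#' Training configuration
#'
#' The published regimen: Adam at learning rate 0.009, batch size 64,
#' cross-entropy loss, 1000 epochs.  Desk-scale work uses far fewer epochs;
#' the defaults here only fix the optimiser family and step sizes.
#'
#' @param n_epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param beta1,beta2,eps Adam moment decay rates and denominator floor.
#' @param seed Seed threaded through initialisation, shuffling and dropout.
#' @return An object of class `mi_train_config`.
#' @export
train_config <- function(n_epochs = 1000L, batch_size = 64L,
                         learning_rate = 0.009, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, seed = 1L) {
  stopifnot(learning_rate >= 0, batch_size >= 1L, n_epochs >= 1L)
  structure(list(n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = as.integer(seed)),
            class = "mi_train_config")
}

## ---- tree utilities over nested parameter lists ----
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(b)) out[[nm]] <- tree_map2(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}

tree_zero_like <- function(g) {
  if (is.list(g)) lapply(g, tree_zero_like) else g * 0
}

# one Adam step over every leaf present in the gradient tree; returns
# list(params, m, v)
adam_step <- function(params, grads, m, v, lr, b1, b2, eps, t) {
  step <- function(p_node, g_node, m_node, v_node) {
    if (is.list(g_node)) {
      for (nm in names(g_node)) {
        r <- step(p_node[[nm]], g_node[[nm]], m_node[[nm]], v_node[[nm]])
        p_node[[nm]] <- r$p; m_node[[nm]] <- r$m; v_node[[nm]] <- r$v
      }
      list(p = p_node, m = m_node, v = v_node)
    } else {
      m_node <- b1 * m_node + (1 - b1) * g_node
      v_node <- b2 * v_node + (1 - b2) * g_node^2
      mhat <- m_node / (1 - b1^t)
      vhat <- v_node / (1 - b2^t)
      list(p = p_node - lr * mhat / (sqrt(vhat) + eps),
           m = m_node, v = v_node)
    }
  }
  step(params, grads, m, v)
}

#' Train the classifier
#'
#' Minimises cross-entropy of the forward pass with Adam, seeded shuffling
#' each epoch, and records the per-epoch mean training loss.  All batch-norm
#' running statistics, dropout draws and the shuffle order derive from
#' `tcfg$seed`, so identical calls give identical loss histories.
#'
#' @param epochs_train An [epoch_set()]; labels must lie in
#'   `0 .. n_classes - 1`.
#' @param cfg A [model_config()].
#' @param flags A [variant_flags()].
#' @param tcfg A [train_config()].
#' @param verbose Print the loss every few epochs.
#' @return An object of class `mi_model`: parameters, configuration and a
#'   `history` tibble with columns `epoch` and `loss`.
#' @export
train_model <- function(epochs_train, cfg, flags = variant_flags(),
                        tcfg = train_config(), verbose = FALSE) {
  check_epochs_config(epochs_train, cfg)
  x <- epochs_train$data
  y <- epochs_train$labels
  n <- dim(x)[1]
  params <- init_params(cfg, flags, tcfg$seed)   # also seeds the RNG stream
  m <- NULL; v <- NULL; t_step <- 0L
  history <- numeric(tcfg$n_epochs)
  for (ep in seq_len(tcfg$n_epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    sizes <- integer(0)
    for (start in seq.int(1L, n, by = tcfg$batch_size)) {
      take <- ord[start:min(start + tcfg$batch_size - 1L, n)]
      fw <- forward_cached(x[take, , , drop = FALSE], cfg, flags, params,
                           training = TRUE)
      params <- fw$params
      sx <- softmax_xent(fw$logits, y[take])
      if (!is.finite(sx$loss)) {
        stop("non-finite training loss at epoch ", ep, call. = FALSE)
      }
      grads <- backward_full(sx$dlogits, fw$cache, cfg, flags, params)
      if (is.null(m)) { m <- tree_zero_like(grads); v <- tree_zero_like(grads) }
      t_step <- t_step + 1L
      r <- adam_step(params, grads, m, v, tcfg$learning_rate,
                     tcfg$beta1, tcfg$beta2, tcfg$eps, t_step)
      params <- r$p; m <- r$m; v <- r$v
      losses <- c(losses, sx$loss)
      sizes <- c(sizes, length(take))
    }
    history[ep] <- sum(losses * sizes) / sum(sizes)
    if (verbose && (ep %% 10L == 0L || ep == 1L)) {
      message(sprintf("epoch %4d  loss %.4f", ep, history[ep]))
    }
  }
  structure(list(params = params, cfg = cfg, flags = flags,
                 train_config = tcfg,
                 history = tibble::tibble(epoch = seq_len(tcfg$n_epochs),
                                          loss = history)),
            class = "mi_model")
}

#' @export
print.mi_model <- function(x, ...) {
  cat("<mi_model> ", x$cfg$n_classes, "-class classifier; ",
      nrow(x$history), " epochs trained, final loss ",
      signif(utils::tail(x$history$loss, 1), 4), "\n", sep = "")
  print(x$flags)
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object An `mi_model`.
#' @param epochs An [epoch_set()].
#' @param type `"prob"` for the class-probability matrix, `"class"` for
#'   0-based hard labels (argmax, ties broken toward the lowest index).
#' @param ... Unused.
#' @return Matrix of probabilities or an integer vector.
#' @export
predict.mi_model <- function(object, epochs, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  probs <- model_forward(epochs, object$cfg, object$flags, object$params,
                         training = FALSE)
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' @importFrom generics tidy
#' @export
tidy.mi_model <- function(x, ...) x$history

#' @importFrom generics glance
#' @export
glance.mi_model <- function(x, ...) {
  count_leaves <- function(p) {
    if (is.list(p)) sum(vapply(p, count_leaves, numeric(1))) else length(p)
  }
  tibble::tibble(
    n_epochs = nrow(x$history),
    final_loss = utils::tail(x$history$loss, 1),
    n_parameters = count_leaves(x$params),
    learning_rate = x$train_config$learning_rate,
    batch_size = x$train_config$batch_size
  )
}

#' Extract per-trial feature vectors
#'
#' Returns the flattened token sequence at the requested site of the
#' network, for embedding or visualisation tools (t-SNE, UMAP, ...).  In
#' inference mode the extraction is deterministic.  With
#' `global_attention = FALSE` the same pre-classifier site is used, so the
#' dimensionality is unchanged.
#'
#' @param model A fitted `mi_model`.
#' @param epochs An [epoch_set()].
#' @param site Currently `"post_global_attention"` (the sequence entering
#'   the classifier head).
#' @return Matrix `n_trials x (L_total * F2)`.
#' @export
extract_features <- function(model, epochs,
                             site = "post_global_attention") {
  sites <- "post_global_attention"
  if (!site %in% sites) {
    stop("unknown site '", site, "'; available sites: ",
         paste(sites, collapse = ", "), call. = FALSE)
  }
  check_epochs_config(epochs, model$cfg)
  fw <- forward_cached(epochs$data, model$cfg, model$flags, model$params,
                       training = FALSE)
  fw$features
}
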