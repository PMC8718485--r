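#' Configuration for the four-hidden-layer classifier
#'
#' The architecture is fixed at four hidden layers; widths, activation
#' and optimization are configurable. Training minimizes the
#' survey-weighted binary cross-entropy by minibatch gradient descent
#' with momentum, with early stopping on the weighted AUC of a
#' held-out fifth of the training rows. Plain (non-adaptive) descent is
#' deliberate: update sizes stay proportional to gradient magnitudes,
#' so first-layer weights of uninformative inputs barely move and the
#' first-layer importance ranking stays interpretable (an adaptive
#' optimizer would let noise inputs random-walk as fast as signal
#' inputs grow). For the same reason the first layer is initialized
#' near zero (`first_layer_init_sd`), so its trained weight mass is
#' learned structure rather than initialization noise; deeper layers
#' use He initialization.
#'
#' @param hidden_sizes exactly four positive layer widths
#'   (default `c(64, 32, 16, 8)`).
#' @param activation `"relu"` or `"tanh"`.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate gradient-descent step size (per batch, on the
#'   weight-normalized loss).
#' @param momentum classical momentum coefficient.
#' @param weight_decay decoupled L2 decay applied to the weight
#'   matrices each step (biases are not decayed); 0 disables.
#' @param first_layer_init_sd Gaussian SD of the first-layer
#'   initialization.
#' @param early_stop_patience epochs without validation-AUC improvement
#'   before stopping.
#' @param val_fraction share of training rows held out for early
#'   stopping.
#' @param importance aggregation of first-layer weights into per-input
#'   importance: `"sum_abs"` (sum of absolute weights, the default) or
#'   `"l2"` (Euclidean norm, for sensitivity analysis).
#' @param seed integer seed (initialization, shuffling, validation
#'   split).
#' @return an `nn_config` list.
#' @export
nn_config <- function(hidden_sizes = c(64, 32, 16, 8),
                      activation = c("relu", "tanh"),
                      epochs = 30, batch_size = 256,
                      learning_rate = 0.1, momentum = 0.9,
                      weight_decay = 0, first_layer_init_sd = 0.05,
                      early_stop_patience = 5,
                      val_fraction = 0.2,
                      importance = c("sum_abs", "l2"),
                      seed = 1L) {
  stopifnot(length(hidden_sizes) == 4, all(hidden_sizes >= 1))
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 activation = match.arg(activation),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 momentum = momentum,
                 weight_decay = weight_decay,
                 first_layer_init_sd = first_layer_init_sd,
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction,
                 importance = match.arg(importance),
                 seed = as.integer(seed)),
            class = "nn_config")
}

nn_act <- function(z, kind) if (kind == "relu") pmax(z, 0) else tanh(z)
nn_act_grad <- function(z, kind)
  if (kind == "relu") (z > 0) * 1 else 1 - tanh(z)^2

nn_forward <- function(W, b, X, kind) {
  a <- list(X); z <- list()
  L <- length(W)
  for (l in seq_len(L)) {
    z[[l]] <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], `+`)
    a[[l + 1]] <- if (l < L) nn_act(z[[l]], kind) else plogis(z[[l]])
  }
  list(a = a, z = z)
}

#' Train the four-hidden-layer classifier
#'
#' @param X numeric design matrix (typically restricted to the lasso
#'   support).
#' @param y binary outcome (0/1).
#' @param w positive survey weights; `NULL` for unit weights.
#' @param config an [nn_config()].
#' @return an `nn_model`: weight matrices `W` (the first of which is
#'   inputs x first-hidden-units), biases `b`, the config, and a
#'   training history.
#' @export
fit_nn <- function(X, y, w = NULL, config = nn_config()) {
  stopifnot(inherits(config, "nn_config"))
  X <- as.matrix(X)
  if (is.null(w)) w <- rep(1, length(y))
  stopifnot(nrow(X) == length(y), length(w) == length(y))
  with_seed(config$seed, fit_nn_impl(X, y, w, config))
}

fit_nn_impl <- function(X, y, w, config) {
  n <- nrow(X); p <- ncol(X)
  sizes <- c(p, config$hidden_sizes, 1L)
  L <- length(sizes) - 1L
  kind <- config$activation

  # held-out fifth for early stopping (stratified)
  val <- integer(0)
  for (cls in unique(y)) {
    rows <- sample(which(y == cls))
    val <- c(val, rows[seq_len(max(1, round(config$val_fraction *
                                              length(rows))))])
  }
  tr <- setdiff(seq_len(n), val)

  W <- list(); b <- list(); uW <- list(); uB <- list()
  for (l in seq_len(L)) {
    sd_init <- if (l == 1) config$first_layer_init_sd else
      sqrt(2 / sizes[l])
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0, sd_init),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
    uW[[l]] <- matrix(0, sizes[l], sizes[l + 1])
    uB[[l]] <- rep(0, sizes[l + 1])
  }

  lr <- config$learning_rate; mom <- config$momentum
  best <- list(auc = -Inf, W = W, b = b, epoch = 0L)
  bad_epochs <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auc = numeric(0))

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_w <- 0
    for (bt in batches) {
      Xb <- X[bt, , drop = FALSE]; yb <- y[bt]; wb <- w[bt]
      fwd <- nn_forward(W, b, Xb, kind)
      pb <- as.numeric(fwd$a[[L + 1]])
      pb <- pmin(pmax(pb, 1e-12), 1 - 1e-12)
      loss <- -sum(wb * (yb * log(pb) + (1 - yb) * log(1 - pb)))
      if (!is.finite(loss) ||
          !all(vapply(W, function(m) all(is.finite(m)), logical(1))))
        stop("divergent loss at epoch ", epoch)
      ep_loss <- ep_loss + loss; ep_w <- ep_w + sum(wb)
      # backprop; delta at output for sigmoid + weighted BCE
      delta <- matrix(wb * (pb - yb) / sum(wb), ncol = 1)
      gW <- vector("list", L); gB <- vector("list", L)
      for (l in rev(seq_len(L))) {
        gW[[l]] <- crossprod(fwd$a[[l]], delta)
        gB[[l]] <- colSums(delta)
        if (l > 1)
          delta <- (delta %*% t(W[[l]])) * nn_act_grad(fwd$z[[l - 1]], kind)
      }
      for (l in seq_len(L)) {
        uW[[l]] <- mom * uW[[l]] + gW[[l]]
        uB[[l]] <- mom * uB[[l]] + gB[[l]]
        W[[l]] <- W[[l]] - lr * uW[[l]]
        b[[l]] <- b[[l]] - lr * uB[[l]]
        if (config$weight_decay > 0)
          W[[l]] <- W[[l]] * (1 - lr * config$weight_decay)
      }
    }
    val_p <- as.numeric(nn_forward(W, b, X[val, , drop = FALSE],
                                   kind)$a[[L + 1]])
    val_auc <- if (length(unique(y[val])) > 1)
      weighted_auc(val_p, y[val], w[val]) else NA_real_
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / ep_w, val_auc = val_auc))
    if (is.finite(val_auc) && val_auc > best$auc) {
      best <- list(auc = val_auc, W = W, b = b, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$early_stop_patience) break
    }
  }
  structure(list(W = best$W, b = best$b, config = config,
                 feature_names = colnames(X),
                 best_epoch = best$epoch, val_auc = best$auc,
                 history = history),
            class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat("<nn_model> ", nrow(x$W[[1]]), " inputs -> ",
      paste(x$config$hidden_sizes, collapse = "-"),
      " -> 1; best epoch ", x$best_epoch,
      " (val AUC ", signif(x$val_auc, 4), ")\n", sep = "")
  invisible(x)
}

#' Predicted probabilities from the classifier
#' @param object an `nn_model`.
#' @param newx design matrix with the training columns.
#' @param ... unused.
#' @return numeric probabilities.
#' @export
predict.nn_model <- function(object, newx, ...) {
  as.numeric(nn_forward(object$W, object$b, as.matrix(newx),
                        object$config$activation)$a[[length(object$W) + 1]])
}

#' First-hidden-layer variable importance
#'
#' Importance of input j aggregates the absolute weights connecting it
#' to the first hidden layer: `sum_u |W1[j, u]|` (derivation
#' `"sum-abs-first-layer"`), or the Euclidean norm when the config
#' selects `"l2"`.
#'
#' @param model an `nn_model`.
#' @return named nonnegative vector with attribute `derivation`.
#' @export
first_layer_importance <- function(model) {
  stopifnot(inherits(model, "nn_model"))
  W1 <- model$W[[1]]
  imp <- switch(model$config$importance,
                sum_abs = rowSums(abs(W1)),
                l2 = sqrt(rowSums(W1^2)))
  names(imp) <- model$feature_names
  attr(imp, "derivation") <- switch(model$config$importance,
                                    sum_abs = "sum-abs-first-layer",
                                    l2 = "l2-first-layer")
  imp
}

#' Lasso-prefiltered neural-network selection pipeline
#'
#' The second analysis strategy: cross-validated lasso on the training
#' split drops zero-coefficient features; the survivors feed the
#' four-hidden-layer classifier; inputs are ranked by first-layer
#' importance; the knee of the importance curve yields the selected
#' set (always a rank prefix).
#'
#' @param enc an `encoded_matrix`.
#' @param control an [ita_control()] (split, penalty grid, folds).
#' @param config an [nn_config()].
#' @return an `nn_report`: selected features/variables, knee rank,
#'   importance curve, survey-weighted test metrics, lasso support.
#' @export
nn_pipeline <- function(enc, control = ita_control(),
                        config = nn_config()) {
  stopifnot(inherits(enc, "encoded_matrix"))
  split <- make_split(enc$y, control$train_fraction, TRUE,
                      derive_seed(control$seed, 0))
  tr <- split$train; te <- split$test
  Xtr <- enc$X[tr, , drop = FALSE]
  ytr <- enc$y[tr]; wtr <- enc$w[tr]
  grid <- default_lambda_grid(Xtr, ytr, wtr, control$nlambda,
                              control$lambda_min_ratio)
  cv <- select_lambda_cv(Xtr, ytr, wtr, grid, control$k_folds,
                         derive_seed(control$seed, 1, 1), "l1")
  lasso <- fit_penalized_logistic(Xtr, ytr, wtr, cv$best_lambda, "l1")
  support <- lasso_support(lasso, control$support_tol)
  if (!length(support))
    return(structure(list(status = "complete",
                          selected_features = character(0),
                          selected_vars = character(0),
                          support = character(0), knee_rank = NA,
                          metrics = NULL, lambda_lasso = cv$best_lambda),
                     class = "nn_report"))
  sidx <- match(support, enc$feature_names)
  model <- fit_nn(as.matrix(enc$X[tr, sidx, drop = FALSE]), ytr, wtr,
                  config)
  imp <- first_layer_importance(model)
  curve <- coefficient_curve(imp, names(imp), source = "nn_importance")
  knee <- find_knee(curve)
  sel_feat <- select_above_knee(curve, knee)
  sel_vars <- unique(enc$provenance$variable[
    match(sel_feat, enc$provenance$feature)])
  p_tr <- predict(model, enc$X[tr, sidx, drop = FALSE])
  p_te <- predict(model, enc$X[te, sidx, drop = FALSE])
  thr <- choose_threshold(p_tr, ytr, wtr)
  structure(list(status = "complete",
                 selected_features = sel_feat,
                 selected_vars = sel_vars,
                 support = support,
                 knee_rank = knee$knee_rank,
                 importance = as.data.frame(curve),
                 metrics = evaluate_scores(p_te, enc$y[te], enc$w[te], thr),
                 lambda_lasso = cv$best_lambda,
                 best_epoch = model$best_epoch),
            class = "nn_report")
}

#' @export
print.nn_report <- function(x, ...) {
  cat("<nn_report> ", length(x$support), " lasso-retained inputs; knee ",
      as.character(x$knee_rank), "; ", length(x$selected_features),
      " features selected", sep = "")
  if (!is.null(x$metrics))
    cat(sprintf("; AUC %.3f, BER %.3f", x$metrics$auc, x$metrics$ber))
  cat("\n")
  invisible(x)
}
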