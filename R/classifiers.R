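#' Classifier specification
#'
#' Describes the architecture trained on normalized expression profiles:
#' either a linear (softmax-regression) classifier or a multilayer
#' perceptron with ReLU hidden layers. The output dimension must equal the
#' ontology size so that logits align with the reachability matrix.
#'
#' @param architecture `"linear"` or `"mlp"`.
#' @param input_dim number of genes.
#' @param output_dim number of ontology classes C.
#' @param hidden_dims integer vector of hidden-layer widths; must be empty
#'   for `"linear"`. Default for `"mlp"` is a single hidden layer of 128.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(architecture = c("linear", "mlp"), input_dim,
                            output_dim, hidden_dims = NULL) {
  architecture <- match.arg(architecture)
  if (architecture == "linear") {
    if (!is.null(hidden_dims) && length(hidden_dims) > 0L) {
      stop("linear classifier takes no hidden layers")
    }
    hidden_dims <- integer(0)
  } else {
    if (is.null(hidden_dims)) hidden_dims <- 128L
    hidden_dims <- as.integer(hidden_dims)
    if (length(hidden_dims) == 0L || any(hidden_dims < 1L)) {
      stop("mlp requires at least one positive hidden width")
    }
  }
  structure(list(architecture = architecture,
                 input_dim = as.integer(input_dim),
                 hidden_dims = hidden_dims,
                 output_dim = as.integer(output_dim)),
            class = "classifier_spec")
}

#' Training configuration
#'
#' @param loss_kind `"ce"` (flat weighted cross-entropy) or `"hce"`
#'   (hierarchical cross-entropy).
#' @param epochs number of passes over the training set.
#' @param batch_size mini-batch size.
#' @param learning_rate SGD step size.
#' @param momentum classical momentum coefficient (0 disables).
#' @param seed integer governing weight initialisation and batch shuffling.
#' @param weighted use inverse-frequency class weights (default TRUE).
#' @param epsilon stabiliser inside the log of both losses.
#' @param patience early-stopping patience on validation macro F1; `Inf`
#'   disables early stopping (default).
#' @return object of class `train_config`.
#' @export
train_config <- function(loss_kind = c("ce", "hce"), epochs = 40L,
                         batch_size = 64L, learning_rate = 0.01,
                         momentum = 0.9, seed = 1L, weighted = TRUE,
                         epsilon = 1e-6, patience = Inf) {
  loss_kind <- match.arg(loss_kind)
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            momentum >= 0, momentum < 1, epsilon > 0)
  structure(list(loss_kind = loss_kind, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed), weighted = weighted,
                 epsilon = epsilon, patience = patience),
            class = "train_config")
}

.init_params <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden_dims, spec$output_dim)
  params <- vector("list", length(dims) - 1L)
  for (l in seq_along(params)) {
    fan_in <- dims[l]
    # He-style initialisation, suited to the ReLU hidden units
    params[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * dims[l + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, dims[l + 1L]),
      b = rep(0, dims[l + 1L])
    )
  }
  params
}

.forward <- function(params, X) {
  acts <- list(X)
  L <- length(params)
  H <- X
  for (l in seq_len(L)) {
    Z <- H %*% params[[l]]$W
    Z <- sweep(Z, 2L, params[[l]]$b, "+")
    if (l < L) {
      H <- pmax(Z, 0)
      acts[[l + 1L]] <- H
    } else {
      acts[[l + 1L]] <- Z
    }
  }
  acts
}

.backward <- function(params, acts, dZ) {
  L <- length(params)
  grads <- vector("list", L)
  delta <- dZ
  for (l in rev(seq_len(L))) {
    A <- acts[[l]]
    grads[[l]] <- list(W = crossprod(A, delta), b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(params[[l]]$W)) * (acts[[l]] > 0)
    }
  }
  grads
}

#' Train a classifier with CE or HCE loss
#'
#' Seeded mini-batch stochastic gradient descent (with momentum) minimising
#' either flat weighted cross-entropy or hierarchical cross-entropy over
#' the ontology's reachability matrix. Class weights are computed from the
#' training labels only. Training is deterministic given the seed, the
#' data and the configuration.
#'
#' @param spec a [classifier_spec()].
#' @param X numeric matrix (cells x genes) of normalized expression.
#' @param y integer vector of 1-based ontology class indices.
#' @param R reachability matrix (required for `loss_kind = "hce"`; ignored
#'   for `"ce"`).
#' @param config a [train_config()].
#' @param X_val,y_val optional validation split for macro-F1 history and
#'   early stopping.
#' @return object of class `hce_classifier`: parameters, spec, config and
#'   a per-epoch history data.frame (`epoch`, `train_loss`, `val_macro_f1`).
#' @export
train_classifier <- function(spec, X, y, R = NULL, config = train_config(),
                             X_val = NULL, y_val = NULL) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(config, "train_config"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (ncol(X) != spec$input_dim) stop("X has wrong gene dimension")
  if (any(y < 1L | y > spec$output_dim)) stop("labels outside [1, C]")
  if (config$loss_kind == "hce") {
    if (is.null(R)) stop("hce loss requires a reachability matrix")
    if (ncol(R) != spec$output_dim) stop("R does not match output_dim")
  }
  Ruse <- if (config$loss_kind == "hce") R else NULL
  cw <- compute_class_weights(y, spec$output_dim)
  if (length(cw$absent) > 0L) {
    warning("classes with no training samples: ",
            paste(cw$absent, collapse = ", "))
  }
  w <- if (config$weighted) cw$w else NULL

  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  params <- .init_params(spec)
  vel <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  n <- nrow(X)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_macro_f1 = numeric(0))
  best_f1 <- -Inf; best_params <- params; stall <- 0L

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    epoch_loss <- 0; nb <- 0L
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      acts <- .forward(params, Xb)
      Z <- acts[[length(acts)]]
      loss <- batch_loss(Z, yb, w = w, R = Ruse, epsilon = config$epsilon)
      if (!is.finite(loss)) stop("non-finite loss at epoch ", epoch,
                                 "; lower the learning rate")
      dZ <- batch_loss_grad(Z, yb, w = w, R = Ruse, epsilon = config$epsilon)
      grads <- .backward(params, acts, dZ)
      for (l in seq_along(params)) {
        vel[[l]]$W <- config$momentum * vel[[l]]$W -
          config$learning_rate * grads[[l]]$W
        vel[[l]]$b <- config$momentum * vel[[l]]$b -
          config$learning_rate * grads[[l]]$b
        params[[l]]$W <- params[[l]]$W + vel[[l]]$W
        params[[l]]$b <- params[[l]]$b + vel[[l]]$b
      }
      epoch_loss <- epoch_loss + loss; nb <- nb + 1L
    }
    val_f1 <- NA_real_
    if (!is.null(X_val)) {
      model_now <- structure(list(params = params, spec = spec),
                             class = "hce_classifier")
      pv <- predict_label(model_now, X_val)
      cs <- confusion_summary(pv, y_val, R = NULL, C = spec$output_dim)
      val_f1 <- macro_f1(cs, include = sort(unique(y_val)))
      if (val_f1 > best_f1 + 1e-12) {
        best_f1 <- val_f1; best_params <- params; stall <- 0L
      } else {
        stall <- stall + 1L
      }
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss / nb,
                                         val_macro_f1 = val_f1))
    if (!is.null(X_val) && stall >= config$patience) break
  }
  if (!is.null(X_val) && is.finite(config$patience)) params <- best_params

  structure(list(params = params, spec = spec, config = config,
                 class_weights = cw, history = history),
            class = "hce_classifier")
}

#' @export
print.hce_classifier <- function(x, ...) {
  cat(sprintf("hce_classifier (%s, %s loss): %d genes -> %d classes, %d epochs\n",
              x$spec$architecture, x$config$loss_kind, x$spec$input_dim,
              x$spec$output_dim, nrow(x$history)))
  invisible(x)
}

#' Predicted class probabilities
#'
#' @param model a fitted `hce_classifier`.
#' @param X expression matrix (cells x genes) matching the training
#'   dimension.
#' @param adjusted if TRUE, return hierarchy-adjusted scores `s = R p`
#'   instead of raw probabilities (requires `R`).
#' @param R reachability matrix, only used when `adjusted = TRUE`.
#' @return matrix (cells x classes); with `adjusted = FALSE` each row is a
#'   probability vector summing to 1.
#' @export
predict_proba <- function(model, X, adjusted = FALSE, R = NULL) {
  stopifnot(inherits(model, "hce_classifier"))
  X <- as.matrix(X)
  if (ncol(X) != model$spec$input_dim) stop("X has wrong gene dimension")
  acts <- .forward(model$params, X)
  P <- softmax(acts[[length(acts)]])
  if (adjusted) {
    if (is.null(R)) stop("adjusted scores require a reachability matrix")
    P <- P %*% t(R)
  }
  P
}

#' Predicted class labels
#'
#' Argmax of the (raw or hierarchy-adjusted) class scores; ties are broken
#' towards the lowest class index.
#'
#' @inheritParams predict_proba
#' @return integer vector of 1-based class indices, one per row of `X`.
#' @export
predict_label <- function(model, X, adjusted = FALSE, R = NULL) {
  P <- predict_proba(model, X, adjusted = adjusted, R = R)
  max.col(P, ties.method = "first")
}
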