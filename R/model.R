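# The purity regression network: a multilayer perceptron with two hidden
# linear layers (32 and 16 neurons, ReLU), dropout on the input layer only,
# no output activation. Trained with Adam on the L1 loss over batches of 64
# freshly simulated pseudobulks; the returned model is the snapshot with the
# lowest 25-batch sliding-window mean loss, and training stops once that
# sliding mean has not reached a new minimum for 200 consecutive batches.
# Outputs are clipped to [0, 1] at inference only.

#' Model configuration
#'
#' Architecture and optimisation hyperparameters of the purity network. The
#' defaults are the tuned operating point: hidden sizes 32 and 16, input
#' dropout 0.4, learning rate 3e-5, weight decay 1e-5, batch size 64, a
#' 25-batch sliding loss window and a 200-batch patience.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param input_dropout dropout probability on the input layer, training mode
#'   only (inverted dropout).
#' @param learning_rate,weight_decay Adam step size and L2 penalty (coupled,
#'   added to the gradient).
#' @param batch_size simulated tumors per batch.
#' @param window length of the sliding loss window, in batches.
#' @param patience batches without a new sliding-mean minimum before training
#'   stops; must be at least `window`.
#' @param max_batches hard cap on the number of batches (a compute guard;
#'   patience normally triggers first).
#' @export
model_config <- function(hidden_sizes = c(32, 16), input_dropout = 0.4,
                         learning_rate = 3e-5, weight_decay = 1e-5,
                         batch_size = 64, window = 25, patience = 200,
                         max_batches = 20000) {
  stopifnot(length(hidden_sizes) >= 1, all(hidden_sizes >= 1),
            input_dropout >= 0, input_dropout < 1,
            learning_rate > 0, weight_decay >= 0,
            batch_size >= 1, window >= 1, patience >= window,
            max_batches >= 1)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 activation = "relu",
                 input_dropout = input_dropout,
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 window = as.integer(window),
                 patience = as.integer(patience),
                 max_batches = as.integer(max_batches),
                 adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8),
            class = "model_config")
}

#' Mean absolute (L1) loss
#'
#' @param y,yhat numeric vectors of equal, positive length.
#' @return `(1/n) * sum(|y - yhat|)`.
#' @export
l1_loss <- function(y, yhat) {
  if (length(y) != length(yhat)) abort("l1_loss: length mismatch")
  if (!length(y)) abort("l1_loss: empty input")
  mean(abs(y - yhat))
}

#' Initialise an untrained purity model
#'
#' Layers are |features| -> hidden sizes -> 1, ReLU after each hidden layer,
#' no output activation. Weights and biases start from the fan-in uniform
#' scheme U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
#'
#' @param features a [feature_set()] or character vector of gene ids.
#' @param config a [model_config()].
#' @param seed optional integer; when given, initialisation is reproducible.
#' @return object of class `purity_model`.
#' @export
init_purity_model <- function(features, config = model_config(), seed = NULL) {
  ids <- feature_ids(features)
  if (!is.null(seed)) set.seed(seed)
  dims <- c(length(ids), config$hidden_sizes, 1L)
  layers <- vector("list", length(dims) - 1L)
  for (k in seq_along(layers)) {
    fan_in <- dims[k]
    bound <- 1 / sqrt(fan_in)
    layers[[k]] <- list(
      W = matrix(runif(fan_in * dims[k + 1], -bound, bound), fan_in, dims[k + 1]),
      b = runif(dims[k + 1], -bound, bound)
    )
  }
  structure(list(feature_ids = ids,
                 provenance = if (inherits(features, "feature_set")) features$provenance else list(),
                 layers = layers,
                 config = config,
                 training = NULL),
            class = "purity_model")
}

#' Number of learnable parameters
#'
#' @param model a `purity_model`.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "purity_model"))
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' @export
print.purity_model <- function(x, ...) {
  dims <- c(length(x$feature_ids), x$config$hidden_sizes, 1L)
  cat(sprintf("<purity_model> %s (%s parameters)%s\n",
              paste(dims, collapse = " -> "),
              format(n_parameters(x), big.mark = ","),
              if (is.null(x$training)) ", untrained" else ""))
  if (!is.null(x$training)) {
    cat(sprintf("  trained %d batches; best window mean %.4f at batch %d (%s)\n",
                x$training$n_batches, x$training$best_window_mean,
                x$training$best_batch, x$training$stop_reason))
  }
  invisible(x)
}

# Forward pass. X is n x d. Returns the raw (unclipped) output vector, plus
# pre-activations when gradients are needed.
mlp_forward <- function(layers, X, keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", length(layers))
  A <- X
  for (k in seq_along(layers)) {
    Z <- A %*% layers[[k]]$W
    Z <- sweep(Z, 2, layers[[k]]$b, "+")
    if (keep_cache) cache[[k]] <- list(input = A, Z = Z)
    A <- if (k < length(layers)) pmax(Z, 0) else Z
  }
  out <- drop(A)
  if (keep_cache) list(yhat = out, cache = cache) else out
}

# Backward pass for L1 loss: d loss / d yhat = sign(yhat - y) / n.
mlp_gradients <- function(layers, cache, y, yhat) {
  n <- length(y)
  grads <- vector("list", length(layers))
  delta <- matrix(sign(yhat - y) / n, ncol = 1)
  for (k in rev(seq_along(layers))) {
    A_in <- cache[[k]]$input
    gW <- crossprod(A_in, delta)
    dimnames(gW) <- NULL
    grads[[k]] <- list(W = gW, b = unname(colSums(delta)))
    if (k > 1) {
      delta <- (delta %*% t(layers[[k]]$W)) * (cache[[k - 1]]$Z > 0)
    }
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
    mb = numeric(length(l$b)), vb = numeric(length(l$b))
  ))
}

adam_step <- function(layers, grads, state, t, cfg) {
  lr <- cfg$learning_rate; b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  eps <- cfg$adam_eps; wd <- cfg$weight_decay
  c1 <- 1 - b1^t
  c2 <- 1 - b2^t
  for (k in seq_along(layers)) {
    gW <- grads[[k]]$W + wd * layers[[k]]$W
    gb <- grads[[k]]$b + wd * layers[[k]]$b
    s <- state[[k]]
    s$mW <- b1 * s$mW + (1 - b1) * gW
    s$vW <- b2 * s$vW + (1 - b2) * gW^2
    s$mb <- b1 * s$mb + (1 - b1) * gb
    s$vb <- b2 * s$vb + (1 - b2) * gb^2
    layers[[k]]$W <- layers[[k]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    layers[[k]]$b <- layers[[k]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[k]] <- s
  }
  list(layers = layers, state = state)
}

#' Train the purity network on simulated pseudobulks
#'
#' Repeats: simulate a batch of labeled pseudobulk tumors from the corpus,
#' forward them in training mode (input dropout active), take an Adam step on
#' the L1 loss, and track the sliding-window mean of the batch losses. The
#' weights are snapshotted whenever the sliding mean reaches a new minimum;
#' training stops when no new minimum has appeared for `patience` batches (or
#' at `max_batches`), and the best snapshot is returned.
#'
#' RNG order per batch: the batch simulation draws (see [simulate_batch()])
#' followed by one dropout mask, so a seeded run is replayable.
#'
#' @param corpus a [single_cell_corpus()].
#' @param features the [feature_set()] fixing the input layout.
#' @param lengths gene lengths for the TPM step of the input transform.
#' @param sim_config a [simulation_config()].
#' @param config a [model_config()].
#' @param seed integer seed for weight initialisation, simulation and dropout.
#' @param verbose report progress every 200 batches.
#' @return a trained `purity_model`; `$training_log` is a tibble (batch,
#'   loss, window_mean, new_best) and `$training` records the stop reason,
#'   best batch and best window mean.
#' @export
train_purity_model <- function(corpus, features, lengths,
                               sim_config = simulation_config(),
                               config = model_config(),
                               seed = 1, verbose = FALSE) {
  stopifnot(inherits(corpus, "single_cell_corpus"),
            inherits(sim_config, "simulation_config"),
            inherits(config, "model_config"))
  sim_config$batch_size <- config$batch_size
  eligible <- eligible_samples(corpus, sim_config$min_cells_per_class)
  split <- corpus_class_split(corpus, eligible)
  gene_ids <- rownames(corpus$counts)
  lengths <- as_gene_lengths(lengths)

  set.seed(seed)
  model <- init_purity_model(features, config, seed = NULL)
  d <- length(model$feature_ids)
  state <- adam_init(model$layers)
  keep <- config$input_dropout
  losses <- numeric(0)
  window_means <- numeric(0)
  new_best <- logical(0)
  best <- list(mean = Inf, batch = NA_integer_, layers = model$layers)
  since_best <- 0L
  stop_reason <- "max_batches"
  b <- 0L

  while (b < config$max_batches) {
    b <- b + 1L
    batch <- simulate_batch_presplit(split, gene_ids, model$feature_ids,
                                     lengths, sim_config)
    X <- batch$x
    if (keep > 0) {
      mask <- matrix(runif(length(X)) >= keep, nrow(X), ncol(X)) / (1 - keep)
      X <- X * mask
    }
    fwd <- mlp_forward(model$layers, X, keep_cache = TRUE)
    loss <- l1_loss(batch$purity, fwd$yhat)
    if (!is.finite(loss)) {
      abort(sprintf("non-finite training loss at batch %d; last losses: %s",
                    b, paste(round(tail(losses, 5), 4), collapse = ", ")))
    }
    grads <- mlp_gradients(model$layers, fwd$cache, batch$purity, fwd$yhat)
    stepped <- adam_step(model$layers, grads, state, b, config)
    model$layers <- stepped$layers
    state <- stepped$state
    losses[b] <- loss

    if (b >= config$window) {
      wm <- mean(losses[(b - config$window + 1L):b])
      window_means[b] <- wm
      if (wm < best$mean) {
        best <- list(mean = wm, batch = b, layers = model$layers)
        new_best[b] <- TRUE
        since_best <- 0L
      } else {
        new_best[b] <- FALSE
        since_best <- since_best + 1L
        if (since_best >= config$patience) {
          stop_reason <- "patience"
          break
        }
      }
    } else {
      window_means[b] <- NA_real_
      new_best[b] <- FALSE
    }
    if (verbose && b %% 200 == 0) {
      inform(sprintf("batch %d: loss %.4f, best window mean %.4f (batch %d)",
                     b, loss, best$mean, best$batch))
    }
  }

  model$layers <- best$layers
  model$training <- list(n_batches = b,
                         best_batch = best$batch,
                         best_window_mean = best$mean,
                         stop_reason = stop_reason,
                         seed = seed)
  model$training_log <- structure(
    tibble(batch = seq_len(b), loss = losses,
           window_mean = window_means, new_best = new_best),
    class = c("purity_training_log", class(tibble())))
  model
}

#' Predict tumor purity for bulk count matrices
#'
#' Applies the model-input transform against the model's frozen feature set
#' (TPM on the full uploaded matrix, zero-fill of absent feature genes,
#' log2(TPM/100 + 1)), runs the network in eval mode (dropout off), and clips
#' the raw outputs to \[0, 1\]. If more than `warn_missing` of the feature
#' genes are absent a warning reports the fraction; at `max_missing` or above
#' the prediction is refused.
#'
#' @param object a trained `purity_model`.
#' @param newdata genes x samples raw count matrix (or data frame with gene
#'   ids in column 1).
#' @param lengths gene lengths covering the genes of `newdata`.
#' @param warn_missing warn above this missing-gene fraction (default 0.01).
#' @param max_missing refuse at or above this fraction (default 0.20).
#' @param strip_versions strip Ensembl version suffixes before matching.
#' @param ... unused.
#' @return tibble with `sample_id`, `purity` (clipped), `raw_output`,
#'   `missing_fraction`, `flag`.
#' @export
predict.purity_model <- function(object, newdata, lengths,
                                 warn_missing = 0.01, max_missing = 0.20,
                                 strip_versions = TRUE, ...) {
  m <- as_count_matrix(newdata)
  transformed <- model_input_transform(m, object$feature_ids, lengths,
                                       strip_versions = strip_versions)
  frac <- transformed$missing_fraction
  if (frac >= max_missing) {
    abort(sprintf(paste0("refusing to predict: %.1f%% of the %d feature genes are ",
                         "missing from the input (limit %.0f%%)"),
                  100 * frac, length(object$feature_ids), 100 * max_missing))
  }
  flag <- ""
  if (frac > warn_missing) {
    warn(sprintf(paste0("%.1f%% of feature genes are missing from the input; ",
                        "purity will be underestimated"), 100 * frac))
    flag <- "missing_genes"
  }
  X <- t(transformed$values)
  if (anyNA(X) || any(!is.finite(X))) abort("non-finite values in transformed input")
  raw <- as.numeric(mlp_forward(object$layers, X))
  tibble(sample_id = colnames(m),
         purity = pmin(pmax(raw, 0), 1),
         raw_output = as.numeric(raw),
         missing_fraction = frac,
         flag = flag)
}

#' Serialize / restore a trained purity model
#'
#' One versioned JSON artifact embedding the feature-set order, every layer's
#' weights and biases, the configuration and the training summary. Weights
#' are stored as full-precision decimal strings, so a load reproduces
#' predictions exactly.
#'
#' @param model a `purity_model`.
#' @param path file path.
#' @export
save_purity_model <- function(model, path) {
  stopifnot(inherits(model, "purity_model"))
  payload <- list(
    version = "bulkpurity_model/1",
    feature_ids = model$feature_ids,
    provenance = model$provenance,
    config = unclass(model$config),
    layers = lapply(model$layers, function(l) list(
      dim = dim(l$W),
      W = sprintf("%.17g", as.numeric(l$W)),
      b = sprintf("%.17g", l$b)
    )),
    training = model$training
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_purity_model
#' @export
load_purity_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort(sprintf("cannot read model artifact: %s",
                                                    conditionMessage(e))))
  if (!identical(obj$version, "bulkpurity_model/1")) {
    abort(sprintf("unsupported model artifact version: %s", obj$version %||% "<missing>"))
  }
  if (is.null(obj$feature_ids) || !length(obj$feature_ids)) {
    abort("model artifact is missing its feature set")
  }
  if (is.null(obj$layers)) abort("model artifact is missing layer weights")
  cfg_fields <- obj$config
  config <- model_config(hidden_sizes = cfg_fields$hidden_sizes,
                         input_dropout = cfg_fields$input_dropout,
                         learning_rate = cfg_fields$learning_rate,
                         weight_decay = cfg_fields$weight_decay,
                         batch_size = cfg_fields$batch_size,
                         window = cfg_fields$window,
                         patience = cfg_fields$patience,
                         max_batches = cfg_fields$max_batches)
  layers <- restore_layers(obj$layers)
  structure(list(feature_ids = as.character(obj$feature_ids),
                 provenance = as.list(obj$provenance),
                 layers = layers,
                 config = config,
                 training = as.list(obj$training)),
            class = "purity_model")
}

restore_layers <- function(raw_layers) {
  # jsonlite may return a data frame of list-columns or a plain list
  if (is.data.frame(raw_layers)) {
    raw_layers <- lapply(seq_len(nrow(raw_layers)), function(i) {
      list(dim = raw_layers$dim[[i]], W = raw_layers$W[[i]], b = raw_layers$b[[i]])
    })
  }
  lapply(raw_layers, function(l) {
    dm <- as.integer(unlist(l$dim))
    W <- matrix(as.numeric(unlist(l$W)), dm[1], dm[2])
    b <- as.numeric(unlist(l$b))
    if (anyNA(W) || anyNA(b)) abort("corrupt weights in model artifact")
    list(W = W, b = b)
  })
}
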