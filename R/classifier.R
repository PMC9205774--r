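# Tile-level classifier trained under weak (patient-level) labels.
# Architecture: fully connected 512x256, 256x256, 256x128, 128x2 with ReLU
# between layers and a softmax output; tile scores are averaged per patient.

#' Training hyperparameters
#'
#' @param batch_size Tiles per optimizer step.
#' @param learning_rate Step size (> 0).
#' @param optimizer `"sgd"` (plain stochastic gradient descent; keeps the
#'   swarm merge exactly linear in the per-peer updates) or `"adaptive"`
#'   (Adam with standard moment decay 0.9/0.999).
#' @param epochs_base Base number of epochs (the conventional value is 5).
#' @return A list of class `sl_hyperparams`.
#' @export
hyperparams <- function(batch_size = 32, learning_rate = 0.03,
                        optimizer = c("sgd", "adaptive"), epochs_base = 5) {
  optimizer <- match.arg(optimizer)
  assert_that(is_count(batch_size) && batch_size >= 1,
              "batch_size must be a positive integer")
  assert_that(is.numeric(learning_rate) && learning_rate >= 0,
              "learning_rate must be non-negative")
  assert_that(is_count(epochs_base) && epochs_base >= 1,
              "epochs_base must be a positive integer")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer = optimizer,
                 epochs_base = as.integer(epochs_base)),
            class = "sl_hyperparams")
}

mlp_layer_sizes <- function(feature_dim = 512) {
  list(c(feature_dim, 256L), c(256L, 256L), c(256L, 128L), c(128L, 2L))
}

#' Initialize the four-layer classifier
#'
#' He-normal weight initialization (s.d. `sqrt(2 / fan_in)`), zero biases;
#' deterministic under the seed.
#'
#' @param seed Integer seed.
#' @param feature_dim Input dimensionality (default 512).
#' @return An object of class `sl_model`: lists `W` (4 weight matrices) and
#'   `b` (4 bias vectors).
#' @examples
#' m <- init_model(seed = 1)
#' n_params(m)  # 230274
#' @export
init_model <- function(seed = 1, feature_dim = 512) {
  sizes <- mlp_layer_sizes(feature_dim)
  with_seed(derive_seed(seed, 37L), {
    W <- lapply(sizes, function(s) {
      matrix(rnorm(s[1] * s[2], sd = sqrt(2 / s[1])), s[1], s[2])
    })
    b <- lapply(sizes, function(s) numeric(s[2]))
    structure(list(W = W, b = b, feature_dim = as.integer(feature_dim)),
              class = "sl_model")
  })
}

#' @export
print.sl_model <- function(x, ...) {
  dims <- vapply(x$W, function(w) paste(dim(w), collapse = "x"), character(1))
  cat("<sl_model>", paste(dims, collapse = " -> "),
      "|", n_params(x), "parameters\n")
  invisible(x)
}

#' @rdname init_model
#' @param model An `sl_model`.
#' @export
n_params <- function(model) {
  sum(vapply(model$W, length, numeric(1))) +
    sum(vapply(model$b, length, numeric(1)))
}

#' Flatten model parameters to a vector and back
#'
#' The flat layout is `W1, b1, W2, b2, W3, b3, W4, b4` (column-major
#' weights); a flatten/unflatten round trip is the identity.
#'
#' @param model An `sl_model`.
#' @param vec Numeric vector of length `n_params(template)`.
#' @param template An `sl_model` providing the shapes.
#' @return `flatten_params()` a numeric vector; `unflatten_params()` an
#'   `sl_model`.
#' @export
flatten_params <- function(model) {
  unlist(purrr::map2(model$W, model$b, ~ c(as.vector(.x), .y)),
         use.names = FALSE)
}

#' @rdname flatten_params
#' @export
unflatten_params <- function(vec, template) {
  assert_that(length(vec) == n_params(template),
              "vector length does not match template parameter count")
  out <- template
  pos <- 0L
  for (l in seq_along(template$W)) {
    nw <- length(template$W[[l]])
    out$W[[l]] <- matrix(vec[pos + seq_len(nw)], nrow(template$W[[l]]),
                         ncol(template$W[[l]]))
    pos <- pos + nw
    nb <- length(template$b[[l]])
    out$b[[l]] <- vec[pos + seq_len(nb)]
    pos <- pos + nb
  }
  out
}

relu <- function(z) z * (z > 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

add_bias <- function(z, b) sweep(z, 2, b, "+")

mlp_forward <- function(model, x) {
  a <- list(x)
  z <- list()
  for (l in 1:4) {
    z[[l]] <- add_bias(a[[l]] %*% model$W[[l]], model$b[[l]])
    a[[l + 1]] <- if (l < 4) relu(z[[l]]) else z[[l]]
  }
  list(a = a, z = z, probs = softmax_rows(z[[4]]))
}

# Mean cross-entropy of tile labels (0/1) under the model.
mlp_loss <- function(model, x, y) {
  p <- mlp_forward(model, x)$probs
  -mean(log(pmax(p[cbind(seq_along(y), y + 1L)], 1e-12)))
}

# Gradient of the mean cross-entropy via backpropagation.
mlp_gradient <- function(model, x, y) {
  fw <- mlp_forward(model, x)
  n <- nrow(x)
  onehot <- matrix(0, n, 2)
  onehot[cbind(seq_len(n), y + 1L)] <- 1
  delta <- (fw$probs - onehot) / n
  gW <- vector("list", 4)
  gb <- vector("list", 4)
  for (l in 4:1) {
    gW[[l]] <- crossprod(fw$a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(model$W[[l]])) * (fw$z[[l - 1]] > 0)
    }
  }
  list(W = gW, b = gb)
}

#' Run a fixed number of optimizer steps
#'
#' Performs exactly `k` optimizer steps of tile-level cross-entropy
#' training, cycling over the supplied batches in order. With `k = 0` the
#' model is returned unchanged. The `"adaptive"` optimizer's moment state
#' is local to the call.
#'
#' @param model An `sl_model`.
#' @param batches List of batches, each a list with `x` (tiles x features
#'   matrix) and `y` (0/1 tile labels, the patient's label inherited by
#'   every tile).
#' @param k Number of steps.
#' @param hp An [hyperparams()] object.
#' @return The updated `sl_model`.
#' @export
train_steps <- function(model, batches, k, hp = hyperparams()) {
  assert_that(inherits(model, "sl_model"), "model must be an sl_model")
  assert_that(is_count(k) && k >= 0, "k must be a non-negative integer")
  if (k == 0) return(model)
  assert_that(length(batches) >= 1, "at least one batch is required")
  for (bt in batches) {
    assert_that(!is.null(bt$x) && nrow(bt$x) >= 1, "empty batch")
    assert_that(ncol(bt$x) == model$feature_dim,
                "batch feature dimension does not match the model")
  }
  adam <- hp$optimizer == "adaptive"
  if (adam) {
    mW <- lapply(model$W, function(w) w * 0); vW <- mW
    mb <- lapply(model$b, function(b) b * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  }
  for (step in seq_len(k)) {
    bt <- batches[[(step - 1L) %% length(batches) + 1L]]
    g <- mlp_gradient(model, bt$x, bt$y)
    if (!adam) {
      for (l in 1:4) {
        model$W[[l]] <- model$W[[l]] - hp$learning_rate * g$W[[l]]
        model$b[[l]] <- model$b[[l]] - hp$learning_rate * g$b[[l]]
      }
    } else {
      for (l in 1:4) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
        mWh <- mW[[l]] / (1 - b1^step); vWh <- vW[[l]] / (1 - b2^step)
        mbh <- mb[[l]] / (1 - b1^step); vbh <- vb[[l]] / (1 - b2^step)
        model$W[[l]] <- model$W[[l]] -
          hp$learning_rate * mWh / (sqrt(vWh) + eps)
        model$b[[l]] <- model$b[[l]] -
          hp$learning_rate * mbh / (sqrt(vbh) + eps)
      }
    }
  }
  model
}

#' Tile-level class probabilities
#'
#' @param model An `sl_model`.
#' @param features Matrix of tile features (rows = tiles) or a tibble with
#'   a `features` matrix column.
#' @return Numeric vector of softmax probabilities of class 1, one per
#'   tile, in input order.
#' @export
predict_tiles <- function(model, features) {
  x <- if (is.data.frame(features)) features$features else features
  assert_that(is.matrix(x), "features must be a matrix or contain one")
  assert_that(ncol(x) == model$feature_dim,
              "feature dimension does not match the model")
  mlp_forward(model, x)$probs[, 2]
}

#' Aggregate tile scores to a patient score
#'
#' The default rule is the arithmetic mean of tile class-1 probabilities;
#' majority vote (fraction of tiles above 0.5) and top-k mean are available
#' behind the `rule` switch.
#'
#' @param tile_scores Numeric vector of tile probabilities (length >= 1).
#' @param rule `"mean"`, `"majority"` or `"top_k"`.
#' @param k Number of tiles for `"top_k"`.
#' @return Scalar patient-level probability.
#' @examples
#' patient_score(c(0.2, 0.8))  # 0.5
#' @export
patient_score <- function(tile_scores, rule = c("mean", "majority", "top_k"),
                          k = 5) {
  rule <- match.arg(rule)
  assert_that(length(tile_scores) >= 1, "at least one tile score is required")
  switch(rule,
         mean = mean(tile_scores),
         majority = mean(tile_scores > 0.5),
         top_k = mean(sort(tile_scores, decreasing = TRUE)[
           seq_len(min(k, length(tile_scores)))]))
}

#' Equalize class counts by random undersampling
#'
#' Undersamples the majority class so both tile classes have exactly
#' `min(class counts)` rows; the result is a subset of the input, in the
#' original row order, deterministic under the seed.
#'
#' @param tiles Tibble with a `label` column (0/1) at the tile level.
#' @param seed Integer seed.
#' @return The balanced subset of `tiles`.
#' @export
balance_by_undersampling <- function(tiles, seed = 1) {
  assert_that(is.data.frame(tiles) && "label" %in% names(tiles),
              "tiles must contain a 'label' column")
  tab <- table(factor(tiles$label, levels = c(0, 1)))
  if (any(tab == 0)) {
    abort("both classes must be present to balance by undersampling")
  }
  m <- min(tab)
  keep <- with_seed(derive_seed(seed, 43L), {
    unlist(lapply(c(0, 1), function(cl) {
      idx <- which(tiles$label == cl)
      if (length(idx) > m) sample(idx, m) else idx
    }))
  })
  tiles[sort(keep), , drop = FALSE]
}

# Batch plan: the ordered list of row-index batches for `epochs` passes over
# n rows, reshuffling each epoch under an epoch-derived seed. The same plan
# generator is used by the local trainer and by every swarm peer, so a
# swarm of identical peers follows exactly the trajectory of a local run.
batch_plan <- function(n, batch_size, epochs, seed) {
  plan <- list()
  for (ep in seq_len(epochs)) {
    perm <- with_seed(derive_seed(seed, 41L, ep), sample.int(n))
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      plan[[length(plan) + 1L]] <- perm[s:min(s + batch_size - 1L, n)]
    }
  }
  plan
}

#' Train a local model on one training table
#'
#' Runs `epochs` passes of mini-batch training over the tile table,
#' reshuffling every epoch under an epoch-derived seed. This is the
#' "local" and "merged" trainer of the experiment harness; the swarm
#' trainer drives the same batch plan through [run_swarm()].
#'
#' @param tiles Tile tibble with `label` and a `features` matrix column
#'   (already balanced if desired).
#' @param hp An [hyperparams()] object.
#' @param epochs Number of epochs (defaults to `hp$epochs_base`).
#' @param seed Integer seed (controls init and shuffling).
#' @param model Optional starting `sl_model` (defaults to
#'   `init_model(seed, feature_dim)`).
#' @return The trained `sl_model`.
#' @export
train_local <- function(tiles, hp = hyperparams(), epochs = NULL, seed = 1,
                        model = NULL) {
  assert_that(all(c("label", "features") %in% names(tiles)),
              "tiles must have 'label' and 'features' columns")
  assert_that(nrow(tiles) >= 1, "training table is empty")
  epochs <- epochs %||% hp$epochs_base
  model <- model %||% init_model(seed, feature_dim = ncol(tiles$features))
  plan <- batch_plan(nrow(tiles), hp$batch_size, epochs, seed)
  batches <- lapply(plan, function(idx) {
    list(x = tiles$features[idx, , drop = FALSE], y = tiles$label[idx])
  })
  train_steps(model, batches, length(batches), hp)
}
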