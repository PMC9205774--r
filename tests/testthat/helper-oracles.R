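# Independent oracles used to cross-check the package implementation.
# These are written as straightforward, loop-based reference code and share
# no internals with the package beyond parameter shapes.

# AUROC by explicit pair counting over all (positive, negative) pairs,
# ties half-credited.
brute_force_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Reference forward pass of the 4-layer ReLU/softmax network, written
# sample-by-sample.
oracle_forward_one <- function(W, b, x) {
  a <- x
  for (l in 1:4) {
    z <- as.vector(a %*% W[[l]]) + b[[l]]
    a <- if (l < 4) pmax(z, 0) else z
  }
  e <- exp(a - max(a))
  e / sum(e)
}

oracle_loss <- function(W, b, X, y) {
  n <- nrow(X)
  s <- 0
  for (i in seq_len(n)) {
    p <- oracle_forward_one(W, b, X[i, ])
    s <- s - log(max(p[y[i] + 1], 1e-12))
  }
  s / n
}

# Reference gradient of the mean cross-entropy, accumulated one sample at a
# time with explicit backward recursions.
oracle_gradient <- function(W, b, X, y) {
  n <- nrow(X)
  gW <- lapply(W, function(w) w * 0)
  gb <- lapply(b, function(v) v * 0)
  for (i in seq_len(n)) {
    a <- list(X[i, ])
    z <- list()
    for (l in 1:4) {
      z[[l]] <- as.vector(a[[l]] %*% W[[l]]) + b[[l]]
      a[[l + 1]] <- if (l < 4) pmax(z[[l]], 0) else z[[l]]
    }
    e <- exp(z[[4]] - max(z[[4]]))
    p <- e / sum(e)
    delta <- p
    delta[y[i] + 1] <- delta[y[i] + 1] - 1
    for (l in 4:1) {
      gW[[l]] <- gW[[l]] + outer(a[[l]], delta) / n
      gb[[l]] <- gb[[l]] + delta / n
      if (l > 1) delta <- as.vector(W[[l]] %*% delta) * (z[[l - 1]] > 0)
    }
  }
  list(W = gW, b = gb)
}

# One plain-SGD step on a batch, via the reference gradient.
oracle_sgd_step <- function(W, b, X, y, lr) {
  g <- oracle_gradient(W, b, X, y)
  for (l in 1:4) {
    W[[l]] <- W[[l]] - lr * g$W[[l]]
    b[[l]] <- b[[l]] - lr * g$b[[l]]
  }
  list(W = W, b = b)
}

# Small labeled feature table for classifier tests: two Gaussian classes
# separated along the first coordinate.
make_separable_tiles <- function(n_per_class = 40, d = 16, shift = 3,
                                 seed = 1) {
  withr::with_seed(seed, {
    x0 <- matrix(rnorm(n_per_class * d), n_per_class, d)
    x1 <- matrix(rnorm(n_per_class * d), n_per_class, d)
    x1[, 1] <- x1[, 1] + shift
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(2 * n_per_class)),
      label = rep(c(0L, 1L), each = n_per_class),
      features = rbind(x0, x1)
    )
  })
}

# Tiny multi-cohort feature setup (train cohorts + test tiles) for
# evaluation-harness tests.
make_tiny_experiment <- function(seed = 1, effect = 2.5) {
  cfg <- synthetic_config(patients_per_cohort = c(16, 24, 20, 20),
                          tiles_per_patient = 6, feature_dim = 24,
                          effect_size = effect, site_shift = 1,
                          prevalence = 0.4, seed = seed)
  ch <- generate_feature_cohorts(cfg)
  tr <- split(ch$tiles, ch$tiles$cohort_id)
  list(train = tr[c("cohort1", "cohort2", "cohort3")],
       test = tr[["cohort4"]], cohorts = ch)
}
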