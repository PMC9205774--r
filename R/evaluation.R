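# Patient-level evaluation: AUROC, replicate experiments over seeds,
# model comparison t-tests, data-efficiency subsets, sync-interval sweep.

#' Patient-level AUROC
#'
#' Area under the ROC curve in its Mann-Whitney formulation: the fraction
#' of (positive, negative) patient pairs in which the positive patient has
#' the higher score, with ties counted 1/2. Computed from midranks.
#'
#' @param labels Binary vector (0/1), one per patient; both classes must
#'   be present.
#' @param scores Numeric scores, same length.
#' @return AUROC in \[0, 1\].
#' @examples
#' patient_auroc(c(0, 0, 1, 1), c(0.1, 0.6, 0.5, 0.9))  # 0.75
#' @export
patient_auroc <- function(labels, scores) {
  assert_that(length(labels) == length(scores),
              "labels and scores must have equal length")
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  assert_that(n1 > 0 && n0 > 0,
              "both classes must be present to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified patient subsample
#'
#' Selects `n` patients preserving class proportions. Per-class counts are
#' the largest-remainder rounding of `n` times each class fraction (floors
#' first, then remaining slots to the largest fractional parts), and the
#' patients within each class are sampled deterministically under the seed.
#'
#' @param patients Tibble with `patient_id` and `label` columns (one row
#'   per patient).
#' @param n Number of patients to select (`n <= nrow(patients)`).
#' @param seed Integer seed.
#' @return The selected subset of `patients`, in original row order.
#' @export
stratified_subsample <- function(patients, n, seed = 1) {
  assert_that(is.data.frame(patients) &&
                all(c("patient_id", "label") %in% names(patients)),
              "patients must have patient_id and label columns")
  assert_that(!anyDuplicated(patients$patient_id),
              "patients must have one row per patient")
  assert_that(is_count(n) && n <= nrow(patients),
              "n must be an integer <= number of patients")
  classes <- sort(unique(patients$label))
  assert_that(n >= length(classes),
              "n is smaller than the number of classes")
  if (n == nrow(patients)) return(patients)
  counts <- vapply(classes, function(cl) sum(patients$label == cl),
                   numeric(1))
  quota <- n * counts / sum(counts)
  take <- floor(quota)
  rem <- n - sum(take)
  if (rem > 0) {
    frac_order <- order(quota - take, decreasing = TRUE)
    take[frac_order[seq_len(rem)]] <- take[frac_order[seq_len(rem)]] + 1
  }
  keep <- with_seed(derive_seed(seed, 47L), {
    unlist(lapply(seq_along(classes), function(i) {
      idx <- which(patients$label == classes[i])
      sample(idx, min(take[i], length(idx)))
    }))
  })
  patients[sort(keep), , drop = FALSE]
}

# Patient-level predictions for a tile table.
predict_patients <- function(model, tiles, rule = "mean") {
  scores <- predict_tiles(model, tiles$features)
  tibble(patient_id = tiles$patient_id, label = tiles$label,
         score = scores) %>%
    group_by(.data$patient_id, .data$label) %>%
    summarise(score = patient_score(.data$score, rule = rule),
              .groups = "drop")
}

# Subsample each training cohort to `subset_size` patients (stratified),
# returning the filtered tile tables.
subset_cohort_tiles <- function(train_cohorts, subset_size, seed) {
  if (is.null(subset_size)) return(train_cohorts)
  purrr::imap(train_cohorts, function(tiles, cid) {
    pts <- dplyr::distinct(tiles, .data$patient_id, .data$label)
    sel <- stratified_subsample(pts, subset_size,
                                derive_seed(seed, 53L, match(cid, names(train_cohorts))))
    tiles[tiles$patient_id %in% sel$patient_id, , drop = FALSE]
  })
}

balance_cohort <- function(tiles, seed, tag) {
  balance_by_undersampling(tiles, derive_seed(seed, 59L, tag))
}

#' Train one model type and evaluate it on a test set
#'
#' The workhorse behind [replicate_experiment()] and
#' [run_experiment_grid()]. Trains the requested model type — a local model
#' on one cohort, a merged model on the concatenated cohorts, or a swarm
#' model (basic or weighted schedule) with one peer per cohort — and
#' returns the patient-level AUROC on the test tiles. Class balancing by
#' undersampling is applied per training cohort (per swarm peer); the
#' merged trainer balances the concatenated set.
#'
#' @param model_type One of `"local:<cohort_id>"`, `"merged"`,
#'   `"b-chkpt1"`, `"b-chkpt2"`, `"w-chkpt"`.
#' @param train_cohorts Named list of tile tibbles, one per cohort.
#' @param test_tiles Tile tibble of the held-out test cohort.
#' @param hp An [hyperparams()] object.
#' @param seed Integer seed controlling subsampling, balancing,
#'   initialization and shuffling.
#' @param subset_size Optional stratified subset size per training cohort.
#' @param sync_interval Sync interval for swarm model types.
#' @return List with `auroc`, `model`, and the per-patient `predictions`.
#' @export
train_and_evaluate <- function(model_type, train_cohorts, test_tiles,
                               hp = hyperparams(), seed = 1,
                               subset_size = NULL, sync_interval = 4) {
  assert_that(!is.null(names(train_cohorts)),
              "train_cohorts must be a named list")
  overlap <- intersect(
    unique(unlist(lapply(train_cohorts, function(t) t$patient_id))),
    unique(test_tiles$patient_id))
  assert_that(length(overlap) == 0,
              "training and test sets share patient ids")
  sub <- subset_cohort_tiles(train_cohorts, subset_size, seed)

  model <- if (startsWith(model_type, "local:")) {
    cid <- sub("^local:", "", model_type)
    assert_that(cid %in% names(sub), paste0("unknown cohort '", cid, "'"))
    tiles <- balance_cohort(sub[[cid]], seed, match(cid, names(sub)))
    train_local(tiles, hp, seed = seed)
  } else if (model_type == "merged") {
    tiles <- balance_cohort(bind_rows(sub), seed, 0L)
    train_local(tiles, hp, seed = seed)
  } else if (model_type %in% c("b-chkpt1", "b-chkpt2", "w-chkpt")) {
    fit <- swarm_fit_for(sub, model_type, hp, seed, sync_interval)
    fit$checkpoints[[sub("-", "_", model_type)]]
  } else {
    abort(paste0("unknown model_type '", model_type, "'"))
  }
  preds <- predict_patients(model, test_tiles)
  list(auroc = patient_auroc(preds$label, preds$score),
       model = model, predictions = preds)
}

# Train the swarm (basic or weighted depending on the requested
# checkpoint) on balanced per-cohort peers.
swarm_fit_for <- function(sub_cohorts, model_type, hp, seed, sync_interval) {
  peer_tiles <- purrr::imap(sub_cohorts, function(tiles, cid) {
    balance_cohort(tiles, seed, match(cid, names(sub_cohorts)))
  })
  mode <- if (model_type == "w-chkpt") "weighted" else "basic"
  counts <- vapply(peer_tiles, nrow, numeric(1))
  sch <- make_schedule(counts, mode = mode, hp = hp,
                       sync_interval = sync_interval)
  run_swarm(peer_tiles, sch, hp, seed)
}

#' Repeat an experiment across random seeds
#'
#' Runs one full train + test cycle per seed (the seed controls
#' initialization, subsampling, balancing and shuffling) and collects the
#' patient-level AUROCs. The conventional replicate count is 5.
#'
#' @inheritParams train_and_evaluate
#' @param seeds Integer vector of distinct seeds (>= 2 for any downstream
#'   statistical comparison).
#' @param test_cohort_id Label stored on the result.
#' @return An object of class `sl_experiment_result` with fields
#'   `model_type`, `test_cohort`, `subset_size`, `seeds`, `aurocs`,
#'   `mean`, `sd` (sample s.d.).
#' @export
replicate_experiment <- function(model_type, train_cohorts, test_tiles,
                                 seeds = 1:5, hp = hyperparams(),
                                 subset_size = NULL, sync_interval = 4,
                                 test_cohort_id = "test") {
  assert_that(!anyDuplicated(seeds), "seeds must be distinct")
  aurocs <- vapply(seeds, function(s) {
    train_and_evaluate(model_type, train_cohorts, test_tiles, hp, s,
                       subset_size, sync_interval)$auroc
  }, numeric(1))
  structure(list(model_type = model_type, test_cohort = test_cohort_id,
                 subset_size = subset_size, seeds = as.integer(seeds),
                 aurocs = aurocs, mean = mean(aurocs), sd = sd(aurocs)),
            class = "sl_experiment_result")
}

#' @export
print.sl_experiment_result <- function(x, ...) {
  cat(sprintf("<sl_experiment_result> %s on %s: AUROC %.4f +/- %.4f (%d seeds)\n",
              x$model_type, x$test_cohort, x$mean,
              ifelse(is.na(x$sd), 0, x$sd), length(x$seeds)))
  invisible(x)
}

#' Compare two replicate AUROC sets by unpaired t-test
#'
#' Two-sided two-sample t-test (classical equal-variance form by default,
#' Welch behind the flag) on the per-seed AUROC lists of two experiments,
#' without multiple-testing correction. When both samples have zero
#' variance the test statistic is undefined: equal means return p = 1 and
#' unequal means p = 0, each with a warning flag.
#'
#' @param a,b `sl_experiment_result` objects or numeric AUROC vectors
#'   (length >= 2 each).
#' @param var_equal Use the classical pooled-variance test (default).
#' @return One-row tibble: `mean_a`, `mean_b`, `statistic`, `df`,
#'   `p_value`, `method`, `flag`.
#' @export
compare_auroc <- function(a, b, var_equal = TRUE) {
  va <- if (inherits(a, "sl_experiment_result")) a$aurocs else a
  vb <- if (inherits(b, "sl_experiment_result")) b$aurocs else b
  assert_that(length(va) >= 2 && length(vb) >= 2,
              "at least two replicates per group are required")
  flag <- NA_character_
  if (sd(va) == 0 && sd(vb) == 0) {
    p <- if (isTRUE(all.equal(mean(va), mean(vb)))) 1 else 0
    warn("both samples have zero variance; p-value set by convention")
    flag <- "zero_variance"
    return(tibble(mean_a = mean(va), mean_b = mean(vb),
                  statistic = NA_real_, df = NA_real_, p_value = p,
                  method = "degenerate", flag = flag))
  }
  tt <- t.test(va, vb, var.equal = var_equal)
  tibble(mean_a = mean(va), mean_b = mean(vb),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, method = tt$method, flag = flag)
}

#' Sweep the synchronization interval
#'
#' Trains one swarm model per (sync interval, seed) on a stratified random
#' subset of each training cohort and evaluates patient-level AUROC on the
#' test tiles. Used to check that the merge frequency does not materially
#' affect classification performance.
#'
#' @inheritParams train_and_evaluate
#' @param intervals Integer vector of sync intervals (e.g.
#'   `c(1, 4, 16, 64)`).
#' @param n_patients Patients per training cohort (stratified subset).
#' @param seeds Integer vector of seeds (conventionally 3).
#' @param checkpoint Which swarm checkpoint to evaluate.
#' @return Tibble with columns `interval`, `seed`, `auroc`.
#' @export
sync_sweep <- function(train_cohorts, test_tiles, intervals = c(1, 4, 16, 64),
                       n_patients = 200, seeds = 1:3, hp = hyperparams(),
                       checkpoint = "b-chkpt2") {
  assert_that(all(intervals >= 1), "intervals must be >= 1")
  grid <- expand.grid(interval = intervals, seed = seeds)
  aurocs <- purrr::map2_dbl(grid$interval, grid$seed, function(iv, s) {
    train_and_evaluate(checkpoint, train_cohorts, test_tiles, hp, s,
                       subset_size = n_patients,
                       sync_interval = iv)$auroc
  })
  tibble(interval = as.integer(grid$interval), seed = as.integer(grid$seed),
         auroc = aurocs)
}

#' Run the full local / merged / swarm experiment grid
#'
#' Trains every requested model type for every subset size and seed, and
#' evaluates each on the held-out test cohort. Basic-swarm checkpoints
#' (`b-chkpt1`, `b-chkpt2`) are read from a single swarm session per
#' (subset, seed). Results are cached in memory by a content hash of the
#' run configuration within the call.
#'
#' @inheritParams train_and_evaluate
#' @param model_types Character vector; default is every local cohort plus
#'   `merged`, `b-chkpt1`, `b-chkpt2`, `w-chkpt`.
#' @param subset_sizes Integer vector of per-cohort subset sizes, or
#'   `list(NULL)` for full cohorts (`NA` in the output).
#' @param seeds Integer vector of seeds.
#' @param test_cohort_id Label recorded in the output.
#' @return Tidy tibble: `model_type`, `subset_size`, `seed`,
#'   `test_cohort`, `auroc`.
#' @export
run_experiment_grid <- function(train_cohorts, test_tiles,
                                model_types = NULL,
                                subset_sizes = list(NULL), seeds = 1:5,
                                hp = hyperparams(), sync_interval = 4,
                                test_cohort_id = "test") {
  model_types <- model_types %||%
    c(paste0("local:", names(train_cohorts)),
      "merged", "b-chkpt1", "b-chkpt2", "w-chkpt")
  if (is.numeric(subset_sizes)) subset_sizes <- as.list(subset_sizes)
  rows <- list()
  swarm_cache <- new.env(parent = emptyenv())
  for (ss in subset_sizes) {
    for (s in seeds) {
      sub <- subset_cohort_tiles(train_cohorts, ss, s)
      for (mt in model_types) {
        if (mt %in% c("b-chkpt1", "b-chkpt2")) {
          key <- hash(list("basic", ss %||% NA, s, sync_interval))
          if (is.null(swarm_cache[[key]])) {
            swarm_cache[[key]] <-
              swarm_fit_for(sub, "b-chkpt1", hp, s, sync_interval)
          }
          model <- swarm_cache[[key]]$checkpoints[[sub("-", "_", mt)]]
          preds <- predict_patients(model, test_tiles)
          au <- patient_auroc(preds$label, preds$score)
        } else {
          au <- train_and_evaluate(mt, train_cohorts, test_tiles, hp, s,
                                   subset_size = ss,
                                   sync_interval = sync_interval)$auroc
        }
        rows[[length(rows) + 1L]] <- tibble(
          model_type = mt, subset_size = ss %||% NA_integer_,
          seed = as.integer(s), test_cohort = test_cohort_id, auroc = au)
      }
    }
  }
  bind_rows(rows)
}

#' Summarize a grid result and all pairwise model comparisons
#'
#' @param grid_results Tibble from [run_experiment_grid()].
#' @return List with `summary` (mean/sd per model type and subset size)
#'   and `t_tests` (pairwise [compare_auroc()] rows per subset size).
#' @export
summarize_experiment_grid <- function(grid_results) {
  summary <- grid_results %>%
    group_by(.data$model_type, .data$subset_size, .data$test_cohort) %>%
    summarise(mean_auroc = mean(.data$auroc), sd_auroc = sd(.data$auroc),
              n_seeds = dplyr::n(), .groups = "drop")
  combos <- list()
  for (ss in unique(grid_results$subset_size)) {
    g <- grid_results[is.na(grid_results$subset_size) == is.na(ss) &
                        (is.na(ss) | grid_results$subset_size %in% ss), ]
    mts <- unique(g$model_type)
    if (length(mts) < 2) next
    for (i in seq_along(mts)) for (j in seq_along(mts)) {
      if (i >= j) next
      va <- g$auroc[g$model_type == mts[i]]
      vb <- g$auroc[g$model_type == mts[j]]
      if (length(va) < 2 || length(vb) < 2) next
      row <- compare_auroc(va, vb)
      row$model_a <- mts[i]; row$model_b <- mts[j]; row$subset_size <- ss
      combos[[length(combos) + 1L]] <- row
    }
  }
  list(summary = summary, t_tests = bind_rows(combos))
}
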