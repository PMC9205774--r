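# In-process simulation of decentralized (swarm) training: peers train in
# lockstep rounds of a fixed number of local optimizer steps, then all
# active peers' parameters are averaged by an elected merger and broadcast.
# The network / blockchain infrastructure of production swarm stacks is
# replaced by a deterministic round coordinator; the learning dynamics are
# the same.

#' Build a swarm training schedule
#'
#' Two schedule modes are supported. In *basic* mode every peer trains the
#' same number of epochs with equal merge weights; a model checkpoint is
#' taken when the smallest peer finishes its final epoch (`b_chkpt1`) and
#' the run ends when the second-smallest finishes (`b_chkpt2`), because at
#' least `min_active_peers` partners are required to continue. In
#' *weighted* mode smaller peers train proportionally more epochs
#' (`e_i = round(E * max(N) / N_i)`, minimum 1) so all peers finish
#' together, and merge weights are strictly proportional to tile counts;
#' a single terminal checkpoint (`w_chkpt`) results.
#'
#' @param tile_counts Named or unnamed vector of per-peer training tile
#'   counts (after balancing/sampling), one per peer; at least 2 peers.
#' @param mode `"basic"` or `"weighted"`.
#' @param hp An [hyperparams()] object (supplies the batch size).
#' @param sync_interval Local optimizer iterations between merges
#'   (conventionally 4).
#' @param epochs_base Base epoch count E (conventionally 5).
#' @param min_active_peers Training stops when fewer peers remain active.
#'
#' @return An object of class `sl_schedule`: `mode`, `sync_interval`,
#'   `min_active_peers`, and a `peers` tibble (`peer_id`, `n_tiles`,
#'   `epochs`, `weight`, `steps_per_epoch`, `total_steps`, `finish_round`).
#' @examples
#' sch <- make_schedule(c(100, 200, 400), mode = "weighted",
#'                      hp = hyperparams(batch_size = 10), epochs_base = 5)
#' sch$peers$epochs  # 20 10 5
#' @export
make_schedule <- function(tile_counts, mode = c("basic", "weighted"),
                          hp = hyperparams(), sync_interval = 4,
                          epochs_base = NULL, min_active_peers = 2) {
  mode <- match.arg(mode)
  assert_that(length(tile_counts) >= 2,
              "at least two peers (partners) are required")
  assert_that(all(tile_counts >= 1), "every active peer needs tiles")
  assert_that(is_count(sync_interval) && sync_interval >= 1,
              "sync_interval must be a positive integer")
  epochs_base <- epochs_base %||% hp$epochs_base
  ids <- names(tile_counts) %||% paste0("peer", seq_along(tile_counts))
  if (is.null(names(tile_counts))) names(tile_counts) <- ids
  assert_that(!anyDuplicated(ids), "peer ids must be distinct")
  n <- as.numeric(tile_counts)
  if (mode == "basic") {
    epochs <- rep(epochs_base, length(n))
    weight <- rep(1 / length(n), length(n))
  } else {
    epochs <- pmax(1L, as.integer(round(epochs_base * max(n) / n)))
    weight <- n / sum(n)
  }
  spe <- ceiling(n / hp$batch_size)
  total <- epochs * spe
  peers <- tibble(
    peer_id = ids,
    n_tiles = as.integer(n),
    epochs = as.integer(epochs),
    weight = weight,
    steps_per_epoch = as.integer(spe),
    total_steps = as.integer(total),
    finish_round = as.integer(ceiling(total / sync_interval))
  )
  structure(list(mode = mode, sync_interval = as.integer(sync_interval),
                 epochs_base = as.integer(epochs_base),
                 min_active_peers = as.integer(min_active_peers),
                 peers = peers),
            class = "sl_schedule")
}

#' @export
print.sl_schedule <- function(x, ...) {
  cat("<sl_schedule>", x$mode, "mode | sync interval", x$sync_interval,
      "| base epochs", x$epochs_base, "\n")
  print(x$peers)
  invisible(x)
}

#' Weighted average of model parameters
#'
#' Element-wise weighted average of every weight matrix and bias vector;
#' the merge operation applied at each sync event.
#'
#' @param params_list List of `sl_model` objects with identical shapes.
#' @param weights Non-negative weights summing to 1 (within 1e-9).
#' @return The merged `sl_model`.
#' @examples
#' m1 <- init_model(1); m2 <- init_model(2)
#' avg <- merge_params(list(m1, m2), c(0.5, 0.5))
#' @export
merge_params <- function(params_list, weights) {
  assert_that(length(params_list) >= 1 &&
                length(weights) == length(params_list),
              "one weight per parameter set is required")
  assert_that(all(weights >= 0) && abs(sum(weights) - 1) < 1e-9,
              "weights must be non-negative and sum to 1")
  dims0 <- lapply(params_list[[1]]$W, dim)
  for (p in params_list[-1]) {
    assert_that(identical(lapply(p$W, dim), dims0),
                "parameter shapes do not match across peers")
  }
  out <- params_list[[1]]
  for (l in seq_along(out$W)) {
    out$W[[l]] <- Reduce(`+`, purrr::map2(params_list, weights,
                                          ~ .x$W[[l]] * .y))
    out$b[[l]] <- Reduce(`+`, purrr::map2(params_list, weights,
                                          ~ .x$b[[l]] * .y))
  }
  out
}

#' Elect the merging peer for a round
#'
#' Deterministic round-robin over the active peers (stands in for the
#' leader election of a blockchain-coordinated swarm; the merge result is
#' independent of which peer performs it).
#'
#' @param round 0-based round index.
#' @param active_peers Character vector of active peer ids.
#' @return The elected peer id.
#' @export
elect_merger <- function(round, active_peers) {
  assert_that(length(active_peers) >= 1, "no active peers")
  active_peers[(round %% length(active_peers)) + 1L]
}

#' Run a swarm training session
#'
#' Simulates lockstep decentralized training. All peers start from the
#' same seeded initialization. Each round, every active peer runs up to
#' `sync_interval` optimizer steps on its own data (cycling through its
#' epoch-reshuffled batch plan), then the parameters of all peers that
#' stepped this round are merged with the schedule weights (renormalized
#' over participants) and broadcast. In basic mode a peer that completes
#' its final epoch emits a checkpoint of the post-merge global model and
#' deactivates; the session ends when fewer than `min_active_peers`
#' remain. In weighted mode all peers finish at (nearly) the same round —
#' peers that finish a few steps early idle with their weight withheld —
#' and the final merge is the single checkpoint.
#'
#' @param peer_data Named list of tile tibbles (columns `label` and
#'   matrix column `features`), one per peer, already balanced.
#' @param schedule An [make_schedule()] object consistent with
#'   `peer_data` (same peer ids and tile counts).
#' @param hp An [hyperparams()] object.
#' @param seed Integer seed (shared initialization and shuffling).
#'
#' @return An object of class `sl_swarm_fit`: `checkpoints` (named list
#'   of `sl_model`: `b_chkpt1`/`b_chkpt2` or `w_chkpt`, plus `final`),
#'   `events` (tibble: `round`, `merger`, `participants`, `weights`,
#'   `digest`), `schedule`, `seed`.
#' @export
run_swarm <- function(peer_data, schedule, hp = hyperparams(), seed = 1) {
  assert_that(inherits(schedule, "sl_schedule"), "schedule must be an sl_schedule")
  peers <- schedule$peers
  assert_that(!is.null(names(peer_data)) &&
                setequal(names(peer_data), peers$peer_id),
              "peer_data names must match the schedule's peer ids")
  peer_data <- peer_data[peers$peer_id]
  for (i in seq_len(nrow(peers))) {
    assert_that(nrow(peer_data[[i]]) == peers$n_tiles[i],
                paste0("peer '", peers$peer_id[i],
                       "' data size does not match the schedule"))
  }
  fdim <- ncol(peer_data[[1]]$features)
  model <- init_model(seed, feature_dim = fdim)

  # Per-peer batch plans; identical peers (same data, same seed) share the
  # same plan, which makes the degenerate all-identical swarm collapse to a
  # single local run.
  plans <- lapply(seq_len(nrow(peers)), function(i) {
    batch_plan(peers$n_tiles[i], hp$batch_size, peers$epochs[i], seed)
  })
  done_steps <- integer(nrow(peers))
  active <- rep(TRUE, nrow(peers))
  # basic-mode checkpoints attach to peers in increasing order of workload
  finish_order <- order(peers$total_steps, peers$n_tiles, peers$peer_id)

  checkpoints <- list()
  events <- list()
  round_i <- 0L
  s_int <- schedule$sync_interval
  repeat {
    stepping <- which(active & done_steps < peers$total_steps)
    if (length(stepping) == 0) break
    locals <- vector("list", nrow(peers))
    for (i in stepping) {
      k <- min(s_int, peers$total_steps[i] - done_steps[i])
      idxs <- plans[[i]][done_steps[i] + seq_len(k)]
      batches <- lapply(idxs, function(ix) {
        list(x = peer_data[[i]]$features[ix, , drop = FALSE],
             y = peer_data[[i]]$label[ix])
      })
      locals[[i]] <- train_steps(model, batches, k, hp)
      done_steps[i] <- done_steps[i] + k
    }
    w <- peers$weight[stepping]
    w <- w / sum(w)
    merger <- elect_merger(round_i, peers$peer_id[stepping])
    model <- merge_params(locals[stepping], w)
    events[[length(events) + 1L]] <- tibble(
      round = round_i,
      merger = merger,
      participants = list(peers$peer_id[stepping]),
      weights = list(setNames(w, peers$peer_id[stepping])),
      digest = params_digest(model$W)
    )
    if (schedule$mode == "basic") {
      finished_now <- which(active & done_steps >= peers$total_steps)
      for (i in intersect(finish_order, finished_now)) {
        nm <- if (length(checkpoints) == 0) "b_chkpt1" else
          if (is.null(checkpoints$b_chkpt2)) "b_chkpt2" else NULL
        if (!is.null(nm)) {
          checkpoints[[nm]] <- model
          attr(checkpoints[[nm]], "provenance") <-
            list(round = round_i, peer = peers$peer_id[i],
                 digest = params_digest(model$W))
        }
        active[i] <- FALSE
      }
      if (sum(active) < schedule$min_active_peers) break
    }
    round_i <- round_i + 1L
  }
  if (schedule$mode == "weighted") {
    checkpoints$w_chkpt <- model
    attr(checkpoints$w_chkpt, "provenance") <-
      list(round = round_i, digest = params_digest(model$W))
  } else {
    # degenerate sessions (e.g. all peers finish in the same round) still
    # expose both basic checkpoints
    if (is.null(checkpoints$b_chkpt1)) checkpoints$b_chkpt1 <- model
    if (is.null(checkpoints$b_chkpt2)) checkpoints$b_chkpt2 <- model
  }
  checkpoints$final <- model
  structure(list(checkpoints = checkpoints,
                 events = bind_rows(events),
                 schedule = schedule, seed = as.integer(seed)),
            class = "sl_swarm_fit")
}

#' @export
print.sl_swarm_fit <- function(x, ...) {
  cat("<sl_swarm_fit>", x$schedule$mode, "mode |",
      nrow(x$events), "sync events |",
      "checkpoints:", paste(setdiff(names(x$checkpoints), "final"),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Write a sync-event log as JSON lines
#'
#' @param fit An `sl_swarm_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(fit$events))) {
    e <- fit$events[i, ]
    writeLines(jsonlite::toJSON(list(
      round = e$round, merger = e$merger,
      participants = e$participants[[1]],
      weights = as.list(e$weights[[1]]),
      digest = e$digest
    ), auto_unbox = TRUE), con)
  }
  invisible(path)
}
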