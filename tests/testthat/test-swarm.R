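test_that("basic schedules use equal epochs and weights with ordered
           checkpoint rounds", {
  hp <- hyperparams(batch_size = 100)
  sch <- make_schedule(c(a = 500, b = 1000, c = 2000), mode = "basic",
                       hp = hp, sync_interval = 4, epochs_base = 5)
  expect_equal(sch$peers$epochs, c(5, 5, 5))
  expect_equal(sch$peers$weight, rep(1 / 3, 3))
  # smallest peer finishes first, second-smallest second
  fr <- sch$peers$finish_round
  expect_lt(fr[1], fr[2])
  expect_lt(fr[2], fr[3])
})

test_that("weighted schedules scale epochs inversely and weights
           proportionally to tile counts", {
  hp <- hyperparams(batch_size = 10)
  sch <- make_schedule(c(100, 200, 400), mode = "weighted", hp = hp,
                       epochs_base = 5)
  expect_equal(sch$peers$epochs, c(20, 10, 5))
  expect_equal(sch$peers$weight, c(1, 2, 4) / 7)
  expect_lt(abs(sum(sch$peers$weight) - 1), 1e-12)
  # equal total work: e_i * N_i constant
  expect_equal(unique(sch$peers$epochs * sch$peers$n_tiles), 2000)
  # equal tile counts degenerate to the basic layout
  eq <- make_schedule(c(300, 300), mode = "weighted", hp = hp)
  expect_equal(eq$peers$epochs, c(5, 5))
  expect_equal(eq$peers$weight, c(0.5, 0.5))
  expect_error(make_schedule(c(100), mode = "basic"), "two peers")
})

test_that("parameter merging is an exact weighted average", {
  m1 <- init_model(1, feature_dim = 8)
  m2 <- init_model(2, feature_dim = 8)
  m3 <- init_model(3, feature_dim = 8)
  same <- merge_params(list(m1, m1, m1), c(0.2, 0.3, 0.5))
  expect_equal(same, m1)
  avg <- merge_params(list(m1, m2), c(0.5, 0.5))
  expect_equal(avg$W[[1]], (m1$W[[1]] + m2$W[[1]]) / 2)
  # tile counts 100 and 300 give weights 1/4, 3/4
  w <- c(100, 300) / 400
  expect_equal(w, c(0.25, 0.75))
  a <- unflatten_params(rep(1, n_params(m1)), m1)
  b <- unflatten_params(rep(5, n_params(m1)), m1)
  expect_equal(flatten_params(merge_params(list(a, b), w)),
               rep(4, n_params(m1)))
  # any linear functional is conserved
  f <- function(m) sum(flatten_params(m) * seq_len(n_params(m)) %% 7)
  ws <- c(0.1, 0.6, 0.3)
  expect_equal(f(merge_params(list(m1, m2, m3), ws)),
               ws[1] * f(m1) + ws[2] * f(m2) + ws[3] * f(m3))
  expect_error(merge_params(list(m1, init_model(1, feature_dim = 4)),
                            c(0.5, 0.5)), "shapes")
  expect_error(merge_params(list(m1, m2), c(0.5, 0.4)), "sum to 1")
})

test_that("merger election is deterministic round-robin over active peers", {
  peers <- c("A", "B", "C")
  expect_equal(vapply(0:3, elect_merger, character(1),
                      active_peers = peers), c("A", "B", "C", "A"))
  expect_equal(elect_merger(7, "Z"), "Z")
})

test_that("identical peers collapse to a single local run at any sync
           interval", {
  tiles <- make_separable_tiles(12, d = 8, seed = 4)  # 24 tiles
  hp <- hyperparams(batch_size = 8, learning_rate = 0.05)
  ref <- train_local(tiles, hp, epochs = 5, seed = 6)
  for (S in c(1, 4, 16)) {
    sch <- make_schedule(c(p1 = nrow(tiles), p2 = nrow(tiles),
                           p3 = nrow(tiles)),
                         mode = "basic", hp = hp, sync_interval = S,
                         epochs_base = 5)
    fit <- run_swarm(list(p1 = tiles, p2 = tiles, p3 = tiles), sch, hp,
                     seed = 6)
    for (nm in c("b_chkpt1", "b_chkpt2", "final")) {
      expect_lt(max(abs(flatten_params(fit$checkpoints[[nm]]) -
                          flatten_params(ref))), 1e-12)
    }
  }
})

test_that("with sync interval 1 the swarm equals centralized SGD on the
           concatenated batch", {
  hp <- hyperparams(batch_size = 8, learning_rate = 0.05)
  peer_tiles <- lapply(1:3, function(i) {
    make_separable_tiles(4, d = 16, seed = 40 + i)  # 8 tiles per peer
  })
  names(peer_tiles) <- c("p1", "p2", "p3")
  rounds <- 20
  sch <- make_schedule(vapply(peer_tiles, nrow, numeric(1)),
                       mode = "basic", hp = hp, sync_interval = 1,
                       epochs_base = rounds)
  fit <- run_swarm(peer_tiles, sch, hp, seed = 2)
  # independent oracle: each round is one SGD step on the 24-tile
  # concatenated batch (equal batch sizes, batch-proportional weights)
  m0 <- init_model(2, feature_dim = 16)
  X <- do.call(rbind, lapply(peer_tiles, function(t) t$features))
  y <- unlist(lapply(peer_tiles, function(t) t$label))
  W <- m0$W; b <- m0$b
  for (r in seq_len(rounds)) {
    upd <- oracle_sgd_step(W, b, X, y, 0.05)
    W <- upd$W; b <- upd$b
  }
  got <- flatten_params(fit$checkpoints$final)
  want <- flatten_params(structure(list(W = W, b = b, feature_dim = 16L),
                                   class = "sl_model"))
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-5)
  expect_equal(nrow(fit$events), rounds)
})

test_that("basic runs log ordered checkpoints with one deactivation between
           them and stop when fewer than two partners remain", {
  peer_tiles <- list(small = make_separable_tiles(8, d = 8, seed = 1),
                     mid = make_separable_tiles(16, d = 8, seed = 2),
                     large = make_separable_tiles(32, d = 8, seed = 3))
  hp <- hyperparams(batch_size = 8, learning_rate = 0.02)
  sch <- make_schedule(vapply(peer_tiles, nrow, numeric(1)),
                       mode = "basic", hp = hp, sync_interval = 2,
                       epochs_base = 3)
  fit <- run_swarm(peer_tiles, sch, hp, seed = 1)
  prov1 <- attr(fit$checkpoints$b_chkpt1, "provenance")
  prov2 <- attr(fit$checkpoints$b_chkpt2, "provenance")
  expect_lt(prov1$round, prov2$round)
  expect_equal(prov1$peer, "small")  # smallest cohort triggers chkpt1
  expect_equal(prov2$peer, "mid")
  # the run stops at chkpt2: no events past that round
  expect_equal(max(fit$events$round), prov2$round)
  # participant counts drop from 3 to 2 after the first checkpoint
  n_part <- vapply(fit$events$participants, length, numeric(1))
  expect_equal(sort(unique(n_part), decreasing = TRUE), c(3, 2))
})

test_that("relabeling peers permutes logs but not checkpoints, and digests
           replay under the same seed", {
  hp <- hyperparams(batch_size = 8, learning_rate = 0.03)
  t1 <- make_separable_tiles(8, d = 8, seed = 11)
  t2 <- make_separable_tiles(12, d = 8, seed = 12)
  t3 <- make_separable_tiles(16, d = 8, seed = 13)
  counts <- c(pA = nrow(t1), pB = nrow(t2), pC = nrow(t3))
  sch <- make_schedule(counts, mode = "weighted", hp = hp, sync_interval = 4)
  fit1 <- run_swarm(list(pA = t1, pB = t2, pC = t3), sch, hp, seed = 3)
  # same peers presented in a different order
  fit2 <- run_swarm(list(pC = t3, pA = t1, pB = t2), sch, hp, seed = 3)
  expect_equal(fit1$checkpoints$w_chkpt, fit2$checkpoints$w_chkpt)
  # replay: digests are reproducible
  fit3 <- run_swarm(list(pA = t1, pB = t2, pC = t3), sch, hp, seed = 3)
  expect_identical(fit1$events$digest, fit3$events$digest)
})

test_that("weighted mode with equal cohorts reproduces the basic final
           model", {
  hp <- hyperparams(batch_size = 8, learning_rate = 0.03)
  tiles <- lapply(21:23, function(s) make_separable_tiles(10, d = 8, seed = s))
  names(tiles) <- paste0("peer", 1:3)
  counts <- vapply(tiles, nrow, numeric(1))
  schW <- make_schedule(counts, "weighted", hp = hp, sync_interval = 4)
  schB <- make_schedule(counts, "basic", hp = hp, sync_interval = 4)
  fw <- run_swarm(tiles, schW, hp, seed = 5)
  fb <- run_swarm(tiles, schB, hp, seed = 5)
  expect_equal(flatten_params(fw$checkpoints$w_chkpt),
               flatten_params(fb$checkpoints$final))
})

test_that("swarm fits expose tidy event logs and glance summaries", {
  hp <- hyperparams(batch_size = 8, learning_rate = 0.03)
  tiles <- list(p1 = make_separable_tiles(8, d = 8, seed = 1),
                p2 = make_separable_tiles(8, d = 8, seed = 2))
  sch <- make_schedule(vapply(tiles, nrow, numeric(1)), "basic", hp = hp,
                       sync_interval = 2)
  names(tiles) <- sch$peers$peer_id
  fit <- run_swarm(tiles, sch, hp, seed = 1)
  ev <- tidy(fit)
  expect_true(all(c("round", "merger", "digest") %in% names(ev)))
  g <- glance(fit)
  expect_equal(g$mode, "basic")
  expect_equal(g$n_events, nrow(ev))
  log <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(fit, log)
  lines <- readLines(log)
  expect_equal(length(lines), nrow(ev))
  expect_equal(jsonlite::fromJSON(lines[1])$round, 0)
})
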