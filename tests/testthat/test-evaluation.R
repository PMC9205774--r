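test_that("patient AUROC matches pair counting on fixed and random cases", {
  expect_equal(patient_auroc(c(0, 1), c(0.2, 0.8)), 1.0)
  expect_equal(patient_auroc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  expect_equal(patient_auroc(c(0, 0, 1, 1), c(0.1, 0.6, 0.5, 0.9)), 0.75)
  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(4:20, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), 2)  # coarse grid provokes ties
      expect_equal(patient_auroc(labels, scores),
                   brute_force_auroc(labels, scores))
    }
  })
  expect_error(patient_auroc(c(1, 1), c(0.1, 0.2)), "both classes")
})

test_that("patient AUROC agrees with pROC and is monotone-invariant", {
  skip_if_not_installed("pROC")
  withr::with_seed(18, {
    labels <- sample(0:1, 60, replace = TRUE, prob = c(0.7, 0.3))
    labels[1:2] <- 0:1
    scores <- runif(60)
  })
  ours <- patient_auroc(labels, scores)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_equal(patient_auroc(labels, qlogis(scores)), ours)
  expect_equal(patient_auroc(labels, scores^3), ours)
})

test_that("stratified subsampling rounds class counts by largest remainder", {
  pts <- tibble::tibble(patient_id = sprintf("P%03d", 1:300),
                        label = rep(c(1, 0), times = c(30, 270)))
  sub <- stratified_subsample(pts, 100, seed = 1)
  expect_equal(sum(sub$label == 1), 10)
  expect_equal(sum(sub$label == 0), 90)
  # 97 patients with 13 positives, n = 50 -> 7 positives (enumeration:
  # quotas 6.701/43.299, floors 6+43, last slot to the larger remainder)
  pts2 <- tibble::tibble(patient_id = sprintf("Q%03d", 1:97),
                         label = rep(c(1, 0), times = c(13, 84)))
  sub2 <- stratified_subsample(pts2, 50, seed = 2)
  expect_equal(sum(sub2$label == 1), 7)
  expect_equal(nrow(sub2), 50)
  expect_identical(stratified_subsample(pts2, 50, seed = 2), sub2)
  expect_identical(stratified_subsample(pts2, 97, seed = 9), pts2)
  expect_error(stratified_subsample(pts2, 1, seed = 1), "number of classes")
  expect_error(stratified_subsample(pts2, 98, seed = 1), "<= number")
})

test_that("replicate experiments record one AUROC per seed and are
           reproducible", {
  ex <- make_tiny_experiment(seed = 31)
  res <- replicate_experiment("merged", ex$train, ex$test, seeds = 1:3,
                              hp = hyperparams(batch_size = 16))
  expect_length(res$aurocs, 3)
  expect_equal(res$mean, mean(res$aurocs))
  expect_equal(res$sd, sd(res$aurocs))
  res2 <- replicate_experiment("merged", ex$train, ex$test, seeds = 1:3,
                               hp = hyperparams(batch_size = 16))
  expect_identical(res$aurocs, res2$aurocs)
  expect_error(replicate_experiment("merged", ex$train, ex$test,
                                    seeds = c(1, 1)), "distinct")
  td <- tidy(res)
  expect_equal(nrow(td), 3)
  expect_equal(glance(res)$mean_auroc, res$mean)
})

test_that("with zero effect size replicate AUROCs hover around chance", {
  ex <- make_tiny_experiment(seed = 32, effect = 0)
  res <- replicate_experiment("merged", ex$train, ex$test, seeds = 1:5,
                              hp = hyperparams(batch_size = 16))
  expect_lt(abs(res$mean - 0.5), 3 * max(res$sd, 0.05))
})

test_that("train/test patient overlap is rejected", {
  ex <- make_tiny_experiment(seed = 33)
  leaky_test <- dplyr::bind_rows(ex$test, ex$train$cohort1[1:3, ])
  expect_error(train_and_evaluate("merged", ex$train, leaky_test),
               "share patient ids")
})

test_that("the AUROC t-test matches its closed form and conventions", {
  a <- c(0.70, 0.71, 0.72, 0.73, 0.74)
  same <- compare_auroc(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  shifted <- compare_auroc(a, a + 0.10)
  # closed form: equal variances, n = 5 each, 8 df
  sp <- sqrt((var(a) + var(a)) / 2)
  t_exp <- -0.10 / (sp * sqrt(2 / 5))
  expect_equal(shifted$statistic, t_exp, tolerance = 1e-12)
  expect_equal(shifted$df, 8)
  expect_lt(shifted$p_value, 0.001)
  expect_equal(shifted$p_value,
               2 * stats::pt(abs(t_exp), df = 8, lower.tail = FALSE))
  # two-sided symmetry
  expect_equal(compare_auroc(a + 0.10, a)$p_value, shifted$p_value)
  expect_warning(deg <- compare_auroc(c(0.5, 0.5), c(0.5, 0.5)),
                 "zero variance")
  expect_equal(deg$p_value, 1)
  expect_equal(deg$flag, "zero_variance")
})

test_that("the experiment grid covers all model types and caches basic
           checkpoints consistently", {
  ex <- make_tiny_experiment(seed = 34)
  hp <- hyperparams(batch_size = 16)
  g <- run_experiment_grid(ex$train, ex$test, seeds = 1:2, hp = hp)
  expect_equal(nrow(g), 7 * 2)  # 3 local + merged + 3 swarm checkpoints
  expect_true(all(g$auroc >= 0 & g$auroc <= 1))
  # grid values equal direct single runs
  direct <- train_and_evaluate("b-chkpt2", ex$train, ex$test, hp, seed = 1)
  expect_equal(g$auroc[g$model_type == "b-chkpt2" & g$seed == 1],
               direct$auroc)
  s <- summarize_experiment_grid(g)
  expect_equal(nrow(s$summary), 7)
  expect_true(all(c("model_a", "model_b", "p_value") %in% names(s$t_tests)))
  p <- plot_experiment_grid(g)
  expect_s3_class(p, "ggplot")
})

test_that("the sync sweep runs one model per interval and seed", {
  ex <- make_tiny_experiment(seed = 35)
  hp <- hyperparams(batch_size = 16)
  sw <- sync_sweep(ex$train, ex$test, intervals = c(1, 4), n_patients = 12,
                   seeds = 1:2, hp = hp)
  expect_equal(nrow(sw), 4)
  expect_identical(
    sw,
    sync_sweep(ex$train, ex$test, intervals = c(1, 4), n_patients = 12,
               seeds = 1:2, hp = hp))
  expect_s3_class(plot_sync_sweep(sw), "ggplot")
})
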