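# broom-style tidiers and plotting helpers for result objects.

#' Tidy a replicate experiment result
#'
#' @param x An `sl_experiment_result`.
#' @param ... Unused.
#' @return One row per seed: `model_type`, `test_cohort`, `subset_size`,
#'   `seed`, `auroc`.
#' @export
tidy.sl_experiment_result <- function(x, ...) {
  tibble(model_type = x$model_type, test_cohort = x$test_cohort,
         subset_size = x$subset_size %||% NA_integer_,
         seed = x$seeds, auroc = x$aurocs)
}

#' @rdname tidy.sl_experiment_result
#' @return `glance()`: a one-row summary with mean and sample s.d.
#' @export
glance.sl_experiment_result <- function(x, ...) {
  tibble(model_type = x$model_type, test_cohort = x$test_cohort,
         subset_size = x$subset_size %||% NA_integer_,
         mean_auroc = x$mean, sd_auroc = x$sd, n_seeds = length(x$seeds))
}

#' Tidy a swarm fit's sync-event log
#'
#' @param x An `sl_swarm_fit`.
#' @param ... Unused.
#' @return The event tibble (`round`, `merger`, `participants`,
#'   `weights`, `digest`).
#' @export
tidy.sl_swarm_fit <- function(x, ...) {
  x$events
}

#' @rdname tidy.sl_swarm_fit
#' @export
glance.sl_swarm_fit <- function(x, ...) {
  tibble(mode = x$schedule$mode,
         n_peers = nrow(x$schedule$peers),
         sync_interval = x$schedule$sync_interval,
         n_events = nrow(x$events),
         checkpoints = paste(setdiff(names(x$checkpoints), "final"),
                             collapse = ","),
         seed = x$seed)
}

#' Tidy a classifier's layer structure
#'
#' @param x An `sl_model`.
#' @param ... Unused.
#' @return One row per layer with input/output sizes and parameter counts.
#' @export
tidy.sl_model <- function(x, ...) {
  tibble(layer = seq_along(x$W),
         d_in = vapply(x$W, nrow, numeric(1)),
         d_out = vapply(x$W, ncol, numeric(1)),
         n_weights = vapply(x$W, length, numeric(1)),
         n_biases = vapply(x$b, length, numeric(1)))
}

#' Box plot of an experiment grid
#'
#' Mirrors the usual local / merged / swarm comparison figure: one box per
#' model type showing the per-seed patient-level AUROCs, faceted by subset
#' size when several are present.
#'
#' @param grid_results Tibble from [run_experiment_grid()].
#' @return A ggplot object.
#' @export
plot_experiment_grid <- function(grid_results) {
  p <- ggplot2::ggplot(grid_results,
                       ggplot2::aes(x = .data$model_type, y = .data$auroc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "Patient-level AUROC") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  if (length(unique(grid_results$subset_size)) > 1) {
    p <- p + ggplot2::facet_wrap(~subset_size)
  }
  p
}

#' Plot a sync-interval sweep
#'
#' @param sweep_results Tibble from [sync_sweep()].
#' @return A ggplot object (AUROC vs sync interval, log2 x-axis).
#' @export
plot_sync_sweep <- function(sweep_results) {
  ggplot2::ggplot(sweep_results,
                  ggplot2::aes(x = .data$interval, y = .data$auroc)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::scale_x_continuous(trans = "log2",
                                breaks = unique(sweep_results$interval)) +
    ggplot2::labs(x = "Sync interval (iterations)",
                  y = "Patient-level AUROC")
}
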