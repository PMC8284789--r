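#' Forest plot of per-taxon PCR bias
#'
#' Posterior mean and credible interval of each taxon's bias after `cycles`
#' cycles of PCR, on the log2 proportion scale or the CLR scale.  Taxa whose
#' interval excludes zero are drawn solid.
#'
#' @param object A [estimate_bias()] result.
#' @param scale,group,cycles,level Passed to [tidy.bias_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bias_estimate
#' @export
autoplot.bias_estimate <- function(object, scale = "log2_fold", group = NULL,
                                   cycles = 35, level = 0.95, ...) {
  df <- tidy(object, scale = scale, group = group, cycles = cycles,
             level = level)
  df$taxon <- stats::reorder(df$taxon, df$mean)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$taxon,
                                   alpha = .data$excludes_zero)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(
      x = if (scale == "log2_fold") {
        sprintf("log2 fold change in proportion after %d cycles", cycles)
      } else sprintf("CLR-scale bias after %d cycles", cycles),
      y = NULL) +
    ggplot2::theme_minimal()
}

#' Calibration-curve fit in log-ratio coordinates
#'
#' Observed log-ratio coordinates of each calibration sample (computed from
#' counts with the fitted posterior mean where counts are zero) against PCR
#' cycle number, with the posterior mean regression line per coordinate.
#'
#' @param bias A [estimate_bias()] result.
#' @param counts The [count_table] the bias was estimated from.
#' @param metadata Metadata tibble with `sample_id` and `cycle`.
#' @param group Group to display (default first).
#' @return A ggplot object.
#' @export
plot_calibration_curve <- function(bias, counts, metadata, group = NULL) {
  stopifnot(inherits(bias, "bias_estimate"))
  if (is.null(group)) group <- bias$groups[1]
  g <- .group_index(bias, group)
  ids <- metadata$sample_id[metadata$group == group]
  eta_hat <- apply(bias$fit$eta_draws, c(1, 2), mean)
  if (is.null(colnames(eta_hat))) colnames(eta_hat) <- colnames(counts)
  keep <- match(ids, colnames(eta_hat))
  obs <- tibble::tibble(
    sample_id = rep(ids, each = nrow(eta_hat)),
    coordinate = rep(paste0("coord_", seq_len(nrow(eta_hat))),
                     length(ids)),
    cycle = rep(metadata$cycle[match(ids, metadata$sample_id)],
                each = nrow(eta_hat)),
    eta = as.numeric(eta_hat[, keep]))
  am <- rowMeans(bias$alpha_draws[, g, , drop = FALSE])
  bm <- rowMeans(bias$beta_draws)
  line <- tidyr::expand_grid(
    coordinate = paste0("coord_", seq_along(am)),
    cycle = seq(min(obs$cycle), max(obs$cycle), length.out = 50))
  line$eta <- am[as.integer(sub("coord_", "", line$coordinate))] +
    bm[as.integer(sub("coord_", "", line$coordinate))] * line$cycle
  ggplot2::ggplot(obs, ggplot2::aes(.data$cycle, .data$eta)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::facet_wrap(~coordinate, scales = "free_y") +
    ggplot2::labs(x = "PCR cycle", y = "log-ratio coordinate") +
    ggplot2::theme_minimal()
}

#' Density plot of batch-effect norms
#'
#' Kernel densities of the posterior Euclidean norm of each PCR machine's
#' effect vector; an outlying machine stands out to the right.
#'
#' @param bias A [estimate_bias()] result fitted with batch covariates.
#' @return A ggplot object.
#' @export
plot_batch_norms <- function(bias) {
  df <- batch_effect_norms(bias)
  ggplot2::ggplot(df, ggplot2::aes(.data$norm, colour = .data$batch)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "posterior ||gamma|| (log-ratio units)", y = "density",
                  colour = "PCR machine") +
    ggplot2::theme_minimal()
}
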