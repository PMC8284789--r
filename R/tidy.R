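#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior coefficient summaries
#'
#' `tidy()` on an [mlnl_fit()] returns one row per log-ratio coordinate and
#' covariate with posterior mean and credible interval; on a
#' [estimate_bias()] result it returns per-taxon bias summaries on the
#' requested scale.
#'
#' @param x An `mlnl_fit` or `bias_estimate` object.
#' @param level Credible level.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mlnl_fit
#' @export
tidy.mlnl_fit <- function(x, level = 0.95, ...) {
  P <- dim(x$lambda_draws)[1]; Q <- dim(x$lambda_draws)[2]
  purrr::map_dfr(seq_len(Q), function(q) {
    draws <- x$lambda_draws[, q, , drop = TRUE]
    if (is.null(dim(draws))) draws <- matrix(draws, nrow = P)
    rownames(draws) <- paste0("coord_", seq_len(P))
    out <- credible_summary(draws, level)
    out$covariate <- x$design$labels[q]
    out$role <- x$design$roles[q]
    out[, c("covariate", "role", "term", "mean", "lower", "upper",
            "excludes_zero")]
  })
}

#' @rdname tidy.mlnl_fit
#' @param scale `"log2_fold"` (proportion-scale log2 fold change after `x`
#'   cycles), `"clr"` (CLR-scale bias after `x` cycles), or `"per_cycle_clr"`.
#' @param group Group whose intercept anchors the proportion-scale fold
#'   change (default: first group).
#' @param cycles Number of cycles the bias acts over (default 35).
#' @method tidy bias_estimate
#' @export
tidy.bias_estimate <- function(x, scale = c("log2_fold", "clr",
                                            "per_cycle_clr"),
                               group = NULL, cycles = 35, level = 0.95, ...) {
  scale <- match.arg(scale)
  if (is.null(group)) group <- x$groups[1]
  draws <- switch(scale,
    log2_fold = bias_fold_change(x, group, cycles),
    clr = bias_clr(x, cycles),
    per_cycle_clr = bias_clr(x, 1))
  out <- credible_summary(draws, level)
  names(out)[names(out) == "term"] <- "taxon"
  out$scale <- scale
  out
}

#' One-row model fit summary
#'
#' Reports dimensions, the Laplace log marginal likelihood, and the posterior
#' mean and credible bounds of the multivariate R-squared.
#'
#' @inheritParams tidy.mlnl_fit
#' @return A one-row tibble.
#' @method glance mlnl_fit
#' @export
glance.mlnl_fit <- function(x, ...) {
  r2 <- posterior_r2(x)
  qs <- stats::quantile(r2, c(0.025, 0.975), type = 7)
  tibble::tibble(
    n_taxa = length(x$taxa),
    n_samples = dim(x$eta_draws)[2],
    n_covariates = dim(x$lambda_draws)[2],
    n_draws = dim(x$eta_draws)[3],
    log_marginal = x$log_marginal,
    r2_mean = mean(r2), r2_lower = qs[[1]], r2_upper = qs[[2]],
    method = x$method
  )
}
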