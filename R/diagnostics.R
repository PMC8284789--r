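#' Posterior multivariate R-squared
#'
#' For each posterior draw \eqn{s}, the fraction of variation in the latent
#' log-ratio matrix explained by the linear predictor:
#' \deqn{R^2_{(s)} = 1 - \frac{\|\eta^{(s)} - \Lambda^{(s)} X\|_F^2}
#'   {\|\eta^{(s)} - \bar\eta^{(s)}\|_F^2}}
#' where \eqn{\bar\eta^{(s)}} centres each log-ratio coordinate at its mean
#' across samples.  Computed in the fit's own log-ratio coordinates.  Values
#' can be negative when the model fits worse than the per-coordinate mean.
#'
#' @param fit An [mlnl_fit()] result.
#' @param design Optional design override (defaults to the fit's design).
#' @return Numeric vector of \eqn{R^2} draws (length S).
#' @export
posterior_r2 <- function(fit, design = NULL) {
  stopifnot(inherits(fit, "mlnl_fit"))
  X <- if (is.null(design)) fit$design$x else {
    if (inherits(design, "mlnl_design")) design$x else as.matrix(design)
  }
  S <- dim(fit$eta_draws)[3]
  vapply(seq_len(S), function(s) {
    eta <- fit$eta_draws[, , s, drop = FALSE]
    dim(eta) <- dim(fit$eta_draws)[1:2]
    lam <- fit$lambda_draws[, , s, drop = FALSE]
    dim(lam) <- dim(fit$lambda_draws)[1:2]
    resid <- eta - lam %*% X
    tot <- eta - rowMeans(eta)
    sst <- sum(tot^2)
    if (sst == 0) stop("total variation of eta is zero; R2 undefined",
                       call. = FALSE)
    1 - sum(resid^2) / sst
  }, numeric(1))
}

#' Posterior Euclidean norms of batch (PCR machine) effects
#'
#' For each non-reference batch and each posterior draw, the Euclidean norm
#' of the batch coefficient vector \eqn{\gamma_b} in the fit's log-ratio
#' coordinates.  A batch whose norm distribution stochastically dominates the
#' others flags a processing problem (e.g. a miscalibrated PCR machine) and
#' is a candidate for exclusion before re-estimating bias.
#'
#' @param bias A [estimate_bias()] result fitted with batch covariates.
#' @return Tibble with columns `batch`, `draw`, `norm`.
#' @export
batch_effect_norms <- function(bias) {
  stopifnot(inherits(bias, "bias_estimate"))
  if (is.null(bias$gamma_draws)) {
    stop("no batch covariates in this fit", call. = FALSE)
  }
  B1 <- dim(bias$gamma_draws)[2]
  S <- dim(bias$gamma_draws)[3]
  labs <- bias$batches[-1]
  purrr::map_dfr(seq_len(B1), function(b) {
    g <- bias$gamma_draws[, b, , drop = TRUE]
    if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
    tibble::tibble(batch = labs[b], draw = seq_len(S),
                   norm = sqrt(colSums(g^2)))
  })
}

#' Equal-tailed credible summary of posterior draws
#'
#' Mean and equal-tailed quantile interval (linear interpolation of order
#' statistics, `stats::quantile` type 7) per row of a draws matrix, with a
#' flag for intervals excluding zero — the convention used to highlight taxa
#' whose bias is credibly nonzero.
#'
#' @param draws Numeric vector of draws, or matrix with draws in columns
#'   (one row per quantity, e.g. taxa).
#' @param level Credible level (default 0.95).
#' @return Tibble with columns `term`, `mean`, `lower`, `upper`,
#'   `excludes_zero`.
#' @export
credible_summary <- function(draws, level = 0.95) {
  if (!is.matrix(draws)) draws <- matrix(draws, nrow = 1L)
  if (ncol(draws) < 2L) stop("need at least 2 draws", call. = FALSE)
  if (any(!is.finite(draws))) stop("draws must be finite", call. = FALSE)
  a <- (1 - level) / 2
  qs <- t(apply(draws, 1L, stats::quantile, probs = c(a, 1 - a), type = 7))
  dimnames(qs) <- NULL
  terms <- rownames(draws)
  if (is.null(terms)) terms <- as.character(seq_len(nrow(draws)))
  tibble::tibble(
    term = terms,
    mean = rowMeans(draws),
    lower = qs[, 1],
    upper = qs[, 2],
    excludes_zero = qs[, 1] > 0 | qs[, 2] < 0
  )
}
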