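#' Prior specification for the multinomial logistic-normal linear model
#'
#' The model for a taxa-by-samples count table \eqn{Y} with design matrix
#' \eqn{X} (Q covariates by N samples) is
#' \deqn{Y_i \sim Multinomial(\pi_i), \quad \pi_i = C[\exp(\Psi^\dagger \eta_i)],}
#' \deqn{\eta_i \sim N(\Lambda X_i, \Sigma), \quad
#'       \Lambda \sim MN(\Theta, \Sigma, \Gamma), \quad
#'       \Sigma \sim IW(\Xi, \upsilon),}
#' where \eqn{\eta_i} are log-ratio coordinates in a [contrast_basis].
#' `mlnl_prior()` validates \eqn{\Theta} ((D-1) x Q), \eqn{\Gamma} (Q x Q),
#' \eqn{\Xi} ((D-1) x (D-1)) and \eqn{\upsilon}; `default_prior()` builds the
#' weakly-informative default used for calibration analyses:
#' \eqn{\Theta = 0}, \eqn{\Gamma = \sigma^2 I_Q}, \eqn{\Xi = \Psi I_D \Psi^T}
#' (independence of taxa on the log scale) and \eqn{\upsilon = D + 2}.
#'
#' @param theta (D-1) x Q prior mean of the coefficient matrix.
#' @param gamma Q x Q symmetric positive-definite covariate covariance.
#' @param xi (D-1) x (D-1) symmetric positive-definite inverse-Wishart scale.
#' @param upsilon Degrees of freedom; must exceed D - 2 for a proper prior.
#' @param sigma2 Scalar recorded when `gamma` is built as `sigma2 * I`.
#' @return An object of class `mlnl_prior`.
#' @export
mlnl_prior <- function(theta, gamma, xi, upsilon, sigma2 = NULL) {
  theta <- as.matrix(theta); gamma <- as.matrix(gamma); xi <- as.matrix(xi)
  P <- nrow(theta); Q <- ncol(theta); D <- P + 1L
  stopifnot(nrow(gamma) == Q, ncol(gamma) == Q,
            nrow(xi) == P, ncol(xi) == P)
  if (max(abs(gamma - t(gamma))) > 1e-8 || max(abs(xi - t(xi))) > 1e-8) {
    stop("gamma and xi must be symmetric", call. = FALSE)
  }
  if (min(eigen(gamma, symmetric = TRUE, only.values = TRUE)$values) <= 0 ||
      min(eigen(xi, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("gamma and xi must be positive-definite", call. = FALSE)
  }
  if (upsilon <= D - 2) stop("upsilon must exceed D - 2", call. = FALSE)
  structure(list(theta = theta, gamma = gamma, xi = xi,
                 upsilon = upsilon, sigma2 = sigma2),
            class = "mlnl_prior")
}

#' @rdname mlnl_prior
#' @param D Number of taxa.
#' @param Q Number of covariates.
#' @param basis [contrast_basis] defining the log-ratio coordinates.
#' @param gamma Optional Q x Q covariance overriding `sigma2 * I` (e.g. a
#'   diagonal with larger scales on intercept covariates).
#' @export
default_prior <- function(D, Q, basis = alr_basis(D), sigma2 = 10,
                          gamma = NULL) {
  stopifnot(D >= 2, Q >= 1)
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  if (is.null(gamma)) gamma <- diag(sigma2, Q)
  mlnl_prior(theta = matrix(0, D - 1L, Q),
             gamma = gamma,
             xi = basis$psi %*% t(basis$psi),
             upsilon = D + 2,
             sigma2 = sigma2)
}

#' Design matrices with covariate roles
#'
#' Wraps a Q x N design matrix with a role tag per row
#' (`"group_intercept"`, `"cycle"`, or `"batch"`) and covariate labels.
#'
#' @param x Q x N numeric matrix (covariates in rows, samples in columns).
#' @param roles Character vector of length Q.
#' @param labels Covariate names (default from rownames).
#' @return An object of class `mlnl_design`.
#' @export
mlnl_design <- function(x, roles = rep("group_intercept", nrow(x)),
                        labels = rownames(x)) {
  x <- as.matrix(x)
  if (is.null(labels)) labels <- paste0("covariate_", seq_len(nrow(x)))
  stopifnot(length(roles) == nrow(x), length(labels) == nrow(x))
  ok <- roles %in% c("group_intercept", "cycle", "batch")
  if (!all(ok)) stop("unknown covariate role: ", roles[!ok][1], call. = FALSE)
  rownames(x) <- labels
  structure(list(x = x, roles = roles, labels = labels),
            class = "mlnl_design")
}

# log of the multivariate gamma function
lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

#' Collapse the prior over coefficients and covariance
#'
#' Integrating \eqn{\Lambda} and \eqn{\Sigma} out of the model yields a
#' matrix-t prior for the latent log-ratio matrix \eqn{\eta}:
#' \deqn{\eta \sim T(\upsilon;\; \Theta X,\; \Xi,\; I_N + X^T \Gamma X)}
#' with log density (up to the matrix-t normalising constant)
#' \eqn{-\frac{\upsilon+N}{2} \log |\Xi + E K^{-1} E^T|},
#' \eqn{E = \eta - \Theta X}, \eqn{K = I_N + X^T \Gamma X}.  In the scalar
#' case (D-1 = 1, N = 1) this reduces to a Student-t with \eqn{\upsilon}
#' degrees of freedom and squared scale \eqn{\Xi K / \upsilon}.
#'
#' @param prior An [mlnl_prior].
#' @param design An [mlnl_design] (or bare Q x N matrix).
#' @return An object of class `mlnl_collapsed` holding the matrix-t mean,
#'   row scale, column scale, degrees of freedom and cached factorisations.
#' @export
collapse_prior <- function(prior, design) {
  X <- if (inherits(design, "mlnl_design")) design$x else as.matrix(design)
  stopifnot(inherits(prior, "mlnl_prior"), ncol(prior$theta) == nrow(X))
  N <- ncol(X); P <- nrow(prior$theta)
  K <- diag(N) + t(X) %*% prior$gamma %*% X
  K <- (K + t(K)) / 2
  ck <- tryCatch(chol(K), error = function(e) {
    stop(sprintf("column scale I + X'GX is not positive-definite (kappa=%.3g)",
                 kappa(K)), call. = FALSE)
  })
  structure(list(
    mean = prior$theta %*% X,
    row_scale = prior$xi,
    col_scale = K,
    df = prior$upsilon,
    Kinv = chol2inv(ck),
    logdet_K = 2 * sum(log(diag(ck))),
    logdet_xi = as.numeric(determinant(prior$xi, logarithm = TRUE)$modulus),
    N = N, P = P
  ), class = "mlnl_collapsed")
}

# Matrix-t log density of eta under a collapsed prior, with gradient.
matrixt_logdensity <- function(eta, collapsed, gradient = FALSE) {
  P <- collapsed$P; N <- collapsed$N
  E <- eta - collapsed$mean
  ERi <- E %*% collapsed$Kinv
  S <- collapsed$row_scale + ERi %*% t(E)
  S <- (S + t(S)) / 2
  cs <- chol(S)
  up <- collapsed$df
  cst <- -P * N / 2 * log(pi) + lmvgamma((up + N) / 2, P) -
    lmvgamma(up / 2, P) + up / 2 * collapsed$logdet_xi -
    P / 2 * collapsed$logdet_K
  val <- cst - (up + N) / 2 * 2 * sum(log(diag(cs)))
  if (!gradient) return(list(value = val))
  Sinv <- chol2inv(cs)
  list(value = val, gradient = -(up + N) * Sinv %*% ERi,
       Sinv = Sinv, ERi = ERi, E = E)
}

#' Collapsed log posterior of the latent log-ratio matrix
#'
#' Sum over samples of the multinomial log likelihood at
#' \eqn{\pi_i = C[\exp(\Psi^\dagger \eta_i)]} (including the multinomial
#' normalising constants) plus the matrix-t log density of \eqn{\eta} from
#' [collapse_prior()].  The gradient is analytic.
#'
#' @param eta (D-1) x N matrix of log-ratio coordinates.
#' @param counts [count_table] (D x N).
#' @param collapsed An `mlnl_collapsed` prior.
#' @param basis [contrast_basis].
#' @param gradient Return the gradient as well?
#' @return List with `value` and (optionally) `gradient` ((D-1) x N).
#' @export
mlnl_log_posterior <- function(eta, counts, collapsed, basis,
                               gradient = FALSE) {
  eta <- as.matrix(eta)
  if (any(!is.finite(eta))) stop("eta must be finite", call. = FALSE)
  Y <- unclass(counts)
  A <- basis$psi_rinv
  stopifnot(nrow(eta) == collapsed$P, ncol(eta) == collapsed$N,
            nrow(Y) == nrow(A), ncol(Y) == ncol(eta))
  n_i <- colSums(Y)
  O <- A %*% eta                                  # D x N log-parts
  mx <- apply(O, 2L, max)
  lse <- mx + log(colSums(exp(sweep(O, 2L, mx, "-"))))
  ll_const <- sum(lgamma(n_i + 1)) - sum(lgamma(Y + 1))
  ll <- sum(Y * O) - sum(n_i * lse) + ll_const
  mt <- matrixt_logdensity(eta, collapsed, gradient = gradient)
  if (!gradient) return(list(value = ll + mt$value))
  Pm <- exp(sweep(O, 2L, lse, "-"))               # D x N fitted proportions
  g_mult <- t(A) %*% (Y - sweep(Pm, 2L, n_i, "*"))
  list(value = ll + mt$value, gradient = g_mult + mt$gradient)
}

# Analytic Hessian of the collapsed log posterior at eta (PN x PN,
# column-major vec ordering: coordinate l of sample i at (i-1)P + l).
mlnl_hessian <- function(eta, counts, collapsed, basis) {
  P <- collapsed$P; N <- collapsed$N
  Y <- unclass(counts); A <- basis$psi_rinv
  n_i <- colSums(Y)
  O <- A %*% eta
  mx <- apply(O, 2L, max)
  lse <- mx + log(colSums(exp(sweep(O, 2L, mx, "-"))))
  Pm <- exp(sweep(O, 2L, lse, "-"))
  mt <- matrixt_logdensity(eta, collapsed, gradient = TRUE)
  up <- collapsed$df
  cc <- up + N
  U <- mt$Sinv %*% mt$ERi                        # P x N
  W <- t(mt$ERi) %*% U                           # N x N = Kinv E' Sinv E Kinv
  H <- cc * kronecker(W - collapsed$Kinv, mt$Sinv)
  li <- rep(seq_len(P), N)
  ii <- rep(seq_len(N), each = P)
  A1 <- U[li, ii, drop = FALSE]
  H <- H + cc * (A1 * t(A1))
  # multinomial blocks (block-diagonal per sample)
  for (i in seq_len(N)) {
    if (n_i[i] == 0) next
    p <- Pm[, i]
    Ap <- t(A) %*% p
    Bi <- -n_i[i] * (t(A) %*% (p * A) - Ap %*% t(Ap))
    idx <- (i - 1L) * P + seq_len(P)
    H[idx, idx] <- H[idx, idx] + Bi
  }
  (H + t(H)) / 2
}

# MAP of the collapsed posterior: L-BFGS with analytic gradient, then Newton
# polish to the stated gradient tolerance.
mlnl_map <- function(counts, collapsed, basis, eta_init = NULL,
                     grad_tol = 1e-6, max_iter = 1e4) {
  P <- collapsed$P; N <- collapsed$N
  Y <- unclass(counts)
  if (is.null(eta_init)) {
    eta_init <- basis$psi %*% log(closure(Y + 0.5))  # initialisation only
  }
  fn <- function(v) {
    -mlnl_log_posterior(matrix(v, P, N), counts, collapsed, basis)$value
  }
  gr <- function(v) {
    -as.numeric(mlnl_log_posterior(matrix(v, P, N), counts, collapsed, basis,
                                   gradient = TRUE)$gradient)
  }
  opt <- stats::optim(as.numeric(eta_init), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 10))
  eta <- matrix(opt$par, P, N)
  # scale-aware tolerance: the likelihood curvature grows with sample depth,
  # so a gradient of grad_tol * depth moves eta by about grad_tol
  tol <- grad_tol * max(1, max(colSums(Y)))
  H <- NULL
  for (it in seq_len(50L)) {
    lp <- mlnl_log_posterior(eta, counts, collapsed, basis, gradient = TRUE)
    g <- lp$gradient
    if (sqrt(sum(g^2)) <= tol) break
    H <- mlnl_hessian(eta, counts, collapsed, basis)
    step <- tryCatch(
      solve(-H + diag(1e-8, P * N), as.numeric(g)),
      error = function(e) NULL)
    if (is.null(step)) break
    f0 <- lp$value
    alpha <- 1
    repeat {
      cand <- eta + matrix(alpha * step, P, N)
      f1 <- mlnl_log_posterior(cand, counts, collapsed, basis)$value
      if (is.finite(f1) && f1 >= f0) { eta <- cand; break }
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    if (alpha < 1e-8) break
    H <- NULL
  }
  lp <- mlnl_log_posterior(eta, counts, collapsed, basis, gradient = TRUE)
  gnorm <- sqrt(sum(lp$gradient^2))
  if (gnorm > max(tol, 1e-3)) {
    stop(sprintf(paste0("MAP optimisation did not converge: |grad| = %.3g ",
                        "(tolerance %.3g) after L-BFGS + Newton polish"),
                 gnorm, tol), call. = FALSE)
  }
  if (is.null(H)) H <- mlnl_hessian(eta, counts, collapsed, basis)
  list(eta = eta, value = lp$value, gradient_norm = gnorm, hessian = H,
       optim = opt)
}

#' Fit the multinomial logistic-normal linear model
#'
#' Posterior inference for the model of [mlnl_prior()]: the latent log-ratio
#' matrix \eqn{\eta} is estimated by quasi-Newton maximisation of the
#' collapsed log posterior (multinomial likelihood times matrix-t prior), a
#' Laplace (Gaussian) approximation at the mode provides joint draws of
#' \eqn{\eta}, and the conjugate matrix-normal / inverse-Wishart updates of
#' [uncollapse()] convert each \eqn{\eta} draw into draws of \eqn{\Lambda}
#' and \eqn{\Sigma}.  Zero counts are handled natively by the multinomial
#' likelihood; no pseudo-counts are involved anywhere.
#'
#' @param counts [count_table], D taxa x N samples.
#' @param design [mlnl_design] (Q x N) matching the samples of `counts`.
#' @param prior [mlnl_prior]; default from [default_prior()].
#' @param basis [contrast_basis]; default ALR with the last taxon as
#'   reference.
#' @param n_draws Number of posterior draws.
#' @param seed Integer seed; the fit is byte-reproducible given the seed.
#' @return An object of class `mlnl_fit` with elements `eta_draws`
#'   ((D-1) x N x S), `lambda_draws` ((D-1) x Q x S), `sigma_draws`
#'   ((D-1) x (D-1) x S), `map_eta`, `log_marginal`, `basis`, `design`,
#'   `prior`, `taxa`, `seed`.
#' @export
mlnl_fit <- function(counts, design, prior = NULL, basis = NULL,
                     n_draws = 2000, seed = 1) {
  stopifnot(inherits(counts, "count_table"), n_draws >= 1)
  if (!inherits(design, "mlnl_design")) design <- mlnl_design(as.matrix(design))
  D <- nrow(counts); N <- ncol(counts); Q <- nrow(design$x)
  if (ncol(design$x) != N) stop("design and counts disagree on N", call. = FALSE)
  if (is.null(basis)) basis <- alr_basis(D)
  if (is.null(prior)) prior <- default_prior(D, Q, basis)
  collapsed <- collapse_prior(prior, design)
  mp <- mlnl_map(counts, collapsed, basis)
  P <- D - 1L
  Cmat <- -mp$hessian + diag(1e-8, P * N)
  R <- tryCatch(chol(Cmat), error = function(e) {
    stop(paste0("Hessian at the mode is not negative-definite even after ",
                "jitter; consider a stronger prior (smaller sigma2 / larger ",
                "upsilon)"), call. = FALSE)
  })
  log_marginal <- mp$value + P * N / 2 * log(2 * pi) - sum(log(diag(R)))
  draws <- withr::with_seed(seed, {
    Z <- matrix(stats::rnorm(P * N * n_draws), P * N, n_draws)
    eta_flat <- as.numeric(mp$eta) + backsolve(R, Z)
    eta_draws <- array(eta_flat, dim = c(P, N, n_draws))
    uc <- uncollapse(eta_draws, design, prior, collapsed = collapsed)
    list(eta = eta_draws, lambda = uc$lambda_draws, sigma = uc$sigma_draws)
  })
  dimnames(draws$eta) <- list(NULL, colnames(counts), NULL)
  dimnames(draws$lambda) <- list(NULL, design$labels, NULL)
  structure(list(
    eta_draws = draws$eta, lambda_draws = draws$lambda,
    sigma_draws = draws$sigma, basis = basis, map_eta = mp$eta,
    log_marginal = log_marginal, design = design, prior = prior,
    taxa = rownames(counts), n_draws = n_draws, seed = seed,
    method = "laplace"
  ), class = "mlnl_fit")
}

#' @export
print.mlnl_fit <- function(x, ...) {
  cat(sprintf(
    "<mlnl_fit> D=%d taxa, N=%d samples, Q=%d covariates, %d draws (%s)\n",
    length(x$taxa), dim(x$eta_draws)[2], dim(x$lambda_draws)[2],
    dim(x$eta_draws)[3], x$method))
  cat(sprintf("  log marginal likelihood (Laplace): %.3f\n", x$log_marginal))
  invisible(x)
}

#' Recover coefficient and covariance draws from latent draws
#'
#' Given draws of \eqn{\eta}, applies the conjugate updates of the
#' multivariate Bayesian regression \eqn{\eta = \Lambda X + E}:
#' \eqn{\Sigma \mid \eta \sim IW(\Xi + E K^{-1} E^T, \upsilon + N)} and
#' \eqn{\Lambda \mid \Sigma, \eta \sim MN(\Theta_N, \Sigma, \Gamma_N)} with
#' \eqn{\Gamma_N = (\Gamma^{-1} + X X^T)^{-1}} and
#' \eqn{\Theta_N = (\Theta \Gamma^{-1} + \eta X^T)\Gamma_N}.
#'
#' @param eta_draws (D-1) x N x S array (a single matrix is promoted).
#' @param design [mlnl_design] or Q x N matrix.
#' @param prior [mlnl_prior].
#' @param collapsed Optional precomputed [collapse_prior()] result.
#' @return List with `lambda_draws` ((D-1) x Q x S) and `sigma_draws`
#'   ((D-1) x (D-1) x S).  Uses the current RNG stream.
#' @export
uncollapse <- function(eta_draws, design, prior, collapsed = NULL) {
  X <- if (inherits(design, "mlnl_design")) design$x else as.matrix(design)
  if (is.matrix(eta_draws)) {
    eta_draws <- array(eta_draws, dim = c(dim(eta_draws), 1L))
  }
  P <- dim(eta_draws)[1]; N <- dim(eta_draws)[2]; S <- dim(eta_draws)[3]
  Q <- nrow(X)
  if (is.null(collapsed)) collapsed <- collapse_prior(prior, design)
  Ginv <- chol2inv(chol(prior$gamma))
  Gn <- chol2inv(chol(Ginv + X %*% t(X)))
  Gn <- (Gn + t(Gn)) / 2
  cGn <- chol(Gn)
  TGinv <- prior$theta %*% Ginv
  M0 <- prior$theta %*% X
  upN <- prior$upsilon + N
  lambda <- array(NA_real_, c(P, Q, S))
  sigma <- array(NA_real_, c(P, P, S))
  for (s in seq_len(S)) {
    eta <- eta_draws[, , s, drop = FALSE]; dim(eta) <- c(P, N)
    E <- eta - M0
    XiN <- prior$xi + (E %*% collapsed$Kinv) %*% t(E)
    XiN <- (XiN + t(XiN)) / 2
    Wdraw <- stats::rWishart(1, upN, chol2inv(chol(XiN)))[, , 1]
    Sig <- chol2inv(chol(Wdraw))
    Sig <- (Sig + t(Sig)) / 2
    ThN <- (TGinv + eta %*% t(X)) %*% Gn
    Z <- matrix(stats::rnorm(P * Q), P, Q)
    lambda[, , s] <- ThN + t(chol(Sig)) %*% Z %*% cGn
    sigma[, , s] <- Sig
  }
  list(lambda_draws = lambda, sigma_draws = sigma)
}

#' Laplace estimate of the log marginal likelihood
#'
#' \eqn{\log p(Y) \approx \log p(Y, \hat\eta) + \frac{d}{2}\log 2\pi
#' - \frac{1}{2}\log|-H|} at the collapsed MAP \eqn{\hat\eta}, with the
#' multinomial normalising constants included.  Used for hyperparameter
#' selection by [select_scale()].
#'
#' @inheritParams mlnl_fit
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(counts, design, prior, basis = NULL) {
  if (!inherits(design, "mlnl_design")) design <- mlnl_design(as.matrix(design))
  D <- nrow(counts)
  if (is.null(basis)) basis <- alr_basis(D)
  collapsed <- collapse_prior(prior, design)
  mp <- mlnl_map(counts, collapsed, basis)
  P <- D - 1L; N <- ncol(counts)
  R <- chol(-mp$hessian + diag(1e-8, P * N))
  mp$value + P * N / 2 * log(2 * pi) - sum(log(diag(R)))
}

#' Select the prior scale by maximum marginal likelihood
#'
#' Profiles the Laplace log marginal likelihood over a grid of values of
#' \eqn{\sigma^2}, the scalar multiplying the covariate covariance
#' \eqn{\Gamma = \sigma^2 \Gamma_{unit}} (default \eqn{\Gamma_{unit} = I_Q}).
#'
#' @inheritParams mlnl_fit
#' @param sigma2_grid Positive values of \eqn{\sigma^2} to profile.
#' @param gamma_unit Optional Q x Q unit structure scaled by each grid value.
#' @return List with `sigma2` (the smallest maximiser, with a warning on
#'   ties) and `profile`, a tibble with columns `sigma2`, `log_marginal`.
#' @export
select_scale <- function(counts, design, basis = NULL, sigma2_grid,
                         gamma_unit = NULL) {
  if (!inherits(design, "mlnl_design")) design <- mlnl_design(as.matrix(design))
  stopifnot(length(sigma2_grid) >= 1, all(sigma2_grid > 0))
  D <- nrow(counts); Q <- nrow(design$x)
  if (is.null(basis)) basis <- alr_basis(D)
  if (is.null(gamma_unit)) gamma_unit <- diag(Q)
  grid <- sort(unique(as.numeric(sigma2_grid)))
  lml <- vapply(grid, function(s2) {
    prior <- default_prior(D, Q, basis, sigma2 = s2,
                           gamma = s2 * gamma_unit)
    log_marginal_likelihood(counts, design, prior, basis)
  }, numeric(1))
  best <- which(lml >= max(lml) - 1e-9)
  if (length(best) > 1L) {
    warning("marginal-likelihood profile has ties; returning the smallest ",
            "maximiser", call. = FALSE)
  }
  list(sigma2 = grid[min(best)],
       profile = tibble::tibble(sigma2 = grid, log_marginal = lml))
}
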