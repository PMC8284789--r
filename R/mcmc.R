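#' Reference MCMC sampler for the multinomial logistic-normal model
#'
#' Asymptotically exact posterior draws of \eqn{\eta}, \eqn{\Lambda} and
#' \eqn{\Sigma} obtained by Gibbs/slice sampling the *uncollapsed* model
#' (multinomial likelihood, normal latent, matrix-normal coefficients,
#' inverse-Wishart covariance) in JAGS.  Intended as a correctness oracle for
#' the Laplace scheme of [mlnl_fit()] on small instances (D <= 10, N <= 50
#' advisory); it is orders of magnitude slower at scale.
#'
#' The matrix-normal prior is encoded by a latent \eqn{N(0, \Sigma)} column
#' per covariate scaled by \eqn{\sqrt{\Gamma_{qq}}}, which requires a
#' diagonal \eqn{\Gamma} (the only form used in calibration analyses).
#' Samples with zero total counts contribute no likelihood term and are
#' sampled from the prior, matching the collapsed treatment.
#'
#' @inheritParams mlnl_fit
#' @param chains Number of chains (split across for convergence checks).
#' @param n_iter Post-warmup iterations per chain.
#' @param n_warmup Warmup (burn-in) iterations per chain.
#' @param thin Thinning interval.
#' @return An `mlnl_fit` object (`method = "mcmc"`) whose draws pool all
#'   chains; element `rhat` holds per-parameter potential scale reduction
#'   factors.  A warning is attached when any R-hat exceeds 1.05.
#' @export
fit_reference_mcmc <- function(counts, design, prior = NULL, basis = NULL,
                               chains = 4, seed = 1, n_iter = 4000,
                               n_warmup = 2000, thin = 1) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    stop("fit_reference_mcmc requires the rjags package", call. = FALSE)
  }
  stopifnot(inherits(counts, "count_table"))
  if (!inherits(design, "mlnl_design")) design <- mlnl_design(as.matrix(design))
  D <- nrow(counts); N <- ncol(counts); Q <- nrow(design$x)
  P <- D - 1L
  if (is.null(basis)) basis <- alr_basis(D)
  if (is.null(prior)) prior <- default_prior(D, Q, basis)
  gd <- diag(prior$gamma)
  if (max(abs(prior$gamma - diag(gd, Q))) > 1e-12) {
    stop("the MCMC reference sampler supports diagonal gamma only",
         call. = FALSE)
  }
  Y <- unclass(counts)
  ntot <- colSums(Y)
  obs <- which(ntot > 0)
  lik <- if (length(obs) > 0) "
  for (k in 1:Nobs) {
    Y[1:D, oidx[k]] ~ dmulti(p[1:D, oidx[k]], ntot[oidx[k]])
  }" else ""
  model_str <- paste0("model {", lik, "
  for (i in 1:N) {
    for (j in 1:D) {
      e[j, i] <- exp(inprod(A[j, 1:P], eta[1:P, i]))
      p[j, i] <- e[j, i] / se[i]
    }
    se[i] <- sum(e[1:D, i])
    eta[1:P, i] ~ dmnorm(mu[1:P, i], Omega[1:P, 1:P])
    for (l in 1:P) { mu[l, i] <- inprod(Lambda[l, 1:Q], X[1:Q, i]) }
  }
  for (q in 1:Q) {
    Z[1:P, q] ~ dmnorm(zeroP[1:P], Omega[1:P, 1:P])
    for (l in 1:P) { Lambda[l, q] <- Theta[l, q] + sqrtg[q] * Z[l, q] }
  }
  Omega ~ dwish(Xi[1:P, 1:P], upsilon)
}")
  dat <- list(A = basis$psi_rinv, X = design$x, N = N, D = D, P = P, Q = Q,
              zeroP = rep(0, P), Theta = prior$theta, sqrtg = sqrt(gd),
              Xi = prior$xi, upsilon = prior$upsilon)
  if (length(obs) > 0) {
    dat$Y <- Y; dat$ntot <- ntot; dat$oidx <- obs; dat$Nobs <- length(obs)
  }
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 1000L + ch) %% .Machine$integer.max)
  })
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          n.chains = chains, inits = inits, quiet = TRUE)
  stats::update(jm, n_warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("eta", "Lambda", "Omega"),
                              n.iter = n_iter, thin = thin,
                              progress.bar = "none")
  rhat <- tryCatch(
    coda::gelman.diag(samp, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1],
    error = function(e) NULL)
  if (!is.null(rhat) && any(rhat > 1.05, na.rm = TRUE)) {
    warning(sprintf("MCMC convergence suspect: max R-hat = %.3f",
                    max(rhat, na.rm = TRUE)), call. = FALSE)
  }
  mat <- do.call(rbind, lapply(samp, as.matrix))
  S <- nrow(mat)
  pick <- function(prefix, d1, d2) {
    out <- array(NA_real_, c(d1, d2, S))
    for (a in seq_len(d1)) for (b in seq_len(d2)) {
      out[a, b, ] <- mat[, sprintf("%s[%d,%d]", prefix, a, b)]
    }
    out
  }
  eta_draws <- pick("eta", P, N)
  lambda_draws <- pick("Lambda", P, Q)
  omega <- pick("Omega", P, P)
  sigma_draws <- array(apply(omega, 3, function(om) chol2inv(chol(om))),
                       c(P, P, S))
  dimnames(eta_draws) <- list(NULL, colnames(counts), NULL)
  dimnames(lambda_draws) <- list(NULL, design$labels, NULL)
  structure(list(
    eta_draws = eta_draws, lambda_draws = lambda_draws,
    sigma_draws = sigma_draws, basis = basis,
    map_eta = apply(eta_draws, c(1, 2), stats::median),
    log_marginal = NA_real_, design = design, prior = prior,
    taxa = rownames(counts), n_draws = S, seed = seed,
    method = "mcmc", rhat = rhat
  ), class = "mlnl_fit")
}
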