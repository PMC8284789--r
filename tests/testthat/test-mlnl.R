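test_that("default prior matches the calibration conventions", {
  b10 <- alr_basis(10)
  pr <- default_prior(10, 15, b10, sigma2 = 10)
  expect_equal(pr$gamma, diag(10, 15))
  expect_equal(pr$upsilon, 12)
  expect_equal(pr$theta, matrix(0, 9, 15))
  # explicit Psi Psi^T for ALR rows (1,0,-1), (0,1,-1)
  pr3 <- default_prior(3, 2, alr_basis(3))
  expect_equal(pr3$xi, rbind(c(2, 1), c(1, 2)))
  # study-specific diagonal override with unequal intercept/other scales
  g_h <- diag(c(4, 4, 4, 4, 1, 1, 1, 1, 1))
  prh <- default_prior(10, 9, b10, gamma = g_h)
  expect_equal(prh$gamma, g_h)
  expect_error(default_prior(3, 2, sigma2 = -1), "positive")
  expect_error(mlnl_prior(matrix(0, 2, 2), diag(2), diag(2), upsilon = 0.5),
               "upsilon")
})

test_that("collapsed matrix-t equals double quadrature in the scalar case", {
  withr::with_seed(10, for (i in 1:8) {
    xi <- runif(1, 0.5, 3); up <- runif(1, 2, 6); g <- runif(1, 0.5, 5)
    x <- runif(1, -2, 2); th <- runif(1, -1, 1); eta <- runif(1, -3, 3)
    prior <- mlnl_prior(matrix(th, 1, 1), matrix(g, 1, 1), matrix(xi, 1, 1),
                        upsilon = up)
    col <- collapse_prior(prior, matrix(x, 1, 1))
    got <- pcrcal:::matrixt_logdensity(matrix(eta, 1, 1), col)$value
    want <- matrixt_quadrature(eta, x, th, g, xi, up)
    expect_equal(got, want, tolerance = 1e-6)
  })
})

test_that("collapse limits and shapes behave", {
  X <- rbind(1, c(0, 1, 2))
  prior0 <- mlnl_prior(matrix(0, 2, 2), diag(1e-12, 2), diag(2), upsilon = 5)
  col0 <- collapse_prior(prior0, X)
  expect_equal(col0$col_scale, diag(3), tolerance = 1e-9)
  withr::with_seed(11, for (i in 1:10) {
    Q <- sample(1:4, 1); N <- sample(2:8, 1)
    Xr <- matrix(rnorm(Q * N), Q, N)
    G <- crossprod(matrix(rnorm(Q * Q), Q)) + diag(0.1, Q)
    pr <- mlnl_prior(matrix(0, 3, Q), G, diag(3), upsilon = 7)
    K <- collapse_prior(pr, Xr)$col_scale
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
  })
})

test_that("collapsed log posterior has an exact gradient and handles zeros", {
  withr::with_seed(12, {
    D <- 4; P <- 3; N <- 5
    X <- rbind(1, seq_len(N))
    basis <- alr_basis(D)
    prior <- default_prior(D, 2, basis, sigma2 = 3)
    col <- collapse_prior(prior, X)
    Y <- matrix(rpois(D * N, 20), D, N)
    Y[sample(D * N, 8)] <- 0L      # heavy zeros, no pseudo-counts
    ct <- count_table(Y)
    for (i in 1:5) {
      eta <- matrix(rnorm(P * N), P, N)
      lp <- mlnl_log_posterior(eta, ct, col, basis, gradient = TRUE)
      fn <- function(v) {
        mlnl_log_posterior(matrix(v, P, N), ct, col, basis)$value
      }
      g_fd <- numDeriv::grad(fn, as.numeric(eta))
      expect_equal(as.numeric(lp$gradient), g_fd, tolerance = 1e-5)
      expect_true(is.finite(lp$value))
    }
    # an all-zero sample contributes only the prior term
    Y0 <- Y; Y0[, 3] <- 0L
    ct0 <- count_table(Y0)
    eta <- matrix(rnorm(P * N), P, N)
    prior_only <- pcrcal:::matrixt_logdensity(eta, col)$value
    Yno <- Y0; Yno[, ] <- 0L
    expect_equal(mlnl_log_posterior(eta, count_table(Yno), col, basis)$value,
                 prior_only, tolerance = 1e-10)
    # analytic Hessian agrees with finite differences of the gradient
    H <- pcrcal:::mlnl_hessian(eta, ct, col, basis)
    H_fd <- numDeriv::hessian(function(v) {
      mlnl_log_posterior(matrix(v, P, N), ct, col, basis)$value
    }, as.numeric(eta))
    expect_equal(H, H_fd, tolerance = 1e-4)
  })
})

test_that("fit respects symmetry, determinism, and sparse tables", {
  # equal counts everywhere + exchangeable prior -> uniform posterior mean
  D <- 4; N <- 6
  Y <- matrix(50L, D, N)
  ct <- count_table(Y)
  des <- mlnl_design(matrix(1, 1, N))
  basis <- contrast_basis(alr_basis(D)$psi)  # MP inverse, exchangeable-ish
  fit <- mlnl_fit(ct, des, default_prior(D, 1, alr_basis(D)), alr_basis(D),
                  n_draws = 1500, seed = 4)
  pbar <- rowMeans(from_logratio(
    matrix(fit$eta_draws, D - 1, N * dim(fit$eta_draws)[3]), fit$basis))
  expect_equal(pbar, rep(1 / D, D), tolerance = 0.02)
  # byte determinism
  fit2 <- mlnl_fit(ct, des, default_prior(D, 1, alr_basis(D)), alr_basis(D),
                   n_draws = 1500, seed = 4)
  expect_identical(fit$eta_draws, fit2$eta_draws)
  expect_identical(fit$lambda_draws, fit2$lambda_draws)
  expect_identical(fit$sigma_draws, fit2$sigma_draws)
  # 50% zero cells: finite fit, no pseudo-counts
  withr::with_seed(13, {
    Yz <- matrix(rpois(5 * 8, 15), 5, 8)
    Yz[sample(40, 20)] <- 0L
  })
  fitz <- mlnl_fit(count_table(Yz), mlnl_design(matrix(1, 1, 8)),
                   n_draws = 200, seed = 1)
  expect_true(all(is.finite(fitz$eta_draws)))
  expect_true(all(is.finite(fitz$lambda_draws)))
})

test_that("uncollapse performs the conjugate updates", {
  withr::with_seed(14, {
    P <- 2; Q <- 2; N <- 40
    X <- rbind(1, rnorm(N))
    basis <- alr_basis(P + 1)
    # gamma -> 0: lambda draws collapse to theta
    th <- matrix(c(1, -1, 2, 0.5), P, Q)
    pr0 <- mlnl_prior(th, diag(1e-10, Q), diag(P), upsilon = 6)
    eta <- matrix(rnorm(P * N), P, N)
    uc0 <- uncollapse(array(eta, c(P, N, 3)), X, pr0)
    for (s in 1:3) expect_equal(uc0$lambda_draws[, , s], th,
                                tolerance = 1e-3)
    # noise-free eta = Lambda0 X with weak prior: posterior mean -> OLS
    L0 <- matrix(c(0.5, -0.2, 0.1, 0.3), P, Q)
    eta_nf <- L0 %*% X
    pr <- mlnl_prior(matrix(0, P, Q), diag(100, Q), diag(P), upsilon = 6)
    uc <- uncollapse(array(rep(eta_nf, 200), c(P, N, 200)), X, pr)
    ols <- t(solve(X %*% t(X), X %*% t(eta_nf)))
    expect_equal(apply(uc$lambda_draws, c(1, 2), mean), ols,
                 tolerance = 0.02)
    expect_equal(ols, L0, tolerance = 1e-9)
    # Sigma | eta moments match the closed-form inverse-Wishart mean
    pr2 <- mlnl_prior(matrix(0, P, Q), diag(2, Q), diag(P), upsilon = 8)
    eta_fix <- matrix(rnorm(P * N), P, N)
    col <- collapse_prior(pr2, X)
    E <- eta_fix
    XiN <- pr2$xi + (E %*% col$Kinv) %*% t(E)
    want_mean <- XiN / (pr2$upsilon + N - P - 1)  # = Xi_N / (upsilon_N - D)
    S <- 4000
    uc2 <- uncollapse(array(rep(eta_fix, S), c(P, N, S)), X, pr2)
    got_mean <- apply(uc2$sigma_draws, c(1, 2), mean)
    mcse <- apply(uc2$sigma_draws, c(1, 2), sd) / sqrt(S)
    expect_true(all(abs(got_mean - want_mean) < 3.5 * mcse))
  })
})

test_that("marginal likelihood is symmetric, Occam-penalised, and IS-consistent", {
  withr::with_seed(15, {
    D <- 3; N <- 8
    X <- rbind(1, scale(seq_len(N))[, 1])
    des <- mlnl_design(X, roles = c("group_intercept", "cycle"))
    basis <- alr_basis(D)
    prior <- default_prior(D, 2, basis, sigma2 = 2)
    Y <- matrix(rpois(D * N, 40), D, N)
    ct <- count_table(Y)
    lml <- log_marginal_likelihood(ct, des, prior, basis)
    # relabeling taxa leaves the marginal unchanged under exchangeable prior
    perm <- c(2, 3, 1)
    ct_perm <- count_table(unclass(ct)[perm, ])
    lml_perm <- log_marginal_likelihood(ct_perm, des, prior, basis)
    expect_equal(lml, lml_perm, tolerance = 1e-4)
    # Occam: with data generated at Lambda = 0, inflating sigma2 can only
    # lower the marginal beyond the optimum
    Y0 <- sapply(1:N, function(i) rmultinom(1, 200, rep(1 / D, D)))
    ct0 <- count_table(Y0)
    grid <- c(1, 10, 100, 1000)
    prof <- sapply(grid, function(s2) {
      log_marginal_likelihood(ct0, des, default_prior(D, 2, basis, s2),
                              basis)
    })
    expect_true(all(diff(prof[-1]) < 0))
    # importance-sampling estimate from the Laplace proposal agrees
    col <- collapse_prior(prior, des$x)
    mp <- pcrcal:::mlnl_map(ct, col, basis)
    P <- D - 1
    R <- chol(-mp$hessian + diag(1e-8, P * N))
    M <- 4000
    Z <- matrix(rnorm(P * N * M), P * N, M)
    draws <- as.numeric(mp$eta) + backsolve(R, Z)
    logq <- -colSums(Z^2) / 2 - P * N / 2 * log(2 * pi) +
      sum(log(diag(R)))
    logp <- apply(draws, 2, function(v) {
      mlnl_log_posterior(matrix(v, P, N), ct, col, basis)$value
    })
    w <- logp - logq
    lml_is <- log(mean(exp(w - max(w)))) + max(w)
    # the residual gap is the Laplace approximation error itself, a fraction
    # of a log unit at these counts -- far below the scale of marginal
    # differences that drive hyperparameter selection
    expect_lt(abs(lml - lml_is), 0.2)
  })
})

test_that("sigma2 selection profiles the grid and handles edge cases", {
  withr::with_seed(16, {
    D <- 3; N <- 12
    X <- rbind(1, scale(rep(1:4, 3))[, 1])
    des <- mlnl_design(X, roles = c("group_intercept", "cycle"))
    basis <- alr_basis(D)
    gen <- default_prior(D, 2, basis, sigma2 = 2)
    sim <- simulate_from_generative(gen, des, basis, depth = 5e3, seed = 21)
    sel <- select_scale(sim$counts, des, basis,
                        sigma2_grid = c(0.5, 2, 8, 32))
    expect_equal(nrow(sel$profile), 4)
    expect_true(sel$sigma2 %in% sel$profile$sigma2)
    one <- select_scale(sim$counts, des, basis, sigma2_grid = 7)
    expect_equal(one$sigma2, 7)
    expect_equal(nrow(one$profile), 1)
  })
})

test_that("fits agree across ALR reference choices after mapping to CLR", {
  withr::with_seed(17, {
    D <- 4; N <- 10
    X <- rbind(1, scale(seq_len(N))[, 1])
    des <- mlnl_design(X, roles = c("group_intercept", "cycle"))
    a <- rand_comp(D)
    Y <- sapply(1:N, function(i) rmultinom(1, 2000, a))
    ct <- count_table(Y)
  })
  fits <- lapply(c(D, 1), function(ref) {
    basis <- alr_basis(D, ref = ref)
    mlnl_fit(ct, des, default_prior(D, 2, basis), basis,
             n_draws = 2000, seed = 30 + ref)
  })
  clr_means <- lapply(fits, function(f) {
    sapply(1:2, function(q) rowMeans(alr_to_clr(f$lambda_draws[, q, ],
                                                f$basis)))
  })
  expect_equal(clr_means[[1]], clr_means[[2]], tolerance = 0.05)
})
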