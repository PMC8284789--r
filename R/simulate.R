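#' Configuration for a simulated calibration experiment
#'
#' Describes a calibration curve with the generative structure the model
#' assumes: a pre-PCR composition `true_a`, per-taxon per-cycle amplification
#' efficiencies `true_b` (2 = perfect doubling), aliquots at each cycle
#' number, multinomial counting at a fixed sequencing depth, logistic-normal
#' technical noise, and optional per-batch CLR perturbations.
#'
#' Defaults emulate a mock-community calibration experiment: 10 taxa, equal
#' starting mixture, efficiencies drawn log-normal around 2 with 0.05 log
#' units of spread (amplification is usually slightly less than a perfect
#' doubling, and taxa differ by a few percent per cycle), cycles 10 to 35
#' with 3 aliquots each, 5e4 reads per sample, and technical noise of 0.1 log
#' units per taxon (a scale at which the calibration curve retains the high
#' reproducibility seen in real calibration experiments).
#'
#' @param D Number of taxa.
#' @param true_a Pre-PCR composition (default: uniform, an equal-amount
#'   pool).
#' @param true_b Positive vector of per-cycle efficiencies (default drawn
#'   log-normal, see above; the draw consumes `seed`).
#' @param cycles Integer cycle numbers sampled by the curve.
#' @param replicates_per_cycle Aliquots sequenced per cycle number.
#' @param depth Reads per sample (scalar or one per sample).
#' @param noise_sigma Logistic-normal noise: either a scalar `s` meaning
#'   independent per-taxon log-scale noise with standard deviation `s`
#'   (ALR covariance \eqn{s^2 \Psi \Psi^T}), or a full (D-1) x (D-1)
#'   covariance matrix in the ALR basis.  Zero disables noise.
#' @param batch_effects Optional list of CLR perturbation vectors (length D,
#'   zero-sum), one per batch after the reference batch; samples are
#'   assigned to batches round-robin.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(D = 10, true_a = NULL, true_b = NULL,
                               cycles = 10:35, replicates_per_cycle = 3,
                               depth = 5e4, noise_sigma = 0.1,
                               batch_effects = NULL, seed = 1) {
  stopifnot(D >= 2, all(cycles >= 0), all(depth >= 0),
            replicates_per_cycle >= 1)
  if (is.null(true_a)) true_a <- rep(1 / D, D)
  check_composition(true_a)
  if (is.null(true_b)) {
    true_b <- withr::with_seed(seed * 7L + 1L,
                               exp(log(2) + stats::rnorm(D, 0, 0.05)))
  }
  if (length(true_b) != D || any(true_b <= 0)) {
    stop("true_b must be D positive efficiencies", call. = FALSE)
  }
  if (length(true_a) != D) stop("true_a must have D parts", call. = FALSE)
  if (is.matrix(noise_sigma)) {
    stopifnot(nrow(noise_sigma) == D - 1L, ncol(noise_sigma) == D - 1L)
    ev <- eigen(noise_sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("noise covariance must be PSD", call. = FALSE)
  } else {
    stopifnot(length(noise_sigma) == 1L, noise_sigma >= 0)
  }
  if (!is.null(batch_effects)) {
    ok <- vapply(batch_effects, function(v) {
      length(v) == D && abs(sum(v)) < 1e-6
    }, logical(1))
    if (!all(ok)) stop("batch effects must be zero-sum CLR vectors of ",
                       "length D", call. = FALSE)
  }
  structure(list(D = as.integer(D), true_a = true_a, true_b = true_b,
                 cycles = as.integer(cycles),
                 replicates_per_cycle = as.integer(replicates_per_cycle),
                 depth = depth, noise_sigma = noise_sigma,
                 batch_effects = batch_effects, seed = as.integer(seed)),
            class = "calibration_config")
}

.noise_chol <- function(config, basis) {
  if (is.matrix(config$noise_sigma)) {
    if (max(abs(config$noise_sigma)) == 0) return(NULL)
    ev <- eigen(config$noise_sigma, symmetric = TRUE)
    return(ev$vectors %*% diag(sqrt(pmax(ev$values, 0)),
                               length(ev$values)))
  }
  if (config$noise_sigma == 0) return(NULL)
  Sig <- config$noise_sigma^2 * basis$psi %*% t(basis$psi)
  t(chol(Sig))
}

#' Simulate a calibration curve
#'
#' For each aliquot at cycle \eqn{x}: the expected composition is
#' \eqn{C[a \odot b^x]} (each taxon's template grows geometrically with its
#' own efficiency); its log-ratio coordinates receive logistic-normal noise
#' and any batch perturbation; counts are multinomial at the configured
#' depth.  Fully reproducible from the config seed.
#'
#' @param config A [calibration_config()].
#' @param basis Optional [contrast_basis] for the noise coordinates (default
#'   ALR, reference last).
#' @return List with `counts` ([count_table]), `metadata` (tibble:
#'   `sample_id`, `cycle`, `group`, `batch`), and `truth` (list: `a`, `b`,
#'   `alpha`, `beta` — the true intercept and slope in `basis` coordinates —
#'   plus `expected_eta`, `basis`, `batch_effects`).
#' @export
simulate_calibration <- function(config, basis = NULL) {
  stopifnot(inherits(config, "calibration_config"))
  D <- config$D
  if (is.null(basis)) basis <- alr_basis(D)
  cyc <- rep(config$cycles, each = config$replicates_per_cycle)
  N <- length(cyc)
  depth <- rep(config$depth, length.out = N)
  n_batch <- if (is.null(config$batch_effects)) 1L else
    length(config$batch_effects) + 1L
  batch <- paste0("machine_", rep_len(seq_len(n_batch), N))
  taxa <- paste0("taxon_", seq_len(D))
  alpha_true <- to_logratio(config$true_a, basis)
  beta_true <- drop(basis$psi %*% log(config$true_b))
  L <- .noise_chol(config, basis)
  out <- withr::with_seed(config$seed, {
    Y <- matrix(0L, D, N)
    eta_exp <- matrix(0, D - 1L, N)
    for (i in seq_len(N)) {
      eta <- alpha_true + beta_true * cyc[i]
      eta_exp[, i] <- eta
      if (!is.null(L)) eta <- eta + drop(L %*% stats::rnorm(D - 1L))
      b_i <- rep_len(seq_len(n_batch), N)[i]
      if (b_i > 1L) {
        eta <- eta + drop(basis$psi %*% config$batch_effects[[b_i - 1L]])
      }
      p <- from_logratio(eta, basis)
      Y[, i] <- stats::rmultinom(1, depth[i], p)
    }
    Y
  })
  rownames(out) <- taxa
  colnames(out) <- sprintf("cal_c%02d_r%d", cyc,
                           stats::ave(cyc, cyc, FUN = seq_along))
  metadata <- tibble::tibble(
    sample_id = colnames(out), cycle = as.integer(cyc),
    group = "calibration", batch = batch)
  list(
    counts = count_table(out),
    metadata = metadata,
    truth = list(a = stats::setNames(config$true_a, taxa),
                 b = stats::setNames(config$true_b, taxa),
                 alpha = alpha_true, beta = beta_true,
                 expected_eta = NULL, basis = basis,
                 batch_effects = config$batch_effects),
    config = config
  )
}

#' Draw a random composition with bounded fold change
#'
#' Samples uniformly from the simplex (flat Dirichlet) by rejection,
#' conditioned on the maximum fold change between any two parts being at
#' most `max_fold` — the constraint used when assembling random mock
#' communities within the dynamic range of laboratory pipettes.
#'
#' @param D Number of parts.
#' @param max_fold Maximum allowed ratio max(p)/min(p); must exceed 1.
#' @param seed Optional seed (uses the current RNG stream when `NULL`).
#' @param max_attempts Rejection cap before giving up.
#' @return A composition of length D satisfying the constraint.
#' @export
draw_constrained_composition <- function(D, max_fold = 10, seed = NULL,
                                         max_attempts = 1e6) {
  stopifnot(D >= 2, max_fold > 1)
  draw <- function() {
    for (i in seq_len(max_attempts)) {
      p <- stats::rgamma(D, 1)   # flat Dirichlet after closure
      p <- p / sum(p)
      if (max(p) / min(p) <= max_fold) return(p)
    }
    stop(sprintf("no draw satisfied max fold %.1f in %d attempts (D = %d ",
                 max_fold, max_attempts, D),
         "is likely too large for the constraint)", call. = FALSE)
  }
  p <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  stopifnot(max(p) / min(p) <= max_fold)
  p
}

#' Simulate a full mock-community study
#'
#' A calibration curve (equal-amount pooled sample, aliquots at each cycle)
#' plus `n_mock` held-out mock communities with random constrained
#' compositions, all amplified with the same per-taxon efficiencies; the
#' mock communities undergo `mock_cycles` cycles of PCR.  Ground truth is
#' bundled so downstream evaluation never re-derives it.
#'
#' @param D,cycles,replicates_per_cycle,depth,noise_sigma,true_b,seed As in
#'   [calibration_config()].
#' @param n_mock Number of held-out mock communities.
#' @param mock_cycles Cycles of PCR applied to the mock communities.
#' @param max_fold Fold-change constraint for random mock compositions.
#' @param basis Optional [contrast_basis].
#' @return List with `counts` (calibration + mock samples), `metadata`,
#'   `truth` (calibration truth plus `mock_compositions`, D x n_mock), and
#'   `config`.
#' @export
simulate_mock_study <- function(D = 10, n_mock = 10, cycles = 10:35,
                                replicates_per_cycle = 3, depth = 5e4,
                                noise_sigma = 0.1, mock_cycles = 35,
                                max_fold = 10, true_b = NULL, seed = 1,
                                basis = NULL) {
  config <- calibration_config(D = D, cycles = cycles,
                               replicates_per_cycle = replicates_per_cycle,
                               depth = depth, noise_sigma = noise_sigma,
                               true_b = true_b, seed = seed)
  if (is.null(basis)) basis <- alr_basis(D)
  cal <- simulate_calibration(config, basis)
  beta_true <- cal$truth$beta
  L <- .noise_chol(config, basis)
  mock <- withr::with_seed(seed * 13L + 3L, {
    comps <- sapply(seq_len(n_mock), function(k) {
      draw_constrained_composition(D, max_fold)
    })
    Y <- matrix(0L, D, n_mock)
    for (k in seq_len(n_mock)) {
      eta <- to_logratio(comps[, k], basis) + beta_true * mock_cycles
      if (!is.null(L)) eta <- eta + drop(L %*% stats::rnorm(D - 1L))
      Y[, k] <- stats::rmultinom(1, rep(depth, length.out = n_mock)[k],
                                 from_logratio(eta, basis))
    }
    list(comps = comps, Y = Y)
  })
  taxa <- rownames(cal$counts)
  rownames(mock$Y) <- taxa
  rownames(mock$comps) <- taxa
  colnames(mock$Y) <- sprintf("mock_%02d", seq_len(n_mock))
  colnames(mock$comps) <- colnames(mock$Y)
  counts <- count_table(cbind(unclass(cal$counts), mock$Y))
  metadata <- rbind(
    cal$metadata,
    tibble::tibble(sample_id = colnames(mock$Y),
                   cycle = as.integer(mock_cycles),
                   group = colnames(mock$Y),
                   batch = "machine_1"))
  truth <- cal$truth
  truth$mock_compositions <- mock$comps
  truth$mock_cycles <- mock_cycles
  list(counts = counts, metadata = metadata, truth = truth, config = config)
}

#' Simulate counts from the full generative model
#'
#' Draws \eqn{\Sigma \sim IW(\Xi, \upsilon)},
#' \eqn{\Lambda \sim MN(\Theta, \Sigma, \Gamma)},
#' \eqn{\eta_i \sim N(\Lambda X_i, \Sigma)} and
#' \eqn{Y_i \sim Multinomial(depth_i, \phi^{-1}(\eta_i))}.  Used for
#' parameter-recovery and posterior-coverage studies, where fitting with the
#' same prior should give nominal credible-interval coverage.
#'
#' @param prior [mlnl_prior].
#' @param design [mlnl_design] or Q x N matrix.
#' @param basis Optional [contrast_basis].
#' @param depth Reads per sample (scalar or length N; 0 gives all-zero
#'   counts, the prior-predictive edge case).
#' @param seed Integer seed.
#' @return List with `counts` ([count_table]) and `truth` (list: `lambda`,
#'   `sigma`, `eta`).
#' @export
simulate_from_generative <- function(prior, design, basis = NULL,
                                     depth = 5e4, seed = 1) {
  stopifnot(inherits(prior, "mlnl_prior"))
  X <- if (inherits(design, "mlnl_design")) design$x else as.matrix(design)
  P <- nrow(prior$theta); D <- P + 1L; N <- ncol(X)
  if (is.null(basis)) basis <- alr_basis(D)
  depth <- rep(depth, length.out = N)
  withr::with_seed(seed, {
    W <- stats::rWishart(1, prior$upsilon, chol2inv(chol(prior$xi)))[, , 1]
    Sig <- chol2inv(chol(W)); Sig <- (Sig + t(Sig)) / 2
    Lsig <- t(chol(Sig))
    Lam <- prior$theta +
      Lsig %*% matrix(stats::rnorm(P * ncol(prior$gamma)), P) %*%
      chol(prior$gamma)
    eta <- Lam %*% X + Lsig %*% matrix(stats::rnorm(P * N), P, N)
    Pi <- from_logratio(eta, basis)
    Y <- vapply(seq_len(N), function(i) {
      if (depth[i] == 0) integer(D) else
        as.integer(stats::rmultinom(1, depth[i], Pi[, i]))
    }, integer(D))
    rownames(Y) <- paste0("taxon_", seq_len(D))
    colnames(Y) <- paste0("sample_", seq_len(N))
    list(counts = count_table(Y),
         truth = list(lambda = Lam, sigma = Sig, eta = eta))
  })
}
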