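# Shared fixtures and independent oracles, all built in code.

# random strictly positive composition
rand_comp <- function(D) {
  p <- stats::rgamma(D, 2)
  p / sum(p)
}

# textbook dynamic-programming Levenshtein distance (test oracle for adist)
lev_brute <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  m <- matrix(0L, length(a) + 1L, length(b) + 1L)
  m[, 1] <- 0:length(a); m[1, ] <- 0:length(b)
  for (i in seq_along(a)) for (j in seq_along(b)) {
    m[i + 1, j + 1] <- min(m[i, j + 1] + 1L, m[i + 1, j] + 1L,
                           m[i, j] + (a[i] != b[j]))
  }
  m[length(a) + 1L, length(b) + 1L]
}

# hand-built bias_estimate with fixed draws (alpha: P x G x S, beta: P x S)
make_bias <- function(alpha, beta, basis, taxa = NULL, groups = NULL,
                      gamma = NULL, batches = NULL) {
  if (is.null(taxa)) taxa <- paste0("taxon_", seq_len(basis$D))
  if (is.null(groups)) groups <- paste0("g", seq_len(dim(alpha)[2]))
  structure(list(alpha_draws = alpha, beta_draws = beta,
                 gamma_draws = gamma, basis = basis, taxa = taxa,
                 groups = groups, batches = batches, fit = NULL),
            class = "bias_estimate")
}

# tiny calibration dataset: D taxa, two groups of cycles, deterministic-ish
small_calibration <- function(D = 3, cycles = c(10, 20, 30), reps = 2,
                              depth = 2000, noise = 0, seed = 1) {
  cfg <- calibration_config(D = D, cycles = cycles,
                            replicates_per_cycle = reps, depth = depth,
                            noise_sigma = noise, seed = seed)
  simulate_calibration(cfg)
}

# scalar-case matrix-t log density by adaptive double quadrature of the
# normal x normal x inverse-Wishart(=inverse-gamma) integrand
matrixt_quadrature <- function(eta, x, theta, g, xi, up) {
  f_inner <- function(s2) {
    sapply(s2, function(v) {
      h <- function(l) {
        stats::dnorm(eta, l * x, sqrt(v)) * stats::dnorm(l, theta, sqrt(v * g))
      }
      stats::integrate(h, -Inf, Inf, rel.tol = 1e-10)$value *
        exp((up / 2) * log(xi / 2) - lgamma(up / 2) -
              (up / 2 + 1) * log(v) - xi / (2 * v))
    })
  }
  log(stats::integrate(f_inner, 0, Inf, rel.tol = 1e-10)$value)
}
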