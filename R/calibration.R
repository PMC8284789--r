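#' Build a calibration design matrix from sample metadata
#'
#' Encodes the calibration-curve regression: one intercept indicator per
#' community/subject group, the raw PCR cycle number as a single covariate,
#' and indicator columns for every PCR machine after the first (the first
#' batch is the reference level and gets no column).  The cycle covariate is
#' deliberately not centred so that the intercept means "cycle 0 =
#' unamplified".
#'
#' @param metadata Tibble/data frame with columns `sample_id`, `group`,
#'   `cycle`, `batch` (see [read_metadata()]).
#' @param groups Optional ordered group labels (default: order of first
#'   appearance).
#' @param batches Optional ordered batch labels; the first is the reference.
#' @return An object of class `calibration_design`: list with `design`
#'   ([mlnl_design], rows ordered groups, cycle, batches), `group_names`,
#'   `batch_names`, `cycle_row`, `sample_id`.
#' @export
build_design <- function(metadata, groups = NULL, batches = NULL) {
  need <- c("sample_id", "group", "cycle", "batch")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(is.na(metadata$cycle)) || any(metadata$cycle < 0)) {
    stop("every sample needs a nonnegative cycle number", call. = FALSE)
  }
  if (is.null(groups)) groups <- unique(as.character(metadata$group))
  if (is.null(batches)) batches <- unique(as.character(metadata$batch))
  unknown_g <- setdiff(as.character(metadata$group), groups)
  if (length(unknown_g)) stop("unknown group in metadata: ", unknown_g[1],
                              call. = FALSE)
  unknown_b <- setdiff(as.character(metadata$batch), batches)
  if (length(unknown_b)) stop("unknown batch in metadata: ", unknown_b[1],
                              call. = FALSE)
  N <- nrow(metadata)
  G <- length(groups); B <- length(batches)
  X <- matrix(0, G + 1L + (B - 1L), N)
  for (g in seq_len(G)) X[g, ] <- as.numeric(metadata$group == groups[g])
  X[G + 1L, ] <- as.numeric(metadata$cycle)
  if (B > 1L) {
    for (b in 2:B) {
      X[G + b, ] <- as.numeric(metadata$batch == batches[b])
    }
  }
  labels <- c(paste0("group:", groups), "cycle",
              if (B > 1L) paste0("batch:", batches[-1]))
  roles <- c(rep("group_intercept", G), "cycle",
             rep("batch", B - 1L))
  colnames(X) <- metadata$sample_id
  structure(list(
    design = mlnl_design(X, roles = roles, labels = labels),
    group_names = groups, batch_names = batches,
    cycle_row = G + 1L, sample_id = as.character(metadata$sample_id)
  ), class = "calibration_design")
}

#' Estimate per-cycle PCR bias from calibration samples
#'
#' Fits the multinomial logistic-normal linear model of [mlnl_fit()] to a
#' calibration experiment and slices the coefficient posterior by covariate
#' role: per-group intercepts \eqn{\alpha = \Psi \log a} (the unamplified
#' compositions), the per-cycle bias slope \eqn{\beta = \Psi \log b}, and
#' batch (PCR machine) terms \eqn{\gamma}.
#'
#' @param counts [count_table] restricted to the samples of `cdesign`
#'   (already filtered, see [filter_min_reads()]).
#' @param cdesign A [build_design()] result.
#' @param prior Optional [mlnl_prior]; default [default_prior()] with
#'   `sigma2 = 10`.
#' @param basis Optional [contrast_basis].
#' @param n_draws,seed Passed to [mlnl_fit()].
#' @return Object of class `bias_estimate`: `alpha_draws` ((D-1) x G x S),
#'   `beta_draws` ((D-1) x S), `gamma_draws` ((D-1) x (B-1) x S or `NULL`),
#'   `basis`, `taxa`, `groups`, `batches`, and the underlying `fit`.
#' @export
estimate_bias <- function(counts, cdesign, prior = NULL, basis = NULL,
                          n_draws = 2000, seed = 1) {
  stopifnot(inherits(cdesign, "calibration_design"))
  X <- cdesign$design$x
  if (!identical(colnames(unclass(counts)), colnames(X))) {
    if (!all(colnames(X) %in% colnames(counts))) {
      stop("count table lacks samples named in the design", call. = FALSE)
    }
    counts <- count_table(unclass(counts)[, colnames(X), drop = FALSE])
  }
  cyc <- X[cdesign$cycle_row, ]
  if (length(unique(cyc)) < 2L) {
    stop("calibration needs at least 2 distinct cycle numbers; ",
         "the per-cycle slope is unidentifiable otherwise", call. = FALSE)
  }
  fit <- mlnl_fit(counts, cdesign$design, prior = prior, basis = basis,
                  n_draws = n_draws, seed = seed)
  roles <- cdesign$design$roles
  gi <- which(roles == "group_intercept")
  bi <- which(roles == "batch")
  alpha <- fit$lambda_draws[, gi, , drop = FALSE]
  beta <- fit$lambda_draws[, cdesign$cycle_row, , drop = TRUE]
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1L)
  gamma <- if (length(bi)) fit$lambda_draws[, bi, , drop = FALSE] else NULL
  structure(list(
    alpha_draws = alpha, beta_draws = beta, gamma_draws = gamma,
    basis = fit$basis, taxa = fit$taxa, groups = cdesign$group_names,
    batches = cdesign$batch_names, fit = fit
  ), class = "bias_estimate")
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat(sprintf("<bias_estimate> %d taxa, %d groups, %d draws\n",
              length(x$taxa), length(x$groups), ncol(x$beta_draws)))
  invisible(x)
}

.group_index <- function(bias, group) {
  g <- match(as.character(group), as.character(bias$groups))
  if (is.na(g)) stop("unknown group: ", group, call. = FALSE)
  g
}

#' Posterior composition of a group at a given PCR cycle
#'
#' For each posterior draw, evaluates the regression at cycle `x` for the
#' requested group (batch terms held at the reference level) and maps back to
#' the simplex: \eqn{\pi = \phi^{-1}(\alpha_g + \beta x)}.  `x = 0` gives the
#' inferred unamplified composition.
#'
#' @param bias A [estimate_bias()] result.
#' @param group Group label.
#' @param x Scalar PCR cycle number.
#' @return D x S matrix of composition draws (taxa in rows).
#' @export
composition_at_cycle <- function(bias, group, x = 0) {
  stopifnot(inherits(bias, "bias_estimate"), length(x) == 1L, x >= 0)
  g <- .group_index(bias, group)
  P <- nrow(bias$beta_draws)
  alpha_g <- bias$alpha_draws[, g, , drop = TRUE]
  if (is.null(dim(alpha_g))) alpha_g <- matrix(alpha_g, nrow = P)
  eta <- alpha_g + bias$beta_draws * x
  out <- from_logratio(eta, bias$basis)
  rownames(out) <- bias$taxa
  out
}

#' Per-taxon bias after x cycles, proportion scale (log2 fold change)
#'
#' For each draw, the base-2 log fold change of every taxon's proportion
#' between cycle `x` and cycle 0:
#' \eqn{\log_2 \pi_j(x) - \log_2 \pi_j(0)}.  A value of 2 means the taxon is
#' over-represented by a factor of 4 after `x` cycles.  Unlike the CLR-scale
#' bias this is not linear in \eqn{\beta}, because closure renormalises the
#' proportions.
#'
#' @inheritParams composition_at_cycle
#' @param x Number of PCR cycles the bias acts over (default 35).
#' @return D x S matrix of log2 fold changes.
#' @export
bias_fold_change <- function(bias, group, x = 35) {
  p_x <- composition_at_cycle(bias, group, x)
  p_0 <- composition_at_cycle(bias, group, 0)
  log2(p_x) - log2(p_0)
}

#' Per-taxon bias after x cycles, CLR scale
#'
#' The difference of CLR coordinates between cycle `x` and cycle 0.  Because
#' PCR bias is a compositional perturbation, this equals the CLR
#' representation of \eqn{x \beta} exactly, is linear in `x`, does not depend
#' on the group intercept, and sums to zero across taxa within each draw.
#'
#' @inheritParams bias_fold_change
#' @return D x S matrix of CLR-scale bias draws.
#' @export
bias_clr <- function(bias, x = 35) {
  stopifnot(inherits(bias, "bias_estimate"), length(x) == 1L)
  out <- alr_to_clr(bias$beta_draws * x, bias$basis)
  rownames(out) <- bias$taxa
  out
}

#' Correct an observed composition for PCR bias
#'
#' Removes the inferred per-cycle bias from a composition measured after `x`
#' cycles of PCR: per posterior draw \eqn{s},
#' \eqn{\phi^{-1}(\Psi \log(p_{obs}) - \beta^{(s)} x)} — equivalently,
#' perturbation by the inverse of the accumulated bias.  Uncertainty in
#' \eqn{\beta} is propagated draw-wise rather than through a plug-in mean.
#'
#' @param observed Composition vector (length D), or a D x S matrix of
#'   composition draws paired with the bias draws.  Must be strictly
#'   positive: observed zeros cannot be log-ratio transformed — correct via
#'   the model-inferred composition ([composition_at_cycle()]) instead.
#' @param bias A [estimate_bias()] result.
#' @param x Number of PCR cycles the observed sample underwent.
#' @return D x S matrix of corrected composition draws.
#' @export
correct_composition <- function(observed, bias, x) {
  stopifnot(inherits(bias, "bias_estimate"))
  if (missing(x) || length(x) != 1L || x < 0) {
    stop("x must be the (single, nonnegative) number of PCR cycles the ",
         "sample underwent", call. = FALSE)
  }
  S <- ncol(bias$beta_draws)
  if (is.matrix(observed)) {
    if (ncol(observed) != S) {
      stop("draw counts of observed and bias estimate differ", call. = FALSE)
    }
    if (any(observed <= 0)) {
      stop("observed composition contains zeros; correct model-inferred ",
           "compositions (composition_at_cycle) instead", call. = FALSE)
    }
    eta_obs <- to_logratio(observed, bias$basis)
  } else {
    if (any(observed <= 0)) {
      stop("observed composition contains zeros; correct model-inferred ",
           "compositions (composition_at_cycle) instead", call. = FALSE)
    }
    eta_obs <- matrix(to_logratio(observed, bias$basis), ncol = S,
                      nrow = bias$basis$D - 1L)
  }
  out <- from_logratio(eta_obs - bias$beta_draws * x, bias$basis)
  rownames(out) <- bias$taxa
  out
}

#' Reference correction terms for mock-community validation
#'
#' When an external reference composition exists for the calibration sample,
#' the residual discrepancy between the model-inferred unamplified
#' composition and that reference can be removed from all related samples as
#' a single compositional perturbation.  `reference_correction()` computes
#' \eqn{\delta = clr(reference) - \overline{clr}} where \eqn{\overline{clr}}
#' is the posterior mean (in CLR space) of the inferred calibration
#' composition; `apply_reference_correction()` perturbs draws by
#' \eqn{\exp(\delta)}.  Perturbation is an isometry of Aitchison geometry, so
#' distances between corrected draws are unchanged.
#'
#' @param inferred_draws D x S matrix of composition draws for the
#'   calibration sample at cycle 0 (see [composition_at_cycle()]).
#' @param reference Reference composition (length D, same taxon order).
#' @return `reference_correction()`: named numeric vector \eqn{\delta} (CLR
#'   scale, sums to zero).  `apply_reference_correction()`: D x S matrix.
#' @export
reference_correction <- function(inferred_draws, reference) {
  if (nrow(inferred_draws) != length(reference)) {
    stop("taxa mismatch between inferred draws and reference", call. = FALSE)
  }
  if (!is.null(rownames(inferred_draws)) && !is.null(names(reference)) &&
      !identical(rownames(inferred_draws), names(reference))) {
    stop("taxon names of inferred draws and reference differ", call. = FALSE)
  }
  check_composition(reference)
  delta <- clr(reference) - rowMeans(clr(inferred_draws))
  stats::setNames(as.numeric(delta), rownames(inferred_draws))
}

#' @rdname reference_correction
#' @param draws D x S matrix of composition draws to correct.
#' @param delta CLR-scale correction from `reference_correction()`.
#' @export
apply_reference_correction <- function(draws, delta) {
  if (nrow(draws) != length(delta)) {
    stop("taxa mismatch between draws and correction vector", call. = FALSE)
  }
  out <- perturb(draws, exp(delta))
  rownames(out) <- rownames(draws)
  out
}
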