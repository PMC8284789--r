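#' Alpha diversity of a composition
#'
#' Shannon entropy (natural log), Simpson index \eqn{1 - \sum p_j^2}, or
#' inverse Simpson \eqn{1 / \sum p_j^2}.  PCR bias perturbs compositions and
#' therefore distorts all three; comparing diversity of corrected versus raw
#' compositions against the truth quantifies how much of that distortion the
#' calibration removes.
#'
#' @param p Composition vector, or D x S matrix of composition draws.
#' @param measure One of `"shannon"`, `"simpson"`, `"inv_simpson"`.
#' @return Scalar, or a length-S vector for matrix input.
#' @examples
#' alpha_diversity(rep(0.1, 10), "shannon")  # log(10)
#' @export
alpha_diversity <- function(p, measure = c("shannon", "simpson",
                                           "inv_simpson")) {
  measure <- match.arg(measure)
  check_composition(p)
  f <- switch(measure,
    shannon = function(q) -sum(q * log(q)),
    simpson = function(q) 1 - sum(q^2),
    inv_simpson = function(q) 1 / sum(q^2))
  if (is.matrix(p)) apply(p, 2L, f) else f(p)
}

#' Centred posterior ECDF accuracy statistic
#'
#' The empirical cumulative distribution function of posterior draws
#' evaluated at the true value, minus 0.5.  Zero means the truth sits at the
#' posterior median; +0.36 means the posterior carries an extra 36% of its
#' mass below the truth; the extremes are -0.5 (truth below all draws) and
#' +0.5 (truth above all draws).  Summarises both the accuracy of the
#' posterior mean and the calibration of its spread in a single number;
#' values closer to zero in absolute value are better.
#'
#' @param posterior_draws Numeric vector of draws (at least 2).
#' @param truth True scalar value.
#' @return Value in \eqn{[-0.5, 0.5]}.
#' @export
ecdf_stat <- function(posterior_draws, truth) {
  if (length(posterior_draws) < 2L) stop("need at least 2 draws",
                                         call. = FALSE)
  if (any(!is.finite(posterior_draws)) || !is.finite(truth)) {
    stop("draws and truth must be finite", call. = FALSE)
  }
  mean(posterior_draws <= truth) - 0.5
}

#' Aitchison-distance improvement from bias correction
#'
#' Compares corrected composition draws and the raw (uncorrected) observed
#' composition against a reference: per draw the Aitchison distance of the
#' corrected composition to the reference, versus the single distance of the
#' uncorrected composition.  Improvement holds when the posterior mean
#' corrected distance is strictly smaller (ties count as no improvement);
#' a value of 0 means perfect bias removal.
#'
#' @param corrected_draws D x S matrix of corrected composition draws.
#' @param uncorrected Observed composition (length D).
#' @param reference Reference composition (length D, same taxon order).
#' @return List with `distances` (tibble: `draw`, `corrected`),
#'   `uncorrected` (scalar distance), `improvement` (logical), and
#'   `mean_corrected`.
#' @export
distance_improvement <- function(corrected_draws, uncorrected, reference) {
  if (nrow(corrected_draws) != length(reference) ||
      length(uncorrected) != length(reference)) {
    stop("taxa mismatch between corrected draws, uncorrected and reference",
         call. = FALSE)
  }
  if (!is.null(rownames(corrected_draws)) && !is.null(names(reference)) &&
      !identical(rownames(corrected_draws), names(reference))) {
    stop("taxon names differ between corrected draws and reference",
         call. = FALSE)
  }
  d_corr <- apply(corrected_draws, 2L, aitchison_distance, y = reference)
  d_unc <- aitchison_distance(uncorrected, reference)
  list(
    distances = tibble::tibble(draw = seq_along(d_corr), corrected = d_corr),
    uncorrected = d_unc,
    mean_corrected = mean(d_corr),
    improvement = mean(d_corr) < d_unc
  )
}
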