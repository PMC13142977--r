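# Posterior summarization and interpretive conversions.

#' Highest posterior density interval
#'
#' Shortest contiguous interval over the sorted draws containing at least
#' `mass` of the posterior probability. On multimodal draw sets the single
#' shortest window is still returned, with a `multimodal` flag set by a
#' coarse unimodality heuristic on a histogram of the draws.
#'
#' @param draws numeric vector of posterior draws (>= 10).
#' @param mass interval probability mass, in (0, 1); default 0.89.
#' @return named numeric vector `c(lower, upper)` with attributes `mass` and
#'   `multimodal`.
#' @examples
#' hpdi(rnorm(4000)) # approx (-1.6, 1.6)
#' @export
hpdi <- function(draws, mass = 0.89) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1) {
    stop("mass must be in (0, 1)")
  }
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 10) stop("need at least 10 draws")
  x <- sort(draws)
  k <- ceiling(mass * n)
  if (k >= n) {
    lo <- x[1]; up <- x[n]
  } else {
    width <- x[(k + 1):n] - x[1:(n - k)]
    i <- which.min(width)
    lo <- x[i]; up <- x[i + k]
  }
  # unimodality heuristic: histogram counts should rise then fall (roughly)
  multimodal <- FALSE
  if (stats::sd(x) > 0 && n >= 100) {
    h <- graphics::hist(x, breaks = max(8, min(30, floor(n / 50))), plot = FALSE)
    cnt <- stats::filter(h$counts, rep(1 / 3, 3), sides = 2)
    cnt <- cnt[!is.na(cnt)]
    if (length(cnt) > 4) {
      peak <- which.max(cnt)
      rises_after <- any(diff(cnt[peak:length(cnt)]) > 0.15 * max(cnt))
      rises_before <- any(diff(rev(cnt[1:peak])) > 0.15 * max(cnt))
      multimodal <- rises_after || rises_before
    }
  }
  structure(c(lower = lo, upper = up), mass = mass, multimodal = multimodal)
}

#' Convert a logit-scale effect to the probability scale
#'
#' Given a baseline normalized entropy and an increase on the logit scale,
#' returns the implied change on the probability (entropy) scale:
#' `plogis(qlogis(baseline) + delta_logit) - baseline`.
#'
#' @param baseline_Hn baseline normalized entropy, strictly in (0, 1).
#' @param delta_logit change on the logit scale.
#' @return change in normalized entropy (same scale as the baseline).
#' @examples
#' effect_on_probability_scale(0.291, 0.11) # ~ +0.023
#' @export
effect_on_probability_scale <- function(baseline_Hn, delta_logit) {
  if (any(baseline_Hn <= 0 | baseline_Hn >= 1)) {
    stop("baseline must be strictly inside (0, 1)")
  }
  stats::plogis(stats::qlogis(baseline_Hn) + delta_logit) - baseline_Hn
}

#' Express an entropy change as a count of maximally variable features
#'
#' Converts an average increase in normalized entropy over `n_features`
#' binary features into the equivalent number of features shifted from a
#' rare-state distribution (state probability `p_low`) to maximal
#' variability (probability 0.5), rounded to the nearest integer.
#'
#' @param delta_Hn average increase in normalized entropy, >= 0.
#' @param n_features number of binary features.
#' @param p_low rare-state probability, in (0, 0.5).
#' @return integer count of features.
#' @examples
#' entropy_change_to_feature_count(0.023, 333, 0.05) # 11
#' @export
entropy_change_to_feature_count <- function(delta_Hn, n_features, p_low) {
  if (delta_Hn < 0) stop("delta_Hn must be >= 0")
  if (p_low <= 0 || p_low >= 0.5) stop("p_low must be in (0, 0.5)")
  gain <- normalized_entropy(c(0.5, 0.5)) -
    normalized_entropy(c(p_low, 1 - p_low))
  round(delta_Hn * n_features / gain)
}

#' Posterior probability of a positive effect
#'
#' @param draws numeric vector of posterior draws (>= 10).
#' @return fraction of draws strictly greater than zero.
#' @export
posterior_prob_positive <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 10) stop("need at least 10 draws")
  mean(draws > 0)
}

# Posterior summary row used across modules.
summarize_draws_vector <- function(draws, name = "param") {
  h50 <- hpdi(draws, 0.50); h89 <- hpdi(draws, 0.89); h95 <- hpdi(draws, 0.95)
  data.frame(term = name, mean = mean(draws), sd = stats::sd(draws),
             median = stats::median(draws),
             hpdi50_lower = h50[1], hpdi50_upper = h50[2],
             hpdi89_lower = h89[1], hpdi89_upper = h89[2],
             hpdi95_lower = h95[1], hpdi95_upper = h95[2],
             prob_positive = mean(draws > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
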