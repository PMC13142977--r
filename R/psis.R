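# Pareto-smoothed importance sampling leave-one-out cross-validation.
# Generalized Pareto tail fit by the Zhang & Stephens (2009) profile
# posterior-mean method; smoothing and elpd assembly follow the standard
# PSIS-LOO recipe (raw importance ratios, GPD-smoothed upper tail, weights
# truncated at the raw maximum).

# Fit GPD(k, sigma) to exceedances x > 0. Returns shape k and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bk <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bk * xstar)
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  ls <- n * (log(bs / ks) + ks - 1)
  w <- exp(ls - logsumexp(ls))
  b_hat <- sum(bs * w)
  # convert to the usual GPD shape xi (positive = heavy tail)
  k_hat <- mean(log1p(-b_hat * x))
  sigma_hat <- -k_hat / b_hat
  list(k = k_hat, sigma = sigma_hat)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Smooth one vector of log importance ratios; returns list(log_weights, k).
psis_smooth <- function(lr) {
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5) return(list(log_weights = lr, k = NA_real_))
  ord <- order(lr)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lr[ord[S - M]]
  exc <- exp(lr[tail_ids]) - exp(cutoff)
  if (max(exc) <= 0) return(list(log_weights = lr, k = NA_real_))
  fit <- gpd_fit(exc[exc > 0])
  p <- (rank(lr[tail_ids], ties.method = "first") - 0.5) / M
  sm <- log(exp(cutoff) + gpd_quantile(p, fit$k, fit$sigma))
  sm <- pmin(sm, 0) # cap at the raw maximum (ratios were shifted to max 0)
  lr[tail_ids] <- sm
  list(log_weights = lr, k = fit$k)
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' @param log_lik draws x observations matrix of pointwise log-likelihood
#'   values.
#' @return list with `elpd`, `se`, `pointwise` (per-observation elpd) and
#'   `pareto_k` diagnostics.
#' @export
psis_loo <- function(log_lik) {
  S <- nrow(log_lik); n <- ncol(log_lik)
  pointwise <- numeric(n)
  k <- numeric(n)
  for (i in seq_len(n)) {
    ll <- log_lik[, i]
    sm <- psis_smooth(-ll)
    lw <- sm$log_weights - logsumexp(sm$log_weights)
    pointwise[i] <- logsumexp(lw + ll)
    k[i] <- sm$k
  }
  list(elpd = sum(pointwise),
       se = sqrt(n * stats::var(pointwise)),
       pointwise = pointwise,
       pareto_k = k)
}

#' Compare fitted models by PSIS-LOO
#'
#' All fits must be on identical observations (matching response vectors).
#'
#' @param fits named list of `diversity_fit` objects.
#' @return data.frame ordered best-first with `elpd`, `se`, `delta_elpd`
#'   (vs the best model), `delta_se` (SE of the pointwise difference) and
#'   `max_pareto_k`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  ys <- lapply(fits, function(f) f$data$y)
  if (length(fits) > 1) {
    same <- vapply(ys[-1], function(y) isTRUE(all.equal(y, ys[[1]])),
                   logical(1))
    if (!all(same)) stop("models were fitted on different datasets")
  }
  loos <- lapply(fits, function(f) psis_loo(f$log_lik))
  elpd <- vapply(loos, `[[`, numeric(1), "elpd")
  se <- vapply(loos, `[[`, numeric(1), "se")
  best <- which.max(elpd)
  n <- length(loos[[1]]$pointwise)
  delta <- elpd[best] - elpd
  delta_se <- vapply(seq_along(loos), function(i) {
    if (i == best) return(0)
    d <- loos[[best]]$pointwise - loos[[i]]$pointwise
    sqrt(n * stats::var(d))
  }, numeric(1))
  out <- data.frame(model = names(fits), elpd = elpd, se = se,
                    delta_elpd = delta, delta_se = delta_se,
                    max_pareto_k = vapply(loos, function(l) {
                      suppressWarnings(max(l$pareto_k, na.rm = TRUE))
                    }, numeric(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$elpd), ]
}
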