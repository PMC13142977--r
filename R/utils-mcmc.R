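# Shared MCMC machinery: seeding, slice sampling, convergence diagnostics,
# LKJ correlation updates, and sparse-precision Gaussian draws.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded package functions do not disturb the
#' caller's random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Univariate slice sampler (Neal 2003, stepping out + shrinkage).
# log_f must be finite at x0; lower/upper bound the support.
slice_sample1 <- function(x0, log_f, w = 1, lower = -Inf, upper = Inf,
                          max_steps = 30L) {
  f0 <- log_f(x0)
  if (!is.finite(f0)) stop("slice_sample1: log density not finite at x0")
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && log_f(max(L, lower)) > z) {
    L <- L - w; j <- j - 1
  }
  while (k > 0 && R < upper && log_f(min(R, upper)) > z) {
    R <- R + w; k <- k - 1
  }
  L <- max(L, lower); R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    if (log_f(x1) >= z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# Split-Rhat (Gelman et al.), draws: iterations x chains matrix.
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W < 1e-300) return(1)
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}

# Bulk effective sample size via Geyer's initial positive sequence,
# averaged across chains. draws: iterations x chains.
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (n < 8) return(NA_real_)
  acov <- sapply(seq_len(m), function(j) {
    x <- draws[, j] - mean(draws[, j])
    stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE,
               type = "covariance", demean = FALSE)$acf[, 1, 1]
  })
  acov <- rowMeans(as.matrix(acov))
  if (acov[1] < 1e-300) return(n * m)
  rho <- acov / acov[1]
  # sum adjacent pairs while positive (initial positive sequence)
  tau <- 1
  t <- 2
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(1, n * m / tau)
}

# ---- LKJ correlation matrices via canonical partial correlations ----------

# Map a vector of partial correlations (upper-triangular, row-major order of
# the vine) to a correlation matrix (Lewandowski, Kurowicka & Joe 2009).
pcors_to_corr <- function(pc, d) {
  P <- matrix(0, d, d)
  P[upper.tri(P)] <- pc
  R <- diag(d)
  for (j in 2:d) {
    for (i in seq_len(j - 1)) {
      r <- P[i, j]
      if (i > 1) {
        for (k in (i - 1):1) {
          r <- r * sqrt((1 - P[k, i]^2) * (1 - P[k, j]^2)) + P[k, i] * P[k, j]
        }
      }
      R[i, j] <- r
      R[j, i] <- r
    }
  }
  R
}

# Log prior density of the vine partial correlations inducing LKJ(eta).
# Independent shifted-Beta: (pc+1)/2 ~ Beta(b_i, b_i), b_i = eta + (d-1-i)/2
# where i is the vine row (1-based).
lkj_pc_logprior <- function(pc, d, eta = 2) {
  idx <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
  b <- eta + (d - 1 - idx[, 1]) / 2
  sum(stats::dbeta((pc + 1) / 2, b, b, log = TRUE))
}

# Multivariate normal log likelihood of rows of U under N(0, diag(tau) R diag(tau)).
mvn_relik <- function(U, tau, R) {
  d <- length(tau)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Us <- U * rep(1 / tau, each = nrow(U))
  q <- forwardsolve(t(ch), t(Us))
  -0.5 * sum(q^2) - nrow(U) * (sum(log(diag(ch))) + sum(log(tau))) -
    nrow(U) * d * 0.5 * log(2 * pi)
}

# One sweep of slice updates for (tau, pc) of a correlated random-effect
# block, U: groups x d matrix of current effects. Works on the sufficient
# statistic S = U'U, so each likelihood evaluation is O(d^2) regardless of
# the number of groups. Returns list(tau, pc, R).
update_sigma_lkj <- function(U, tau, pc, prior_sd = 2, eta = 2,
                             pc_step = 0.15) {
  d <- length(tau)
  npc <- d * (d - 1) / 2
  n <- nrow(U)
  S <- crossprod(U)
  R <- if (d > 1) pcors_to_corr(pc, d) else matrix(1, 1, 1)
  # -2 x profile pieces: loglik(tau, Rinv, logdetR) up to a constant
  ll_suff <- function(tau, Rinv, ldR) {
    inv_t <- 1 / tau
    -0.5 * n * (ldR + 2 * sum(log(tau))) -
      0.5 * sum(Rinv * (S * outer(inv_t, inv_t)))
  }
  chR <- chol(R)
  Rinv <- chol2inv(chR)
  ldR <- 2 * sum(log(diag(chR)))
  for (k in seq_len(d)) {
    lf <- function(lt) {
      t2 <- tau; t2[k] <- exp(lt)
      ll_suff(t2, Rinv, ldR) + stats::dnorm(t2[k], 0, prior_sd, log = TRUE) + lt
    }
    tau[k] <- exp(slice_sample1(log(tau[k]), lf, w = 0.7))
  }
  pc_accept <- NA
  if (d > 1 && npc > 0) {
    # correlations: one joint random-walk Metropolis move on the vine
    # partial correlations (independent shifted-Beta priors induce LKJ(eta))
    idx <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
    bvec <- eta + (d - 1 - idx[, 1]) / 2
    lp <- function(p2) {
      Rk <- pcors_to_corr(p2, d)
      ck <- tryCatch(chol(Rk), error = function(e) NULL)
      if (is.null(ck)) return(list(v = -Inf))
      list(v = ll_suff(tau, chol2inv(ck), 2 * sum(log(diag(ck)))) +
             sum(stats::dbeta((p2 + 1) / 2, bvec, bvec, log = TRUE)),
           R = Rk)
    }
    cur <- lp(pc)
    prop <- pc + pc_step * stats::rnorm(npc)
    pc_accept <- 0
    if (all(abs(prop) < 0.999)) {
      cand <- lp(prop)
      if (is.finite(cand$v) &&
          log(stats::runif(1)) < cand$v - cur$v) {
        pc <- prop
        cur <- cand
        pc_accept <- 1
      }
    }
    R <- if (!is.null(cur$R)) cur$R else pcors_to_corr(pc, d)
  }
  list(tau = tau, pc = pc, R = R, pc_accept = pc_accept)
}

# Slice update for an iid-normal scale parameter given its effects u,
# with half-Normal(0, prior_sd) prior on the scale.
update_scale <- function(sigma, u, prior_sd = 2, min_scale = 1e-5) {
  lf <- function(ls) {
    s <- exp(ls)
    sum(stats::dnorm(u, 0, s, log = TRUE)) +
      stats::dnorm(s, 0, prior_sd, log = TRUE) + ls
  }
  exp(slice_sample1(log(max(sigma, min_scale)), lf, w = 0.7,
                    lower = log(min_scale), upper = log(50)))
}

# Interweaving (ASIS) update for a scale parameter of a Gaussian-likelihood
# block. Given the whitened effects w_i = (Z u / sigma)_i per observation,
# current residuals e (excluding nothing: e = response - full linear
# predictor) and observation weights W (precisions), redraws the scale as a
# regression coefficient on w in the non-centered parameterisation.
# Returns list(s = signed scale draw, e = updated residuals).
asis_scale <- function(e, W, w, sigma, prior_sd = 2) {
  r <- e + sigma * w
  prec <- sum(W * w^2) + 1 / prior_sd^2
  mu <- sum(W * w * r) / prec
  s <- stats::rnorm(1, mu, sqrt(1 / prec))
  list(s = s, e = r - s * w)
}

# Draw from N(Q^{-1} b, Q^{-1}) with sparse precision Q (dsCMatrix/dgCMatrix).
rmvn_prec_sparse <- function(Q, b) {
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Q), LDL = FALSE, perm = TRUE)
  mu <- Matrix::solve(ch, b, system = "A")
  z <- stats::rnorm(nrow(Q))
  y <- Matrix::solve(ch, z, system = "Lt")
  x <- Matrix::solve(ch, y, system = "Pt")
  as.numeric(mu) + as.numeric(x)
}

# Closure version that caches the symbolic Cholesky analysis: the sparsity
# pattern of Q is fixed across iterations, so only the numeric factorization
# is redone. Q must be symmetric (dsCMatrix).
make_prec_sampler <- function() {
  ch <- NULL
  function(Q, b) {
    if (is.null(ch)) {
      ch <<- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
    } else {
      ch <<- tryCatch(Matrix::update(ch, Q),
                      error = function(e) {
                        Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
                      })
    }
    mu <- Matrix::solve(ch, b, system = "A")
    z <- stats::rnorm(nrow(Q))
    y <- Matrix::solve(ch, z, system = "Lt")
    x <- Matrix::solve(ch, y, system = "Pt")
    as.numeric(mu) + as.numeric(x)
  }
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
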