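# Blocked Gibbs sampler for Gaussian hierarchical models with iid random
# intercepts and a tensor-product spline smooth. All coefficients are drawn
# jointly from their exact Gaussian full conditional (sparse precision
# Cholesky); scale parameters get slice updates under half-Normal(0, 2)
# priors. Used for the cell-level Wright's F model and as the backbone of
# the measurement-error diversity regression.

#' Sampler control settings
#'
#' @param chains number of chains.
#' @param warmup warmup iterations per chain (discarded).
#' @param iter retained iterations per chain.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param spline_k marginal basis size of the tensor smooth (the 2-D basis
#'   has `spline_k^2` columns); 0 disables the smooth.
#' @param prior_sd prior SD for intercepts, fixed effects and all scale
#'   parameters (half-Normal for scales).
#' @param allow_nonconverged if `TRUE`, [fit_diversity_model()] returns the
#'   fit (with diagnostics) instead of erroring when split-Rhat exceeds
#'   1.05 -- intended for replicate calibration sweeps at reduced settings.
#' @param fix_sigma optionally hold the residual SD of the diversity
#'   regression at a fixed value instead of sampling it.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 2, warmup = 300, iter = 300, seed = 1,
                         spline_k = 5, prior_sd = 2,
                         allow_nonconverged = FALSE, fix_sigma = NULL) {
  structure(list(chains = chains, warmup = warmup, iter = iter, seed = seed,
                 spline_k = spline_k, prior_sd = prior_sd,
                 allow_nonconverged = allow_nonconverged,
                 fix_sigma = fix_sigma),
            class = "mcmc_control")
}

# Tensor-product of two marginal cubic B-spline bases over planar
# coordinates, column-centered so the smooth carries no intercept.
tensor_spline_basis <- function(xy, k = 5) {
  if (k <= 0) return(NULL)
  if (k < 4) k <- 4 # cubic B-spline basis needs >= degree + 1 functions
  bx <- splines::bs(xy[, 1], df = k, intercept = TRUE)
  by <- splines::bs(xy[, 2], df = k, intercept = TRUE)
  k <- ncol(bx)
  n <- nrow(xy)
  out <- matrix(0, n, k * k)
  for (j in seq_len(k)) {
    out[, ((j - 1) * k + 1):(j * k)] <- bx * by[, j]
  }
  sweep(out, 2, colMeans(out))
}

sparse_indicator <- function(f) {
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                       dims = c(length(f), nlevels(f)))
}

# y, y_sd: observation vector and known per-observation SD (0 allowed);
# X: fixed-effect design (prior N(0, prior_sd) per column);
# iid_groups: named list of factors (random intercepts);
# smooth: optional pre-built spline design (ridge prior with sampled scale).
gibbs_gaussian <- function(y, y_sd, X, iid_groups = list(), smooth = NULL,
                           control = mcmc_control()) {
  n <- length(y)
  p <- ncol(X)
  K <- if (is.null(smooth)) 0L else ncol(smooth)
  Gs <- vapply(iid_groups, nlevels, integer(1))
  blocks <- list(Matrix::Matrix(X, sparse = TRUE))
  if (K > 0) blocks <- c(blocks, list(Matrix::Matrix(smooth, sparse = TRUE)))
  blocks <- c(blocks, lapply(iid_groups, sparse_indicator))
  A <- do.call(cbind, blocks)
  homosked <- all(y_sd == 0)
  AtA <- if (homosked) Matrix::crossprod(A) else NULL
  Aty <- if (homosked) Matrix::crossprod(A, y) else NULL
  idx_beta <- seq_len(p)
  idx_sm <- if (K > 0) p + seq_len(K) else integer(0)
  off <- p + K
  idx_grp <- lapply(Gs, function(g) { i <- off + seq_len(g); off <<- off + g; i })
  ntot <- off
  g_int <- lapply(iid_groups, as.integer)
  prior_sd <- control$prior_sd
  n_keep <- control$iter
  chains <- control$chains
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res[[ch]] <- with_seed(control$seed + ch - 1, {
      sigma <- stats::sd(y); if (!is.finite(sigma) || sigma < 0.05) sigma <- 0.5
      sig_sm <- 0.5
      sig_g <- stats::setNames(rep(0.5, length(Gs)), names(Gs))
      theta <- rep(0, ntot)
      keep_beta <- matrix(NA_real_, n_keep, p)
      keep_sm <- matrix(NA_real_, n_keep, K)
      keep_grp <- lapply(Gs, function(g) matrix(NA_real_, n_keep, g))
      keep_sig <- matrix(NA_real_, n_keep, 2 + length(Gs))
      colnames(keep_sig) <- c("sigma", "sigma_spline",
                              paste0("sigma_", names(Gs)))
      total <- control$warmup + n_keep
      for (it in seq_len(total)) {
        prior_prec <- c(rep(1 / prior_sd^2, p),
                        rep(1 / sig_sm^2, K),
                        unlist(mapply(function(g, s) rep(1 / s^2, g),
                                      Gs, sig_g, SIMPLIFY = FALSE)))
        if (homosked) {
          Q <- AtA / sigma^2 + Matrix::Diagonal(x = prior_prec)
          b <- Aty / sigma^2
        } else {
          W <- 1 / (y_sd^2 + sigma^2)
          Q <- Matrix::crossprod(A, W * A) + Matrix::Diagonal(x = prior_prec)
          b <- Matrix::crossprod(A, W * y)
        }
        theta <- rmvn_prec_sparse(Q, b)
        e <- y - as.numeric(A %*% theta)
        W <- 1 / (y_sd^2 + sigma^2)
        # centered slice update then interweaved (ASIS) rescale per block
        if (K > 0) {
          sig_sm <- update_scale(sig_sm, theta[idx_sm], prior_sd)
          ut <- theta[idx_sm] / max(sig_sm, 1e-5)
          wv <- as.numeric(smooth %*% ut)
          up <- asis_scale(e, W, wv, sig_sm, prior_sd)
          sig_sm <- max(abs(up$s), 1e-5)
          theta[idx_sm] <- up$s * ut
          e <- up$e
        }
        for (gi in seq_along(Gs)) {
          sig_g[gi] <- update_scale(sig_g[gi], theta[idx_grp[[gi]]], prior_sd)
          ut <- theta[idx_grp[[gi]]] / max(sig_g[gi], 1e-5)
          wv <- ut[g_int[[gi]]]
          up <- asis_scale(e, W, wv, sig_g[gi], prior_sd)
          sig_g[gi] <- max(abs(up$s), 1e-5)
          theta[idx_grp[[gi]]] <- up$s * ut
          e <- up$e
        }
        lf_sig <- function(ls) {
          s <- exp(ls)
          sum(stats::dnorm(e, 0, sqrt(y_sd^2 + s^2), log = TRUE)) +
            stats::dnorm(s, 0, prior_sd, log = TRUE) + ls
        }
        sigma <- exp(slice_sample1(log(sigma), lf_sig, w = 0.5,
                                   lower = log(1e-5), upper = log(50)))
        if (it > control$warmup) {
          j <- it - control$warmup
          keep_beta[j, ] <- theta[idx_beta]
          if (K > 0) keep_sm[j, ] <- theta[idx_sm]
          for (gi in seq_along(Gs)) keep_grp[[gi]][j, ] <- theta[idx_grp[[gi]]]
          keep_sig[j, ] <- c(sigma, sig_sm, sig_g)
        }
      }
      list(beta = keep_beta, smooth = keep_sm, group = keep_grp,
           scales = keep_sig)
    })
  }
  draws <- list(
    beta = do.call(rbind, lapply(res, `[[`, "beta")),
    smooth = do.call(rbind, lapply(res, `[[`, "smooth")),
    group = stats::setNames(lapply(seq_along(Gs), function(gi) {
      do.call(rbind, lapply(res, function(r) r$group[[gi]]))
    }), names(Gs)),
    scales = do.call(rbind, lapply(res, `[[`, "scales")))
  mon <- cbind(draws$beta, draws$scales)
  rh <- apply(mon, 2, function(col) {
    split_rhat(matrix(col, ncol = chains))
  })
  es <- apply(mon, 2, function(col) {
    ess_basic(matrix(col, ncol = chains))
  })
  list(draws = draws, chains = chains, n_keep = n_keep,
       group_levels = lapply(iid_groups, levels),
       max_rhat = max(rh, na.rm = TRUE), min_ess = min(es, na.rm = TRUE),
       rhat = rh, ess = es)
}
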