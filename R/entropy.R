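# Per-feature hierarchical spatial models (Bernoulli / categorical with
# logit link) and posterior normalized Shannon entropy per grid cell.
#
# Sampling uses Polya-Gamma data augmentation (Polson, Scott & Windle),
# which turns the logistic likelihood into a conditionally Gaussian one, so
# coefficients are drawn jointly from sparse Gaussian full conditionals.
# PG(1, z) variates are drawn from the infinite gamma convolution truncated
# at 100 terms with a closed-form correction for the mean of the dropped
# tail.

rpg1 <- function(z, K = 100L) {
  n <- length(z)
  a <- abs(z) / (2 * pi)
  kk <- (seq_len(K) - 0.5)^2
  denom <- outer(a^2, kk, "+")
  E <- matrix(stats::rexp(n * K), n, K)
  tail_sum <- ifelse(a > 1e-12, (pi / 2 - atan(K / a)) / a, 1 / K)
  (rowSums(E / denom) + tail_sum) / (2 * pi^2)
}

#' Normalized Shannon entropy of a state-probability vector
#'
#' `Hn = -sum_j p_j log(p_j) / log(J)` with `0 log 0 = 0`, so `Hn` is 0 when
#' one state is certain and 1 for the uniform distribution.
#'
#' @param probs simplex vector of length `J >= 2`, or a matrix whose rows
#'   are simplex vectors.
#' @param J number of states; defaults to `length(probs)` (or `ncol`).
#' @return entropy value(s) in `[0, 1]`.
#' @examples
#' normalized_entropy(c(0.5, 0.5)) # 1
#' normalized_entropy(c(1, 0))     # 0
#' @export
normalized_entropy <- function(probs, J = NULL) {
  if (is.matrix(probs)) {
    if (is.null(J)) J <- ncol(probs)
    if (any(probs < 0)) stop("probabilities must be non-negative")
    pl <- ifelse(probs > 0, probs * log(probs), 0)
    return(-rowSums(pl) / log(J))
  }
  if (is.null(J)) J <- length(probs)
  if (J < 2) stop("need at least 2 states")
  if (any(probs < 0)) stop("probabilities must be non-negative")
  pl <- ifelse(probs > 0, probs * log(probs), 0)
  -sum(pl) / log(J)
}

#' Fit a hierarchical spatial model for one structural feature
#'
#' Binary features are modeled as `state_i ~ Bernoulli(plogis(eta_i))` and
#' categorical features (J > 2 observed states) as
#' `state_i ~ Categorical(softmax(eta_i1, ..., eta_iJ))` with
#' `eta = alpha + a_area + a_cell + a_family + t2(x, y)`, random intercepts
#' by geohistorical area, grid cell and language family, and a
#' tensor-product spline over the projected cell centroid of each language.
#' Priors: Normal(0, 2) on the intercept, half-Normal(0, 2) on every scale.
#' The categorical model uses the first observed state as the reference
#' class (its linear predictor is 0) and shares the group scales across
#' classes.
#'
#' @param feature name of the feature column in `language_table`.
#' @param language_table data.frame with columns `language_id`, `lon`,
#'   `lat`, `family`, `area`, optionally `cell_id`, plus feature columns
#'   (`NA` = missing / uncoded).
#' @param grid a `geo_grid`; used to assign cells when `cell_id` is absent
#'   and to supply projected centroids for the smooth.
#' @param control see [mcmc_control()].
#' @return object of class `feature_fit` with coefficient draws per class,
#'   the model design, state levels, and convergence diagnostics.
#' @export
fit_feature_model <- function(feature, language_table, grid,
                              control = mcmc_control()) {
  lt <- language_table
  if (!feature %in% names(lt)) stop("unknown feature column: ", feature)
  coded <- !is.na(lt[[feature]])
  lt <- lt[coded, , drop = FALSE]
  if (!nrow(lt)) stop("feature has no coded languages")
  unmapped <- is.na(lt$family) | is.na(lt$area)
  if (any(unmapped)) {
    stop("unmapped language(s): ",
         paste(utils::head(lt$language_id[unmapped], 5), collapse = ", "))
  }
  if (is.null(lt$cell_id)) lt$cell_id <- assign_points(lt$lon, lt$lat, grid)
  state <- factor(lt[[feature]])
  J <- nlevels(state)
  if (J < 2) stop("feature '", feature, "' has a single observed state; ",
                  "entropy is degenerate")
  cell <- factor(lt$cell_id)
  area <- factor(lt$area)
  family <- factor(lt$family)
  ci <- match(levels(cell), grid$cells$cell_id)
  xy_cell <- cbind(grid$cells$centroid_x[ci], grid$cells$centroid_y[ci])
  S_cell <- tensor_spline_basis(xy_cell, k = control$spline_k)
  K <- if (is.null(S_cell)) 0L else ncol(S_cell)
  blocks <- list(Matrix::Matrix(matrix(1, nrow(lt), 1), sparse = TRUE))
  if (K > 0) {
    blocks <- c(blocks, list(Matrix::Matrix(
      S_cell[as.integer(cell), , drop = FALSE], sparse = TRUE)))
  }
  groups <- list(area = area, cell = cell, family = family)
  blocks <- c(blocks, lapply(groups, sparse_indicator))
  A <- do.call(cbind, blocks)
  Gs <- vapply(groups, nlevels, integer(1))
  idx_sm <- if (K > 0) 1 + seq_len(K) else integer(0)
  off <- 1 + K
  idx_grp <- lapply(Gs, function(g) { i <- off + seq_len(g); off <<- off + g; i })
  ntot <- off
  g_int <- lapply(groups, as.integer)
  n <- nrow(lt)
  nclass <- J - 1 # non-reference classes carry coefficients
  Y <- matrix(0, n, J)
  Y[cbind(seq_len(n), as.integer(state))] <- 1
  prior_sd <- control$prior_sd
  n_keep <- control$iter
  run_chain <- function(chain_seed) with_seed(chain_seed, {
    theta <- matrix(0, ntot, nclass)
    sig_sm <- 0.5
    sig_g <- stats::setNames(rep(0.5, length(Gs)), names(Gs))
    keep_theta <- array(NA_real_, c(n_keep, ntot, nclass))
    keep_sig <- matrix(NA_real_, n_keep, 1 + length(Gs))
    colnames(keep_sig) <- c("sigma_spline", paste0("sigma_", names(Gs)))
    total <- control$warmup + n_keep
    eta <- matrix(0, n, J) # class 1 = reference, always 0
    for (it in seq_len(total)) {
      prior_prec <- c(1 / prior_sd^2,
                      rep(1 / max(sig_sm, 1e-5)^2, K),
                      unlist(mapply(function(g, s) rep(1 / max(s, 1e-5)^2, g),
                                    Gs, sig_g, SIMPLIFY = FALSE)))
      om_last <- NULL
      for (j in seq_len(nclass)) {
        cls <- j + 1L
        eta_j <- as.numeric(A %*% theta[, j])
        if (J == 2) {
          psi <- eta_j
          cj <- 0
        } else {
          other <- eta[, -cls, drop = FALSE]
          cj <- apply(other, 1, logsumexp)
          psi <- eta_j - cj
        }
        om <- rpg1(psi)
        kap <- Y[, cls] - 0.5
        b <- Matrix::crossprod(A, kap + om * cj)
        Q <- Matrix::crossprod(A, om * A) + Matrix::Diagonal(x = prior_prec)
        theta[, j] <- rmvn_prec_sparse(Q, b)
        eta[, cls] <- as.numeric(A %*% theta[, j])
        om_last <- om
      }
      # scale updates: centered slice, plus an interweaved (ASIS) rescale in
      # the binary case where the augmented likelihood is a single Gaussian
      if (K > 0) {
        sig_sm <- update_scale(sig_sm, as.numeric(theta[idx_sm, ]), prior_sd)
      }
      for (gi in seq_along(Gs)) {
        sig_g[gi] <- update_scale(sig_g[gi],
                                  as.numeric(theta[idx_grp[[gi]], ]), prior_sd)
      }
      if (J == 2) {
        z <- (Y[, 2] - 0.5) / om_last
        e <- z - eta[, 2]
        if (K > 0) {
          ut <- theta[idx_sm, 1] / max(sig_sm, 1e-5)
          wv <- as.numeric(S_cell[as.integer(cell), , drop = FALSE] %*% ut)
          up <- asis_scale(e, om_last, wv, sig_sm, prior_sd)
          sig_sm <- max(abs(up$s), 1e-5)
          theta[idx_sm, 1] <- up$s * ut
          e <- up$e
        }
        for (gi in seq_along(Gs)) {
          ut <- theta[idx_grp[[gi]], 1] / max(sig_g[gi], 1e-5)
          wv <- ut[g_int[[gi]]]
          up <- asis_scale(e, om_last, wv, sig_g[gi], prior_sd)
          sig_g[gi] <- max(abs(up$s), 1e-5)
          theta[idx_grp[[gi]], 1] <- up$s * ut
          e <- up$e
        }
        eta[, 2] <- z - e
      }
      if (it > control$warmup) {
        k2 <- it - control$warmup
        keep_theta[k2, , ] <- theta
        keep_sig[k2, ] <- c(sig_sm, sig_g)
      }
    }
    list(theta = keep_theta, sig = keep_sig)
  })
  res <- lapply(seq_len(control$chains),
                function(ch) run_chain(control$seed + ch - 1))
  theta_draws <- do.call(abind1, lapply(res, `[[`, "theta"))
  sig_draws <- do.call(rbind, lapply(res, `[[`, "sig"))
  mon <- cbind(theta_draws[, 1, , drop = TRUE], sig_draws)
  mon <- as.matrix(mon)
  rh <- apply(mon, 2, function(col) split_rhat(matrix(col, ncol = control$chains)))
  es <- apply(mon, 2, function(col) ess_basic(matrix(col, ncol = control$chains)))
  structure(list(
    feature = feature, levels = levels(state), J = J,
    theta = theta_draws, sig = sig_draws,
    A = A, language_id = lt$language_id, cell = cell, area = area,
    idx_smooth = idx_sm, idx_group = idx_grp, S_cell = S_cell,
    cell_levels = levels(cell), area_of_cell = cell_area_lookup(cell, area),
    n_draws = nrow(sig_draws), chains = control$chains,
    max_rhat = max(rh, na.rm = TRUE), min_ess = min(es, na.rm = TRUE)),
    class = "feature_fit")
}

abind1 <- function(...) {
  args <- list(...)
  d <- dim(args[[1]])
  out <- array(NA_real_, c(sum(vapply(args, function(a) dim(a)[1], 1)),
                           d[2], d[3]))
  at <- 0
  for (a in args) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

cell_area_lookup <- function(cell, area) {
  vapply(levels(cell), function(cl) {
    as.character(area[match(cl, as.character(cell))])
  }, character(1))
}

#' Posterior state probabilities per grid cell
#'
#' For each posterior draw, computes every language's expected state
#' probability vector and aggregates to the cell level. The default
#' `"language_mean"` policy averages the vectors of all coded languages in
#' the cell (unweighted); `"cell_effect"` instead evaluates the linear
#' predictor directly at the cell (intercept + area + cell effects +
#' smooth, no family term).
#'
#' @param fit a `feature_fit`.
#' @param aggregation `"language_mean"` (default) or `"cell_effect"`.
#' @return named list (by `cell_id`) of draws x J probability matrices,
#'   each row on the simplex.
#' @export
cell_state_probabilities <- function(fit,
                                     aggregation = c("language_mean",
                                                     "cell_effect")) {
  aggregation <- match.arg(aggregation)
  D <- fit$n_draws
  J <- fit$J
  cells <- fit$cell_levels
  out <- stats::setNames(
    lapply(cells, function(cl) matrix(0, D, J,
                                      dimnames = list(NULL, fit$levels))),
    cells)
  if (aggregation == "language_mean") {
    n <- length(fit$cell)
    cell_int <- as.integer(fit$cell)
    counts <- tabulate(cell_int, nbins = length(cells))
    for (d in seq_len(D)) {
      eta <- matrix(0, n, J)
      for (j in seq_len(J - 1)) {
        eta[, j + 1] <- as.numeric(fit$A %*% fit$theta[d, , j])
      }
      P <- exp(eta - apply(eta, 1, logsumexp))
      agg <- rowsum(P, cell_int) / counts
      for (ci in seq_along(cells)) out[[ci]][d, ] <- agg[ci, ]
    }
  } else {
    nc <- length(cells)
    K <- length(fit$idx_smooth)
    area_idx <- match(fit$area_of_cell, levels(fit$area))
    for (d in seq_len(D)) {
      eta <- matrix(0, nc, J)
      for (j in seq_len(J - 1)) {
        th <- fit$theta[d, , j]
        e <- th[1] +
          th[fit$idx_group$area][area_idx] +
          th[fit$idx_group$cell]
        if (K > 0) e <- e + as.numeric(fit$S_cell %*% th[fit$idx_smooth])
        eta[, j + 1] <- e
      }
      P <- exp(eta - apply(eta, 1, logsumexp))
      for (ci in seq_len(nc)) out[[ci]][d, ] <- P[ci, ]
    }
  }
  out
}

#' Summarize posterior entropy per cell
#'
#' Computes the normalized Shannon entropy of each draw's cell-level state
#' probability vector, then its posterior mean and SD, and the same for
#' `logit(Hn)` with `Hn` clamped to `[1e-6, 1 - 1e-6]` before the logit
#' (exact 0/1 entropies occur in degenerate cells).
#'
#' @param cell_probs output of [cell_state_probabilities()].
#' @param feature_id feature label carried into the output.
#' @return data.frame with `feature_id`, `cell_id`, `mean_Hn`, `sd_Hn`,
#'   `mean_logit_Hn`, `sd_logit_Hn`.
#' @export
summarize_entropy <- function(cell_probs, feature_id = "feature") {
  rows <- lapply(names(cell_probs), function(cl) {
    P <- cell_probs[[cl]]
    if (nrow(P) < 2) stop("need at least 2 draws")
    hn <- normalized_entropy(P)
    hn_cl <- pmin(pmax(hn, 1e-6), 1 - 1e-6)
    lh <- stats::qlogis(hn_cl)
    data.frame(feature_id = feature_id, cell_id = cl,
               mean_Hn = mean(hn), sd_Hn = stats::sd(hn),
               mean_logit_Hn = mean(lh), sd_logit_Hn = stats::sd(lh),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Entropy summaries for a set of features
#'
#' Fits one hierarchical model per feature (independently, no cross-feature
#' pooling) and returns the stacked per-cell entropy summaries.
#'
#' @param features character vector of feature column names.
#' @param language_table see [fit_feature_model()].
#' @param grid a `geo_grid`.
#' @param control see [mcmc_control()].
#' @param aggregation passed to [cell_state_probabilities()].
#' @return data.frame of entropy summaries, one row per feature x cell.
#' @export
entropy_summaries <- function(features, language_table, grid,
                              control = mcmc_control(),
                              aggregation = "language_mean") {
  out <- lapply(seq_along(features), function(i) {
    ctl <- control
    ctl$seed <- control$seed + 1000L * (i - 1L)
    fit <- fit_feature_model(features[i], language_table, grid, ctl)
    summarize_entropy(cell_state_probabilities(fit, aggregation),
                      feature_id = features[i])
  })
  do.call(rbind, out)
}
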