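# The measurement-error hierarchical regression of logit-entropy on scaled
# Wright's F and cell-level covariates (model ladder m1-m8), with correlated
# varying intercepts/slopes by feature and by geohistorical area, varying
# intercepts by grid cell, a tensor-product spatial smooth, known
# per-observation response SD, and (when F is included) a latent true
# predictor with Normal(F_obs, F_sd) measurement model.
#
# Inference is a blocked Gibbs sampler: all regression coefficients are
# drawn jointly from their sparse Gaussian full conditional; the latent
# per-cell F values have Gaussian full conditionals; scales get slice
# updates (half-Normal(0,2) priors) with interweaving for the iid blocks;
# the LKJ(2) correlation matrices are updated by slice sampling their vine
# partial correlations.

MODEL_LADDER <- list(
  m1 = c("R", "T"),
  m2 = c("R", "T", "P1", "P2"),
  m3 = c("R", "T", "D"),
  m4 = c("R", "T", "F"),
  m5 = c("R", "T", "P1", "P2", "D"),
  m6 = c("R", "T", "P1", "P2", "F"),
  m7 = c("R", "T", "D", "F"),
  m8 = c("R", "T", "P1", "P2", "D", "F"))

#' Model specifications of the additive predictor ladder
#'
#' `m1` is the null model with log language richness (`R`) and log taxonomic
#' diversity (`T`); `m2`-`m7` add environmental PCs (`P1`, `P2`), log
#' population density (`D`) and/or scaled Wright's F (`F`); `m8` includes
#' all predictors. Every included fixed effect has matching varying slopes
#' by feature and by area; all models carry varying intercepts by feature,
#' area and cell, and the tensor smooth.
#'
#' @param name one of `"m1"`..`"m8"`.
#' @return list with `name` and `fixed` (character vector of predictors).
#' @export
model_spec <- function(name) {
  name <- match.arg(name, names(MODEL_LADDER))
  list(name = name, fixed = MODEL_LADDER[[name]])
}

#' Assemble the regression dataset
#'
#' Inner join of per-feature-per-cell entropy summaries, per-cell scaled F
#' estimates and per-cell covariates: one row per feature x cell where both
#' the linguistic and the genetic data are available. The predictors `R`,
#' `T`, `P1`, `P2`, `D` are centered and scaled over the unique included
#' cells (not over rows, to avoid weighting by feature coverage); `F` keeps
#' the scale set by [scale_F()].
#'
#' @param entropy data.frame from [entropy_summaries()] /
#'   [summarize_entropy()].
#' @param f_cells data.frame from [scale_F()] (needs `cell_id`, `scaled_F`,
#'   `scaled_sd`).
#' @param covariates data.frame with `cell_id`, `area`, and raw predictor
#'   columns `R`, `T`, `P1`, `P2`, `D`.
#' @param grid a `geo_grid` supplying projected cell centroids.
#' @return data.frame of regression rows (`feature_id`, `cell_id`, `area`,
#'   `y`, `y_sd`, centered predictors, `F_obs`, `F_sd`, `cx`, `cy`).
#' @export
build_dataset <- function(entropy, f_cells, covariates, grid) {
  cells <- Reduce(intersect, list(unique(entropy$cell_id), f_cells$cell_id,
                                  covariates$cell_id))
  if (!length(cells)) stop("no cells with both linguistic and genetic data")
  cov2 <- covariates[match(cells, covariates$cell_id), , drop = FALSE]
  for (v in c("R", "T", "P1", "P2", "D")) {
    if (!v %in% names(cov2)) stop("covariates lack column ", v)
    s <- stats::sd(cov2[[v]])
    cov2[[v]] <- if (s > 0) (cov2[[v]] - mean(cov2[[v]])) / s else 0
  }
  ent <- entropy[entropy$cell_id %in% cells, , drop = FALSE]
  m <- match(ent$cell_id, cells)
  fidx <- match(ent$cell_id, f_cells$cell_id)
  gi <- match(ent$cell_id, grid$cells$cell_id)
  data.frame(
    feature_id = ent$feature_id, cell_id = ent$cell_id,
    area = cov2$area[m],
    y = ent$mean_logit_Hn, y_sd = ent$sd_logit_Hn,
    R = cov2$R[m], T = cov2$T[m], P1 = cov2$P1[m], P2 = cov2$P2[m],
    D = cov2$D[m],
    F_obs = f_cells$scaled_F[fidx], F_sd = f_cells$scaled_sd[fidx],
    cx = grid$cells$centroid_x[gi], cy = grid$cells$centroid_y[gi],
    stringsAsFactors = FALSE)
}

# Build the sparse design template. Returns the matrix (with placeholder 1s
# in F-dependent entries), index bookkeeping, and positions in @x of the
# F-dependent entries together with the cell index feeding each.
build_regression_design <- function(rows, fixed, S_exp) {
  n <- nrow(rows)
  feat <- factor(rows$feature_id)
  area <- factor(rows$area)
  cell <- factor(rows$cell_id)
  p <- length(fixed)
  d <- 1L + p
  has_F <- "F" %in% fixed
  Xcov <- lapply(fixed, function(v) if (v == "F") rep(1, n) else rows[[v]])
  names(Xcov) <- fixed
  K <- if (is.null(S_exp)) 0L else ncol(S_exp)
  Gf <- nlevels(feat); Ga <- nlevels(area); Gc <- nlevels(cell)
  iv <- integer(0); jv <- integer(0); xv <- numeric(0); fdep <- logical(0)
  add <- function(i, j, x, isF) {
    iv <<- c(iv, i); jv <<- c(jv, j); xv <<- c(xv, x)
    fdep <<- c(fdep, rep(isF, length(i)))
  }
  # fixed: intercept + p covariates
  add(seq_len(n), rep(1L, n), rep(1, n), FALSE)
  for (k in seq_len(p)) {
    add(seq_len(n), rep(1L + k, n), Xcov[[k]], fixed[k] == "F")
  }
  off <- 1L + p
  if (K > 0) {
    for (k in seq_len(K)) add(seq_len(n), rep(off + k, n), S_exp[, k], FALSE)
    off <- off + K
  }
  idx_sm <- if (K > 0) 1L + p + seq_len(K) else integer(0)
  add(seq_len(n), off + as.integer(cell), rep(1, n), FALSE)
  idx_cell <- off + seq_len(Gc)
  off <- off + Gc
  # correlated blocks: coefficients ordered group-major (g1: d, g2: d, ...)
  for (blk in c("feat", "area")) {
    fac <- if (blk == "feat") feat else area
    base <- off + (as.integer(fac) - 1L) * d
    add(seq_len(n), base + 1L, rep(1, n), FALSE)
    for (k in seq_len(p)) {
      add(seq_len(n), base + 1L + k, Xcov[[k]], fixed[k] == "F")
    }
    off <- off + nlevels(fac) * d
  }
  idx_feat <- 1L + p + K + Gc + seq_len(Gf * d)
  idx_area <- 1L + p + K + Gc + Gf * d + seq_len(Ga * d)
  ntot <- off
  # use placeholder 1 in F-dependent slots so the sparsity pattern is fixed,
  # and nudge exact zeros so no entry is dropped from the pattern
  xv[fdep] <- 1
  xv[xv == 0] <- 1e-300
  A <- Matrix::sparseMatrix(i = iv, j = jv, x = xv, dims = c(n, ntot))
  ordc <- order(jv, iv)
  pos <- integer(length(iv)); pos[ordc] <- seq_along(iv)
  list(A = A, pos_F = pos[fdep], cell_of_F = as.integer(cell)[iv[fdep]],
       iF_rows = iv[fdep], iF_cols = jv[fdep],
       n = n, p = p, d = d, K = K, has_F = has_F,
       feat = feat, area = area, cell = cell,
       idx_beta = seq_len(1L + p), idx_sm = idx_sm, idx_cell = idx_cell,
       idx_feat = idx_feat, idx_area = idx_area, ntot = ntot)
}

#' Fit a diversity regression model
#'
#' Fits the measurement-error hierarchical regression
#' `y_i ~ N(eta_i, sigma_i)` with `sigma_i = sqrt(y_sd_i^2 + sigma^2)`,
#' where `eta` includes the intercept, the spec's fixed effects with
#' correlated varying intercepts/slopes by feature and by area (LKJ(2)
#' priors on the correlation matrices, half-Normal(0,2) on all SDs),
#' varying intercepts by cell, and a tensor-product smooth over projected
#' cell coordinates. When `F` is included it enters as a latent per-cell
#' true value with measurement model `F_obs_c ~ N(F_true_c, F_sd_c)`.
#'
#' @param spec a [model_spec()] (or model name string).
#' @param rows data.frame from [build_dataset()] or
#'   [simulate_regression_rows()].
#' @param control see [mcmc_control()].
#' @return object of class `diversity_fit` with posterior draw matrices,
#'   pointwise log-likelihood (`log_lik`), data, and convergence
#'   diagnostics. An error is raised (with the diagnostics attached) if
#'   split-Rhat exceeds 1.05 on monitored parameters, unless
#'   `control$allow_nonconverged` is set.
#' @export
fit_diversity_model <- function(spec, rows, control = mcmc_control()) {
  if (is.character(spec)) spec <- model_spec(spec)
  fixed <- spec$fixed
  if (nlevels(factor(rows$feature_id)) < 2 ||
      nlevels(factor(rows$area)) < 2) {
    stop("need >= 2 features and >= 2 areas for the correlated varying effects")
  }
  ucell <- !duplicated(rows$cell_id)
  S_cell <- tensor_spline_basis(cbind(rows$cx, rows$cy)[ucell, , drop = FALSE],
                                k = control$spline_k)
  S_exp <- if (is.null(S_cell)) NULL else {
    S_cell[match(rows$cell_id, rows$cell_id[ucell]), , drop = FALSE]
  }
  des <- build_regression_design(rows, fixed, S_exp)
  n <- des$n; p <- des$p; d <- des$d; K <- des$K
  y <- rows$y; y_sd <- rows$y_sd
  has_F <- des$has_F
  cell_int <- as.integer(des$cell)
  Gc <- nlevels(des$cell); Gf <- nlevels(des$feat); Ga <- nlevels(des$area)
  if (has_F) {
    F_obs <- rows$F_obs[match(levels(des$cell), rows$cell_id)]
    F_sd <- rows$F_sd[match(levels(des$cell), rows$cell_id)]
    iF <- which(fixed == "F") # position among covariates; slope comp = 1 + iF
  }
  feat_int <- as.integer(des$feat); area_int <- as.integer(des$area)
  # per-row covariate values for the d random-effect components
  # (intercept + slopes); the F column tracks the latent F_true draws
  Xrow <- cbind(1, vapply(fixed, function(v) {
    if (v == "F") rep(1, n) else rows[[v]]
  }, numeric(n)))
  prior_sd <- control$prior_sd
  n_keep <- control$iter
  npc <- d * (d - 1) / 2
  # prior-precision template: pattern fixed, numeric values updated in place
  ut_d <- upper.tri(matrix(0, d, d), diag = TRUE)
  tmpl_blocks <- list(Matrix::Diagonal(x = rep(1, 1 + p)))
  if (K > 0) tmpl_blocks <- c(tmpl_blocks,
                              list(Matrix::Diagonal(x = rep(1, K))))
  tmpl_blocks <- c(tmpl_blocks, list(Matrix::Diagonal(x = rep(1, Gc))),
                   rep(list(matrix(1, d, d)), Gf + Ga))
  P0_template <- Matrix::forceSymmetric(Matrix::bdiag(tmpl_blocks))
  p0_x <- function(sig_sm, sig_cell, Om_f, Om_a) {
    c(rep(1 / control$prior_sd^2, 1 + p),
      if (K > 0) rep(1 / sig_sm^2, K),
      rep(1 / sig_cell^2, Gc),
      rep(Om_f[ut_d], Gf), rep(Om_a[ut_d], Ga))
  }
  # small problems run much faster in dense arithmetic (no sparse-S4
  # dispatch overhead); large ones keep the sparse Cholesky path
  dense <- des$ntot <= 400 && n <= 3000
  ij_F <- cbind(des$iF_rows, des$iF_cols)
  run_chain <- function(chain_seed) with_seed(chain_seed, {
    A <- if (dense) as.matrix(des$A) else des$A
    P0 <- P0_template
    draw_theta <- make_prec_sampler()
    sigma <- max(stats::sd(y) / 2, 0.05)
    sig_cell <- 0.3; sig_sm <- 0.3
    tau_f <- rep(0.3, d); tau_a <- rep(0.3, d)
    pc_f <- rep(0, npc); pc_a <- rep(0, npc)
    step_f <- 0.15; step_a <- 0.15
    R_f <- diag(d); R_a <- diag(d)
    F_true <- if (has_F) F_obs else NULL
    theta <- rep(0, des$ntot)
    keep <- list(
      beta = matrix(NA_real_, n_keep, 1 + p,
                    dimnames = list(NULL, c("alpha", fixed))),
      smooth = matrix(NA_real_, n_keep, K),
      cell = matrix(NA_real_, n_keep, Gc),
      feat = array(NA_real_, c(n_keep, Gf, d)),
      area = array(NA_real_, c(n_keep, Ga, d)),
      scales = matrix(NA_real_, n_keep, 2 + 2 * d,
                      dimnames = list(NULL, c("sigma", "sigma_cell",
                                              paste0("tau_feat", seq_len(d)),
                                              paste0("tau_area", seq_len(d))))),
      sigma_spline = matrix(NA_real_, n_keep, 1),
      corr_f = array(NA_real_, c(n_keep, d, d)),
      corr_a = array(NA_real_, c(n_keep, d, d)),
      F_true = if (has_F) matrix(NA_real_, n_keep, Gc) else NULL,
      log_lik = matrix(NA_real_, n_keep, n))
    total <- control$warmup + n_keep
    for (it in seq_len(total)) {
      if (has_F) {
        if (dense) {
          A[ij_F] <- F_true[des$cell_of_F]
        } else {
          A@x[des$pos_F] <- F_true[des$cell_of_F]
        }
      }
      W <- 1 / (y_sd^2 + sigma^2)
      Om_f <- chol2inv(chol(diag(tau_f) %*% R_f %*% diag(tau_f)))
      Om_a <- chol2inv(chol(diag(tau_a) %*% R_a %*% diag(tau_a)))
      P0@x <- p0_x(sig_sm, sig_cell, Om_f, Om_a)
      if (dense) {
        Q <- crossprod(sqrt(W) * A) + as.matrix(P0)
        b <- crossprod(A, W * y)
        chQ <- chol(Q)
        mu <- backsolve(chQ, backsolve(chQ, b, transpose = TRUE))
        theta <- as.numeric(mu + backsolve(chQ, stats::rnorm(des$ntot)))
      } else {
        Aw <- sqrt(W) * A
        Q <- Matrix::crossprod(Aw) + P0
        b <- Matrix::crossprod(A, W * y)
        theta <- draw_theta(Q, b)
      }
      eta <- as.numeric(A %*% theta)
      e <- y - eta
      # latent F per cell
      if (has_F) {
        Uf <- matrix(theta[des$idx_feat], ncol = d, byrow = TRUE)
        Ua <- matrix(theta[des$idx_area], ncol = d, byrow = TRUE)
        g <- theta[1 + iF] + Uf[feat_int, 1 + iF] + Ua[area_int, 1 + iF]
        r <- e + g * F_true[cell_int]
        prec <- 1 / pmax(F_sd, 1e-6)^2 +
          as.numeric(rowsum(W * g^2, cell_int, reorder = TRUE))
        mu <- (F_obs / pmax(F_sd, 1e-6)^2 +
                 as.numeric(rowsum(W * g * r, cell_int, reorder = TRUE))) / prec
        F_true <- mu + stats::rnorm(Gc) / sqrt(prec)
        F_true[F_sd == 0] <- F_obs[F_sd == 0]
        e <- r - g * F_true[cell_int]
        Xrow[, 1 + iF] <- F_true[cell_int]
      }
      # scale updates (slice + interweaving for the iid blocks)
      sig_cell <- update_scale(sig_cell, theta[des$idx_cell], prior_sd)
      ut <- theta[des$idx_cell] / max(sig_cell, 1e-5)
      up <- asis_scale(e, W, ut[cell_int], sig_cell, prior_sd)
      sig_cell <- max(abs(up$s), 1e-5)
      theta[des$idx_cell] <- up$s * ut
      e <- up$e
      if (K > 0) {
        sig_sm <- update_scale(sig_sm, theta[des$idx_sm], prior_sd)
        ut <- theta[des$idx_sm] / max(sig_sm, 1e-5)
        wv <- as.numeric(S_exp %*% ut)
        up <- asis_scale(e, W, wv, sig_sm, prior_sd)
        sig_sm <- max(abs(up$s), 1e-5)
        theta[des$idx_sm] <- up$s * ut
        e <- up$e
      }
      Uf <- matrix(theta[des$idx_feat], ncol = d, byrow = TRUE)
      Ua <- matrix(theta[des$idx_area], ncol = d, byrow = TRUE)
      # scales and correlations: centered slice updates for the SDs,
      # adaptive joint Metropolis for the correlations, interweaved with a
      # non-centered Gaussian rescale per component (u[, k] = tau_k xi[, k]
      # with xi ~ N(0, R) independent of tau). The sweep runs twice: the
      # group-scale parameters are the slowest-mixing block.
      for (sweep2 in 1:2) {
        upf <- update_sigma_lkj(Uf, tau_f, pc_f, prior_sd, pc_step = step_f)
        tau_f <- upf$tau; pc_f <- upf$pc; R_f <- upf$R
        upa <- update_sigma_lkj(Ua, tau_a, pc_a, prior_sd, pc_step = step_a)
        tau_a <- upa$tau; pc_a <- upa$pc; R_a <- upa$R
        if (it <= control$warmup) { # Robbins-Monro step adaptation
          if (!is.na(upf$pc_accept)) {
            step_f <- min(0.6, max(0.01,
                                   step_f * exp(0.1 * (upf$pc_accept - 0.25))))
          }
          if (!is.na(upa$pc_accept)) {
            step_a <- min(0.6, max(0.01,
                                   step_a * exp(0.1 * (upa$pc_accept - 0.25))))
          }
        }
        for (k in seq_len(d)) {
          xi <- Uf[, k] / max(tau_f[k], 1e-6)
          up <- asis_scale(e, W, xi[feat_int] * Xrow[, k], tau_f[k], prior_sd)
          tau_f[k] <- max(abs(up$s), 1e-5)
          Uf[, k] <- up$s * xi
          e <- up$e
        }
        for (k in seq_len(d)) {
          xi <- Ua[, k] / max(tau_a[k], 1e-6)
          up <- asis_scale(e, W, xi[area_int] * Xrow[, k], tau_a[k], prior_sd)
          tau_a[k] <- max(abs(up$s), 1e-5)
          Ua[, k] <- up$s * xi
          e <- up$e
        }
      }
      theta[des$idx_feat] <- as.numeric(t(Uf))
      theta[des$idx_area] <- as.numeric(t(Ua))
      if (is.null(control$fix_sigma)) {
        lf_sig <- function(ls) {
          s <- exp(ls)
          sum(stats::dnorm(e, 0, sqrt(y_sd^2 + s^2), log = TRUE)) +
            stats::dnorm(s, 0, prior_sd, log = TRUE) + ls
        }
        sigma <- exp(slice_sample1(log(sigma), lf_sig, w = 0.4,
                                   lower = log(1e-4), upper = log(50)))
      } else {
        sigma <- control$fix_sigma
      }
      if (it > control$warmup) {
        j <- it - control$warmup
        keep$beta[j, ] <- theta[des$idx_beta]
        if (K > 0) keep$smooth[j, ] <- theta[des$idx_sm]
        keep$cell[j, ] <- theta[des$idx_cell]
        keep$feat[j, , ] <- Uf
        keep$area[j, , ] <- Ua
        keep$scales[j, ] <- c(sigma, sig_cell, tau_f, tau_a)
        keep$sigma_spline[j, 1] <- sig_sm
        keep$corr_f[j, , ] <- R_f
        keep$corr_a[j, , ] <- R_a
        if (has_F) keep$F_true[j, ] <- F_true
        keep$log_lik[j, ] <- stats::dnorm(y, y - e, sqrt(y_sd^2 + sigma^2),
                                          log = TRUE)
      }
    }
    keep
  })
  res <- lapply(seq_len(control$chains),
                function(ch) run_chain(control$seed + ch - 1))
  bindm <- function(name) do.call(rbind, lapply(res, `[[`, name))
  binda <- function(name) {
    a <- lapply(res, `[[`, name)
    out <- array(NA_real_, c(sum(vapply(a, function(x) dim(x)[1], 1)),
                             dim(a[[1]])[2], dim(a[[1]])[3]))
    at <- 0
    for (x in a) { out[at + seq_len(dim(x)[1]), , ] <- x; at <- at + dim(x)[1] }
    out
  }
  draws <- list(beta = bindm("beta"), smooth = bindm("smooth"),
                cell = bindm("cell"), feat = binda("feat"),
                area = binda("area"), scales = bindm("scales"),
                sigma_spline = bindm("sigma_spline"),
                corr_f = binda("corr_f"), corr_a = binda("corr_a"),
                F_true = if (has_F) bindm("F_true") else NULL)
  log_lik <- bindm("log_lik")
  mon <- cbind(draws$beta, draws$scales)
  rh <- apply(mon, 2, function(col) split_rhat(matrix(col, ncol = control$chains)))
  es <- apply(mon, 2, function(col) ess_basic(matrix(col, ncol = control$chains)))
  fit <- structure(list(
    spec = spec, draws = draws, log_lik = log_lik,
    data = list(y = y, y_sd = y_sd, rows = rows),
    levels = list(feature = levels(des$feat), area = levels(des$area),
                  cell = levels(des$cell)),
    fixed = fixed, d = d,
    max_rhat = max(rh, na.rm = TRUE), min_ess = min(es, na.rm = TRUE),
    rhat = rh, ess = es, control = control), class = "diversity_fit")
  if (fit$max_rhat > 1.05 && !isTRUE(control$allow_nonconverged)) {
    worst <- names(which.max(rh))
    stop(sprintf(paste0("diversity model '%s' did not converge at the ",
                        "configured settings: max split-Rhat %.3f (%s); ",
                        "increase warmup/iter"),
                 spec$name, fit$max_rhat, worst))
  }
  fit
}

#' @export
print.diversity_fit <- function(x, ...) {
  cat(sprintf("diversity regression %s: %d rows, %d features, %d areas, %d cells\n",
              x$spec$name, length(x$data$y), length(x$levels$feature),
              length(x$levels$area), length(x$levels$cell)))
  cat(sprintf("max split-Rhat %.3f, min ESS %.0f\n", x$max_rhat, x$min_ess))
  print(posterior_summary(x))
  invisible(x)
}

#' Posterior summary of fixed effects and scales
#'
#' @param fit a `diversity_fit`.
#' @return data.frame with mean, SD, 50/89/95% HPDIs and `P(>0)` per term.
#' @export
posterior_summary <- function(fit) {
  mon <- cbind(fit$draws$beta, fit$draws$scales)
  do.call(rbind, lapply(colnames(mon), function(cn) {
    summarize_draws_vector(mon[, cn], cn)
  }))
}

#' Group-level marginal slopes
#'
#' Per-group slope draws `beta_p + group deviation` for a given predictor,
#' by feature or by area, with posterior mean, 50/89/95% HPDIs,
#' `P(slope > 0)`, and the 89%-HPDI-excludes-zero classification.
#'
#' @param fit a `diversity_fit` including the predictor.
#' @param group `"feature"` or `"area"`.
#' @param predictor one of the fit's fixed effects (default `"F"`).
#' @return data.frame, one row per group level.
#' @export
marginal_slopes <- function(fit, group = c("feature", "area"),
                            predictor = "F") {
  group <- match.arg(group)
  if (!predictor %in% fit$fixed) {
    stop("model ", fit$spec$name, " does not include predictor ", predictor)
  }
  comp <- 1 + match(predictor, fit$fixed)
  arr <- if (group == "feature") fit$draws$feat else fit$draws$area
  lev <- fit$levels[[if (group == "feature") "feature" else "area"]]
  bcol <- fit$draws$beta[, 1 + match(predictor, fit$fixed)]
  out <- lapply(seq_along(lev), function(g) {
    s <- summarize_draws_vector(bcol + arr[, g, comp], lev[g])
    s$excludes_zero_89 <- s$hpdi89_lower > 0 | s$hpdi89_upper < 0
    s
  })
  out <- do.call(rbind, out)
  names(out)[1] <- "group"
  out
}

#' Taxonomic diversity of a set of languages
#'
#' Surrogate index rewarding many families/branches at similar taxonomic
#' levels: the mean, over taxonomy levels, of the effective number of
#' distinct nodes at that level (the exponential of the Shannon entropy of
#' node frequencies). Languages with shallower taxonomies than the deepest
#' local path keep occupying their terminal node at deeper levels, which
#' adjusts for uneven taxonomic depths. Strictly increases when a language
#' from a new family is added; the log of the index is the regression
#' predictor `T`.
#'
#' @param paths character vector of rooted taxonomy paths, one per
#'   language, `"family/branch/.../language"`.
#' @return the index (>= 1); empty input is an error.
#' @examples
#' taxonomic_diversity(c("F1/B1/L1", "F1/B1/L2", "F2/B1/L3"))
#' @export
taxonomic_diversity <- function(paths) {
  if (!length(paths)) stop("empty cell: taxonomic diversity undefined")
  parts <- strsplit(paths, "/", fixed = TRUE)
  depth <- max(lengths(parts))
  eff <- vapply(seq_len(depth), function(l) {
    nodes <- vapply(parts, function(p) {
      paste(p[seq_len(min(l, length(p)))], collapse = "/")
    }, character(1))
    f <- table(nodes) / length(nodes)
    exp(-sum(f * log(f)))
  }, numeric(1))
  mean(eff)
}

#' Simulate regression rows from the model's own generative structure
#'
#' Draws a dataset exactly from the diversity-regression model: correlated
#' feature and area effects, cell intercepts, known response SDs, and a
#' latent scaled-F predictor observed with error. Used for parameter
#' recovery, calibration and model-comparison experiments against known
#' truth.
#'
#' @param n_cells,n_features,n_areas dataset dimensions.
#' @param beta named vector of true fixed effects (subset of
#'   `R,T,P1,P2,D,F`); the `F` entry mirrors the effect scale of interest.
#' @param alpha true intercept.
#' @param tau_feature,tau_area SD of group intercepts and slopes (recycled
#'   to length `1 + length(beta)`).
#' @param sigma_cell SD of cell intercepts.
#' @param sigma residual SD.
#' @param y_sd_range range of the known per-row response SDs (uniform).
#' @param F_sd measurement SD of the scaled-F predictor.
#' @param seed integer seed.
#' @return list with `rows` (ready for [fit_diversity_model()]) and `truth`.
#' @export
simulate_regression_rows <- function(n_cells = 200, n_features = 40,
                                     n_areas = 10,
                                     beta = c(R = 0.1, T = -0.05, P1 = 0.05,
                                              P2 = 0, D = 0.05, F = 0.11),
                                     alpha = -0.9,
                                     tau_feature = c(0.5, rep(0.1, length(beta))),
                                     tau_area = c(0.3, rep(0.08, length(beta))),
                                     sigma_cell = 0.15, sigma = 0.2,
                                     y_sd_range = c(0.05, 0.3),
                                     F_sd = 0.2, seed = 1) {
  with_seed(seed, {
    p <- length(beta)
    d <- 1 + p
    tau_feature <- rep_len(tau_feature, d)
    tau_area <- rep_len(tau_area, d)
    cells <- sprintf("C%04d", seq_len(n_cells))
    areas <- sprintf("A%02d", sample.int(n_areas, n_cells, replace = TRUE))
    cx <- stats::runif(n_cells, -8000, 8000)
    cy <- stats::runif(n_cells, -6000, 6000)
    covs <- matrix(stats::rnorm(n_cells * p), n_cells, p,
                   dimnames = list(NULL, names(beta)))
    F_true <- if ("F" %in% names(beta)) stats::rnorm(n_cells) else NULL
    if (!is.null(F_true)) covs[, "F"] <- F_true
    Uf <- sweep(matrix(stats::rnorm(n_features * d), n_features, d), 2,
                tau_feature, "*")
    Ua <- sweep(matrix(stats::rnorm(n_areas * d), n_areas, d), 2,
                tau_area, "*")
    cc <- stats::rnorm(n_cells, 0, sigma_cell)
    area_int <- as.integer(factor(areas, levels = sprintf("A%02d", 1:n_areas)))
    rows <- expand.grid(feature = seq_len(n_features), cell = seq_len(n_cells))
    fi <- rows$feature; ci <- rows$cell; ai <- area_int[ci]
    X <- cbind(1, covs[ci, , drop = FALSE])
    eta <- alpha + X[, -1, drop = FALSE] %*% beta + Uf[fi, 1] + Ua[ai, 1] +
      rowSums(X[, -1, drop = FALSE] * (Uf[fi, -1, drop = FALSE] +
                                         Ua[ai, -1, drop = FALSE])) + cc[ci]
    y_sd <- stats::runif(nrow(rows), y_sd_range[1], y_sd_range[2])
    y <- stats::rnorm(nrow(rows), as.numeric(eta), sqrt(y_sd^2 + sigma^2))
    F_obs <- if (!is.null(F_true)) F_true + stats::rnorm(n_cells, 0, F_sd)
    out <- data.frame(
      feature_id = sprintf("feat%03d", fi), cell_id = cells[ci],
      area = areas[ci], y = y, y_sd = y_sd,
      R = if ("R" %in% names(beta)) covs[ci, "R"] else 0,
      T = if ("T" %in% names(beta)) covs[ci, "T"] else 0,
      P1 = if ("P1" %in% names(beta)) covs[ci, "P1"] else 0,
      P2 = if ("P2" %in% names(beta)) covs[ci, "P2"] else 0,
      D = if ("D" %in% names(beta)) covs[ci, "D"] else 0,
      F_obs = if (!is.null(F_true)) F_obs[ci] else 0,
      F_sd = if (!is.null(F_true)) rep(F_sd, length(ci)) else 0,
      cx = cx[ci], cy = cy[ci], stringsAsFactors = FALSE)
    list(rows = out,
         truth = list(alpha = alpha, beta = beta, tau_feature = tau_feature,
                      tau_area = tau_area, sigma_cell = sigma_cell,
                      sigma = sigma, F_true = F_true, Uf = Uf, Ua = Ua))
  })
}
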