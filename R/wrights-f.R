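# Wright's inbreeding coefficient F from SNP genotypes, and its
# hierarchically smoothed, z-scored cell-level summaries.

#' Compute individual-level Wright's F from genotypes
#'
#' For each individual, `F = (H_O - H_E) / (N_NM - H_E)` where `H_O` is the
#' observed number of homozygous genotypes over the individual's non-missing
#' SNPs, `N_NM` the number of non-missing SNPs, and `H_E` the expected
#' homozygote count under Hardy-Weinberg: `H_E = sum_j (1 - 2 p_j q_j c_j)`
#' over the same SNPs. With `correction = "small_sample"` the factor
#' `c_j = N_j / (N_j - 1)` (with `N_j` = non-missing individuals at SNP `j`,
#' counted in allele-bearing individuals) mirrors the reference tool's
#' finite-sample adjustment; `correction = "none"` uses the plain
#' Hardy-Weinberg expectation `c_j = 1`.
#'
#' Monomorphic SNPs (estimated frequency 0 or 1) are excluded. By default
#' allele frequencies are estimated from the full pooled sample.
#'
#' @param genotypes integer matrix, individuals x SNPs, values in
#'   `{0, 1, 2, NA}` (minor-allele dosage).
#' @param allele_freqs optional numeric vector of per-SNP allele
#'   frequencies in (0, 1); if `NULL` they are estimated from `genotypes`.
#' @param correction `"small_sample"` (default) or `"none"`.
#' @return data.frame with `individual_id`, `H_O`, `H_E`, `N_NM`, `F`;
#'   individuals with a degenerate denominator (`N_NM == H_E`) get `F = NA`
#'   and are flagged in the `degenerate` column.
#' @export
compute_individual_F <- function(genotypes,
                                 allele_freqs = NULL,
                                 correction = c("small_sample", "none")) {
  correction <- match.arg(correction)
  G <- as.matrix(genotypes)
  if (!all(G %in% c(0L, 1L, 2L, NA))) {
    stop("genotypes must be coded 0/1/2 with NA for missing")
  }
  n_obs <- colSums(!is.na(G))
  if (is.null(allele_freqs)) {
    p_est <- colSums(G, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  } else {
    if (length(allele_freqs) != ncol(G)) {
      stop("allele_freqs length must match the number of SNPs")
    }
    p_est <- allele_freqs
  }
  keep <- is.finite(p_est) & p_est > 0 & p_est < 1 & n_obs >= 1
  if (!any(keep)) stop("no polymorphic SNPs available")
  G <- G[, keep, drop = FALSE]
  p <- p_est[keep]
  q <- 1 - p
  cj <- if (correction == "small_sample") {
    Nj <- n_obs[keep]
    2 * Nj / (2 * Nj - 1)
  } else {
    rep(1, sum(keep))
  }
  exp_hom_j <- 1 - 2 * p * q * cj
  nm <- !is.na(G)
  H_O <- rowSums((G == 0 | G == 2) & nm, na.rm = TRUE)
  N_NM <- rowSums(nm)
  H_E <- as.numeric(nm %*% exp_hom_j)
  denom <- N_NM - H_E
  degenerate <- abs(denom) < 1e-9
  Fv <- ifelse(degenerate, NA_real_, (H_O - H_E) / denom)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- sprintf("I%05d", seq_len(nrow(G)))
  data.frame(individual_id = ids, H_O = H_O, H_E = H_E, N_NM = N_NM,
             F = Fv, degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the hierarchical spatial model for cell-level F
#'
#' Gaussian hierarchical model for individual F with random intercepts by
#' geohistorical area, grid cell and population, plus a tensor-product
#' spline smooth over the projected cell centroids:
#' `F_i ~ N(alpha + a_area + a_cell + a_pop + t2(x, y), sigma)`, with
#' half-Normal(0, 2) priors on all scales and Normal(0, 2) on the intercept.
#' Sampled by a blocked Gibbs sampler (joint Gaussian coefficient updates,
#' slice updates for scales).
#'
#' @param f_individuals data.frame from [compute_individual_F()], rows with
#'   `NA` F are dropped.
#' @param assignments data.frame with one row per individual (same order):
#'   `population`, `area`, `cell_id`.
#' @param grid a `geo_grid` (provides centroid coordinates for the smooth).
#' @param control sampler control list, see [mcmc_control()].
#' @return object of class `f_cell_fit`: `cells` data.frame
#'   (`cell_id`, `mean_F`, `sd_F`), draw matrices, and convergence
#'   diagnostics (`max_rhat`, `min_ess`).
#' @export
fit_F_model <- function(f_individuals, assignments, grid,
                        control = mcmc_control()) {
  stopifnot(nrow(f_individuals) == nrow(assignments))
  ok <- is.finite(f_individuals$F)
  y <- f_individuals$F[ok]
  asg <- assignments[ok, , drop = FALSE]
  cell <- factor(asg$cell_id)
  area <- factor(asg$area)
  pop <- factor(asg$population)
  ci <- match(levels(cell), grid$cells$cell_id)
  if (anyNA(ci)) stop("assignments contain cell ids absent from the grid")
  xy <- cbind(grid$cells$centroid_x[ci], grid$cells$centroid_y[ci])
  S_cell <- tensor_spline_basis(xy, k = control$spline_k)
  fit <- gibbs_gaussian(
    y = y, y_sd = rep(0, length(y)),
    X = matrix(1, length(y), 1, dimnames = list(NULL, "alpha")),
    iid_groups = list(area = area, cell = cell, population = pop),
    smooth = S_cell[as.integer(cell), , drop = FALSE],
    control = control)
  # cell-level expected F: intercept + area effect + cell effect + smooth
  area_of_cell <- factor(
    vapply(levels(cell),
           function(cl) as.character(asg$area[match(cl, asg$cell_id)]),
           character(1)), levels = levels(area))
  eta <- fit$draws$beta[, 1] +
    fit$draws$group$area[, as.integer(area_of_cell), drop = FALSE] +
    fit$draws$group$cell
  if (!is.null(S_cell)) eta <- eta + fit$draws$smooth %*% t(S_cell)
  cells <- data.frame(cell_id = levels(cell),
                      mean_F = colMeans(eta),
                      sd_F = apply(eta, 2, stats::sd),
                      stringsAsFactors = FALSE)
  structure(list(cells = cells, cell_draws = eta, fit = fit,
                 max_rhat = fit$max_rhat, min_ess = fit$min_ess),
            class = "f_cell_fit")
}

#' z-score cell-level F estimates
#'
#' Centers and scales the posterior mean F across cells; the posterior SDs
#' are divided by the same scale factor so predictor and measurement error
#' stay on one scale. `plot_transform = TRUE` additionally returns
#' `1 - scaled_F` (the plotting transform under which higher values mean
#' higher genetic diversity).
#'
#' @param estimates `f_cell_fit` or a data.frame with `cell_id`, `mean_F`,
#'   `sd_F`.
#' @param plot_transform also include the `1 - scaled_F` column.
#' @return data.frame with `cell_id`, `mean_F`, `sd_F`, `scaled_F`,
#'   `scaled_sd` (and optionally `one_minus_scaled_F`).
#' @export
scale_F <- function(estimates, plot_transform = FALSE) {
  cells <- if (inherits(estimates, "f_cell_fit")) estimates$cells else estimates
  if (nrow(cells) < 2) stop("need at least 2 cells to z-score")
  s <- stats::sd(cells$mean_F)
  if (s < 1e-12) stop("zero variance in cell means; cannot z-score")
  cells$scaled_F <- (cells$mean_F - mean(cells$mean_F)) / s
  cells$scaled_sd <- cells$sd_F / s
  if (plot_transform) cells$one_minus_scaled_F <- 1 - cells$scaled_F
  cells
}
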