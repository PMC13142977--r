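# The measurement-error hierarchical regression: dataset assembly, model
# ladder, taxonomic diversity, fitting properties and marginal slopes.

test_that("the model ladder has the prescribed predictor sets", {
  expect_equal(model_spec("m1")$fixed, c("R", "T"))
  expect_setequal(model_spec("m2")$fixed, c("R", "T", "P1", "P2"))
  expect_setequal(model_spec("m3")$fixed, c("R", "T", "D"))
  expect_setequal(model_spec("m4")$fixed, c("R", "T", "F"))
  expect_setequal(model_spec("m5")$fixed, c("R", "T", "P1", "P2", "D"))
  expect_setequal(model_spec("m6")$fixed, c("R", "T", "P1", "P2", "F"))
  expect_setequal(model_spec("m7")$fixed, c("R", "T", "D", "F"))
  expect_setequal(model_spec("m8")$fixed, c("R", "T", "P1", "P2", "D", "F"))
  expect_error(model_spec("m9"))
})

test_that("build_dataset performs the documented inner join", {
  g <- test_grid()
  cells <- g$cells$cell_id
  ent <- data.frame(
    feature_id = rep(c("f1", "f2", "f3"), times = c(10, 20, 5)),
    cell_id = c(cells[1:10], cells[1:20], cells[61:65]),
    mean_logit_Hn = 0, sd_logit_Hn = 0.1, stringsAsFactors = FALSE)
  fc <- data.frame(cell_id = cells[1:30], scaled_F = rnorm(30),
                   scaled_sd = 0.2, stringsAsFactors = FALSE)
  cov <- data.frame(cell_id = cells[1:40], area = "A1",
                    R = log(1:40), T = runif(40), P1 = rnorm(40),
                    P2 = rnorm(40), D = rnorm(40), stringsAsFactors = FALSE)
  rows <- build_dataset(ent, fc, cov, g)
  # f1 coded in 10 genetic cells, f2 in 20, f3 in 0 -> 30 rows
  expect_equal(nrow(rows), 30)
  expect_equal(sort(unique(rows$feature_id)), c("f1", "f2"))
  # predictors centered/scaled over unique cells
  u <- !duplicated(rows$cell_id)
  for (v in c("R", "T", "P1", "P2", "D")) {
    expect_lt(abs(mean(rows[[v]][u])), 1e-9)
  }
  # disjoint cell sets reject
  fc2 <- fc; fc2$cell_id <- cells[80:92][seq_len(nrow(fc2)) %% 13 + 1]
  expect_error(build_dataset(ent, data.frame(cell_id = cells[80:85],
                                             scaled_F = rnorm(6),
                                             scaled_sd = 0.2),
                             cov[31:40, ], g), "no cells")
})

test_that("taxonomic diversity rewards new families over sister dialects", {
  expect_equal(taxonomic_diversity("F1/B1/L1"), 1)
  expect_equal(log(taxonomic_diversity("F1/B1/L1")), 0)
  # k singleton families -> effective number k at every level
  expect_equal(taxonomic_diversity(c("F1/L1", "F2/L2", "F3/L3")), 3)
  base <- c("F1/B1/L1", "F1/B1/L2")
  sister <- taxonomic_diversity(c(base, "F1/B1/L3"))
  new_fam <- taxonomic_diversity(c(base, "F2/B1/L4"))
  expect_gt(new_fam, sister)
  expect_gt(sister, 0) # still defined
  # strictly increases when a new family's language is added
  expect_gt(new_fam, taxonomic_diversity(base))
  expect_error(taxonomic_diversity(character(0)), "empty")
})

test_that("simulated regression rows reproduce their own truth record", {
  sim <- simulate_regression_rows(n_cells = 30, n_features = 5, n_areas = 4,
                                  seed = 3)
  expect_equal(nrow(sim$rows), 150)
  expect_identical(sim$rows,
                   simulate_regression_rows(n_cells = 30, n_features = 5,
                                            n_areas = 4, seed = 3)$rows)
  expect_equal(length(sim$truth$F_true), 30)
  # observed F differs from the truth by the stated measurement scale
  dif <- sim$rows$F_obs[!duplicated(sim$rows$cell_id)] - sim$truth$F_true
  expect_lt(abs(sd(dif) - 0.2), 0.08)
})

test_that("identifiability preconditions are enforced", {
  sim <- simulate_regression_rows(n_cells = 10, n_features = 1, n_areas = 1,
                                  seed = 4)
  expect_error(fit_diversity_model("m1", sim$rows), ">= 2 features")
})

test_that("doubling the response SDs widens the genetic-slope posterior", {
  sim <- simulate_regression_rows(n_cells = 40, n_features = 8, n_areas = 5,
                                  beta = c(R = 0.1, T = -0.05, F = 0.2),
                                  seed = 11)
  ctl <- mcmc_control(chains = 2, warmup = 250, iter = 300, seed = 7,
                      spline_k = 0)
  ctl$fix_sigma <- 0.2 # hold the residual SD at truth so only y_sd moves
  ctl$allow_nonconverged <- TRUE
  f1 <- fit_diversity_model("m4", sim$rows, ctl)
  rows2 <- sim$rows
  rows2$y_sd <- 2 * rows2$y_sd
  f2 <- fit_diversity_model("m4", rows2, ctl)
  expect_gt(sd(f2$draws$beta[, "F"]), sd(f1$draws$beta[, "F"]))
})

test_that("vanishing response SDs converge to the error-free regression", {
  sim <- simulate_regression_rows(n_cells = 40, n_features = 8, n_areas = 5,
                                  beta = c(R = 0.1, T = -0.05, F = 0.2),
                                  seed = 13)
  ctl <- mcmc_control(chains = 2, warmup = 250, iter = 300, seed = 7,
                      spline_k = 0)
  ctl$allow_nonconverged <- TRUE
  rows0 <- sim$rows; rows0$y_sd <- 0
  rows_eps <- sim$rows; rows_eps$y_sd <- 1e-6
  f0 <- fit_diversity_model("m4", rows0, ctl)
  fe <- fit_diversity_model("m4", rows_eps, ctl)
  for (term in colnames(f0$draws$beta)) {
    expect_lt(abs(mean(f0$draws$beta[, term]) - mean(fe$draws$beta[, term])),
              3 * sd(f0$draws$beta[, term]) / sqrt(50) +
                3 * sd(fe$draws$beta[, term]) / sqrt(50) + 0.02)
  }
})

test_that("the plotting transform 1 - F flips the genetic slope", {
  sim <- simulate_regression_rows(n_cells = 40, n_features = 8, n_areas = 5,
                                  beta = c(R = 0.1, T = -0.05, F = 0.25),
                                  seed = 17)
  ctl <- mcmc_control(chains = 2, warmup = 250, iter = 300, seed = 7,
                      spline_k = 0)
  ctl$allow_nonconverged <- TRUE
  f1 <- fit_diversity_model("m4", sim$rows, ctl)
  rows2 <- sim$rows
  rows2$F_obs <- 1 - rows2$F_obs
  f2 <- fit_diversity_model("m4", rows2, ctl)
  b1 <- f1$draws$beta[, "F"]; b2 <- f2$draws$beta[, "F"]
  expect_lt(abs(mean(b1) + mean(b2)),
            3 * (sd(b1) + sd(b2)) / sqrt(50) + 0.02)
  expect_gt(posterior_prob_positive(b1), 0.8)
  expect_lt(posterior_prob_positive(b2), 0.2)
})

test_that("marginal slopes combine the fixed effect and group deviations", {
  # exact arithmetic on a crafted posterior object
  d <- 3 # intercept + R + F
  draws <- list(
    beta = matrix(c(rep(0, 20), rep(0.5, 20), seq(0.1, 2, length.out = 20)),
                  20, 3, dimnames = list(NULL, c("alpha", "R", "F"))),
    feat = array(0, c(20, 4, d)),
    area = array(0, c(20, 2, d)))
  draws$feat[, 2, 3] <- 1 # feature 2 deviates on the F slope
  fit <- structure(list(spec = list(name = "m4"), draws = draws,
                        fixed = c("R", "F"), d = d,
                        levels = list(feature = paste0("f", 1:4),
                                      area = c("a1", "a2"))),
                   class = "diversity_fit")
  ms <- marginal_slopes(fit, "feature", "F")
  expect_equal(ms$mean[1], mean(draws$beta[, "F"]))
  expect_equal(ms$mean[2], mean(draws$beta[, "F"] + 1))
  expect_equal(ms$prob_positive[1], 1) # all draws positive
  ma <- marginal_slopes(fit, "area", "F")
  expect_equal(ma$mean, rep(mean(draws$beta[, "F"]), 2)) # zero deviations
  expect_error(marginal_slopes(fit, "feature", "D"), "does not include")
})

test_that("per-feature slopes recover a mixed-sign generating partition", {
  sim <- simulate_regression_rows(n_cells = 80, n_features = 15, n_areas = 5,
                                  beta = c(R = 0.1, T = -0.05, F = 0.15),
                                  tau_feature = c(0.5, 0.1, 0.1, 0.35),
                                  seed = 21)
  fit <- fit_diversity_model("m4", sim$rows,
                             mcmc_control(chains = 2, warmup = 250,
                                          iter = 300, seed = 9,
                                          spline_k = 0))
  ms <- marginal_slopes(fit, "feature")
  truth <- sim$truth$beta["F"] + sim$truth$Uf[, 4]
  expect_gt(cor(ms$mean, truth), 0.5)
  # features the fit classifies as nonzero really have larger |truth|
  if (any(ms$excludes_zero_89)) {
    expect_gt(mean(abs(truth[ms$excludes_zero_89])),
              mean(abs(truth)) - 0.05)
  }
})
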