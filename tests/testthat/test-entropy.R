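# Normalized Shannon entropy and the per-feature hierarchical models.

test_that("normalized entropy matches the closed form at landmark points", {
  expect_equal(normalized_entropy(c(0.5, 0.5)), 1)
  expect_equal(normalized_entropy(c(1, 0)), 0)
  expect_equal(normalized_entropy(c(0.05, 0.95)), 0.28640, tolerance = 1e-4)
  expect_equal(normalized_entropy(rep(1 / 6, 6)), 1)
  expect_error(normalized_entropy(c(-0.1, 1.1)), "non-negative")
  expect_error(normalized_entropy(c(1), J = 1), "at least 2")
})

test_that("entropy agrees with a brute-force oracle on random simplexes", {
  set.seed(55)
  for (J in c(2, 3, 6)) {
    for (r in 1:200) {
      p <- random_simplex(J)
      expect_equal(normalized_entropy(p), entropy_oracle(p, J),
                   tolerance = 1e-12)
      expect_equal(normalized_entropy(sample(p)), normalized_entropy(p),
                   tolerance = 1e-12) # permutation symmetry
    }
  }
  # matrix interface agrees with the vector interface row by row
  P <- t(replicate(50, random_simplex(3)))
  expect_equal(normalized_entropy(P),
               apply(P, 1, entropy_oracle, J = 3), tolerance = 1e-12)
})

test_that("binary and ternary entropy are concave along mixtures", {
  # concavity spot-check against a dense grid: H(mix) >= mix of H
  grid2 <- seq(0.01, 0.99, length.out = 99)
  h <- vapply(grid2, function(p) normalized_entropy(c(p, 1 - p)), 1)
  expect_true(all(diff(diff(h)) < 1e-8))
  set.seed(66)
  for (r in 1:50) {
    p1 <- random_simplex(3); p2 <- random_simplex(3); w <- runif(1)
    expect_gte(normalized_entropy(w * p1 + (1 - w) * p2) + 1e-12,
               w * normalized_entropy(p1) + (1 - w) * normalized_entropy(p2))
  }
})

test_that("a regionally fixed state is recovered with high probability", {
  g <- test_grid()
  set.seed(44)
  cells <- g$cells$cell_id[c(1:6, 40:45)]
  n_per <- 15
  lt <- data.frame(language_id = sprintf("L%03d", 1:(12 * n_per)),
                   cell_id = rep(cells, each = n_per),
                   stringsAsFactors = FALSE)
  ci <- match(lt$cell_id, g$cells$cell_id)
  lt$lon <- g$cells$centroid_lon[ci]
  lt$lat <- g$cells$centroid_lat[ci]
  lt$area <- rep(c("A1", "A2"), each = 6 * n_per)
  lt$family <- sample(paste0("F", 1:12), nrow(lt), TRUE)
  lt$feat <- rep(c("yes", "no"), each = 6 * n_per)
  fit <- fit_feature_model("feat", lt, g,
                           mcmc_control(chains = 2, warmup = 250, iter = 300,
                                        seed = 2, spline_k = 0))
  cp <- cell_state_probabilities(fit)
  pyes <- sapply(cp[cells[1:6]], function(m) mean(m[, "yes"]))
  expect_true(all(pyes > 0.9))
  pno <- sapply(cp[cells[7:12]], function(m) mean(m[, "yes"]))
  expect_true(all(pno < 0.1))
  # entropy summaries: uniform-state cells are low entropy
  es <- summarize_entropy(cp, "feat")
  expect_true(all(es$mean_Hn < 0.5))
  expect_true(all(es$mean_Hn >= 0 & es$mean_Hn <= 1))
})

test_that("cell probabilities equal the mean of language-level draws", {
  g <- test_grid()
  set.seed(47)
  n <- 60
  lt <- data.frame(language_id = sprintf("L%03d", 1:n),
                   cell_id = sample(g$cells$cell_id[1:10], n, TRUE),
                   stringsAsFactors = FALSE)
  ci <- match(lt$cell_id, g$cells$cell_id)
  lt$lon <- g$cells$centroid_lon[ci]
  lt$lat <- g$cells$centroid_lat[ci]
  lt$area <- "A1"
  lt$family <- sample(paste0("F", 1:6), n, TRUE)
  lt$feat <- sample(c("a", "b", "c"), n, TRUE)
  fit <- fit_feature_model("feat", lt, g,
                           mcmc_control(chains = 1, warmup = 100, iter = 60,
                                        seed = 5, spline_k = 0))
  cp <- cell_state_probabilities(fit)
  # recomputation oracle straight from the stored coefficient draws
  for (cl in names(cp)[1:3]) {
    langs <- which(as.character(fit$cell) == cl)
    for (d in c(1, 30, 60)) {
      eta <- matrix(0, length(langs), fit$J)
      for (j in seq_len(fit$J - 1)) {
        eta[, j + 1] <- as.numeric(fit$A[langs, , drop = FALSE] %*%
                                     fit$theta[d, , j])
      }
      P <- exp(eta) / rowSums(exp(eta))
      expect_equal(unname(cp[[cl]][d, ]), unname(colMeans(P)),
                   tolerance = 1e-10)
    }
  }
  # a single-language cell's vector equals that language's own probabilities
  singles <- names(which(table(as.character(fit$cell)) == 1))
  if (length(singles)) {
    cl <- singles[1]
    lang <- which(as.character(fit$cell) == cl)
    eta <- c(0, sapply(seq_len(fit$J - 1), function(j) {
      as.numeric(fit$A[lang, , drop = FALSE] %*% fit$theta[10, , j])
    }))
    expect_equal(unname(cp[[cl]][10, ]), unname(exp(eta) / sum(exp(eta))),
                 tolerance = 1e-10)
  }
  # simplex invariant
  expect_true(all(vapply(cp, function(m) max(abs(rowSums(m) - 1)) < 1e-9,
                         TRUE)))
  # the two aggregation policies agree on direction
  cp2 <- cell_state_probabilities(fit, aggregation = "cell_effect")
  m1 <- sapply(cp, function(m) mean(m[, 2]))
  m2 <- sapply(cp2, function(m) mean(m[, 2]))
  expect_gt(cor(m1, m2), 0.5)
})

test_that("summarize_entropy reduces draws exactly", {
  probs <- list(
    CA = matrix(c(0.2, 0.8, 0.2, 0.8), 2, 2, byrow = TRUE),   # constant
    CB = rbind(c(0.5, 0.5), c(0.9, 0.1), c(0.3, 0.7)))
  es <- summarize_entropy(probs, "toy")
  expect_equal(es$sd_Hn[1], 0)
  hn <- apply(probs$CB, 1, entropy_oracle)
  expect_equal(es$mean_Hn[2], mean(hn), tolerance = 1e-12)
  expect_equal(es$sd_Hn[2], sd(hn), tolerance = 1e-12)
  lh <- qlogis(pmin(pmax(hn, 1e-6), 1 - 1e-6))
  expect_equal(es$mean_logit_Hn[2], mean(lh), tolerance = 1e-12)
  # degenerate entropies survive the logit thanks to clamping
  deg <- list(CC = rbind(c(1, 0), c(1, 0)))
  es2 <- summarize_entropy(deg, "deg")
  expect_true(is.finite(es2$mean_logit_Hn))
  expect_error(summarize_entropy(list(C = rbind(c(0.5, 0.5))), "x"),
               "at least 2 draws")
})

test_that("degenerate features and unmapped languages are rejected", {
  g <- test_grid()
  lt <- data.frame(language_id = c("L1", "L2"), lon = c(0, 10),
                   lat = c(0, 10), family = c("F1", NA),
                   area = c("A1", "A1"), feat = c("x", "x"),
                   stringsAsFactors = FALSE)
  expect_error(fit_feature_model("feat", lt, g), "unmapped language")
  lt$family[2] <- "F2"
  expect_error(fit_feature_model("feat", lt, g), "single observed state")
  expect_error(fit_feature_model("nope", lt, g), "unknown feature")
})

test_that("Polya-Gamma draws match the analytic mean", {
  set.seed(77)
  for (z in c(0, 1, 3)) {
    om <- glottodiv:::rpg1(rep(z, 8000))
    m <- if (z == 0) 0.25 else tanh(z / 2) / (2 * z)
    expect_lt(abs(mean(om) - m), 4 * sd(om) / sqrt(8000))
    expect_true(all(om > 0))
  }
})

test_that("89% HPDIs for the baseline are calibrated over replicates", {
  g <- test_grid()
  cover <- logical(30)
  for (r in 1:30) {
    cfg <- world_config(seed = 100 + r, n_languages = 80, n_families = 10,
                        n_features_binary = 1, n_features_categorical = 0,
                        sigma_family = 1.5, sigma_cell = 0.3,
                        sigma_area = 0.3, sigma_language = 0,
                        marginal_sd = 0, coupling = 0, feature_alpha_sd = 0,
                        feature_missing = 0, n_populations = 3, n_snps = 20)
    w <- generate_world(cfg, g)
    fit <- fit_feature_model("BF01", w$languages, g,
                             mcmc_control(chains = 1, warmup = 120,
                                          iter = 160, seed = r,
                                          spline_k = 0))
    h <- hpdi(fit$theta[, 1, 1], 0.89)
    cover[r] <- h[1] <= 0 && 0 <= h[2] # generating baseline is 0
  }
  # nominal 0.89 within a generous binomial band for 30 replicates
  expect_gte(mean(cover), 0.72)
})

test_that("with zero group variances cell probabilities collapse to the
           global baseline", {
  g <- test_grid()
  cfg <- world_config(seed = 5, n_languages = 400, n_features_binary = 1,
                      n_features_categorical = 0, sigma_area = 0,
                      sigma_cell = 0, sigma_family = 0, sigma_language = 0,
                      marginal_sd = 0, coupling = 0, feature_alpha_sd = 0,
                      feature_missing = 0, n_populations = 5, n_snps = 30)
  w <- generate_world(cfg, g)
  fit <- fit_feature_model("BF01", w$languages, g,
                           mcmc_control(chains = 2, warmup = 200, iter = 250,
                                        seed = 3, spline_k = 4))
  pm <- sapply(cell_state_probabilities(fit), function(m) mean(m[, 2]))
  expect_lt(max(abs(pm - mean(pm))), 0.2)
  expect_lt(abs(mean(pm) - 0.5), 0.05) # baseline itself is recovered
})

test_that("isolated regions end up with higher posterior entropy", {
  g <- test_grid_fine()
  w <- generate_world(
    world_config(seed = 201, n_languages = 450, n_features_binary = 3,
                 n_features_categorical = 0, coupling = 1.0,
                 sigma_language = 0.9, sigma_area = 0.4,
                 feature_alpha_sd = 0.5, feature_missing = 0,
                 n_populations = 10, n_snps = 50), g)
  ent <- entropy_summaries(w$features$feature_id, w$languages, g,
                           mcmc_control(chains = 2, warmup = 150, iter = 200,
                                        seed = 1, spline_k = 4))
  agg <- aggregate(mean_Hn ~ cell_id, ent, mean)
  iso <- w$cells$isolation[match(agg$cell_id, w$cells$cell_id)]
  expect_gt(cor(agg$mean_Hn, iso, method = "spearman"), 0.05)
  ter <- quantile(iso, c(1 / 3, 2 / 3))
  expect_gt(mean(agg$mean_Hn[iso > ter[2]]), mean(agg$mean_Hn[iso < ter[1]]))
})

test_that("feature fits meet the convergence contract at test settings", {
  w <- test_world()
  g <- test_grid_fine()
  fit <- fit_feature_model("BF01", w$languages, g,
                           mcmc_control(chains = 2, warmup = 400, iter = 800,
                                        seed = 9, spline_k = 4))
  expect_lte(fit$max_rhat, 1.05)
  expect_gte(fit$min_ess, 100)
  # draw-level reproducibility under a fixed seed and configuration
  fit2 <- fit_feature_model("BF01", w$languages, g,
                            mcmc_control(chains = 2, warmup = 400, iter = 800,
                                         seed = 9, spline_k = 4))
  expect_identical(fit$theta, fit2$theta)
})
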