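# Synthetic-world generator: determinism, degenerate configs, generative
# structure of feature states, genotypes and covariates.

test_that("identical (config, grid) give byte-identical worlds", {
  g <- test_grid()
  cfg <- world_config(seed = 1, n_languages = 80, n_families = 8,
                      n_populations = 10, n_snps = 200)
  w1 <- generate_world(cfg, g)
  w2 <- generate_world(cfg, g)
  expect_identical(w1$languages, w2$languages)
  expect_identical(w1$genotypes, w2$genotypes)
  expect_identical(w1$covariates, w2$covariates)
  expect_identical(w1$truth, w2$truth)
})

test_that("an empty language inventory still yields a valid world", {
  g <- test_grid()
  cfg <- world_config(seed = 2, n_languages = 0, n_families = 5,
                      n_populations = 5, n_snps = 100)
  w <- generate_world(cfg, g)
  expect_equal(nrow(w$languages), 0)
  expect_equal(nrow(w$covariates), 0)
  expect_gt(nrow(w$populations), 0) # genetics exists independently
})

test_that("invalid configurations are rejected", {
  expect_error(world_config(n_families = 50, n_languages = 10),
               "more families than languages")
  expect_error(world_config(sigma_cell = -1), ">= 0")
  expect_error(world_config(f_base = 1), "\\[0, 1\\)")
  expect_error(world_config(categorical_states = 1), "J >= 2")
})

test_that("every language and individual maps to one cell and one area", {
  w <- test_world()
  g <- test_grid_fine()
  expect_true(all(w$languages$cell_id %in% g$cells$cell_id))
  expect_true(all(w$individuals$cell_id %in% g$cells$cell_id))
  expect_false(anyNA(w$languages$area))
  # language coordinates resolve to their recorded cell's neighborhood:
  # jitter stays within ~a cell radius, so recorded and re-assigned cells
  # agree for a clear majority
  re <- assign_points(w$languages$lon, w$languages$lat, g)
  expect_gt(mean(re == w$languages$cell_id), 0.5)
  expect_true(all(w$genotypes %in% c(0L, 1L, 2L, NA)))
})

test_that("degenerate variance config gives iid Bernoulli(1/2) states", {
  g <- test_grid()
  cfg <- world_config(seed = 3, n_languages = 2000, n_families = 20,
                      n_features_binary = 1, n_features_categorical = 0,
                      sigma_area = 0, sigma_cell = 0, sigma_family = 0,
                      marginal_sd = 0, coupling = 0, feature_alpha_sd = 0,
                      feature_missing = 0, n_populations = 5, n_snps = 50)
  w <- generate_world(cfg, g)
  p <- mean(w$languages$BF01 == "s1")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 2000)) # 3 MC sigmas
})

test_that("dominant family variance produces family concordance", {
  g <- test_grid()
  cfg <- world_config(seed = 4, n_languages = 600, n_families = 30,
                      n_features_binary = 4, n_features_categorical = 0,
                      sigma_family = 3, sigma_area = 0.1, sigma_cell = 0.1,
                      marginal_sd = 0.1, coupling = 0, feature_missing = 0,
                      n_populations = 5, n_snps = 50)
  w <- generate_world(cfg, g)
  concord <- function(states, fam, within) {
    idx <- which(!is.na(states))
    pairs <- 0; same <- 0
    set.seed(99)
    for (k in 1:4000) {
      ij <- sample(idx, 2)
      if ((fam[ij[1]] == fam[ij[2]]) == within) {
        pairs <- pairs + 1
        same <- same + (states[ij[1]] == states[ij[2]])
      }
    }
    same / pairs
  }
  rates <- sapply(sprintf("BF%02d", 1:4), function(f) {
    c(concord(w$languages[[f]], w$languages$family, TRUE),
      concord(w$languages[[f]], w$languages$family, FALSE))
  })
  expect_gt(mean(rates[1, ]), mean(rates[2, ]) + 0.1)
})

test_that("categorical features emit exactly one of J states", {
  w <- test_world()
  st <- w$languages$CF01
  expect_true(all(is.na(st) | st %in% sprintf("s%d", 1:4)))
  expect_gt(length(unique(na.omit(st))), 1)
  # J up to 7 is supported (word-order-like features)
  g <- test_grid()
  cfg <- world_config(seed = 6, n_languages = 300, n_features_binary = 0,
                      n_features_categorical = 1, categorical_states = 7,
                      n_populations = 5, n_snps = 50)
  w7 <- generate_world(cfg, g)
  expect_true(all(is.na(w7$languages$CF01) |
                    w7$languages$CF01 %in% sprintf("s%d", 1:7)))
})

test_that("per-population heterozygosity matches (1 - f) * 2pq", {
  g <- test_grid()
  cfg <- world_config(seed = 7, n_populations = 6,
                      individuals_per_population = 30, n_snps = 2000,
                      fst = 0, geno_missing = 0, n_languages = 30,
                      n_families = 3)
  w <- generate_world(cfg, g)
  w <- generate_genotypes(w, cfg, f_override = 0.4)
  p <- w$truth$p_global
  expected_het <- (1 - 0.4) * mean(2 * p * (1 - p))
  observed_het <- mean(w$genotypes == 1)
  expect_lt(abs(observed_het - expected_het), 0.01)
})

test_that("covariates: richness is an exact recount, fields standardized", {
  w <- test_world()
  cov <- w$covariates
  recount <- table(w$languages$cell_id)
  expect_equal(cov$R, as.numeric(log(recount[cov$cell_id])))
  one_lang <- cov$cell_id[recount[cov$cell_id] == 1]
  expect_true(all(cov$R[cov$cell_id %in% one_lang] == 0))
  for (v in c("P1", "P2", "D")) {
    expect_lt(abs(mean(cov[[v]])), 1e-9)
    expect_equal(sd(cov[[v]]), 1, tolerance = 1e-9)
  }
})

test_that("per-area means of the isolation field track the area intercepts", {
  g <- test_grid_fine() # 362 cells
  cfg <- world_config(seed = 8, n_languages = 50, n_families = 5,
                      n_populations = 5, n_snps = 50, sigma_area = 1)
  w <- generate_world(cfg, g)
  by_area <- tapply(w$cells$isolation, w$cells$area, mean)
  truth <- w$truth$area_iso[names(by_area)]
  expect_gt(cor(as.numeric(by_area), as.numeric(truth)), 0.9)
})

test_that("the truth record round-trips through JSON serialization", {
  skip_if_not_installed("jsonlite")
  w <- test_world()
  s <- jsonlite::toJSON(w$truth, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(s)
  expect_equal(unname(back$area_iso), unname(as.numeric(w$truth$area_iso)),
               tolerance = 1e-12)
  expect_equal(back$isolation, w$truth$isolation, tolerance = 1e-12)
  expect_equal(unname(back$f_true),
               unname(as.numeric(w$truth$f_true)), tolerance = 1e-12)
  expect_equal(back$config$n_languages, w$config$n_languages)
})

test_that("world writers emit readable plain-text files", {
  w <- generate_world(world_config(seed = 9, n_languages = 40,
                                   n_families = 4, n_populations = 4,
                                   individuals_per_population = 3,
                                   n_snps = 30), test_grid())
  d <- tempfile()
  write_world(w, d)
  expect_true(all(file.exists(file.path(
    d, c("languages.csv", "covariates.csv", "genotypes.tsv", "world.ped",
         "world.map")))))
  G <- read_genotypes_tsv(file.path(d, "genotypes.tsv"))
  expect_equal(unname(G), unname(w$genotypes))
  # PLINK-text round trip recovers the dosage matrix exactly
  pl <- read_plink_ped(file.path(d, "world"))
  expect_equal(unname(pl$genotypes), unname(w$genotypes))
  expect_equal(pl$fam$individual, w$individuals$individual_id)
  expect_equal(ncol(pl$genotypes), ncol(w$genotypes))
  unlink(d, recursive = TRUE)
})
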