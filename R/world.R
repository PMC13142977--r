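# Synthetic-world generator: geohistorical areas, nested language families,
# languages with hierarchically generated feature states, populations with
# controllable autozygosity, and per-cell covariates -- all with a recorded
# ground truth, under the same generative structure the analysis assumes.
#
# Spatial autocorrelation is generated as a squared-exponential Gaussian
# random field over the cell centers, realized with random Fourier features
# on the spherical embedding (chordal distances), so large grids stay cheap
# and the field is reproducible from the seed alone.

#' Configuration of a synthetic world
#'
#' Defaults mirror the structure of the real-data setting at desk scale:
#' ten geohistorical areas, nested families, a few hundred languages over a
#' few hundred data-bearing cells, populations with a median of eight
#' sampled individuals, and a latent isolation field that couples low
#' genetic diversity to high feature-state dispersion.
#'
#' @param n_areas number of geohistorical areas.
#' @param n_families,taxonomy_depth,n_languages language inventory shape.
#' @param n_features_binary number of binary features.
#' @param n_features_categorical number of categorical features.
#' @param categorical_states states per categorical feature (vector
#'   recycled; each must be in 3..7).
#' @param n_populations,individuals_per_population,n_snps genetic design
#'   (`individuals_per_population` is the Poisson mean, floored at 2; the
#'   default gives a median of ~8).
#' @param sigma_area,sigma_cell,sigma_family,sigma_population hierarchical
#'   SDs (logit scale for features; `sigma_population` perturbs logit
#'   autozygosity).
#' @param sigma_language baseline SD of per-language feature-state
#'   deviations; the isolation coupling multiplies it per cell.
#' @param length_scale_km,marginal_sd squared-exponential field parameters.
#' @param coupling effect of standardized latent isolation on the log of
#'   the cell-intercept dispersion of feature states (the generative
#'   analogue of a positive isolation-diversity effect).
#' @param beta_R,beta_T,beta_P1,beta_P2,beta_D optional covariate effects
#'   on the same log-dispersion (0 = inert).
#' @param feature_alpha_sd SD of the per-feature (and per-class) global
#'   baseline intercepts.
#' @param f_base baseline autozygosity (probability scale).
#' @param f_isolation_slope logit-scale effect of standardized isolation on
#'   autozygosity.
#' @param fst Balding-Nichols differentiation of per-population allele
#'   frequencies around the global frequencies.
#' @param feature_missing,geno_missing missingness rates.
#' @param seed integer seed; the world is a deterministic function of
#'   (config, grid).
#' @return list of class `world_config`.
#' @export
world_config <- function(n_areas = 10, n_families = 24, taxonomy_depth = 3,
                         n_languages = 400, n_features_binary = 6,
                         n_features_categorical = 1, categorical_states = 6,
                         n_populations = 50, individuals_per_population = 8,
                         n_snps = 1500, sigma_area = 0.75, sigma_cell = 0.4,
                         sigma_family = 1.25, sigma_population = 0.3,
                         sigma_language = 0.75,
                         length_scale_km = 2500, marginal_sd = 0.75,
                         coupling = 0.6, beta_R = 0, beta_T = 0, beta_P1 = 0,
                         beta_P2 = 0, beta_D = 0, feature_alpha_sd = 1,
                         f_base = 0.06,
                         f_isolation_slope = 1, fst = 0.05,
                         feature_missing = 0.15, geno_missing = 0.02,
                         seed = 1) {
  cfg <- as.list(environment())
  sds <- c(cfg$sigma_area, cfg$sigma_cell, cfg$sigma_family,
           cfg$sigma_population, cfg$sigma_language, cfg$marginal_sd)
  if (any(sds < 0)) stop("variance components must be >= 0")
  if (cfg$n_families > cfg$n_languages && cfg$n_languages > 0) {
    stop("config demands more families than languages")
  }
  if (cfg$f_base < 0 || cfg$f_base >= 1) stop("f_base must be in [0, 1)")
  if (any(cfg$categorical_states < 2)) stop("categorical features need J >= 2")
  rates <- c(cfg$feature_missing, cfg$geno_missing, cfg$fst)
  if (any(rates < 0 | rates > 1)) stop("rates must be probabilities")
  structure(cfg, class = "world_config")
}

# Squared-exponential GRF over points on the sphere (xyz in km), via
# random Fourier features; deterministic given the RNG state.
grf_sphere <- function(xyz_km, length_scale_km, marginal_sd, M = 256L) {
  W <- matrix(stats::rnorm(3 * M, 0, 1 / length_scale_km), 3, M)
  b <- stats::runif(M, 0, 2 * pi)
  a <- stats::rnorm(M)
  phi <- cos(sweep(xyz_km %*% W, 2, b, "+"))
  as.numeric(marginal_sd * sqrt(2 / M) * (phi %*% a))
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a complete synthetic world
#'
#' Builds areas (contiguous k-means partition of the grid), latent spatial
#' fields (isolation, environment PCs, population density), nested language
#' families with homelands, language locations and feature states,
#' populations with genotypes, and per-cell covariates. The `truth` element
#' records every generating parameter and latent field needed to score
#' downstream estimators.
#'
#' @param config a [world_config()].
#' @param grid a `geo_grid`.
#' @return object of class `synthetic_world`.
#' @export
generate_world <- function(config, grid) {
  stopifnot(inherits(config, "world_config"), inherits(grid, "geo_grid"))
  world <- with_seed(config$seed, {
    xyz <- grid$centers_xyz * EARTH_RADIUS_KM
    nC <- nrow(grid$cells)
    km <- suppressWarnings(stats::kmeans(grid$centers_xyz,
                                         centers = config$n_areas,
                                         nstart = 5, iter.max = 200))
    ord <- order(atan2(km$centers[, 2], km$centers[, 1]))
    area_lab <- sprintf("A%02d", match(seq_len(config$n_areas), ord))
    cell_area <- area_lab[km$cluster]
    area_iso <- stats::rnorm(config$n_areas, 0, config$sigma_area)
    names(area_iso) <- sprintf("A%02d", seq_len(config$n_areas))
    isolation <- area_iso[cell_area] +
      grf_sphere(xyz, config$length_scale_km, config$marginal_sd)
    pc1 <- grf_sphere(xyz, config$length_scale_km, 1)
    pc2 <- grf_sphere(xyz, config$length_scale_km, 1)
    dens <- grf_sphere(xyz, config$length_scale_km, 1)
    cells <- data.frame(grid$cells[, c("cell_id", "centroid_lon",
                                       "centroid_lat", "centroid_x",
                                       "centroid_y")],
                        area = cell_area, isolation = as.numeric(isolation),
                        pc1 = pc1, pc2 = pc2, density = dens,
                        stringsAsFactors = FALSE)
    # nested families with homelands; languages cluster around homelands
    nL <- config$n_languages
    languages <- if (nL > 0) {
      fam_w <- stats::rgamma(config$n_families, 1)
      fam <- sprintf("F%02d", sample.int(config$n_families, nL, TRUE,
                                         prob = fam_w / sum(fam_w)))
      n_branch <- pmax(1L, stats::rpois(config$n_families, 1.2) + 1L)
      branch <- vapply(seq_len(nL), function(i) {
        fi <- as.integer(substring(fam[i], 2))
        sprintf("B%d", sample.int(n_branch[fi], 1))
      }, character(1))
      homeland <- sample.int(nC, config$n_families, replace = TRUE)
      lang_cell <- vapply(seq_len(nL), function(i) {
        fi <- as.integer(substring(fam[i], 2))
        d <- gc_dist_xyz(matrix(grid$centers_xyz[homeland[fi], ], nC, 3,
                                byrow = TRUE), grid$centers_xyz)
        sample.int(nC, 1, prob = exp(-(d / 1500)^2) + 1e-9)
      }, integer(1))
      ctr <- grid$cells[lang_cell, ]
      jit <- jitter_points(ctr$centroid_lon, ctr$centroid_lat,
                           max_radius_km = stats::median(
                             grid$cells$diameter_km, na.rm = TRUE) * 0.3)
      path <- if (config$taxonomy_depth >= 3) {
        paste(fam, branch, sprintf("L%04d", seq_len(nL)), sep = "/")
      } else {
        paste(fam, sprintf("L%04d", seq_len(nL)), sep = "/")
      }
      data.frame(language_id = sprintf("L%04d", seq_len(nL)),
                 lon = jit$lon, lat = jit$lat, family = fam, branch = branch,
                 taxonomy = path,
                 area = cells$area[lang_cell],
                 cell_id = cells$cell_id[lang_cell],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(language_id = character(0), lon = numeric(0),
                 lat = numeric(0), family = character(0),
                 branch = character(0), taxonomy = character(0),
                 area = character(0), cell_id = character(0),
                 stringsAsFactors = FALSE)
    }
    structure(list(config = config, grid = grid, cells = cells,
                   languages = languages, features = NULL,
                   populations = NULL, individuals = NULL, genotypes = NULL,
                   covariates = NULL,
                   truth = list(config = unclass(config)[
                     !vapply(unclass(config), is.function, logical(1))],
                     area_iso = area_iso,
                     isolation = as.numeric(isolation))),
              class = "synthetic_world")
  })
  world <- generate_feature_states(world, config)
  world <- generate_genotypes(world, config)
  world <- generate_covariates(world, config)
  world
}

#' Generate hierarchical feature states for a world's languages
#'
#' Each feature follows the hierarchical logistic (binary) or softmax
#' (categorical) model with a global baseline, area, family and cell
#' intercepts, a smooth spatial field, and per-language deviations. The
#' isolation coupling scales the per-language deviation SD within a cell by
#' `exp(coupling * standardized isolation)` (plus any configured covariate
#' terms): languages in isolated cells diverge more from one another, which
#' raises the cell's expected entropy when `coupling > 0`.
#'
#' @param world a `synthetic_world` (languages already placed).
#' @param config its [world_config()].
#' @return the world with feature columns appended to `$languages` and
#'   feature-level truth recorded.
#' @export
generate_feature_states <- function(world, config) {
  lt <- world$languages
  cells <- world$cells
  nC <- nrow(cells)
  xyz <- world$grid$centers_xyz * EARTH_RADIUS_KM
  iso_z <- zscore(cells$isolation)
  log_disp <- config$coupling * iso_z +
    config$beta_P1 * zscore(cells$pc1) + config$beta_P2 * zscore(cells$pc2) +
    config$beta_D * zscore(cells$density)
  sd_lang_c <- config$sigma_language * exp(log_disp)
  nB <- config$n_features_binary
  nK <- config$n_features_categorical
  Js <- rep_len(config$categorical_states, max(nK, 1L))
  feature_ids <- c(sprintf("BF%02d", seq_len(nB)),
                   if (nK > 0) sprintf("CF%02d", seq_len(nK)))
  fam_lev <- sprintf("F%02d", seq_len(config$n_families))
  area_lev <- sprintf("A%02d", seq_len(config$n_areas))
  li_cell <- match(lt$cell_id, cells$cell_id)
  li_area <- match(lt$area, area_lev)
  li_fam <- match(lt$family, fam_lev)
  truth_feat <- list()
  out <- with_seed(config$seed + 101L, {
    res <- list()
    for (fi in seq_along(feature_ids)) {
      fid <- feature_ids[fi]
      J <- if (fi <= nB) 2L else Js[fi - nB]
      if (J < 2) stop("categorical feature needs J >= 2")
      nclass <- if (J == 2) 1L else J - 1L
      eta <- matrix(0, max(nrow(lt), 1L), J)
      pars <- list(J = J)
      for (j in seq_len(nclass)) {
        alpha <- stats::rnorm(1, 0, config$feature_alpha_sd)
        a_eff <- stats::rnorm(config$n_areas, 0, config$sigma_area)
        f_eff <- stats::rnorm(config$n_families, 0, config$sigma_family)
        c_eff <- stats::rnorm(nC, 0, config$sigma_cell)
        field <- grf_sphere(xyz, config$length_scale_km, config$marginal_sd)
        if (nrow(lt) > 0) {
          l_eff <- stats::rnorm(nrow(lt), 0, sd_lang_c[li_cell])
          eta[, if (J == 2) 2L else j + 1L] <-
            alpha + a_eff[li_area] + f_eff[li_fam] + c_eff[li_cell] +
            field[li_cell] + l_eff
        }
        pars[[paste0("class", j)]] <- list(alpha = alpha, area = a_eff,
                                           family = f_eff)
      }
      truth_feat[[fid]] <- pars
      if (nrow(lt) > 0) {
        P <- exp(eta - apply(eta, 1, logsumexp))
        st <- apply(P, 1, function(p) sample.int(J, 1, prob = p))
        st <- if (J == 2) c("s0", "s1")[st] else sprintf("s%d", st)
        st[stats::runif(nrow(lt)) < config$feature_missing] <- NA
        res[[fid]] <- st
      } else {
        res[[fid]] <- character(0)
      }
    }
    list(states = res, truth = truth_feat)
  })
  for (fid in names(out$states)) lt[[fid]] <- out$states[[fid]]
  world$languages <- lt
  world$features <- data.frame(
    feature_id = feature_ids,
    type = c(rep("binary", nB), if (nK > 0) rep("categorical", nK)),
    J = c(rep(2L, nB), if (nK > 0) Js[seq_len(nK)]),
    stringsAsFactors = FALSE)
  world$truth$features <- out$truth
  world$truth$sd_language_by_cell <- sd_lang_c
  world
}

#' Generate populations, individuals and genotypes
#'
#' Populations are placed on cells; each has a true autozygosity
#' `f = plogis(qlogis(f_base) + f_isolation_slope * iso_z + N(0,
#' sigma_population))`. Per-population allele frequencies follow a
#' Balding-Nichols Beta around global Beta(2,2)-drawn frequencies. A
#' genotype is autozygous (homozygous, allele by frequency) with
#' probability `f`, otherwise a Hardy-Weinberg draw; missingness applies at
#' the configured rate.
#'
#' @param world a `synthetic_world`.
#' @param config its [world_config()].
#' @param f_override optional single autozygosity applied to every
#'   population (must be in `[0, 1)`), for controlled recovery experiments.
#' @return the world with `populations`, `individuals`, `genotypes` filled
#'   in and the genetic truth recorded.
#' @export
generate_genotypes <- function(world, config, f_override = NULL) {
  if (!is.null(f_override) && (f_override < 0 || f_override >= 1)) {
    stop("autozygosity must be in [0, 1)")
  }
  cells <- world$cells
  with_seed(config$seed + 202L, {
    nP <- config$n_populations
    # sampled populations concentrate where languages are spoken
    has_lang <- cells$cell_id %in% world$languages$cell_id
    wgt <- exp(zscore(cells$density)) * ifelse(has_lang, 20, 1)
    pop_cell <- sample.int(nrow(cells), nP, replace = TRUE, prob = wgt)
    iso_z <- zscore(cells$isolation)[pop_cell]
    f_true <- if (is.null(f_override)) {
      stats::plogis(stats::qlogis(max(config$f_base, 1e-4)) +
                      config$f_isolation_slope * iso_z +
                      stats::rnorm(nP, 0, config$sigma_population))
    } else {
      rep(f_override, nP)
    }
    sizes <- pmax(2L, stats::rpois(nP, config$individuals_per_population))
    p_glob <- stats::rbeta(config$n_snps, 2, 2) * 0.9 + 0.05
    fst <- config$fst
    pops <- data.frame(population = sprintf("P%03d", seq_len(nP)),
                       cell_id = cells$cell_id[pop_cell],
                       area = cells$area[pop_cell],
                       lon = cells$centroid_lon[pop_cell],
                       lat = cells$centroid_lat[pop_cell],
                       f_true = f_true, n_individuals = sizes,
                       stringsAsFactors = FALSE)
    n_ind <- sum(sizes)
    G <- matrix(NA_integer_, n_ind, config$n_snps)
    ind_pop <- rep(seq_len(nP), sizes)
    for (k in seq_len(nP)) {
      pk <- if (fst > 0) {
        stats::rbeta(config$n_snps, p_glob * (1 - fst) / fst,
                     (1 - p_glob) * (1 - fst) / fst)
      } else {
        p_glob
      }
      pk <- pmin(pmax(pk, 1e-4), 1 - 1e-4)
      rows <- which(ind_pop == k)
      nk <- length(rows)
      auto <- matrix(stats::runif(nk * config$n_snps) < f_true[k], nk)
      hw <- matrix(stats::rbinom(nk * config$n_snps, 2L,
                                 rep(pk, each = nk)), nk)
      az <- matrix(2L * stats::rbinom(nk * config$n_snps, 1L,
                                      rep(pk, each = nk)), nk)
      G[rows, ] <- ifelse(auto, az, hw)
    }
    if (config$geno_missing > 0) {
      G[matrix(stats::runif(length(G)) < config$geno_missing,
               nrow(G))] <- NA_integer_
    }
    rownames(G) <- sprintf("I%05d", seq_len(n_ind))
    individuals <- data.frame(
      individual_id = rownames(G),
      population = pops$population[ind_pop],
      cell_id = pops$cell_id[ind_pop], area = pops$area[ind_pop],
      lon = pops$lon[ind_pop], lat = pops$lat[ind_pop],
      stringsAsFactors = FALSE)
    world$populations <- pops
    world$individuals <- individuals
    world$genotypes <- G
    world$truth$f_true <- stats::setNames(f_true, pops$population)
    world$truth$p_global <- p_glob
    world
  })
}

#' Compute per-cell covariates
#'
#' Log language richness and log taxonomic diversity are computed from the
#' language table (never simulated); the environmental PCs and log
#' population density come from the latent smooth fields, centered and
#' scaled over the data-bearing cells.
#'
#' @param world a `synthetic_world`.
#' @param config its [world_config()].
#' @return the world with a per-cell `covariates` table (cells holding at
#'   least one language).
#' @export
generate_covariates <- function(world, config) {
  lt <- world$languages
  if (!nrow(lt)) {
    world$covariates <- data.frame(cell_id = character(0), area = character(0),
                                   R = numeric(0), T = numeric(0),
                                   P1 = numeric(0), P2 = numeric(0),
                                   D = numeric(0), stringsAsFactors = FALSE)
    return(world)
  }
  counts <- table(lt$cell_id)
  ids <- names(counts)
  m <- match(ids, world$cells$cell_id)
  taxdiv <- vapply(ids, function(cl) {
    taxonomic_diversity(lt$taxonomy[lt$cell_id == cl])
  }, numeric(1))
  world$covariates <- data.frame(
    cell_id = ids, area = world$cells$area[m],
    R = log(as.numeric(counts)), T = log(taxdiv),
    P1 = zscore(world$cells$pc1[m]), P2 = zscore(world$cells$pc2[m]),
    D = zscore(world$cells$density[m]),
    stringsAsFactors = FALSE)
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("synthetic world: %d languages (%d families, %d areas), ",
                     "%d populations / %d individuals, %d SNPs, %d features\n"),
              nrow(x$languages), x$config$n_families, x$config$n_areas,
              if (is.null(x$populations)) 0 else nrow(x$populations),
              if (is.null(x$genotypes)) 0 else nrow(x$genotypes),
              x$config$n_snps,
              if (is.null(x$features)) 0 else nrow(x$features)))
  invisible(x)
}

#' Write a synthetic world to plain-text files
#'
#' Writes `languages.csv`, `covariates.csv`, `genotypes.tsv` (individuals x
#' SNPs, NA = missing), a PLINK-text-style `world.ped`/`world.map` pair,
#' and `truth.json` (requires jsonlite).
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(world$languages, file.path(dir, "languages.csv"),
                   row.names = FALSE)
  utils::write.csv(world$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.table(world$genotypes, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  G <- world$genotypes
  al <- matrix("0 0", nrow(G), ncol(G))
  al[!is.na(G) & G == 0] <- "A A"
  al[!is.na(G) & G == 1] <- "A B"
  al[!is.na(G) & G == 2] <- "B B"
  ped <- cbind(world$individuals$population, world$individuals$individual_id,
               0, 0, 0, -9, al)
  utils::write.table(ped, file.path(dir, "world.ped"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  map <- data.frame(chr = 1, id = sprintf("snp%05d", seq_len(ncol(G))),
                    cm = 0, pos = seq_len(ncol(G)))
  utils::write.table(map, file.path(dir, "world.map"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a genotype TSV written by [write_world()]
#'
#' @param path the `genotypes.tsv` file.
#' @return integer matrix with individual row names.
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Read PLINK-text .ped/.map genotypes
#'
#' Reads the biallelic A/B coding written by [write_world()]: per SNP, the
#' count of `B` alleles (0/1/2), `0 0` as missing. Returns the genotype
#' matrix plus the pedigree columns.
#'
#' @param prefix path prefix; `<prefix>.ped` and `<prefix>.map` must exist.
#' @return list with `genotypes` (individuals x SNPs integer matrix, row
#'   names = individual IDs, column names = SNP IDs from the .map) and
#'   `fam` (data.frame of the six leading pedigree columns).
#' @export
read_plink_ped <- function(prefix) {
  ped_file <- paste0(prefix, ".ped")
  map_file <- paste0(prefix, ".map")
  if (!file.exists(ped_file) || !file.exists(map_file)) {
    stop("need both ", ped_file, " and ", map_file)
  }
  map <- utils::read.table(map_file, header = FALSE,
                           col.names = c("chr", "id", "cm", "pos"))
  ped <- utils::read.table(ped_file, header = FALSE,
                           colClasses = "character")
  n_snp <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_snp) {
    stop("ped/map mismatch: expected ", 6 + 2 * n_snp, " columns, found ",
         ncol(ped))
  }
  fam <- stats::setNames(ped[, 1:6],
                         c("family", "individual", "father", "mother",
                           "sex", "phenotype"))
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(n_snp) - 1])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(n_snp)])
  G <- (a1 == "B") + (a2 == "B")
  G[a1 == "0" | a2 == "0"] <- NA_integer_
  mode(G) <- "integer"
  dimnames(G) <- list(fam$individual, map$id)
  list(genotypes = G, fam = fam)
}
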