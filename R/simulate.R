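#' Configuration for the synthetic community generator
#'
#' Bundles every knob of the simulated study: the belt/plot layout, the
#' species pool and per-belt richness, the dominance structure of covers,
#' and the trait model. The trait model is additive: a species' expected
#' value is `base_trait_mean` plus a between-species deviation
#' (`between_species_sd`) plus a turnover shift proportional to the belt
#' where the species first occurs (`turnover_effect` per belt step, so
#' species pools drift along the gradient); an individual measured in belt
#' b additionally shifts by `covariation_sign * sign(turnover_effect) *
#' itv_slope * (b - c_s)`, where `c_s` is the centre of the belts the
#' species occupies, so `covariation_sign = +1` makes within-species trends
#' run parallel to the turnover trend (positive covariation), `-1` makes
#' them oppose it, and `0` removes any systematic within-species trend;
#' residual measurement noise has sd `individual_sd`. Centring the trend on
#' each species' own occupied belts keeps the intraspecific signal out of
#' the pooled fixed means, so the two generator effects map cleanly onto
#' the turnover and intraspecific components of the decomposition.
#'
#' @param n_belts Number of ordered belts.
#' @param plots_per_belt Integer vector, plots per belt.
#' @param species_pool_size Size of the regional species pool.
#' @param species_per_belt Target measured richness per belt.
#' @param adjacent_overlap Fraction (of the smaller richness) of species
#'   shared between adjacent belts, default 0.5.
#' @param occupancy Probability that a belt species occurs in a given plot,
#'   default 0.85 (gives within-belt composition variation).
#' @param cover_concentration Dirichlet concentration of per-plot cover
#'   weights; small values (< 1) produce strong dominance.
#' @param base_trait_mean,between_species_sd Trait location (trait units)
#'   and between-species sd.
#' @param turnover_effect Shift of the species-pool trait mean per belt
#'   step (trait units; sign sets the direction of the gradient trend).
#' @param itv_slope Magnitude of the within-species shift per belt step
#'   (trait units, >= 0).
#' @param covariation_sign +1, 0 or -1 (alignment of the within-species
#'   trend with the turnover trend).
#' @param individual_sd Residual sd of individual measurements.
#' @param n_individuals Individuals measured per species per belt.
#' @param trait_name Label of the simulated trait, default `"H"`.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_belts = 3,
                             plots_per_belt = c(5, 5, 5),
                             species_pool_size = 14,
                             species_per_belt = c(6, 6, 6),
                             adjacent_overlap = 0.5,
                             occupancy = 0.85,
                             cover_concentration = 0.8,
                             base_trait_mean = 30,
                             between_species_sd = 6,
                             turnover_effect = -3,
                             itv_slope = 1,
                             covariation_sign = 1,
                             individual_sd = 2,
                             n_individuals = 10,
                             trait_name = "H",
                             seed = 1) {
  cfg <- list(n_belts = as.integer(n_belts),
              plots_per_belt = as.integer(plots_per_belt),
              species_pool_size = as.integer(species_pool_size),
              species_per_belt = as.integer(species_per_belt),
              adjacent_overlap = adjacent_overlap,
              occupancy = occupancy,
              cover_concentration = cover_concentration,
              base_trait_mean = base_trait_mean,
              between_species_sd = between_species_sd,
              turnover_effect = turnover_effect,
              itv_slope = itv_slope,
              covariation_sign = covariation_sign,
              individual_sd = individual_sd,
              n_individuals = as.integer(n_individuals),
              trait_name = trait_name,
              seed = as.integer(seed))
  if (cfg$n_belts < 2) stop("at least two belts are required")
  if (length(cfg$plots_per_belt) != cfg$n_belts) {
    stop("`plots_per_belt` must have one entry per belt")
  }
  if (length(cfg$species_per_belt) != cfg$n_belts) {
    stop("`species_per_belt` must have one entry per belt")
  }
  if (any(cfg$plots_per_belt < 2)) stop("every belt needs at least two plots")
  if (any(cfg$species_per_belt < 2)) stop("every belt needs at least two species")
  if (cfg$adjacent_overlap < 0 || cfg$adjacent_overlap > 1) {
    stop("`adjacent_overlap` must be in [0, 1]")
  }
  if (cfg$occupancy <= 0 || cfg$occupancy > 1) stop("`occupancy` must be in (0, 1]")
  if (cfg$cover_concentration <= 0) stop("`cover_concentration` must be positive")
  if (cfg$between_species_sd < 0 || cfg$individual_sd < 0 || cfg$itv_slope < 0) {
    stop("standard deviations and `itv_slope` must be nonnegative")
  }
  if (!cfg$covariation_sign %in% c(-1, 0, 1)) {
    stop("`covariation_sign` must be -1, 0 or +1")
  }
  if (cfg$n_individuals < 1) stop("`n_individuals` must be at least 1")
  # feasibility: new species needed beyond what overlap re-uses
  shared <- c(0, floor(cfg$adjacent_overlap *
                         pmin(cfg$species_per_belt[-1],
                              cfg$species_per_belt[-cfg$n_belts])))
  if (sum(cfg$species_per_belt - shared) > cfg$species_pool_size) {
    stop("infeasible richness: species pool too small for the requested ",
         "per-belt richness and overlap")
  }
  structure(cfg, class = "generator_config")
}

#' Four-belt stratified gradient preset
#'
#' The default configuration mirrors a Mediterranean mountain grassland
#' survey layout: four 250-m elevational belts from 1325 to 2375 m holding
#' 9, 10, 11 and 15 plots, with 11, 10, 12 and 17 measured species per belt
#' and 15 individuals measured per species per belt. Trait defaults are
#' height-like (base 30 cm) with a declining turnover trend along the
#' gradient, a weaker parallel within-species trend (positive covariation),
#' and moderate measurement noise.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [generator_config()].
#' @return A `generator_config`.
#' @export
preset_gradient_design <- function(seed = 1, ...) {
  args <- list(n_belts = 4,
               plots_per_belt = c(9, 10, 11, 15),
               species_pool_size = 40,
               species_per_belt = c(11, 10, 12, 17),
               adjacent_overlap = 0.5,
               occupancy = 0.85,
               cover_concentration = 0.6,
               base_trait_mean = 30,
               between_species_sd = 8,
               turnover_effect = -3,
               itv_slope = 1,
               covariation_sign = 1,
               individual_sd = 4,
               n_individuals = 15,
               trait_name = "H",
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

#' Generate a synthetic cover matrix and trait measurements
#'
#' Draws (1) per-belt species sets from the pool with the configured
#' adjacent-belt overlap, so composition turns over along the gradient while
#' some species span belts; (2) per-plot occupancy and Dirichlet cover
#' weights (small concentration = strong dominance); (3) individual trait
#' measurements for every (species, belt) pair of the belt sets, following
#' the additive trait model described in [generator_config()]. Output is a
#' deterministic function of the config (including its seed); the caller's
#' RNG state is left untouched.
#'
#' @param config A `generator_config`.
#' @return List of class `synthetic_dataset` with elements `cover`
#'   (a `cover_matrix`), `measurements` (a `trait_measurements`), `design`,
#'   `species_sets` (per-belt species), `species_means` (expected species
#'   trait values) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_preserved_seed(config$seed, {
    nb <- config$n_belts
    belts <- sprintf("B%d", seq_len(nb))
    lower <- 1325 + 250 * (seq_len(nb) - 1)
    design <- study_design(
      data.frame(belt = belts, lower = lower, upper = lower + 250),
      data.frame(plot = sprintf("P%02d", seq_len(sum(config$plots_per_belt))),
                 belt = rep(belts, config$plots_per_belt)))

    pool <- sprintf("sp%02d", seq_len(config$species_pool_size))
    unused <- pool
    sets <- vector("list", nb)
    names(sets) <- belts
    for (b in seq_len(nb)) {
      r <- config$species_per_belt[b]
      shared <- character(0)
      if (b > 1) {
        n_shared <- floor(config$adjacent_overlap *
                            min(r, config$species_per_belt[b - 1]))
        shared <- sort(sample(sets[[b - 1]], n_shared))
      }
      n_new <- r - length(shared)
      if (n_new > length(unused)) {
        stop("infeasible richness: species pool exhausted in belt ", belts[b])
      }
      fresh <- sort(sample(unused, n_new))
      unused <- setdiff(unused, fresh)
      sets[[b]] <- sort(c(shared, fresh))
    }

    used <- sort(unique(unlist(sets)))
    home <- vapply(used, function(s) {
      which(vapply(sets, function(st) s %in% st, logical(1)))[1]
    }, numeric(1))
    centre <- (nb + 1) / 2
    species_means <- config$base_trait_mean +
      rnorm(length(used), 0, config$between_species_sd) +
      config$turnover_effect * (home - centre)
    names(species_means) <- used

    # per-plot occupancy and Dirichlet cover weights
    m <- matrix(0, nrow(design$plots), length(used),
                dimnames = list(design$plots$plot, used))
    for (i in seq_len(nrow(design$plots))) {
      sp <- sets[[design$plots$belt[i]]]
      present <- sp[runif(length(sp)) < config$occupancy]
      if (length(present) < 2) present <- sample(sp, min(2, length(sp)))
      w <- rgamma(length(present), shape = config$cover_concentration)
      while (sum(w) <= 0) w <- rgamma(length(present),
                                      shape = config$cover_concentration)
      m[i, present] <- 100 * w / sum(w)
    }
    cover <- cover_matrix(m, design)

    dir <- if (config$turnover_effect < 0) -1 else 1
    # each species' within-species trend is centred on the belts where it is
    # actually measured, so belt-exclusive species express no trend and the
    # intraspecific signal stays orthogonal to the turnover signal
    occupied <- lapply(used, function(s) {
      which(vapply(sets, function(st) s %in% st, logical(1)))
    })
    names(occupied) <- used
    recs <- do.call(rbind, lapply(seq_len(nb), function(b) {
      sp <- sets[[b]]
      do.call(rbind, lapply(sp, function(s) {
        shift <- config$covariation_sign * dir * config$itv_slope *
          (b - mean(occupied[[s]]))
        mu <- species_means[[s]] + shift
        v <- rnorm(config$n_individuals, mu, config$individual_sd)
        for (tries in seq_len(1000)) {
          bad <- v <= 0
          if (!any(bad)) break
          v[bad] <- rnorm(sum(bad), mu, config$individual_sd)
        }
        v[v <= 0] <- .Machine$double.eps
        data.frame(species = s, belt = belts[b], trait = config$trait_name,
                   value = v, stringsAsFactors = FALSE)
      }))
    }))
    measurements <- trait_measurements(recs, design)

    structure(list(cover = cover, measurements = measurements,
                   design = design, species_sets = sets,
                   species_means = species_means, config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic community dataset (seed ", x$config$seed, ")\n", sep = "")
  print(x$design)
  cat("  ", nrow(x$measurements), " individual measurements of trait '",
      x$config$trait_name, "'\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset as the standard CSV inputs
#'
#' Emits `cover_wide.csv` (plots x species), `trait_measurements.csv`
#' (long: species, belt, trait, value), `plot_belt.csv` and `belts.csv`
#' into `dir`, i.e. exactly the files the readers consume.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cov <- data.frame(plot = rownames(dataset$cover$cover),
                    dataset$cover$cover, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.csv(cov, file.path(dir, "cover_wide.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(as.data.frame(dataset$measurements),
            file.path(dir, "trait_measurements.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(dataset$design$plots, file.path(dir, "plot_belt.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(dataset$design$belts, file.path(dir, "belts.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a generator configuration from a YAML or JSON file
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` file whose keys match
#'   the arguments of [generator_config()].
#' @return A `generator_config`.
#' @export
read_generator_config <- function(file) {
  vals <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  do.call(generator_config, vals)
}

# Run `code` with a fixed seed without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
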