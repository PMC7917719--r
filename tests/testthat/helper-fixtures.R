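# Shared builders and independent oracles for the test suite.

# Two-belt, four-plot toy design.
tiny_design <- function() {
  study_design(
    belts = data.frame(belt = c("B1", "B2"), lower = c(1325, 1575),
                       upper = c(1575, 1825)),
    plots = data.frame(plot = c("P1", "P2", "P3", "P4"),
                       belt = c("B1", "B1", "B2", "B2")))
}

tiny_cover <- function(design = tiny_design()) {
  m <- matrix(c(60, 30, 10,
                40, 40, 20,
                10, 50, 40,
                 0, 70, 30),
              nrow = 4, byrow = TRUE,
              dimnames = list(design$plots$plot, c("A", "B", "C")))
  cover_matrix(m, design)
}

# Measurements for one trait on the tiny design; values chosen so the
# specific belt means and pooled fixed means are simple round numbers.
tiny_measurements <- function(design = tiny_design()) {
  trait_measurements(data.frame(
    species = rep(c("A", "B", "C"), each = 4),
    belt = rep(c("B1", "B1", "B2", "B2"), times = 3),
    trait = "H",
    value = c(10, 20, 30, 40,    # A: specific 15 / 35, fixed 25
              12, 18, 22, 28,    # B: specific 15 / 25, fixed 20
               5, 15, 25, 35)),  # C: specific 10 / 30, fixed 20
    design)
}

# Naive double-loop sums of squares, independent of one_way_ss().
oracle_one_way_ss <- function(values, groups) {
  groups <- as.character(groups)
  grand <- sum(values) / length(values)
  ss_total <- 0
  for (v in values) ss_total <- ss_total + (v - grand)^2
  ss_within <- 0
  ss_between <- 0
  for (g in unique(groups)) {
    vs <- values[groups == g]
    gm <- sum(vs) / length(vs)
    for (v in vs) ss_within <- ss_within + (v - gm)^2
    ss_between <- ss_between + length(vs) * (gm - grand)^2
  }
  list(ss_between = ss_between, ss_within = ss_within, ss_total = ss_total)
}

# Build a community_series directly from values + belts (bypasses the
# cover/trait machinery; used to feed the inference layer known numbers).
series_from_values <- function(values, belts, variant = "specific",
                               weighting = "weighted", trait = "H") {
  itvpart:::new_community_series(
    plot = sprintf("P%02d", seq_along(values)),
    belt = as.character(belts), value = values,
    trait = trait, weighting = weighting, variant = variant)
}

# Small generator config used by property tests (fast but non-degenerate).
small_config <- function(seed, ...) {
  generator_config(n_belts = 3, plots_per_belt = c(4, 4, 4),
                   species_pool_size = 12, species_per_belt = c(5, 5, 5),
                   n_individuals = 5, seed = seed, ...)
}

# Full pipeline on a synthetic dataset down to the decomposition table.
decompose_synthetic <- function(ds, weighting = "weighted",
                                threshold = NULL) {
  tt <- build_trait_table(ds$measurements, ds$config$trait_name)
  keep <- measured_species(tt)
  if (!is.null(threshold)) {
    for (b in names(keep)) {
      keep[[b]] <- intersect(select_dominant_species(ds$cover, b, threshold),
                             keep[[b]])
    }
  }
  restricted <- restrict_and_renormalize(ds$cover, keep)
  spec <- compute_series(restricted, tt, weighting, "specific")
  fix <- compute_series(restricted, tt, weighting, "fixed")
  itv <- compute_series(restricted, tt, weighting, "intraspecific")
  decompose_ss(spec, fix, itv)
}
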