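#' Build the fixed and specific trait means for one trait
#'
#' For each species the "specific" mean is the arithmetic mean of its
#' individual measurements within one belt, so it carries the within-species
#' trend along the gradient. The "fixed" mean pools the measured individuals
#' of all belts into a single gradient-wide mean, so it carries only
#' between-species (turnover) information. With unequal per-belt sample
#' sizes the pooled fixed mean equals the sample-size-weighted mean of the
#' belt means, not their plain average (an equal-belt-weight variant is
#' available via `fixed_method`).
#'
#' The optional log10 transform is applied to the individual measurements
#' before any averaging, so means live on the log scale; transforming
#' community means afterwards is deliberately not supported.
#'
#' @param measurements A `trait_measurements` object.
#' @param trait Name of the trait to extract (e.g. `"H"`, `"SLA"`, `"SM"`).
#' @param transform `"none"` or `"log10"`.
#' @param fixed_method `"pooled"` (default; mean over all individuals) or
#'   `"belt_equal"` (unweighted mean of the belt means).
#' @return An object of class `trait_table`: list with `trait`, `transform`,
#'   `specific` (species x belt matrix of belt means, NA where unmeasured),
#'   `fixed` (named vector of pooled means), `n` (species x belt counts)
#'   and `design`.
#' @examples
#' d <- study_design(c("B1", "B2"),
#'                   data.frame(plot = c("P1", "P2"), belt = c("B1", "B2")))
#' tm <- trait_measurements(data.frame(
#'   species = "X", belt = c("B1", "B1", "B2", "B2"), trait = "H",
#'   value = c(10, 20, 30, 40)), d)
#' tt <- build_trait_table(tm, "H")
#' tt$specific  # 15 and 35
#' tt$fixed     # 25
#' @export
build_trait_table <- function(measurements, trait,
                              transform = c("none", "log10"),
                              fixed_method = c("pooled", "belt_equal")) {
  stopifnot(inherits(measurements, "trait_measurements"))
  transform <- match.arg(transform)
  fixed_method <- match.arg(fixed_method)
  design <- attr(measurements, "design")
  rec <- measurements[measurements$trait == trait, , drop = FALSE]
  if (!nrow(rec)) stop("no measurements for trait: ", trait)
  x <- rec$value
  if (transform == "log10") {
    if (any(x <= 0)) stop("log10 transform requires strictly positive values")
    x <- log10(x)
  }
  species <- sort(unique(rec$species))
  belts <- belt_levels(design)
  spf <- factor(rec$species, levels = species)
  bf <- factor(rec$belt, levels = belts)
  specific <- tapply(x, list(spf, bf), mean)
  n <- tapply(rec$value, list(spf, bf), length)
  n[is.na(n)] <- 0L
  fixed <- if (fixed_method == "pooled") {
    tapply(x, spf, mean)
  } else {
    rowMeans(specific, na.rm = TRUE)
  }
  structure(list(trait = trait, transform = transform,
                 specific = specific, fixed = c(fixed), n = n,
                 design = design),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table for '", x$trait, "' (transform: ", x$transform, ")\n",
      sep = "")
  cat("  ", nrow(x$specific), " species x ", ncol(x$specific), " belts; ",
      sum(!is.na(x$specific)), " specific means\n", sep = "")
  invisible(x)
}

#' Species measured in each belt of a trait table
#'
#' @param traits A `trait_table`.
#' @return Named list, one character vector of species per belt (the species
#'   with a specific mean in that belt). Suitable as the `measured` argument
#'   of [restrict_and_renormalize()].
#' @export
measured_species <- function(traits) {
  stopifnot(inherits(traits, "trait_table"))
  belts <- colnames(traits$specific)
  setNames(lapply(belts, function(b) {
    rownames(traits$specific)[!is.na(traits$specific[, b])]
  }), belts)
}
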