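#' Define a belt-structured sampling design
#'
#' A study design is the fixed frame of the analysis: a set of ordered belts
#' (e.g. 250-m elevational bands) and a set of plots, each assigned to
#' exactly one belt. Belts are ordered by their lower elevation bound when
#' bounds are supplied, otherwise by the order given.
#'
#' @param belts Either a character vector of belt labels (already in
#'   gradient order) or a data frame with columns `belt`, `lower`, `upper`
#'   giving elevation bounds in metres.
#' @param plots A data frame with columns `plot` and `belt` mapping every
#'   plot to its belt.
#' @return An object of class `study_design` with elements `belts`
#'   (data frame: `belt`, `lower`, `upper`) and `plots` (data frame:
#'   `plot`, `belt`).
#' @examples
#' d <- study_design(
#'   belts = data.frame(belt = c("B1", "B2"), lower = c(1325, 1575),
#'                      upper = c(1575, 1825)),
#'   plots = data.frame(plot = c("P1", "P2", "P3", "P4"),
#'                      belt = c("B1", "B1", "B2", "B2")))
#' belt_of(d, "P3")
#' @export
study_design <- function(belts, plots) {
  if (is.character(belts)) {
    belts <- data.frame(belt = belts, lower = NA_real_, upper = NA_real_)
  }
  belts <- as.data.frame(belts, stringsAsFactors = FALSE)
  if (!"belt" %in% names(belts)) stop("`belts` needs a `belt` column")
  if (!"lower" %in% names(belts)) belts$lower <- NA_real_
  if (!"upper" %in% names(belts)) belts$upper <- NA_real_
  belts$belt <- as.character(belts$belt)
  if (anyDuplicated(belts$belt)) stop("belt labels must be unique")
  if (!anyNA(belts$lower)) {
    belts <- belts[order(belts$lower), , drop = FALSE]
    if (any(!is.na(belts$upper) & belts$upper <= belts$lower)) {
      stop("belt upper bound must exceed its lower bound")
    }
  }
  rownames(belts) <- NULL

  plots <- as.data.frame(plots, stringsAsFactors = FALSE)
  if (!all(c("plot", "belt") %in% names(plots))) {
    stop("`plots` needs columns `plot` and `belt`")
  }
  plots$plot <- as.character(plots$plot)
  plots$belt <- as.character(plots$belt)
  if (anyDuplicated(plots$plot)) stop("plot identifiers must be unique")
  unknown <- setdiff(plots$belt, belts$belt)
  if (length(unknown)) {
    stop("plots assigned to unknown belt(s): ", paste(unknown, collapse = ", "))
  }
  plots <- plots[order(match(plots$belt, belts$belt), plots$plot), c("plot", "belt")]
  rownames(plots) <- NULL
  structure(list(belts = belts, plots = plots), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", nrow(x$belts), "belts,", nrow(x$plots), "plots\n")
  tab <- table(factor(x$plots$belt, levels = x$belts$belt))
  for (b in x$belts$belt) {
    rng <- x$belts[x$belts$belt == b, c("lower", "upper")]
    rng_txt <- if (is.na(rng$lower)) "" else
      sprintf(" (%g-%g m)", rng$lower, rng$upper)
    cat("  ", b, rng_txt, ": ", tab[[b]], " plots\n", sep = "")
  }
  invisible(x)
}

#' Belt labels of a design, in gradient order
#' @param design A `study_design`.
#' @return Character vector of belt labels.
#' @export
belt_levels <- function(design) {
  stopifnot(inherits(design, "study_design"))
  design$belts$belt
}

#' Belt of one or more plots
#' @param design A `study_design`.
#' @param plot Character vector of plot identifiers.
#' @return Character vector of belt labels, one per plot.
#' @export
belt_of <- function(design, plot) {
  stopifnot(inherits(design, "study_design"))
  idx <- match(plot, design$plots$plot)
  if (anyNA(idx)) {
    stop("unknown plot(s): ", paste(plot[is.na(idx)], collapse = ", "))
  }
  design$plots$belt[idx]
}

#' Construct a plot-by-species cover matrix
#'
#' Covers are relative weights (any common unit, typically percent cover);
#' rows need not sum to 100. Downstream community means always renormalize
#' within the species retained for a plot.
#'
#' @param cover Numeric matrix, plots in rows (rownames = plot ids),
#'   species in columns (colnames = species ids). Entries are nonnegative
#'   relative covers; 0 means absent.
#' @param design A `study_design`; every design plot must be a row.
#' @return An object of class `cover_matrix` with elements `cover` and
#'   `design`.
#' @export
cover_matrix <- function(cover, design) {
  stopifnot(inherits(design, "study_design"))
  cover <- as.matrix(cover)
  if (is.null(rownames(cover)) || is.null(colnames(cover))) {
    stop("`cover` needs plot rownames and species colnames")
  }
  if (anyDuplicated(colnames(cover))) stop("species identifiers must be unique")
  missing_plots <- setdiff(design$plots$plot, rownames(cover))
  if (length(missing_plots)) {
    stop("design plots missing from cover matrix: ",
         paste(missing_plots, collapse = ", "))
  }
  extra <- setdiff(rownames(cover), design$plots$plot)
  if (length(extra)) {
    stop("cover rows for plots not in the design: ", paste(extra, collapse = ", "))
  }
  storage.mode(cover) <- "double"
  if (anyNA(cover)) stop("cover values must not be NA")
  if (any(cover < 0)) {
    bad <- which(cover < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative cover for plot '%s', species '%s'",
                 rownames(cover)[bad[1]], colnames(cover)[bad[2]]))
  }
  empty <- rownames(cover)[rowSums(cover) <= 0]
  if (length(empty)) {
    stop("plot(s) with no positive cover: ", paste(empty, collapse = ", "))
  }
  cover <- cover[design$plots$plot, , drop = FALSE]
  structure(list(cover = cover, design = design), class = "cover_matrix")
}

#' @export
print.cover_matrix <- function(x, ...) {
  cat("Cover matrix:", nrow(x$cover), "plots x", ncol(x$cover), "species\n")
  cat("  total cover per plot: ",
      paste(signif(range(rowSums(x$cover)), 4), collapse = " - "), "\n")
  invisible(x)
}

#' Individual-level trait measurements
#'
#' Long table of raw measurements: one row per measured individual (or
#' measured organ, e.g. a leaf or a seed batch) per species per belt per
#' trait. Values must be strictly positive, as traits here are sizes,
#' areas per mass, or masses.
#'
#' @param records Data frame with columns `species`, `belt`, `trait`,
#'   `value`.
#' @param design A `study_design`; all belts in `records` must exist in it.
#' @return Object of class `trait_measurements` (a validated data frame
#'   with the design attached as attribute `design`).
#' @export
trait_measurements <- function(records, design) {
  stopifnot(inherits(design, "study_design"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("species", "belt", "trait", "value")
  if (!all(need %in% names(records))) {
    stop("`records` needs columns ", paste(need, collapse = ", "))
  }
  records <- records[need]
  records$species <- as.character(records$species)
  records$belt <- as.character(records$belt)
  records$trait <- as.character(records$trait)
  records$value <- as.numeric(records$value)
  unknown <- setdiff(records$belt, belt_levels(design))
  if (length(unknown)) {
    stop("measurements refer to unknown belt(s): ",
         paste(unknown, collapse = ", "))
  }
  if (anyNA(records$value) || any(records$value <= 0)) {
    stop("trait values must be strictly positive and non-missing")
  }
  structure(records, design = design, class = c("trait_measurements", "data.frame"))
}

#' Read a plot-to-belt map and belt table into a study design
#'
#' @param plot_file CSV/TSV with columns `plot`, `belt`.
#' @param belts Optional belt table (see [study_design()]); defaults to the
#'   belts present in `plot_file`, in order of first appearance.
#' @return A `study_design`.
#' @export
read_belt_map <- function(plot_file, belts = NULL) {
  plots <- read_delim_auto(plot_file)
  if (!all(c("plot", "belt") %in% names(plots))) {
    stop("belt map needs columns `plot` and `belt`: ", plot_file)
  }
  if (is.null(belts)) belts <- unique(as.character(plots$belt))
  study_design(belts, plots)
}

#' Read individual trait measurements from a long CSV/TSV
#'
#' @param file Path to a delimited file with columns `species`, `belt`,
#'   `trait`, `value`.
#' @param design A `study_design`.
#' @return A `trait_measurements` object.
#' @export
read_trait_measurements <- function(file, design) {
  trait_measurements(read_delim_auto(file), design)
}

# Delimiter by extension: .tsv/.tab -> tab, otherwise comma.
read_delim_auto <- function(file) {
  sep <- if (grepl("\\.(tsv|tab)$", file, ignore.case = TRUE)) "\t" else ","
  read.csv(file, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}
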