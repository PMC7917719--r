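#' Read a cover table into a cover matrix
#'
#' Two layouts are supported. `wide`: plots in rows (first column or a
#' `plot` column holds plot ids), species in columns. `long`: one row per
#' (plot, species) pair with columns `plot`, `species`, `cover`; species
#' absent from a plot may simply be omitted and get cover 0.
#'
#' Covers are relative weights: rows are not required to sum to any fixed
#' total, because community means renormalize within the retained species.
#'
#' @param file Path to a CSV (or TSV, by extension) file with a header row.
#' @param layout `"wide"` or `"long"`.
#' @param design A `study_design` naming every plot.
#' @return A `cover_matrix`.
#' @export
read_cover_table <- function(file, layout = c("wide", "long"), design) {
  layout <- match.arg(layout)
  tab <- read_delim_auto(file)
  if (layout == "long") {
    need <- c("plot", "species", "cover")
    if (!all(need %in% names(tab))) {
      stop("long cover table needs columns ", paste(need, collapse = ", "))
    }
    tab$plot <- as.character(tab$plot)
    tab$species <- as.character(tab$species)
    tab$cover <- as.numeric(tab$cover)
    bad <- which(is.na(tab$cover) | tab$cover < 0)
    if (length(bad)) {
      stop(sprintf("invalid cover in row %d (plot '%s', species '%s'): %s",
                   bad[1], tab$plot[bad[1]], tab$species[bad[1]],
                   tab$cover[bad[1]]))
    }
    unknown <- which(!(tab$plot %in% design$plots$plot))
    if (length(unknown)) {
      stop(sprintf("row %d refers to unknown plot '%s'",
                   unknown[1], tab$plot[unknown[1]]))
    }
    species <- sort(unique(tab$species))
    m <- matrix(0, nrow = nrow(design$plots), ncol = length(species),
                dimnames = list(design$plots$plot, species))
    # later duplicates of the same (plot, species) pair overwrite earlier ones
    m[cbind(tab$plot, tab$species)] <- tab$cover
  } else {
    plot_col <- if ("plot" %in% names(tab)) "plot" else names(tab)[1]
    plots <- as.character(tab[[plot_col]])
    unknown <- which(!(plots %in% design$plots$plot))
    if (length(unknown)) {
      stop(sprintf("row %d refers to unknown plot '%s'",
                   unknown[1], plots[unknown[1]]))
    }
    vals <- tab[setdiff(names(tab), c(plot_col, "belt"))]
    m <- as.matrix(vals)
    storage.mode(m) <- "double"
    if (anyNA(m)) stop("wide cover table contains non-numeric or missing covers")
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      stop(sprintf("negative cover in row %d (plot '%s', species '%s')",
                   neg[1, 1], plots[neg[1, 1]], colnames(m)[neg[1, 2]]))
    }
    rownames(m) <- plots
    missing_plots <- setdiff(design$plots$plot, plots)
    if (length(missing_plots)) {
      stop("design plots missing from cover table: ",
           paste(missing_plots, collapse = ", "))
    }
  }
  cover_matrix(m, design)
}

#' Select the dominant species of a belt (cumulative-cover rule)
#'
#' Species are ranked by their total cover across the belt's plots
#' (descending; ties broken by species identifier) and the shortest prefix
#' whose cumulative share of total belt cover reaches `threshold` is
#' returned. With the default 0.80 this is the usual "species making up at
#' least 80% of the vegetation cover" rule used to decide which species are
#' worth measuring.
#'
#' @param cover A `cover_matrix`.
#' @param belt A belt label of the design.
#' @param threshold Cumulative cover fraction in (0, 1], default 0.80.
#' @return Character vector of dominant species, in rank order.
#' @examples
#' d <- study_design("B1", data.frame(plot = "P1", belt = "B1"))
#' cm <- cover_matrix(matrix(c(50, 20, 15, 10, 5), 1,
#'                    dimnames = list("P1", LETTERS[1:5])), d)
#' select_dominant_species(cm, "B1")  # A, B, C: cumulative 85% >= 80%
#' @export
select_dominant_species <- function(cover, belt, threshold = 0.80) {
  stopifnot(inherits(cover, "cover_matrix"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]")
  }
  if (!belt %in% belt_levels(cover$design)) stop("unknown belt: ", belt)
  plots <- cover$design$plots$plot[cover$design$plots$belt == belt]
  if (!length(plots)) stop("belt has no plots: ", belt)
  tot <- colSums(cover$cover[plots, , drop = FALSE])
  tot <- tot[tot > 0]
  if (!length(tot)) stop("belt has no positive cover: ", belt)
  ord <- order(-tot, names(tot))
  tot <- tot[ord]
  share <- cumsum(tot) / sum(tot)
  k <- which(share >= threshold - 1e-12)[1]
  names(tot)[seq_len(k)]
}

#' Restrict a cover matrix to measured species and renormalize
#'
#' Drops species without trait data and rescales each plot's remaining
#' covers to sum to one, so they can be used directly as CWM weights.
#' The measured set may be global (one character vector) or belt-specific
#' (a named list, one species vector per belt), the latter matching designs
#' where species were measured belt by belt.
#'
#' @param cover A `cover_matrix`.
#' @param measured Character vector of species, or named list
#'   `belt -> character vector`.
#' @return A `cover_matrix` whose rows sum to 1 (species never measured
#'   anywhere are dropped from the matrix; a cover retained in no belt is 0).
#' @export
restrict_and_renormalize <- function(cover, measured) {
  stopifnot(inherits(cover, "cover_matrix"))
  m <- cover$cover
  belts <- belt_of(cover$design, rownames(m))
  if (is.list(measured)) {
    missing_belts <- setdiff(unique(belts), names(measured))
    if (length(missing_belts)) {
      stop("no measured-species set for belt(s): ",
           paste(missing_belts, collapse = ", "))
    }
    keep_any <- sort(unique(unlist(measured, use.names = FALSE)))
    out <- matrix(0, nrow(m), length(keep_any),
                  dimnames = list(rownames(m), keep_any))
    for (i in seq_len(nrow(m))) {
      sp <- intersect(colnames(m), measured[[belts[i]]])
      out[i, sp] <- m[i, sp]
    }
  } else {
    keep_any <- intersect(colnames(m), measured)
    out <- m[, keep_any, drop = FALSE]
  }
  tot <- rowSums(out)
  dead <- rownames(out)[tot <= 0]
  if (length(dead)) {
    stop("plot(s) retain no measured species with positive cover: ",
         paste(dead, collapse = ", "))
  }
  out <- out / tot
  cover_matrix(out, cover$design)
}
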