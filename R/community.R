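#' Community mean of a trait for one plot
#'
#' The weighted form is the community-weighted mean CWM = sum(p_i * x_i)
#' over the species present, with p_i the species' relative cover weights;
#' the unweighted form is the plain average CM = sum(x_i) / S over the S
#' present species, ignoring cover.
#'
#' @param weights Named nonnegative weights summing to 1 (required for
#'   `weighting = "weighted"`; for `"unweighted"` they only define presence).
#' @param trait_values Named trait values covering every present species.
#' @param weighting `"weighted"` or `"unweighted"`.
#' @return A single numeric community mean.
#' @examples
#' community_mean(c(A = 0.6, B = 0.4), c(A = 10, B = 20), "weighted")    # 14
#' community_mean(c(A = 0.6, B = 0.4), c(A = 10, B = 20), "unweighted")  # 15
#' @export
community_mean <- function(weights, trait_values,
                           weighting = c("weighted", "unweighted")) {
  weighting <- match.arg(weighting)
  if (!length(weights)) stop("at least one species is required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  present <- names(weights)[weights > 0]
  if (!length(present)) stop("at least one species must have positive weight")
  missing_x <- setdiff(present, names(trait_values))
  if (length(missing_x) || anyNA(trait_values[present])) {
    bad <- c(missing_x, present[is.na(trait_values[present])])
    stop("species without trait value: ", paste(unique(bad), collapse = ", "))
  }
  x <- trait_values[present]
  if (weighting == "weighted") {
    w <- weights[present]
    if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to 1")
    sum(w * x)
  } else {
    mean(x)
  }
}

#' Compute a per-plot community-mean series
#'
#' Evaluates one trait under one weighting for one trait variant across all
#' plots of the design. Variants: `"specific"` uses the belt-level species
#' means of the plot's own belt (turnover + intraspecific information),
#' `"fixed"` uses the gradient-pooled species means (turnover only), and
#' `"intraspecific"` is their per-plot difference specific - fixed.
#'
#' The cover matrix must already be restricted to measured species; each
#' plot's weights are renormalized over its present species, so any
#' positive scaling of covers gives the same result.
#'
#' @param cover A `cover_matrix` (typically from
#'   [restrict_and_renormalize()]).
#' @param traits A `trait_table`.
#' @param weighting `"weighted"` (CWM) or `"unweighted"` (CM).
#' @param variant `"specific"`, `"fixed"` or `"intraspecific"`.
#' @return An object of class `community_series`: data frame with columns
#'   `plot`, `belt`, `value` and attributes `trait`, `weighting`, `variant`.
#' @export
compute_series <- function(cover, traits,
                           weighting = c("weighted", "unweighted"),
                           variant = c("specific", "fixed", "intraspecific")) {
  stopifnot(inherits(cover, "cover_matrix"), inherits(traits, "trait_table"))
  weighting <- match.arg(weighting)
  variant <- match.arg(variant)
  if (variant == "intraspecific") {
    sp <- compute_series(cover, traits, weighting, "specific")
    fx <- compute_series(cover, traits, weighting, "fixed")
    sp$value <- sp$value - fx$value
    attr(sp, "variant") <- "intraspecific"
    return(sp)
  }
  m <- cover$cover
  plots <- rownames(m)
  belts <- belt_of(cover$design, plots)
  vals <- vapply(seq_along(plots), function(i) {
    w <- setNames(as.vector(m[i, ]), colnames(m))
    present <- names(w)[w > 0]
    x <- if (variant == "specific") {
      xs <- traits$specific[present, belts[i]]
      if (anyNA(xs)) {
        bad <- present[is.na(xs)]
        stop(sprintf("no specific mean for species %s in belt '%s' (plot '%s')",
                     paste(bad, collapse = ", "), belts[i], plots[i]))
      }
      xs
    } else {
      xf <- traits$fixed[present]
      if (anyNA(xf)) {
        stop("no fixed mean for species: ",
             paste(present[is.na(xf)], collapse = ", "))
      }
      xf
    }
    names(x) <- present
    community_mean(w[present] / sum(w[present]), x, weighting)
  }, numeric(1))
  new_community_series(plots, belts, vals, traits$trait, weighting, variant)
}

new_community_series <- function(plot, belt, value, trait, weighting, variant) {
  structure(data.frame(plot = plot, belt = belt, value = value,
                       stringsAsFactors = FALSE, row.names = NULL),
            trait = trait, weighting = weighting, variant = variant,
            class = c("community_series", "data.frame"))
}

#' @export
print.community_series <- function(x, ...) {
  cat(sprintf("Community series: trait '%s', %s, %s variant, %d plots\n",
              attr(x, "trait"),
              if (attr(x, "weighting") == "weighted") "CWM" else "CM",
              attr(x, "variant"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' Export community series to a long CSV
#'
#' Columns: plot, belt, trait, weighting, variant, value; one block per
#' series, in the order given.
#'
#' @param series A `community_series` or list of them.
#' @param file Output path.
#' @return The combined data frame, invisibly.
#' @export
write_series <- function(series, file) {
  if (inherits(series, "community_series")) series <- list(series)
  out <- do.call(rbind, lapply(series, function(s) {
    data.frame(plot = s$plot, belt = s$belt, trait = attr(s, "trait"),
               weighting = attr(s, "weighting"), variant = attr(s, "variant"),
               value = s$value, stringsAsFactors = FALSE)
  }))
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(out)
}
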