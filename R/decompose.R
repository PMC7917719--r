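#' One-way sums of squares
#'
#' Between-group, within-group and total sums of squares of a numeric
#' response grouped by a categorical factor (here, the belt), with their
#' degrees of freedom. This is the building block of both the ANOVA tables
#' and the turnover/intraspecific/covariation decomposition.
#'
#' @param values Numeric vector, one value per observation (plot).
#' @param groups Vector of group labels, same length as `values`.
#' @return List with `ss_between`, `ss_within`, `ss_total`, `df_between`,
#'   `df_within`, `n`, `k`.
#' @examples
#' one_way_ss(c(1, 2, 3, 5), c("a", "a", "b", "b"))
#' # ss_between 6.25, ss_within 2.5, df 1 and 2
#' @export
one_way_ss <- function(values, groups) {
  if (!length(values)) stop("empty input")
  if (length(values) != length(groups)) {
    stop("`values` and `groups` must have the same length")
  }
  if (anyNA(values) || anyNA(groups)) stop("missing values are not allowed")
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2) stop("at least two groups are required")
  n <- length(values)
  gm <- mean(values)
  means <- tapply(values, g, mean)
  sizes <- tapply(values, g, length)
  ss_between <- sum(sizes * (means - gm)^2)
  ss_within <- sum((values - means[g])^2)
  list(ss_between = ss_between, ss_within = ss_within,
       ss_total = ss_between + ss_within,
       df_between = k - 1L, df_within = n - k, n = n, k = k)
}

#' Decompose community-trait variation into turnover, intraspecific and
#' covariation sums of squares
#'
#' Applies a one-way (belt) sum-of-squares analysis separately to the
#' fixed, intraspecific and specific community-mean series and assembles
#' the 3 x 4 decomposition matrix: rows `belt` (explained), `residual`,
#' `total`; columns `turnover` (from the fixed series), `intraspecific`
#' (from the specific - fixed difference), `covariation` and `total` (from
#' the specific series). Because specific = fixed + intraspecific per plot,
#' the total column splits as SS_specific = SS_turnover +
#' SS_intraspecific + SS_covariation in every row; the covariation column
#' is obtained by subtracting the first two columns from the last, and is
#' the only column that may be negative (opposing turnover and
#' within-species trends).
#'
#' @param specific,fixed,intraspecific `community_series` objects over the
#'   same plots; `intraspecific` may be omitted and is then computed as
#'   specific - fixed.
#' @return An object of class `ss_table`: the 3 x 4 numeric matrix with
#'   attributes `df_between`, `df_within`, `trait`, `weighting`.
#' @export
decompose_ss <- function(specific, fixed, intraspecific = NULL) {
  stopifnot(inherits(specific, "community_series"),
            inherits(fixed, "community_series"))
  if (is.null(intraspecific)) {
    intraspecific <- specific
    intraspecific$value <- specific$value - fixed$value
    attr(intraspecific, "variant") <- "intraspecific"
  }
  if (!identical(specific$plot, fixed$plot) ||
      !identical(specific$plot, intraspecific$plot)) {
    stop("the three series must cover identical plots in identical order")
  }
  resid_itv <- intraspecific$value - (specific$value - fixed$value)
  if (max(abs(resid_itv)) > 1e-8 * max(1, max(abs(specific$value)))) {
    stop("intraspecific series is not specific - fixed per plot")
  }
  g <- specific$belt
  parts <- list(turnover = one_way_ss(fixed$value, g),
                intraspecific = one_way_ss(intraspecific$value, g),
                total = one_way_ss(specific$value, g))
  m <- matrix(NA_real_, 3, 4,
              dimnames = list(c("belt", "residual", "total"),
                              c("turnover", "intraspecific", "covariation",
                                "total")))
  for (cn in names(parts)) {
    p <- parts[[cn]]
    m[, cn] <- c(p$ss_between, p$ss_within, p$ss_total)
  }
  m[, "covariation"] <- m[, "total"] - m[, "turnover"] - m[, "intraspecific"]
  structure(m, df_between = parts$total$df_between,
            df_within = parts$total$df_within,
            trait = attr(specific, "trait"),
            weighting = attr(specific, "weighting"),
            class = c("ss_table", "matrix", "array"))
}

#' @export
print.ss_table <- function(x, digits = 3, ...) {
  cat(sprintf("Sum-of-squares decomposition (trait '%s', %s; df %d/%d)\n",
              attr(x, "trait") %||% "?",
              if (identical(attr(x, "weighting"), "weighted")) "CWM" else "CM",
              attr(x, "df_between"), attr(x, "df_within")))
  print(round(unclass(x)[, , drop = FALSE], digits))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a decomposition to proportions of total variation
#'
#' Divides every cell by the grand total (total row, total column), i.e. by
#' the total sum of squares of the specific series, so the bottom-right
#' cell is exactly 1 and cells read as shares of the total community trait
#' variation.
#'
#' @param ss An `ss_table`.
#' @return A `proportion_table` (same shape and attributes).
#' @export
to_proportions <- function(ss) {
  stopifnot(inherits(ss, "ss_table"))
  denom <- ss["total", "total"]
  if (!is.finite(denom) || denom <= 0) {
    stop("total variation is zero; proportions are undefined")
  }
  out <- unclass(ss) / denom
  attributes(out)[c("df_between", "df_within", "trait", "weighting")] <-
    attributes(ss)[c("df_between", "df_within", "trait", "weighting")]
  class(out) <- c("proportion_table", "matrix", "array")
  out
}

#' @export
print.proportion_table <- function(x, digits = 3, ...) {
  cat(sprintf("Proportions of total variation (trait '%s', %s)\n",
              attr(x, "trait") %||% "?",
              if (identical(attr(x, "weighting"), "weighted")) "CWM" else "CM"))
  print(round(unclass(x)[, , drop = FALSE], digits))
  invisible(x)
}

#' Summary statistics of a decomposition
#'
#' Reports (a) the turnover : intraspecific ratio of total sums of squares
#' (how many times larger between-species variation is than within-species
#' variation) and (b) the percentage of each component's variation left
#' unexplained by the belt factor, computed against the component's own
#' column total (100 * residual / total per column).
#'
#' @param ss An `ss_table`.
#' @return List with `turnover_itv_ratio` (NA if the intraspecific total is
#'   zero) and `pct_unexplained`, a named vector over turnover,
#'   intraspecific and total (NA where the column total is zero).
#' @export
summarize_components <- function(ss) {
  stopifnot(inherits(ss, "ss_table"))
  ratio <- if (ss["total", "intraspecific"] > 0) {
    ss["total", "turnover"] / ss["total", "intraspecific"]
  } else NA_real_
  comps <- c("turnover", "intraspecific", "total")
  pct <- vapply(comps, function(cn) {
    tot <- ss["total", cn]
    if (tot > 0) 100 * ss["residual", cn] / tot else NA_real_
  }, numeric(1))
  list(turnover_itv_ratio = ratio, pct_unexplained = pct)
}

#' Export a decomposition (or proportion) table to CSV
#'
#' @param x An `ss_table` or `proportion_table`.
#' @param file Output path.
#' @return The exported data frame, invisibly.
#' @export
write_ss_table <- function(x, file) {
  stopifnot(inherits(x, "ss_table") || inherits(x, "proportion_table"))
  out <- data.frame(row = rownames(x), unclass(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(out)
}
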