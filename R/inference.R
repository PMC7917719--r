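#' One-way ANOVA on a community series
#'
#' Standard fixed-effects one-way ANOVA of the per-plot community means on
#' the belt factor: F is the ratio of the between- to within-belt mean
#' squares and p its upper-tail probability under the F distribution.
#' Degenerate cases follow the usual conventions: all values identical
#' gives F = 0, p = 1; nonzero between-belt variation with zero
#' within-belt variation gives F = Inf, p = 0.
#'
#' @param series A `community_series` (or any data frame with `value` and
#'   `belt` columns).
#' @return Object of class `anova_oneway`: list with `ss_between`,
#'   `ss_within`, `df_between`, `df_within`, `ms_between`, `ms_within`,
#'   `f`, `p`, and the group `means` and `sizes`.
#' @export
anova_oneway <- function(series) {
  ss <- one_way_ss(series$value, series$belt)
  if (ss$df_within < 1) stop("at least one within-group degree of freedom is required")
  ms_b <- ss$ss_between / ss$df_between
  ms_w <- ss$ss_within / ss$df_within
  if (ss$ss_within <= 0 && ss$ss_between <= 0) {
    f <- 0; p <- 1
  } else if (ss$ss_within <= 0) {
    f <- Inf; p <- 0
  } else {
    f <- ms_b / ms_w
    p <- pf(f, ss$df_between, ss$df_within, lower.tail = FALSE)
  }
  g <- factor(series$belt)
  structure(list(ss_between = ss$ss_between, ss_within = ss$ss_within,
                 df_between = ss$df_between, df_within = ss$df_within,
                 ms_between = ms_b, ms_within = ms_w, f = f, p = p,
                 means = c(tapply(series$value, g, mean)),
                 sizes = c(tapply(series$value, g, length)),
                 trait = attr(series, "trait"),
                 weighting = attr(series, "weighting"),
                 variant = attr(series, "variant")),
            class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("One-way ANOVA (%s %s, %s variant)\n",
              if (identical(x$weighting, "weighted")) "CWM" else "CM",
              x$trait %||% "", x$variant %||% ""))
  tab <- data.frame(SS = c(x$ss_between, x$ss_within),
                    DF = c(x$df_between, x$df_within),
                    MS = c(x$ms_between, x$ms_within),
                    F = c(x$f, NA), p = c(x$p, NA),
                    row.names = c("Belt", "Residuals"))
  print(round(tab, 4))
  invisible(x)
}

#' Tukey-Kramer HSD pairwise comparisons between belts
#'
#' All-pairs comparisons after a one-way ANOVA, controlling the family-wise
#' error rate via the studentized range distribution. The Kramer form of
#' the standard error, sqrt(MS_within / 2 * (1/n_a + 1/n_b)), handles
#' unequal belt sample sizes; with equal n it reduces to classic HSD.
#' Adjusted p-values are upper-tail studentized-range probabilities with
#' k groups and the ANOVA's residual degrees of freedom.
#'
#' @param series A `community_series`.
#' @param alpha Significance level used for the `significant` flag
#'   (default 0.05).
#' @return Object of class `tukey_hsd`: data frame with one row per
#'   unordered belt pair (`belt_a`, `belt_b`, `diff` = mean_b - mean_a,
#'   `se`, `q`, `p_adj`, `significant`), plus attributes `alpha`, `k`,
#'   `df`, `ms_within`.
#' @export
tukey_hsd <- function(series, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)")
  }
  an <- anova_oneway(series)
  k <- length(an$means)
  belts <- names(an$means)
  pairs <- utils::combn(belts, 2)
  res <- data.frame(belt_a = pairs[1, ], belt_b = pairs[2, ],
                    stringsAsFactors = FALSE)
  res$diff <- an$means[res$belt_b] - an$means[res$belt_a]
  res$se <- sqrt(an$ms_within / 2 *
                   (1 / an$sizes[res$belt_a] + 1 / an$sizes[res$belt_b]))
  res$q <- ifelse(res$se > 0, abs(res$diff) / res$se,
                  ifelse(abs(res$diff) > 0, Inf, 0))
  res$p_adj <- ifelse(is.finite(res$q),
                      ptukey(res$q, nmeans = k, df = an$df_within,
                             lower.tail = FALSE),
                      0)
  res$p_adj[res$q == 0] <- 1
  res$significant <- res$p_adj < alpha
  rownames(res) <- NULL
  structure(res, alpha = alpha, k = k, df = an$df_within,
            ms_within = an$ms_within, means = an$means,
            trait = attr(series, "trait"),
            weighting = attr(series, "weighting"),
            variant = attr(series, "variant"),
            class = c("tukey_hsd", "data.frame"))
}

#' @export
print.tukey_hsd <- function(x, ...) {
  cat(sprintf("Tukey-Kramer HSD (%d groups, df = %d, alpha = %g)\n",
              attr(x, "k"), attr(x, "df"), attr(x, "alpha")))
  df <- as.data.frame(x)
  df$p_adj <- format_pvalue(df$p_adj)
  print(df)
  invisible(x)
}

#' Compact letter display for pairwise comparisons
#'
#' Assigns letters to belts so that two belts share a letter if and only if
#' their Tukey comparison is not significant at `alpha`, using the
#' insert-and-absorb algorithm: start from one group containing all belts;
#' for every significant pair split each group containing both members into
#' two (dropping one member each), then absorb groups contained in another.
#' Letters follow the design's belt order deterministically.
#'
#' @param result A `tukey_hsd` object covering all belt pairs.
#' @param alpha Significance level (default: the level stored in `result`).
#' @return Named character vector of letter codes, one per belt.
#' @export
compact_letters <- function(result, alpha = attr(result, "alpha")) {
  stopifnot(inherits(result, "tukey_hsd"))
  belts <- names(attr(result, "means"))
  sets <- list(belts)
  sig <- result[result$p_adj < alpha, c("belt_a", "belt_b"), drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$belt_a[i]; b <- sig$belt_b[i]
    new_sets <- list()
    for (s in sets) {
      if (all(c(a, b) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop any set contained in another
    keep <- vapply(seq_along(new_sets), function(j) {
      !any(vapply(seq_along(new_sets), function(l) {
        l != j && all(new_sets[[j]] %in% new_sets[[l]]) &&
          !(length(new_sets[[l]]) == length(new_sets[[j]]) && l < j)
      }, logical(1)))
    }, logical(1))
    sets <- new_sets[keep]
  }
  # order sets by position of their first belt, then assign letters
  first <- vapply(sets, function(s) min(match(s, belts)), numeric(1))
  sets <- sets[order(first)]
  letters_out <- setNames(rep("", length(belts)), belts)
  for (j in seq_along(sets)) {
    lab <- make_letter(j)
    for (b in sets[[j]]) {
      letters_out[b] <- paste0(letters_out[b], lab)
    }
  }
  letters_out
}

make_letter <- function(j) {
  # a, b, ..., z, aa, ab, ... for pathological numbers of groups
  out <- ""
  while (j > 0) {
    out <- paste0(letters[(j - 1) %% 26 + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

#' Format p-values the way decomposition tables are usually printed
#'
#' Exact to three decimals, with `<0.001` and `<0.0001` below those
#' thresholds. Stored p-values are never truncated; this only affects
#' rendering.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 1e-4, "<0.0001",
         ifelse(p < 1e-3, "<0.001", sprintf("%.3f", p)))
}

#' Export an ANOVA + Tukey pair as a CSV table
#'
#' Writes the ANOVA rows (SS, DF, MS, F, p) followed by the pairwise
#' adjusted p-values, mirroring the usual published layout.
#'
#' @param anova An `anova_oneway`.
#' @param tukey The matching `tukey_hsd`.
#' @param file Output path.
#' @return The exported data frame, invisibly.
#' @export
write_anova_table <- function(anova, tukey, file) {
  top <- data.frame(
    term = c("Belt", "Residuals"),
    SS = round(c(anova$ss_between, anova$ss_within), 3),
    DF = c(anova$df_between, anova$df_within),
    MS = round(c(anova$ms_between, anova$ms_within), 3),
    F = c(round(anova$f, 3), NA),
    p = c(format_pvalue(anova$p), NA),
    stringsAsFactors = FALSE)
  pw <- data.frame(
    term = paste(tukey$belt_a, "vs.", tukey$belt_b),
    SS = NA, DF = NA, MS = NA, F = NA,
    p = format_pvalue(tukey$p_adj), stringsAsFactors = FALSE)
  out <- rbind(top, pw)
  write.csv(out, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(out)
}
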