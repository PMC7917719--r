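#' Assemble a decomposition table from component sums of squares
#'
#' Builds an `ss_table` from the between-belt ("belt") and residual sums of
#' squares of the three one-way analyses (turnover = fixed series,
#' intraspecific = difference series, total = specific series), applying
#' the package's assembly rules: the total row is belt + residual per
#' column, and the covariation column is total - turnover - intraspecific
#' per row. This is the entry point when the component analyses come from
#' elsewhere (e.g. a printed results table) rather than from
#' [decompose_ss()] on plot-level series.
#'
#' @param turnover,intraspecific,total Numeric length-2 vectors
#'   `c(belt, residual)` of sums of squares for the fixed, difference and
#'   specific analyses.
#' @param df_between,df_within Degrees of freedom of the one-way analyses.
#' @param trait,weighting Optional labels.
#' @return An `ss_table`.
#' @export
as_ss_table <- function(turnover, intraspecific, total,
                        df_between, df_within,
                        trait = NULL, weighting = NULL) {
  stopifnot(length(turnover) == 2, length(intraspecific) == 2,
            length(total) == 2)
  m <- matrix(NA_real_, 3, 4,
              dimnames = list(c("belt", "residual", "total"),
                              c("turnover", "intraspecific", "covariation",
                                "total")))
  m[c("belt", "residual"), "turnover"] <- turnover
  m[c("belt", "residual"), "intraspecific"] <- intraspecific
  m[c("belt", "residual"), "total"] <- total
  m["total", ] <- m["belt", ] + m["residual", ]
  m[, "covariation"] <- m[, "total"] - m[, "turnover"] - m[, "intraspecific"]
  structure(m, df_between = as.integer(df_between),
            df_within = as.integer(df_within),
            trait = trait, weighting = weighting,
            class = c("ss_table", "matrix", "array"))
}

#' Published decomposition matrices bundled with the package
#'
#' Sum-of-squares (B) and proportion (C) decomposition matrices transcribed
#' from a published study of Mediterranean mountain grassland communities
#' along a four-belt elevational gradient (45 plots, df 3/41), for three
#' traits (plant height H, specific leaf area SLA, seed mass SM) under both
#' weightings (CWM and CM). These serve as printed-arithmetic reference
#' values: re-applying the package's assembly, division and summary rules
#' to the measured cells reproduces the printed covariation cells and
#' proportion matrices.
#'
#' @return Named list (`cwm_h`, `cm_h`, `cwm_sla`, `cm_sla`, `cwm_sm`,
#'   `cm_sm`); each element is a list with `B` and `C`, 3 x 4 matrices with
#'   rows belt/residual/total and columns
#'   turnover/intraspecific/covariation/total, plus `df_between`,
#'   `df_within`.
#' @export
published_decomposition_tables <- function() {
  file <- system.file("extdata", "published_decomposition_matrices.csv",
                      package = "itvpart", mustWork = TRUE)
  tab <- read.csv(file, stringsAsFactors = FALSE)
  cols <- c("turnover", "intraspecific", "covariation", "total")
  out <- lapply(split(tab, tab$analysis), function(a) {
    mats <- lapply(split(a, a$matrix), function(m) {
      m <- m[match(c("belt", "residual", "total"), m$row), ]
      mat <- as.matrix(m[cols])
      rownames(mat) <- m$row
      mat
    })
    c(mats, list(df_between = 3L, df_within = 41L))
  })
  out[unique(tab$analysis)]
}

#' Published one-way ANOVA component tables bundled with the package
#'
#' The part-A companion of [published_decomposition_tables()]: sums of
#' squares, degrees of freedom, mean squares and F statistics of the
#' fixed, specific and intraspecific one-way analyses for each trait and
#' weighting, as printed.
#'
#' @return Data frame with columns `analysis`, `component`, `ss_belt`,
#'   `ss_residual`, `df_belt`, `df_residual`, `ms_belt`, `ms_residual`,
#'   `f`.
#' @export
published_anova_components <- function() {
  file <- system.file("extdata", "published_anova_components.csv",
                      package = "itvpart", mustWork = TRUE)
  read.csv(file, stringsAsFactors = FALSE)
}
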