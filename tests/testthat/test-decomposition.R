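test_that("one-way sums of squares match hand and brute-force oracles", {
  r <- one_way_ss(c(1, 2, 3, 5), c("a", "a", "b", "b"))
  expect_equal(r$ss_between, 6.25)
  expect_equal(r$ss_within, 2.5)
  expect_equal(r$df_between, 1L)
  expect_equal(r$df_within, 2L)

  # constant data has zero variation everywhere
  r0 <- one_way_ss(rep(4, 6), rep(c("a", "b"), 3))
  expect_equal(r0$ss_between, 0)
  expect_equal(r0$ss_within, 0)

  # a 45-plot, 4-group layout yields df 3 and 41
  g45 <- rep(paste0("B", 1:4), c(9, 10, 11, 15))
  r45 <- one_way_ss(seq_len(45), g45)
  expect_equal(r45$df_between, 3L)
  expect_equal(r45$df_within, 41L)

  expect_error(one_way_ss(1:3, rep("a", 3)), "two groups")
  expect_error(one_way_ss(numeric(0), character(0)), "empty")

  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    k <- sample(2:min(5, n - 1), 1)
    g <- sample(letters[1:k], n, replace = TRUE)
    while (length(unique(g)) < 2) g <- sample(letters[1:k], n, replace = TRUE)
    v <- rnorm(n, sd = runif(1, 0.1, 10))
    got <- one_way_ss(v, g)
    want <- oracle_one_way_ss(v, g)
    expect_equal(got$ss_between, want$ss_between, tolerance = 1e-10)
    expect_equal(got$ss_within, want$ss_within, tolerance = 1e-10)
    expect_equal(got$ss_total, want$ss_total, tolerance = 1e-10)
  }
})

test_that("decomposition satisfies its additive identities", {
  for (seed in c(3, 17, 41)) {
    for (cs in c(-1, 0, 1)) {
      ds <- generate_dataset(small_config(seed = seed, covariation_sign = cs))
      for (wt in c("weighted", "unweighted")) {
        ss <- decompose_synthetic(ds, wt)
        # row identity: belt + residual = total, per column
        expect_equal(unname(ss["belt", ] + ss["residual", ]),
                     unname(ss["total", ]),
                     tolerance = 1e-9)
        # column identity: turnover + intraspecific + covariation = total
        expect_equal(unname(ss[, "turnover"] + ss[, "intraspecific"] +
                              ss[, "covariation"]),
                     unname(ss[, "total"]), tolerance = 1e-9)
        # covariation equals the row-wise subtraction oracle
        expect_equal(unname(ss[, "covariation"]),
                     unname(ss[, "total"] - ss[, "turnover"] -
                              ss[, "intraspecific"]))
        expect_true(all(ss[, c("turnover", "intraspecific", "total")] >= 0))
      }
    }
  }
})

test_that("degenerate decompositions behave as expected", {
  # fixed == specific: intraspecific and covariation vanish
  ds <- generate_dataset(small_config(seed = 5, itv_slope = 0,
                                      individual_sd = 0))
  ss <- decompose_synthetic(ds)
  expect_equal(unname(ss[, "intraspecific"]), rep(0, 3), tolerance = 1e-18)
  expect_equal(unname(ss[, "covariation"]), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(ss[, "turnover"]), unname(ss[, "total"]),
               tolerance = 1e-9)

  # mismatched plots are rejected
  tt <- build_trait_table(ds$measurements, "H")
  restricted <- restrict_and_renormalize(ds$cover, measured_species(tt))
  spec <- compute_series(restricted, tt, "weighted", "specific")
  fix <- compute_series(restricted, tt, "weighted", "fixed")
  fix_perm <- fix[rev(seq_len(nrow(fix))), ]
  expect_error(decompose_ss(spec, fix_perm), "identical plots")

  # a series that is not specific - fixed is rejected
  bad_itv <- spec
  bad_itv$value <- spec$value - fix$value + 1
  expect_error(decompose_ss(spec, fix, bad_itv), "not specific - fixed")
})

test_that("proportions divide by total variation and are scale-free", {
  ss <- as_ss_table(turnover = c(302.300, 615.400),
                    intraspecific = c(32.620, 45.650),
                    total = c(443.900, 687.000),
                    df_between = 3, df_within = 41)
  p <- to_proportions(ss)
  expect_equal(p["belt", "turnover"], 302.300 / 1130.900, tolerance = 1e-12)
  expect_equal(round(p["belt", "turnover"], 3), 0.267)
  expect_equal(p["total", "total"], 1, tolerance = 1e-12)

  ss_scaled <- ss
  ss_scaled[] <- unclass(ss) * 13.7
  expect_equal(unclass(to_proportions(ss_scaled)), unclass(p),
               tolerance = 1e-12)

  ss0 <- as_ss_table(c(0, 0), c(0, 0), c(0, 0), 3, 41)
  expect_error(to_proportions(ss0), "zero")
})

test_that("proportion tables ignore affine shifts of the trait", {
  ds <- generate_dataset(small_config(seed = 23))
  tt <- build_trait_table(ds$measurements, "H")
  restricted <- restrict_and_renormalize(ds$cover, measured_species(tt))
  mk <- function(tt) {
    decompose_ss(compute_series(restricted, tt, "weighted", "specific"),
                 compute_series(restricted, tt, "weighted", "fixed"),
                 compute_series(restricted, tt, "weighted", "intraspecific"))
  }
  tt2 <- tt
  tt2$specific <- 3 * tt$specific + 11
  tt2$fixed <- 3 * tt$fixed + 11
  p1 <- to_proportions(mk(tt))
  p2 <- to_proportions(mk(tt2))
  expect_equal(unclass(p2), unclass(p1), tolerance = 1e-9)
})

test_that("summary statistics follow the column-total convention", {
  ss <- as_ss_table(turnover = c(302.300, 615.400),
                    intraspecific = c(32.620, 45.650),
                    total = c(443.900, 687.000),
                    df_between = 3, df_within = 41)
  s <- summarize_components(ss)
  # between-species variation ~ 11.7 times the within-species variation
  expect_equal(s$turnover_itv_ratio, 917.700 / 78.270, tolerance = 1e-12)
  # 45.650 / 78.270 = 58% of intraspecific variation unexplained
  expect_equal(round(s$pct_unexplained[["intraspecific"]]), 58)
  expect_equal(round(s$pct_unexplained[["turnover"]]), 67)

  ss2 <- as_ss_table(turnover = c(499.300, 299.700),
                     intraspecific = c(14.580, 15.670),
                     total = c(631.600, 305.900),
                     df_between = 3, df_within = 41)
  expect_equal(summarize_components(ss2)$turnover_itv_ratio,
               799.000 / 30.250, tolerance = 1e-12)
  expect_gt(summarize_components(ss2)$turnover_itv_ratio, 26)

  # zero residual row: everything explained
  ss3 <- as_ss_table(c(5, 0), c(2, 0), c(8, 0), 2, 9)
  expect_equal(unname(summarize_components(ss3)$pct_unexplained),
               c(0, 0, 0))
  # zero intraspecific total: ratio undefined, flagged as NA not an error
  ss4 <- as_ss_table(c(5, 5), c(0, 0), c(5, 5), 2, 9)
  expect_true(is.na(summarize_components(ss4)$turnover_itv_ratio))
})

test_that("ss tables export and re-import losslessly", {
  ds <- generate_dataset(small_config(seed = 2))
  ss <- decompose_synthetic(ds)
  f <- tempfile(fileext = ".csv")
  write_ss_table(ss, f)
  back <- read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
  expect_equal(back$row, c("belt", "residual", "total"))
  expect_equal(back$turnover, unname(ss[, "turnover"]))
  expect_equal(back$covariation, unname(ss[, "covariation"]))
})
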