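test_that("study designs validate belts and plot assignments", {
  d <- tiny_design()
  expect_equal(belt_levels(d), c("B1", "B2"))
  expect_equal(belt_of(d, c("P3", "P1")), c("B2", "B1"))

  # belts reordered by lower elevation bound
  d2 <- study_design(
    data.frame(belt = c("high", "low"), lower = c(2000, 1000),
               upper = c(2250, 1250)),
    data.frame(plot = c("a", "b"), belt = c("low", "high")))
  expect_equal(belt_levels(d2), c("low", "high"))

  expect_error(study_design(c("B1", "B1"),
                            data.frame(plot = "P1", belt = "B1")),
               "unique")
  expect_error(study_design("B1", data.frame(plot = "P1", belt = "B9")),
               "unknown belt")
  expect_error(study_design("B1", data.frame(plot = c("P1", "P1"),
                                             belt = c("B1", "B1"))),
               "unique")
})

test_that("long and wide cover tables parse, with row-level error reporting", {
  d <- tiny_design()
  long <- tempfile(fileext = ".csv")
  writeLines(c("plot,species,cover",
               "P1,A,60", "P1,B,40",
               "P2,A,50", "P2,B,50",
               "P3,A,30", "P3,B,70",
               "P4,A,20", "P4,B,80"), long)
  cm <- read_cover_table(long, "long", d)
  expect_s3_class(cm, "cover_matrix")
  expect_equal(dim(cm$cover), c(4L, 2L))
  expect_equal(cm$cover["P1", c("A", "B")], c(A = 60, B = 40))

  # wide layout; row totals differ from 100 and that is fine (covers are
  # relative weights)
  wide <- tempfile(fileext = ".csv")
  writeLines(c("plot,A,B,C",
               "P1,60,30,10", "P2,4,4,2", "P3,1,5,4", "P4,0,7,3"), wide)
  cw <- read_cover_table(wide, "wide", d)
  expect_equal(unname(rowSums(cw$cover)), c(100, 10, 10, 10))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("plot,species,cover", "P1,A,60", "P2,A,-5", "P3,A,1",
               "P4,A,1"), bad)
  expect_error(read_cover_table(bad, "long", d), "row 2.*P2")

  unk <- tempfile(fileext = ".csv")
  writeLines(c("plot,species,cover", "P9,A,60"), unk)
  expect_error(read_cover_table(unk, "long", d), "unknown plot 'P9'")
})

test_that("trait tables pool individuals for the fixed mean", {
  d <- tiny_design()
  # species X measured in 2 belts with equal n: fixed mean is plain average
  tm <- trait_measurements(data.frame(
    species = "X", belt = c("B1", "B1", "B2", "B2"), trait = "H",
    value = c(10, 20, 30, 40)), d)
  tt <- build_trait_table(tm, "H")
  expect_equal(unname(tt$specific["X", ]), c(15, 35))
  expect_equal(unname(tt$fixed["X"]), 25)

  # unequal n: pooled over the 3 individuals (oracle: (10+20+30)/3 = 20),
  # not the 22.5 the equal-belt-weight average would give
  tm2 <- trait_measurements(data.frame(
    species = "X", belt = c("B1", "B1", "B2"), trait = "H",
    value = c(10, 20, 30)), d)
  tt2 <- build_trait_table(tm2, "H")
  expect_equal(unname(tt2$fixed["X"]), 20)
  tt2b <- build_trait_table(tm2, "H", fixed_method = "belt_equal")
  expect_equal(unname(tt2b$fixed["X"]), 22.5)
  expect_equal(unname(tt2$n["X", ]), c(2, 1))

  # log10 is applied to individuals before averaging
  tm3 <- trait_measurements(data.frame(
    species = "X", belt = c("B1", "B1", "B2", "B2"), trait = "SLA",
    value = c(10, 100, 10, 1000)), d)
  tt3 <- build_trait_table(tm3, "SLA", transform = "log10")
  expect_equal(unname(tt3$specific["X", "B1"]), 1.5)
  expect_equal(unname(tt3$fixed["X"]), mean(log10(c(10, 100, 10, 1000))))

  expect_error(trait_measurements(data.frame(
    species = "X", belt = "B1", trait = "H", value = -1), d),
    "strictly positive")
})

test_that("log10 trait means are geometric means of the raw values", {
  set.seed(42)
  d <- tiny_design()
  vals <- exp(rnorm(40, 2, 0.5))
  tm <- trait_measurements(data.frame(
    species = rep(c("A", "B"), each = 20),
    belt = rep(rep(c("B1", "B2"), each = 10), 2),
    trait = "H", value = vals), d)
  tt <- build_trait_table(tm, "H", transform = "log10")
  geo <- function(x) exp(mean(log(x)))
  for (sp in c("A", "B")) for (b in c("B1", "B2")) {
    raw <- tm$value[tm$species == sp & tm$belt == b]
    expect_equal(10^tt$specific[sp, b], geo(raw), tolerance = 1e-12)
  }
  # fixed mean within the range of the belt means
  expect_true(all(tt$fixed >= apply(tt$specific, 1, min) - 1e-12))
  expect_true(all(tt$fixed <= apply(tt$specific, 1, max) + 1e-12))
})

test_that("dominant species follow the cumulative 80% rule", {
  d <- study_design("B1", data.frame(plot = "P1", belt = "B1"))
  cm <- function(v) cover_matrix(
    matrix(v, 1, dimnames = list("P1", LETTERS[seq_along(v)])), d)

  expect_equal(select_dominant_species(cm(c(50, 20, 15, 10, 5)), "B1"),
               c("A", "B", "C"))
  # boundary: exactly 80% meets the threshold
  expect_equal(select_dominant_species(cm(c(80, 20)), "B1"), "A")
  # tie broken by species identifier
  expect_equal(select_dominant_species(cm(c(40, 40, 20)), "B1"),
               c("A", "B"))
  # invariant to uniform rescaling of covers
  expect_equal(select_dominant_species(cm(c(50, 20, 15, 10, 5) * 7), "B1"),
               c("A", "B", "C"))
  expect_error(select_dominant_species(cm(c(80, 20)), "B9"), "unknown belt")
  expect_error(select_dominant_species(cm(c(80, 20)), "B1", threshold = 0),
               "threshold")
})

test_that("restriction renormalizes plot weights to one", {
  cov <- tiny_cover()
  r <- restrict_and_renormalize(cov, c("A", "B"))
  expect_equal(unname(r$cover["P1", ]), c(2 / 3, 1 / 3))
  expect_equal(unname(rowSums(r$cover)), rep(1, 4), tolerance = 1e-12)

  # restriction to everything: weights proportional to original covers
  r_all <- restrict_and_renormalize(cov, c("A", "B", "C"))
  expect_equal(r_all$cover["P2", ], cov$cover["P2", ] / 100, tolerance = 1e-12)

  # single-species plots collapse to weight 1
  r_one <- restrict_and_renormalize(cov, "B")
  expect_equal(unname(r_one$cover[, "B"]), rep(1, 4))

  # P4 has no A cover, so restricting to {A} must fail naming the plot
  expect_error(restrict_and_renormalize(cov, "A"), "P4")

  # belt-specific measured sets
  r_belt <- restrict_and_renormalize(
    cov, list(B1 = c("A", "B"), B2 = c("B", "C")))
  expect_equal(unname(r_belt$cover["P1", c("A", "B", "C")]),
               c(2 / 3, 1 / 3, 0))
  expect_equal(unname(r_belt$cover["P3", c("A", "B", "C")]),
               c(0, 5 / 9, 4 / 9))
  expect_equal(unname(rowSums(r_belt$cover)), rep(1, 4), tolerance = 1e-12)
})
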