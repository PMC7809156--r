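library(tibble)

test_that("dataset summaries compute n/mean/sd and respect the case table", {
  geo <- tibble(dataset = rep(c("A1", "A2"), c(3, 1)),
                type = "neurite",
                mean_curvature = c(0.2, 0.4, 0.6, 0.5))
  cases <- tibble(dataset = c("A1", "A2"), case = c("S1", "S2"),
                  group = c("schizophrenia", "control"),
                  area = c("BA22", "BA22"))
  s <- dataset_summary(geo, cases, mean_curvature)
  expect_equal(s$mean[s$dataset == "A1"], 0.4)
  expect_equal(s$sd[s$dataset == "A1"], 0.2)
  expect_equal(s$n, c(3L, 1L))
  expect_true(is.na(s$sd[s$dataset == "A2"]))

  shuffled <- geo[c(3, 1, 4, 2), ]
  expect_identical(dataset_summary(shuffled, cases, mean_curvature), s)

  geo_bad <- dplyr::mutate(geo, dataset = sub("A2", "ZZ", dataset))
  expect_error(dataset_summary(geo_bad, cases, mean_curvature), "ZZ")
})

test_that("Welch ANOVA reduces to the Welch t-test for two groups", {
  d <- withr::with_seed(31, tibble(
    v = c(rnorm(8, 0, 1), rnorm(12, 0.8, 2.5)),
    g = rep(c("a", "b"), c(8, 12))))
  w <- welch_anova(d, v, g)
  tt <- t.test(v ~ g, data = d)
  expect_equal(w$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(w$p, tt$p.value, tolerance = 1e-12)
  expect_equal(w$df2, unname(tt$parameter), tolerance = 1e-12)
})

test_that("Welch ANOVA matches the textbook formula on a fixed fixture", {
  d <- withr::with_seed(77, tibble(
    v = c(rnorm(5, 0, 1), rnorm(5, 0.5, 2), rnorm(5, -0.3, 0.5)),
    g = rep(c("a", "b", "c"), each = 5)))
  w <- welch_anova(d, v, g)
  o <- oracle_welch(d$v, d$g)
  expect_equal(w$statistic, o$statistic, tolerance = 1e-8)
  expect_equal(w$df2, o$df2, tolerance = 1e-8)
  expect_equal(w$p, o$p, tolerance = 1e-8)

  same <- tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  w0 <- welch_anova(same, v, g)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p, 1)

  expect_error(welch_anova(tibble(v = c(1, 1, 2, 3), g = c("a", "a", "b", "b")),
                           v, g), "zero-variance")
  expect_error(welch_anova(tibble(v = 1:3, g = "a"), v, g), ">= 2")
})

test_that("two-way ANOVA matches a sums-of-squares oracle and checks balance", {
  cm <- withr::with_seed(5, tibble(
    case = rep(sprintf("C%d", 1:8), each = 2),
    group = rep(c("schizophrenia", "control"), each = 8),
    area = rep(c("BA22", "BA24"), 8),
    mean = rnorm(16, 0.5, 0.1)))
  tw <- two_way_anova(cm)
  o <- oracle_twoway(cm$mean, cm$group, cm$area)
  expect_equal(tw$terms$statistic[tw$terms$term == "group"], o$F_a,
               tolerance = 1e-8)
  expect_equal(tw$terms$statistic[tw$terms$term == "area"], o$F_b,
               tolerance = 1e-8)
  expect_equal(tw$terms$statistic[tw$terms$term == "group:area"], o$F_ab,
               tolerance = 1e-8)
  expect_equal(tw$residual_df, 12)
  expect_equal(two_way_anova(cm, interaction = FALSE)$residual_df, 13)

  # permuting case labels within groups leaves every F unchanged
  cm2 <- cm
  cm2$case <- rep(sprintf("C%d", c(2, 1, 4, 3, 6, 5, 8, 7)), each = 2)
  expect_equal(two_way_anova(cm2)$terms$statistic, tw$terms$statistic)

  expect_error(two_way_anova(cm[-1, ]), "unbalanced")
})

test_that("Bartlett's test matches its formula and degenerates to p = 1", {
  d <- withr::with_seed(41, tibble(
    v = c(rnorm(10, 0, 1), rnorm(10, 0, 3), rnorm(10, 0, 0.5)),
    g = rep(c("a", "b", "c"), each = 10)))
  b <- bartlett_test(d, v, g)
  o <- oracle_bartlett(d$v, d$g)
  expect_equal(b$statistic, o$statistic, tolerance = 1e-8)
  expect_equal(b$p, o$p, tolerance = 1e-8)
  expect_equal(b$df1, 2)

  same <- tibble(v = rep(c(1, 2, 4), 2), g = rep(c("a", "b"), each = 3))
  b0 <- bartlett_test(same, v, g)
  expect_equal(b0$statistic, 0, tolerance = 1e-12)
  expect_equal(b0$p, 1)
})

test_that("KS + Holm reproduces the hand-computed step-down adjustment", {
  expect_equal(oracle_holm(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "holm"), c(0.03, 0.04, 0.04))

  d <- withr::with_seed(51, tibble(
    case = rep(sprintf("C%d", 1:4), each = 400),
    area = rep(rep(c("BA22", "BA24"), each = 200), 4),
    v = c(rnorm(200), rnorm(200, 2),        # strong shift
          rnorm(200), rnorm(200, 0.3),      # weak shift
          rnorm(400),                       # null
          rnorm(200), rnorm(200, 1))))      # medium shift
  ks <- ks_holm(d, v, case, area)
  expect_equal(nrow(ks), 4)
  expect_true(all(ks$p.adjusted >= ks$p.value))
  expect_true(all(diff(ks$p.adjusted[order(ks$p.value)]) >= -1e-15))
  expect_equal(ks$p.adjusted, oracle_holm(ks$p.value), tolerance = 1e-12)
  # per-pair D and asymptotic p match the direct oracle
  for (nm in unique(d$case)) {
    a <- d$v[d$case == nm & d$area == "BA22"]
    b <- d$v[d$case == nm & d$area == "BA24"]
    o <- oracle_ks(a, b)
    row <- ks[ks$name == nm, ]
    expect_equal(row$statistic, o$D, tolerance = 1e-12)
    expect_equal(row$p.value, o$p, tolerance = 1e-8)
  }
  expect_equal(ks$stars[ks$name == "C1"], "****")

  same <- tibble(case = "C1", area = rep(c("BA22", "BA24"), each = 5),
                 v = rep(1:5, 2))
  ks0 <- ks_holm(same, v, case, area)
  expect_equal(ks0$statistic, 0)
  expect_equal(ks0$p.value, 1)
})

test_that("quartile summaries use linear interpolation", {
  q <- quartile_summary(1:5)
  expect_equal(unlist(q), c(q1 = 2, median = 3, q3 = 4))
  expect_equal(unlist(quartile_summary(rep(7, 10))),
               c(q1 = 7, median = 7, q3 = 7))
  x <- withr::with_seed(61, runif(101))
  s <- sort(x)
  expect_equal(quartile_summary(x)$median, s[51])
  expect_equal(quartile_summary(x)$q1, s[26])  # h = (n-1)p + 1 = 26 exactly
  expect_equal(quartile_summary(x)$q3, s[76])
})

test_that("radius correlation and curvature-radius fit recover structure", {
  d <- tibble(neurite_radius = seq(0.2, 0.6, length.out = 8),
              spine_radius = 0.5 * seq(0.2, 0.6, length.out = 8))
  rc <- radius_correlation(d)
  expect_equal(rc$pearson_r, 1)
  expect_equal(rc$slope, 0.5, tolerance = 1e-12)

  # kappa = 0.2 / r exactly
  d2 <- tibble(mean_radius = seq(0.1, 1, length.out = 10),
               mean_curvature = 0.2 / seq(0.1, 1, length.out = 10))
  f <- curvature_radius_fit(d2)
  expect_equal(f$exponent, -1, tolerance = 1e-12)
  expect_equal(f$coefficient, 0.2, tolerance = 1e-12)

  # scaling r leaves the exponent unchanged
  d3 <- dplyr::mutate(d2, mean_radius = mean_radius * 2)
  expect_equal(curvature_radius_fit(d3)$exponent, -1, tolerance = 1e-12)

  expect_error(radius_correlation(d[1:2, ]), ">= 3")
  expect_error(curvature_radius_fit(dplyr::mutate(d2, mean_radius = -mean_radius)),
               "positive")
})

test_that("cohort parameter recovery: coupled slope and linked spine radii", {
  sp <- cohort_spec(seed = 19, coupling = TRUE, coupling_c = 0.2,
                    case_sd = 0.4, neurites_per_dataset = 2000L,
                    spines_per_dataset = 100L)
  ch <- generate_geometry_cohort(sp)
  kk <- case_area_means(ch$geometry, parameter = mean_curvature,
                        types = "neurite")
  rr <- case_area_means(ch$geometry, parameter = mean_radius,
                        types = "neurite")
  pts <- dplyr::inner_join(dplyr::rename(kk, mean_curvature = "mean"),
                           dplyr::rename(rr, mean_radius = "mean"),
                           by = c("case", "group", "area"))
  f <- curvature_radius_fit(pts)
  expect_equal(f$exponent, -1, tolerance = 0.02)

  # uncoupled cohort: spine radii track neurite radii across cells
  sp2 <- cohort_spec(seed = 23, case_sd = 0.3, neurites_per_dataset = 150L,
                     spines_per_dataset = 150L)
  ch2 <- generate_geometry_cohort(sp2)
  nr <- case_area_means(ch2$geometry, parameter = mean_radius,
                        types = "neurite")
  sr <- case_area_means(ch2$geometry, parameter = mean_radius,
                        types = "spine")
  both <- dplyr::inner_join(dplyr::rename(nr, neurite_radius = "mean"),
                            dplyr::rename(sr, spine_radius = "mean"),
                            by = c("case", "group", "area"))
  rc <- radius_correlation(both)
  expect_gt(rc$pearson_r, 0.8)
  expect_equal(rc$slope, cohort_spec()$spine_radius_ratio, tolerance = 0.2)
})

test_that("stat results tidy into one-row tibbles with stars", {
  d <- withr::with_seed(71, tibble(v = rnorm(40), g = rep(letters[1:4], 10)))
  td <- tidy(welch_anova(d, v, g))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("statistic", "df1", "df2", "p.value", "stars") %in%
                    names(td)))
  expect_equal(significance_stars(c(1e-9, 1e-5, 1e-3, 0.03, 0.5)),
               c("****", "***", "**", "*", "ns"))
})
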