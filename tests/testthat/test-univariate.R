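test_that("collapse models produce the published 2x2 cells", {
  tab <- count_panel("SULT1A1_Arg213His", "UADT_inside")
  dom <- collapse_genotypes(tab, "dominant")
  expect_equal(unclass(dom)[c("a", "b", "c", "d")],
               c(a = 49L, b = 60L, c = 62L, d = 132L),
               ignore_attr = TRUE)
  ext <- collapse_genotypes(tab, "extreme")
  expect_equal(unclass(ext)[c("a", "b", "c", "d")],
               c(a = 6L, b = 60L, c = 2L, d = 132L),
               ignore_attr = TRUE)
  het <- collapse_genotypes(tab, "heterozygous")
  # dominant exposed cells are the sum of heterozygous and extreme exposed
  expect_equal(dom[["a"]], het[["a"]] + ext[["a"]])
  expect_equal(dom[["c"]], het[["c"]] + ext[["c"]])
  # zero variant homozygotes stay zero, no correction at collapse stage
  tab0 <- genotype_count_table(c(10, 5, 0), c(8, 4, 0))
  expect_equal(collapse_genotypes(tab0, "extreme")[["a"]], 0L)
})

test_that("crude odds ratio matches the published point estimates", {
  r_dom <- crude_odds_ratio(two_by_two(49, 60, 62, 132))
  expect_equal(round(r_dom$or, 2), 1.74)
  r_ext <- crude_odds_ratio(two_by_two(6, 60, 2, 132))
  expect_equal(round(r_ext$or, 1), 6.6)
  expect_true(r_ext$ci_low <= r_ext$or && r_ext$or <= r_ext$ci_high)
})

test_that("balanced table gives OR 1 with a log-symmetric interval", {
  r <- crude_odds_ratio(two_by_two(10, 10, 10, 10))
  expect_equal(r$or, 1)
  expect_equal(log(r$ci_high), -log(r$ci_low), tolerance = 1e-12)
})

test_that("relabelling exposure inverts the odds ratio", {
  set.seed(11)
  for (i in 1:25) {
    t <- rpois(4, 12) + 1L
    r1 <- crude_odds_ratio(two_by_two(t[1], t[2], t[3], t[4]))
    r2 <- crude_odds_ratio(two_by_two(t[2], t[1], t[4], t[3]))
    expect_equal(r1$or * r2$or, 1, tolerance = 1e-12)
  }
})

test_that("zero-cell policy: 0/Inf by default, Haldane on demand", {
  # frozen hand computation: (0.5 * 132.5) / (60.5 * 2.5)
  r_h <- crude_odds_ratio(two_by_two(0, 60, 2, 132), "haldane")
  expect_equal(r_h$or, 0.4380165289, tolerance = 1e-09)
  expect_true(r_h$method$corrected)

  r0 <- crude_odds_ratio(two_by_two(0, 60, 2, 132))
  expect_equal(r0$or, 0)
  expect_equal(r0$ci_low, 0)
  expect_true(is.finite(r0$ci_high) && r0$ci_high > 0)
  expect_false(r0$method$corrected)

  r_inf <- crude_odds_ratio(two_by_two(5, 0, 2, 132))
  expect_equal(r_inf$or, Inf)
  expect_true(is.finite(r_inf$ci_low))

  expect_error(crude_odds_ratio(two_by_two(0, 5, 3, 0)), "diagonal")
})

test_that("Fisher exact p matches the published value and stats::fisher.test", {
  p <- fisher_exact_p(two_by_two(6, 60, 2, 132))
  expect_equal(p, 0.0166925698, tolerance = 1e-08)  # frozen cross-check
  expect_lt(abs(p - 0.017), 0.005)                  # printed value
  # identical case/control odds
  expect_gte(fisher_exact_p(two_by_two(10, 10, 10, 10)), 0.99)
  # mid-P is smaller by half the point probability
  expect_lt(fisher_exact_p(two_by_two(6, 60, 2, 132), midp = TRUE), p)
})

test_that("Fisher exact p equals full enumeration on random small tables", {
  set.seed(13)
  for (i in 1:50) {
    t <- rpois(4, 3)
    expect_equal(fisher_exact_p(two_by_two(t[1], t[2], t[3], t[4])),
                 fisher_enum_oracle(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
  }
})

test_that("logistic model without covariates reproduces the crude OR", {
  ds <- count_fixture("SULT1A1_Arg213His", "UADT_inside")
  adj <- adjusted_odds_ratio(ds, "SULT1A1_Arg213His", "dominant",
                             covariates = character(0))
  crude <- crude_odds_ratio(
    collapse_genotypes(tabulate_genotypes(ds, "SULT1A1_Arg213His"), "dominant")
  )
  expect_equal(adj$or, crude$or, tolerance = 1e-06)
})

test_that("adjusted OR recovers a known conditional effect and ignores constants", {
  set.seed(11)
  n <- 2000
  g <- simulate_genotypes_hwe(n, 0.3)
  carrier <- as.integer(g > 0)
  age <- round(rnorm(n, 50, 10))
  gender <- rbinom(n, 1, 0.5)
  lp <- -2 + log(2) * carrier + 0.02 * (age - 50) + 0.3 * gender
  status <- rbinom(n, 1, plogis(lp))
  ds <- genotype_dataset(matrix(g, ncol = 1, dimnames = list(NULL, "G")),
                         status = status,
                         covariates = data.frame(age = age, gender = gender))
  adj <- adjusted_odds_ratio(ds, "G", "dominant")
  expect_true(adj$method$converged)
  expect_equal(adj$or, 2, tolerance = 0.125)  # within +/- 0.25

  # a constant covariate must not move the estimate
  ds$covariates$const <- 1
  adj2 <- adjusted_odds_ratio(ds, "G", "dominant",
                              covariates = c("age", "gender", "const"))
  expect_equal(adj2$or, adj$or, tolerance = 1e-06)
})

test_that("separated data is flagged instead of reported", {
  v <- matrix(c(rep(1L, 20), rep(0L, 20)), ncol = 1,
              dimnames = list(NULL, "G"))
  ds <- genotype_dataset(v, status = c(rep(1L, 20), rep(0L, 20)))
  adj <- adjusted_odds_ratio(ds, "G", "dominant", covariates = character(0))
  expect_false(adj$method$converged)
  expect_true(is.na(adj$or))
})

test_that("univariate scan covers every SNP x group x model with Bonferroni column", {
  ds <- count_fixture(group = "UADT_inside")
  scan <- univariate_scan(ds)
  expect_equal(nrow(scan), 7L * 3L)
  expect_true(all(scan$p_bonferroni >= scan$p_value))
  expect_true(all(scan$p_bonferroni <= 1))
  row <- scan[scan$factor == "SULT1A1_Arg213His" & scan$model == "dominant", ]
  expect_equal(round(row$or, 2), 1.74)
})

test_that("tabulation is invariant under subject permutation", {
  ds <- xor_cohort(n_snps = 3, n_cases = 30, n_controls = 30, seed = 5)
  tab1 <- tabulate_genotypes(ds, "SNP1")
  set.seed(1)
  ds2 <- availmdr:::ds_rows(ds, sample(length(ds$subjects)))
  tab2 <- tabulate_genotypes(ds2, "SNP1")
  expect_equal(unclass(tab1), unclass(tab2), ignore_attr = TRUE)
})
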