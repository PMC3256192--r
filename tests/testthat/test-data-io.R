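test_that("TSV reader builds a validated dataset and maps missing codes", {
  path <- write_tsv_fixture(c(
    "sample_id\tstatus\tSNP1\tSNP2",
    "s1\t1\t0\t2",
    "s2\t0\t1\tNA",
    "s3\t0\t2\t0"
  ))
  ds <- read_genotypes_tsv(path)
  expect_s3_class(ds, "genotype_dataset")
  expect_equal(length(ds$subjects), 3L)
  expect_equal(sum(is.na(ds$values)), 1L)
  expect_equal(ds$values[, "SNP1"], c(0L, 1L, 2L))
  expect_equal(vapply(ds$factors, `[[`, character(1), "kind"),
               c("snp", "snp"))
})

test_that("TSV reader rejects bad status codes and malformed rows", {
  bad_status <- write_tsv_fixture(c(
    "sample_id\tstatus\tSNP1", "s1\t2\t0"
  ))
  expect_error(read_genotypes_tsv(bad_status), "status.*0/1")

  ragged <- write_tsv_fixture(c(
    "sample_id\tstatus\tSNP1\tSNP2", "s1\t1\t0\t1", "s2\t0\t1"
  ))
  expect_error(read_genotypes_tsv(ragged), "parse error")

  undeclared <- write_tsv_fixture(c(
    "sample_id\tstatus\tSNP1", "s1\t1\t7", "s2\t0\t0"
  ))
  decl <- list(factor_definition("SNP1", "snp"))
  expect_error(read_genotypes_tsv(undeclared, factors = decl),
               "undeclared category")
})

test_that("write then read is the identity on a simulated dataset", {
  cfg <- simulation_config(
    25, 25, snps = c(SNP1 = 0.3, SNP2 = 0.2), habit = c(0.2, 0.6, 0.2),
    penetrance = penetrance_model("SNP1", c(0.1, 0.15, 0.2)),
    missing_rate = 0.05, covariates = TRUE
  )
  ds <- simulate_case_control(cfg, seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_genotypes_tsv(ds, path)
  back <- read_genotypes_tsv(path)
  expect_identical(back$subjects, ds$subjects)
  expect_identical(back$status, ds$status)
  expect_identical(back$group, ds$group)
  expect_identical(back$values, ds$values)
  expect_equal(back$covariates$age, ds$covariates$age)
  expect_equal(back$covariates$gender, ds$covariates$gender)
  # habit inferred as snp-coded 0/1/2 is acceptable for values; levels match
  expect_identical(colnames(back$values), colnames(ds$values))
})

test_that("PED/MAP recoding counts the minor allele and handles missing", {
  map <- tempfile(fileext = ".map")
  writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t200"), map)
  ped <- tempfile(fileext = ".ped")
  writeLines(c(
    "f1 i1 0 0 1 2 A A C C",
    "f2 i2 0 0 1 1 A G C T",
    "f3 i3 0 0 2 1 G G 0 0",
    "f4 i4 0 0 1 2 A A C T"
  ), ped)
  ds <- read_ped_map(ped, map)
  # rs1: G is minor (3 of 8 alleles) -> A A=0, A G=1, G G=2
  expect_equal(ds$values[, "rs1"], c(0L, 1L, 2L, 0L))
  # rs2: T is minor; "0 0" missing
  expect_equal(ds$values[, "rs2"], c(0L, 1L, NA, 1L))
  expect_equal(ds$status, c(1L, 0L, 0L, 1L))
})

test_that("PED with a 3-allele locus raises a format error", {
  map <- tempfile(fileext = ".map"); writeLines("1\trs1\t0\t100", map)
  ped <- tempfile(fileext = ".ped")
  writeLines(c("f1 i1 0 0 1 2 A C", "f2 i2 0 0 1 1 G G"), ped)
  expect_error(read_ped_map(ped, map), "biallelic")
})

test_that("PED minor-allele tie goes to the lexicographically smaller allele", {
  map <- tempfile(fileext = ".map"); writeLines("1\trs1\t0\t100", map)
  ped <- tempfile(fileext = ".ped")
  writeLines(c("f1 i1 0 0 1 2 A G", "f2 i2 0 0 1 1 G A"), ped)
  ds <- read_ped_map(ped, map)
  # A and G equally frequent -> A is the variant; "A G" carries one copy
  expect_equal(ds$values[, "rs1"], c(1L, 1L))
})

test_that("high-missingness exclusion respects the more-than-5 boundary", {
  v <- matrix(0L, 3, 21, dimnames = list(NULL, paste0("S", 1:21)))
  v[1, 1:6] <- NA  # 6 missing -> excluded
  v[2, 1:5] <- NA  # exactly 5 -> retained
  ds <- genotype_dataset(v, status = c(1L, 1L, 0L),
                         subjects = c("drop", "keep5", "full"))
  res <- exclude_high_missing(ds, max_missing = 5)
  expect_identical(res$report$excluded, "drop")
  expect_identical(res$dataset$subjects, c("keep5", "full"))
  expect_equal(unname(res$report$per_subject), c(6, 5, 0))

  # idempotent
  res2 <- exclude_high_missing(res$dataset, max_missing = 5)
  expect_identical(res2$dataset$subjects, res$dataset$subjects)
  expect_length(res2$report$excluded, 0)

  # identity on complete data
  full <- genotype_dataset(matrix(0L, 2, 3), status = c(1L, 0L))
  res3 <- exclude_high_missing(full)
  expect_identical(res3$dataset$values, full$values)
  expect_length(res3$report$excluded, 0)
})

test_that("from_marginal_counts reproduces its input marginals exactly", {
  panel <- genotype_count_table(c(132, 60, 2), c(60, 43, 6),
                                snp = "SULT1A1_Arg213His")
  ds <- from_marginal_counts(panel, case_group = "UADT_inside")
  expect_equal(sum(ds$status == 0L), 194L)
  expect_equal(sum(ds$status == 1L), 109L)
  tab <- tabulate_genotypes(ds, "SULT1A1_Arg213His", "UADT_inside")
  expect_equal(unname(tab[, "control"]), c(132L, 60L, 2L))
  expect_equal(unname(tab[, "case"]), c(60L, 43L, 6L))

  empty <- from_marginal_counts(genotype_count_table(c(0, 0, 0), c(0, 0, 0)))
  expect_equal(length(empty$subjects), 0L)

  expect_error(
    from_marginal_counts(structure(cbind(control = c(-1L, 0L, 0L),
                                         case = c(0L, 0L, 0L)),
                                   class = c("genotype_count_table", "matrix"))),
    "negative"
  )
})

test_that("tabulation of random marginal reconstructions round-trips", {
  set.seed(7)
  for (i in 1:100) {
    ctrl <- rpois(3, 20)
    cas <- rpois(3, 15)
    panel <- genotype_count_table(ctrl, cas, snp = "X")
    ds <- from_marginal_counts(panel)
    tab <- tabulate_genotypes(ds, "X")
    expect_equal(unname(tab[, "control"]), as.integer(ctrl))
    expect_equal(unname(tab[, "case"]), as.integer(cas))
  }
})

test_that("multi-SNP reconstruction with unequal totals fills independently", {
  p1 <- genotype_count_table(c(10, 5, 1), c(8, 4, 2), snp = "A")
  p2 <- genotype_count_table(c(9, 4, 1), c(7, 3, 1), snp = "B")
  ds <- from_marginal_counts(list(p1, p2))
  expect_equal(length(ds$subjects), 16L + 14L)
  # B has 2 fewer genotyped controls and 3 fewer genotyped cases
  expect_equal(sum(is.na(ds$values[, "B"])), 5L)
  tb <- tabulate_genotypes(ds, "B")
  expect_equal(unname(tb[, "control"]), c(9L, 4L, 1L))
  expect_equal(unname(tb[, "case"]), c(7L, 3L, 1L))
})

test_that("dataset validation catches structural violations", {
  expect_error(genotype_dataset(matrix(0L, 2, 1), status = c(1L, 2L)),
               "status")
  expect_error(genotype_dataset(matrix(5L, 2, 1,
                                       dimnames = list(NULL, "A")),
                                status = c(1L, 0L),
                                factors = list(factor_definition("A", "snp"))),
               "undeclared")
  expect_error(factor_definition("A", "snp", levels = 0:3), "exactly 3")
  expect_error(factor_definition("A", "snp", missing_code = "2"),
               "missing_code")
})
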