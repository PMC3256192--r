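test_that("available-case subsets depend only on the model's own factors", {
  ds <- toy_dataset()
  # subject s4 misses A only: excluded from models containing A,
  # included for B+C
  expect_false("s4" %in% names(available_cases(ds, c("A", "B"))))
  expect_true("s4" %in% names(available_cases(ds, c("B", "C"))))
  # s3 misses B only
  expect_false("s3" %in% names(available_cases(ds, c("B", "C"))))
  # complete data: every combination uses everyone
  full <- genotype_dataset(matrix(0L, 4, 2, dimnames = list(NULL, c("A", "B"))),
                           status = c(1L, 1L, 0L, 0L))
  expect_length(available_cases(full, c("A", "B")), 4L)
  expect_error(available_cases(ds, character(0)), "non-empty")
  expect_error(available_cases(ds, "nope"), "unknown factor")
})

test_that("cell tables conserve counts and reduce to univariate margins", {
  ds <- xor_cohort(n_snps = 2, n_cases = 10, n_controls = 10, seed = 2)
  cells <- tabulate_cells(ds, c("SNP1", "SNP2"))
  expect_equal(nrow(cells), 9L)
  expect_equal(sum(cells$n_case) + sum(cells$n_control), 20L)
  expect_equal(attr(cells, "n_available"), 20L)

  one <- tabulate_cells(ds, "SNP1")
  tab <- tabulate_genotypes(ds, "SNP1")
  expect_equal(one$n_control, unname(tab[, "control"]))
  expect_equal(one$n_case, unname(tab[, "case"]))
})

test_that("permuting the factor order permutes cell keys isomorphically", {
  ds <- xor_cohort(n_snps = 3, n_cases = 25, n_controls = 25, seed = 8)
  ab <- tabulate_cells(ds, c("SNP1", "SNP2"))
  ba <- tabulate_cells(ds, c("SNP2", "SNP1"))
  m_ab <- ab[order(ab$SNP1, ab$SNP2), c("n_case", "n_control")]
  m_ba <- ba[order(ba$SNP1, ba$SNP2), c("n_case", "n_control")]
  expect_equal(unname(as.matrix(m_ab)), unname(as.matrix(m_ba)))
})

test_that("cell classification follows the threshold, tie and empty rules", {
  cells <- data.frame(SNP1 = c(0, 1, 2, 0), n_case = c(5L, 0L, 0L, 2L),
                      n_control = c(2L, 0L, 3L, 2L))
  lab <- classify_cells(cells, threshold = 1)$label
  expect_equal(lab, c("high", "empty", "low", "high"))  # tie (2:2 at T=1) -> high
  # exact-ratio tie with unbalanced threshold given as a count pair
  cells2 <- data.frame(x = 1, n_case = 3L, n_control = 7L)
  expect_equal(classify_cells(cells2, threshold = c(30L, 70L))$label, "high")
  expect_equal(classify_cells(cells2, threshold = c(31L, 70L))$label, "low")
})

test_that("fold assignment stratifies by status into consecutive blocks", {
  st <- c(rep(1L, 23), rep(0L, 37))
  f <- mdr_folds(st, 10)
  expect_equal(sort(unique(f)), 1:10)
  # stratification: case folds differ by at most one
  expect_lte(diff(range(table(f[st == 1L]))), 1)
  expect_lte(diff(range(table(f[st == 0L]))), 1)
  # partition of everyone
  expect_equal(sum(table(f)), 60)
  # few cases, many controls: no fold left empty
  st2 <- c(rep(1L, 3), rep(0L, 7))
  expect_equal(sort(unique(mdr_folds(st2, 10))), 1:10)
  expect_error(mdr_folds(rep(1L, 5), 10), "fewer subjects")
})

test_that("a perfectly separating factor scores accuracy 1 in train and test", {
  v <- matrix(c(rep(1L, 30), rep(0L, 30)), ncol = 1,
              dimnames = list(NULL, "G"))
  ds <- genotype_dataset(v, status = c(rep(1L, 30), rep(0L, 30)))
  cv <- evaluate_model_cv(ds, "G", folds = 10)
  expect_equal(cv$train_accuracy, rep(1, 10))
  expect_equal(cv$test_accuracy, rep(1, 10))
  expect_equal(cv$n_available, 60L)
})

test_that("training and test subject counts are conserved per fold", {
  ds <- xor_cohort(n_snps = 3, n_cases = 27, n_controls = 33, seed = 4,
                   missing_rate = 0.05)
  cv <- evaluate_model_cv(ds, c("SNP1", "SNP2"), folds = 10)
  expect_equal(length(cv$fold), cv$n_available)
  expect_equal(sum(table(cv$fold)), cv$n_available)
})

test_that("exhaustive search matches the naive brute-force oracle", {
  ds <- xor_cohort(n_snps = 5, n_cases = 30, n_controls = 30, seed = 5,
                   missing_rate = 0.08)
  res <- exhaustive_search(ds, 1, 3, folds = 10)
  orc <- oracle_mdr_search(ds, 1, 3, folds = 10)
  for (k in 1:3) {
    kk <- as.character(k)
    got <- res$models[res$models$k == k, ]
    got <- got[match(orc[[kk]]$combination, got$combination), ]
    expect_equal(got$cvc, orc[[kk]]$cvc)
    expect_equal(got$train_accuracy, orc[[kk]]$train, tolerance = 1e-12)
    expect_equal(got$test_accuracy, orc[[kk]]$test, tolerance = 1e-12)
    expect_equal(res$winners[[kk]], orc[[kk]]$winners)
    # CVC conservation
    expect_equal(sum(got$cvc, na.rm = TRUE), 10L)
  }
})

test_that("high/low labelling maximizes training accuracy over all labelings", {
  # balanced data, T = 1: compare against enumeration of all 2^cells labelings
  ds <- xor_cohort(n_snps = 2, n_cases = 20, n_controls = 20, seed = 9)
  cells <- classify_cells(tabulate_cells(ds, c("SNP1", "SNP2")))
  acc_of <- function(high_mask) {
    (sum(cells$n_case[high_mask]) + sum(cells$n_control[!high_mask])) /
      (sum(cells$n_case) + sum(cells$n_control))
  }
  best <- 0
  for (code in 0:(2^nrow(cells) - 1)) {
    mask <- as.logical(bitwAnd(bitwShiftR(code, seq_len(nrow(cells)) - 1), 1))
    best <- max(best, acc_of(mask))
  }
  expect_equal(acc_of(cells$label == "high"), best, tolerance = 1e-12)
})

test_that("repeats reduce to a single search and are seed-reproducible", {
  ds <- xor_cohort(n_snps = 4, n_cases = 25, n_controls = 25, seed = 6)
  one <- repeat_with_shuffles(ds, 1, 2, folds = 10, repeats = 1, seed = 7)
  # repeat 1 shuffles with seed 8 = 7 + 1; reproduce by hand
  restore <- availmdr:::snapshot_rng(); on.exit(restore())
  set.seed(8)
  perm <- sample.int(50)
  direct <- exhaustive_search(availmdr:::ds_rows(ds, perm), 1, 2, folds = 10)
  expect_equal(one$summary$model, direct$best_per_k$combination)
  expect_equal(one$summary$mean_cvc, as.numeric(direct$best_per_k$cvc))
  expect_equal(one$summary$mean_test_accuracy, direct$best_per_k$test_accuracy)

  again <- repeat_with_shuffles(ds, 1, 2, folds = 10, repeats = 1, seed = 7)
  expect_identical(one, again)

  multi <- repeat_with_shuffles(ds, 1, 2, folds = 10, repeats = 3, seed = 7)
  expect_true(all(multi$summary$mean_cvc >= 0 & multi$summary$mean_cvc <= 10))
  expect_true(all(multi$summary$selected_count >= 1))
})

test_that("status permutation drives test accuracy to chance", {
  ds <- xor_cohort(n_snps = 6, n_cases = 100, n_controls = 100, seed = 10)
  accs <- c()
  restore <- availmdr:::snapshot_rng(); on.exit(restore())
  for (s in 1:5) {
    set.seed(100 + s)
    ds$status <- sample(ds$status)
    ds$group <- ifelse(ds$status == 1L, "case", "control")
    res <- exhaustive_search(ds, 1, 2, folds = 10)
    accs <- c(accs, res$best_per_k$test_accuracy)
  }
  expect_lt(abs(mean(accs) - 0.5), 0.08)
})
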