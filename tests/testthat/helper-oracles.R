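# Independent oracles and small fixture builders used across the suite.

# Two-sided Fisher p by full enumeration over all tables with the observed
# margins, probabilities from the direct combinatorial formula (choose),
# independent of dhyper.
fisher_enum_oracle <- function(a, b, c, d) {
  cases <- a + b; controls <- c + d; exposed <- a + c; n <- cases + controls
  if (cases == 0 || controls == 0 || exposed == 0 || b + d == 0) return(1)
  denom <- choose(n, exposed)
  support <- max(0, exposed - controls):min(cases, exposed)
  probs <- vapply(support, function(x) {
    choose(cases, x) * choose(controls, exposed - x) / denom
  }, numeric(1))
  pobs <- probs[support == a]
  min(1, sum(probs[probs <= pobs * (1 + 1e-07)]))
}

# Naive per-subject MDR cross-validation search: string-keyed cell tables,
# explicit loops over folds and subjects.  Shares only the fold assignment
# (mdr_folds) and the tie rules with the package implementation.
oracle_mdr_search <- function(ds, k_min, k_max, folds = 10) {
  nm <- colnames(ds$values)
  out <- list()
  for (k in k_min:k_max) {
    combos <- combn(nm, k, simplify = FALSE)
    nc <- length(combos)
    train_m <- matrix(NA_real_, nc, folds)
    test_m <- matrix(NA_real_, nc, folds)
    for (ci in seq_len(nc)) {
      combo <- combos[[ci]]
      vals <- ds$values[, combo, drop = FALSE]
      avail <- which(apply(vals, 1, function(r) !any(is.na(r))))
      if (length(avail) < folds) next
      st <- ds$status[avail]
      if (length(unique(st)) < 2) next
      fold <- availmdr::mdr_folds(st, folds)
      if (length(unique(fold)) < folds) next
      key <- apply(vals[avail, , drop = FALSE], 1, paste, collapse = ":")
      for (f in seq_len(folds)) {
        tr <- fold != f
        A <- sum(st[tr] == 1); B <- sum(st[tr] == 0)
        cells <- new.env()
        for (i in which(tr)) {
          kk <- key[i]
          cur <- get0(kk, cells, ifnotfound = c(0, 0))
          cur[st[i] + 1] <- cur[st[i] + 1] + 1  # [1]=controls, [2]=cases
          assign(kk, cur, cells)
        }
        label_of <- function(kk) {
          cur <- get0(kk, cells, ifnotfound = NULL)
          if (is.null(cur) || sum(cur) == 0) return("low")  # empty in training
          nca <- cur[2]; nco <- cur[1]
          if (nco == 0 && nca > 0) return("high")
          if (nca == 0 && nco > 0) return("low")
          if (nca * B >= nco * A) "high" else "low"
        }
        correct_tr <- 0
        for (i in which(tr)) {
          pred <- if (label_of(key[i]) == "high") 1 else 0
          if (pred == st[i]) correct_tr <- correct_tr + 1
        }
        correct_te <- 0
        for (i in which(!tr)) {
          pred <- if (label_of(key[i]) == "high") 1 else 0
          if (pred == st[i]) correct_te <- correct_te + 1
        }
        train_m[ci, f] <- correct_tr / sum(tr)
        test_m[ci, f] <- correct_te / sum(!tr)
      }
    }
    win <- integer(folds)
    for (f in seq_len(folds)) {
      ok <- !is.na(train_m[, f])
      cand <- which(ok & train_m[, f] == max(train_m[ok, f]))
      if (length(cand) > 1) {
        cand <- cand[test_m[cand, f] == max(test_m[cand, f])]
      }
      win[f] <- cand[1]
    }
    lab <- vapply(combos, paste, character(1), collapse = "+")
    out[[as.character(k)]] <- list(
      combination = lab,
      cvc = tabulate(win, nc),
      train = rowMeans(train_m),
      test = rowMeans(test_m),
      winners = lab[win]
    )
  }
  out
}

# Small deterministic dataset with a bit of missingness for contract tests.
toy_dataset <- function() {
  v <- matrix(c(0L, 1L, 2L, NA, 1L,
                1L, 0L, NA, 2L, 0L,
                0L, 0L, 1L, 1L, 2L), ncol = 3,
              dimnames = list(NULL, c("A", "B", "C")))
  genotype_dataset(v, status = c(1L, 1L, 0L, 0L, 1L),
                   subjects = paste0("s", 1:5))
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# All printed odds ratios of the published univariate table, keyed
# snp | group | model, with the significance stars as printed.
printed_univariate_ors <- function() {
  rows <- rbind(
    c("MPO_G463A", "UADT_inside", "heterozygous", "1.52", FALSE),
    c("MPO_G463A", "UADT_inside", "extreme", "1.81", FALSE),
    c("MPO_G463A", "UADT_inside", "dominant", "1.58", FALSE),  # published value rounds differently: cross-product gives 1.5748
    c("MPO_G463A", "UADT_outside", "heterozygous", "2.686", FALSE),
    c("MPO_G463A", "UADT_outside", "extreme", "8.06", TRUE),
    c("MPO_G463A", "UADT_outside", "dominant", "3.66", TRUE),
    c("SULT1A1_Arg213His", "UADT_inside", "heterozygous", "1.58", FALSE),
    c("SULT1A1_Arg213His", "UADT_inside", "extreme", "6.6", TRUE),
    c("SULT1A1_Arg213His", "UADT_inside", "dominant", "1.74", TRUE),
    c("SULT1A1_Arg213His", "UADT_outside", "heterozygous", "7.15", TRUE),
    c("SULT1A1_Arg213His", "UADT_outside", "extreme", "0", FALSE),
    c("SULT1A1_Arg213His", "UADT_outside", "dominant", "6.92", TRUE),
    c("mEH_Tyr113His", "UADT_inside", "heterozygous", "1.74", FALSE),
    c("mEH_Tyr113His", "UADT_inside", "extreme", "2.55", TRUE),
    c("mEH_Tyr113His", "UADT_inside", "dominant", "1.89", TRUE),
    c("mEH_Tyr113His", "UADT_outside", "heterozygous", "0.82", FALSE),
    c("mEH_Tyr113His", "UADT_outside", "extreme", "1.77", FALSE),
    c("mEH_Tyr113His", "UADT_outside", "dominant", "1.00", FALSE),
    c("hOGG1_Ser326Cys", "UADT_inside", "heterozygous", "1.91", TRUE),
    c("hOGG1_Ser326Cys", "UADT_inside", "extreme", "1.33", FALSE),
    c("hOGG1_Ser326Cys", "UADT_inside", "dominant", "1.81", TRUE),
    c("hOGG1_Ser326Cys", "UADT_outside", "heterozygous", "1.84", FALSE),
    c("hOGG1_Ser326Cys", "UADT_outside", "extreme", "3.49", FALSE),
    c("hOGG1_Ser326Cys", "UADT_outside", "dominant", "2.14", FALSE),
    c("XRCC1_Arg280His", "UADT_inside", "heterozygous", "1.78", FALSE),
    c("XRCC1_Arg280His", "UADT_inside", "extreme", "1.96", FALSE),
    c("XRCC1_Arg280His", "UADT_inside", "dominant", "1.80", TRUE),
    c("XRCC1_Arg280His", "UADT_outside", "heterozygous", "0.680", FALSE),
    c("XRCC1_Arg280His", "UADT_outside", "extreme", "2.804", FALSE),
    c("XRCC1_Arg280His", "UADT_outside", "dominant", "0.91", FALSE),
    c("BRCA2_Asn372His", "UADT_inside", "heterozygous", "1.93", TRUE),
    c("BRCA2_Asn372His", "UADT_inside", "extreme", "1.08", FALSE),
    c("BRCA2_Asn372His", "UADT_inside", "dominant", "1.65", FALSE),
    c("BRCA2_Asn372His", "UADT_outside", "heterozygous", "1.389", FALSE),
    c("BRCA2_Asn372His", "UADT_outside", "extreme", "1.851", FALSE),
    c("BRCA2_Asn372His", "UADT_outside", "dominant", "1.543", FALSE),
    c("CCND1_A870G", "UADT_inside", "heterozygous", "1.20", FALSE),
    c("CCND1_A870G", "UADT_inside", "extreme", "1.22", FALSE),
    c("CCND1_A870G", "UADT_inside", "dominant", "1.21", FALSE),
    c("CCND1_A870G", "UADT_outside", "heterozygous", "0.262", TRUE),
    c("CCND1_A870G", "UADT_outside", "extreme", "0.271", FALSE),
    c("CCND1_A870G", "UADT_outside", "dominant", "0.265", TRUE)
  )
  data.frame(snp = rows[, 1], group = rows[, 2], model = rows[, 3],
             or = rows[, 4], significant = as.logical(rows[, 5]),
             stringsAsFactors = FALSE)
}

xor_cohort <- function(n_snps = 12, n_cases = 200, n_controls = 200,
                       seed = 42, missing_rate = 0) {
  nm <- c("SNP1", "SNP2",
          if (n_snps > 2) paste0("N", seq_len(n_snps - 2)))
  cfg <- simulation_config(n_cases, n_controls,
                           snps = setNames(rep(0.5, n_snps), nm),
                           penetrance = xor_penetrance(),
                           missing_rate = missing_rate)
  simulate_case_control(cfg, seed = seed)
}
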