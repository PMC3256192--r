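#' Subjects with complete data for a factor combination
#'
#' The "Available" analysis uses, for every candidate interaction model, all
#' subjects with complete data on exactly the factors of that model, so
#' different combinations may use different subject subsets.
#'
#' @param ds A `genotype_dataset`.
#' @param combination Character vector of factor names.
#' @return Integer row indices of the available subjects, named by subject
#'   id, in the dataset's current order.
#' @export
available_cases <- function(ds, combination) {
  if (!length(combination)) stop("combination must be non-empty", call. = FALSE)
  j <- match(combination, colnames(ds$values))
  if (anyNA(j)) {
    stop(sprintf("unknown factor(s): %s",
                 paste(combination[is.na(j)], collapse = ", ")), call. = FALSE)
  }
  idx <- which(complete.cases(ds$values[, j, drop = FALSE]))
  names(idx) <- ds$subjects[idx]
  idx
}

#' Joint genotype-cell counts for a factor combination
#'
#' Tabulates cases and controls over the full Cartesian product of the
#' factors' levels (3^k cells for k SNPs, times the habit levels when the
#' exposure is included).
#'
#' @param ds A `genotype_dataset`.
#' @param combination Character vector of factor names.
#' @param subset Optional integer row indices (default:
#'   [available_cases()]).
#' @return A data.frame of class `cell_table`: one row per cell, the level
#'   code of each factor, `n_case` and `n_control`; attributes
#'   `combination` and `n_available`.
#' @export
tabulate_cells <- function(ds, combination, subset = NULL) {
  subset <- subset %||% available_cases(ds, combination)
  lv <- lapply(combination, function(f) ds_factor(ds, f)$levels)
  names(lv) <- combination
  grid <- expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(lv)), drop = FALSE]  # first factor varies slowest
  C <- nrow(grid)
  code <- vapply(seq_along(combination), function(k) {
    match(ds$values[subset, combination[k]], lv[[k]]) - 1L
  }, integer(length(subset)))
  if (length(subset) == 1L) code <- matrix(code, nrow = 1L)
  L <- lengths(lv)
  idx <- rep(0L, length(subset))
  for (k in seq_along(combination)) idx <- idx * L[k] + code[, k]
  st <- ds$status[subset]
  n_case <- tabulate(idx[st == 1L] + 1L, C)
  n_control <- tabulate(idx[st == 0L] + 1L, C)
  out <- cbind(grid, n_case = n_case, n_control = n_control)
  attr(out, "combination") <- combination
  attr(out, "n_available") <- length(subset)
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Label cells high- or low-risk against a threshold ratio
#'
#' A cell is high-risk when its case:control ratio is at least the threshold
#' T (classically the training data's overall case:control ratio); a cell
#' with controls = 0 and cases > 0 is high, cases = 0 and controls > 0 is
#' low, both 0 is empty.  A ratio exactly equal to T is labelled high.
#'
#' @param cells A `cell_table`.
#' @param threshold Either a single ratio T, or a length-2 vector
#'   `c(total_cases, total_controls)` for exact integer arithmetic.
#'   Default: the cell table's own totals.
#' @return `cells` with an added `label` column (`"high"`, `"low"`,
#'   `"empty"`).
#' @export
classify_cells <- function(cells, threshold = NULL) {
  a <- cells$n_case; b <- cells$n_control
  if (is.null(threshold)) threshold <- c(sum(a), sum(b))
  if (length(threshold) == 2L) {
    A <- threshold[1]; B <- threshold[2]
  } else {
    A <- threshold; B <- 1
  }
  if (A <= 0 && B <= 0) stop("threshold must be positive", call. = FALSE)
  lab <- ifelse(a + b == 0L, "empty", ifelse(a * B >= b * A, "high", "low"))
  cells$label <- lab
  cells
}

#' Status-stratified cross-validation folds from the current subject order
#'
#' Cases and controls are split separately into consecutive blocks of
#' near-equal size, so shuffling the order of individuals changes the folds
#' and nothing else.  Leftover cases go to the earliest folds and leftover
#' controls to the latest folds, which keeps every fold non-empty whenever
#' the subject count allows it.
#'
#' @param status Binary status vector of the subjects, in order.
#' @param folds Number of folds.
#' @return Integer fold assignment (1..folds) per subject.
#' @export
mdr_folds <- function(status, folds = 10L) {
  n <- length(status)
  if (n < folds) stop("fewer subjects than folds", call. = FALSE)
  out <- integer(n)
  block <- function(m, front) {
    base <- m %/% folds; extra <- m %% folds
    sizes <- base + if (front) as.integer(seq_len(folds) <= extra)
                    else as.integer(seq_len(folds) > folds - extra)
    rep(seq_len(folds), sizes)
  }
  out[status == 1L] <- block(sum(status == 1L), front = TRUE)
  out[status == 0L] <- block(sum(status == 0L), front = FALSE)
  out
}

## Core cross-validation engine for one combination.
## Z: integer matrix of 0-based level codes; returns NULL when the
## combination is not evaluable (too few subjects or an empty fold).
cv_engine <- function(Z, status, cols, Lvec, folds) {
  sub <- Z[, cols, drop = FALSE]
  ok <- complete.cases(sub)
  n <- sum(ok)
  if (n < folds) return(NULL)
  sub <- sub[ok, , drop = FALSE]
  st <- status[ok]
  if (all(st == 1L) || all(st == 0L)) return(NULL)
  fold <- mdr_folds(st, folds)
  if (length(unique(fold)) < folds) return(NULL)
  C <- prod(Lvec[cols])
  idx <- rep(0L, n)
  for (k in seq_along(cols)) idx <- idx * Lvec[cols[k]] + sub[, k]
  key <- idx + C * (fold - 1L) + C * folds * st
  cnt <- tabulate(key + 1L, C * folds * 2L)
  arr <- array(cnt, c(C, folds, 2L))
  test_co <- arr[, , 1L, drop = FALSE]; dim(test_co) <- c(C, folds)
  test_ca <- arr[, , 2L, drop = FALSE]; dim(test_ca) <- c(C, folds)
  tot_co <- rowSums(test_co); tot_ca <- rowSums(test_ca)
  train_ca <- tot_ca - test_ca; train_co <- tot_co - test_co
  A <- colSums(train_ca); B <- colSums(train_co)
  Bm <- matrix(B, C, folds, byrow = TRUE)
  Am <- matrix(A, C, folds, byrow = TRUE)
  empty <- (train_ca + train_co) == 0L
  high <- (train_ca * Bm >= train_co * Am) & !empty
  train_acc <- colSums(train_ca * high + train_co * !high) / (A + B)
  test_tot <- colSums(test_ca) + colSums(test_co)
  test_acc <- colSums(test_ca * high + test_co * !high) / test_tot
  list(n_available = n, fold = fold, avail = which(ok),
       train_accuracy = train_acc, test_accuracy = test_acc)
}

encode_dataset <- function(ds) {
  Z <- matrix(NA_integer_, nrow(ds$values), ncol(ds$values),
              dimnames = dimnames(ds$values))
  L <- integer(ncol(Z))
  for (j in seq_len(ncol(Z))) {
    lev <- ds$factors[[j]]$levels
    Z[, j] <- match(ds$values[, j], lev) - 1L
    L[j] <- length(lev)
  }
  list(Z = Z, L = L)
}

#' Cross-validated accuracy of one interaction model
#'
#' Splits the combination's available subjects into status-stratified folds
#' from the current subject order; on each training portion builds the
#' high/low-risk cell labelling with threshold T = training case:control
#' ratio, and scores training and held-out accuracy (high cell <-> case,
#' low or training-empty cell <-> control).
#'
#' @param ds A `genotype_dataset`.
#' @param combination Character vector of factor names.
#' @param folds Number of cross-validation folds (default 10).
#' @return An object of class `mdr_cv` with fields `combination`,
#'   `n_available`, `fold` (assignment of the available subjects),
#'   `train_accuracy` and `test_accuracy` (one value per fold).
#' @export
evaluate_model_cv <- function(ds, combination, folds = 10L) {
  enc <- encode_dataset(ds)
  cols <- match(combination, colnames(enc$Z))
  if (anyNA(cols)) stop("unknown factor in combination", call. = FALSE)
  r <- cv_engine(enc$Z, ds$status, cols, enc$L, folds)
  if (is.null(r)) {
    stop("combination not evaluable: too few available subjects for the fold count",
         call. = FALSE)
  }
  structure(
    list(combination = combination, n_available = r$n_available,
         fold = r$fold, subjects = ds$subjects[r$avail],
         train_accuracy = r$train_accuracy, test_accuracy = r$test_accuracy),
    class = "mdr_cv"
  )
}

#' @export
print.mdr_cv <- function(x, ...) {
  cat(sprintf("<mdr_cv> %s: n=%d, mean train %.3f, mean test %.3f over %d folds\n",
              paste(x$combination, collapse = "+"), x$n_available,
              mean(x$train_accuracy), mean(x$test_accuracy),
              length(x$train_accuracy)))
  invisible(x)
}

#' Exhaustive MDR search over all k-way factor combinations
#'
#' Every k-subset of the factors (k from `k_min` to `k_max`) is evaluated by
#' cross-validation; within each fold the best k-way combination is the one
#' maximizing training accuracy (ties: higher test accuracy, then the
#' earlier combination in enumeration order, i.e. lexicographic by factor
#' position).  A model's CVC is the number of folds in which it won; the
#' per-k winner has maximal CVC, ties broken by mean test accuracy.
#'
#' @param ds A `genotype_dataset` (in its current subject order; shuffle the
#'   rows to change the folds).
#' @param k_min,k_max Interaction orders to search.
#' @param folds Number of cross-validation folds.
#' @param factors Factor names to search over (default: all).
#' @return An object of class `mdr_search`: `models` (data.frame over all
#'   combinations with CVC and fold-mean accuracies), `best_per_k` (which
#'   additionally carries `prediction_accuracy`, the held-out accuracy of
#'   each fold's winner on its own fold -- the classic cross-validated
#'   prediction estimate, selected on training data only), `winners`
#'   (per-k winning combination per fold), and the search settings.
#' @export
exhaustive_search <- function(ds, k_min = 1L, k_max = 5L, folds = 10L,
                              factors = NULL) {
  factors <- factors %||% colnames(ds$values)
  if (k_min < 1L || k_min > k_max) stop("need 1 <= k_min <= k_max", call. = FALSE)
  if (length(factors) < k_max) {
    stop("fewer factors than k_max", call. = FALSE)
  }
  enc <- encode_dataset(ds)
  fcols <- match(factors, colnames(enc$Z))
  if (anyNA(fcols)) stop("unknown factor name", call. = FALSE)
  all_models <- list()
  winners <- list()
  best_rows <- list()
  for (k in k_min:k_max) {
    combos <- combn(seq_along(fcols), k)
    combos[] <- fcols[combos]
    nc <- ncol(combos)
    train_m <- matrix(NA_real_, nc, folds)
    test_m <- matrix(NA_real_, nc, folds)
    n_avail <- integer(nc)
    for (i in seq_len(nc)) {
      r <- cv_engine(enc$Z, ds$status, combos[, i], enc$L, folds)
      if (is.null(r)) next
      train_m[i, ] <- r$train_accuracy
      test_m[i, ] <- r$test_accuracy
      n_avail[i] <- r$n_available
    }
    evaluable <- !is.na(train_m[, 1L])
    if (!any(evaluable)) {
      stop(sprintf("no evaluable %d-way combination (too much missing data for %d folds)",
                   k, folds), call. = FALSE)
    }
    win <- integer(folds)
    for (f in seq_len(folds)) {
      tr <- train_m[, f]; te <- test_m[, f]
      cand <- which(evaluable & tr == max(tr[evaluable]))
      if (length(cand) > 1L) cand <- cand[te[cand] == max(te[cand])]
      win[f] <- cand[1L]
    }
    cvc <- tabulate(win, nc)
    ## held-out accuracy of each fold's winner on its own fold: the classic
    ## cross-validated prediction estimate (selection on training data only)
    pred_acc <- mean(test_m[cbind(win, seq_len(folds))])
    labels <- apply(combos, 2L, function(j)
      paste(colnames(enc$Z)[j], collapse = "+"))
    df <- data.frame(
      k = k, combination = labels, cvc = cvc,
      train_accuracy = rowMeans(train_m), test_accuracy = rowMeans(test_m),
      n_available = n_avail, evaluable = evaluable,
      stringsAsFactors = FALSE
    )
    ord <- order(-df$cvc, -df$test_accuracy, seq_len(nc), na.last = TRUE)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    all_models[[as.character(k)]] <- df
    winners[[as.character(k)]] <- labels[win]
    best <- df[1L, , drop = FALSE]
    best$prediction_accuracy <- pred_acc
    best_rows[[as.character(k)]] <- best
  }
  best_per_k <- do.call(rbind, best_rows)
  rownames(best_per_k) <- NULL
  structure(
    list(models = do.call(rbind, c(all_models, make.row.names = FALSE)),
         best_per_k = best_per_k, winners = winners,
         k_min = k_min, k_max = k_max, folds = folds, factors = factors),
    class = "mdr_search"
  )
}

#' @export
print.mdr_search <- function(x, ...) {
  cat(sprintf("<mdr_search> k = %d..%d, %d folds\n", x$k_min, x$k_max, x$folds))
  print(x$best_per_k, digits = 3)
  invisible(x)
}

#' Repeated MDR analysis with shuffled subject order
#'
#' Runs the exhaustive search `repeats` times, each time after shuffling the
#' order of individuals (which re-derives the cross-validation folds), and
#' averages cross-validation consistency and accuracies.  Per interaction
#' order k the modal winning model across repeats is reported with its mean
#' CVC, mean training and test accuracy (averaged over all repeats) and the
#' number of repeats in which it was selected.  The overall best model has
#' maximal mean CVC, ties broken by mean test accuracy.
#'
#' @param ds A `genotype_dataset`.
#' @param k_min,k_max Interaction orders to search.
#' @param folds Cross-validation folds.
#' @param repeats Number of shuffled repetitions.
#' @param seed Master seed; repeat r uses seed `seed + r`.  The caller's RNG
#'   state is restored on exit.
#' @param factors Factor names to search over (default: all).
#' @return An object of class `mdr_result`: `summary` (per-k modal models,
#'   the published table layout), `best` (overall best model), `winners`
#'   (per-k winner per repeat) and the run settings.
#' @export
repeat_with_shuffles <- function(ds, k_min = 1L, k_max = 5L, folds = 10L,
                                 repeats = 10L, seed = 42L, factors = NULL) {
  stopifnot(repeats >= 1L)
  restore <- snapshot_rng()
  on.exit(restore(), add = TRUE)
  n <- length(ds$subjects)
  per_repeat <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    perm <- sample.int(n)
    per_repeat[[r]] <- exhaustive_search(ds_rows(ds, perm), k_min, k_max,
                                         folds, factors)
  }
  ks <- k_min:k_max
  summary_rows <- list()
  winners <- list()
  for (k in ks) {
    kk <- as.character(k)
    win_r <- vapply(per_repeat, function(s) s$best_per_k$combination[
      s$best_per_k$k == k], character(1))
    winners[[kk]] <- win_r
    stats_for <- function(model) {
      m <- t(vapply(per_repeat, function(s) {
        row <- s$models[s$models$k == k & s$models$combination == model, ]
        c(row$cvc, row$train_accuracy, row$test_accuracy)
      }, numeric(3)))
      colMeans(m, na.rm = TRUE)
    }
    tab <- table(win_r)
    cand <- names(tab)[tab == max(tab)]
    if (length(cand) > 1L) {
      cs <- vapply(cand, stats_for, numeric(3))
      ord <- order(-cs[1, ], -cs[3, ], cand)
      cand <- cand[ord]
    }
    modal <- cand[1L]
    st <- stats_for(modal)
    summary_rows[[kk]] <- data.frame(
      k = k, model = modal, selected_count = as.integer(tab[[modal]]),
      mean_cvc = st[1], mean_train_accuracy = st[2],
      mean_test_accuracy = st[3], stringsAsFactors = FALSE
    )
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  ord <- order(-summary$mean_cvc, -summary$mean_test_accuracy)
  best_row <- summary[ord[1L], ]
  best <- list(combination = strsplit(best_row$model, "+", fixed = TRUE)[[1]],
               k = best_row$k, mean_cvc = best_row$mean_cvc,
               mean_train_accuracy = best_row$mean_train_accuracy,
               mean_test_accuracy = best_row$mean_test_accuracy,
               selected_count = best_row$selected_count)
  structure(
    list(summary = summary, best = best, winners = winners,
         k_min = k_min, k_max = k_max, folds = folds, repeats = repeats,
         seed = seed),
    class = "mdr_result"
  )
}

#' @export
print.mdr_result <- function(x, ...) {
  cat(sprintf("<mdr_result> %d repeats x %d folds, k = %d..%d (seed %d)\n",
              x$repeats, x$folds, x$k_min, x$k_max, x$seed))
  print(x$summary, digits = 3)
  cat(sprintf("overall best: %s (mean CVC %.1f, mean test accuracy %.3f)\n",
              paste(x$best$combination, collapse = "/"), x$best$mean_cvc,
              x$best$mean_test_accuracy))
  invisible(x)
}
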