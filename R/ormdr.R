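#' Cell-level odds ratios for a final MDR model (OR-MDR)
#'
#' For each non-empty cell j of the final model with (aj cases, bj controls),
#' the effect size is OR_j = (aj/bj) / (a0/b0), where the reference (a0, b0)
#' pools the counts of all low-risk cells (or, with
#' `reference = "lowest"`, uses the single cell with the smallest
#' case:control ratio).  The 95% interval is
#' exp(ln OR_j +/- z sqrt(1/aj + 1/bj + 1/a0 + 1/b0)); cells involving a
#' zero count are Haldane-corrected (+0.5 everywhere) and flagged.  A cell
#' is marked significant when its interval excludes 1.
#'
#' @param ds A `genotype_dataset`.
#' @param combination Character vector: the factors of the final model.
#' @param reference `"pooled"` (default) or `"lowest"`.
#' @param conf_level Confidence level.
#' @return A data.frame of class `or_mdr`: one row per non-empty cell with
#'   its level codes, counts, risk label, odds ratio, interval, correction
#'   and significance flags.  The reference counts are attached as
#'   attributes `ref_cases` / `ref_controls`.
#' @export
or_mdr <- function(ds, combination, reference = c("pooled", "lowest"),
                   conf_level = 0.95) {
  reference <- match.arg(reference)
  cells <- tabulate_cells(ds, combination)
  a_tot <- sum(cells$n_case); b_tot <- sum(cells$n_control)
  if (a_tot == 0L || b_tot == 0L) {
    stop("final model needs both cases and controls among available subjects",
         call. = FALSE)
  }
  cells <- classify_cells(cells, c(a_tot, b_tot))
  low <- cells$label == "low"
  if (!any(low)) {
    stop("no low-risk cell exists: OR-MDR reference undefined", call. = FALSE)
  }
  if (reference == "pooled") {
    a0 <- sum(cells$n_case[low]); b0 <- sum(cells$n_control[low])
  } else {
    ratio <- cells$n_case[low] / pmax(cells$n_control[low], 1L)
    pick <- which(low)[order(ratio, -cells$n_control[low])][1L]
    a0 <- cells$n_case[pick]; b0 <- cells$n_control[pick]
  }
  keep <- cells$label != "empty"
  out <- cells[keep, , drop = FALSE]
  z <- qnorm(1 - (1 - conf_level) / 2)
  n_cell <- nrow(out)
  or <- lo <- hi <- numeric(n_cell)
  corrected <- logical(n_cell)
  for (i in seq_len(n_cell)) {
    aj <- out$n_case[i]; bj <- out$n_control[i]
    cellv <- c(aj, bj, a0, b0)
    if (any(cellv == 0)) {
      cellv <- cellv + 0.5
      corrected[i] <- TRUE
    }
    or[i] <- (cellv[1] / cellv[2]) / (cellv[3] / cellv[4])
    se <- sqrt(sum(1 / cellv))
    lo[i] <- exp(log(or[i]) - z * se)
    hi[i] <- exp(log(or[i]) + z * se)
  }
  out$or <- or
  out$ci_low <- lo
  out$ci_high <- hi
  out$corrected <- corrected
  out$significant <- lo > 1 | hi < 1
  rownames(out) <- NULL
  attr(out, "combination") <- combination
  attr(out, "reference") <- reference
  attr(out, "ref_cases") <- a0
  attr(out, "ref_controls") <- b0
  class(out) <- c("or_mdr", "data.frame")
  out
}
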