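#' Collapse a 3-genotype table to a 2x2 exposure table
#'
#' The three published collapse models: `heterozygous` compares genotype 1
#' against genotype 0 (variant homozygotes dropped), `extreme` compares
#' genotype 2 against 0 (heterozygotes dropped), and `dominant` compares
#' carriers (1+2) against genotype 0.
#'
#' @param table A `genotype_count_table` (rows genotype 0/1/2, columns
#'   control/case).
#' @param model One of `"heterozygous"`, `"extreme"`, `"dominant"`.
#' @return A named integer vector of class `two_by_two` with elements
#'   `a` (exposed cases), `b` (unexposed cases), `c` (exposed controls),
#'   `d` (unexposed controls).  No zero-cell correction is applied here.
#' @export
collapse_genotypes <- function(table, model = c("heterozygous", "extreme",
                                                "dominant")) {
  model <- match.arg(model)
  stopifnot(inherits(table, "genotype_count_table"))
  exp_rows <- switch(model, heterozygous = 2L, extreme = 3L, dominant = 2:3)
  t <- two_by_two(a = sum(table[exp_rows, "case"]),
                  b = table[1L, "case"],
                  c = sum(table[exp_rows, "control"]),
                  d = table[1L, "control"])
  attr(t, "model") <- model
  t
}

#' 2x2 exposure-by-status table
#'
#' @param a,b,c,d Non-negative counts: exposed cases, unexposed cases,
#'   exposed controls, unexposed controls.
#' @return Named integer vector of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  t <- c(a = as.integer(a), b = as.integer(b), c = as.integer(c),
         d = as.integer(d))
  if (anyNA(t) || any(t < 0L)) {
    stop("2x2 cells must be non-negative integers", call. = FALSE)
  }
  structure(t, class = "two_by_two")
}

association_result <- function(model, or, ci_low, ci_high, p_value,
                               ci_method, p_method, corrected = FALSE,
                               converged = TRUE, table = NULL) {
  structure(
    list(model = model, or = or, ci_low = ci_low, ci_high = ci_high,
         p_value = p_value,
         method = list(ci = ci_method, p = p_method, corrected = corrected,
                       converged = converged),
         table = table),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  flag <- if (isTRUE(x$method$corrected)) " [0.5-corrected]" else ""
  if (!isTRUE(x$method$converged)) flag <- paste0(flag, " [not converged]")
  cat(sprintf("<%s model> OR %.3f (95%% CI %.3f-%.3f), p = %.4g%s\n",
              x$model %||% "exposure", x$or, x$ci_low, x$ci_high,
              x$p_value, flag))
  invisible(x)
}

#' Crude odds ratio with Woolf confidence interval
#'
#' OR = (a d)/(b c) with the 95% log-scale (Woolf) interval
#' exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d)) and a two-sided exact
#' p-value from [fisher_exact_p()].  With `zero_correction = "haldane"` and a
#' zero cell, 0.5 is added to every cell first and the result is flagged.
#' With `"none"`, a zero cell yields OR 0 or Inf and the finite interval
#' bound is computed from the 0.5-corrected cells.
#'
#' @param t A `two_by_two` (or anything coercible via [two_by_two()]).
#' @param zero_correction `"none"` or `"haldane"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An `association_result`.
#' @examples
#' crude_odds_ratio(two_by_two(49, 60, 62, 132))  # OR 1.74
#' @export
crude_odds_ratio <- function(t, zero_correction = c("none", "haldane"),
                             conf_level = 0.95) {
  zero_correction <- match.arg(zero_correction)
  if (!inherits(t, "two_by_two")) t <- do.call(two_by_two, as.list(t))
  a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
  if ((a == 0L && d == 0L) || (b == 0L && cc == 0L) ||
      ((a == 0L || d == 0L) && (b == 0L || cc == 0L))) {
    stop("odds ratio undefined: two diagonal zero cells", call. = FALSE)
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- fisher_exact_p(t)
  has_zero <- any(c(a, b, cc, d) == 0L)
  woolf <- function(a, b, cc, d) {
    or <- (a * d) / (b * cc)
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    c(or, exp(log(or) - z * se), exp(log(or) + z * se))
  }
  if (!has_zero) {
    w <- woolf(a, b, cc, d)
    return(association_result(attr(t, "model"), w[1], w[2], w[3], p,
                              "woolf", "fisher-exact", FALSE, table = t))
  }
  if (zero_correction == "haldane") {
    w <- woolf(a + 0.5, b + 0.5, cc + 0.5, d + 0.5)
    return(association_result(attr(t, "model"), w[1], w[2], w[3], p,
                              "woolf", "fisher-exact", TRUE, table = t))
  }
  wc <- woolf(a + 0.5, b + 0.5, cc + 0.5, d + 0.5)
  if (a == 0L || d == 0L) {
    association_result(attr(t, "model"), 0, 0, wc[3], p,
                       "woolf", "fisher-exact", FALSE, table = t)
  } else {
    association_result(attr(t, "model"), Inf, wc[2], Inf, p,
                       "woolf", "fisher-exact", FALSE, table = t)
  }
}

#' Two-sided Fisher exact p-value
#'
#' Point-probability rule: the p-value is the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table.  `midp = TRUE` subtracts half
#' the observed table's probability.
#'
#' @param t A `two_by_two`.
#' @param midp Use the mid-P variant.
#' @return The p-value.
#' @export
fisher_exact_p <- function(t, midp = FALSE) {
  if (!inherits(t, "two_by_two")) t <- do.call(two_by_two, as.list(t))
  a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
  cases <- a + b; controls <- cc + d; exposed <- a + cc
  if (cases == 0L || controls == 0L || exposed == 0L || b + d == 0L) {
    return(1)
  }
  lo <- max(0L, exposed - controls)
  hi <- min(cases, exposed)
  dens <- dhyper(lo:hi, m = cases, n = controls, k = exposed)
  pobs <- dhyper(a, m = cases, n = controls, k = exposed)
  p <- sum(dens[dens <= pobs * (1 + 1e-07)])
  if (midp) p <- p - pobs / 2
  min(1, p)
}

#' Covariate-adjusted odds ratio by logistic regression
#'
#' Maximum-likelihood binary logistic model of status on the collapsed
#' exposure indicator plus covariates, with a Wald 95% interval.  With no
#' covariates this reproduces the crude odds ratio exactly (saturated 2x2
#' logistic identity).
#'
#' @param ds A `genotype_dataset` with the covariates present.
#' @param factor SNP factor name.
#' @param model Collapse model, as in [collapse_genotypes()].
#' @param covariates Character vector of covariate names (default
#'   `c("age", "gender")`); may be empty.
#' @param case_group Optional group tag restricting the cases.
#' @param conf_level Confidence level.
#' @param max_iter IRLS iteration cap.
#' @return An `association_result`; on non-convergence or separation the
#'   estimate is `NA` and `method$converged` is `FALSE`.
#' @export
adjusted_odds_ratio <- function(ds, factor, model = c("heterozygous",
                                                      "extreme", "dominant"),
                                covariates = c("age", "gender"),
                                case_group = NULL, conf_level = 0.95,
                                max_iter = 100L) {
  model <- match.arg(model)
  def <- ds_factor(ds, factor)
  if (def$kind != "snp") stop(sprintf("'%s' is not a SNP factor", factor),
                              call. = FALSE)
  keep <- ds$status == 0L |
    (ds$status == 1L & (is.null(case_group) | ds$group %in% case_group))
  g <- ds$values[, factor]
  inc <- switch(model,
                heterozygous = !is.na(g) & g %in% c(0L, 1L),
                extreme = !is.na(g) & g %in% c(0L, 2L),
                dominant = !is.na(g))
  keep <- keep & inc
  x <- as.integer(g > 0L)
  df <- data.frame(status = ds$status[keep], exposed = x[keep])
  if (length(covariates)) {
    if (is.null(ds$covariates) || !all(covariates %in% names(ds$covariates))) {
      stop("requested covariates are not present in the dataset", call. = FALSE)
    }
    df <- cbind(df, ds$covariates[keep, covariates, drop = FALSE])
    df <- df[complete.cases(df), , drop = FALSE]
  }
  if (length(unique(df$status)) < 2L) {
    stop("at least one case and one control are required", call. = FALSE)
  }
  fit <- suppressWarnings(
    glm(status ~ ., data = df, family = binomial(),
        control = list(maxit = max_iter))
  )
  sm <- summary(fit)$coefficients
  beta <- sm["exposed", "Estimate"]
  se <- sm["exposed", "Std. Error"]
  ok <- fit$converged && is.finite(se) && se < 20
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (!ok) {
    return(association_result(model, NA_real_, NA_real_, NA_real_, NA_real_,
                              "wald", "wald", converged = FALSE))
  }
  association_result(model, exp(beta), exp(beta - z * se), exp(beta + z * se),
                     2 * pnorm(-abs(beta / se)), "wald", "wald")
}

#' Per-SNP association scan across groups and collapse models
#'
#' Runs tabulate -> collapse -> crude odds ratio for every SNP factor, case
#' stratum and collapse model, mirroring the layout of a published
#' univariate table.  A Bonferroni-adjusted p-value column is emitted for
#' transparency but never used to gate significance.
#'
#' @param ds A `genotype_dataset`.
#' @param case_groups Case stratum tags to analyse (default: all group tags
#'   observed among cases).
#' @param models Collapse models to run.
#' @param zero_correction Passed to [crude_odds_ratio()].
#' @return A data.frame with one row per SNP x group x model.
#' @export
univariate_scan <- function(ds, case_groups = NULL,
                            models = c("heterozygous", "extreme", "dominant"),
                            zero_correction = "none") {
  snps <- factor_names(ds, "snp")
  case_groups <- case_groups %||% unique(ds$group[ds$status == 1L])
  rows <- list()
  for (grp in case_groups) {
    for (snp in snps) {
      tab <- tabulate_genotypes(ds, snp, grp)
      if (any(colSums(tab) == 0L)) next
      for (m in models) {
        t <- collapse_genotypes(tab, m)
        res <- tryCatch(crude_odds_ratio(t, zero_correction),
                        error = function(e) NULL)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          factor = snp, group = grp, model = m,
          a = t[["a"]], b = t[["b"]], c = t[["c"]], d = t[["d"]],
          or = res$or, ci_low = res$ci_low, ci_high = res$ci_high,
          p_value = res$p_value, corrected = res$method$corrected,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(factor = character(), group = character(),
                      model = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), or = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_value = numeric(), corrected = logical(),
                      p_bonferroni = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  out
}

#' @importFrom stats pnorm
NULL
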