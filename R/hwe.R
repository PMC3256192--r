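#' Hardy-Weinberg equilibrium chi-square test
#'
#' Given genotype counts (n0, n1, n2) for wild-type homozygotes,
#' heterozygotes and variant homozygotes, the variant allele frequency is
#' q = (n1 + 2 n2) / (2 n), the expected counts are (p^2 n, 2pq n, q^2 n),
#' and the statistic is the usual sum of (obs - exp)^2 / exp over the three
#' classes on 1 degree of freedom.  A monomorphic input (q = 0 or 1) returns
#' chi-square 0 and p = 1.
#'
#' @param counts Length-3 numeric genotype counts, or a
#'   `genotype_count_table` (its control column is used, matching the usual
#'   practice of testing HWE in healthy controls).
#' @return An object of class `hwe_result` with fields `chi_square`, `df`,
#'   `p_value`, `q` (variant allele frequency), `expected`, `observed`,
#'   `monomorphic`.
#' @examples
#' hwe_test(c(25, 50, 25))  # exact HW proportions: chi-square 0
#' @export
hwe_test <- function(counts) {
  if (inherits(counts, "genotype_count_table")) counts <- counts[, "control"]
  counts <- as.numeric(counts)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0)) {
    stop("genotype counts must be 3 non-negative numbers", call. = FALSE)
  }
  n <- sum(counts)
  if (n <= 0) stop("total genotype count must be positive", call. = FALSE)
  q <- (counts[2] + 2 * counts[3]) / (2 * n)
  p <- 1 - q
  expected <- c(p^2, 2 * p * q, q^2) * n
  mono <- q == 0 || q == 1
  chi <- if (mono) 0 else sum((counts - expected)^2 / expected)
  structure(
    list(chi_square = chi, df = 1L,
         p_value = if (mono) 1 else pchisq(chi, 1L, lower.tail = FALSE),
         q = q, expected = expected, observed = counts, monomorphic = mono),
    class = "hwe_result"
  )
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("<hwe_result> q = %.4f, chi-square = %.4f (1 df), p = %.4g%s\n",
              x$q, x$chi_square, x$p_value,
              if (x$monomorphic) " [monomorphic]" else ""))
  invisible(x)
}

#' HWE scan over all SNPs in the control group
#'
#' @param ds A `genotype_dataset`.
#' @return A data.frame with one row per SNP: observed control counts,
#'   variant allele frequency, chi-square and p-value.
#' @export
hwe_scan <- function(ds) {
  snps <- factor_names(ds, "snp")
  rows <- lapply(snps, function(s) {
    tab <- tabulate_genotypes(ds, s)
    if (sum(tab[, "control"]) == 0L) return(NULL)
    h <- hwe_test(tab[, "control"])
    data.frame(factor = s, n0 = tab[1, "control"], n1 = tab[2, "control"],
               n2 = tab[3, "control"], q = h$q, chi_square = h$chi_square,
               p_value = h$p_value, monomorphic = h$monomorphic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(factor = character(), n0 = integer(), n1 = integer(),
                      n2 = integer(), q = numeric(), chi_square = numeric(),
                      p_value = numeric(), monomorphic = logical())
  }
  rownames(out) <- NULL
  out
}
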