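#' Pairwise linkage disequilibrium from unphased genotypes
#'
#' Two-locus haplotype frequencies are estimated by EM: every genotype pair
#' determines its two haplotypes unambiguously except the double
#' heterozygote, whose mass is split between the coupling (00/11) and
#' repulsion (01/10) resolutions proportionally to the current haplotype
#' frequencies, iterating to convergence.  Initial frequencies are the
#' linkage-equilibrium allele-frequency products, so the procedure is
#' deterministic.  Reported are D = p11 - pA pB (for the variant alleles),
#' D' = |D| / Dmax, r^2 = D^2 / (pA pa pB pb), and a genotype-association
#' chi-square on the 3x3 table.
#'
#' @param ds A `genotype_dataset`.
#' @param snp_a,snp_b Names of two SNP factors.
#' @param tol EM convergence tolerance on haplotype frequencies.
#' @param max_iter EM iteration cap.
#' @return An object of class `ld_result` with fields `D`, `D_prime`,
#'   `r_squared`, `chi_square`, `chi_p_value`, `haplotype_freq`, `n`,
#'   `em_iterations`, `converged`, `monomorphic`.
#' @export
ld_pairwise <- function(ds, snp_a, snp_b, tol = 1e-08, max_iter = 1000L) {
  for (s in c(snp_a, snp_b)) {
    if (ds_factor(ds, s)$kind != "snp") {
      stop(sprintf("'%s' is not a SNP factor", s), call. = FALSE)
    }
  }
  ga <- ds$values[, snp_a]; gb <- ds$values[, snp_b]
  ok <- !is.na(ga) & !is.na(gb)
  if (sum(ok) < 5L) {
    stop("at least 5 subjects with both genotypes are required", call. = FALSE)
  }
  ga <- ga[ok]; gb <- gb[ok]
  n <- length(ga)
  tab <- matrix(0, 3, 3)  # rows genotype at A, cols at B
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(ga == i & gb == j)

  pa_var <- (sum(ga == 1L) + 2 * sum(ga == 2L)) / (2 * n)
  pb_var <- (sum(gb == 1L) + 2 * sum(gb == 2L)) / (2 * n)
  mono <- pa_var %in% c(0, 1) || pb_var %in% c(0, 1)

  ## haplotype order: h[1]=00, h[2]=01, h[3]=10, h[4]=11
  ## (first index: variant allele at A present; second: at B)
  h <- c((1 - pa_var) * (1 - pb_var), (1 - pa_var) * pb_var,
         pa_var * (1 - pb_var), pa_var * pb_var)
  h[h == 0] <- 1e-12
  h <- h / sum(h)
  converged <- FALSE
  iter <- 0L
  if (!mono) {
    for (iter in seq_len(max_iter)) {
      w <- (h[1] * h[4]) / (h[1] * h[4] + h[2] * h[3])  # P(coupling | double het)
      c00 <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1] + w * tab[2, 2]
      c01 <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3] + (1 - w) * tab[2, 2]
      c10 <- 2 * tab[3, 1] + tab[2, 1] + tab[3, 2] + (1 - w) * tab[2, 2]
      c11 <- 2 * tab[3, 3] + tab[2, 3] + tab[3, 2] + w * tab[2, 2]
      h_new <- c(c00, c01, c10, c11) / (2 * n)
      delta <- max(abs(h_new - h))
      h <- h_new
      if (delta < tol) { converged <- TRUE; break }
    }
  }

  if (mono) {
    D <- NA_real_; Dp <- NA_real_; r2 <- NA_real_
  } else {
    pA <- h[3] + h[4]   # variant allele frequency at A
    pB <- h[2] + h[4]
    D <- h[4] - pA * pB
    Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    Dp <- if (Dmax == 0) 0 else abs(D) / Dmax
    r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  }

  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  chi <- chi_p <- NA_real_
  if (sum(keep_r) > 1L && sum(keep_c) > 1L) {
    ct <- suppressWarnings(chisq.test(tab[keep_r, keep_c, drop = FALSE],
                                      correct = FALSE))
    chi <- unname(ct$statistic); chi_p <- ct$p.value
  }

  structure(
    list(snp_a = snp_a, snp_b = snp_b, n = n, D = D, D_prime = Dp,
         r_squared = r2, chi_square = chi, chi_p_value = chi_p,
         haplotype_freq = c(`00` = h[1], `01` = h[2], `10` = h[3], `11` = h[4]),
         em_iterations = iter, converged = converged && !mono,
         monomorphic = mono),
    class = "ld_result"
  )
}

#' @export
print.ld_result <- function(x, ...) {
  if (x$monomorphic) {
    cat(sprintf("<ld_result> %s x %s: undefined (monomorphic SNP)\n",
                x$snp_a, x$snp_b))
  } else {
    cat(sprintf("<ld_result> %s x %s (n=%d): D=%.4f D'=%.4f r2=%.4f (EM %d it)\n",
                x$snp_a, x$snp_b, x$n, x$D, x$D_prime, x$r_squared,
                x$em_iterations))
  }
  invisible(x)
}

#' LD scan over configured SNP pairs
#'
#' @param ds A `genotype_dataset`.
#' @param pairs List of length-2 character vectors naming SNP pairs.
#' @return A data.frame with one row per pair.
#' @export
ld_scan <- function(ds, pairs) {
  rows <- lapply(pairs, function(p) {
    r <- tryCatch(ld_pairwise(ds, p[1], p[2]), error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(snp_a = r$snp_a, snp_b = r$snp_b, n = r$n, D = r$D,
               D_prime = r$D_prime, r_squared = r$r_squared,
               chi_square = r$chi_square, chi_p_value = r$chi_p_value,
               converged = r$converged, monomorphic = r$monomorphic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(snp_a = character(), snp_b = character(), n = integer(),
                      D = numeric(), D_prime = numeric(),
                      r_squared = numeric(), chi_square = numeric(),
                      chi_p_value = numeric(), converged = logical(),
                      monomorphic = logical())
  }
  rownames(out) <- NULL
  out
}
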