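#' Simulate biallelic genotypes under Hardy-Weinberg equilibrium
#'
#' Genotypes 0/1/2 are drawn with probabilities (p^2, 2pq, q^2) where q is
#' the minor allele frequency.
#'
#' @param n Number of genotypes.
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param seed Optional seed (caller's RNG state restored on exit).
#' @return Integer genotype vector.
#' @export
simulate_genotypes_hwe <- function(n, maf, seed = NULL) {
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5) {
    stop("'maf' must lie in (0, 0.5]", call. = FALSE)
  }
  if (!is.null(seed)) {
    restore <- snapshot_rng(); on.exit(restore(), add = TRUE)
    set.seed(seed)
  }
  q <- maf; p <- 1 - q
  sample.int(3L, n, replace = TRUE, prob = c(p^2, 2 * p * q, q^2)) - 1L
}

#' Penetrance model mapping factor-level combinations to disease probability
#'
#' @param factors Character vector of factor names the table is indexed by.
#' @param table Numeric array of disease probabilities with one dimension per
#'   factor (dimension k has one entry per level of factor k, in level
#'   order).
#' @param baseline Disease probability for individuals outside the table
#'   (unused when the table covers the full level product, which it must for
#'   the factors it names).
#' @return An object of class `penetrance_model`.
#' @export
penetrance_model <- function(factors, table, baseline = 0.01) {
  table <- as.array(table)
  if (length(dim(table)) != length(factors)) {
    stop("penetrance table needs one dimension per factor", call. = FALSE)
  }
  if (anyNA(table) || any(table < 0) || any(table > 1)) {
    stop("penetrance probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (baseline < 0 || baseline > 1) stop("baseline must lie in [0, 1]",
                                         call. = FALSE)
  structure(list(factors = factors, table = table, baseline = baseline),
            class = "penetrance_model")
}

#' Two-locus XOR-style penetrance model
#'
#' High disease probability exactly when one of the two loci (and not the
#' other) carries at least one variant allele; the canonical benchmark for
#' interaction detection because neither locus has a marginal effect pattern
#' detectable by single-SNP collapse at strong interaction strength.
#'
#' @param loci Names of the two interacting SNPs.
#' @param high,low Disease probabilities for high- and low-risk cells.
#' @return A `penetrance_model` over the 3x3 genotype grid.
#' @export
xor_penetrance <- function(loci = c("SNP1", "SNP2"), high = 0.45, low = 0.05) {
  tab <- matrix(low, 3, 3)
  for (i in 0:2) for (j in 0:2) {
    if (xor(i >= 1, j >= 1)) tab[i + 1, j + 1] <- high
  }
  penetrance_model(loci, tab, baseline = low)
}

#' Configuration for the case-control simulator
#'
#' @param n_cases,n_controls Target sample sizes (case-control
#'   ascertainment keeps drawing from the population until both are met).
#' @param snps Named numeric vector of minor allele frequencies.
#' @param habit Optional probability vector over the tobacco-habit levels
#'   0/1/2 (no habit / only tobacco / tobacco + alcohol); `NULL` omits the
#'   exposure.
#' @param penetrance A [penetrance_model()]; its factors must be among the
#'   simulated factors.
#' @param missing_rate MCAR probability applied per genotype cell.
#' @param covariates Also draw age (normal around 50, clamped to 20-84) and
#'   gender covariates, independent of disease.
#' @param seed Default seed used by [simulate_case_control()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cases, n_controls, snps, habit = NULL,
                              penetrance, missing_rate = 0,
                              covariates = FALSE, seed = NULL) {
  stopifnot(n_cases >= 0, n_controls >= 0)
  if (is.null(names(snps)) || any(!nzchar(names(snps)))) {
    stop("'snps' must be a named MAF vector", call. = FALSE)
  }
  if (any(snps <= 0 | snps > 0.5)) stop("MAFs must lie in (0, 0.5]",
                                        call. = FALSE)
  if (!is.null(habit)) {
    if (any(habit < 0) || abs(sum(habit) - 1) > 1e-08) {
      stop("habit level probabilities must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  stopifnot(inherits(penetrance, "penetrance_model"))
  fac_names <- c(names(snps), if (!is.null(habit)) "habit")
  if (!all(penetrance$factors %in% fac_names)) {
    stop("penetrance factors must be among the simulated factors",
         call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("'missing_rate' must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         snps = snps, habit = habit, penetrance = penetrance,
         missing_rate = missing_rate, covariates = covariates, seed = seed),
    class = "simulation_config"
  )
}

#' Simulate a case-control cohort under a penetrance model
#'
#' Individuals are drawn from the population model (SNPs in HWE at the
#' configured MAFs, habit from its level probabilities), disease is assigned
#' by the penetrance table, and rejection sampling continues until the case
#' and control targets are both reached (clinic-accrual style
#' ascertainment).  MCAR missingness, if configured, is injected afterwards.
#'
#' @param cfg A [simulation_config()].
#' @param seed Seed (default `cfg$seed`); the caller's RNG state is
#'   restored on exit.
#' @param case_group Group tag for cases (default `"case"`).
#' @param max_draws Safety cap on population draws before an ascertainment
#'   timeout error.
#' @return A `genotype_dataset` with `cfg$n_cases + cfg$n_controls`
#'   subjects (cases first).
#' @export
simulate_case_control <- function(cfg, seed = cfg$seed, case_group = "case",
                                  max_draws = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(seed)) {
    restore <- snapshot_rng(); on.exit(restore(), add = TRUE)
    set.seed(seed)
  }
  target <- cfg$n_cases + cfg$n_controls
  max_draws <- max_draws %||% max(2e6, 2000 * target)
  fac_names <- c(names(cfg$snps), if (!is.null(cfg$habit)) "habit")
  pen <- cfg$penetrance
  pen_idx <- match(pen$factors, fac_names)
  pen_dim <- dim(pen$table)

  got_cases <- got_controls <- 0L
  keep_vals <- list(); keep_status <- list()
  drawn <- 0
  batch <- max(1000L, 4L * target)
  while (got_cases < cfg$n_cases || got_controls < cfg$n_controls) {
    if (drawn >= max_draws) {
      stop(sprintf(
        "ascertainment timeout: %d draws yielded %d/%d cases and %d/%d controls",
        drawn, got_cases, cfg$n_cases, got_controls, cfg$n_controls),
        call. = FALSE)
    }
    vals <- matrix(NA_integer_, batch, length(fac_names),
                   dimnames = list(NULL, fac_names))
    for (j in seq_along(cfg$snps)) {
      vals[, j] <- simulate_genotypes_hwe(batch, cfg$snps[[j]])
    }
    if (!is.null(cfg$habit)) {
      vals[, "habit"] <- sample.int(length(cfg$habit), batch, replace = TRUE,
                                    prob = cfg$habit) - 1L
    }
    ## disease probability by penetrance table lookup (level codes are the
    ## array indices, offset by one)
    sub <- vals[, pen_idx, drop = FALSE]
    lin <- rep(1L, batch); mult <- 1L
    for (k in seq_along(pen_idx)) {
      lin <- lin + sub[, k] * mult
      mult <- mult * pen_dim[k]
    }
    p <- pen$table[lin]
    disease <- rbinom(batch, 1L, p)
    need_case <- cfg$n_cases - got_cases
    need_ctrl <- cfg$n_controls - got_controls
    take_case <- which(disease == 1L)[seq_len(min(need_case, sum(disease == 1L)))]
    take_ctrl <- which(disease == 0L)[seq_len(min(need_ctrl, sum(disease == 0L)))]
    take <- c(take_case, take_ctrl)
    if (length(take)) {
      keep_vals[[length(keep_vals) + 1L]] <- vals[take, , drop = FALSE]
      keep_status[[length(keep_status) + 1L]] <- disease[take]
    }
    got_cases <- got_cases + length(take_case)
    got_controls <- got_controls + length(take_ctrl)
    drawn <- drawn + batch
  }
  values <- do.call(rbind, keep_vals)
  status <- unlist(keep_status)
  ord <- order(-status)  # cases first, stable
  values <- values[ord, , drop = FALSE]
  status <- status[ord]
  n <- length(status)
  defs <- c(lapply(names(cfg$snps), factor_definition, kind = "snp"),
            if (!is.null(cfg$habit)) list(habit_factor()))
  covariates <- NULL
  if (isTRUE(cfg$covariates)) {
    covariates <- data.frame(
      age = as.integer(pmin(84, pmax(20, round(rnorm(n, 50, 12))))),
      gender = rbinom(n, 1L, 0.5)
    )
  }
  ds <- genotype_dataset(
    values, status = status,
    subjects = sprintf("S%05d", seq_len(n)),
    group = ifelse(status == 1L, case_group, "control"),
    factors = defs, covariates = covariates
  )
  if (cfg$missing_rate > 0) ds <- inject_missingness(ds, cfg$missing_rate)
  ds
}

#' Inject missing-completely-at-random genotype gaps
#'
#' Each genotype cell is independently set missing with the given
#' probability; status, group and covariates are never masked.
#'
#' @param ds A `genotype_dataset`.
#' @param rate MCAR probability in [0, 1).
#' @param seed Optional seed (caller's RNG state restored on exit).
#' @return The dataset with missing values injected.
#' @export
inject_missingness <- function(ds, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("'rate' must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(ds)
  if (!is.null(seed)) {
    restore <- snapshot_rng(); on.exit(restore(), add = TRUE)
    set.seed(seed)
  }
  mask <- matrix(runif(length(ds$values)) < rate, nrow(ds$values))
  ds$values[mask] <- NA_integer_
  ds
}

#' @importFrom stats runif
NULL
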