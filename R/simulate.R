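#' Configuration for a simulated expression cohort
#'
#' Describes a cohort in which one driver gene controls survival, a block of
#' genes is positively co-regulated with the driver, one gene is negatively
#' correlated with it (an E-cadherin-like anti-gene), and all remaining genes
#' are independent noise. Expression values are on a log2-like intensity
#' scale: mean-zero unit-variance values plus a constant offset of 8.0, so
#' they resemble processed array intensities. Survival times follow an
#' exponential proportional-hazards model: the per-sample hazard is
#' `baseline_hazard * exp(hazard_coef * z)` where `z` is the driver's
#' (standard-normal) expression score, so `hazard_coef > 0` means high driver
#' expression shortens survival. Censoring is independent uniform thinning:
#' with probability `censor_rate` a sample is censored at a uniform fraction
#' of its event time.
#'
#' @param n_samples Number of samples (patients).
#' @param n_genes Total number of genes; must be at least `block_size + 2`.
#' @param driver_gene Symbol used for the driver gene row.
#' @param block_size Number of co-regulated block genes (the 15-gene
#'   analogue).
#' @param block_coupling Correlation in `[0, 1]` between each block gene and
#'   the driver.
#' @param anti_gene_coupling Strength in `[0, 1]` of the negative coupling of
#'   the anti-gene with the driver.
#' @param hazard_coef Log-hazard ratio per unit driver z-score.
#' @param baseline_hazard Baseline event rate per month; must be positive.
#' @param censor_rate Per-sample probability of censoring, in `[0, 1)`.
#' @param seed Integer seed; all randomness in [simulate_cohort()] flows from
#'   it.
#' @return A list of class `cohort_sim_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_sim_config <- function(n_samples, n_genes, driver_gene = "SPP1",
                              block_size = 15L, block_coupling = 0.7,
                              anti_gene_coupling = 0.4, hazard_coef = 0.7,
                              baseline_hazard = 0.01, censor_rate = 0.2,
                              seed = 1L) {
  .check_count(n_samples, "n_samples")
  .check_count(n_genes, "n_genes")
  if (!is.character(driver_gene) || length(driver_gene) != 1L ||
      is.na(driver_gene) || !nzchar(driver_gene)) {
    stop("invalid configuration: 'driver_gene' must be a single gene symbol",
         call. = FALSE)
  }
  if (!is.numeric(block_size) || length(block_size) != 1L ||
      is.na(block_size) || block_size < 0 || block_size != trunc(block_size)) {
    stop("invalid configuration: 'block_size' must be a non-negative integer",
         call. = FALSE)
  }
  .check_unit(block_coupling, "block_coupling")
  .check_unit(anti_gene_coupling, "anti_gene_coupling")
  if (!is.numeric(hazard_coef) || length(hazard_coef) != 1L ||
      !is.finite(hazard_coef)) {
    stop("invalid configuration: 'hazard_coef' must be a finite real",
         call. = FALSE)
  }
  if (!is.numeric(baseline_hazard) || length(baseline_hazard) != 1L ||
      !is.finite(baseline_hazard) || baseline_hazard <= 0) {
    stop("invalid configuration: 'baseline_hazard' must be > 0",
         call. = FALSE)
  }
  if (!is.numeric(censor_rate) || length(censor_rate) != 1L ||
      is.na(censor_rate) || censor_rate < 0 || censor_rate >= 1) {
    stop("invalid configuration: 'censor_rate' must be in [0, 1)",
         call. = FALSE)
  }
  if (block_size + 2L > n_genes) {
    stop("invalid configuration: 'n_genes' must be at least block_size + 2",
         call. = FALSE)
  }
  .check_seed(seed)
  structure(
    list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
         driver_gene = driver_gene, block_size = as.integer(block_size),
         block_coupling = block_coupling,
         anti_gene_coupling = anti_gene_coupling, hazard_coef = hazard_coef,
         baseline_hazard = baseline_hazard, censor_rate = censor_rate,
         seed = as.integer(seed)),
    class = "cohort_sim_config"
  )
}

#' Configuration for a simulated drug reference-profile library
#'
#' Describes a library of `n_drugs` drugs, each with a replicate count drawn
#' uniformly from `n_replicates_range`. For null drugs each replicate's
#' per-gene differential statistic is i.i.d. standard normal; for drugs
#' listed in `planted_reversers` the statistics of the query signature's
#' genes are shifted by `-reversal_strength * sign(gene)` before ranking, so
#' those drugs reverse the signature. Statistics are converted to signed
#' ranks: the gene with the largest absolute statistic receives rank
#' magnitude `G`, and the sign of the rank is the sign of the statistic.
#'
#' @param n_drugs Number of drugs in the library (the screened count N).
#' @param n_replicates_range Integer pair `c(min, max)` of replicate counts;
#'   min must be at least 1.
#' @param gene_universe Character vector of gene symbols covered by every
#'   profile (size G).
#' @param planted_reversers Character vector of drug ids to plant as
#'   signature reversers; must be a subset of the generated drug ids
#'   (`"drug_0001"`, ..., zero-padded to the width of `n_drugs`).
#' @param reversal_strength Non-negative shift applied to signature genes of
#'   planted reversers, in units of the null statistic's standard deviation.
#' @param seed Integer seed.
#' @return A list of class `ref_sim_config`.
#' @seealso [simulate_reference_library()]
#' @export
ref_sim_config <- function(n_drugs, gene_universe,
                           n_replicates_range = c(1L, 3L),
                           planted_reversers = character(),
                           reversal_strength = 0, seed = 1L) {
  .check_count(n_drugs, "n_drugs")
  if (!is.character(gene_universe) || length(gene_universe) < 1L ||
      anyDuplicated(gene_universe)) {
    stop("invalid configuration: 'gene_universe' must be unique gene symbols",
         call. = FALSE)
  }
  if (!is.numeric(n_replicates_range) || length(n_replicates_range) != 2L ||
      any(is.na(n_replicates_range)) || n_replicates_range[1L] < 1 ||
      n_replicates_range[2L] < n_replicates_range[1L] ||
      any(n_replicates_range != trunc(n_replicates_range))) {
    stop("invalid configuration: 'n_replicates_range' must be an integer pair with min >= 1",
         call. = FALSE)
  }
  if (!is.numeric(reversal_strength) || length(reversal_strength) != 1L ||
      is.na(reversal_strength) || reversal_strength < 0) {
    stop("invalid configuration: 'reversal_strength' must be >= 0",
         call. = FALSE)
  }
  ids <- .drug_ids(as.integer(n_drugs))
  if (length(planted_reversers) && !all(planted_reversers %in% ids)) {
    bad <- setdiff(planted_reversers, ids)
    stop("invalid configuration: planted reversers not among generated drug ids: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  .check_seed(seed)
  structure(
    list(n_drugs = as.integer(n_drugs),
         n_replicates_range = as.integer(n_replicates_range),
         gene_universe = gene_universe,
         planted_reversers = as.character(planted_reversers),
         reversal_strength = reversal_strength, seed = as.integer(seed)),
    class = "ref_sim_config"
  )
}

.drug_ids <- function(n) {
  sprintf(paste0("drug_%0", max(4L, nchar(n)), "d"), seq_len(n))
}

#' Simulate an expression cohort with survival annotations
#'
#' Generates a gene-by-sample expression matrix and matching clinical table
#' under the model described in [cohort_sim_config()]. The driver gene's
#' standardized expression is standard normal; each block gene equals
#' `block_coupling * driver + sqrt(1 - block_coupling^2) * noise`, the
#' anti-gene has the same construction with a negative sign, and all other
#' genes are independent standard normal. A constant offset of 8.0 is added
#' to every value to mimic log2 array intensities. Event times are
#' exponential with hazard `baseline_hazard * exp(hazard_coef * driver)`;
#' censored samples are observed at a uniform fraction of their event time.
#' Output is deterministic given `config$seed`.
#'
#' @param config A [cohort_sim_config()].
#' @return An object of class `expression_cohort`: a list with `values`
#'   (numeric matrix, genes x samples) and `clinical` (data frame with
#'   columns `sample_id`, `time_months`, `event`). The attribute `"truth"`
#'   records the driver, block and anti-gene symbols.
#' @examples
#' co <- simulate_cohort(cohort_sim_config(n_samples = 40, n_genes = 30,
#'                                         block_size = 5, seed = 7))
#' dim(co$values)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_sim_config")) {
    stop("'config' must be a cohort_sim_config", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_samples
  g <- config$n_genes
  b <- config$block_size
  n_noise <- g - b - 2L

  driver <- stats::rnorm(n)
  block_names <- if (b > 0L) sprintf("COREG%02d", seq_len(b)) else character()
  anti_name <- "ANTICOR1"
  noise_names <- if (n_noise > 0L) sprintf("RND%04d", seq_len(n_noise)) else character()

  rho <- config$block_coupling
  blk <- if (b > 0L) {
    noise <- matrix(stats::rnorm(b * n), nrow = b)
    rho * matrix(driver, nrow = b, ncol = n, byrow = TRUE) +
      sqrt(1 - rho^2) * noise
  } else {
    matrix(numeric(), nrow = 0L, ncol = n)
  }
  rho_a <- config$anti_gene_coupling
  anti <- -rho_a * driver + sqrt(1 - rho_a^2) * stats::rnorm(n)
  noise_rows <- if (n_noise > 0L) {
    matrix(stats::rnorm(n_noise * n), nrow = n_noise)
  } else {
    matrix(numeric(), nrow = 0L, ncol = n)
  }

  values <- rbind(matrix(driver, nrow = 1L), blk, matrix(anti, nrow = 1L),
                  noise_rows) + 8.0
  rownames(values) <- c(config$driver_gene, block_names, anti_name,
                        noise_names)
  sample_ids <- sprintf("S%04d", seq_len(n))
  colnames(values) <- sample_ids

  rate <- config$baseline_hazard * exp(config$hazard_coef * driver)
  event_time <- stats::rexp(n, rate = rate)
  censored <- stats::runif(n) < config$censor_rate
  frac <- stats::runif(n)
  time_obs <- ifelse(censored, frac * event_time, event_time)
  clinical <- data.frame(sample_id = sample_ids,
                         time_months = time_obs,
                         event = as.integer(!censored),
                         stringsAsFactors = FALSE)

  structure(
    list(values = values, clinical = clinical),
    truth = list(driver = config$driver_gene, block = block_names,
                 anti_gene = anti_name),
    class = "expression_cohort"
  )
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("expression cohort: %d genes x %d samples, %d events / %d samples with clinical data\n",
              nrow(x$values), ncol(x$values), sum(x$clinical$event),
              nrow(x$clinical)))
  invisible(x)
}

#' Simulate a drug reference-profile library
#'
#' Generates per-drug, per-replicate signed-rank profiles over the
#' configured gene universe, with the drugs listed in
#' `config$planted_reversers` shifted against the query signature as
#' described in [ref_sim_config()]. Output is deterministic given
#' `config$seed`.
#'
#' @param config A [ref_sim_config()].
#' @param signature A [gene_signature()]; its genes must all be contained in
#'   the configured gene universe.
#' @return A list with components `refs` (a `reference_profile_set`: list
#'   with `gene_universe`, `drugs` -- a named list of integer signed-rank
#'   matrices, genes x replicates -- and `N`) and `truth` (data frame with
#'   columns `drug_id`, `is_reverser`).
#' @export
simulate_reference_library <- function(config, signature) {
  if (!inherits(config, "ref_sim_config")) {
    stop("'config' must be a ref_sim_config", call. = FALSE)
  }
  signature <- as_gene_signature(signature)
  missing <- setdiff(signature$gene, config$gene_universe)
  if (length(missing)) {
    stop("signature genes absent from the gene universe: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed)
  genes <- config$gene_universe
  G <- length(genes)
  ids <- .drug_ids(config$n_drugs)
  rev_flag <- ids %in% config$planted_reversers
  sig_idx <- match(signature$gene, genes)
  shift <- config$reversal_strength * signature$sign

  rng <- config$n_replicates_range
  n_reps <- if (rng[1L] == rng[2L]) {
    rep.int(rng[1L], config$n_drugs)
  } else {
    sample(seq.int(rng[1L], rng[2L]), config$n_drugs, replace = TRUE)
  }

  drugs <- vector("list", config$n_drugs)
  names(drugs) <- ids
  for (i in seq_along(ids)) {
    stat <- matrix(stats::rnorm(G * n_reps[i]), nrow = G)
    if (rev_flag[i]) stat[sig_idx, ] <- stat[sig_idx, ] - shift
    ranks <- apply(stat, 2L, function(s) as.integer(sign(s) * rank(abs(s))))
    ranks <- matrix(ranks, nrow = G, dimnames = list(genes, NULL))
    drugs[[i]] <- ranks
  }
  refs <- structure(list(gene_universe = genes, drugs = drugs,
                         N = config$n_drugs),
                    class = "reference_profile_set")
  list(refs = refs,
       truth = data.frame(drug_id = ids, is_reverser = rev_flag,
                          stringsAsFactors = FALSE))
}

#' @export
print.reference_profile_set <- function(x, ...) {
  reps <- vapply(x$drugs, ncol, integer(1))
  cat(sprintf("reference profile set: N = %d drugs, G = %d genes, %d replicate profiles\n",
              x$N, length(x$gene_universe), sum(reps)))
  invisible(x)
}

.check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != trunc(x)) {
    stop(sprintf("invalid configuration: '%s' must be a positive integer",
                 name), call. = FALSE)
  }
}

.check_unit <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("invalid configuration: '%s' must be in [0, 1]", name),
         call. = FALSE)
  }
}

.check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed)) {
    stop("invalid configuration: 'seed' must be an integer", call. = FALSE)
  }
}
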