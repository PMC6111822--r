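#' Settings for a connectivity-mapping run
#'
#' Bundles the screen-wide settings: the number of drugs screened `N`, the
#' per-drug significance threshold (exactly `1/N` unless overridden), the
#' tail of the test, the null-distribution method and its Monte-Carlo
#' budget and seed.
#'
#' @param N Number of drugs screened.
#' @param tail `"negative"` to detect signature-reversing drugs (the
#'   default), `"positive"` for signature-mimicking drugs.
#' @param null_method `"analytic"` (normal approximation, default),
#'   `"monte_carlo"` (seeded random signatures) or `"exact"` (full
#'   enumeration of same-size gene sets, feasible for `choose(G, m) <= 1e5`).
#' @param n_draws Number of Monte-Carlo signatures when
#'   `null_method = "monte_carlo"`.
#' @param seed Integer seed for Monte-Carlo draws.
#' @param threshold Per-drug p-value threshold; defaults to
#'   [significance_threshold()] of `N`.
#' @return A list of class `connectivity_run`.
#' @export
connectivity_run <- function(N, tail = c("negative", "positive"),
                             null_method = c("analytic", "monte_carlo",
                                             "exact"),
                             n_draws = 10000L, seed = 1L,
                             threshold = NULL) {
  .check_count(N, "N")
  tail <- match.arg(tail)
  null_method <- match.arg(null_method)
  .check_count(n_draws, "n_draws")
  .check_seed(seed)
  if (is.null(threshold)) threshold <- significance_threshold(N)
  structure(list(N = as.integer(N), threshold = as.numeric(threshold),
                 tail = tail, null_method = null_method,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "connectivity_run")
}

#' Expected-false-positive significance threshold
#'
#' Returns exactly `1/N`. With N drugs screened and uniform null p-values,
#' declaring a drug significant at p < 1/N controls the expected number of
#' falsely significant drugs at one.
#'
#' @param N Number of drugs screened (>= 1).
#' @return The threshold `1/N`, with the control rationale attached as the
#'   `"rationale"` attribute.
#' @examples
#' significance_threshold(1432)  # 0.000698..., i.e. .0007
#' @export
significance_threshold <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1 ||
      N != trunc(N)) {
    stop("'N' must be a positive integer", call. = FALSE)
  }
  structure(1 / N,
            rationale = "controls the expected number of falsely significant drugs at 1")
}

#' Expected false-discovery rate of a screen
#'
#' Under the `1/N` threshold rule the expected number of false positives is
#' one, so with `n_significant` drugs declared significant the expected
#' false-discovery rate is `1/n_significant`.
#'
#' @param n_significant Number of significant drugs (>= 1).
#' @return `1/n_significant`; `NA` with a warning when no drug is
#'   significant (the rate is undefined).
#' @examples
#' expected_false_discovery(95)  # about 1%
#' @export
expected_false_discovery <- function(n_significant) {
  if (!is.numeric(n_significant) || length(n_significant) != 1L ||
      is.na(n_significant) || n_significant < 0 ||
      n_significant != trunc(n_significant)) {
    stop("'n_significant' must be a non-negative integer", call. = FALSE)
  }
  if (n_significant == 0) {
    warning("no significant drugs; expected false-discovery rate undefined",
            call. = FALSE)
    return(NA_real_)
  }
  1 / n_significant
}

#' Connection strength of a signature against one reference profile
#'
#' The connection strength is the sum of the profile's signed ranks over the
#' signature's genes, weighted by the signature signs:
#' `c = sum_g sign(g) * rank(g)`. The normalized score divides by the
#' maximum attainable sum `G + (G-1) + ... + (G-m+1)`, so it lies in
#' `[-1, 1]`; strongly negative values mean the drug reverses the signature.
#'
#' @param profile Named numeric vector of signed ranks over the gene
#'   universe (rank magnitudes a permutation of `1..G`).
#' @param signature A [gene_signature()]; all its genes must be in the
#'   profile.
#' @return List with `c` and `c_normalized`.
#' @export
connection_strength <- function(profile, signature) {
  signature <- as_gene_signature(signature)
  idx <- match(signature$gene, names(profile))
  if (anyNA(idx)) {
    stop("signature genes missing from profile: ",
         paste(signature$gene[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  G <- length(profile)
  m <- signature$m
  cc <- sum(signature$sign * profile[idx])
  max_sum <- sum(G - seq_len(m) + 1)
  list(c = unname(cc), c_normalized = unname(cc) / max_sum)
}

#' Null moments of the connection strength under random signatures
#'
#' Treats the null signature as `m` genes drawn uniformly without
#' replacement from the profile, all with sign +1 (actual signature signs
#' are equivalently absorbed into the profile's signed ranks). Then
#' `mu = m * mean(ranks)` and
#' `var = m * popvar(ranks) * (G - m) / (G - 1)` with the population
#' variance and the finite-population correction.
#'
#' @param profile Named numeric vector of signed ranks.
#' @param m Signature size, `1 <= m <= G`.
#' @return List with `mu` and `var`.
#' @export
null_moments <- function(profile, m) {
  G <- length(profile)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m > G ||
      m != trunc(m)) {
    stop("'m' must be an integer in 1..G", call. = FALSE)
  }
  r <- as.numeric(profile)
  mu1 <- mean(r)
  popvar <- mean(r^2) - mu1^2
  fpc <- if (G == 1L) 0 else (G - m) / (G - 1)
  list(mu = m * mu1, var = m * popvar * fpc)
}

#' Standardized score and one-tailed p-value for a connection strength
#'
#' Standardizes `c` by the [null_moments()] of the profile,
#' `z = (c - mu) / sqrt(var)`, and computes a one-tailed p-value under the
#' run's null method. With `tail = "negative"` small (strongly negative)
#' scores are significant: analytic `p = pnorm(z)`; Monte-Carlo
#' `p = (1 + #\{C <= c\}) / (1 + n_draws)` over seeded random signatures, so
#' p is never zero; exact mode enumerates all `choose(G, m)` gene sets
#' (allowed up to 1e5) and reports the tail fraction, floored at one over
#' the number of sets.
#'
#' @param c Observed connection strength.
#' @param profile Named numeric vector of signed ranks (or, internally, the
#'   per-gene sums of several replicate profiles).
#' @param m Signature size.
#' @param run A [connectivity_run()].
#' @param mu,var Optional pre-computed null moments (used when combining
#'   replicates, where the analytic moments are summed over replicates).
#' @return List with `z` and `p`.
#' @export
connection_pvalue <- function(c, profile, m, run, mu = NULL, var = NULL) {
  if (!inherits(run, "connectivity_run")) {
    stop("'run' must be a connectivity_run", call. = FALSE)
  }
  if (is.null(mu) || is.null(var)) {
    mom <- null_moments(profile, m)
    mu <- mom$mu
    var <- mom$var
  }
  if (var <= 0) {
    stop("null variance is zero; standardized score undefined",
         call. = FALSE)
  }
  z <- (c - mu) / sqrt(var)
  lower <- run$tail == "negative"
  p <- switch(run$null_method,
    analytic = stats::pnorm(z, lower.tail = lower),
    monte_carlo = {
      w <- as.numeric(profile)
      G <- length(w)
      set.seed(run$seed)
      draws <- vapply(seq_len(run$n_draws),
                      function(i) sum(w[sample.int(G, m)]), numeric(1))
      k <- if (lower) sum(draws <= c) else sum(draws >= c)
      (1 + k) / (1 + run$n_draws)
    },
    exact = {
      w <- as.numeric(profile)
      G <- length(w)
      n_comb <- choose(G, m)
      if (n_comb > 1e5) {
        stop("exact enumeration infeasible: choose(G, m) = ", n_comb,
             " exceeds 1e5", call. = FALSE)
      }
      sets <- utils::combn(G, m)
      totals <- colSums(matrix(w[sets], nrow = m))
      k <- if (lower) sum(totals <= c) else sum(totals >= c)
      max(k, 1) / n_comb
    })
  list(z = z, p = p)
}

#' Score one drug's replicate profiles against a signature
#'
#' Per-replicate connection strengths are summed,
#' `c_total = sum_i c_i`, and the null moments combine additively across
#' replicates (`mu_total = sum mu_i`, `var_total = sum var_i`, replicates
#' independent), reproducing the `sqrt(n)`-fold gain in the standardized
#' score for concordant replicates. In Monte-Carlo or exact mode the null
#' draws one gene set shared by all replicates, evaluated on the per-gene
#' sums of the replicate ranks. The drug is marked significant when
#' `p < run$threshold`.
#'
#' @param replicates Integer matrix of signed ranks, genes x replicates,
#'   with gene row names.
#' @param signature A [gene_signature()].
#' @param run A [connectivity_run()].
#' @return List with `replicate_count`, `c_total`, `c_normalized`, `z`,
#'   `p` and `significance_mark`.
#' @export
score_drug <- function(replicates, signature, run) {
  signature <- as_gene_signature(signature)
  if (is.null(dim(replicates))) {
    replicates <- matrix(replicates, ncol = 1L,
                         dimnames = list(names(replicates), NULL))
  }
  idx <- match(signature$gene, rownames(replicates))
  if (anyNA(idx)) {
    stop("signature genes missing from profile: ",
         paste(signature$gene[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  G <- nrow(replicates)
  m <- signature$m
  c_i <- colSums(replicates[idx, , drop = FALSE] * signature$sign)
  c_total <- sum(c_i)
  mean_i <- colMeans(replicates)
  popvar_i <- colMeans(replicates^2) - mean_i^2
  fpc <- if (G == 1L) 0 else (G - m) / (G - 1)
  mu_total <- m * sum(mean_i)
  var_total <- m * fpc * sum(popvar_i)
  w <- rowSums(replicates)
  names(w) <- rownames(replicates)
  zp <- connection_pvalue(c_total, w, m, run, mu = mu_total,
                          var = var_total)
  max_sum <- ncol(replicates) * sum(G - seq_len(m) + 1)
  list(replicate_count = ncol(replicates), c_total = c_total,
       c_normalized = c_total / max_sum, z = zp$z, p = zp$p,
       significance_mark = as.integer(zp$p < run$threshold))
}

#' Perturbation stability of a drug's connection
#'
#' Builds the `m` leave-one-out versions of the signature (each deleting
#' one gene), re-scores the drug against each, and reports the fraction
#' under which the drug remains significant at the run threshold. Stability
#' 1 marks connections robust to every single-gene perturbation.
#'
#' @inheritParams score_drug
#' @return A value in `{0, 1/m, ..., 1}`.
#' @export
perturbation_stability <- function(replicates, signature, run) {
  signature <- as_gene_signature(signature)
  m <- signature$m
  if (m < 2L) {
    stop("perturbation stability needs a signature of at least 2 genes",
         call. = FALSE)
  }
  hits <- 0L
  for (j in seq_len(m)) {
    loo <- gene_signature(signature$gene[-j], signature$sign[-j])
    sc <- score_drug(replicates, loo, run)
    hits <- hits + sc$significance_mark
  }
  hits / m
}

#' Rank scored drugs
#'
#' Orders a results table ascending by p-value, then descending by
#' perturbation stability, then ascending by standardized score (most
#' negative first), with the drug id as a final deterministic tie-break.
#'
#' @param results Data frame with columns `drug_id`, `p`,
#'   `perturb_stability` and `z` (as produced by [cmap_screen()]).
#' @return The same data frame, reordered, with row names reset.
#' @export
rank_drugs <- function(results) {
  stab <- results$perturb_stability
  stab[is.na(stab)] <- -1  # unstability-annotated drugs sort last among ties
  ord <- order(results$p, -stab, results$z, results$drug_id)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen a drug reference library against a gene signature
#'
#' Scores every drug in a `reference_profile_set` against the query
#' signature ([score_drug()]), annotates perturbation stability
#' ([perturbation_stability()]) when the signature has at least two genes,
#' marks significance at the `1/N` threshold and ranks the table
#' ([rank_drugs()]).
#'
#' @param signature A [gene_signature()] (or character vector of genes, all
#'   signs +1).
#' @param refs A `reference_profile_set` (see
#'   [simulate_reference_library()] and [read_reference_profiles()]).
#' @param stability Compute perturbation stability (default `TRUE`; skipped
#'   with a warning for single-gene signatures).
#' @param threshold Per-drug significance threshold; defaults to `1/N`.
#' @inheritParams connectivity_run
#' @return An object of class `cmap_screen`: list with the ranked `results`
#'   data frame (columns `drug_id`, `replicate_count`, `c_total`, `z`, `p`,
#'   `significance_mark`, `perturb_stability`), the `run` settings, `N`,
#'   `threshold`, `n_significant` and `expected_fdr`.
#' @examples
#' sig <- gene_signature(c("SPP1", "CLEC5A", "TREM2"))
#' lib <- simulate_reference_library(
#'   ref_sim_config(n_drugs = 10, gene_universe = c(sig$gene,
#'                  sprintf("G%03d", 1:97)), seed = 3), sig)
#' scr <- cmap_screen(sig, lib$refs)
#' scr
#' @export
cmap_screen <- function(signature, refs, tail = "negative",
                        null_method = "analytic", n_draws = 10000L,
                        seed = 1L, threshold = NULL, stability = TRUE) {
  signature <- as_gene_signature(signature)
  if (!inherits(refs, "reference_profile_set")) {
    stop("'refs' must be a reference_profile_set", call. = FALSE)
  }
  run <- connectivity_run(N = refs$N, tail = tail,
                          null_method = null_method, n_draws = n_draws,
                          seed = seed, threshold = threshold)
  do_stab <- stability && signature$m >= 2L
  if (stability && !do_stab) {
    warning("single-gene signature: perturbation stability skipped",
            call. = FALSE)
  }
  rows <- lapply(names(refs$drugs), function(id) {
    sc <- score_drug(refs$drugs[[id]], signature, run)
    stab <- if (do_stab) {
      perturbation_stability(refs$drugs[[id]], signature, run)
    } else {
      NA_real_
    }
    data.frame(drug_id = id, replicate_count = sc$replicate_count,
               c_total = sc$c_total, z = sc$z, p = sc$p,
               significance_mark = sc$significance_mark,
               perturb_stability = stab, stringsAsFactors = FALSE)
  })
  results <- rank_drugs(do.call(rbind, rows))
  n_sig <- sum(results$significance_mark)
  efdr <- if (n_sig > 0) expected_false_discovery(n_sig) else NA_real_
  structure(list(results = results, run = run, N = refs$N,
                 threshold = run$threshold, signature = signature,
                 n_significant = n_sig, expected_fdr = efdr),
            class = "cmap_screen")
}

#' @export
print.cmap_screen <- function(x, n = 10L, ...) {
  cat(sprintf("connectivity screen: %d drugs, signature m = %d, tail = %s\n",
              x$N, x$signature$m, x$run$tail))
  cat(sprintf("threshold 1/N = %.3g; %d significant drugs", x$threshold,
              x$n_significant))
  if (!is.na(x$expected_fdr)) {
    cat(sprintf(" (expected FDR %.3g)", x$expected_fdr))
  }
  cat("\n\ntop drugs:\n")
  print(utils::head(x$results, n))
  invisible(x)
}

#' @export
summary.cmap_screen <- function(object, ...) {
  r <- object$results
  out <- list(N = object$N, threshold = object$threshold,
              n_significant = object$n_significant,
              n_stable_significant = sum(r$significance_mark == 1 &
                                         !is.na(r$perturb_stability) &
                                         r$perturb_stability == 1),
              expected_fdr = object$expected_fdr)
  cat(sprintf("%d drugs screened at threshold %.3g\n", out$N,
              out$threshold))
  cat(sprintf("%d significant, of which %d with perturbation stability 1\n",
              out$n_significant, out$n_stable_significant))
  if (!is.na(out$expected_fdr)) {
    cat(sprintf("expected false-discovery rate %.3g\n", out$expected_fdr))
  }
  invisible(out)
}

#' @export
as.data.frame.cmap_screen <- function(x, ...) x$results

#' @export
plot.cmap_screen <- function(x, ...) {
  significance_plot(x$results, x$threshold, ...)
}

#' Significance plot of a connectivity screen
#'
#' Scatter of drugs (standardized connection score on the x axis) against
#' `-log10(p)`, with a horizontal line at `-log10(threshold)`: drugs above
#' the line are significant. Significant drugs with perturbation stability
#' 1 are drawn green, other significant drugs red, the rest grey. For a
#' screen of 1432 drugs the line sits at `-log10(1/1432) = 3.16`.
#'
#' @param results Scored results data frame (see [cmap_screen()]).
#' @param threshold Significance threshold on the p-value scale.
#' @param out_path Optional PNG path; when given the plot is written there,
#'   otherwise it is drawn on the current device.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the y position of the threshold line,
#'   `-log10(threshold)`.
#' @export
significance_plot <- function(results, threshold, out_path = NULL, ...) {
  if (nrow(results) == 0L) stop("no results to plot", call. = FALSE)
  line_y <- -log10(threshold)
  if (!is.null(out_path)) {
    grDevices::png(out_path, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  stab <- results$perturb_stability
  col <- ifelse(results$significance_mark == 1,
                ifelse(!is.na(stab) & stab == 1, "forestgreen", "red2"),
                "grey60")
  graphics::plot(results$z, -log10(results$p), col = col, pch = 16,
                 xlab = "standardized connection score",
                 ylab = expression(-log[10](italic(p))), ...)
  graphics::abline(h = line_y, col = "blue")
  invisible(line_y)
}
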