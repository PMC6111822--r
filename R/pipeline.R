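#' Run the full prognostic-signature / drug-screening pipeline
#'
#' Orchestrates the end-to-end analysis over two or more expression
#' cohorts: median-split survival analysis of the driver gene in each
#' cohort, optional gene-gene correlation report, cross-cohort derivation
#' of the co-regulated signature, connectivity screening of the signature
#' against a drug reference library, and the Table-style results outputs.
#' Every stage writes its output eagerly so stages can be inspected and
#' re-run; any stage failure aborts with the stage name and removes the
#' partial outputs. A fixed config and seed reproduce every output
#' byte-for-byte.
#'
#' @param config A list (or path to a JSON file) with fields:
#'   \describe{
#'     \item{cohorts}{list of `list(expression =, clinical =)` TSV path
#'       pairs, at least two, or ready `expression_cohort` objects;}
#'     \item{refs}{path to a long-format reference profile TSV, or a
#'       `reference_profile_set`;}
#'     \item{driver}{driver gene symbol;}
#'     \item{k}{number of co-regulated genes (default 15);}
#'     \item{tau}{optional RMST truncation time in months;}
#'     \item{correlate_with}{optional gene symbols correlated with the
#'       driver in each cohort;}
#'     \item{tail, null_method, n_draws, seed, threshold}{connectivity
#'       settings (see [connectivity_run()]);}
#'     \item{out_dir}{output directory.}
#'   }
#' @return The run manifest (also written to `manifest.json`): versions,
#'   seed, threshold, per-stage row counts and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(k = 15L, tau = NULL, correlate_with = character(),
                   tail = "negative", null_method = "analytic",
                   n_draws = 10000L, seed = 1L, threshold = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("cohorts", "driver", "refs", "out_dir")) {
    if (is.null(config[[nm]])) {
      stop("pipeline config is missing field '", nm, "'", call. = FALSE)
    }
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  note <- function(path) {
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohorts <- stage("load", {
    lapply(config$cohorts, function(co) {
      if (inherits(co, "expression_cohort")) return(co)
      read_expression_tsv(co$expression, co$clinical)
    })
  })
  if (length(cohorts) < 2L) {
    stop("pipeline stage 'load' failed: at least two cohorts are required for consistency ranking",
         call. = FALSE)
  }
  cohort_names <- names(config$cohorts)
  if (is.null(cohort_names) || any(!nzchar(cohort_names))) {
    cohort_names <- sprintf("cohort%d", seq_along(cohorts))
  }

  surv <- stage("survival", {
    reports <- lapply(cohorts, survival_report, gene = config$driver,
                      tau = config$tau)
    names(reports) <- cohort_names
    jsonlite::write_json(reports,
                         note(file.path(out_dir, "survival_report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    reports
  })

  if (length(config$correlate_with)) {
    stage("correlation", {
      rows <- do.call(rbind, unlist(lapply(seq_along(cohorts), function(i) {
        lapply(config$correlate_with, function(g) {
          cbind(cohort = cohort_names[i],
                pearson_correlation(cohorts[[i]], config$driver, g))
        })
      }), recursive = FALSE))
      utils::write.table(rows,
                         note(file.path(out_dir, "correlations.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rows
    })
  }

  signature <- stage("signature", {
    if (config$k > 0L) {
      rankings <- lapply(cohorts, function(co) {
        rank_differential_genes(co, median_split(co, config$driver),
                                exclude = config$driver)
      })
      co_genes <- consistent_top_genes(rankings, config$k)
    } else {
      co_genes <- character()
    }
    sig <- build_signature(config$driver, co_genes)
    write_signature_gmt(sig, note(file.path(out_dir, "signature.gmt")),
                        name = paste0(config$driver, "_signature"),
                        description = sprintf("driver plus top %d co-regulated genes",
                                              config$k))
    sig
  })

  refs <- stage("load_refs", {
    if (inherits(config$refs, "reference_profile_set")) {
      config$refs
    } else {
      read_reference_profiles(config$refs)
    }
  })

  screen <- stage("connectivity", {
    scr <- cmap_screen(signature, refs, tail = config$tail,
                       null_method = config$null_method,
                       n_draws = config$n_draws, seed = config$seed,
                       threshold = config$threshold)
    write_results_table(scr$results,
                        note(file.path(out_dir, "connectivity_results.tsv")))
    significance_plot(scr$results, scr$threshold,
                      note(file.path(out_dir, "significance_plot.png")))
    scr
  })

  manifest <- stage("manifest", {
    man <- list(
      package_version = as.character(utils::packageVersion("sigrev")),
      r_version = as.character(getRversion()),
      driver = config$driver, k = config$k, seed = config$seed,
      tail = config$tail, null_method = config$null_method,
      n_drugs = screen$N, threshold = screen$threshold,
      n_significant = screen$n_significant,
      n_stable_significant = sum(screen$results$significance_mark == 1 &
                                 !is.na(screen$results$perturb_stability) &
                                 screen$results$perturb_stability == 1),
      expected_fdr = screen$expected_fdr,
      signature = screen$signature$gene,
      cohorts = lapply(seq_along(cohorts), function(i) {
        list(name = cohort_names[i], n_genes = nrow(cohorts[[i]]$values),
             n_samples = ncol(cohorts[[i]]$values),
             logrank_p = surv[[i]]$logrank_p)
      }),
      significant_drugs = screen$results$drug_id[
        screen$results$significance_mark == 1],
      outputs = written
    )
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    man
  })
  invisible(manifest)
}
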