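#' Assemble an expression cohort from a matrix and clinical table
#'
#' Validates the invariants shared by all cohort producers: unique gene and
#' sample ids, finite expression values, and clinical records matching the
#' expression samples.
#'
#' @param values Numeric matrix, genes x samples, with row and column names.
#' @param clinical Data frame with columns `sample_id`, `time_months`
#'   (positive) and `event` (0/1).
#' @return An object of class `expression_cohort`.
#' @export
expression_cohort <- function(values, clinical) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry gene row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids in expression matrix: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression matrix contains non-finite values", call. = FALSE)
  }
  req <- c("sample_id", "time_months", "event")
  if (!all(req %in% names(clinical))) {
    stop("clinical table must have columns sample_id, time_months, event",
         call. = FALSE)
  }
  if (!all(clinical$sample_id %in% colnames(values))) {
    stop("clinical records refer to samples absent from the expression matrix",
         call. = FALSE)
  }
  if (any(clinical$time_months <= 0) || !all(clinical$event %in% c(0, 1))) {
    stop("clinical table needs positive times and 0/1 events",
         call. = FALSE)
  }
  structure(list(values = values, clinical = clinical),
            class = "expression_cohort")
}

#' Read an expression matrix and clinical table into a cohort
#'
#' The expression file is a simplified series-matrix dialect: a header row
#' of sample ids, first column the probe/gene id, tab-separated numeric
#' values. The clinical file has columns `sample_id`, `time_months`,
#' `event`. Samples are restricted to the intersection of the two files, in
#' the order of the expression header; a message reports any samples
#' dropped.
#'
#' @param path Expression TSV path.
#' @param clinical_path Clinical TSV path.
#' @return An `expression_cohort`.
#' @export
read_expression_tsv <- function(path, clinical_path) {
  raw <- utils::read.delim(path, check.names = FALSE, row.names = NULL,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file has no sample columns",
                           call. = FALSE)
  ids <- as.character(raw[[1L]])
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in expression header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1L, drop = FALSE], 2L,
                                              as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric expression value at row %d, column '%s'",
                 bad[1L, 1L], sample_ids[bad[1L, 2L]]), call. = FALSE)
  }
  rownames(mat) <- ids
  if (anyDuplicated(ids)) {
    stop("duplicate probe/gene ids in expression file; collapse probes first (see collapse_probes)",
         call. = FALSE)
  }

  clin <- utils::read.delim(clinical_path, stringsAsFactors = FALSE)
  req <- c("sample_id", "time_months", "event")
  if (!all(req %in% names(clin))) {
    stop("clinical file must have columns sample_id, time_months, event",
         call. = FALSE)
  }
  if (anyDuplicated(clin$sample_id)) {
    stop("duplicate sample ids in clinical file", call. = FALSE)
  }
  common <- sample_ids[sample_ids %in% clin$sample_id]
  if (length(common) == 0L) {
    stop("no samples shared between expression and clinical files",
         call. = FALSE)
  }
  dropped <- length(sample_ids) - length(common) +
    sum(!clin$sample_id %in% sample_ids)
  if (dropped > 0L) {
    message(sprintf("read_expression_tsv: %d genes, %d samples kept, %d samples dropped (no intersection)",
                    nrow(mat), length(common), dropped))
  }
  mat <- mat[, common, drop = FALSE]
  clin <- clin[match(common, clin$sample_id), req, drop = FALSE]
  rownames(clin) <- NULL
  expression_cohort(mat, clin)
}

#' Write a cohort to the expression/clinical TSV pair
#'
#' Inverse of [read_expression_tsv()]; the expression file's first column
#' is named `gene_id`.
#'
#' @param cohort An `expression_cohort`.
#' @param path Expression TSV path.
#' @param clinical_path Clinical TSV path.
#' @return Invisibly, `cohort`.
#' @export
write_expression_tsv <- function(cohort, path, clinical_path) {
  df <- data.frame(gene_id = rownames(cohort$values), cohort$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$clinical, clinical_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(cohort)
}

#' Collapse probe-level rows to one row per gene
#'
#' Several array probes can map to one gene; for each gene the probe with
#' the highest mean expression across samples is kept (ties broken by the
#' lexicographically smaller probe id). Probes absent from the mapping are
#' dropped and counted in a message.
#'
#' @param values Numeric matrix, probes x samples, probe ids as row names.
#' @param probe_to_gene Named character vector mapping probe id to gene
#'   symbol.
#' @return A matrix with one row per gene.
#' @export
collapse_probes <- function(values, probe_to_gene) {
  if (length(probe_to_gene) == 0L) {
    stop("probe-to-gene mapping is empty", call. = FALSE)
  }
  probes <- rownames(values)
  mapped <- probes[probes %in% names(probe_to_gene)]
  n_dropped <- length(probes) - length(mapped)
  if (n_dropped > 0L) {
    message(sprintf("collapse_probes: %d unmapped probes dropped", n_dropped))
  }
  if (length(mapped) == 0L) {
    stop("no probes matched the mapping", call. = FALSE)
  }
  genes <- probe_to_gene[mapped]
  means <- rowMeans(values[mapped, , drop = FALSE])
  # per gene keep max-mean probe, tie -> smaller probe id
  ord <- order(genes, -means, mapped, method = "radix")
  keep <- mapped[ord][!duplicated(genes[ord])]
  out <- values[keep, , drop = FALSE]
  rownames(out) <- probe_to_gene[keep]
  out[order(rownames(out), method = "radix"), , drop = FALSE]
}

#' Read or write a gene signature in GMT format
#'
#' One tab-separated line: set name, description, then gene tokens. A
#' regulation sign is encoded with an optional `|+1` / `|-1` suffix on the
#' gene token (default +1). Writing then reading yields an identical
#' signature.
#'
#' @param path GMT file path.
#' @return [read_signature_gmt()]: a [gene_signature()];
#'   [write_signature_gmt()]: invisibly, the signature.
#' @export
read_signature_gmt <- function(path) {
  line <- readLines(path, warn = FALSE)
  line <- line[nzchar(line)]
  if (length(line) == 0L) stop("empty GMT file", call. = FALSE)
  tokens <- strsplit(line[1L], "\t", fixed = TRUE)[[1L]]
  if (length(tokens) < 3L) {
    stop("GMT line must contain a name, description and at least one gene",
         call. = FALSE)
  }
  gene_tok <- tokens[-(1:2)]
  gene_tok <- gene_tok[nzchar(gene_tok)]
  if (length(gene_tok) == 0L) stop("GMT line has an empty gene list",
                                   call. = FALSE)
  parts <- strsplit(gene_tok, "|", fixed = TRUE)
  genes <- vapply(parts, `[[`, character(1), 1L)
  signs <- vapply(parts, function(p) {
    if (length(p) == 1L) return(1L)
    s <- suppressWarnings(as.integer(p[[2L]]))
    if (is.na(s) || !s %in% c(-1L, 1L)) {
      stop("invalid sign suffix on gene token: ", paste(p, collapse = "|"),
           call. = FALSE)
    }
    s
  }, integer(1))
  if (anyDuplicated(genes)) {
    stop("duplicate genes in GMT signature: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  sig <- gene_signature(genes, signs)
  attr(sig, "name") <- tokens[1L]
  attr(sig, "description") <- tokens[2L]
  sig
}

#' @param signature A [gene_signature()].
#' @param name,description Set name and description written to the GMT
#'   line.
#' @rdname read_signature_gmt
#' @export
write_signature_gmt <- function(signature, path, name = "signature",
                                description = "") {
  signature <- as_gene_signature(signature)
  tok <- ifelse(signature$sign == 1L, signature$gene,
                paste0(signature$gene, "|-1"))
  writeLines(paste(c(name, description, tok), collapse = "\t"), path)
  invisible(signature)
}

#' Read or write drug reference profiles as a long TSV
#'
#' Long format with columns `drug_id`, `replicate_index`, `gene`,
#' `signed_rank`. Every profile must cover exactly the same gene universe
#' and its rank magnitudes must be a permutation of `1..G`; violations are
#' rejected naming the offending profile.
#'
#' @param path TSV path.
#' @return [read_reference_profiles()]: a `reference_profile_set`;
#'   [write_reference_profiles()]: invisibly, the set.
#' @export
read_reference_profiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("drug_id", "replicate_index", "gene", "signed_rank")
  if (!all(req %in% names(df))) {
    stop("reference profile file must have columns drug_id, replicate_index, gene, signed_rank",
         call. = FALSE)
  }
  key <- paste(df$drug_id, df$replicate_index, df$gene, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("duplicate entry for drug '%s' replicate %s gene '%s'",
                 df$drug_id[i], df$replicate_index[i], df$gene[i]),
         call. = FALSE)
  }
  universe <- sort(unique(df$gene), method = "radix")
  G <- length(universe)
  drugs <- list()
  for (id in unique(df$drug_id)) {
    sub <- df[df$drug_id == id, , drop = FALSE]
    reps <- sort(unique(sub$replicate_index))
    mat <- matrix(NA_integer_, nrow = G, ncol = length(reps),
                  dimnames = list(universe, NULL))
    for (k in seq_along(reps)) {
      pr <- sub[sub$replicate_index == reps[k], , drop = FALSE]
      idx <- match(universe, pr$gene)
      if (anyNA(idx) || nrow(pr) != G) {
        stop(sprintf("profile of drug '%s' replicate %s does not cover the gene universe",
                     id, reps[k]), call. = FALSE)
      }
      rk <- as.integer(pr$signed_rank[idx])
      if (!identical(sort(abs(rk)), seq_len(G))) {
        stop(sprintf("rank magnitudes of drug '%s' replicate %s are not a permutation of 1..%d",
                     id, reps[k], G), call. = FALSE)
      }
      mat[, k] <- rk
    }
    drugs[[id]] <- mat
  }
  structure(list(gene_universe = universe, drugs = drugs,
                 N = length(drugs)),
            class = "reference_profile_set")
}

#' @param set A `reference_profile_set`.
#' @rdname read_reference_profiles
#' @export
write_reference_profiles <- function(set, path) {
  if (!inherits(set, "reference_profile_set")) {
    stop("'set' must be a reference_profile_set", call. = FALSE)
  }
  parts <- lapply(names(set$drugs), function(id) {
    mat <- set$drugs[[id]]
    data.frame(drug_id = id,
               replicate_index = rep(seq_len(ncol(mat)),
                                     each = nrow(mat)),
               gene = rep(rownames(mat), ncol(mat)),
               signed_rank = as.vector(mat), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, parts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(set)
}

#' Write a ranked connectivity results table
#'
#' Emits the screen's ranked results with the columns `Compound`,
#' `Replicate`, `P value`, `zscore`, `Significance_mark` and
#' `Perturb_stability`, p-values in scientific notation with three
#' significant digits, rows ordered by [rank_drugs()].
#'
#' @param results Scored results data frame (see [cmap_screen()]).
#' @param path Output TSV path.
#' @return Invisibly, the written data frame.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("no results to write", call. = FALSE)
  }
  ranked <- rank_drugs(results)
  out <- data.frame(Compound = ranked$drug_id,
                    Replicate = ranked$replicate_count,
                    `P value` = sprintf("%.2E", ranked$p),
                    zscore = ranked$z,
                    Significance_mark = ranked$significance_mark,
                    Perturb_stability = ranked$perturb_stability,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
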