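#' Construct a gene signature
#'
#' A gene signature is an ordered set of unique gene symbols with regulation
#' signs (+1 up, -1 down). It is the query of connectivity mapping.
#'
#' @param gene Character vector of unique gene symbols.
#' @param sign Integer vector of +1/-1, recycled from a scalar; defaults to
#'   all +1 (a co-up-regulated signature).
#' @return An object of class `gene_signature`: list with `gene`, `sign` and
#'   size `m`.
#' @export
gene_signature <- function(gene, sign = 1L) {
  if (!is.character(gene) || length(gene) < 1L || anyNA(gene)) {
    stop("signature must contain at least one gene symbol", call. = FALSE)
  }
  if (anyDuplicated(gene)) {
    stop("duplicate genes in signature: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(sign) == 1L) sign <- rep.int(sign, length(gene))
  if (length(sign) != length(gene) || !all(sign %in% c(-1L, 1L))) {
    stop("signs must be +1 or -1, one per gene", call. = FALSE)
  }
  structure(list(gene = gene, sign = as.integer(sign),
                 m = length(gene)),
            class = "gene_signature")
}

as_gene_signature <- function(x) {
  if (inherits(x, "gene_signature")) return(x)
  if (is.character(x)) return(gene_signature(x))
  stop("cannot interpret object as a gene signature", call. = FALSE)
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene signature (m = %d):\n", x$m))
  tag <- ifelse(x$sign > 0, "+", "-")
  cat(" ", paste0(tag, x$gene, collapse = " "), "\n")
  invisible(x)
}

#' Assemble a query signature from a driver gene and its co-regulated genes
#'
#' The driver comes first, followed by the co-regulated genes in the given
#' order. By default every gene carries sign +1, matching a signature of
#' co-up-regulated genes.
#'
#' @param driver Driver gene symbol; must not appear in `co_genes`.
#' @param co_genes Character vector of co-regulated gene symbols.
#' @param signs Optional vector of +1/-1 for all `1 + length(co_genes)`
#'   entries (driver first).
#' @return A [gene_signature()] of size `1 + length(co_genes)`.
#' @examples
#' build_signature("SPP1", c("CLEC5A", "TREM2"))
#' @export
build_signature <- function(driver, co_genes = character(), signs = NULL) {
  genes <- c(driver, co_genes)
  if (anyDuplicated(genes)) {
    stop("duplicate gene between driver and co_genes: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(signs)) signs <- rep.int(1L, length(genes))
  gene_signature(genes, signs)
}

#' Rank genes by differential expression between stratified groups
#'
#' Computes a per-gene Welch two-sample t statistic contrasting the "high"
#' group against the "low" group of a [median_split()] stratification, and
#' ranks genes by descending statistic, so rank 1 is the gene most
#' up-regulated in the high group. Genes constant in both groups with equal
#' means get statistic 0. Ties are broken lexicographically by gene symbol.
#'
#' @param cohort An `expression_cohort`.
#' @param labels A `stratified_cohort` from [median_split()] covering the
#'   cohort's samples.
#' @param exclude Genes to omit from the ranking (typically the driver
#'   itself).
#' @return A data frame of class `differential_ranking` with columns `gene`,
#'   `statistic`, `rank` and `direction`, ordered by rank.
#' @export
rank_differential_genes <- function(cohort, labels, exclude = character()) {
  values <- cohort$values
  lab <- labels$labels[colnames(values)]
  if (anyNA(lab)) {
    stop("stratification labels missing for some cohort samples",
         call. = FALSE)
  }
  hi <- values[, lab == "high", drop = FALSE]
  lo <- values[, lab == "low", drop = FALSE]
  if (ncol(hi) < 2L || ncol(lo) < 2L) {
    stop("each stratified group needs at least 2 samples (high: ",
         ncol(hi), ", low: ", ncol(lo), ")", call. = FALSE)
  }
  keep <- setdiff(rownames(values), exclude)
  hi <- hi[keep, , drop = FALSE]
  lo <- lo[keep, , drop = FALSE]
  mh <- rowMeans(hi); ml <- rowMeans(lo)
  vh <- .row_var(hi); vl <- .row_var(lo)
  se2 <- vh / ncol(hi) + vl / ncol(lo)
  stat <- ifelse(se2 == 0, 0, (mh - ml) / sqrt(se2))
  ord <- order(-stat, keep)
  out <- data.frame(gene = keep[ord], statistic = stat[ord],
                    rank = seq_along(keep),
                    direction = ifelse(stat[ord] >= 0, 1L, -1L),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("differential_ranking", "data.frame")
  out
}

.row_var <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}

#' Genes consistently top-ranked across several cohorts
#'
#' For each gene shared by all rankings, the consistency score is its worst
#' (largest) rank across cohorts; the `k` genes with the smallest score are
#' returned, ordered by it. This maximin rule requires a gene to be highly
#' ranked in every cohort, implementing "consistently differential across
#' datasets". Ties are broken by the sum of ranks, then lexicographically.
#'
#' @param rankings List of two or more [rank_differential_genes()] results.
#' @param k Number of genes to return.
#' @return Character vector of `k` gene symbols.
#' @export
consistent_top_genes <- function(rankings, k) {
  if (!is.list(rankings) || length(rankings) < 2L) {
    stop("at least two rankings are required", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != trunc(k)) {
    stop("'k' must be a positive integer", call. = FALSE)
  }
  shared <- Reduce(intersect, lapply(rankings, function(r) r$gene))
  if (length(shared) < k) {
    stop(sprintf("only %d genes shared across rankings, need k = %d",
                 length(shared), k), call. = FALSE)
  }
  rank_mat <- vapply(rankings,
                     function(r) r$rank[match(shared, r$gene)],
                     numeric(length(shared)))
  rank_mat <- matrix(rank_mat, nrow = length(shared))
  worst <- apply(rank_mat, 1L, max)
  total <- rowSums(rank_mat)
  ord <- order(worst, total, shared)
  shared[ord][seq_len(k)]
}

#' Pearson correlation between two genes in a cohort
#'
#' Sample Pearson correlation with a two-sided p-value from the t transform
#' on `n - 2` degrees of freedom (as computed by [stats::cor.test()]).
#'
#' @param cohort An `expression_cohort`.
#' @param gene_a,gene_b Gene symbols present in the cohort.
#' @return A data frame with columns `gene_a`, `gene_b`, `r`, `p_two_sided`
#'   and `n`.
#' @export
pearson_correlation <- function(cohort, gene_a, gene_b) {
  values <- cohort$values
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(values)) {
      stop("gene not found in cohort: ", g, call. = FALSE)
    }
  }
  x <- values[gene_a, ]
  y <- values[gene_b, ]
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples for a correlation", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in ", if (stats::sd(x) == 0) gene_a else gene_b,
         "; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(gene_a = gene_a, gene_b = gene_b,
             r = unname(ct$estimate), p_two_sided = ct$p.value, n = n,
             stringsAsFactors = FALSE)
}
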