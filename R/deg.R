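#' Read a table of differential-expression results
#'
#' Tab-separated file with a header; columns holding the gene id, the
#' log2 fold change and the BH-adjusted p-value are located by name,
#' case-insensitively, among common spellings (or given explicitly).
#' Rows missing the fold change or the adjusted p are dropped with a
#' warning; scientific notation is accepted.
#'
#' @param path path to the TSV file.
#' @param col_gene,col_fold,col_p optional explicit column names.
#' @return data.frame with columns `gene_id`, `log2_fold`, `p_adj`.
#' @export
read_deg_table <- function(path, col_gene = NULL, col_fold = NULL,
                           col_p = NULL) {
  if (!file.exists(path)) stop("DEG table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pick <- function(given, candidates, what) {
    if (!is.null(given)) {
      if (!given %in% names(tab)) stop("no column '", given, "' in ", path)
      return(given)
    }
    hit <- names(tab)[tolower(names(tab)) %in% candidates]
    if (!length(hit))
      stop("no recognizable ", what, " column in ", path,
           " (looked for: ", paste(candidates, collapse = ", "), ")")
    hit[1]
  }
  g <- pick(col_gene, c("gene_id", "gene", "symbol", "gene_symbol", "id"),
            "gene id")
  f <- pick(col_fold, c("log2_fold", "log2fold", "log2foldchange",
                        "log2.fold", "logfc", "log2fc"), "log2 fold change")
  p <- pick(col_p, c("p_adj", "padj", "adj.p.val", "fdr", "qvalue", "q_value"),
            "adjusted p-value")
  out <- data.frame(gene_id = as.character(tab[[g]]),
                    log2_fold = suppressWarnings(as.numeric(tab[[f]])),
                    p_adj = suppressWarnings(as.numeric(tab[[p]])),
                    stringsAsFactors = FALSE)
  bad <- !is.finite(out$log2_fold) | is.na(out$p_adj)
  if (any(bad)) {
    warning(sum(bad), " row(s) dropped from ", basename(path),
            ": missing fold change or adjusted p")
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0L)
    warning("no usable rows in ", basename(path))
  if (nrow(out) && (any(out$p_adj < 0) || any(out$p_adj > 1)))
    stop("adjusted p-values outside [0, 1] in ", path)
  rownames(out) <- NULL
  out
}

#' Select foreground (differentially expressed) genes
#'
#' A gene is in the `"up"` foreground when `p_adj < p_max` and
#' `log2_fold > log2(min_fold)`; in the `"down"` foreground when
#' `p_adj < p_max` and `log2_fold < -log2(min_fold)`. Both inequalities
#' are strict.
#'
#' @param deg data.frame from [read_deg_table()].
#' @param p_max adjusted-p cutoff (default 0.1).
#' @param min_fold fold-change cutoff on the linear scale, > 1
#'   (default 2.0; 1.5 is the common milder alternative).
#' @param direction `"up"` or `"down"`.
#' @return character vector of gene ids.
#' @export
select_foreground <- function(deg, p_max = 0.1, min_fold = 2.0,
                              direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(min_fold > 1)
  lf <- log2(min_fold)
  keep <- deg$p_adj < p_max &
    if (direction == "up") deg$log2_fold > lf else deg$log2_fold < -lf
  deg$gene_id[keep]
}

#' Select the background sampling pool
#'
#' Non-differential genes: `p_adj > p_min` and linear fold change within
#' `[fold_low, fold_high]` (bounds inclusive). Background groups for the
#' Monte-Carlo test are drawn from this pool.
#'
#' @param deg data.frame from [read_deg_table()].
#' @param p_min adjusted-p floor (default 0.1).
#' @param fold_low,fold_high inclusive linear fold-change bounds
#'   (defaults 0.80 and 1.25).
#' @param foreground optional foreground gene ids; if given, an error is
#'   raised when the pool is smaller than the foreground.
#' @return character vector of gene ids.
#' @export
select_background_pool <- function(deg, p_min = 0.1, fold_low = 0.80,
                                   fold_high = 1.25, foreground = NULL) {
  stopifnot(fold_low > 0, fold_low < 1, fold_high > 1)
  fold <- 2^deg$log2_fold
  pool <- deg$gene_id[deg$p_adj > p_min & fold >= fold_low & fold <= fold_high]
  if (!is.null(foreground) && length(pool) < length(foreground))
    stop("background pool (", length(pool), ") smaller than foreground (",
         length(foreground), "); relax fold_low/fold_high or p_min")
  pool
}

#' Rank upregulated genes by fold change
#'
#' Reporting order for the foreground: descending log2 fold change
#' (ascending for `direction = "down"`, i.e. strongest change first).
#'
#' @param deg data.frame from [read_deg_table()].
#' @param genes gene ids to rank (e.g. a foreground set).
#' @param direction `"up"` or `"down"`.
#' @return data.frame `gene_id`, `log2_fold`, `p_adj`, `rank`.
#' @export
rank_genes_by_fold <- function(deg, genes, direction = c("up", "down")) {
  direction <- match.arg(direction)
  sub <- deg[deg$gene_id %in% genes, , drop = FALSE]
  ord <- order(sub$log2_fold, decreasing = (direction == "up"))
  sub <- sub[ord, , drop = FALSE]
  sub$rank <- seq_len(nrow(sub))
  rownames(sub) <- NULL
  sub
}
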