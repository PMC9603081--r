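#' Simulate a promoter universe
#'
#' I.i.d. mononucleotide sequences at the given base frequencies, one
#' fixed-length promoter per gene, ids `g0001`, `g0002`, ...
#'
#' @param n_genes number of promoters.
#' @param promoter_length length in bp (default 2001, the (-2000; +1)
#'   window width).
#' @param background_freqs length-4 base probabilities (A, C, G, T).
#' @param seed RNG seed.
#' @return a `promoter_set`.
#' @export
simulate_promoters <- function(n_genes, promoter_length = 2001L,
                               background_freqs = rep(0.25, 4), seed = 1L) {
  stopifnot(n_genes >= 1, promoter_length >= 1,
            length(background_freqs) == 4,
            abs(sum(background_freqs) - 1) < 1e-8)
  set.seed(seed)
  m <- matrix(sample(DNA_BASES, n_genes * promoter_length, replace = TRUE,
                     prob = background_freqs),
              nrow = promoter_length)
  seqs <- apply(m, 2, paste0, collapse = "")
  names(seqs) <- sprintf("g%04d", seq_len(n_genes))
  promoter_set(seqs)
}

#' Plant motif sites into promoters
#'
#' Each candidate promoter is independently selected with probability
#' `rate`; a site is drawn base-by-base from the motif's probability
#' columns and written over the existing sequence (replacement, not
#' insertion, so promoter length and window alignment are preserved) at a
#' uniformly random offset on the forward strand. The planted sites are
#' returned as ground truth.
#'
#' @param promoters a `promoter_set`.
#' @param pwm a `pcm` or `pwm` supplying the probability columns.
#' @param rate per-promoter planting probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param gene_ids restrict planting to these genes (default: all).
#' @return list with `promoters` (modified set) and `sites` (data.frame
#'   `gene_id`, `offset`, `strand`, `site`).
#' @export
plant_sites <- function(promoters, pwm, rate, seed = 1L, gene_ids = NULL) {
  stopifnot(inherits(promoters, "promoter_set"), rate >= 0, rate <= 1)
  probs <- motif_probs(pwm)
  L <- nrow(probs)
  plen <- nchar(promoters$sequences[[1]])
  if (plen < L) stop("promoters shorter than the motif")
  if (is.null(gene_ids)) gene_ids <- names(promoters$sequences)
  stopifnot(all(gene_ids %in% names(promoters$sequences)))
  set.seed(seed)
  chosen <- gene_ids[stats::runif(length(gene_ids)) < rate]
  seqs <- promoters$sequences
  sites <- vector("list", length(chosen))
  for (i in seq_along(chosen)) {
    g <- chosen[i]
    site <- paste0(vapply(seq_len(L), function(pos)
      sample(DNA_BASES, 1, prob = probs[pos, ]), character(1)),
      collapse = "")
    offset <- sample.int(plen - L + 1L, 1) - 1L
    substr(seqs[[g]], offset + 1L, offset + L) <- site
    sites[[i]] <- data.frame(gene_id = g, offset = offset, strand = "+",
                             site = site, stringsAsFactors = FALSE)
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(gene_id = character(), offset = integer(),
               strand = character(), site = character())
  list(promoters = promoter_set(seqs, promoters$coords), sites = sites)
}

#' Generate a random position count matrix
#'
#' Decoy motifs for calibration and power studies: each position draws a
#' preferred base and mixes it with the uniform distribution, giving
#' motifs of moderate information content comparable to curated library
#' entries.
#'
#' @param motif_id motif identifier.
#' @param length number of positions (default 8).
#' @param depth total count per position (default 40, a typical
#'   ChIP-seq-derived matrix depth).
#' @param sharpness weight of the preferred base in the mixture, in
#'   `(0, 1)` (default 0.75).
#' @param seed RNG seed.
#' @return a [pcm].
#' @export
random_pcm <- function(motif_id, length = 8L, depth = 40, sharpness = 0.75,
                       seed = 1L) {
  stopifnot(length >= 1, depth > 0, sharpness > 0, sharpness < 1)
  set.seed(seed)
  counts <- t(vapply(seq_len(length), function(i) {
    p <- rep((1 - sharpness) / 4, 4)
    p[sample.int(4, 1)] <- p[1] + sharpness
    as.numeric(stats::rmultinom(1, depth, p))
  }, numeric(4)))
  pcm(motif_id, counts)
}

#' Simulate a differential-expression table with known ground truth
#'
#' Foreground genes get `log2_fold = effect_log2fold` and
#' `p_adj ~ U(0, 0.01)`; all other genes get `log2_fold ~ N(0, 0.1)`
#' truncated to a linear fold change within `[0.80, 1.25]` and
#' `p_adj ~ U(0.2, 1)`. Under the default selection thresholds,
#' [select_foreground()] and [select_background_pool()] recover the
#' planted partition exactly (provided `|effect_log2fold| > 1`).
#'
#' @param gene_ids all gene ids of the universe.
#' @param n_foreground number of planted differential genes.
#' @param effect_log2fold log2 fold change given to foreground genes
#'   (positive = upregulated).
#' @param seed RNG seed.
#' @return data.frame `gene_id`, `log2_fold`, `p_adj`, with the planted
#'   foreground ids in attribute `"foreground"`.
#' @export
simulate_deg_table <- function(gene_ids, n_foreground,
                               effect_log2fold = 2.0, seed = 1L) {
  stopifnot(n_foreground <= length(gene_ids), n_foreground >= 0)
  set.seed(seed)
  fg <- sample(gene_ids, n_foreground)
  is_fg <- gene_ids %in% fg
  lf <- numeric(length(gene_ids))
  pa <- numeric(length(gene_ids))
  lf[is_fg] <- effect_log2fold
  pa[is_fg] <- stats::runif(n_foreground, 0, 0.01)
  n_bg <- sum(!is_fg)
  bounds <- log2(c(0.80, 1.25))
  draw <- function(n) {
    x <- stats::rnorm(n, 0, 0.1)
    while (any(bad <- x < bounds[1] | x > bounds[2]))
      x[bad] <- stats::rnorm(sum(bad), 0, 0.1)
    x
  }
  lf[!is_fg] <- draw(n_bg)
  pa[!is_fg] <- stats::runif(n_bg, 0.2, 1)
  out <- data.frame(gene_id = gene_ids, log2_fold = lf, p_adj = pa,
                    stringsAsFactors = FALSE)
  attr(out, "foreground") <- fg
  out
}

#' Write a DEG table as TSV
#'
#' @param deg data.frame with `gene_id`, `log2_fold`, `p_adj`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_deg_table <- function(deg, path) {
  utils::write.table(deg[c("gene_id", "log2_fold", "p_adj")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a complete benchmark study
#'
#' Generates a promoter universe, a DEG table whose foreground is known,
#' and plants the motif into foreground promoters at `planting_rate_fg`
#' (and optionally into all remaining promoters at `planting_rate_bg`).
#' When `out_dir` is given, writes `promoters.fa`, a synthetic genome
#' layout (`genome.fa` + `tss.tsv`: promoters laid head-to-tail on one
#' chromosome so that [extract_promoters()] reproduces the set),
#' `deg.tsv` and the ground-truth `sites.tsv`.
#'
#' @param n_genes universe size.
#' @param n_foreground number of differential genes.
#' @param pwm planted motif (`pcm` or `pwm`).
#' @param planting_rate_fg,planting_rate_bg per-promoter planting
#'   probabilities for foreground and non-foreground genes.
#' @param promoter_length promoter width (default 2001).
#' @param background_freqs mononucleotide background (default uniform).
#' @param effect_log2fold foreground log2 fold change (default 2).
#' @param seed RNG seed; all randomness derives from it.
#' @param out_dir optional output directory for the file bundle.
#' @return list with `promoters`, `deg`, `foreground`, `sites`,
#'   and (if written) `files`.
#' @export
simulate_study <- function(n_genes, n_foreground, pwm,
                           planting_rate_fg = 0.6, planting_rate_bg = 0,
                           promoter_length = 2001L,
                           background_freqs = rep(0.25, 4),
                           effect_log2fold = 2.0, seed = 1L,
                           out_dir = NULL) {
  ps <- simulate_promoters(n_genes, promoter_length, background_freqs,
                           seed = seed)
  deg <- simulate_deg_table(gene_ids(ps), n_foreground,
                            effect_log2fold = effect_log2fold,
                            seed = seed + 1L)
  fg <- attr(deg, "foreground")
  pl <- plant_sites(ps, pwm, planting_rate_fg, seed = seed + 2L,
                    gene_ids = fg)
  sites <- pl$sites
  ps <- pl$promoters
  if (planting_rate_bg > 0) {
    pl2 <- plant_sites(ps, pwm, planting_rate_bg, seed = seed + 3L,
                       gene_ids = setdiff(gene_ids(ps), fg))
    ps <- pl2$promoters
    sites <- rbind(sites, pl2$sites)
  }
  out <- list(promoters = ps, deg = deg, foreground = fg, sites = sites)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(out_dir, c("promoters.fa", "genome.fa", "tss.tsv",
                              "deg.tsv", "sites.tsv"))
    names(f) <- c("promoters", "genome", "tss", "deg", "sites")
    write_promoter_set(ps, f[["promoters"]])
    lay <- genome_layout(ps)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(lay$genome), f[["genome"]])
    utils::write.table(lay$tss, f[["tss"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_deg_table(deg, f[["deg"]])
    utils::write.table(sites, f[["sites"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$files <- f
  }
  out
}

# lay promoters head-to-tail on one synthetic chromosome (+ strand),
# with TSS placed so the (-L+1; +1) window recovers each promoter
genome_layout <- function(ps, spacer = 10L) {
  plen <- nchar(ps$sequences[[1]])
  pad <- strrep("N", spacer)
  genome <- paste0(pad, paste0(ps$sequences, pad, collapse = ""))
  starts <- spacer + (seq_along(ps$sequences) - 1L) * (plen + spacer)
  tss <- data.frame(gene_id = names(ps$sequences), chrom = "chrS",
                    strand = "+", tss = starts + plen - 1L,
                    stringsAsFactors = FALSE)
  list(genome = c(chrS = genome), tss = tss)
}
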