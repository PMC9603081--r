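# per-position probability matrix of either a pcm or a pwm
motif_probs <- function(x) {
  if (inherits(x, "pwm")) return(x$probs)
  if (inherits(x, "pcm")) return(x$counts / rowSums(x$counts))
  stop("expected a pcm or pwm object")
}

# reverse complement of a probability matrix (positions as rows)
rc_probs <- function(p) {
  out <- p[rev(seq_len(nrow(p))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- DNA_BASES
  out
}

# Pearson correlation between aligned probability columns, one value per
# aligned position (rows of a and b). Constant columns have no defined
# correlation: two equal constants count as 1, otherwise 0.
aligned_col_cors <- function(a, b) {
  ca <- a - rowMeans(a)
  cb <- b - rowMeans(b)
  ssa <- rowSums(ca * ca)
  ssb <- rowSums(cb * cb)
  r <- rowSums(ca * cb) / sqrt(ssa * ssb)
  flat_a <- ssa < 1e-20
  flat_b <- ssb < 1e-20
  both <- flat_a & flat_b
  r[flat_a | flat_b] <- 0
  if (any(both))
    r[both] <- as.numeric(rowSums(abs(a[both, , drop = FALSE] -
                                        b[both, , drop = FALSE])) < 1e-12)
  r
}

# best mean per-column correlation between probability matrices A and B
# over all ungapped offsets with at least min_overlap aligned positions
best_overlap_score <- function(A, B, min_overlap = 4L) {
  La <- nrow(A); Lb <- nrow(B)
  best <- -Inf
  for (s in seq.int(-(Lb - min_overlap), La - min_overlap)) {
    ia <- max(1L, 1L + s):min(La, Lb + s)
    ib <- ia - s
    sc <- mean(aligned_col_cors(A[ia, , drop = FALSE], B[ib, , drop = FALSE]))
    if (sc > best) best <- sc
  }
  best
}

#' Ungapped similarity score of two motifs
#'
#' Maximum, over all ungapped offsets and both orientations of the second
#' motif, of the mean per-aligned-position Pearson correlation between
#' base-probability columns; at least `min_overlap` positions must align.
#' A motif scores 1 against itself and against its reverse complement.
#'
#' @param a,b `pcm` or `pwm` objects, both at least `min_overlap` long.
#' @param min_overlap minimum aligned positions (default 4).
#' @return similarity score in `[-1, 1]`.
#' @export
motif_similarity_score <- function(a, b, min_overlap = 4L) {
  A <- motif_probs(a); B <- motif_probs(b)
  if (nrow(A) < min_overlap || nrow(B) < min_overlap)
    stop("overlap impossible: both motifs must have at least ",
         min_overlap, " positions")
  max(best_overlap_score(A, B, min_overlap),
      best_overlap_score(A, rc_probs(B), min_overlap))
}

#' Permutation test for motif similarity
#'
#' The null distribution is built by permuting the positions (probability
#' columns) of the second motif uniformly at random `n_perm` times and
#' re-scoring; `p = (1 + #{null >= observed}) / (n_perm + 1)`, so the
#' smallest attainable p is `1/(n_perm + 1)`.
#'
#' @inheritParams motif_similarity_score
#' @param n_perm number of permutations (at least 100; default 1000).
#' @param seed RNG seed.
#' @param alpha significance cutoff used for the `significant` flag
#'   (default 0.05; larger p means "distinct motifs").
#' @return data.frame row: `motif_a`, `motif_b`, `best_score`, `p_value`,
#'   `significant`.
#' @export
motif_similarity_p <- function(a, b, n_perm = 1000L, seed = 1L,
                               min_overlap = 4L, alpha = 0.05) {
  stopifnot(n_perm >= 100)
  set.seed(seed)
  obs <- motif_similarity_score(a, b, min_overlap)
  A <- motif_probs(a); B <- motif_probs(b)
  Lb <- nrow(B)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    Bp <- B[sample.int(Lb), , drop = FALSE]
    null <- max(best_overlap_score(A, Bp, min_overlap),
                best_overlap_score(A, rc_probs(Bp), min_overlap))
    if (null >= obs - 1e-12) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_perm + 1)
  data.frame(motif_a = motif_id_of(a), motif_b = motif_id_of(b),
             best_score = obs, p_value = p, significant = p < alpha,
             stringsAsFactors = FALSE)
}

motif_id_of <- function(x) x$motif_id

#' Pairwise motif-similarity significance matrix
#'
#' Runs the permutation test for every unordered pair (including the
#' diagonal) and assembles symmetric score and p-value matrices — the
#' shading companion of a ranked enrichment table, where empty cells mark
#' significantly distinct motifs (p > `alpha`).
#'
#' @param pwms list of `pcm`/`pwm` objects (at least 2).
#' @inheritParams motif_similarity_p
#' @return an `esdeg_similarity`: list with symmetric matrices `score` and
#'   `p`, the pair table `entries`, and `alpha`.
#' @export
similarity_matrix <- function(pwms, n_perm = 1000L, seed = 1L,
                              min_overlap = 4L, alpha = 0.05) {
  stopifnot(length(pwms) >= 2)
  ids <- vapply(pwms, motif_id_of, character(1))
  if (anyDuplicated(ids)) stop("duplicate motif ids")
  M <- length(pwms)
  p <- score <- matrix(NA_real_, M, M, dimnames = list(ids, ids))
  entries <- vector("list", M * (M + 1) / 2)
  set.seed(seed)
  k <- 0L
  for (i in seq_len(M)) for (j in seq_len(i)) {
    # one RNG stream, fixed pair order => deterministic given seed
    e <- motif_similarity_p(pwms[[i]], pwms[[j]], n_perm = n_perm,
                            seed = sample.int(.Machine$integer.max, 1),
                            min_overlap = min_overlap, alpha = alpha)
    p[i, j] <- p[j, i] <- e$p_value
    score[i, j] <- score[j, i] <- e$best_score
    k <- k + 1L
    entries[[k]] <- e
  }
  structure(list(score = score, p = p,
                 entries = do.call(rbind, entries), alpha = alpha),
            class = "esdeg_similarity")
}

#' @export
print.esdeg_similarity <- function(x, ...) {
  n_sig <- sum(x$p[lower.tri(x$p)] < x$alpha)
  cat(sprintf("motif similarity matrix: %d motifs, %d significant off-diagonal pair(s) at p < %g\n",
              nrow(x$p), n_sig, x$alpha))
  invisible(x)
}

#' Export a similarity matrix as TSV
#'
#' Cells hold `-log10(p)` for significant pairs and are empty otherwise,
#' with motif ids as row and column labels.
#'
#' @param x an `esdeg_similarity`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_similarity_matrix <- function(x, path) {
  stopifnot(inherits(x, "esdeg_similarity"))
  cells <- ifelse(x$p < x$alpha, sprintf("%.4g", -log10(x$p)), "")
  dimnames(cells) <- dimnames(x$p)
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
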