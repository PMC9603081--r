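#' Construct a position count matrix
#'
#' @param motif_id motif identifier (e.g. a HOCOMOCO id).
#' @param counts numeric L x 4 matrix of non-negative base counts, columns
#'   ordered A, C, G, T; one row per motif position.
#' @return an object of class `pcm`.
#' @export
pcm <- function(motif_id, counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("motif ", motif_id, ": counts must have 4 columns (A, C, G, T)")
  if (nrow(counts) < 1L)
    stop("motif ", motif_id, ": empty count matrix")
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(counts < 0))
    stop("motif ", motif_id, ": negative or missing count")
  if (any(rowSums(counts) <= 0))
    stop("motif ", motif_id, ": every position must have positive total count")
  colnames(counts) <- DNA_BASES
  rownames(counts) <- NULL
  structure(list(motif_id = motif_id, counts = counts, length = nrow(counts)),
            class = "pcm")
}

#' @export
print.pcm <- function(x, ...) {
  cat(sprintf("pcm %s: %d positions\n", x$motif_id, x$length))
  invisible(x)
}

#' Parse a motif library file
#'
#' Supported formats:
#' * `hocomoco_pcm`: records start with a `>` id line followed by one row
#'   per motif position, 4 whitespace-separated numbers in A C G T order.
#' * `jaspar_like`: `>` id line followed by 4 base rows like
#'   `A [ 3 5 0 ... ]` (brackets optional).
#' * `plain`: blank-line-separated blocks; first line of a block is the id,
#'   remaining lines are position rows as in `hocomoco_pcm`.
#'
#' @param path path to the motif file.
#' @param format one of `"hocomoco_pcm"`, `"jaspar_like"`, `"plain"`.
#' @return list of [pcm] objects, in file order.
#' @export
parse_motif_library <- function(path,
                                format = c("hocomoco_pcm", "jaspar_like", "plain")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (format == "jaspar_like") return(parse_jaspar_like(lines))
  if (format == "plain") {
    # normalize to hocomoco layout: id lines get a '>' marker
    blocks <- split(lines, cumsum(lines == ""))
    lines <- unlist(lapply(blocks, function(b) {
      b <- b[b != ""]
      if (length(b)) b[1] <- paste0(">", b[1])
      b
    }), use.names = FALSE)
  }
  lines <- lines[lines != ""]
  if (!length(lines) || !startsWith(lines[1], ">"))
    stop("malformed motif file: expected '>' id line at top of ", path)
  idx <- cumsum(startsWith(lines, ">"))
  recs <- unname(split(lines, idx))
  lapply(recs, function(rec) {
    id <- sub("^>\\s*", "", rec[1])
    id <- strsplit(id, "\\s+")[[1]][1]
    if (length(rec) < 2L) stop("motif ", id, ": no count rows")
    rows <- strsplit(trimws(rec[-1]), "\\s+")
    n <- lengths(rows)
    if (any(n != 4L))
      stop("motif ", id, ": ragged matrix (row with ", n[n != 4L][1],
           " fields, expected 4)")
    counts <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                     ncol = 4, byrow = TRUE)
    if (anyNA(counts)) stop("motif ", id, ": non-numeric count")
    pcm(id, counts)
  })
}

parse_jaspar_like <- function(lines) {
  lines <- lines[lines != ""]
  idx <- cumsum(startsWith(lines, ">"))
  recs <- unname(split(lines, idx))
  lapply(recs, function(rec) {
    id <- strsplit(sub("^>\\s*", "", rec[1]), "\\s+")[[1]][1]
    body <- rec[-1]
    if (length(body) != 4L)
      stop("motif ", id, ": jaspar_like record needs exactly 4 base rows")
    base <- toupper(substr(trimws(body), 1, 1))
    if (!setequal(base, DNA_BASES))
      stop("motif ", id, ": base rows must be labelled A, C, G, T")
    vals <- lapply(body, function(l) {
      l <- gsub("[][]", " ", sub("^\\s*[ACGTacgt]", "", l))
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(vals))) != 1L)
      stop("motif ", id, ": ragged matrix across base rows")
    counts <- do.call(cbind, vals[order(match(base, DNA_BASES))])
    pcm(id, counts)
  })
}

#' Write a motif library in HOCOMOCO PCM layout
#'
#' @param pcms list of [pcm] objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_motif_library <- function(pcms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in pcms) {
    writeLines(paste0(">", m$motif_id), con)
    utils::write.table(m$counts, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Filter a motif collection
#'
#' With an explicit `exclude` list of motif ids, drops exactly those
#' motifs. Without one, applies a quality fallback: motifs shorter than
#' `min_length` positions or with total information content below
#' `min_ic` bits (uniform background) are removed. Input order is
#' preserved.
#'
#' @param pcms list of [pcm] objects.
#' @param exclude character vector of motif ids to drop, or `NULL` to use
#'   the quality rule.
#' @param min_length,min_ic quality-rule cutoffs.
#' @return filtered list of [pcm] objects.
#' @export
filter_motifs <- function(pcms, exclude = NULL, min_length = 6, min_ic = 5) {
  if (!is.null(exclude)) {
    keep <- !vapply(pcms, function(m) m$motif_id %in% exclude, logical(1))
  } else {
    keep <- vapply(pcms, function(m) {
      m$length >= min_length && total_ic(m) >= min_ic
    }, logical(1))
  }
  pcms[keep]
}

# total information content in bits, uniform background
total_ic <- function(pcm) {
  p <- pcm$counts / rowSums(pcm$counts)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  sum(2 + rowSums(plogp))
}

#' Convert a count matrix to a log-odds position weight matrix
#'
#' Weights are natural-log odds against the background:
#' `w[i, b] = ln((counts[i, b] + pc * bg[b]) / (N_i + pc)) - ln(bg[b])`
#' where `N_i` is the row-i count total and `pc` the pseudocount. The
#' default pseudocount is `0.25 * sqrt(N)` with `N` the mean row total, a
#' common motif-library convention.
#'
#' @param x a [pcm].
#' @param background length-4 base probabilities (A, C, G, T), summing to 1,
#'   all positive.
#' @param pseudocount positive smoothing mass; default `0.25 * sqrt(N)`.
#' @return an object of class `pwm` carrying the weights, the smoothed
#'   per-position base probabilities, and the cached maximum achievable
#'   score.
#' @export
pcm_to_pwm <- function(x, background = rep(0.25, 4), pseudocount = NULL) {
  stopifnot(inherits(x, "pcm"))
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 positive probabilities")
  if (abs(sum(background) - 1) > 1e-8)
    stop("background must sum to 1")
  n_i <- rowSums(x$counts)
  if (is.null(pseudocount)) pseudocount <- 0.25 * sqrt(mean(n_i))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  probs <- sweep(x$counts, 2, background, function(cnt, bg) cnt + pseudocount * bg)
  probs <- probs / (n_i + pseudocount)
  weights <- log(probs) - matrix(log(background), nrow = x$length,
                                 ncol = 4, byrow = TRUE)
  colnames(weights) <- DNA_BASES
  structure(list(motif_id = x$motif_id, weights = weights, probs = probs,
                 background = background, pseudocount = pseudocount,
                 length = x$length, max_score = sum(apply(weights, 1, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: %d positions, max score %.3f\n",
              x$motif_id, x$length, x$max_score))
  invisible(x)
}

# weights of the reverse-complement motif: reversed positions, swapped bases
rc_weights <- function(w) {
  out <- w[rev(seq_len(nrow(w))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- DNA_BASES
  out
}

#' Score one window under a PWM
#'
#' Sum of per-position log-odds weights. Any N (or other non-ACGT base) in
#' the window makes it unmatchable: the score is `-Inf`.
#'
#' @param pwm a [pcm_to_pwm()] object.
#' @param window DNA string of exactly the motif length.
#' @return numeric score.
#' @export
score_window <- function(pwm, window) {
  stopifnot(inherits(pwm, "pwm"))
  codes <- encode_dna(window)
  if (length(codes) != pwm$length)
    stop("window length ", length(codes), " != motif length ", pwm$length)
  scan_codes(codes, pwm$weights)[1]
}

#' Scan a promoter for motif hits
#'
#' Slides the motif over every offset of the sequence; on the reverse
#' strand the reverse complement of each window is scored (implemented by
#' scanning with the reverse-complemented weight matrix, so offsets refer
#' to the forward coordinates of the window). Windows containing N never
#' score; overlapping hits are all reported.
#'
#' @param pwm a `pwm` object.
#' @param sequence a DNA string (or a single-element named character
#'   vector, whose name is used as the gene id).
#' @param threshold minimum score for a hit.
#' @param both_strands scan the reverse strand too (default `TRUE`).
#' @param gene_id id recorded in the hit table.
#' @return data.frame with columns `gene_id`, `offset` (0-based window
#'   start), `strand`, `score`, `motif_id`, sorted by offset then strand.
#' @export
scan_promoter <- function(pwm, sequence, threshold, both_strands = TRUE,
                          gene_id = NULL) {
  stopifnot(inherits(pwm, "pwm"), length(sequence) == 1L)
  if (is.null(gene_id))
    gene_id <- if (!is.null(names(sequence))) names(sequence) else NA_character_
  codes <- encode_dna(sequence)
  empty <- data.frame(gene_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      motif_id = character(), stringsAsFactors = FALSE)
  if (length(codes) < pwm$length) return(empty)
  strand_hits <- function(scores, strand) {
    sel <- which(scores >= threshold)
    data.frame(offset = sel - 1L, strand = rep(strand, length(sel)),
               score = scores[sel])
  }
  hits <- strand_hits(scan_codes(codes, pwm$weights), "+")
  if (both_strands)
    hits <- rbind(hits, strand_hits(scan_codes(codes, rc_weights(pwm$weights)), "-"))
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$offset, match(hits$strand, c("+", "-"))), ]
  rownames(hits) <- NULL
  data.frame(gene_id = gene_id, hits, motif_id = pwm$motif_id,
             stringsAsFactors = FALSE)
}

#' Scan a whole promoter set for motif hits
#'
#' @param pwm a `pwm` object.
#' @param promoters a `promoter_set`.
#' @inheritParams scan_promoter
#' @return one hit data.frame (see [scan_promoter()]) over all promoters.
#' @export
scan_hits <- function(pwm, promoters, threshold, both_strands = TRUE) {
  stopifnot(inherits(promoters, "promoter_set"))
  out <- lapply(gene_ids(promoters), function(g)
    scan_promoter(pwm, promoters$sequences[[g]], threshold,
                  both_strands = both_strands, gene_id = g))
  do.call(rbind, out)
}

# all window scores of one encoded promoter (forward then reverse strand,
# if requested), as a single numeric vector; -Inf marks N windows
promoter_scores <- function(pwm, codes, both_strands = TRUE) {
  fwd <- scan_codes(codes, pwm$weights)
  if (!both_strands) return(fwd)
  c(fwd, scan_codes(codes, rc_weights(pwm$weights)))
}
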