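# near-deterministic count matrix for a consensus word: `depth - 3 * off`
# counts on the consensus base, `off` elsewhere
consensus_pcm <- function(id, word, depth = 500, off = 1) {
  bases <- strsplit(word, "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  counts <- t(vapply(bases, function(b) {
    row <- c(A = off, C = off, G = off, T = off)
    row[b] <- depth - 3 * off
    row
  }, numeric(4)))
  pcm(id, counts)
}

# zero-information matrix: every window scores exactly 0 under its PWM
uniform_pcm <- function(id, L, depth = 40) {
  pcm(id, matrix(depth / 4, nrow = L, ncol = 4))
}

example_motif_file <- function() {
  system.file("extdata", "example_motifs_synthetic.pcm", package = "esdeg")
}

deg_fixture_file <- function() {
  system.file("extdata", "rat_midbrain_degs.tsv", package = "esdeg")
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

REVCOMP_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(x) {
  paste(rev(REVCOMP_MAP[strsplit(x, "")[[1]]]), collapse = "")
}

# independent window scorer: naive per-position lookup, no package scanner
oracle_window_score <- function(weights, window) {
  ch <- strsplit(window, "")[[1]]
  if (any(!ch %in% c("A", "C", "G", "T"))) return(-Inf)
  sum(vapply(seq_along(ch), function(i) weights[i, ch[i]], numeric(1)))
}

# exhaustive enumeration of all windows x strands at/above a threshold
oracle_scan <- function(weights, seq, threshold, both_strands = TRUE) {
  L <- nrow(weights)
  n <- nchar(seq)
  rows <- list()
  for (o in seq_len(n - L + 1) - 1L) {
    win <- substr(seq, o + 1L, o + L)
    sf <- oracle_window_score(weights, win)
    if (sf >= threshold)
      rows[[length(rows) + 1L]] <- data.frame(offset = o, strand = "+", score = sf)
    if (both_strands) {
      sr <- oracle_window_score(weights, oracle_revcomp(win))
      if (sr >= threshold)
        rows[[length(rows) + 1L]] <- data.frame(offset = o, strand = "-", score = sr)
    }
  }
  if (!length(rows))
    return(data.frame(offset = integer(), strand = character(), score = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$offset, match(out$strand, c("+", "-"))), , drop = FALSE]
}
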