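test_that("motif library parsing reads HOCOMOCO-style records", {
  pcms <- parse_motif_library(example_motif_file())
  expect_length(pcms, 3)
  expect_identical(pcms[[1]]$motif_id, "EBOX_CAGCTG_SYNTH")
  expect_identical(vapply(pcms, `[[`, integer(1), "length"), c(10L, 8L, 8L))
  expect_true(all(vapply(pcms, function(m) all(m$counts >= 0), logical(1))))
})

test_that("write-then-parse round trip preserves matrices", {
  pcms <- list(consensus_pcm("M1", "CAGCTG"), uniform_pcm("M2", 5),
               random_pcm("M3", length = 9, seed = 4))
  f <- tempfile(fileext = ".pcm")
  write_motif_library(pcms, f)
  back <- parse_motif_library(f)
  expect_identical(vapply(back, `[[`, character(1), "motif_id"),
                   c("M1", "M2", "M3"))
  for (i in 1:3)
    expect_equal(back[[i]]$counts, pcms[[i]]$counts, ignore_attr = TRUE)
})

test_that("malformed matrices are rejected with the motif named", {
  f <- tempfile()
  writeLines(c(">BAD", "1 2 3 4", "1 2 3"), f)
  expect_error(parse_motif_library(f), "BAD.*ragged")
  writeLines(c(">NEG", "1 2 3 4", "1 -2 3 4"), f)
  expect_error(parse_motif_library(f), "NEG")
  expect_error(pcm("Z", matrix(0, 2, 4)), "positive total")
})

test_that("jaspar-like and plain formats parse", {
  f <- tempfile()
  writeLines(c(">M0001", "A [ 3 10  0 ]", "C [ 5  0 12 ]",
               "G [ 2  1  1 ]", "T [ 2  1  (9) ]"), f)
  # malformed bracket content should not silently parse
  suppressWarnings(expect_error(parse_motif_library(f, format = "jaspar_like")))
  writeLines(c(">M0001", "A [ 3 10  0 ]", "C [ 5  0 12 ]",
               "G [ 2  1  1 ]", "T [ 2  1  9 ]"), f)
  m <- parse_motif_library(f, format = "jaspar_like")
  expect_identical(m[[1]]$length, 3L)
  expect_identical(m[[1]]$counts[, "C"], c(5, 0, 12))

  writeLines(c("P1", "1 2 3 4", "4 3 2 1", "", "P2", "9 9 9 9"), f)
  m <- parse_motif_library(f, format = "plain")
  expect_identical(vapply(m, `[[`, character(1), "motif_id"), c("P1", "P2"))
})

test_that("filter_motifs applies exclusion lists and the quality fallback", {
  pcms <- parse_motif_library(example_motif_file())
  expect_identical(filter_motifs(pcms, exclude = character()), pcms)
  kept <- filter_motifs(pcms, exclude = "EBOX_CACGTG_SYNTH")
  expect_identical(vapply(kept, `[[`, character(1), "motif_id"),
                   c("EBOX_CAGCTG_SYNTH", "AT_RICH_SYNTH"))

  with_short <- c(pcms, list(consensus_pcm("SHORT4", "ACGT")))
  kept <- filter_motifs(with_short)
  expect_false("SHORT4" %in% vapply(kept, `[[`, character(1), "motif_id"))
  with_flat <- c(pcms, list(uniform_pcm("FLAT", 10)))
  kept <- filter_motifs(with_flat)
  expect_false("FLAT" %in% vapply(kept, `[[`, character(1), "motif_id"))
})

test_that("log-odds construction matches closed-form arithmetic", {
  # one uniform column: all four weights identical (scanning is
  # base-independent there)
  p <- pcm_to_pwm(pcm("U", matrix(1, 1, 4)))
  expect_equal(max(p$weights) - min(p$weights), 0, tolerance = 1e-12)

  # column (10, 0, 0, 0), uniform background, pseudocount 1
  p <- pcm_to_pwm(pcm("C", matrix(c(10, 0, 0, 0), 1, 4)), pseudocount = 1)
  expect_equal(unname(p$weights[1, "A"]), log(10.25 / 11) - log(0.25),
               tolerance = 1e-12)
  expect_equal(unname(p$weights[1, "C"]), log(0.25 / 11) - log(0.25),
               tolerance = 1e-12)

  # growing the pseudocount shrinks every weight toward 0
  m <- random_pcm("R", length = 6, seed = 2)
  w1 <- pcm_to_pwm(m, pseudocount = 0.5)$weights
  w2 <- pcm_to_pwm(m, pseudocount = 5)$weights
  expect_true(all(abs(w2) <= abs(w1) + 1e-12))

  expect_error(pcm_to_pwm(m, background = c(0.5, 0.5, 0, 0)), "positive")
  expect_error(pcm_to_pwm(m, background = c(0.3, 0.3, 0.3, 0.2)), "sum to 1")
})

test_that("window scoring matches a per-position oracle and handles N", {
  pwm <- pcm_to_pwm(uniform_pcm("Z", 4))
  expect_identical(score_window(pwm, "ACGT"), 0)
  expect_identical(score_window(pwm, "ACNT"), -Inf)
  expect_error(score_window(pwm, "ACGTA"), "length")

  pwm <- pcm_to_pwm(random_pcm("R8", length = 8, seed = 9))
  consensus <- paste(c("A", "C", "G", "T")[apply(pwm$weights, 1, which.max)],
                     collapse = "")
  expect_equal(score_window(pwm, consensus), pwm$max_score, tolerance = 1e-12)

  set.seed(10)
  for (i in 1:20) {
    win <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
    expect_equal(score_window(pwm, win), oracle_window_score(pwm$weights, win),
                 tolerance = 1e-12)
    expect_lte(score_window(pwm, win), pwm$max_score + 1e-12)
  }
})

test_that("promoter scanning equals exhaustive window enumeration", {
  pwm <- pcm_to_pwm(random_pcm("R6", length = 6, seed = 12))
  set.seed(13)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 30, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    for (thr in c(-5, 0, 3)) {
      got <- scan_promoter(pwm, s, thr, gene_id = "g")
      want <- oracle_scan(pwm$weights, s, thr)
      expect_identical(got$offset, want$offset)
      expect_identical(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-12)
    }
  }
})

test_that("scanning respects strand symmetry and threshold monotonicity", {
  pwm <- pcm_to_pwm(random_pcm("R7", length = 7, seed = 14))
  expect_identical(nrow(scan_promoter(pwm, "ACGTACGTACGT",
                                      pwm$max_score + 1)), 0L)

  # palindromic motif: every + hit has a - hit at the same offset
  pal <- pcm_to_pwm(consensus_pcm("PAL", "CACGTG"))
  hits <- scan_promoter(pal, "TTCACGTGTTTTCACGTGTT", 5)
  plus <- hits[hits$strand == "+", "offset"]
  minus <- hits[hits$strand == "-", "offset"]
  expect_identical(plus, minus)

  set.seed(15)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  # same multiset of scores on the reverse complement with strands swapped
  h1 <- scan_promoter(pwm, s, -20)
  h2 <- scan_promoter(pwm, oracle_revcomp(s), -20)
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-12)
  n_hits <- vapply(c(-5, 0, 2, 4, 8), function(t)
    nrow(scan_promoter(pwm, s, t)), integer(1))
  expect_true(all(diff(n_hits) <= 0))
})

test_that("scan_hits covers a promoter set with gene ids attached", {
  ps <- simulate_promoters(4, 60, seed = 16)
  pwm <- pcm_to_pwm(random_pcm("R5", length = 5, seed = 17))
  hits <- scan_hits(pwm, ps, 0)
  expect_true(all(hits$gene_id %in% gene_ids(ps)))
  expect_identical(unique(hits$motif_id), "R5")
})
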