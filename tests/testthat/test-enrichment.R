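test_that("site frequency counts promoters carrying a hit", {
  pwm <- pcm_to_pwm(consensus_pcm("M", "TACGATCGTTAG"))
  ps <- simulate_promoters(4, 80, seed = 41)
  expect_identical(site_frequency(pwm, ps, pwm$max_score + 1), 0)

  seqs <- ps$sequences
  for (g in gene_ids(ps)[1:3])
    substr(seqs[[g]], 11, 22) <- "TACGATCGTTAG"
  planted <- promoter_set(seqs)
  expect_equal(site_frequency(pwm, planted, pwm$max_score - 1e-9), 0.75)

  # per-window frequency counts hits, not promoters
  f_win <- site_frequency(pwm, planted, pwm$max_score - 1e-9,
                          frequency = "window")
  expect_equal(f_win, 0.75 / (2 * (80 - 12 + 1)), tolerance = 1e-12)
})

test_that("planted consensus sites give the planting-rate frequency", {
  hard <- pcm(motif_id = "HARD",
              counts = consensus_pcm("HARD", "TGACGTCATAGC", depth = 1e6,
                                     off = 1e-9)$counts)
  pwm <- pcm_to_pwm(hard)
  ps <- simulate_promoters(20, 100, seed = 42)
  pl <- plant_sites(ps, pwm, rate = 1, seed = 43, gene_ids = gene_ids(ps)[1:12])
  # at any threshold up to the consensus score the 12 planted promoters hit
  consensus_score <- score_window(pwm, "TGACGTCATAGC")
  expect_equal(site_frequency(pwm, pl$promoters, consensus_score), 0.6)
  expect_equal(site_frequency(pwm, pl$promoters, consensus_score / 2), 0.6)
})

test_that("per-level Z and p follow the normal-tail arithmetic", {
  # background frequencies with mean 0.3 and sd 0.1 exactly
  bg <- c(0.2, 0.3, 0.4)
  st <- esdeg:::level_stat(0.5, bg)
  expect_equal(st[["z"]], 2.0, tolerance = 1e-12)
  expect_equal(st[["p"]], pnorm(2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(st[["p"]], 0.02275, tolerance = 1e-4)

  st <- esdeg:::level_stat(0.3, bg)
  expect_identical(st[["z"]], 0)
  expect_identical(st[["p"]], 0.5)

  # degenerate background spread
  expect_warning(st <- esdeg:::level_stat(0.1, rep(0.2, 50)), "degenerate")
  expect_identical(st[["p"]], 1)
  expect_warning(st <- esdeg:::level_stat(0.5, rep(0.2, 50)), "degenerate")
  expect_equal(st[["p"]], 1 / 51)
})

test_that("mc_enrichment is unbiased under the null and deterministic", {
  ps <- simulate_promoters(100, 300, seed = 44)
  pwm <- pcm_to_pwm(random_pcm("R8", length = 8, seed = 45))
  tt5 <- calibrate_thresholds(pwm, ps, err_grid(n_levels = 5))
  ids <- gene_ids(ps)

  reps <- 30
  zbar <- matrix(NA_real_, reps, 5)
  set.seed(46)
  for (r in seq_len(reps)) {
    fg <- sample(ids, 15)
    lev <- suppressWarnings(
      mc_enrichment(pwm, fg, setdiff(ids, fg), ps, tt5,
                    n_resamples = 100, seed = 1000 + r))
    zbar[r, ] <- lev$z
  }
  # degenerate (zero-spread) levels yield infinite z; average the rest
  means <- apply(zbar, 2, function(z) mean(z[is.finite(z)]))
  expect_true(all(abs(means) < 3 / sqrt(reps)))

  fg <- ids[1:15]
  a <- mc_enrichment(pwm, fg, setdiff(ids, fg), ps, tt5,
                     n_resamples = 100, seed = 7)
  b <- mc_enrichment(pwm, fg, setdiff(ids, fg), ps, tt5,
                     n_resamples = 100, seed = 7)
  expect_identical(a, b)
  expect_error(mc_enrichment(pwm, ids[1:5], ids[3:20], ps, tt5,
                             n_resamples = 10, seed = 1), "overlap")
})

test_that("Hartung combination obeys its limiting cases and formula", {
  for (p in c(0.001, 0.07, 0.5, 0.93))
    expect_equal(hartung_combine(rep(p, 30)), p, tolerance = 1e-12)
  expect_identical(hartung_combine(0.07), 0.07)

  # independent straight-from-the-formula computation
  oracle <- function(p, kappa = 0.2) {
    t <- qnorm(pmin(pmax(p, 1e-300), 1 - 1e-16))
    L <- length(t)
    rho <- max(-1 / (L - 1), 1 - sum((t - mean(t))^2) / (L - 1))
    pnorm(sum(t) / sqrt(L + (L^2 - L) *
                          (rho + kappa * sqrt(2 / (L + 1)) * (1 - rho))))
  }
  expect_equal(hartung_combine(c(0.01, 0.04, 0.10, 0.20, 0.50)),
               oracle(c(0.01, 0.04, 0.10, 0.20, 0.50)), tolerance = 1e-12)
  set.seed(47)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(hartung_combine(p), oracle(p), tolerance = 1e-12)
    expect_equal(hartung_combine(p), hartung_combine(sample(p)),
                 tolerance = 1e-12)
  }
  expect_error(hartung_combine(c(0.5, 1.2)), "lie in")
  expect_error(hartung_combine(c(0.5, NA)), "lie in")
  expect_error(hartung_combine(numeric()), "empty")
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.10)), c(0.01, 0.10))
  # mapped back to input order
  expect_equal(bh_adjust(c(0.10, 0.005)), c(0.10, 0.01))
})

test_that("motif ranking sorts by adjusted p with deterministic tie-breaks", {
  res <- data.frame(motif_id = c("B", "A", "C"),
                    unified_p = c(0.001, 0.001, 0.02),
                    p_adj = c(0.01, 0.01, 0.05))
  r <- rank_motifs(res, report_p = 0.05)
  expect_identical(r$rank, 1:3)
  expect_identical(r$motif_id, c("A", "B", "C"))   # tie broken by id
  expect_identical(r$reported, c(TRUE, TRUE, FALSE))
  expect_equal(r$minus_log10_p_adj[1], 2)
})

test_that("a heavier planting rate never weakens the planted motif", {
  pcms <- parse_motif_library(example_motif_file())
  pwm <- pcm_to_pwm(pcms[[1]])
  ps <- simulate_promoters(120, 400, seed = 48)
  deg <- simulate_deg_table(gene_ids(ps), 20, 2, seed = 49)
  fg <- attr(deg, "foreground")
  pool <- select_background_pool(deg)
  unified <- vapply(c(4, 16), function(k) {
    pl <- plant_sites(ps, pwm, 1, seed = 50, gene_ids = fg[seq_len(k)])
    res <- suppressWarnings(
      esdeg_enrichment(pl$promoters, list(pwm), fg, pool,
                       err_levels = err_grid(n_levels = 10),
                       n_resamples = 200, seed = 51, verbose = FALSE))
    res$table$unified_p
  }, numeric(1))
  expect_lt(unified[2], unified[1])
})

test_that("enrichment results are reproducible and exportable", {
  pcms <- parse_motif_library(example_motif_file())
  pwms <- lapply(pcms, pcm_to_pwm)
  ps <- simulate_promoters(60, 200, seed = 52)
  deg <- simulate_deg_table(gene_ids(ps), 10, 2, seed = 53)
  fg <- attr(deg, "foreground")
  pool <- select_background_pool(deg)
  run <- function() suppressWarnings(
    esdeg_enrichment(ps, pwms, fg, pool, err_levels = err_grid(n_levels = 8),
                     n_resamples = 100, seed = 54, verbose = FALSE))
  a <- run(); b <- run()
  expect_identical(a$table, b$table)
  expect_identical(a$levels, b$levels)
  expect_true(all(a$table$p_adj >= a$table$unified_p))

  f <- tempfile(fileext = ".tsv")
  write_enrichment_table(a, f)
  tab <- read.delim(f)
  expect_identical(nrow(tab), 3L)
  expect_true(all(sprintf("z_%02d", 1:8) %in% names(tab)))

  # genes absent from the universe are dropped, not fatal
  expect_message(
    suppressWarnings(esdeg_enrichment(ps, pwms[1], c(fg, "ghost"), pool,
                                      err_levels = err_grid(n_levels = 3),
                                      n_resamples = 50, seed = 55)),
    "dropping")
})
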