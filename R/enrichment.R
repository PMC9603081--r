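#' Site frequency of a motif in a promoter group
#'
#' Default definition (`frequency = "promoter"`): the fraction of
#' promoters in the group carrying at least one hit at or above the
#' threshold. Alternative (`frequency = "window"`): hits per scanned
#' window, averaged over promoters (identical to the pooled rate when all
#' promoters have equal length, as they do in a `promoter_set`).
#'
#' @param pwm a `pwm` object.
#' @param promoters a `promoter_set` (the group).
#' @param threshold score cutoff.
#' @param frequency `"promoter"` or `"window"`.
#' @param both_strands scan both strands (default `TRUE`).
#' @return a frequency in `[0, 1]`.
#' @export
site_frequency <- function(pwm, promoters, threshold,
                           frequency = c("promoter", "window"),
                           both_strands = TRUE) {
  frequency <- match.arg(frequency)
  stopifnot(inherits(promoters, "promoter_set"), length(promoters) >= 1)
  per <- vapply(promoters$sequences, function(s) {
    sc <- promoter_scores(pwm, encode_dna(s), both_strands)
    if (frequency == "promoter") as.numeric(any(sc >= threshold))
    else {
      sc <- sc[is.finite(sc)]
      if (!length(sc)) 0 else mean(sc >= threshold)
    }
  }, numeric(1))
  mean(per)
}

# per-level Z and one-sided p from a foreground frequency and the
# resampled background frequencies; the degenerate SD_BACK == 0 case
# yields p = 1 (not enriched) or the 1/(n+1) resolution floor (enriched)
level_stat <- function(av_for, bg_freqs,
                       alternative = c("greater", "less"),
                       warn_degenerate = TRUE) {
  alternative <- match.arg(alternative)
  av_back <- mean(bg_freqs)
  sd_back <- stats::sd(bg_freqs)
  n <- length(bg_freqs)
  if (sd_back == 0) {
    if (warn_degenerate)
      warning("degenerate background: zero frequency spread at this level")
    delta <- av_for - av_back
    enriched <- if (alternative == "greater") delta > 0 else delta < 0
    z <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (enriched) 1 / (n + 1) else 1
  } else {
    z <- (av_for - av_back) / sd_back
    p <- stats::pnorm(z, lower.tail = (alternative == "less"))
  }
  c(av_for = av_for, av_back = av_back, sd_back = sd_back, z = z, p = p)
}

# hit/rate statistics for one motif over a promoter universe:
# thresholds calibrated on the whole universe, plus the per-promoter
# quantity needed to form group frequencies at every level
motif_level_data <- function(pwm, codes, err_levels, frequency, both_strands) {
  scores <- lapply(codes, function(cd) promoter_scores(pwm, cd, both_strands))
  pooled <- unlist(scores, use.names = FALSE)
  cal <- thresholds_from_scores(pooled, err_levels)
  thr <- cal$threshold
  if (frequency == "promoter") {
    ms <- vapply(scores, function(s) if (length(s)) max(s) else -Inf, numeric(1))
    stat <- outer(ms, thr, `>=`) * 1         # n_promoters x n_levels
  } else {
    stat <- t(vapply(scores, function(s) {
      s <- s[is.finite(s)]
      if (!length(s)) return(numeric(length(thr)))
      vapply(thr, function(t) mean(s >= t), numeric(1))
    }, numeric(length(thr))))
  }
  rownames(stat) <- names(codes)
  list(stat = stat, threshold = thr, realized_err = cal$realized,
       universe_positions = cal$n)
}

#' Monte-Carlo motif enrichment for one motif
#'
#' For each threshold level, compares the foreground site frequency
#' (AV_FOR) with the distribution of frequencies over `n_resamples`
#' background groups, each drawn uniformly without replacement from the
#' background pool and of the same size as the foreground. The Z-score is
#' `(AV_FOR - AV_BACK) / SD_BACK` with `SD_BACK` the sample standard
#' deviation of the resampled frequencies, and the p-value the one-sided
#' upper normal tail (enrichment; set `alternative = "less"` for
#' depletion).
#'
#' @param pwm a `pwm` object.
#' @param foreground,background_pool gene ids within `promoters`; disjoint,
#'   pool at least as large as the foreground.
#' @param promoters a `promoter_set` covering both groups (frequencies are
#'   computed on these promoters; thresholds come from `thresholds`).
#' @param thresholds a `threshold_table` from [calibrate_thresholds()],
#'   or a numeric vector of score thresholds.
#' @param n_resamples number of background groups (default 1000).
#' @param seed RNG seed; results are deterministic given it.
#' @param frequency `"promoter"` (presence fraction, default) or
#'   `"window"` (hits per scanned window).
#' @param both_strands scan both strands (default `TRUE`).
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @return data.frame with one row per level: `level`, `nominal_err`,
#'   `score_threshold`, `av_for`, `av_back`, `sd_back`, `z`, `p`.
#' @export
mc_enrichment <- function(pwm, foreground, background_pool, promoters,
                          thresholds, n_resamples = 1000L, seed = 1L,
                          frequency = c("promoter", "window"),
                          both_strands = TRUE,
                          alternative = c("greater", "less")) {
  frequency <- match.arg(frequency)
  alternative <- match.arg(alternative)
  stopifnot(inherits(promoters, "promoter_set"), n_resamples >= 2)
  check_groups(foreground, background_pool, promoters)
  if (inherits(thresholds, "threshold_table")) {
    err <- thresholds$nominal_err
    thr <- thresholds$score_threshold
  } else {
    thr <- as.numeric(thresholds)
    err <- rep(NA_real_, length(thr))
  }
  set.seed(seed)
  idx <- resample_indices(length(background_pool), length(foreground),
                          n_resamples)
  used <- promoters[c(foreground, background_pool)]
  codes <- lapply(used$sequences, encode_dna)
  scores <- lapply(codes, function(cd) promoter_scores(pwm, cd, both_strands))
  stat <- group_stat(scores, thr, frequency)
  stats_by_level(stat, foreground, background_pool, idx, err, thr,
                 alternative)
}

# per-promoter x per-level statistic from precomputed score vectors
group_stat <- function(scores, thr, frequency) {
  if (frequency == "promoter") {
    ms <- vapply(scores, function(s) if (length(s)) max(s) else -Inf, numeric(1))
    stat <- outer(ms, thr, `>=`) * 1
  } else {
    stat <- t(vapply(scores, function(s) {
      s <- s[is.finite(s)]
      if (!length(s)) return(numeric(length(thr)))
      vapply(thr, function(t) mean(s >= t), numeric(1))
    }, numeric(length(thr))))
  }
  rownames(stat) <- names(scores)
  stat
}

resample_indices <- function(pool_size, group_size, n_resamples) {
  matrix(vapply(seq_len(n_resamples),
                function(i) sample.int(pool_size, group_size, replace = FALSE),
                integer(group_size)),
         nrow = group_size)              # group_size x n_resamples
}

stats_by_level <- function(stat, foreground, background_pool, idx,
                           err, thr, alternative) {
  n_lev <- length(thr)
  fg <- stat[foreground, , drop = FALSE]
  pool <- stat[background_pool, , drop = FALSE]
  out <- vector("list", n_lev)
  degenerate <- FALSE
  for (k in seq_len(n_lev)) {
    av_for <- mean(fg[, k])
    v <- pool[, k]
    bg <- colMeans(matrix(v[idx], nrow = nrow(idx)))
    st <- level_stat(av_for, bg, alternative, warn_degenerate = FALSE)
    if (st[["sd_back"]] == 0) degenerate <- TRUE
    out[[k]] <- st
  }
  if (degenerate)
    warning("zero background frequency spread at one or more levels; ",
            "p set to 1 (not enriched) or the Monte-Carlo floor (enriched)")
  res <- as.data.frame(do.call(rbind, out))
  data.frame(level = seq_len(n_lev), nominal_err = err,
             score_threshold = thr, res, row.names = NULL)
}

check_groups <- function(foreground, background_pool, promoters) {
  if (length(intersect(foreground, background_pool)))
    stop("foreground and background pool overlap")
  missing <- setdiff(c(foreground, background_pool), gene_ids(promoters))
  if (length(missing))
    stop("genes absent from the promoter set: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (length(background_pool) < length(foreground))
    stop("background pool smaller than foreground; relax the pool criteria")
  invisible(TRUE)
}

#' Combine dependent p-values by Hartung's inverse-normal method
#'
#' Each p is transformed to a probit `t_i = qnorm(p_i)`; the inter-statistic
#' correlation is estimated as `rho = 1 - var(t)` (truncated below at
#' `-1/(L-1)`) and the combined statistic is
#' `H = sum(t) / sqrt(L + (L^2 - L) * (rho* + kappa * sqrt(2/(L+1)) * (1 - rho*)))`,
#' giving the unified p `pnorm(H)`. Equal weights are used. With a single
#' p-value the input is returned unchanged. Inputs are clamped to
#' `[1e-300, 1 - 1e-16]` before the probit transform.
#'
#' @param p numeric vector of p-values in (0, 1) (one per threshold level).
#' @param kappa small positive regularisation constant (default 0.2).
#' @return the unified p-value.
#' @export
hartung_combine <- function(p, kappa = 0.2) {
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in (0, 1)")
  if (length(p) == 1L) return(p)
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  t <- stats::qnorm(p)
  L <- length(t)
  rho_hat <- 1 - sum((t - mean(t))^2) / (L - 1)
  rho_star <- max(-1 / (L - 1), rho_hat)
  denom <- L + (L^2 - L) *
    (rho_star + kappa * sqrt(2 / (L + 1)) * (1 - rho_star))
  # guard against tail underflow: unified p stays in (0, 1]
  min(max(stats::pnorm(sum(t) / sqrt(denom)), 1e-300), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction across the motif collection
#' (wraps [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric vector of unified p-values.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Rank an enrichment table
#'
#' Sorts by adjusted p ascending, breaking ties by unified p and then
#' motif id, assigns ranks 1..M, and attaches `-log10(p_adj)` plus a
#' `reported` flag (`p_adj < report_p`) marking rows that belong in the
#' printed table; all rows are retained.
#'
#' @param results data.frame with columns `motif_id`, `unified_p`, `p_adj`.
#' @param report_p report cutoff on `p_adj` (default 0.05).
#' @return the ranked data.frame with `rank`, `minus_log10_p_adj`,
#'   `reported` columns added.
#' @export
rank_motifs <- function(results, report_p = 0.05) {
  stopifnot(all(c("motif_id", "unified_p", "p_adj") %in% names(results)))
  ord <- order(results$p_adj, results$unified_p, results$motif_id)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$minus_log10_p_adj <- -log10(out$p_adj)
  out$reported <- out$p_adj < report_p
  rownames(out) <- NULL
  out
}

#' Motif over-representation in a foreground promoter set
#'
#' The full procedure for a motif collection: for each motif, thresholds
#' are calibrated on the whole promoter universe at the ERR grid, the
#' foreground site frequency at each level is compared against
#' `n_resamples` background groups resampled without replacement from the
#' pool (the same resampled gene sets are used for every motif), per-level
#' one-sided normal p-values are unified across levels with
#' [hartung_combine()], and unified p-values are BH-adjusted over the
#' collection.
#'
#' @param promoters a `promoter_set`: the whole universe (calibration uses
#'   every promoter in it).
#' @param pwms list of `pwm` objects.
#' @param foreground,background_pool gene ids present in `promoters`;
#'   genes missing from the universe are dropped with a message.
#' @param err_levels ERR grid (default [err_grid()]).
#' @param n_resamples background groups per motif (default 1000).
#' @param seed RNG seed; all randomness derives from it.
#' @param frequency `"promoter"` or `"window"` site-frequency definition.
#' @param both_strands scan both strands (default `TRUE`).
#' @param alternative `"greater"` (enrichment) or `"less"` (depletion).
#' @param kappa Hartung regularisation constant.
#' @param report_p report cutoff passed to [rank_motifs()].
#' @param verbose log group sizes and dropped genes (default `TRUE`).
#' @return an `esdeg_result`: list with `table` (ranked data.frame:
#'   `rank`, `motif_id`, `unified_p`, `p_adj`, `minus_log10_p_adj`,
#'   `reported`), `levels` (named list of per-level stat data.frames, one
#'   per motif), and the run parameters.
#' @export
esdeg_enrichment <- function(promoters, pwms, foreground, background_pool,
                             err_levels = err_grid(), n_resamples = 1000L,
                             seed = 1L, frequency = c("promoter", "window"),
                             both_strands = TRUE,
                             alternative = c("greater", "less"),
                             kappa = 0.2, report_p = 0.05, verbose = TRUE) {
  frequency <- match.arg(frequency)
  alternative <- match.arg(alternative)
  stopifnot(inherits(promoters, "promoter_set"), length(pwms) >= 1,
            n_resamples >= 2)
  universe <- gene_ids(promoters)
  drop_fg <- setdiff(foreground, universe)
  drop_bg <- setdiff(background_pool, universe)
  if (length(drop_fg) || length(drop_bg))
    esdeg_log("dropping genes without promoters: ", length(drop_fg),
              " foreground, ", length(drop_bg), " pool", verbose = verbose)
  foreground <- intersect(foreground, universe)
  background_pool <- intersect(background_pool, universe)
  if (!length(foreground)) stop("empty foreground after intersection with universe")
  check_groups(foreground, background_pool, promoters)
  esdeg_log("foreground: ", length(foreground), " promoters; pool: ",
            length(background_pool), "; universe: ", length(universe),
            "; motifs: ", length(pwms), verbose = verbose)

  set.seed(seed)
  idx <- resample_indices(length(background_pool), length(foreground),
                          n_resamples)
  codes <- lapply(promoters$sequences, encode_dna)

  ids <- vapply(pwms, `[[`, character(1), "motif_id")
  if (anyDuplicated(ids)) stop("duplicate motif ids in collection")
  levels_out <- vector("list", length(pwms))
  unified <- numeric(length(pwms))
  for (m in seq_along(pwms)) {
    ld <- motif_level_data(pwms[[m]], codes, err_levels, frequency,
                           both_strands)
    lev <- stats_by_level(ld$stat, foreground, background_pool, idx,
                          err_levels, ld$threshold, alternative)
    lev$realized_err <- ld$realized_err
    levels_out[[m]] <- lev
    unified[m] <- hartung_combine(lev$p, kappa = kappa)
  }
  names(levels_out) <- ids
  tab <- data.frame(motif_id = ids, unified_p = unified,
                    p_adj = bh_adjust(unified), stringsAsFactors = FALSE)
  tab <- rank_motifs(tab, report_p = report_p)
  structure(list(table = tab, levels = levels_out,
                 params = list(err_levels = err_levels,
                               n_resamples = n_resamples, seed = seed,
                               frequency = frequency,
                               both_strands = both_strands,
                               alternative = alternative, kappa = kappa,
                               report_p = report_p,
                               n_foreground = length(foreground),
                               n_pool = length(background_pool),
                               n_universe = length(universe))),
            class = "esdeg_result")
}

#' @export
print.esdeg_result <- function(x, ...) {
  cat(sprintf(
    "esdeg enrichment: %d motifs, foreground %d vs pool %d (universe %d), %d resamples\n",
    nrow(x$table), x$params$n_foreground, x$params$n_pool,
    x$params$n_universe, x$params$n_resamples))
  rep <- x$table[x$table$reported, c("rank", "motif_id",
                                     "minus_log10_p_adj", "unified_p")]
  if (nrow(rep)) {
    cat(sprintf("%d motif(s) with p_adj < %g:\n", nrow(rep), x$params$report_p))
    print(rep, row.names = FALSE, digits = 4)
  } else {
    cat(sprintf("no motif reaches p_adj < %g\n", x$params$report_p))
  }
  invisible(x)
}

#' Write an enrichment result as TSV
#'
#' Wide format: one row per motif with rank, `-log10(p_adj)`, unified p,
#' adjusted p, and the per-level Z-scores as columns `z_01`, `z_02`, ...
#'
#' @param x an `esdeg_result`.
#' @param path output path.
#' @param reported_only write only rows below the report cutoff.
#' @return invisibly, `path`.
#' @export
write_enrichment_table <- function(x, path, reported_only = FALSE) {
  stopifnot(inherits(x, "esdeg_result"))
  tab <- x$table
  zmat <- t(vapply(x$levels[tab$motif_id], function(l) l$z,
                   numeric(nrow(x$levels[[1]]))))
  colnames(zmat) <- sprintf("z_%02d", seq_len(ncol(zmat)))
  out <- cbind(tab[c("rank", "motif_id", "minus_log10_p_adj", "unified_p",
                     "p_adj", "reported")], as.data.frame(zmat))
  if (reported_only) out <- out[out$reported, , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
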