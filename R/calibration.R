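#' Grid of expected recognition rates
#'
#' Log-equidistant grid of expected recognition rates (ERRs) from
#' `err_max` down to `err_min`, endpoints included. The defaults give the
#' 30 levels from 5e-4 to 1e-4 used throughout the package.
#'
#' @param err_max,err_min grid endpoints, `0 < err_min < err_max <= 1`.
#' @param n_levels number of levels, at least 2.
#' @return numeric vector of length `n_levels`, strictly decreasing, with
#'   a constant ratio between consecutive values.
#' @export
err_grid <- function(err_max = 5e-4, err_min = 1e-4, n_levels = 30L) {
  if (!(err_min > 0 && err_min < err_max && err_max <= 1))
    stop("need 0 < err_min < err_max <= 1")
  if (n_levels < 2L) stop("need at least 2 grid levels")
  g <- exp(seq(log(err_max), log(err_min), length.out = n_levels))
  g[1] <- err_max
  g[n_levels] <- err_min
  g
}

# thresholds from a pooled score vector (N windows already -Inf):
# for each nominal err e, the smallest score t with
# #{scores >= t} / n <= e, realized err being that fraction.
# Ties at t all count as hits; if even the top score exceeds the budget,
# the threshold is +Inf with realized err 0.
thresholds_from_scores <- function(scores, err_levels) {
  scores <- scores[is.finite(scores)]
  n <- length(scores)
  if (n == 0L) stop("no scorable windows in the universe")
  s <- sort(scores, decreasing = TRUE)
  r <- rle(s)
  cum <- cumsum(r$lengths)           # #{scores >= r$values[j]}
  thr <- numeric(length(err_levels))
  realized <- numeric(length(err_levels))
  for (k in seq_along(err_levels)) {
    budget <- err_levels[k] * n * (1 + 1e-12)
    j <- findInterval(budget, cum)   # largest j with cum[j] <= budget
    if (j == 0L) {
      thr[k] <- Inf
      realized[k] <- 0
    } else {
      thr[k] <- r$values[j]
      realized[k] <- cum[j] / n
    }
  }
  list(threshold = thr, realized = realized, n = n)
}

#' Calibrate motif score thresholds on the promoter universe
#'
#' Scans every promoter of the universe (both strands by default), pools
#' all window scores, and for each ERR level picks the smallest score
#' threshold whose realized recognition rate does not exceed the nominal
#' level. Windows containing N are excluded from both numerator and
#' denominator.
#'
#' @param pwm a `pwm` object.
#' @param promoters a `promoter_set`: the scanning universe.
#' @param err_levels decreasing ERR grid, see [err_grid()].
#' @param both_strands scan both strands (default `TRUE`).
#' @return a `threshold_table`: data.frame with columns `motif_id`,
#'   `level`, `nominal_err`, `score_threshold`, `realized_err`, with the
#'   number of scored windows in attribute `universe_positions`.
#' @export
calibrate_thresholds <- function(pwm, promoters, err_levels = err_grid(),
                                 both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm"), inherits(promoters, "promoter_set"))
  if (pwm$length > nchar(promoters$sequences[[1]]))
    stop("motif ", pwm$motif_id, " is longer than the promoters")
  codes <- lapply(promoters$sequences, encode_dna)
  pooled <- unlist(lapply(codes, function(cd)
    promoter_scores(pwm, cd, both_strands)), use.names = FALSE)
  res <- thresholds_from_scores(pooled, err_levels)
  out <- data.frame(motif_id = pwm$motif_id,
                    level = seq_along(err_levels),
                    nominal_err = err_levels,
                    score_threshold = res$threshold,
                    realized_err = res$realized,
                    stringsAsFactors = FALSE)
  attr(out, "universe_positions") <- res$n
  class(out) <- c("threshold_table", "data.frame")
  out
}

#' Write a threshold table as TSV
#'
#' @param x a `threshold_table` (or several row-bound together).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_threshold_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
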