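#' Read a flat key = value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment; values that look
#' numeric are coerced. Keys mirror the arguments of [run_pipeline()].
#'
#' @param path path to the config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- lapply(kv, function(m) {
    v <- trimws(gsub('^"|"$', "", trimws(m[3])))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num) && grepl("^[-+0-9.eE]+$", v)) num else v
  })
  names(vals) <- vapply(kv, `[`, character(1), 2)
  vals
}

default_pipeline_params <- function() {
  list(direction = "both", p_max = 0.1, min_fold = 2.0,
       pool_p_min = 0.1, pool_fold_low = 0.80, pool_fold_high = 1.25,
       err_max = 5e-4, err_min = 1e-4, levels = 30, resamples = 1000,
       seed = 1, frequency = "promoter", both_strands = TRUE,
       motif_format = "hocomoco_pcm", report_p = 0.05,
       similarity_n_perm = 1000, upstream = 2000, downstream = 1)
}

#' Run the full enrichment pipeline
#'
#' Wires the stages together: read promoters (FASTA, or genome FASTA plus
#' TSS table), parse and convert motifs, read the DEG table, select
#' foreground and background pool, run the Monte-Carlo enrichment for the
#' requested direction(s), compute the pairwise similarity matrix of the
#' reported motifs, and write everything plus a run manifest into
#' `out_dir`.
#'
#' @param config named list of parameters, or path to a `key = value`
#'   config file ([read_run_config()]). Required keys: `motifs`,
#'   `deg_table`, and either `promoters` (FASTA) or `genome` + `tss_table`.
#'   Optional keys and their defaults: `direction` ("both"), `p_max` (0.1),
#'   `min_fold` (2.0), `pool_p_min` (0.1), `pool_fold_low` (0.80),
#'   `pool_fold_high` (1.25), `err_max` (5e-4), `err_min` (1e-4),
#'   `levels` (30), `resamples` (1000), `seed` (1), `frequency`
#'   ("promoter"), `both_strands` (TRUE), `motif_format` ("hocomoco_pcm"),
#'   `report_p` (0.05), `similarity_n_perm` (1000), `upstream` (2000),
#'   `downstream` (1).
#' @param out_dir output directory (created if needed).
#' @param overrides named list applied on top of the config (CLI flags).
#' @param verbose log progress to stderr.
#' @return invisibly, a list with the per-direction results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, overrides = list(),
                         verbose = TRUE) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  params <- utils::modifyList(default_pipeline_params(), config)
  params <- utils::modifyList(params, overrides)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- character()
  promoters <- stage("promoters", {
    if (!is.null(params$promoters)) {
      inputs["promoters"] <- params$promoters
      promoters_from_fasta(params$promoters)
    } else if (!is.null(params$genome) && !is.null(params$tss_table)) {
      inputs["genome"] <- params$genome
      inputs["tss_table"] <- params$tss_table
      extract_promoters(read_fasta(params$genome),
                        read_tss_table(params$tss_table),
                        upstream = params$upstream,
                        downstream = params$downstream)
    } else stop("config must name 'promoters', or 'genome' and 'tss_table'")
  })
  pwms <- stage("motifs", {
    if (is.null(params$motifs)) stop("config must name 'motifs'")
    inputs["motifs"] <- params$motifs
    pcms <- parse_motif_library(params$motifs, format = params$motif_format)
    if (!is.null(params$motif_exclude)) {
      excl <- readLines(params$motif_exclude, warn = FALSE)
      pcms <- filter_motifs(pcms, exclude = excl)
    }
    lapply(pcms, pcm_to_pwm)
  })
  deg <- stage("deg_table", {
    if (is.null(params$deg_table)) stop("config must name 'deg_table'")
    inputs["deg_table"] <- params$deg_table
    read_deg_table(params$deg_table)
  })

  directions <- if (identical(params$direction, "both")) c("up", "down")
                else params$direction
  err_levels <- err_grid(params$err_max, params$err_min, params$levels)
  results <- list()
  outputs <- character()
  for (dir in directions) {
    res <- stage(paste0("enrichment_", dir), {
      fg <- select_foreground(deg, p_max = params$p_max,
                              min_fold = params$min_fold, direction = dir)
      if (!length(fg)) stop("empty ", dir, " foreground under the given cutoffs")
      pool <- select_background_pool(deg, p_min = params$pool_p_min,
                                     fold_low = params$pool_fold_low,
                                     fold_high = params$pool_fold_high,
                                     foreground = fg)
      esdeg_enrichment(promoters, pwms, fg, pool, err_levels = err_levels,
                       n_resamples = as.integer(params$resamples),
                       seed = as.integer(params$seed),
                       frequency = params$frequency,
                       both_strands = isTRUE(params$both_strands) ||
                         identical(params$both_strands, "TRUE"),
                       report_p = params$report_p, verbose = verbose)
    })
    f_full <- file.path(out_dir, paste0(dir, "_enrichment.tsv"))
    f_top <- file.path(out_dir, paste0(dir, "_enrichment_top.tsv"))
    write_enrichment_table(res, f_full)
    write_enrichment_table(res, f_top, reported_only = TRUE)
    outputs <- c(outputs, f_full, f_top)
    rep_ids <- res$table$motif_id[res$table$reported]
    if (length(rep_ids) >= 2) {
      sim <- stage(paste0("similarity_", dir), {
        similarity_matrix(pwms[match(rep_ids,
                                     vapply(pwms, `[[`, character(1), "motif_id"))],
                          n_perm = as.integer(params$similarity_n_perm),
                          seed = as.integer(params$seed))
      })
      f_sim <- file.path(out_dir, paste0(dir, "_similarity.tsv"))
      write_similarity_matrix(sim, f_sim)
      outputs <- c(outputs, f_sim)
      results[[dir]] <- list(enrichment = res, similarity = sim)
    } else {
      results[[dir]] <- list(enrichment = res, similarity = NULL)
    }
  }

  manifest <- list(
    tool = "esdeg",
    version = as.character(utils::packageVersion("esdeg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(stats::setNames(tools::md5sum(inputs),
                                     basename(inputs))),
    parameters = params[order(names(params))],
    outputs = as.list(stats::setNames(tools::md5sum(outputs),
                                      basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  esdeg_log("pipeline complete: ", out_dir, verbose = verbose)
  invisible(list(results = results, manifest = manifest, out_dir = out_dir))
}
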