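#' Construct a promoter set
#'
#' A promoter set holds one fixed-length sequence per gene: the scanning
#' universe used both for threshold calibration and for enrichment. All
#' sequences must have equal length and gene ids must be unique.
#'
#' @param sequences named character vector of uppercase DNA sequences
#'   (A/C/G/T/N); names are gene ids.
#' @param coords optional data.frame with columns `gene_id`, `chrom`,
#'   `strand`, `window_start`, `window_end` (0-based, half-open genomic
#'   coordinates), one row per sequence.
#' @return an object of class `promoter_set`.
#' @export
promoter_set <- function(sequences, coords = NULL) {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all sequences must be named by gene id")
  if (anyDuplicated(ids))
    stop("duplicate gene ids in promoter set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("all promoter sequences must have equal length; saw lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("non-ACGTN characters in sequences of: ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    need <- c("gene_id", "chrom", "strand", "window_start", "window_end")
    if (!all(need %in% names(coords)))
      stop("coords must have columns: ", paste(need, collapse = ", "))
    if (!identical(sort(as.character(coords$gene_id)), sort(ids)))
      stop("coords gene ids must match sequence names")
    coords <- coords[match(ids, coords$gene_id), , drop = FALSE]
    rownames(coords) <- NULL
  }
  structure(list(sequences = sequences, coords = coords),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d promoters of length %d bp%s\n",
              length(x$sequences), nchar(x$sequences[[1]]),
              if (is.null(x$coords)) "" else " (with genomic coordinates)"))
  invisible(x)
}

#' @export
length.promoter_set <- function(x) length(x$sequences)

#' Gene ids of a promoter set
#' @param x a `promoter_set`.
#' @return character vector of gene ids.
#' @export
gene_ids <- function(x) {
  stopifnot(inherits(x, "promoter_set"))
  names(x$sequences)
}

#' Subset a promoter set by gene id or index
#' @param x a `promoter_set`.
#' @param i gene ids or indices.
#' @param ... ignored.
#' @return a `promoter_set` with the selected records.
#' @export
`[.promoter_set` <- function(x, i, ...) {
  seqs <- x$sequences[i]
  if (anyNA(names(seqs)) || anyNA(seqs))
    stop("unknown gene ids in promoter_set subset")
  coords <- if (!is.null(x$coords))
    x$coords[match(names(seqs), x$coords$gene_id), , drop = FALSE]
  promoter_set(seqs, coords)
}

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @param non_acgt how to treat characters outside A/C/G/T/N: map them to
#'   `"N"` (default) or raise an `"error"`.
#' @return named character vector of uppercase sequences, in file order;
#'   ids are the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path, non_acgt = c("N", "error")) {
  non_acgt <- match.arg(non_acgt)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyNA(ids) || any(ids == ""))
    stop("malformed FASTA header (empty id) in ", path)
  has_other <- grepl("[^ACGTN]", seqs)
  if (any(has_other)) {
    if (non_acgt == "error")
      stop("non-ACGTN characters in records: ",
           paste(utils::head(ids[has_other], 5), collapse = ", "))
    seqs[has_other] <- gsub("[^ACGTN]", "N", seqs[has_other])
  }
  names(seqs) <- ids
  seqs
}

#' Read promoters from FASTA into a promoter set
#'
#' @inheritParams read_fasta
#' @return a `promoter_set`.
#' @export
promoters_from_fasta <- function(path, non_acgt = c("N", "error")) {
  promoter_set(read_fasta(path, non_acgt))
}

#' Read a TSS table
#'
#' Tab-separated file with header columns `gene_id`, `chrom`, `strand`,
#' `tss`. A minimal interchange format: one transcription start site per
#' gene (alternative transcripts are expected to have been collapsed
#' upstream, or are collapsed by [extract_promoters()] keeping the first
#' occurrence).
#'
#' @param path path to the TSV file.
#' @return data.frame with the four columns.
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) stop("TSS table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(tab)))
    stop("TSS table must have header columns: ", paste(need, collapse = ", "))
  tab[need]
}

#' Extract promoter windows around transcription start sites
#'
#' Builds the fixed-width promoter universe: for each gene, the window
#' covering `upstream` bases before the TSS plus `downstream` bases from
#' the TSS onwards (defaults 2000 and 1, i.e. the (-2000; +1) window of
#' length 2001 including the TSS base). Coordinates are 0-based half-open
#' internally; set `tss_base = "one"` for 1-based TSS input.
#'
#' For a + strand gene the genomic window is `[tss - upstream,
#' tss + downstream)`. For a − strand gene it is
#' `[tss - downstream + 1, tss + upstream + 1)` and the sequence is
#' reverse-complemented, so position 0 of every returned promoter is its
#' most upstream base.
#'
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param tss_table data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tss`.
#' @param upstream,downstream window extent in bases; `upstream >= 0`,
#'   `downstream >= 1`.
#' @param tss_base `"zero"` (default) or `"one"`: coordinate convention of
#'   the `tss` column.
#' @return a `promoter_set` with genomic coordinates attached. Genes whose
#'   window runs off the chromosome are dropped with a warning; duplicate
#'   gene ids keep the first occurrence.
#' @export
extract_promoters <- function(genome, tss_table,
                              upstream = 2000L, downstream = 1L,
                              tss_base = c("zero", "one")) {
  tss_base <- match.arg(tss_base)
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  stopifnot(is.character(genome), !is.null(names(genome)))
  genome <- toupper(genome)
  tab <- as.data.frame(tss_table)
  need <- c("gene_id", "chrom", "strand", "tss")
  stopifnot(all(need %in% names(tab)))
  if (upstream < 0 || downstream < 1)
    stop("need upstream >= 0 and downstream >= 1")
  if (any(!tab$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(tab$tss < ifelse(tss_base == "one", 1, 0)))
    stop("negative TSS coordinate for gene(s): ",
         paste(tab$gene_id[tab$tss < ifelse(tss_base == "one", 1, 0)],
               collapse = ", "))
  unknown <- setdiff(unique(tab$chrom), names(genome))
  if (length(unknown))
    stop("unknown chromosome(s) ", paste(unknown, collapse = ", "),
         " for gene(s): ",
         paste(tab$gene_id[tab$chrom %in% unknown], collapse = ", "))

  dup <- duplicated(tab$gene_id)
  if (any(dup)) {
    esdeg_log(sum(dup), " duplicate gene id(s) in TSS table; keeping first occurrence")
    tab <- tab[!dup, , drop = FALSE]
  }
  tss0 <- if (tss_base == "one") tab$tss - 1L else tab$tss
  plus <- tab$strand == "+"
  start <- ifelse(plus, tss0 - upstream, tss0 - downstream + 1L)
  end   <- ifelse(plus, tss0 + downstream, tss0 + upstream + 1L)
  chr_len <- nchar(genome)[tab$chrom]
  ok <- start >= 0 & end <= chr_len
  if (any(!ok)) {
    warning(sum(!ok), " gene(s) dropped: promoter window outside chromosome bounds (",
            paste(utils::head(tab$gene_id[!ok], 5), collapse = ", "), ")")
    tab <- tab[ok, , drop = FALSE]
    start <- start[ok]; end <- end[ok]
  }
  if (nrow(tab) == 0L) stop("no promoters could be extracted")
  seqs <- substr(genome[tab$chrom], start + 1L, end)
  minus <- tab$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp_dna(seqs[minus])
  names(seqs) <- tab$gene_id
  promoter_set(seqs, coords = data.frame(
    gene_id = tab$gene_id, chrom = tab$chrom, strand = tab$strand,
    window_start = start, window_end = end, stringsAsFactors = FALSE))
}

#' Write a promoter set to FASTA (and optionally BED6)
#'
#' @param x a `promoter_set`.
#' @param fasta_path output FASTA path.
#' @param bed_path optional output BED6 path (requires coordinates;
#'   columns chrom, start, end, gene_id, score 0, strand).
#' @return invisibly, `fasta_path`.
#' @export
write_promoter_set <- function(x, fasta_path, bed_path = NULL) {
  stopifnot(inherits(x, "promoter_set"))
  set <- Biostrings::DNAStringSet(x$sequences)
  Biostrings::writeXStringSet(set, fasta_path)
  if (!is.null(bed_path)) {
    if (is.null(x$coords))
      stop("promoter set has no coordinates; cannot write BED")
    bed <- data.frame(x$coords$chrom, x$coords$window_start,
                      x$coords$window_end, x$coords$gene_id, 0L,
                      x$coords$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_path)
}
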