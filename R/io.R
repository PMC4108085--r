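# Readers/writers for the plain-text formats the pipeline exchanges.
# All genomic coordinates are 0-based half-open, matching BED.

#' Read a genome from FASTA
#'
#' @param path FASTA file (gzip accepted).
#' @return Named character vector of uppercase sequences.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) abort(paste0("no sequences in FASTA: ", path))
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(out))) abort("duplicate sequence names in FASTA")
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a BED file into a tibble
#'
#' Reads BED3/BED6 (0-based half-open) into `chrom`, `start`, `end` plus
#' `name`, `score`, `strand` when present.
#'
#' @param path BED file (gzip accepted).
#' @return Tibble of intervals.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  df <- suppressWarnings(read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                                  comment = "#", progress = FALSE))
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  names(df) <- cols[seq_len(min(ncol(df), 6L))]
  df <- df |> mutate(start = as.integer(.data$start), end = as.integer(.data$end))
  validate_intervals(df, arg = basename(path))
  as_tibble(df)
}

#' Write intervals to BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  readr::write_tsv(intervals[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' Accepts either a refGene-style TSV (columns `name`, `chrom`, `strand`,
#' `txStart`, `txEnd`, `exonStarts`, `exonEnds`, the last two
#' comma-separated) or BED12. Both are 0-based half-open.
#'
#' @param path Gene model file.
#' @return Tibble with `name`, `chrom`, `strand`, `txStart`, `txEnd` and
#'   list-columns `exon_starts`, `exon_ends`.
#' @export
read_genes <- function(path) {
  first <- readLines(path, n = 1L)
  nfield <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (grepl("txStart", first)) {
    df <- read_tsv(path, show_col_types = FALSE, progress = FALSE,
                   col_types = cols(exonStarts = col_character(),
                                    exonEnds = col_character(),
                                    .default = readr::col_guess()))
    genes <- tibble(
      name = as.character(df$name), chrom = df$chrom, strand = df$strand,
      txStart = as.integer(df$txStart), txEnd = as.integer(df$txEnd),
      exon_starts = map(strsplit(as.character(df$exonStarts), ","), as.integer),
      exon_ends = map(strsplit(as.character(df$exonEnds), ","), as.integer)
    )
  } else if (nfield >= 12) {
    df <- read_tsv(path, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
    sizes <- map(strsplit(as.character(df$X11), ","), as.integer)
    offs <- map(strsplit(as.character(df$X12), ","), as.integer)
    genes <- tibble(
      name = as.character(df$X4), chrom = df$X1, strand = df$X6,
      txStart = as.integer(df$X2), txEnd = as.integer(df$X3),
      exon_starts = map2(offs, as.integer(df$X2), ~ .x + .y),
      exon_ends = pmap(list(offs, sizes, as.integer(df$X2)),
                       function(o, s, t) o + s + t)
    )
  } else {
    abort("gene model file is neither refGene-style TSV nor BED12")
  }
  validate_genes(genes)
}

#' Write gene models as refGene-style TSV
#'
#' @param genes Gene tibble as returned by [read_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  out <- genes |>
    mutate(exonStarts = map_chr(.data$exon_starts, paste, collapse = ","),
           exonEnds = map_chr(.data$exon_ends, paste, collapse = ",")) |>
    select("name", "chrom", "strand", "txStart", "txEnd", "exonStarts", "exonEnds")
  write_tsv(out, path, progress = FALSE)
  invisible(path)
}

validate_genes <- function(genes) {
  stopifnot(all(genes$strand %in% c("+", "-")))
  ok <- pmap(list(genes$exon_starts, genes$exon_ends, genes$txStart, genes$txEnd),
             function(s, e, t0, t1) {
               length(s) == length(e) && all(s < e) && all(s >= t0) &&
                 all(e <= t1) && !is.unsorted(s) && all(head(e, -1) <= tail(s, -1))
             })
  if (!all(unlist(ok))) abort("invalid exon structure in gene models")
  genes
}

#' Read MSCC reads from FASTQ
#'
#' @param path FASTQ file (gzip accepted).
#' @return Tibble with `id` and `seq`.
#' @export
read_mscc_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(id = sub("\\s.*$", "", names(x)), seq = as.character(x))
}

#' Write MSCC reads to FASTQ
#'
#' Qualities are constant dummies; MSCC tag matching does not use them.
#'
#' @param reads Tibble with `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mscc_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq", compress = grepl("\\.gz$", path),
    qualities = Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  )
  invisible(path)
}
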