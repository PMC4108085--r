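# Virtual HpaII/MspI digestion: CCGG site enumeration and the MmeI 18-bp
# tag library. Both isoschizomers recognise CCGG and cut C^CGG; MmeI then
# releases a fixed-length genomic tag from the adaptor-ligated end, so each
# CCGG site is represented by (up to) two 18-mers, one per side of the cut.

#' Enumerate CCGG sites in a genome
#'
#' Scans every chromosome for occurrences of the HpaII/MspI recognition
#' sequence CCGG. `pos` is the 0-based coordinate of the first C on the
#' forward strand; the site is strand-symmetric (CCGG is palindromic).
#'
#' @param genome Named character vector of sequences (see [read_genome()]).
#' @return Tibble with `site_id` (dense, sorted by chrom then pos),
#'   `chrom`, `pos`.
#' @export
find_ccgg_sites <- function(genome) {
  stopifnot(length(genome) > 0, !is.null(names(genome)))
  hits <- imap(genome[order(names(genome))], function(seq, ch) {
    m <- Biostrings::matchPattern("CCGG", Biostrings::DNAString(seq))
    tibble(chrom = ch, pos = BiocGenerics::start(m) - 1L)
  })
  out <- list_rbind(hits) |> arrange(.data$chrom, .data$pos)
  out$site_id <- seq_len(nrow(out))
  out[, c("site_id", "chrom", "pos")]
}

#' Build the MmeI tag library for a set of CCGG sites
#'
#' For a site whose first C sits at 0-based position `p`, the cut C^CGG
#' leaves a fragment starting at `p + 1`, so the forward-side tag is
#' `[p + 1, p + 1 + tag_length)`. By palindromy the opposite-side tag is the
#' reverse complement of `[p + 3 - tag_length, p + 3)`. Both tags begin
#' with "CGG". Tags that would extend past a chromosome end are omitted for
#' that side; tags observed at more than one (site, side) pair are moved to
#' the ambiguous set and excluded from matching entirely.
#'
#' @param genome Named character vector of sequences.
#' @param sites Output of [find_ccgg_sites()] on the same genome.
#' @param tag_length Tag length in bp (MmeI's 18/20 heterogeneity is
#'   collapsed to a fixed 18).
#' @return Object of class `mscc_tag_library`: list with `tags` (tibble
#'   `tag`, `site_id`, `side`), `ambiguous` (character), `standards`
#'   (tibble `tag`, `library`), `tag_length`.
#' @export
build_tag_library <- function(genome, sites, tag_length = 18L) {
  stopifnot(tag_length >= 4L)
  chrom_len <- setNames(nchar(genome), names(genome))
  len <- chrom_len[sites$chrom]
  seqs <- genome[sites$chrom]
  p <- sites$pos

  fwd_ok <- p + 1L + tag_length <= len
  fwd <- tibble(
    tag = str_sub(seqs, p + 2L, p + 1L + tag_length),
    site_id = sites$site_id, side = "fwd"
  )[fwd_ok, ]

  rev_ok <- p + 3L - tag_length >= 0L
  rev_ctx <- str_sub(seqs, p + 4L - tag_length, p + 3L)
  rev <- tibble(
    tag = revcomp(rev_ctx), site_id = sites$site_id, side = "rev"
  )[rev_ok, ]

  all_tags <- bind_rows(fwd, rev) |> arrange(.data$site_id, .data$side)
  dup <- unique(all_tags$tag[duplicated(all_tags$tag)])
  structure(
    list(
      tags = all_tags[!all_tags$tag %in% dup, ],
      ambiguous = sort(dup),
      standards = tibble(tag = character(), library = character()),
      tag_length = as.integer(tag_length)
    ),
    class = "mscc_tag_library"
  )
}

#' @export
print.mscc_tag_library <- function(x, ...) {
  cat("<mscc_tag_library> ", nrow(x$tags), " usable tags (",
      length(x$ambiguous), " ambiguous, ", nrow(x$standards),
      " spike-in standards), tag length ", x$tag_length, "\n", sep = "")
  invisible(x)
}

#' Attach spike-in standard tags to a tag library
#'
#' Standard DNA is modelled as one dedicated tag set per library
#' (HpaII and inverse); matched standard reads are routed to spike-in
#' counts instead of the site count table.
#'
#' @param tag_library An `mscc_tag_library`.
#' @param n_per_library Number of standard tags per library.
#' @param seed Integer seed for tag generation.
#' @return The tag library with `standards` filled in.
#' @export
add_standard_tags <- function(tag_library, n_per_library = 4L, seed = 1L) {
  set.seed(seed)
  used <- c(tag_library$tags$tag, tag_library$ambiguous)
  std <- character(0)
  while (length(std) < 2L * n_per_library) {
    cand <- paste(sample(c("A", "C", "G", "T"), tag_library$tag_length,
                         replace = TRUE), collapse = "")
    if (!cand %in% used && !cand %in% std) std <- c(std, cand)
  }
  tag_library$standards <- tibble(
    tag = std,
    library = rep(c("hpaii", "inverse"), each = n_per_library)
  )
  tag_library
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
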