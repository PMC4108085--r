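# Demultiplexing and mismatch-tolerant tag matching. The search is a
# hash lookup over the tag library plus single-substitution neighbour
# enumeration; at toy-genome scale this is exact and fast, so no aligner
# heuristics are needed.

#' Demultiplex reads by library index
#'
#' Splits reads into (sample, library) streams by exact match of the read
#' prefix against the index table; any other prefix is unassigned.
#'
#' @param reads Tibble with `id`, `seq` (see [read_mscc_fastq()]).
#' @param index_table Tibble with `index`, `sample`, `library`; indices
#'   must be unique and of equal length.
#' @return Tibble of assigned reads (`sample`, `library`, `tag` = the read
#'   minus its index) with attributes `unassigned` (count) and `total`.
#' @export
demultiplex <- function(reads, index_table) {
  lens <- unique(nchar(index_table$index))
  if (length(lens) != 1) {
    abort("index table has ragged index lengths; all indices must match")
  }
  if (anyDuplicated(index_table$index)) abort("index sequences must be unique")
  prefix <- str_sub(reads$seq, 1L, lens)
  hit <- match(prefix, index_table$index)
  out <- tibble(
    sample = index_table$sample[hit],
    library = index_table$library[hit],
    tag = str_sub(reads$seq, lens + 1L, -1L)
  )[!is.na(hit), ]
  attr(out, "unassigned") <- sum(is.na(hit))
  attr(out, "total") <- nrow(reads)
  out
}

#' Match one tag against the tag library
#'
#' Searches mismatch tiers 0..`max_mismatch` in order and accepts only if
#' exactly one library tag (site or spike-in standard) matches at the
#' lowest non-empty tier; otherwise the rejection reason is `no_hit` or
#' `ambiguous`. Non-ACGT bases simply never match, i.e. they count as a
#' mismatch at their position.
#'
#' @param read_tag Character tag of the library's tag length.
#' @param tag_library An `mscc_tag_library`.
#' @param max_mismatch Maximum substitutions tolerated (default 1,
#'   i.e. fewer than 2 mismatches; set 2 for the permissive reading).
#' @return One-row tibble: `status` (`site`, `standard` or rejection
#'   reason), `site_id`, `side`, `std_library`, `mismatches`.
#' @export
match_tag <- function(read_tag, tag_library, max_mismatch = 1L) {
  res <- match_tags_vec(read_tag, tag_library, max_mismatch)
  res
}

# Vectorised matcher over a character vector of tags.
match_tags_vec <- function(tags, tag_library, max_mismatch = 1L) {
  lib <- tag_library$tags
  std <- tag_library$standards
  if (nrow(lib) + nrow(std) == 0) abort("empty tag library")
  all_tags <- c(lib$tag, std$tag)
  is_std <- c(rep(FALSE, nrow(lib)), rep(TRUE, nrow(std)))
  L <- tag_library$tag_length

  out <- tibble(status = rep("no_hit", length(tags)),
                site_id = NA_integer_, side = NA_character_,
                std_library = NA_character_, mismatches = NA_integer_)
  fill <- function(out, i, ref) {
    std_hit <- is_std[ref]
    out$status[i] <- ifelse(std_hit, "standard", "site")
    out$site_id[i[!std_hit]] <- lib$site_id[ref[!std_hit]]
    out$side[i[!std_hit]] <- lib$side[ref[!std_hit]]
    out$std_library[i[std_hit]] <- std$library[ref[std_hit] - nrow(lib)]
    out
  }

  # tier 0: exact (library tags are unique, so a hit is unique)
  exact <- match(tags, all_tags)
  hit0 <- !is.na(exact)
  if (any(hit0)) {
    out <- fill(out, which(hit0), exact[hit0])
    out$mismatches[hit0] <- 0L
  }
  todo <- which(!hit0)
  if (max_mismatch >= 1L && length(todo) > 0) {
    q <- tags[todo]
    hits <- vector("list", length(q))
    for (pos in seq_len(L)) {
      left <- str_sub(q, 1L, pos - 1L)
      right <- str_sub(q, pos + 1L, L)
      orig <- str_sub(q, pos, pos)
      for (b in BASES) {
        cand <- paste0(left, b, right)
        m <- match(cand, all_tags)
        ok <- which(!is.na(m) & b != orig)
        for (j in ok) hits[[j]] <- c(hits[[j]], m[j])
      }
    }
    nhit <- lengths(lapply(hits, unique))
    uniq <- which(nhit == 1L)
    if (length(uniq) > 0) {
      refs <- vapply(hits[uniq], function(h) unique(h)[1], integer(1))
      out <- fill(out, todo[uniq], refs)
      out$mismatches[todo[uniq]] <- 1L
    }
    out$status[todo[nhit > 1L]] <- "ambiguous"
    todo <- todo[nhit == 0L]
  }
  if (max_mismatch >= 2L && length(todo) > 0) {
    ref_mat <- matrix(unlist(strsplit(all_tags, "")), nrow = L)
    for (i in todo) {
      qc <- strsplit(tags[i], "")[[1]]
      d <- colSums(ref_mat != qc)
      best <- min(d)
      if (best <= max_mismatch) {
        refs <- which(d == best)
        if (length(refs) == 1L) {
          out <- fill(out, i, refs)
          out$mismatches[i] <- as.integer(best)
        } else {
          out$status[i] <- "ambiguous"
        }
      }
    }
  }
  out
}

#' Count matched tags into the dual-library site count table
#'
#' Matches every demultiplexed read's tag, incrementing the HpaII-library
#' count `u` for hpaii-stream site hits and the inverse-library count `m`
#' for inverse-stream site hits; standard-tag hits accumulate into
#' spike-in counts. Every read falls in exactly one report category
#' (mapped, no_hit, ambiguous).
#'
#' @param streams Tibble from [demultiplex()] (`sample`, `library`, `tag`).
#' @param tag_library An `mscc_tag_library`.
#' @param max_mismatch Passed to the matcher.
#' @return List with `counts` (`sample`, `site_id`, `u`, `m`; complete
#'   over library sites x samples seen), `spike_ins` (`sample`,
#'   `library`, `count`) and `report` (`sample`, `library`, `total`,
#'   `mapped`, `no_hit`, `ambiguous`).
#' @export
count_tags <- function(streams, tag_library, max_mismatch = 1L) {
  if (nrow(tag_library$tags) + nrow(tag_library$standards) == 0) {
    abort("empty tag library")
  }
  utags <- unique(streams$tag)
  res <- match_tags_vec(utags, tag_library, max_mismatch)
  idx <- match(streams$tag, utags)
  per_read <- bind_cols(streams, res[idx, ])

  samples <- unique(streams$sample)
  base <- expand_grid(sample = samples,
                      site_id = sort(unique(tag_library$tags$site_id)))
  counts <- per_read |>
    filter(.data$status == "site") |>
    count(.data$sample, .data$library, .data$site_id) |>
    pivot_wider(names_from = "library", values_from = "n", values_fill = 0L)
  for (col in c("hpaii", "inverse")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- base |>
    left_join(counts, by = c("sample", "site_id")) |>
    mutate(u = replace_na(.data$hpaii, 0L), m = replace_na(.data$inverse, 0L)) |>
    select("sample", "site_id", "u", "m")

  spike <- expand_grid(sample = samples, library = c("hpaii", "inverse")) |>
    left_join(
      per_read |> filter(.data$status == "standard") |>
        count(.data$sample, .data$library, name = "count"),
      by = c("sample", "library")
    ) |>
    mutate(count = replace_na(.data$count, 0L))

  report <- per_read |>
    mutate(cat = ifelse(.data$status %in% c("site", "standard"),
                        "mapped", .data$status)) |>
    count(.data$sample, .data$library, .data$cat) |>
    pivot_wider(names_from = "cat", values_from = "n", values_fill = 0L)
  for (col in c("mapped", "no_hit", "ambiguous")) {
    if (!col %in% names(report)) report[[col]] <- 0L
  }
  report <- report |>
    mutate(total = .data$mapped + .data$no_hit + .data$ambiguous) |>
    select("sample", "library", "total", "mapped", "no_hit", "ambiguous")

  list(counts = counts, spike_ins = spike, report = report)
}
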