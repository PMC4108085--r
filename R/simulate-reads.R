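# Read-level simulation: every site count becomes one index+tag read.

#' Build a library index table
#'
#' Assigns one deterministic index sequence to every (sample, library)
#' stream. Indices are 6-mers built by doubling each base of successive
#' 3-mers, so any two indices differ in at least two positions.
#'
#' @param samples Ordered sample labels.
#' @param libraries Library labels.
#' @return Tibble with `index`, `sample`, `library`.
#' @export
make_index_table <- function(samples, libraries = c("hpaii", "inverse")) {
  combos <- expand.grid(b1 = BASES, b2 = BASES, b3 = BASES,
                        stringsAsFactors = FALSE)
  n <- length(samples) * length(libraries)
  stopifnot(n <= nrow(combos))
  idx <- with(combos[seq_len(n), ],
              paste0(strrep(b1, 2), strrep(b2, 2), strrep(b3, 2)))
  expand_grid(sample = samples, library = libraries) |>
    mutate(index = idx, .before = 1)
}

#' Simulate MSCC sequencing reads
#'
#' Emits one read per count in the site count table: the stream's index
#' followed by an 18-bp tag drawn uniformly from the site's usable tags
#' (HpaII-library reads for `u`, inverse-library reads for `m`). Spike-in
#' counts are emitted as standard-tag reads of their library. Per-base
#' substitution errors are applied to the tag portion only; the index is
#' left intact (demultiplexing is exact-match by design). Sites with no
#' usable tag are dropped and reported in the ledger.
#'
#' @param sim_counts List from [simulate_counts()] (`counts`, `spike_ins`).
#' @param tag_library An `mscc_tag_library` with standard tags attached
#'   (see [add_standard_tags()]).
#' @param index_table Tibble from [make_index_table()].
#' @param seq_error_rate Per-base substitution probability on the tag.
#' @param seed Integer seed.
#' @return List with `reads` (tibble `id`, `seq`) and `ledger` (tibble
#'   `sample`, `library`, `emitted`, `dropped`).
#' @export
simulate_reads <- function(sim_counts, tag_library, index_table,
                           seq_error_rate = 0, seed = 1L) {
  set.seed(seed)
  if (nrow(tag_library$standards) == 0 && any(sim_counts$spike_ins$count > 0)) {
    abort("tag library has no standard tags; call add_standard_tags() first")
  }
  tags_wide <- tag_library$tags |>
    group_by(.data$site_id) |>
    summarise(tag1 = .data$tag[1],
              tag2 = if (n() > 1) .data$tag[2] else NA_character_,
              n_tags = n(), .groups = "drop")

  long <- sim_counts$counts |>
    tidyr::pivot_longer(c("u", "m"), names_to = "which", values_to = "count") |>
    mutate(library = ifelse(.data$which == "u", "hpaii", "inverse")) |>
    filter(.data$count > 0) |>
    left_join(tags_wide, by = "site_id")

  dropped <- long |>
    filter(is.na(.data$n_tags)) |>
    group_by(.data$sample, .data$library) |>
    summarise(dropped = sum(.data$count), .groups = "drop")
  long <- filter(long, !is.na(.data$n_tags))

  reads <- long[rep(seq_len(nrow(long)), long$count), ]
  use2 <- reads$n_tags == 2 & runif(nrow(reads)) < 0.5
  reads$tag <- ifelse(use2, reads$tag2, reads$tag1)

  std <- sim_counts$spike_ins |> filter(.data$count > 0)
  std_reads <- NULL
  if (nrow(std) > 0) {
    std_long <- std[rep(seq_len(nrow(std)), std$count), c("sample", "library")]
    std_long <- std_long |>
      group_by(.data$library) |>
      mutate(tag = {
        pool <- tag_library$standards$tag[tag_library$standards$library ==
                                            .data$library[1]]
        pool[sample.int(length(pool), n(), replace = TRUE)]
      }) |>
      ungroup()
    std_reads <- std_long
  }

  all_reads <- bind_rows(reads[, c("sample", "library", "tag")], std_reads) |>
    left_join(index_table, by = c("sample", "library"))

  tag <- mutate_tags(all_reads$tag, seq_error_rate)
  out <- tibble(
    id = sprintf("read%08d", seq_along(tag)),
    seq = paste0(all_reads$index, tag)
  )
  ledger <- all_reads |>
    count(.data$sample, .data$library, name = "emitted") |>
    full_join(dropped, by = c("sample", "library")) |>
    mutate(emitted = ifelse(is.na(.data$emitted), 0L, as.integer(.data$emitted)),
           dropped = ifelse(is.na(.data$dropped), 0L, as.integer(.data$dropped)))
  list(reads = out, ledger = ledger)
}

# Substitution errors at `rate` per base, uniform over the three other bases.
mutate_tags <- function(tags, rate) {
  if (rate <= 0 || length(tags) == 0) return(tags)
  len <- nchar(tags[1])
  n_err <- rbinom(length(tags), len, rate)
  for (i in which(n_err > 0)) {
    chars <- strsplit(tags[i], "")[[1]]
    at <- sample.int(len, n_err[i])
    chars[at] <- vapply(chars[at],
                        function(b) sample(setdiff(BASES, b), 1L), character(1))
    tags[i] <- paste(chars, collapse = "")
  }
  tags
}
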