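# Interval arithmetic on 0-based half-open [start, end) tibbles.
# Toy-genome scale: plain sorted-vector scans, no interval trees needed.

#' Merge overlapping or touching intervals
#'
#' Collapses a set of genomic intervals (0-based half-open) into a minimal
#' sorted set of disjoint intervals per chromosome. Touching intervals
#' (`end == start`) are merged.
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end`.
#' @return Tibble with columns `chrom`, `start`, `end`, sorted.
#' @export
merge_intervals <- function(intervals) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  intervals |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    mutate(grp = cumsum(.data$start > lag(cummax(.data$end), default = -1L))) |>
    group_by(.data$chrom, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    select("chrom", "start", "end")
}

validate_intervals <- function(intervals, arg = "intervals") {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(intervals))) {
    abort(paste0("`", arg, "` must have columns chrom, start, end"))
  }
  bad <- intervals$start < 0 | intervals$end <= intervals$start
  if (any(bad)) {
    abort(paste0("`", arg, "` has invalid intervals (need 0 <= start < end)"))
  }
  invisible(intervals)
}

# Distance from each position to the nearest interval base: 0 if inside,
# k if the nearest contained base is k bp away, Inf if the chromosome has
# no interval. Intervals must be merged (disjoint, sorted) beforehand.
interval_distance <- function(chrom, pos, intervals) {
  stopifnot(length(chrom) == length(pos))
  out <- rep(Inf, length(pos))
  if (nrow(intervals) == 0 || length(pos) == 0) {
    return(out)
  }
  for (ch in unique(chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (nrow(iv) == 0) next
    p <- pos[sel]
    idx <- findInterval(p, iv$start)          # last interval starting <= p
    inside <- idx > 0 & p < iv$end[pmax(idx, 1L)]
    d_left <- ifelse(idx > 0, p - (iv$end[pmax(idx, 1L)] - 1L), Inf)  # gap to interval on the left
    d_right <- ifelse(idx < nrow(iv), iv$start[pmin(idx + 1L, nrow(iv))] - p, Inf)
    d <- pmin(pmax(d_left, 0), pmax(d_right, 0))
    d[inside] <- 0
    out[sel] <- d
  }
  out
}

in_intervals <- function(chrom, pos, intervals) {
  interval_distance(chrom, pos, merge_intervals(intervals)) == 0
}

# Rejection-sampling placement of n non-overlapping intervals, keeping
# `pad` bp clear of each other and of `existing` intervals.
place_intervals <- function(chrom_lengths, n, width_min, width_max, pad = 0,
                            existing = NULL, max_tries = 5000L) {
  if (n == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  occupied <- existing %||% tibble(chrom = character(), start = integer(), end = integer())
  placed <- vector("list", n)
  chroms <- names(chrom_lengths)
  k <- 0L
  tries <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(paste0(
        "could not place ", n, " intervals of width ", width_min, "-", width_max,
        " bp with pad ", pad, " bp: chromosomes too small or too crowded ",
        "(placed ", k, "); increase chrom_length or reduce feature counts"
      ))
    }
    ch <- sample(chroms, 1L)
    len <- chrom_lengths[[ch]]
    w <- sample(width_min:width_max, 1L)
    if (len < w + 2L) next
    s <- sample.int(len - w, 1L) - 1L
    cand <- tibble(chrom = ch, start = s, end = s + w)
    pads <- tibble(chrom = occupied$chrom,
                   start = pmax(occupied$start - pad, 0L),
                   end = occupied$end + pad)
    if (nrow(pads) > 0 &&
        any(pads$chrom == ch & cand$start < pads$end & pads$start < cand$end)) {
      next
    }
    k <- k + 1L
    placed[[k]] <- cand
    occupied <- bind_rows(occupied, cand)
  }
  bind_rows(placed) |> arrange(.data$chrom, .data$start)
}
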