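# Descriptive genome-context analyses: metagene profiles on a
# percent-of-gene-length axis with half-length flanks, expression-tertile
# contrasts, histone-peak overlap and short-RNA proximity summaries.

# Nearest gene per site (deterministic tie-break: smaller txStart, then
# name) plus the strand-aware relative coordinate in that gene's frame:
# 0 at the TSS, 1 at the TES, negative upstream.
gene_relative_position <- function(sites, genes) {
  n <- nrow(sites)
  gi <- rep(NA_integer_, n)
  dist <- rep(Inf, n)
  for (g in order(genes$txStart, genes$name)) {
    on <- which(sites$chrom == genes$chrom[g])
    if (length(on) == 0) next
    p <- sites$pos[on]
    d <- pmax(genes$txStart[g] - p, p - (genes$txEnd[g] - 1L), 0L)
    upd <- d < dist[on]
    gi[on[upd]] <- g
    dist[on[upd]] <- d[upd]
  }
  len <- genes$txEnd - genes$txStart
  rel <- ifelse(genes$strand[gi] == "+",
                (sites$pos - genes$txStart[gi]) / len[gi],
                (genes$txEnd[gi] - 1L - sites$pos) / len[gi])
  tibble(site_id = sites$site_id,
         gene = genes$name[gi],
         rel = rel,
         inside = !is.na(rel) & rel >= 0 & rel < 1,
         dist = ifelse(is.finite(dist), dist, NA_real_))
}

#' Metagene methylation profile
#'
#' Maps every quantified site to its nearest gene's relative frame
#' (0 = TSS, 1 = TES; flanks of half the gene length per side span
#' -50%..150%), bins the axis and averages levels per bin (unweighted).
#' Sites beyond the flanks are excluded; zero-length genes are skipped.
#' A moving average (window `smooth_window` bins) is attached.
#'
#' @param calls Call tibble with `chrom`, `pos`.
#' @param genes Gene tibble.
#' @param body_bins Bins across the gene body.
#' @param flank_bins Bins per flank.
#' @param smooth_window Moving-average window in bins (odd).
#' @return Tibble of class `mscc_metagene`: `bin`, `region`, `position`
#'   (bin midpoint on the -0.5..1.5 axis), `n`, `mean_level`, `smoothed`.
#' @export
metagene_profile <- function(calls, genes, body_bins = 40L, flank_bins = 20L,
                             smooth_window = 11L) {
  zero_len <- genes$txEnd <= genes$txStart
  if (any(zero_len)) {
    warn(paste0(sum(zero_len), " zero-length genes skipped"))
    genes <- genes[!zero_len, ]
  }
  pos <- gene_relative_position(rename_site_cols(calls), genes)
  out <- bin_profile(pos$rel, calls$level, body_bins, flank_bins, smooth_window)
  class(out) <- c("mscc_metagene", class(out))
  out
}

bin_profile <- function(rel, level, body_bins, flank_bins, smooth_window) {
  keep <- !is.na(rel) & rel >= -0.5 & rel <= 1.5
  rel <- rel[keep]; level <- level[keep]
  breaks <- metagene_breaks(body_bins, flank_bins)
  bin <- findInterval(rel, breaks, rightmost.closed = TRUE)
  prof <- tibble(bin = seq_len(length(breaks) - 1L)) |>
    left_join(tibble(bin = bin, level = level) |>
                group_by(.data$bin) |>
                summarise(n = n(), mean_level = mean(.data$level),
                          .groups = "drop"),
              by = "bin") |>
    mutate(n = ifelse(is.na(.data$n), 0L, as.integer(.data$n)),
           position = (breaks[.data$bin] + breaks[.data$bin + 1L]) / 2,
           region = cut(.data$position, c(-0.5, 0, 1, 1.5),
                        labels = c("upstream", "body", "downstream"),
                        include.lowest = TRUE))
  prof$smoothed <- moving_average_na(prof$mean_level, smooth_window)
  prof[, c("bin", "region", "position", "n", "mean_level", "smoothed")]
}

metagene_breaks <- function(body_bins, flank_bins) {
  c(seq(-0.5, 0, length.out = flank_bins + 1L),
    seq(0, 1, length.out = body_bins + 1L)[-1L],
    seq(1, 1.5, length.out = flank_bins + 1L)[-1L])
}

rename_site_cols <- function(calls) {
  tibble(site_id = calls$site_id, chrom = calls$chrom, pos = calls$pos)
}

#' Centered moving average
#'
#' Centered mean with the stated edge rule: near the series ends the
#' window is truncated to the available indices (so the first value of a
#' window-3 smooth is the mean of the first two elements). A window not
#' smaller than the series returns the overall mean everywhere; window 1
#' is the identity.
#'
#' @param series Numeric vector.
#' @param window Odd positive window length in elements.
#' @return Smoothed numeric vector, same length.
#' @export
moving_average <- function(series, window = 11L) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(series)
  if (n == 0) return(series)
  if (window >= n) return(rep(mean(series), n))
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(series[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

# moving average tolerant of empty-bin NAs
moving_average_na <- function(series, window) {
  n <- length(series)
  if (n == 0) return(series)
  if (all(is.na(series))) return(series)
  if (window >= n) return(rep(mean(series, na.rm = TRUE), n))
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(series[max(1L, i - h):min(n, i + h)], na.rm = TRUE)
  }, numeric(1))
}

#' Split genes into expression tertiles
#'
#' Equal-count thirds by rank (nearest-rank split); ordering is
#' deterministic by (expression, gene name), so boundary ties fall in the
#' lower tertile. Tertile 3 is the highest-expressed third.
#'
#' @param expression Tibble (`gene`, `expression`).
#' @return Tibble (`gene`, `expression`, `tertile`).
#' @export
expression_tertiles <- function(expression) {
  stopifnot(all(c("gene", "expression") %in% names(expression)))
  n <- nrow(expression)
  ord <- order(expression$expression, expression$gene)
  tert <- integer(n)
  tert[ord] <- ceiling(seq_len(n) * 3 / n)
  expression |> mutate(tertile = tert)
}

#' Metagene profiles by expression tertile
#'
#' Splits genes into expression tertiles, computes one metagene profile
#' per tertile, and a contrast table with each tertile's mean level in the
#' TSS region (+-`tss_halfwidth` bp of the TSS) and in the latter half of
#' the gene body (relative coordinate 0.5-1).
#'
#' @param calls Call tibble with `chrom`, `pos`.
#' @param genes Gene tibble.
#' @param expression Tibble (`gene`, `expression`); genes without
#'   expression are excluded and counted.
#' @param tss_halfwidth TSS window half-width in bp.
#' @inheritParams metagene_profile
#' @return Object of class `mscc_tertiles`: list with `profiles` (bound
#'   per-tertile profiles with `tertile` column), `contrast` (tibble
#'   `tertile`, `n_genes`, `tss_mean`, `tss_n`, `body2_mean`, `body2_n`)
#'   and `n_genes_missing_expression`.
#' @export
expression_tertile_profiles <- function(calls, genes, expression,
                                        tss_halfwidth = 1000L,
                                        body_bins = 40L, flank_bins = 20L) {
  known <- genes$name %in% expression$gene
  n_missing <- sum(!known)
  genes <- genes[known, ]
  tert <- expression_tertiles(expression |>
                                filter(.data$gene %in% genes$name))
  gt <- setNames(tert$tertile, tert$gene)

  pos <- gene_relative_position(rename_site_cols(calls), genes)
  df <- bind_cols(calls, pos[, c("gene", "rel", "dist")]) |>
    mutate(tertile = unname(gt[.data$gene]))

  profiles <- map(1:3, function(t) {
    sub <- df |> filter(!is.na(.data$tertile), .data$tertile == t)
    if (nrow(sub) == 0) return(NULL)
    p <- bin_profile(sub$rel, sub$level, body_bins, flank_bins, 11L)
    p$tertile <- t
    p
  }) |> list_rbind()

  tss <- gene_tss(genes)
  names(tss) <- genes$name
  tss_chrom <- setNames(genes$chrom, genes$name)
  df$near_tss <- !is.na(df$gene) &
    abs(df$pos - unname(tss[df$gene])) <= tss_halfwidth &
    df$chrom == unname(tss_chrom[df$gene])
  df$body2 <- !is.na(df$rel) & df$rel >= 0.5 & df$rel < 1

  contrast <- tibble(tertile = 1:3) |>
    left_join(
      df |> filter(.data$near_tss) |> group_by(.data$tertile) |>
        summarise(tss_mean = mean(.data$level), tss_n = n(), .groups = "drop"),
      by = "tertile") |>
    left_join(
      df |> filter(.data$body2) |> group_by(.data$tertile) |>
        summarise(body2_mean = mean(.data$level), body2_n = n(),
                  .groups = "drop"),
      by = "tertile") |>
    left_join(count(tert, .data$tertile, name = "n_genes"), by = "tertile")

  structure(list(profiles = profiles, contrast = contrast,
                 n_genes_missing_expression = n_missing),
            class = "mscc_tertiles")
}

#' Methylation within vs outside histone peaks
#'
#' Per mark (independently): unweighted mean level and site count of
#' quantified sites inside any (merged) peak and outside all peaks.
#'
#' @param calls Call tibble with `chrom`, `pos`.
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `mark`).
#' @return Tibble (`mark`, `stratum` in within/without, `n`,
#'   `mean_level`); an empty stratum has count 0 and `NA` mean.
#' @export
peak_overlap_summary <- function(calls, peaks) {
  stopifnot("mark" %in% names(peaks))
  map(unique(peaks$mark), function(mk) {
    inside <- in_intervals(calls$chrom, calls$pos,
                           peaks[peaks$mark == mk, c("chrom", "start", "end")])
    tibble(mark = mk, stratum = c("within", "without"),
           n = c(sum(inside), sum(!inside)),
           mean_level = c(if (any(inside)) mean(calls$level[inside]) else NA_real_,
                          if (any(!inside)) mean(calls$level[!inside]) else NA_real_))
  }) |> list_rbind()
}

#' Methylation by proximity to short-RNA loci
#'
#' Classifies quantified sites as `within` a (merged) short-RNA interval,
#' `near` (outside all intervals but within `flank` bp of one, boundary
#' inclusive) or `without`, and reports the fraction and mean level per
#' class.
#'
#' @param calls Call tibble with `chrom`, `pos`.
#' @param shortrna Interval tibble (`chrom`, `start`, `end`).
#' @param flank Proximity distance in bp.
#' @return Tibble (`class`, `n`, `fraction`, `mean_level`).
#' @export
shortrna_proximity_summary <- function(calls, shortrna, flank = 2000L) {
  d <- interval_distance(calls$chrom, calls$pos, merge_intervals(shortrna))
  cls <- ifelse(d == 0, "within", ifelse(d <= flank, "near", "without"))
  tibble(class = c("within", "near", "without")) |>
    left_join(
      tibble(class = cls, level = calls$level) |>
        group_by(.data$class) |>
        summarise(n = n(), mean_level = mean(.data$level), .groups = "drop"),
      by = "class") |>
    mutate(n = ifelse(is.na(.data$n), 0L, as.integer(.data$n)),
           fraction = .data$n / max(sum(.data$n), 1L))
}
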