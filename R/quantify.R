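# Spike-in normalized methylation calls. The inverse library's reads are
# evidence of methylation, the HpaII library's of its absence; per-library
# spike-in standards calibrate the relative scale of the two libraries.

#' Normalize counts and call per-site methylation levels
#'
#' Per library L, scale factor `f_L = K / spike_in(sample, L)` (K is an
#' arbitrary constant that cancels in the ratio); the methylation level is
#' `m f_I / (m f_I + u f_H)`. Sites with raw depth `u + m < min_depth`
#' are excluded -- sampling noise is governed by raw reads, so the filter
#' uses unnormalized depth. A site with depth exactly `min_depth` is kept.
#'
#' @param counts Tibble (`sample`, `site_id`, `u`, `m`).
#' @param spike_ins Tibble (`sample`, `library`, `count`), positive for
#'   every sample/library pair; `NULL` skips normalization (f_H = f_I).
#' @param sites Optional site tibble (`site_id`, `chrom`, `pos`) joined
#'   into the output.
#' @param min_depth Minimum raw depth (default 30, the "30+ reads" rule).
#' @param scale_constant The constant K (default 1e6); any positive value
#'   yields identical levels.
#' @return Call tibble: `sample`, `site_id` (plus `chrom`, `pos` when
#'   `sites` given), `u`, `m`, `depth`, `level`.
#' @export
normalize_and_call <- function(counts, spike_ins, sites = NULL,
                               min_depth = 30L, scale_constant = 1e6) {
  if (!is.null(spike_ins)) {
    bad <- spike_ins$count <= 0
    if (any(bad)) {
      abort(paste0("non-positive spike-in count for ",
                   paste(spike_ins$sample[bad], spike_ins$library[bad],
                         sep = "/", collapse = ", "),
                   "; cannot form scale factors"))
    }
    f <- spike_ins |>
      mutate(f = scale_constant / .data$count) |>
      pivot_wider(id_cols = "sample", names_from = "library",
                  values_from = "f", names_prefix = "f_")
    calls <- counts |> left_join(f, by = "sample")
    if (anyNA(calls$f_hpaii) || anyNA(calls$f_inverse)) {
      abort("spike-in counts missing for some sample/library")
    }
  } else {
    calls <- counts |> mutate(f_hpaii = 1, f_inverse = 1)
  }
  calls <- calls |>
    mutate(depth = .data$u + .data$m,
           level = .data$m * .data$f_inverse /
             (.data$m * .data$f_inverse + .data$u * .data$f_hpaii)) |>
    filter(.data$depth >= min_depth, .data$depth > 0) |>
    select("sample", "site_id", "u", "m", "depth", "level")
  if (!is.null(sites)) {
    calls <- calls |>
      left_join(sites[, c("site_id", "chrom", "pos")], by = "site_id") |>
      select("sample", "site_id", "chrom", "pos", "u", "m", "depth", "level")
  }
  calls
}

#' Pairwise accuracy as a function of depth threshold
#'
#' For two call tables over a shared site set (e.g. independent
#' simulations of the same methylome, or two samples of an unchanged
#' methylome), computes the Pearson correlation of levels over sites with
#' depth >= t in both tables, per threshold t. Deeper sites estimate the
#' level more precisely, so the correlation rises with t.
#'
#' @param calls_a,calls_b Call tibbles (same `site_id` space).
#' @param depth_thresholds Integer vector of thresholds.
#' @param min_shared Thresholds with fewer shared sites are skipped.
#' @return Tibble of class `mscc_depth_curve`: `threshold`, `n`, `r`.
#' @export
depth_accuracy_curve <- function(calls_a, calls_b,
                                 depth_thresholds = c(10, 30, 50, 100),
                                 min_shared = 10L) {
  shared <- inner_join(
    calls_a[, c("site_id", "depth", "level")],
    calls_b[, c("site_id", "depth", "level")],
    by = "site_id", suffix = c("_a", "_b")
  )
  rows <- map(depth_thresholds, function(t) {
    sub <- shared |> filter(.data$depth_a >= t, .data$depth_b >= t)
    if (nrow(sub) < min_shared) {
      warn(paste0("threshold ", t, " skipped: only ", nrow(sub),
                  " shared sites"))
      return(NULL)
    }
    tibble(threshold = t, n = nrow(sub),
           r = cor(sub$level_a, sub$level_b))
  })
  out <- list_rbind(rows)
  class(out) <- c("mscc_depth_curve", class(out))
  out
}

#' Per-chromosome methylation summary
#'
#' Unweighted mean call level and surviving site count per chromosome;
#' chromosomes present in `sites` but without surviving calls are reported
#' with an `NA` mean rather than dropped. The overall mean across
#' chromosome means is attached as attribute `overall_mean` and returned
#' by [glance()].
#'
#' @param calls Call tibble including `chrom` (pass `sites` to
#'   [normalize_and_call()]).
#' @param sites Site tibble (`site_id`, `chrom`, `pos`) defining the
#'   chromosome universe.
#' @return Tibble of class `mscc_chrom_summary`: `chrom`, `n_sites`,
#'   `mean_level`.
#' @export
chromosome_summary <- function(calls, sites) {
  if (!"chrom" %in% names(calls)) {
    calls <- left_join(calls, sites[, c("site_id", "chrom")], by = "site_id")
  }
  out <- tibble(chrom = sort(unique(sites$chrom))) |>
    left_join(
      calls |> group_by(.data$chrom) |>
        summarise(n_sites = n_distinct(.data$site_id),
                  mean_level = mean(.data$level), .groups = "drop"),
      by = "chrom"
    ) |>
    mutate(n_sites = ifelse(is.na(.data$n_sites), 0L, as.integer(.data$n_sites)))
  attr(out, "overall_mean") <- mean(out$mean_level, na.rm = TRUE)
  class(out) <- c("mscc_chrom_summary", class(out))
  out
}
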