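# broom-style views of fitted result objects.

#' Tidy a DMR analysis
#'
#' @param x An `mscc_dmr` from [compare_all_units()].
#' @param ... Ignored.
#' @return The per-unit, per-comparison tibble (`unit_id`, `kind`,
#'   `sample_b`, means, `delta`, `p`, `q`, pass flags).
#' @export
tidy.mscc_dmr <- function(x, ...) {
  as_tibble(x$comparisons)
}

#' One-line summary of a DMR analysis
#'
#' @param x An `mscc_dmr`.
#' @param ... Ignored.
#' @return One-row tibble: units tested, comparisons, passing
#'   comparisons, consistent DMRs under both criteria.
#' @export
glance.mscc_dmr <- function(x, ...) {
  tibble(
    n_units = nrow(x$calls),
    n_comparisons = nrow(x$comparisons),
    n_passing_comparisons = sum(x$comparisons$passes),
    n_consistent = sum(x$calls$consistent),
    n_consistent_delta_only = sum(x$calls$consistent_delta_only),
    baseline = x$baseline,
    delta_cutoff = x$delta_cutoff,
    q_cutoff = x$q_cutoff
  )
}

#' Tidy a metagene profile
#'
#' @param x An `mscc_metagene`.
#' @param ... Ignored.
#' @return The per-bin tibble.
#' @export
tidy.mscc_metagene <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "mscc_metagene")
  out
}

#' One-line summary of a metagene profile
#'
#' @param x An `mscc_metagene`.
#' @param ... Ignored.
#' @return One-row tibble: sites binned, bins, minimum-smoothed-bin
#'   position (the profile's dip).
#' @export
glance.mscc_metagene <- function(x, ...) {
  tibble(
    n_sites = sum(x$n),
    n_bins = nrow(x),
    dip_position = x$position[which.min(x$smoothed)],
    dip_level = min(x$smoothed, na.rm = TRUE)
  )
}

#' One-line summary of a chromosome summary
#'
#' @param x An `mscc_chrom_summary`.
#' @param ... Ignored.
#' @return One-row tibble: chromosome count, overall mean of chromosome
#'   means, surviving sites.
#' @export
glance.mscc_chrom_summary <- function(x, ...) {
  tibble(
    n_chroms = nrow(x),
    overall_mean = attr(x, "overall_mean"),
    n_sites = sum(x$n_sites)
  )
}
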