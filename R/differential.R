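# Differential methylation machinery: 200-bp non-overlapping windows and
# CGIs as analysis units, unit means over sites shared between the two
# samples, a pooled-count Fisher exact test, the 25% delta cutoff, and
# the consistency-across-timepoints rule.

#' Tile a genome into non-overlapping analysis windows
#'
#' Tiles every chromosome into `width`-bp windows `[0, width)`,
#' `[width, 2 width)`, ...; a trailing partial window is kept.
#'
#' @param chrom_lengths Named vector of chromosome lengths, or a genome
#'   (named character vector of sequences).
#' @param width Window width in bp.
#' @return Unit tibble: `unit_id`, `kind` ("window"), `chrom`, `start`,
#'   `end`.
#' @export
make_windows <- function(chrom_lengths, width = 200L) {
  if (is.character(chrom_lengths)) {
    chrom_lengths <- setNames(nchar(chrom_lengths), names(chrom_lengths))
  }
  stopifnot(width >= 1, !is.null(names(chrom_lengths)))
  out <- imap(chrom_lengths[order(names(chrom_lengths))], function(L, ch) {
    starts <- seq.int(0L, L - 1L, by = width)
    tibble(chrom = ch, start = as.integer(starts),
           end = as.integer(pmin(starts + width, L)))
  }) |> list_rbind()
  out |>
    mutate(unit_id = sprintf("win_%s_%d", .data$chrom, .data$start),
           kind = "window") |>
    select("unit_id", "kind", "chrom", "start", "end")
}

#' Turn CGI intervals into analysis units
#'
#' @param cgi CGI interval tibble (`chrom`, `start`, `end`, optional
#'   `name`).
#' @return Unit tibble: `unit_id`, `kind` ("cgi"), `chrom`, `start`, `end`.
#' @export
cgi_units <- function(cgi) {
  validate_intervals(cgi, "cgi")
  cgi |>
    arrange(.data$chrom, .data$start) |>
    mutate(unit_id = if ("name" %in% names(cgi) && !anyNA(cgi$name)) {
      as.character(.data$name)
    } else {
      sprintf("cgi_%s_%d", .data$chrom, .data$start)
    },
    kind = "cgi") |>
    select("unit_id", "kind", "chrom", "start", "end")
}

# Assign each call row to its unit (sites outside every unit drop out).
assign_units <- function(calls, units) {
  stopifnot(all(c("chrom", "pos") %in% names(calls)))
  res <- vector("list", length(unique(units$chrom)))
  out <- calls
  out$unit_id <- NA_character_
  for (ch in unique(units$chrom)) {
    iv <- units[units$chrom == ch, ] |> arrange(.data$start)
    sel <- which(calls$chrom == ch)
    if (length(sel) == 0) next
    idx <- findInterval(calls$pos[sel], iv$start)
    ok <- idx > 0 & calls$pos[sel] < iv$end[pmax(idx, 1L)]
    out$unit_id[sel[ok]] <- iv$unit_id[idx[ok]]
  }
  out |> filter(!is.na(.data$unit_id))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test: with margins fixed, the p-value is the sum of
#' hypergeometric probabilities of all tables whose probability does not
#' exceed the observed table's (relative tolerance 1e-7 on the
#' comparison). A zero margin gives p = 1.
#'
#' @param table 2x2 matrix, or vector `c(a, b, c, d)` read row-wise.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(table) {
  x <- as.integer(round(as.vector(t(table))))
  stopifnot(length(x) == 4, all(x >= 0))
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  r1 <- a + b; c1 <- a + c_; N <- a + b + c_ + d
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) return(1.0)
  lo <- max(0L, r1 + c1 - N)
  hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, N - c1, r1)
  p_obs <- probs[a - lo + 1L]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1.0)
}

#' Per-unit methylation comparison between two samples
#'
#' Over the sites of one unit quantified in *both* samples: unweighted
#' mean level per sample, the pooled 2x2 raw-count table (m, u summed over
#' the shared sites), and eligibility. A unit enters testing only with at
#' least `min_sites` shared sites (">3 sequenced CpGs" means >= 4).
#'
#' @param calls_a,calls_b Call tibbles for the two samples, restricted to
#'   one unit's member sites.
#' @param min_sites Minimum shared quantified sites.
#' @return One-row tibble: `n_sites`, `mean_a`, `mean_b`, `delta`, `m_a`,
#'   `u_a`, `m_b`, `u_b`, `eligible`, `reason`.
#' @export
unit_stats <- function(calls_a, calls_b, min_sites = 4L) {
  shared <- inner_join(calls_a, calls_b, by = "site_id",
                       suffix = c("_a", "_b"))
  if (nrow(shared) < min_sites) {
    return(tibble(n_sites = nrow(shared), mean_a = NA_real_, mean_b = NA_real_,
                  delta = NA_real_, m_a = NA_integer_, u_a = NA_integer_,
                  m_b = NA_integer_, u_b = NA_integer_,
                  eligible = FALSE, reason = "min_sites"))
  }
  tibble(
    n_sites = nrow(shared),
    mean_a = mean(shared$level_a), mean_b = mean(shared$level_b),
    delta = mean(shared$level_b) - mean(shared$level_a),
    m_a = sum(shared$m_a), u_a = sum(shared$u_a),
    m_b = sum(shared$m_b), u_b = sum(shared$u_b),
    eligible = TRUE, reason = NA_character_
  )
}

#' Compare all units between every treated sample and the baseline
#'
#' For each treated sample vs the baseline and each eligible unit:
#' shared-site means, delta, pooled-count Fisher p, BH-adjusted q (within
#' the comparison, across eligible units), and pass flags. A unit is a
#' consistent DMR if it passes in every treated-vs-baseline comparison;
#' `mode = "delta_only"` drops the q condition and applies the delta
#' cutoff alone.
#'
#' @param units Unit tibble ([make_windows()] / [cgi_units()]).
#' @param calls Call tibble over all samples (needs `chrom`, `pos`).
#' @param baseline Baseline sample label.
#' @param delta_cutoff Absolute unit-mean difference required (default
#'   0.25, the 25% rule).
#' @param q_cutoff BH-adjusted significance cutoff.
#' @param min_sites Minimum shared sites per unit and comparison.
#' @param mode `"delta_q"` (delta and q) or `"delta_only"`.
#' @return Object of class `mscc_dmr`: list with `comparisons` (per unit
#'   x treated sample) and `calls` (per unit: `consistent`,
#'   `consistent_delta_only`, `n_comparisons`).
#' @export
compare_all_units <- function(units, calls, baseline = "S0h",
                              delta_cutoff = 0.25, q_cutoff = 0.05,
                              min_sites = 4L, mode = c("delta_q", "delta_only")) {
  mode <- match.arg(mode)
  samples <- unique(calls$sample)
  if (!baseline %in% samples) {
    abort(paste0("baseline sample '", baseline, "' not present in calls"))
  }
  treated <- setdiff(samples, baseline)
  if (length(treated) == 0) abort("need at least one treated sample")

  assigned <- assign_units(calls, units)
  base_calls <- assigned |> filter(.data$sample == baseline)

  comps <- map(treated, function(s) {
    tr <- assigned |> filter(.data$sample == s)
    shared <- inner_join(
      base_calls[, c("unit_id", "site_id", "level", "m", "u")],
      tr[, c("unit_id", "site_id", "level", "m", "u")],
      by = c("unit_id", "site_id"), suffix = c("_a", "_b")
    )
    st <- shared |>
      group_by(.data$unit_id) |>
      summarise(n_sites = n(),
                mean_a = mean(.data$level_a), mean_b = mean(.data$level_b),
                m_a = sum(.data$m_a), u_a = sum(.data$u_a),
                m_b = sum(.data$m_b), u_b = sum(.data$u_b),
                .groups = "drop") |>
      filter(.data$n_sites >= min_sites) |>
      mutate(delta = .data$mean_b - .data$mean_a)
    st$p <- vapply(seq_len(nrow(st)), function(i) {
      fisher_exact_two_sided(c(st$m_a[i], st$u_a[i], st$m_b[i], st$u_b[i]))
    }, numeric(1))
    st |>
      mutate(q = p.adjust(.data$p, method = "BH"),
             passes_delta = abs(.data$delta) > delta_cutoff,
             passes = if (mode == "delta_q") {
               .data$passes_delta & .data$q < q_cutoff
             } else {
               .data$passes_delta
             },
             sample_a = baseline, sample_b = s)
  }) |> list_rbind()

  comps <- comps |>
    left_join(units[, c("unit_id", "kind", "chrom", "start", "end")],
              by = "unit_id") |>
    select("unit_id", "kind", "chrom", "start", "end", "sample_a", "sample_b",
           "n_sites", "mean_a", "mean_b", "delta", "m_a", "u_a", "m_b", "u_b",
           "p", "q", "passes_delta", "passes")

  dmr_calls <- comps |>
    group_by(.data$unit_id, .data$kind) |>
    summarise(n_comparisons = n(),
              consistent = n() == length(treated) && all(.data$passes),
              consistent_delta_only = n() == length(treated) &&
                all(.data$passes_delta),
              .groups = "drop")

  structure(list(comparisons = comps, calls = dmr_calls,
                 baseline = baseline, treated = treated,
                 delta_cutoff = delta_cutoff, q_cutoff = q_cutoff,
                 mode = mode),
            class = "mscc_dmr")
}

#' @export
print.mscc_dmr <- function(x, ...) {
  cat("<mscc_dmr> ", nrow(x$calls), " units tested across ",
      length(x$treated), " comparisons vs ", x$baseline, "\n",
      "  consistent DMRs (", x$mode, "): ", sum(x$calls$consistent),
      "\n", sep = "")
  invisible(x)
}

#' Per-site methylation-change consistency
#'
#' A site (quantified in the baseline and every treated sample) is flagged
#' when the absolute level change vs baseline exceeds `delta_cutoff` in
#' *every* treated sample. `same_sign = TRUE` additionally requires all
#' changes to share a direction.
#'
#' @param calls Call tibble over all samples.
#' @param baseline Baseline sample label.
#' @param delta_cutoff Per-site absolute level-change cutoff.
#' @param same_sign Require a common direction of change.
#' @return List: `sites` (tibble `site_id`, `consistent`), `n_eligible`,
#'   `n_flagged`, `fraction` (flagged / eligible), `n_excluded` (sites
#'   not quantified in all samples).
#' @export
site_level_consistency <- function(calls, baseline = "S0h",
                                   delta_cutoff = 0.25, same_sign = FALSE) {
  samples <- unique(calls$sample)
  stopifnot(baseline %in% samples)
  treated <- setdiff(samples, baseline)
  wide <- calls |>
    select("sample", "site_id", "level") |>
    pivot_wider(names_from = "sample", values_from = "level")
  complete <- stats::complete.cases(wide[, samples])
  n_excluded <- sum(!complete)
  wide <- wide[complete, ]
  d <- as.matrix(wide[, treated, drop = FALSE]) - wide[[baseline]]
  flag <- apply(abs(d) > delta_cutoff, 1L, all)
  if (same_sign) {
    flag <- flag & (apply(d > 0, 1L, all) | apply(d < 0, 1L, all))
  }
  list(sites = tibble(site_id = wide$site_id, consistent = flag),
       n_eligible = nrow(wide), n_flagged = sum(flag),
       fraction = if (nrow(wide) > 0) mean(flag) else NA_real_,
       n_excluded = n_excluded)
}
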