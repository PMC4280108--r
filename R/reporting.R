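#' Paired-design Cohen's d
#'
#' Effect size for paired samples: mean of the differences divided by the
#' standard deviation of the differences. Undefined (with a warning) when
#' the differences have zero variance.
#'
#' @param a,b paired numeric vectors of equal length >= 2.
#' @return scalar d (NA when degenerate).
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0)) return(0)  # identical samples: no effect
    warning("zero variance of differences; Cohen's d undefined")
    return(NA_real_)
  }
  mean(d) / s
}

#' Resting-state coherence time course relative to baseline
#'
#' Expresses band coherence over the six resting-state intervals relative
#' to the first (baseline) interval, per band (and any extra grouping
#' columns present, e.g. session). Missing intervals are flagged with `NA`
#' rows.
#'
#' @param conn tibble with columns `rs_index`, `band`, `coherence` (e.g.
#'   stacked [msc()] outputs of per-RS spectral estimates).
#' @param baseline rs index used as reference (default 1).
#' @param n_rs expected number of resting-state intervals (default 6).
#' @return tibble with `rs_index`, `band`, `coherence`, `rel_coherence`.
#' @export
resting_time_course <- function(conn, baseline = 1, n_rs = 6) {
  stopifnot(all(c("rs_index", "band", "coherence") %in% names(conn)))
  extra <- intersect("session", names(conn))
  grp <- c("band", extra)
  out <- conn |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(df, key) {
      full <- dplyr::left_join(tibble::tibble(rs_index = seq_len(n_rs)),
                               df, by = "rs_index")
      ref <- full$coherence[full$rs_index == baseline]
      full$rel_coherence <- if (length(ref) == 1 && !is.na(ref) && ref > 0) {
        full$coherence / ref
      } else {
        NA_real_
      }
      full
    }) |>
    dplyr::ungroup()
  if (any(is.na(out$coherence))) {
    warning("missing resting-state interval(s) flagged with NA")
  }
  out
}

#' Assemble a summary report from module outputs
#'
#' Bundles figure-level tables (coherence spectra/bands, resting time
#' course, entropy and AEC maps, behavior) with Cohen's d effect sizes into
#' a provenance-carrying [results_container()].
#'
#' @param ... named result tables.
#' @param seed seed recorded as provenance.
#' @param config configuration recorded as a hash.
#' @return a `results_container`.
#' @export
summary_report <- function(..., seed = NA_integer_, config = NULL) {
  results_container(..., seed = seed, config = config)
}
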