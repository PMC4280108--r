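#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cluster permutation result
#'
#' @param x a `cluster_result`.
#' @param ... unused.
#' @return tibble with one row per cluster: `cluster`, `size`, `sum_t`,
#'   `p.value`, `significant`, `members` (list column of element indices).
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::as_tibble(x$clusters)
}

#' @rdname tidy.cluster_result
#' @return `glance()`: one-row tibble with `kind`, `n_clusters`,
#'   `n_significant`, `min_p`, `n_permutations`, `cluster_alpha`, `seed`.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    min_p = if (nrow(x$clusters)) min(x$clusters$p.value) else NA_real_,
    n_permutations = x$n_permutations,
    cluster_alpha = x$cluster_alpha,
    seed = x$seed
  )
}

#' Tidy a spectral estimate
#'
#' @param x a `spectral_estimate`.
#' @param ... unused.
#' @return long tibble: `channel`, `freq`, `power`, `regime`.
#' @export
tidy.spectral_estimate <- function(x, ...) {
  tibble::tibble(
    channel = rep(rownames(x$power), times = length(x$freqs)),
    freq = rep(x$freqs, each = nrow(x$power)),
    power = as.vector(x$power),
    regime = rep(x$method$regime, each = nrow(x$power))
  )
}

#' @rdname tidy.spectral_estimate
#' @export
glance.spectral_estimate <- function(x, ...) {
  tibble::tibble(
    n_channels = nrow(x$power), n_pairs = nrow(x$cross),
    n_freqs = length(x$freqs), n_segments = x$n_segments,
    n_tapers = x$method$n_tapers,
    taper_window_s = x$method$taper_window_s,
    hann_window_s = x$method$hann_window_s
  )
}

#' Tidy a channel layout
#'
#' @param x a `channel_layout`.
#' @param ... unused.
#' @return the channel tibble with a `pair` column (NA for midline).
#' @export
tidy.channel_layout <- function(x, ...) {
  ch <- x$channels
  ch$pair <- NA_integer_
  ch$pair[x$pairs$left] <- x$pairs$pair
  ch$pair[x$pairs$right] <- x$pairs$pair
  ch
}
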