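#' Read and write event streams as tab-separated text
#'
#' Files have two columns, `time_s` and `label`, with a header row. On read,
#' times must be non-decreasing and labels must belong to the event
#' vocabulary; an empty file yields an empty (valid) stream.
#'
#' @param ev an `event_stream`.
#' @param path file path.
#' @return `read_events` returns an `event_stream`; `write_events` returns
#'   `path` invisibly.
#' @export
write_events <- function(ev, path) {
  utils::write.table(
    data.frame(time_s = sprintf("%.9g", ev$time), label = ev$label),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, colClasses = c("numeric", "character"))
  if (nrow(df) == 0L) return(event_stream())
  if (is.unsorted(df$time_s)) stop("event times must be non-decreasing in ", path)
  event_stream(df$time_s, df$label)
}

#' Read and write recordings (raw_matrix dialect)
#'
#' The `raw_matrix` dialect stores samples as 64-bit little-endian floats
#' (channel-major: all samples of channel 1, then channel 2, ...) in
#' `<path>.f64`, with a text sidecar `<path>.hdr` holding the sampling rate,
#' unit scale to microvolts, condition metadata and channel names. The
#' round trip is numerically lossless. A `delim` dialect writes a plain
#' tab-separated matrix instead (channels in columns), for small text
#' fixtures.
#'
#' @param rec a `recording`.
#' @param path base path (extensions are added).
#' @param dialect `"raw_matrix"` or `"delim"`.
#' @param layout layout to attach on read; default [default_layout()]. The
#'   sidecar's channel names must match the layout.
#' @return `read_recording` returns a `recording`; `write_recording` returns
#'   `path` invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("raw_matrix", "delim")) {
  dialect <- match.arg(dialect)
  hdr <- c(
    sprintf("rate_hz\t%.10g", rec$rate),
    sprintf("n_channels\t%d", nrow(rec$data)),
    sprintf("n_samples\t%d", ncol(rec$data)),
    "unit_scale_uV\t1",
    sprintf("session\t%s", rec$session),
    sprintf("condition\t%s", rec$condition),
    sprintf("rs_index\t%d", rec$rs_index),
    sprintf("dialect\t%s", dialect),
    paste0("channels\t", paste(rownames(rec$data), collapse = ","))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  if (dialect == "raw_matrix") {
    con <- file(paste0(path, ".f64"), "wb")
    on.exit(close(con))
    writeBin(as.vector(t(rec$data)), con, size = 8, endian = "little")
  } else {
    utils::write.table(t(rec$data), paste0(path, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = rownames(rec$data))
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, layout = default_layout()) {
  hp <- paste0(path, ".hdr")
  if (!file.exists(hp)) stop("missing sidecar header: ", hp)
  kv <- strsplit(readLines(hp), "\t", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  val <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("malformed header: missing field '", k, "' in ", hp)
    kv[[i]][2]
  }
  rate <- as.numeric(val("rate_hz"))
  if (!is.finite(rate) || rate <= 0) stop("malformed header: bad rate_hz in ", hp)
  nch <- as.integer(val("n_channels"))
  ns <- as.integer(val("n_samples"))
  scale <- as.numeric(val("unit_scale_uV"))
  chn <- strsplit(val("channels"), ",", fixed = TRUE)[[1]]
  if (length(chn) != nch) stop("malformed header: channel list length != n_channels")
  if (nch != nrow(layout$channels)) {
    stop("channel count (", nch, ") does not match layout (",
         nrow(layout$channels), ")")
  }
  dialect <- val("dialect")
  if (dialect == "raw_matrix") {
    bp <- paste0(path, ".f64")
    if (!file.exists(bp)) stop("missing data file: ", bp)
    expected <- nch * ns
    x <- readBin(bp, "double", n = expected + 1L, size = 8, endian = "little")
    if (length(x) != expected) {
      stop("truncated or oversized data file: ", bp, " (expected ", expected,
           " samples, found ", length(x), ")")
    }
    data <- t(matrix(x, nrow = ns, ncol = nch))
  } else {
    m <- as.matrix(utils::read.delim(paste0(path, ".tsv"), check.names = FALSE))
    if (nrow(m) != ns || ncol(m) != nch) stop("truncated data table for ", path)
    data <- t(m)
  }
  ses <- val("session"); cond <- val("condition")
  new_recording(data * scale, rate, layout,
                session = if (ses == "NA") NA_character_ else ses,
                condition = if (cond == "NA") NA_character_ else cond,
                rs_index = suppressWarnings(as.integer(val("rs_index"))))
}

#' Results container with provenance
#'
#' A named container for analysis results (spectra, connectivity, entropy
#' maps, cluster results, behavioral summaries, ...) carrying provenance:
#' random seed, a hash of the generating configuration, and the package
#' version. Serialized with `saveRDS`; the numeric round trip is lossless.
#'
#' @param ... named results to store.
#' @param seed random seed used to produce the results.
#' @param config optional configuration list; a digest is stored.
#' @return an object of class `results_container`.
#' @export
results_container <- function(..., seed = NA_integer_, config = NULL) {
  items <- list(...)
  if (length(items) && is.null(names(items))) stop("results must be named")
  structure(
    list(items = items,
         provenance = list(
           seed = seed,
           config_hash = config_hash(config),
           package_version = as.character(utils::packageVersion("gammacoh")),
           created = NA  # timestamps excluded from reproducibility contract
         )),
    class = "results_container"
  )
}

config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 12)),
               collapse = "\n")
  # small stable FNV-1a hash; avoids external digest dependencies
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @rdname results_container
#' @param x a `results_container`.
#' @param path file path.
#' @export
save_results <- function(x, path) {
  stopifnot(inherits(x, "results_container"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname results_container
#' @export
load_results <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "results_container"))
  x
}
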