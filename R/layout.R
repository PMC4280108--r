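#' Synthetic mirror-symmetric 31-channel layout
#'
#' A fixed, deterministic sensor layout standing in for an equidistant
#' 31-channel cap: 13 left-hemisphere sensors, their 13 mirror images on the
#' right, and 5 midline sensors, all on the unit disc. The 13 interhemispheric
#' pairs match each left sensor with its mirror image; the pair of interest is
#' the most posterior (parieto-occipital) pair. Adjacency is the Delaunay
#' neighbor graph of the 2D positions (symmetric, irreflexive).
#'
#' Coordinates use the usual top-view convention: +y anterior, +x right.
#'
#' @return An object of class `channel_layout`: a list with
#'   \describe{
#'     \item{channels}{tibble (`name`, `x`, `y`, `hemisphere`)}
#'     \item{pairs}{tibble (`pair`, `left`, `right`) of channel indices, 13 rows}
#'     \item{pair_of_interest}{index into `pairs`}
#'     \item{adjacency}{31 x 31 logical matrix}
#'   }
#' @export
default_layout <- function() {
  # left-hemisphere template: three parasagittal columns plus one deep
  # posterior sensor (the pair of interest after mirroring)
  lx <- c(rep(-0.30, 5), rep(-0.60, 4), rep(-0.85, 3), -0.40)
  ly <- c(0.75, 0.375, 0, -0.375, -0.75,
          0.60, 0.20, -0.20, -0.60,
          0.40, 0.00, -0.40,
          -0.90)
  mz <- c(0.90, 0.45, 0.00, -0.45, -0.90)

  channels <- tibble::tibble(
    name = c(sprintf("L%02d", seq_along(lx)),
             sprintf("R%02d", seq_along(lx)),
             sprintf("Z%02d", seq_along(mz))),
    x = c(lx, -lx, rep(0, length(mz))),
    y = c(ly, ly, mz),
    hemisphere = c(rep("left", length(lx)), rep("right", length(lx)),
                   rep("midline", length(mz)))
  )

  n_l <- length(lx)
  pairs <- tibble::tibble(
    pair = seq_len(n_l),
    left = seq_len(n_l),
    right = n_l + seq_len(n_l)
  )
  poi <- which.min(ly)  # most posterior pair

  tri <- deldir::deldir(channels$x, channels$y, suppressMsge = TRUE)
  adj <- matrix(FALSE, nrow(channels), nrow(channels),
                dimnames = list(channels$name, channels$name))
  for (k in seq_len(nrow(tri$delsgs))) {
    i <- tri$delsgs$ind1[k]; j <- tri$delsgs$ind2[k]
    adj[i, j] <- TRUE
    adj[j, i] <- TRUE
  }

  structure(
    list(channels = channels, pairs = pairs, pair_of_interest = poi,
         adjacency = adj),
    class = "channel_layout"
  )
}

#' @export
print.channel_layout <- function(x, ...) {
  cat("<channel_layout> ", nrow(x$channels), " channels, ",
      nrow(x$pairs), " interhemispheric pairs (pair of interest: ",
      x$channels$name[x$pairs$left[x$pair_of_interest]], "-",
      x$channels$name[x$pairs$right[x$pair_of_interest]], ")\n", sep = "")
  invisible(x)
}

validate_layout <- function(layout) {
  stopifnot(inherits(layout, "channel_layout"))
  ch <- layout$channels
  if (nrow(ch) != 31L) stop("layout must have exactly 31 channels")
  if (nrow(layout$pairs) != 13L) stop("layout must declare 13 interhemispheric pairs")
  hl <- ch$hemisphere[layout$pairs$left]
  hr <- ch$hemisphere[layout$pairs$right]
  if (!all(hl == "left") || !all(hr == "right")) {
    stop("each pair must match one left with one right channel")
  }
  if (!isTRUE(all(layout$adjacency == t(layout$adjacency)))) {
    stop("adjacency must be symmetric")
  }
  if (any(diag(layout$adjacency))) stop("adjacency must be irreflexive")
  if (layout$pair_of_interest < 1 || layout$pair_of_interest > nrow(layout$pairs)) {
    stop("pair_of_interest out of range")
  }
  invisible(layout)
}

#' Adjacency between interhemispheric pairs
#'
#' Two pairs are adjacent when their left members or their right members are
#' adjacent channels; used for clustering statistics computed per pair.
#'
#' @param layout a `channel_layout`.
#' @return 13 x 13 logical matrix.
#' @export
pair_adjacency <- function(layout = default_layout()) {
  p <- layout$pairs
  a <- layout$adjacency
  n <- nrow(p)
  out <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      out[i, j] <- a[p$left[i], p$left[j]] || a[p$right[i], p$right[j]]
    }
  }
  out | t(out)
}

#' Write / read a layout as delimited text
#'
#' Serializes channel table, pair list and adjacency edges as a single
#' tab-separated file with section markers.
#'
#' @param layout a `channel_layout`.
#' @param path file path.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns a
#'   `channel_layout`.
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#channels\tname\tx\ty\themisphere", con)
  with(layout$channels, writeLines(sprintf("ch\t%s\t%.10g\t%.10g\t%s",
                                           name, x, y, hemisphere), con))
  writeLines("#pairs\tleft\tright", con)
  writeLines(sprintf("pr\t%d\t%d", layout$pairs$left, layout$pairs$right), con)
  writeLines(sprintf("#poi\t%d", layout$pair_of_interest), con)
  edges <- which(layout$adjacency & upper.tri(layout$adjacency), arr.ind = TRUE)
  writeLines("#adjacency\ti\tj", con)
  writeLines(sprintf("ad\t%d\t%d", edges[, 1], edges[, 2]), con)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(fields, `[[`, "", 1L)
  chf <- fields[tag == "ch"]
  channels <- tibble::tibble(
    name = vapply(chf, `[[`, "", 2L),
    x = as.numeric(vapply(chf, `[[`, "", 3L)),
    y = as.numeric(vapply(chf, `[[`, "", 4L)),
    hemisphere = vapply(chf, `[[`, "", 5L)
  )
  prf <- fields[tag == "pr"]
  pairs <- tibble::tibble(
    pair = seq_along(prf),
    left = as.integer(vapply(prf, `[[`, "", 2L)),
    right = as.integer(vapply(prf, `[[`, "", 3L))
  )
  poi <- as.integer(fields[tag == "#poi"][[1]][2])
  adj <- matrix(FALSE, nrow(channels), nrow(channels),
                dimnames = list(channels$name, channels$name))
  for (f in fields[tag == "ad"]) {
    i <- as.integer(f[2]); j <- as.integer(f[3])
    adj[i, j] <- adj[j, i] <- TRUE
  }
  validate_layout(structure(
    list(channels = channels, pairs = pairs, pair_of_interest = poi,
         adjacency = adj),
    class = "channel_layout"
  ))
}
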