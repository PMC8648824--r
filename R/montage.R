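#' Construct a rectangular grid montage
#'
#' Builds a channel layout on an `n_rows` x `n_cols` grid with 4-connected
#' spatial adjacency (horizontal and vertical grid neighbours). The neighbour
#' relation drives the spatial part of cluster connectivity and the
#' at-least-one-significant-neighbour restriction.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @return An object of class `eeg_montage`: list with `channels` (character
#'   vector), `positions` (n x 2 matrix of grid coordinates), and `neighbors`
#'   (named list mapping each channel to its neighbouring channel names; the
#'   relation is symmetric and irreflexive).
#' @examples
#' m <- make_montage(2, 2)
#' lengths(m$neighbors)        # every corner channel has 2 neighbours
#' @export
make_montage <- function(n_rows, n_cols) {
  if (n_rows < 1 || n_cols < 1) abort("n_rows and n_cols must be >= 1")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  rc <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  # row-major channel order: ch01 = (1,1), ch02 = (1,2), ...
  rc <- rc[order(rc$row, rc$col), ]
  n <- nrow(rc)
  channels <- sprintf("ch%02d", seq_len(n))
  positions <- cbind(x = rc$col, y = rc$row)
  rownames(positions) <- channels
  idx <- matrix(seq_len(n), nrow = n_rows, ncol = n_cols, byrow = TRUE)
  neighbors <- vector("list", n)
  names(neighbors) <- channels
  for (r in seq_len(n_rows)) for (cc in seq_len(n_cols)) {
    nb <- integer(0)
    if (r > 1) nb <- c(nb, idx[r - 1, cc])
    if (r < n_rows) nb <- c(nb, idx[r + 1, cc])
    if (cc > 1) nb <- c(nb, idx[r, cc - 1])
    if (cc < n_cols) nb <- c(nb, idx[r, cc + 1])
    neighbors[[idx[r, cc]]] <- channels[sort(nb)]
  }
  m <- list(channels = channels, positions = positions, neighbors = neighbors)
  class(m) <- "eeg_montage"
  validate_montage(m)
  m
}

#' Validate a montage's neighbour relation
#'
#' Checks that every channel is present in the neighbour map, that the
#' relation is symmetric and irreflexive, and that all named neighbours are
#' known channels.
#'
#' @param montage An `eeg_montage`.
#' @return The montage, invisibly; errors on violation.
#' @export
validate_montage <- function(montage) {
  ch <- montage$channels
  if (!setequal(names(montage$neighbors), ch))
    abort("neighbor map must cover exactly the montage channels")
  for (c1 in ch) {
    nb <- montage$neighbors[[c1]]
    if (c1 %in% nb) abort("channel %s is its own neighbor", c1)
    if (length(setdiff(nb, ch)))
      abort("channel %s has unknown neighbor(s)", c1)
    for (c2 in nb)
      if (!(c1 %in% montage$neighbors[[c2]]))
        abort("neighbor relation not symmetric: %s -> %s", c1, c2)
  }
  invisible(montage)
}

#' Read or write a montage as JSON
#'
#' Serialises channels, positions and the neighbour map.
#'
#' @param montage An `eeg_montage`.
#' @param path File path.
#' @return `read_montage` returns an `eeg_montage`; `write_montage` returns
#'   `path` invisibly.
#' @export
write_montage <- function(montage, path) {
  obj <- list(channels = montage$channels,
              positions = apply(montage$positions, 1, as.numeric,
                                simplify = FALSE),
              neighbors = montage$neighbors)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- do.call(rbind, obj$positions)
  colnames(pos) <- c("x", "y")
  rownames(pos) <- obj$channels
  nb <- lapply(obj$neighbors, as.character)
  m <- list(channels = obj$channels, positions = pos, neighbors = nb)
  class(m) <- "eeg_montage"
  validate_montage(m)
  m
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels, %d neighbor pairs\n",
              length(x$channels), sum(lengths(x$neighbors)) / 2))
  invisible(x)
}
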