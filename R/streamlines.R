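#' Streamline set container
#'
#' Stores polylines in world mm coordinates as one stacked coordinate matrix
#' plus per-streamline point counts, with a tag table (subdivision, subject,
#' side) carrying one row per streamline. This flat layout keeps large
#' tractograms cheap to concatenate and voxelize.
#'
#' @param coords numeric matrix with 3 columns (x, y, z in world mm), rows of
#'   all streamlines stacked in order.
#' @param npts integer vector, number of points of each streamline
#'   (`sum(npts) == nrow(coords)`).
#' @param tags data frame with one row per streamline; columns `subdivision`,
#'   `subject` and `side` are created (as `NA`) when missing.
#' @return an object of class `streamline_set`.
#' @export
streamline_set <- function(coords = matrix(numeric(), 0, 3),
                           npts = integer(),
                           tags = NULL) {
  coords <- rbind3_or_empty(coords)
  npts <- as.integer(npts)
  if (sum(npts) != nrow(coords))
    stop("sum(npts) must equal nrow(coords)")
  if (length(npts) && any(npts < 2L))
    stop("each streamline needs at least 2 points")
  if (nrow(coords) && !all(is.finite(coords)))
    stop("streamline coordinates must be finite")
  if (is.null(tags)) tags <- data.frame(row.names = seq_along(npts))
  for (col in c("subdivision", "subject", "side"))
    if (is.null(tags[[col]])) tags[[col]] <- rep(NA_character_, length(npts))
  tags <- as.data.frame(tags, stringsAsFactors = FALSE)
  if (nrow(tags) != length(npts))
    stop("tags must have one row per streamline")
  structure(list(coords = coords, npts = npts, tags = tags),
            class = "streamline_set")
}

rbind3_or_empty <- function(x) {
  if (is.null(dim(x)) && length(x) == 0) return(matrix(numeric(), 0, 3))
  rbind3(x)
}

#' Number of streamlines in a set
#' @param x a [streamline_set()].
#' @return integer count.
#' @export
n_streamlines <- function(x) length(x$npts)

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines, %d points\n",
              n_streamlines(x), nrow(x$coords)))
  if (n_streamlines(x)) {
    tab <- table(x$tags$subdivision, useNA = "no")
    if (length(tab))
      cat("  subdivisions:", paste(names(tab), tab, sep = "=", collapse = ", "),
          "\n")
  }
  invisible(x)
}

# row offsets: streamline i occupies rows (off[i]+1):(off[i]+npts[i])
sl_offsets <- function(x) c(0L, cumsum(x$npts))

#' Extract one streamline's points
#' @param x a [streamline_set()].
#' @param i streamline index.
#' @return n x 3 matrix of world mm points.
#' @export
streamline_points <- function(x, i) {
  off <- sl_offsets(x)
  x$coords[(off[i] + 1L):(off[i + 1L]), , drop = FALSE]
}

#' Subset a streamline set
#' @param x a [streamline_set()].
#' @param keep logical or integer index over streamlines.
#' @return a [streamline_set()] with the selected streamlines.
#' @export
subset_streamlines <- function(x, keep) {
  idx <- seq_len(n_streamlines(x))[keep]
  off <- sl_offsets(x)
  rows <- unlist(lapply(idx, function(i) (off[i] + 1L):(off[i + 1L])),
                 use.names = FALSE)
  streamline_set(x$coords[rows, , drop = FALSE], x$npts[idx],
                 x$tags[idx, , drop = FALSE])
}

#' Arc lengths of all streamlines
#' @param x a [streamline_set()].
#' @return numeric vector of polyline lengths in mm.
#' @export
streamline_lengths <- function(x) {
  if (!n_streamlines(x)) return(numeric())
  d <- x$coords[-1, , drop = FALSE] - x$coords[-nrow(x$coords), , drop = FALSE]
  seg <- sqrt(rowSums(d^2))
  # drop the spurious joints between consecutive streamlines
  ends <- cumsum(x$npts)
  joint <- ends[-length(ends)]
  if (length(joint)) seg <- seg[-joint]
  grp <- rep(seq_along(x$npts), x$npts - 1L)
  unname(rowsum(seg, grp)[, 1])
}

#' Concatenate streamline sets
#'
#' Used to merge per-subject groups of fibers into one group set; tags are
#' preserved row-by-row. Inputs that declare grids must agree on the affine.
#'
#' @param sets a list of [streamline_set()] objects.
#' @return a single [streamline_set()] containing all inputs in order.
#' @export
concat_streamlines <- function(sets) {
  stopifnot(length(sets) >= 1L)
  lapply(sets, function(s) stopifnot(inherits(s, "streamline_set")))
  tags <- do.call(rbind, lapply(sets, function(s) s$tags))
  streamline_set(do.call(rbind, lapply(sets, function(s) s$coords)),
                 unlist(lapply(sets, function(s) s$npts), use.names = FALSE),
                 tags)
}

#' Apply a point transform to every vertex
#' @param x a [streamline_set()].
#' @param f function mapping an n x 3 matrix of points to an n x 3 matrix.
#' @return transformed [streamline_set()].
#' @export
map_streamline_points <- function(x, f) {
  out <- x
  if (nrow(x$coords)) out$coords <- f(x$coords)
  out
}
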