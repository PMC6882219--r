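#' Read and write streamline sets
#'
#' Two formats are supported, chosen by extension:
#'
#' * `.tck` — the MRtrix track format: a text header followed by binary
#'   little-endian float32 point triplets, one `NaN` triplet between
#'   streamlines and an `Inf` triplet at the end. Coordinates are stored,
#'   as the format specifies, in world (scanner) mm — identical to this
#'   package's internal convention, so no voxel-space conversion applies.
#' * `.tsv` / `.txt` — a plain-text table (`streamline`, `x`, `y`, `z`; one
#'   point per row) for small fixtures.
#'
#' Per-streamline tags (`subdivision`, `subject`, `side`) are stored in a
#' JSON sidecar `<path>.tags.json` and restored on read.
#'
#' @param x a [streamline_set()].
#' @param path output path with a supported extension.
#' @return `write_streamlines` returns `path` invisibly; `read_streamlines`
#'   a [streamline_set()].
#' @export
write_streamlines <- function(x, path) {
  stopifnot(inherits(x, "streamline_set"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "tck") write_tck(x, path)
  else if (ext %in% c("tsv", "txt")) write_sl_table(x, path)
  else stop("unsupported streamline format '.", ext,
            "'; supported: .tck, .tsv, .txt")
  tags_path <- paste0(path, ".tags.json")
  jsonlite::write_json(as.list(x$tags), tags_path, auto_unbox = FALSE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_streamlines
#' @export
read_streamlines <- function(path) {
  ext <- tolower(tools::file_ext(path))
  out <- if (ext == "tck") read_tck(path)
  else if (ext %in% c("tsv", "txt")) read_sl_table(path)
  else stop("unsupported streamline format '.", ext,
            "'; supported: .tck, .tsv, .txt")
  tags_path <- paste0(path, ".tags.json")
  if (file.exists(tags_path)) {
    tg <- jsonlite::read_json(tags_path, simplifyVector = TRUE)
    if (length(tg) && length(tg[[1]]) == n_streamlines(out))
      out$tags <- data.frame(lapply(tg, function(col) {
        col[vapply(col, is.null, logical(1))] <- NA
        unlist(col)
      }), stringsAsFactors = FALSE)
  }
  out
}

write_tck <- function(x, path) {
  ntrk <- n_streamlines(x)
  hdr <- paste0("mrtrix tracks\n",
                "datatype: Float32LE\n",
                sprintf("count: %d\n", ntrk))
  # the 'file' line points at the binary offset; pad the header to a fixed
  # size so the offset is self-consistent
  offset <- nchar(hdr, type = "bytes") + 40L
  hdr <- paste0(hdr, sprintf("file: . %-10d\nEND\n", offset))
  stopifnot(nchar(hdr, type = "bytes") <= offset)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeBin(raw(offset - nchar(hdr, type = "bytes")), con)
  off <- sl_offsets(x)
  nan3 <- rep(NaN, 3)
  buf <- numeric(0)
  for (i in seq_len(ntrk)) {
    p <- x$coords[(off[i] + 1L):(off[i + 1L]), , drop = FALSE]
    buf <- c(buf, as.vector(t(p)), nan3)
  }
  buf <- c(buf, rep(Inf, 3))
  writeBin(as.numeric(buf), con, size = 4, endian = "little")
  invisible(path)
}

read_tck <- function(path) {
  if (!file.exists(path)) stop("no such track file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  # header: text lines up to END; find the binary offset from the file: line
  head_raw <- readBin(con, "raw", n = 4096)
  # decode only the text header (up to the END line); the rest is binary
  end_pat <- charToRaw("END\n")
  end_at <- NA_integer_
  for (i in seq_len(max(0, length(head_raw) - 3)))
    if (identical(head_raw[i:(i + 3)], end_pat)) { end_at <- i + 3L; break }
  if (is.na(end_at)) stop("malformed .tck header (no END line)")
  head_txt <- rawToChar(head_raw[seq_len(end_at)])
  if (!startsWith(head_txt, "mrtrix tracks"))
    stop(path, " is not an MRtrix .tck file")
  m <- regmatches(head_txt, regexec("file: \\. +([0-9]+)", head_txt))[[1]]
  if (length(m) < 2) stop("malformed .tck header (no file offset)")
  offset <- as.integer(m[2])
  seek(con, offset)
  vals <- readBin(con, "numeric", n = file.size(path), size = 4,
                  endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  is_end <- is.infinite(pts[, 1])
  is_sep <- is.nan(pts[, 1])
  if (any(is_end)) pts <- pts[seq_len(which(is_end)[1] - 1), , drop = FALSE]
  sep <- which(is.nan(pts[, 1]))
  starts <- c(1L, sep + 1L)
  ends <- c(sep - 1L, nrow(pts))
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(streamline_set())
  coords <- do.call(rbind, mapply(function(s, e)
    pts[s:e, , drop = FALSE], starts, ends, SIMPLIFY = FALSE))
  streamline_set(coords, ends - starts + 1L)
}

write_sl_table <- function(x, path) {
  off <- sl_offsets(x)
  df <- data.frame(streamline = rep(seq_along(x$npts), x$npts),
                   x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_sl_table <- function(path) {
  if (!file.exists(path)) stop("no such streamline table: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!nrow(df)) return(streamline_set())
  ids <- unique(df$streamline)
  npts <- vapply(ids, function(i) sum(df$streamline == i), integer(1))
  streamline_set(as.matrix(df[c("x", "y", "z")]), npts)
}
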