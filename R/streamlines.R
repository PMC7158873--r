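#' Streamline sets
#'
#' An ordered collection of 3-D polylines in world millimetres, the output of
#' fibre tractography. Each polyline is an n x 3 matrix with at least two
#' points and finite coordinates.
#'
#' @param polylines a list of numeric matrices (n_i x 3).
#' @param step nominal tracking step size in mm (metadata only).
#' @return an object of class `streamlines`.
#' @export
streamlines <- function(polylines, step = NA_real_) {
  if (!is.list(polylines)) stop("`polylines` must be a list of matrices")
  for (p in polylines) {
    if (!is.matrix(p) || ncol(p) != 3L || nrow(p) < 2L)
      stop("each polyline must be a matrix with 3 columns and >= 2 points")
    if (!all(is.finite(p))) stop("polyline coordinates must be finite")
  }
  structure(list(polylines = polylines, count = length(polylines),
                 step = step), class = "streamlines")
}

#' @export
print.streamlines <- function(x, ...) {
  np <- vapply(x$polylines, nrow, integer(1))
  cat("<streamlines> ", x$count, " polylines, ",
      if (x$count) paste0(min(np), "-", max(np)) else "0",
      " points each\n", sep = "")
  invisible(x)
}

#' Read and write streamlines in TCK format
#'
#' MRtrix TCK: a text header terminated by `END`, then little-endian float32
#' triplets with an all-NaN triplet between streamlines and an all-Inf
#' triplet at the end. Coordinates are world mm (scanner space).
#'
#' @param s a `streamlines` object.
#' @param path file path.
#' @return `read_tck` returns a `streamlines`; `write_tck` returns `path`
#'   invisibly.
#' @export
write_tck <- function(s, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c("mrtrix tracks",
              "datatype: Float32LE",
              sprintf("count: %d", s$count))
  # file_offset must account for its own line; compute with a fixed-width field
  body <- paste0(paste(header, collapse = "\n"), "\n")
  offset_line_len <- nchar("file: . ") + 6 + 1   # 6-digit zero-padded offset
  offset <- nchar(body) + offset_line_len + nchar("END\n")
  body <- paste0(body, sprintf("file: . %06d\n", offset), "END\n")
  writeChar(body, con, eos = NULL)
  for (p in s$polylines) {
    writeBin(as.vector(t(p)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # locate the END marker while still in the text header (binary data may
  # contain nul bytes, so only the header region is decoded)
  end_pat <- charToRaw("\nEND\n")
  header_end <- NA_integer_
  for (i in seq_len(min(length(raw) - 4L, 4096L))) {
    if (raw[i] == end_pat[1] && all(raw[i + 1:4] == end_pat[2:5])) {
      header_end <- i + 4L
      break
    }
  }
  if (is.na(header_end)) stop("TCK header has no END marker")
  txt <- rawToChar(raw[seq_len(header_end)])
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (!grepl("^mrtrix tracks", lines[1])) stop("not a TCK file: ", path)
  offs <- grep("^file: ", lines, value = TRUE)
  if (!length(offs)) stop("TCK header missing file offset")
  offset <- as.integer(sub("^file: \\S+ ", "", offs[1]))
  n <- (length(raw) - offset) %/% 4L
  vals <- readBin(raw[(offset + 1):length(raw)], "numeric", n = n, size = 4L,
                  endian = "little")
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  sep <- rowSums(!is.finite(m)) > 0
  idx <- cumsum(sep)
  polys <- list()
  for (g in split(seq_len(nrow(m))[!sep], idx[!sep]))
    polys[[length(polys) + 1L]] <- m[g, , drop = FALSE]
  streamlines(polys)
}
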