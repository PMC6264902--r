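#' Write a retina pattern to CSV
#'
#' One lattice row per line, comma-separated 0/1 values, optionally
#' preceded by a `#`-prefixed metadata line recording the dimensions and
#' the furrow convention (column 1 = posterior-most).
#'
#' @param pattern A [retina_pattern()] or plain binary matrix.
#' @param path Output file path.
#' @param header Write the metadata comment line (default `TRUE`).
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_pattern(retina_pattern(diag(1L, 3)), f)
#' read_pattern(f)
#' @export
write_pattern <- function(pattern, path, header = TRUE) {
  a <- as_retina_pattern(pattern)
  lines <- apply(a, 1L, paste, collapse = ",")
  if (header) {
    lines <- c(sprintf("# rows=%d cols=%d origin=posterior",
                       nrow(a), ncol(a)), lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a retina pattern from CSV
#'
#' Parses comma-separated 0/1 rows as written by [write_pattern()];
#' `#`-prefixed lines and blank lines are skipped. Rectangularity and
#' binary values are validated with distinct error messages.
#'
#' @param path Path to the CSV file.
#' @return A [retina_pattern()].
#' @export
read_pattern <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("empty pattern file: ", path, call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop("ragged rows: lines have differing numbers of cells",
         call. = FALSE)
  vals <- suppressWarnings(as.numeric(trimws(unlist(cells))))
  if (anyNA(vals) || !all(vals %in% c(0, 1)))
    stop("non-binary cell: pattern values must be 0 or 1", call. = FALSE)
  retina_pattern(matrix(as.integer(vals), nrow = length(lines),
                        ncol = widths[1L], byrow = TRUE))
}

#' Render a retina pattern to a PNG image
#'
#' Draws the pattern as a hex-packed raster: each ommatidium is a square
#' block of `cell` pixels, with alternate columns offset vertically by
#' half a cell to suggest the hexagonal lattice. Green cells (1) are drawn
#' green, red cells (0) red. Columns are flipped horizontally so that the
#' anterior (last-generated) side appears on the left, matching the usual
#' presentation of fly eyes. Requires the `png` package.
#'
#' @param pattern A [retina_pattern()] or plain binary matrix.
#' @param path Output PNG path.
#' @param cell Edge length of one cell in pixels.
#' @param flip Draw anterior on the left (default `TRUE`).
#' @return `path`, invisibly.
#' @export
render_pattern <- function(pattern, path, cell = 10, flip = TRUE) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("render_pattern() requires the `png` package", call. = FALSE)
  a <- as_retina_pattern(pattern)
  stopifnot(is.numeric(cell), cell >= 1)
  cell <- as.integer(cell)
  n <- nrow(a); m <- ncol(a)
  half <- cell %/% 2L
  height <- n * cell + half
  width <- m * cell
  img <- array(1, dim = c(height, width, 3))  # white background
  green <- c(0.13, 0.65, 0.25)
  red <- c(0.80, 0.12, 0.10)
  for (j in seq_len(m)) {
    jj <- if (flip) m - j + 1L else j  # display column
    x0 <- (jj - 1L) * cell
    off <- if (jj %% 2L == 0L) half else 0L
    for (i in seq_len(n)) {
      y0 <- (i - 1L) * cell + off
      col <- if (a[i, j] == 1L) green else red
      img[(y0 + 1L):(y0 + cell), (x0 + 1L):(x0 + cell), ] <-
        rep(col, each = cell * cell)
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
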