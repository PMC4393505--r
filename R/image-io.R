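#' Read a grayscale image (PGM or PNG)
#'
#' Reads an 8-bit grayscale raster into a numeric matrix with rows indexed
#' top to bottom and columns left to right.  PGM files may be plain (`P2`)
#' or binary (`P5`) with `maxval <= 255`; PNG files are read through the
#' \pkg{png} package and collapsed to a single channel if necessary.
#'
#' @param path Path to a `.pgm` or `.png` file.
#' @return Numeric matrix with values in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    pgm = read_pgm(path),
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- a[, , 1L]
      round(a * 255)
    },
    stop_field("path", sprintf("unsupported image extension '%s'", ext))
  )
  img
}

#' Write a grayscale image (PGM or PNG)
#'
#' @param image Numeric matrix, values in `[0, 255]`.
#' @param path Output path; format chosen from the extension.
#' @param ascii For PGM, write plain `P2` text instead of binary `P5`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path, ascii = FALSE) {
  stopifnot(is.matrix(image))
  image <- pmin(pmax(round(image), 0), 255)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = write_pgm(image, path, ascii = ascii),
    png = png::writePNG(image / 255, target = path),
    stop_field("path", sprintf("unsupported image extension '%s'", ext))
  )
  invisible(path)
}

# Plain/binary PGM reader.  Comments (#...) allowed anywhere in the header.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5"))
    stop_field("path", sprintf("not a PGM file (magic '%s')", magic))
  header <- integer(0)
  buf <- character(0)
  # token scanner that skips whitespace and comments
  next_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") {
        if (nzchar(tok)) return(tok)
        stop_field("path", "truncated PGM header")
      }
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch %in% c("\n", "\r", "")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else tok <- paste0(tok, ch)
    }
  }
  w <- as.integer(next_token())
  h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval > 255L)
    stop_field("path", "bad PGM header (only maxval <= 255 supported)")
  n <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = n))
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE,
                 comment.char = "#")
  }
  if (length(vals) < n) stop_field("path", "truncated PGM pixel data")
  # PGM stores rows top-to-bottom in row-major order
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(image, path, ascii = FALSE) {
  h <- nrow(image); w <- ncol(image)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    write(t(image), file = con, ncolumns = min(w, 20L))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(as.integer(t(image))), con)
  }
  invisible(path)
}

#' Write a binary mask as a PGM image
#'
#' Foreground is written as 255 and background as 0.
#'
#' @param mask Logical matrix.
#' @param path Output `.pgm` path.
#' @param ascii Write plain-text `P2` instead of binary `P5`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, ascii = FALSE) {
  assert_mask(mask)
  write_pgm(ifelse(mask, 255L, 0L) * 1L, path, ascii = ascii)
}

#' Read a PGM mask back as a logical matrix
#'
#' @param path Path to a PGM file; nonzero pixels become `TRUE`.
#' @return Logical matrix.
#' @export
read_mask <- function(path) read_pgm(path) > 0
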