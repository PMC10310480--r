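#' Read a grayscale image from PNG, TIFF or JPEG
#'
#' Decodes the file to a numeric intensity matrix in \[0, 1\]. 8-bit
#' samples are divided by 255 and 16-bit samples by 65535 (the underlying
#' decoders already return this normalization). Color inputs are reduced to
#' luminance with the Rec. 709 weights
#' \eqn{0.2126\,R + 0.7152\,G + 0.0722\,B}; an alpha channel, if present,
#' is discarded. The source bit depth is recorded in the `"bit_depth"`
#' attribute.
#'
#' JPEG is accepted as an input format only (it is lossy); writing is
#' restricted to lossless PNG/TIFF, see [write_gray_image()].
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return Numeric matrix in \[0, 1\] with attribute `bit_depth` (8 or 16).
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image '%s': file does not exist", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw_img <- tryCatch(switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("the 'jpeg' package is required to read JPEG files")
      }
      jpeg::readJPEG(path)
    },
    stop(sprintf("unsupported image format '.%s' (PNG, TIFF, JPEG only)",
                 ext))
  ), error = function(e) {
    stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })

  bit_depth <- guess_bit_depth(raw_img, ext)
  img <- if (length(dim(raw_img)) == 3L) {
    ch <- dim(raw_img)[3]
    if (ch >= 3L) {
      0.2126 * raw_img[, , 1] + 0.7152 * raw_img[, , 2] +
        0.0722 * raw_img[, , 3]
    } else {
      raw_img[, , 1]   # gray + alpha
    }
  } else {
    raw_img
  }
  img <- pmin(pmax(img, 0), 1)
  attr(img, "bit_depth") <- bit_depth
  img
}

#' Write a grayscale image as 8-bit PNG or 16-bit TIFF
#'
#' Quantizes intensities by `round(v * (2^bit_depth - 1))` using
#' round-half-away-from-zero (so intensity 0.5 at 8 bits stores 128, not
#' the banker's-rounding 127.5 -> 128 ambiguity) and writes losslessly.
#' 8-bit output goes to PNG, 16-bit to TIFF; the extension must match.
#'
#' @param image Numeric matrix with values in \[0, 1\].
#' @param path Output path: `.png` for `bit_depth = 8`, `.tif`/`.tiff` for
#'   `bit_depth = 16`.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path, bit_depth = 8L) {
  check_image(image)
  if (!bit_depth %in% c(8L, 16L)) {
    stop("'bit_depth' must be 8 or 16", call. = FALSE)
  }
  levels <- 2^bit_depth - 1
  q <- round_half_away(image * levels) / levels
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (bit_depth == 8L) {
      if (!ext %in% "png") {
        stop("8-bit output must use a .png path")
      }
      png::writePNG(q, path)
    } else {
      if (!ext %in% c("tif", "tiff")) {
        stop("16-bit output must use a .tif/.tiff path")
      }
      tiff::writeTIFF(q, path, bits.per.sample = 16L)
    }
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write image '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

# round half away from zero (base round() is round-half-even)
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

guess_bit_depth <- function(raw_img, ext) {
  # PNG/JPEG decoders normalize 8-bit to /255 and (PNG) 16-bit to /65535;
  # a 16-bit source leaves values off the 1/255 grid.
  on_8bit_grid <- all(abs(raw_img * 255 - round(raw_img * 255)) < 1e-9)
  if (on_8bit_grid) 8L else 16L
}
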