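# Image and metadata I/O: format dispatch, transform JSON, run
# manifests.

#' Read a 2-D grayscale image
#'
#' Dispatches on the file magic: PNG (8/16-bit grayscale or RGB, see
#' [read_png()]) or PGM (`P2` ASCII / `P5` binary).  RGB is converted by
#' luminance, 16-bit rescaled linearly to `[0, 255]`.  TIFF and DICOM
#' are deliberately not supported; convert to PNG first.
#'
#' @param path image file path.
#' @return numeric matrix in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file '%s' does not exist", path))
  magic <- readBin(path, "raw", 8L)
  if (length(magic) >= 8 && identical(magic[1:8], png_sig)) return(read_png(path))
  if (length(magic) >= 2 && magic[1L] == charToRaw("P")) {
    tag <- rawToChar(magic[2L])
    if (tag %in% c("2", "5")) return(read_pgm(path))
  }
  stop(sprintf("unsupported image format for '%s' (expected PNG or PGM; convert TIFF/DICOM to PNG)", path))
}

#' Write a grayscale image
#'
#' 8-bit grayscale PNG (values rounded and clipped to `[0, 255]`).
#'
#' @param image numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) write_png(image, path)

read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  tok <- function() {  # next whitespace-separated token, skipping comments
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch)) stop("truncated PGM header")
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
                                if (!length(c2) || c2 == "\n") break } ; next }
      if (!grepl("^\\s$", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || grepl("^\\s$", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  W <- as.integer(tok()); H <- as.integer(tok()); mx <- as.integer(tok())
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = W * H, quiet = TRUE)
  } else if (magic == "P5") {
    if (mx > 255) stop("16-bit binary PGM not supported")
    as.integer(readBin(con, "raw", W * H))
  } else stop("not a PGM file")
  img <- matrix(as.numeric(vals), H, W, byrow = TRUE)
  if (mx != 255) img <- img * (255 / mx)
  img
}

write_pgm <- function(image, path) {
  px <- as.integer(round(clamp(image, 0, 255)))
  m <- matrix(px, nrow(image), ncol(image))
  lines <- c("P2", sprintf("%d %d", ncol(image), nrow(image)), "255",
             apply(m, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a rigid transform to JSON
#'
#' @param transform a [rigid_transform()].
#' @param path optional file path.
#' @return JSON string (invisibly when written to a file).
#' @export
transform_to_json <- function(transform, path = NULL) {
  js <- jsonlite::toJSON(list(tx = transform$tx, ty = transform$ty,
                              angle_deg = transform$angle),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read a rigid transform from JSON
#'
#' @param x JSON string or file path.
#' @return a [rigid_transform()].
#' @export
transform_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  rigid_transform(doc$tx, doc$ty, doc$angle_deg %||% doc$angle)
}

#' Write a registration result to disk
#'
#' Writes the estimated transform as JSON at `path`, a run manifest
#' (seed, package version, convergence diagnostics, output paths) next
#' to it, and optionally the warped floating image as PNG.
#'
#' @param result a `registration_result` from [register_images()].
#' @param path output path for the transform JSON.
#' @param pair optional [image_pair()]; required when `warped` is given.
#' @param warped optional PNG path for `warp_image(floating, transform)`.
#' @return character vector of files written, invisibly.
#' @export
write_result <- function(result, path, pair = NULL, warped = NULL) {
  transform_to_json(result$transform, path)
  files <- path
  if (!is.null(warped)) {
    if (is.null(pair)) stop("writing the warped image requires the image pair")
    w <- warp_image(pair$floating, result$transform, fill = 0)
    write_png(w$image, warped)
    files <- c(files, warped)
  }
  manifest <- sub("\\.json$", "", path)
  manifest <- paste0(manifest, "_manifest.json")
  doc <- list(
    package = "bggreg",
    version = as.character(utils::packageVersion("bggreg")),
    seed = result$seed,
    transform = list(tx = result$transform$tx, ty = result$transform$ty,
                     angle_deg = result$transform$angle),
    converged = result$converged,
    iterations_used = result$iterations_used,
    pad = result$pad,
    outputs = files)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null"),
             manifest)
  invisible(c(files, manifest))
}
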