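# Plain-format serialization: multi-page 32-bit float TIFF for image
# stacks, with a JSON sidecar carrying the affine scaling, mode and
# acquisition metadata.  Complex data are stored as interleaved
# real/imaginary pages.

sidecar_path <- function(path) paste0(path, ".json")

page_encode <- function(x) {
  rng <- range(x)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  list(page = (x - rng[1]) / scale, offset = rng[1], scale = scale)
}

#' Write a single image as 32-bit float TIFF
#'
#' @param x Real matrix.
#' @param path Output file; a `.json` sidecar records the affine scaling.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path) {
  enc <- page_encode(x)
  tiff::writeTIFF(enc$page, path, bits.per.sample = 32)
  jsonlite::write_json(list(kind = "image", offset = enc$offset,
                            scale = enc$scale, dim = dim(x)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a frame stack as multi-page TIFF with a JSON sidecar
#'
#' Real (incoherent) stacks are written one page per frame; complex
#' (coherent) stacks as interleaved real/imaginary page pairs.  The sidecar
#' records the per-page affine scaling, the mode, the seed and any
#' simulation metadata, so [read_frame_stack()] round-trips to within
#' 32-bit float precision.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF file.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  fr <- stack$frames
  M <- dim(fr)[3]
  complexmode <- is.complex(fr)
  pages <- list()
  offs <- numeric(0); scls <- numeric(0)
  for (m in seq_len(M)) {
    parts <- if (complexmode) list(Re(fr[, , m]), Im(fr[, , m])) else list(fr[, , m])
    for (p in parts) {
      enc <- page_encode(p)
      pages[[length(pages) + 1L]] <- enc$page
      offs <- c(offs, enc$offset); scls <- c(scls, enc$scale)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  meta <- stack$meta
  meta$modulation$factors <- NULL
  jsonlite::write_json(list(kind = "frame_stack", mode = stack$mode,
                            complex = complexmode, M = M,
                            dim = dim(fr)[1:2], seed = stack$seed,
                            offset = offs, scale = scls, meta = meta),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF file with its `.json` sidecar alongside.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path) {
  info <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(seq_along(pages),
                  function(i) pages[[i]] * info$scale[i] + info$offset[i])
  d <- c(info$dim, info$M)
  if (isTRUE(info$complex)) {
    fr <- array(0i, d)
    for (m in seq_len(info$M)) {
      fr[, , m] <- pages[[2 * m - 1]] + 1i * pages[[2 * m]]
    }
  } else {
    fr <- array(unlist(pages), d)
  }
  frame_stack(fr, info$mode, seed = info$seed,
              meta = if (is.null(info$meta)) list() else info$meta)
}

#' Write / read a complex field as paired TIFF pages
#'
#' @param field A [complex_field()] or complex matrix.
#' @param path TIFF file path.
#' @return `path` (write) or a [complex_field()] (read).
#' @export
write_field <- function(field, path) {
  cf <- if (inherits(field, "complex_field")) field else complex_field(field)
  er <- page_encode(Re(cf$field)); ei <- page_encode(Im(cf$field))
  tiff::writeTIFF(list(er$page, ei$page), path, bits.per.sample = 32)
  jsonlite::write_json(list(kind = "field", plane = cf$plane,
                            pitch_um = cf$pitch_um,
                            offset = c(er$offset, ei$offset),
                            scale = c(er$scale, ei$scale),
                            dim = dim(cf$field)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  info <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  re <- pages[[1]] * info$scale[1] + info$offset[1]
  im <- pages[[2]] * info$scale[2] + info$offset[2]
  complex_field(re + 1i * im, info$pitch_um, info$plane)
}
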