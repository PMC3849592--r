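#' Three-channel image stack of one microscopic field
#'
#' Container for the co-registered channels of one field: sarcolemma
#' (membrane) label, carbonyl label and HNE label, all in gsu on a 12-bit
#' scale, plus the physical pixel size.
#'
#' @param membrane,carbonyl,hne Numeric matrices of identical dimensions
#'   with values in \[0, 4095\].
#' @param pixel_size_um Micrometers per pixel (> 0).
#' @return An `image_stack` object.
#' @export
image_stack <- function(membrane, carbonyl, hne, pixel_size_um) {
  stopifnot(
    is.matrix(membrane), is.matrix(carbonyl), is.matrix(hne),
    identical(dim(membrane), dim(carbonyl)),
    identical(dim(membrane), dim(hne)),
    pixel_size_um > 0,
    min(membrane, carbonyl, hne) >= 0,
    max(membrane, carbonyl, hne) <= GSU_MAX
  )
  structure(list(membrane = membrane, carbonyl = carbonyl, hne = hne,
                 pixel_size_um = pixel_size_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d x %d px, %.3g um/px\n",
              nrow(x$membrane), ncol(x$membrane), x$pixel_size_um))
  for (ch in c("membrane", "carbonyl", "hne"))
    cat(sprintf("  %-9s range [%g, %g] gsu\n", ch, min(x[[ch]]), max(x[[ch]])))
  invisible(x)
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Page order: membrane, carbonyl, HNE. The 12-bit data are stored in a
#' 16-bit container; pixel values are rounded to integers on write.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  pages <- lapply(stack[c("membrane", "carbonyl", "hne")],
                  function(m) round(m) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  # pixel size travels in the sidecar manifest; TIFF resolution tags are
  # not round-tripped portably by all readers
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' Expects the page order written by [write_image_stack()] (membrane,
#' carbonyl, HNE) in a 16-bit container holding 12-bit data.
#'
#' @param path TIFF file path.
#' @param pixel_size_um Micrometers per pixel of the acquisition.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, pixel_size_um) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3)
    stop("expected 3 channels (membrane, carbonyl, hne), found ",
         length(pages), " in ", path)
  to_gsu <- function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    round(m * 65535)
  }
  pages <- lapply(pages, to_gsu)
  image_stack(pages[[1]], pages[[2]], pages[[3]], pixel_size_um)
}

#' Write a label map as a 16-bit TIFF
#'
#' Page 1 holds the fiber labels; when the map carries the segmentation's
#' membrane classification, it is stored as a second (binary) page so that
#' background estimation downstream can distinguish the extracellular rim
#' from filtered-out fiber interiors.
#'
#' @param label_map A [label_map()] or integer matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(label_map, path) {
  if (inherits(label_map, "label_map")) {
    m <- label_map$labels
    mask <- label_map$membrane_mask
  } else {
    m <- label_map
    mask <- NULL
  }
  pages <- list(m / 65535)
  if (!is.null(mask)) pages <- c(pages, list(mask * 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#' @param path TIFF file path.
#' @return A [label_map()]; the membrane mask is restored when the file
#'   carries one.
#' @export
read_label_map <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  flat <- function(m) if (length(dim(m)) == 3) m[, , 1] else m
  m <- flat(pages[[1]])
  labels <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  mask <- if (length(pages) > 1) flat(pages[[2]]) > 0.5 else NULL
  label_map(labels, membrane_mask = mask)
}
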