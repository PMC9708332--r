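# Label-map I/O. Primary on-disk form: 16-bit grayscale PNG/TIFF (lossless
# for labels up to 65535); secondary: plain TSV integer grids. Round trips
# are bit-exact.

map_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png", "tif", "tiff")) "image" else if (ext %in% c("tsv", "txt")) {
    "tsv"
  } else {
    stop("unsupported label-map extension '", ext, "' for ", path,
         " (use .png/.tif/.tiff or .tsv)")
  }
}

# ---- minimal 16-bit grayscale PNG writer ------------------------------------
# No installed package writes 16-bit PNG (EBImage and png::writePNG emit
# 8-bit), so the container is assembled directly: IHDR (bit depth 16,
# grayscale), one zlib-compressed IDAT (memCompress emits the zlib format),
# IEND, with table-driven CRC-32.

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(bitwAnd(c, -2L), 1L), -306674912L)  # 0xEDB88320
      } else {
        bitwShiftR(bitwAnd(c, -2L), 1L)
      }
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    c <- bitwXor(crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L],
                 bitwShiftR(bitwAnd(c, -256L), 8L))
  }
  bitwXor(c, -1L)
}

u32_raw <- function(x) {
  # unsigned 32-bit big-endian from a (possibly negative) 32-bit integer
  writeBin(as.integer(x), raw(), size = 4L, endian = "big")
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_raw(length(data)), body, u32_raw(crc32(body)))
}

write_png16 <- function(map, path) {
  h <- nrow(map); w <- ncol(map)
  ihdr <- c(u32_raw(w), u32_raw(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  v <- as.integer(t(map))                       # scanline (row) major
  hi <- as.raw(v %/% 256L); lo <- as.raw(v %% 256L)
  pix <- as.raw(as.vector(rbind(hi, lo)))       # big-endian 16-bit samples
  scan <- matrix(pix, nrow = 2L * w)
  lines <- as.raw(rbind(as.raw(0L), scan))      # filter byte 0 per scanline
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", memCompress(as.vector(lines), "gzip")), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

#' Read an instance or type label map
#'
#' Accepts 8/16-bit grayscale PNG or TIFF (pixel values are the labels) or a
#' TSV integer grid. RGB images and non-integer values are errors.
#'
#' @param path file path.
#' @return integer matrix.
#' @export
read_instance_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (map_format(path) == "tsv") {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) > 2L) {
      stop("expected a grayscale label image, got ", dim(img)[3],
           " channels: ", path)
    }
    m <- img * 65535
  } else {
    img <- EBImage::readImage(path)
    d <- dim(img)
    if (length(d) > 2L && d[3] > 1L) {
      stop("expected a grayscale label image, got ", d[3], " channels: ", path)
    }
    m <- t(as.matrix(img) * 65535)
  }
  if (any(abs(m - round(m)) > 1e-6)) {
    stop("non-integer label value ", m[which.max(abs(m - round(m)))],
         " in ", path)
  }
  m <- round(m)
  if (any(m < 0)) stop("negative label value ", min(m), " in ", path)
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Write an instance or type label map
#'
#' @param map integer matrix (labels 0..65535).
#' @param path destination; `.png`/`.tif`/`.tiff` writes 16-bit grayscale,
#'   `.tsv` a plain integer grid.
#' @return the path, invisibly.
#' @export
write_instance_map <- function(map, path) {
  check_instance_map(map)
  if (max(map) > 65535) stop("labels above 65535 cannot be stored losslessly")
  type <- tolower(tools::file_ext(path))
  if (map_format(path) == "tsv") {
    utils::write.table(map, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  } else if (type == "png") {
    write_png16(matrix(as.integer(map), nrow(map), ncol(map)), path)
  } else {
    if (type == "tif") type <- "tiff"
    EBImage::writeImage(EBImage::Image(t(map) / 65535), path, type = type,
                        bits = 16L)
  }
  invisible(path)
}

#' Write a rendered scene image
#' @param image H x W x 3 array in `[0, 1]`.
#' @param path `.png` or `.tif`/`.tiff` destination.
#' @return the path, invisibly.
#' @export
write_scene_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  type <- tolower(tools::file_ext(path))
  if (type == "tif") type <- "tiff"
  img <- EBImage::Image(aperm(image, c(2L, 1L, 3L)), colormode = "Color")
  EBImage::writeImage(img, path, type = type, bits = 8L)
  invisible(path)
}

#' Remap labels of a type map
#'
#' Applies an old-to-new lookup to every positive label; labels without an
#' entry are kept. Used e.g. to merge fine-grained nuclear classes into
#' coarser ones before evaluation.
#'
#' @param map integer label map.
#' @param mapping named integer vector: names are old labels, values new.
#' @return remapped integer matrix.
#' @export
remap_labels <- function(map, mapping) {
  check_instance_map(map)
  out <- map
  for (old in names(mapping)) {
    out[map == as.integer(old)] <- as.integer(mapping[[old]])
  }
  out
}

#' Class merge for 7-type colorectal nuclei annotations
#'
#' The conventional merge for the 7-class colorectal labelling: normal and
#' malignant/dysplastic epithelium (3, 4) become one epithelial class;
#' fibroblast, muscle and endothelium (5, 6, 7) become one spindle-shaped
#' class. Resulting classes: 1 other, 2 inflammatory, 3 epithelial,
#' 4 spindle.
#'
#' @return named integer vector usable with [remap_labels()].
#' @export
consep_class_merge <- function() {
  c(`1` = 1L, `2` = 2L, `3` = 3L, `4` = 3L, `5` = 4L, `6` = 4L, `7` = 4L)
}

#' Save / load a prediction stack
#'
#' Prediction stacks (float probability and distance maps) are exchanged as
#' RDS files.
#'
#' @param stack a `prediction_stack`.
#' @param path `.rds` destination.
#' @return the path (write) or the stack (read).
#' @export
write_prediction_stack <- function(stack, path) {
  stopifnot(inherits(stack, "prediction_stack"))
  saveRDS(stack, path)
  invisible(path)
}

#' @rdname write_prediction_stack
#' @export
read_prediction_stack <- function(path) {
  stack <- readRDS(path)
  stopifnot(inherits(stack, "prediction_stack"))
  stack
}
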