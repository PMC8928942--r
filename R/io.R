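#' Read an MRC/MRCS image or stack
#'
#' Minimal reader for the MRC2014 format: parses the 1024-byte header,
#' skips any extended header, and reads data modes 0 (int8), 1 (int16),
#' 2 (float32) and 6 (uint16), little-endian. Each section must be
#' square.
#'
#' @param path path to an `.mrc`/`.mrcs` file.
#' @return a list of numeric m x m matrices (row = y, column = x), with
#'   attributes `pixel_size` (Angstrom per pixel, when the header records
#'   a cell) and `mode`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 1024L)
  if (length(hdr) < 1024L) stop("corrupt MRC header: file too short",
                                call. = FALSE)
  int_at <- function(off) readBin(hdr[(off + 1):(off + 4)], "integer",
                                  size = 4, endian = "little")
  flt_at <- function(off) readBin(hdr[(off + 1):(off + 4)], "numeric",
                                  size = 4, endian = "little")
  nx <- int_at(0); ny <- int_at(4); nz <- int_at(8)
  mode <- int_at(12)
  mx <- int_at(28)
  xlen <- flt_at(40)
  nsymbt <- int_at(92)
  if (nx <= 0 || ny <= 0 || nz <= 0 || nx > 1e5 || ny > 1e5 || nz > 1e6)
    stop("corrupt MRC header: implausible dimensions", call. = FALSE)
  if (nx != ny)
    stop(sprintf("non-square MRC sections: %d x %d", nx, ny), call. = FALSE)
  if (nsymbt < 0 || nsymbt > 1e7)
    stop("corrupt MRC header: bad extended header size", call. = FALSE)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  n <- nx * ny * nz
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                             endian = "little")),
    stop(sprintf("unsupported MRC mode %d", mode), call. = FALSE))
  if (length(data) < n) stop("truncated MRC data block", call. = FALSE)
  imgs <- vector("list", nz)
  for (k in seq_len(nz)) {
    # MRC stores x fastest; transpose so rows are y and columns are x
    imgs[[k]] <- t(matrix(data[((k - 1) * nx * ny + 1):(k * nx * ny)],
                          nx, ny))
  }
  attr(imgs, "mode") <- mode
  if (mx > 0 && xlen > 0) attr(imgs, "pixel_size") <- xlen / mx
  imgs
}

#' Write images to an MRC/MRCS stack
#'
#' Writes a list of equally sized square images as a mode-2 (float32)
#' MRC2014 stack, little-endian, with the `MAP ` tag and machine stamp.
#'
#' @param images a single matrix or a list of numeric m x m matrices.
#' @param path output path.
#' @param pixel_size Angstrom per pixel recorded in the cell header
#'   (default 1).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(images, path, pixel_size = 1) {
  if (is.matrix(images)) images <- list(images)
  m <- nrow(images[[1]])
  for (im in images) {
    assert_square_image(im)
    if (nrow(im) != m) stop("stack images have mixed sizes", call. = FALSE)
  }
  nz <- length(images)
  all_vals <- unlist(lapply(images, function(im) as.vector(t(im))))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(c(m, m, nz))            # nx ny nz
  wi(2L)                     # mode 2: float32
  wi(c(0L, 0L, 0L))          # nxstart nystart nzstart
  wi(c(m, m, nz))            # mx my mz
  wf(c(m, m, nz) * pixel_size)  # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1L, 2L, 3L))          # mapc mapr maps
  wf(c(min(all_vals), max(all_vals), mean(all_vals)))  # dmin dmax dmean
  wi(c(1L, 0L))              # ispg, nsymbt
  writeBin(raw(100), con)    # extra
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(all_vals))    # rms
  wi(0L)                     # nlabl
  writeBin(raw(800), con)    # labels
  wf(all_vals)
  invisible(path)
}

#' Read a particle stack or single image
#'
#' Dispatches on the file extension: `.mrc`/`.mrcs` stacks go through
#' [read_mrc()]; single `.png` and `.tif`/`.tiff` images are read through
#' the png and tiff packages (color images are averaged to one channel).
#'
#' @param path input file.
#' @return an object of class `"particle_stack"`: a list with `images`
#'   (list of m x m matrices), `m`, `n`, `pixel_size` (or `NA`), and
#'   `source`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- NA_real_
  if (ext %in% c("mrc", "mrcs")) {
    imgs <- read_mrc(path)
    if (!is.null(attr(imgs, "pixel_size"))) px <- attr(imgs, "pixel_size")
    attributes(imgs) <- NULL
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to read PNG files", call. = FALSE)
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                        c(1, 2), mean)
    imgs <- list(a)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to read TIFF files", call. = FALSE)
    a <- tiff::readTIFF(path)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                        c(1, 2), mean)
    imgs <- list(a)
  } else {
    stop("unsupported input format: .", ext, call. = FALSE)
  }
  for (im in imgs) {
    if (nrow(im) != ncol(im))
      stop(sprintf("non-square image in %s: %d x %d", basename(path),
                   nrow(im), ncol(im)), call. = FALSE)
  }
  m <- nrow(imgs[[1]])
  for (im in imgs) if (nrow(im) != m)
    stop("mixed image dimensions in stack", call. = FALSE)
  structure(list(images = imgs, m = m, n = length(imgs),
                 pixel_size = px, source = path),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  cat(sprintf("Particle stack: %d image(s), %d x %d px%s\n", x$n, x$m, x$m,
              if (is.na(x$pixel_size)) ""
              else sprintf(", %.3g A/px", x$pixel_size)))
  cat("source:", x$source, "\n")
  invisible(x)
}

#' Write classification results to a directory
#'
#' Writes the class averages as an MRCS stack, the per-image labels and
#' alignment parameters as a CSV with a header row, and a JSON manifest
#' recording the configuration, seed, and package version. Re-running the
#' pipeline with the manifest's configuration and seed reproduces the
#' label CSV byte for byte.
#'
#' @param classes a `"cryo_classes"` object from [classify_stack()].
#' @param out_dir output directory (created if missing).
#' @param pixel_size Angstrom per pixel for the averages stack.
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
write_results <- function(classes, out_dir, pixel_size = 1) {
  if (!inherits(classes, "cryo_classes"))
    stop("classes must come from classify_stack()", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)

  filled <- which(!vapply(classes$averages, is.null, logical(1)))
  avg_imgs <- lapply(classes$averages[filled], `[[`, "image")
  write_mrc(avg_imgs, file.path(out_dir, "class_averages.mrcs"),
            pixel_size = pixel_size)

  tab <- classes$params
  tab$medoid <- classes$medoids[tab$label]
  tab$is_medoid <- tab$index == tab$medoid
  utils::write.csv(tab, file.path(out_dir, "labels.csv"), row.names = FALSE)

  manifest <- list(config = classes$config,
                   n_images = length(classes$labels),
                   classes_written = filled,
                   package = "cryoalign2d",
                   version = as.character(utils::packageVersion("cryoalign2d")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
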