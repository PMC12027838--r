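## Image and label I/O: 8-bit grayscale PNG, single-slice NIfTI-1, and a
## comma-separated labels sidecar (columns id,label,file; UTF-8, LF, header).

quantize8 <- function(x) floor(255 * clamp01(x) + 0.5)   # round half-up

#' Write image samples to disk
#'
#' PNG output is 8-bit grayscale with intensities scaled by 255 and rounded
#' half-up, so write -> read -> write round-trips byte-identically.  NIfTI
#' output is a single-slice volume with an identity affine.  A `labels.csv`
#' sidecar with columns `id,label,file` is always written.
#'
#' @param samples list of [image_sample()] objects.
#' @param dir output directory (created if missing).
#' @param format `"png"` or `"nifti"`.
#' @return invisibly, the sidecar data frame.
#' @export
write_images <- function(samples, dir, format = c("png", "nifti")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    fn <- paste0(s$id, if (format == "png") ".png" else ".nii")
    path <- file.path(dir, fn)
    if (format == "png") {
      png::writePNG(quantize8(s$pixels) / 255, path)
    } else {
      RNifti::writeNifti(RNifti::asNifti(array(s$pixels, c(dim(s$pixels), 1L))),
                         path)
    }
    data.frame(id = s$id, label = s$label, file = fn)
  })
  df <- do.call(rbind, rows)
  con <- file(file.path(dir, "labels.csv"), open = "wb")
  writeLines("id,label,file", con, sep = "\n")
  writeLines(sprintf("%s,%d,%s", df$id, df$label, df$file), con, sep = "\n")
  close(con)
  invisible(df)
}

#' Read an image directory written by [write_images()]
#'
#' Reads PNG or NIfTI images listed in `labels.csv` (or, absent a sidecar,
#' every `.png`/`.nii` file with label `NA`).  Each image is min-max
#' rescaled to `[0, 1]` unless it already lies inside the unit interval.
#'
#' @param dir directory path.
#' @return list of [image_sample()] objects.
#' @export
read_image_dir <- function(dir) {
  assert_that(dir.exists(dir), "no such directory: ", dir)
  side <- file.path(dir, "labels.csv")
  if (file.exists(side)) {
    df <- read.csv(side, stringsAsFactors = FALSE)
  } else {
    fs <- list.files(dir, pattern = "\\.(png|nii)$")
    assert_that(length(fs) > 0, "no PNG or NIfTI images found in ", dir)
    df <- data.frame(id = sub("\\.(png|nii)$", "", fs), label = NA_integer_, file = fs)
  }
  lapply(seq_len(nrow(df)), function(i) {
    path <- file.path(dir, df$file[i])
    px <- if (grepl("\\.png$", path)) {
      m <- png::readPNG(path)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    } else {
      v <- RNifti::readNifti(path)
      if (length(dim(v)) == 3) v <- v[, , 1]
      matrix(as.numeric(v), dim(v)[1], dim(v)[2])
    }
    rng <- range(px)
    if (rng[1] < 0 || rng[2] > 1)
      px <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
    image_sample(px, if (is.na(df$label[i])) 0L else df$label[i], df$id[i])
  })
}
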