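#' Single-stain channel image
#'
#' A 2-D grid of 8-bit intensities for one stain of one section. Pixels are
#' stored as an integer matrix in (row, col) orientation, 0-based origin at the
#' top-left when written to disk; all values must lie in \[0, 255\].
#'
#' @param pixels Integer matrix of intensities in \[0, 255\]; at least 1x1.
#' @param channel Channel name, e.g. `"hoechst"`, `"mkate"`, `"her2"`, `"cd31"`.
#' @param pixel_size Physical pixel size in micrometres per pixel.
#' @param section_id Identifier of the tissue section.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel, pixel_size = 0.75,
                          section_id = "section") {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("`pixels` must be a matrix of at least 1x1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel intensities must lie in [0, 255] with no missing values")
  storage.mode(pixels) <- "integer"
  if (!is.character(channel) || length(channel) != 1L || !nzchar(channel))
    stop("`channel` must be a single non-empty name")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be positive (micrometres per pixel)")
  structure(
    list(pixels = pixels, channel = channel,
         pixel_size = pixel_size, section_id = section_id),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s / %s: %d x %d px, %.3g um/px, range [%d, %d]\n",
              x$section_id, x$channel, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

#' Aligned multi-channel tumor map
#'
#' Bundles the mutually aligned channel images of one section. All channels
#' must share the same shape and pixel size.
#'
#' @param channels Named list of [channel_image()] objects; names must match
#'   each image's `channel` field.
#' @param section_id Section identifier; defaults to the first channel's.
#' @return An object of class `tumor_map`.
#' @export
tumor_map <- function(channels, section_id = NULL) {
  if (!is.list(channels) || length(channels) < 1L)
    stop("`channels` must be a non-empty named list of channel images")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("`channels` must be named by channel")
  for (nm in names(channels)) {
    ci <- channels[[nm]]
    if (!inherits(ci, "channel_image"))
      stop(sprintf("channel '%s' is not a channel_image", nm))
    if (!identical(ci$channel, nm))
      stop(sprintf("list name '%s' disagrees with channel field '%s'", nm, ci$channel))
  }
  shp <- dim(channels[[1L]]$pixels)
  psz <- channels[[1L]]$pixel_size
  for (ci in channels) {
    if (!identical(dim(ci$pixels), shp))
      stop("all channels of a tumor map must share the same shape")
    if (!isTRUE(all.equal(ci$pixel_size, psz)))
      stop("all channels of a tumor map must share the same pixel size")
  }
  if (is.null(section_id)) section_id <- channels[[1L]]$section_id
  structure(
    list(channels = channels, section_id = section_id, shape = shp,
         pixel_size = psz),
    class = "tumor_map"
  )
}

#' @export
print.tumor_map <- function(x, ...) {
  cat(sprintf("<tumor_map> %s: %d x %d px, channels: %s\n", x$section_id,
              x$shape[1L], x$shape[2L], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Region-of-interest label set
#'
#' An integer label image partitioning a section into lesions, normal-tissue
#' regions and excluded artifacts, with a per-region metadata table. Label 0 is
#' unassigned background, -1 marks artifacts (excluded from all statistics),
#' and positive labels are region ids described in `table`.
#'
#' @param labels Integer matrix of region labels (0, -1, or positive ids).
#' @param table Data frame with columns `id`, `kind` (`"lesion"`, `"normal"`
#'   or `"artifact"`), `organ`, `area_px`. Built from `labels` when `NULL`
#'   (every positive label becomes a lesion).
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(labels, table = NULL) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(is.na(labels))) stop("`labels` must not contain missing values")
  ids <- sort(unique(labels[labels > 0L]))
  areas <- if (length(ids)) vapply(ids, function(i) sum(labels == i), 0L) else integer(0)
  if (is.null(table)) {
    table <- data.frame(id = ids, kind = rep("lesion", length(ids)),
                        organ = rep(NA_character_, length(ids)),
                        area_px = areas, stringsAsFactors = FALSE)
  } else {
    req <- c("id", "kind", "organ", "area_px")
    miss <- setdiff(req, names(table))
    if (length(miss))
      stop("ROI table missing column(s): ", paste(miss, collapse = ", "))
    table <- table[order(table$id), req, drop = FALSE]
    if (!identical(as.integer(table$id), as.integer(ids)))
      stop("ROI table ids must match the positive labels present in the image")
    if (!identical(as.integer(table$area_px), as.integer(areas)))
      stop("ROI table areas disagree with label pixel counts")
    bad <- setdiff(unique(table$kind), c("lesion", "normal", "artifact"))
    if (length(bad))
      stop("unknown ROI kind(s): ", paste(bad, collapse = ", "))
  }
  rownames(table) <- NULL
  structure(list(labels = labels, table = table), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d x %d px, %d region(s), %d artifact px\n",
              nrow(x$labels), ncol(x$labels), nrow(x$table), sum(x$labels == -1L)))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' Binary segmentation mask
#'
#' @param pixels Logical matrix.
#' @param source_channel Channel the mask was derived from.
#' @param threshold_used Intensity threshold that produced the mask.
#' @param min_object_px Minimum connected-component size retained.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, source_channel = NA_character_,
                        threshold_used = NA_real_, min_object_px = 1L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!is.logical(pixels)) {
    if (!all(pixels %in% c(0, 1))) stop("mask pixels must be logical or 0/1")
    pixels <- pixels == 1
  }
  structure(
    list(pixels = pixels, source_channel = source_channel,
         threshold_used = threshold_used, min_object_px = as.integer(min_object_px)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> from %s: %d x %d px, %d positive (%.2f%%), threshold %s\n",
              x$source_channel, nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels), format(x$threshold_used)))
  invisible(x)
}

# Coerce a channel_image or bare matrix to an intensity matrix.
as_pixels <- function(x) {
  if (inherits(x, "channel_image")) x$pixels
  else if (inherits(x, "binary_mask")) x$pixels
  else if (is.matrix(x)) x
  else stop("expected a channel_image, binary_mask or matrix")
}

# Run code with a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
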