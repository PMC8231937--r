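#' Write a channel image as single-page 8-bit grayscale TIFF
#'
#' @param ci A [channel_image()].
#' @param path Output path; conventionally `<section>_<channel>.tif`.
#' @return The path, invisibly.
#' @export
write_channel_tiff <- function(ci, path) {
  stopifnot(inherits(ci, "channel_image"))
  tiff::writeTIFF(ci$pixels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Read a single-channel grayscale TIFF as a channel image
#'
#' 8-bit files are read verbatim. 16-bit files are rescaled to 8-bit by
#' max-normalization (`round half-up of v * 255 / max(v)`), and the rescaling
#' is reported via a message. RGB files are rejected: channels must be
#' supplied as separate grayscale files.
#'
#' @param path TIFF file path.
#' @param channel Channel name to attach.
#' @param pixel_size Micrometres per pixel.
#' @param section_id Section identifier.
#' @return A [channel_image()].
#' @export
read_channel_tiff <- function(path, channel, pixel_size = 0.75,
                              section_id = "section") {
  x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(x)) == 3L)
    stop(sprintf(
      "'%s' is a multi-sample (RGB) TIFF; split it into one grayscale file per channel",
      path))
  bits <- attr(x, "bits.per.sample")
  if (!is.null(bits) && bits > 8L) {
    mx <- max(x)
    if (mx > 0L) {
      message(sprintf("rescaling %d-bit '%s' to 8-bit by 255/%d", bits, path, mx))
      x <- floor(x * (255 / mx) + 0.5)  # round half-up
    }
  }
  attributes(x) <- list(dim = dim(x))
  channel_image(x, channel, pixel_size, section_id)
}

#' Read the channels of one section into a tumor map
#'
#' @param paths Named character vector, channel name -> TIFF path.
#' @param pixel_size Micrometres per pixel.
#' @param section_id Section identifier.
#' @return A [tumor_map()]. Channels with differing shapes are an error.
#' @export
read_section <- function(paths, pixel_size = 0.75, section_id = "section") {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("`paths` must be named by channel")
  channels <- lapply(names(paths), function(ch)
    read_channel_tiff(paths[[ch]], ch, pixel_size, section_id))
  names(channels) <- names(paths)
  shapes <- vapply(channels, function(ci) dim(ci$pixels), integer(2))
  if (any(shapes[1L, ] != shapes[1L, 1L]) || any(shapes[2L, ] != shapes[2L, 1L]))
    stop("channel images of one section must share the same shape")
  tumor_map(channels, section_id)
}

#' Write all channels of a tumor map as `<section>_<channel>.tif`
#'
#' @param map A [tumor_map()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_tumor_map <- function(map, dir) {
  stopifnot(inherits(map, "tumor_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(map$channels), function(ch) {
    p <- file.path(dir, sprintf("%s_%s.tif", map$section_id, ch))
    write_channel_tiff(map$channels[[ch]], p)
    p
  }, character(1))
  paths
}

# artifact pixels (-1) are stored as the 16-bit maximum in label TIFFs
ARTIFACT_TIFF_VALUE <- 65535L

#' Write / read an ROI label set (16-bit label TIFF + metadata CSV)
#'
#' Labels are stored as a 16-bit grayscale TIFF; artifact pixels (-1) are
#' encoded as the label maximum 65535 (recorded in a JSON sidecar next to the
#' CSV). The metadata CSV has columns `id`, `kind`, `organ`, `area_px`.
#'
#' @param rois A [roi_set()].
#' @param tiff_path Path for the label TIFF.
#' @param csv_path Path for the metadata CSV.
#' @return Invisibly, the two paths.
#' @export
write_roi_set <- function(rois, tiff_path, csv_path) {
  stopifnot(inherits(rois, "roi_set"))
  if (any(rois$labels > ARTIFACT_TIFF_VALUE - 1L))
    stop("region ids exceed the 16-bit label range")
  lab <- rois$labels
  lab[lab == -1L] <- ARTIFACT_TIFF_VALUE
  tiff::writeTIFF(lab / 65535, tiff_path, bits.per.sample = 16L,
                  compression = "none")
  utils::write.csv(rois$table, csv_path, row.names = FALSE)
  sidecar <- paste0(csv_path, ".meta.json")
  jsonlite::write_json(list(artifact_tiff_value = ARTIFACT_TIFF_VALUE),
                       sidecar, auto_unbox = TRUE)
  invisible(c(tiff = tiff_path, csv = csv_path))
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(tiff_path, csv_path = NULL) {
  lab <- tiff::readTIFF(tiff_path, as.is = TRUE)
  attributes(lab) <- list(dim = dim(lab))
  lab[lab == ARTIFACT_TIFF_VALUE] <- -1L
  storage.mode(lab) <- "integer"
  table <- NULL
  if (!is.null(csv_path) && file.exists(csv_path)) {
    table <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
    table$organ <- as.character(table$organ)
  }
  roi_set(lab, table)
}

#' Write per-lesion profiles to CSV
#'
#' @param profiles Data frame of per-lesion profiles (see [profile_lesions()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' Tile grid of microscope fields
#'
#' @param tiles List of entries `list(grid_row =, grid_col =, image =)` where
#'   `image` is a [channel_image()]; 1-based grid positions.
#' @param grid_shape Length-2 integer (grid rows, grid cols); inferred from
#'   the maximum positions when `NULL`.
#' @return An object of class `tile_grid`.
#' @export
tile_grid <- function(tiles, grid_shape = NULL) {
  if (!length(tiles)) stop("`tiles` must be non-empty")
  pos <- t(vapply(tiles, function(t) c(t$grid_row, t$grid_col), numeric(2)))
  if (is.null(grid_shape)) grid_shape <- c(max(pos[, 1L]), max(pos[, 2L]))
  grid_shape <- as.integer(grid_shape)
  structure(list(tiles = tiles, grid_shape = grid_shape), class = "tile_grid")
}

#' Assemble tiled fields of view into a whole-section montage
#'
#' Tiles are placed without overlap or blending: tile (i, j) occupies the
#' block rows `(i-1)*tile_rows + 1 ... i*tile_rows` and the analogous
#' columns, reproducing the automatic tiling of adjacent microscope fields
#' into a section montage.
#'
#' @param grid A [tile_grid()]. Every grid position must be present exactly
#'   once and all tiles must share one shape and channel.
#' @return A [channel_image()] of shape (grid_rows x tile_rows,
#'   grid_cols x tile_cols).
#' @export
assemble_montage <- function(grid) {
  stopifnot(inherits(grid, "tile_grid"))
  gs <- grid$grid_shape
  pos <- t(vapply(grid$tiles, function(t) c(t$grid_row, t$grid_col), numeric(2)))
  key <- paste(pos[, 1L], pos[, 2L])
  if (anyDuplicated(key))
    stop("duplicate tile position(s): ", paste(unique(key[duplicated(key)]), collapse = "; "))
  want <- expand.grid(r = seq_len(gs[1L]), c = seq_len(gs[2L]))
  missing <- setdiff(paste(want$r, want$c), key)
  if (length(missing))
    stop("missing tile position(s): ", paste0("(", gsub(" ", ",", missing), ")",
                                              collapse = ", "))
  shapes <- t(vapply(grid$tiles, function(t) dim(t$image$pixels), integer(2)))
  if (any(shapes[, 1L] != shapes[1L, 1L]) || any(shapes[, 2L] != shapes[1L, 2L]))
    stop("all tiles must share the same shape")
  chans <- vapply(grid$tiles, function(t) t$image$channel, character(1))
  if (length(unique(chans)) != 1L)
    stop("all tiles must come from the same channel")
  tr <- shapes[1L, 1L]; tc <- shapes[1L, 2L]
  out <- matrix(0L, gs[1L] * tr, gs[2L] * tc)
  for (t in grid$tiles) {
    out[(t$grid_row - 1L) * tr + seq_len(tr),
        (t$grid_col - 1L) * tc + seq_len(tc)] <- t$image$pixels
  }
  first <- grid$tiles[[1L]]$image
  channel_image(out, first$channel, first$pixel_size, first$section_id)
}

# Shift a matrix by (dr, dc) with zero fill: out[r, c] = m[r - dr, c - dc].
shift_matrix <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  ok_r <- rs - dr >= 1L & rs - dr <= nr
  ok_c <- cs - dc >= 1L & cs - dc <= nc
  if (any(ok_r) && any(ok_c))
    out[rs[ok_r], cs[ok_c]] <- m[rs[ok_r] - dr, cs[ok_c] - dc]
  out
}

# Zero-mean normalized cross-correlation between ref and img shifted by
# (dr, dc), computed on the overlap region only. NA when either side is
# constant on the overlap.
ncc_at_shift <- function(ref, img, dr, dc) {
  nr <- nrow(ref); nc <- ncol(ref)
  r1 <- max(1L, 1L + dr):min(nr, nr + dr)
  c1 <- max(1L, 1L + dc):min(nc, nc + dc)
  x <- as.numeric(ref[r1, c1]); y <- as.numeric(img[r1 - dr, c1 - dc])
  x <- x - mean(x); y <- y - mean(y)
  den <- sqrt(sum(x * x) * sum(y * y))
  if (den == 0) return(NA_real_)
  sum(x * y) / den
}

#' Align the channels of one section by integer translation
#'
#' Each non-reference channel is shifted by the integer (row, col)
#' translation that maximizes the zero-mean normalized cross-correlation with
#' the reference over a `(-max_shift .. max_shift)^2` window, emulating the
#' overlay-and-align step applied to separately imaged stains of one physical
#' section. Translation only — the channels come from re-imaging the same
#' section, so rotation/scaling are not modeled. Vacated border pixels are
#' zero-filled.
#'
#' Ties, and degenerate (zero-variance) images, resolve deterministically to
#' shift (0, 0) with a `"degenerate_correlation"` flag; a best shift on the
#' window boundary is flagged `"boundary"`.
#'
#' @param channels Named list of [channel_image()] objects (>= 2, equal shapes).
#' @param reference Name of the reference channel.
#' @param max_shift Half-width of the search window in pixels.
#' @return A list with `map` (aligned [tumor_map()]) and `shifts` (data frame
#'   with columns `channel`, `dr`, `dc`, `ncc`, `flag`).
#' @export
align_channels <- function(channels, reference = "hoechst", max_shift = 20L) {
  if (inherits(channels, "tumor_map")) channels <- channels$channels
  if (length(channels) < 2L) stop("need at least 2 channels to align")
  if (!reference %in% names(channels))
    stop(sprintf("reference channel '%s' not present", reference))
  shp <- dim(channels[[1L]]$pixels)
  for (ci in channels)
    if (!identical(dim(ci$pixels), shp)) stop("channel shapes differ")
  ref <- channels[[reference]]$pixels
  shifts <- data.frame(channel = character(0), dr = integer(0), dc = integer(0),
                       ncc = numeric(0), flag = character(0))
  aligned <- channels
  window <- seq.int(-max_shift, max_shift)
  for (ch in names(channels)) {
    if (ch == reference) {
      shifts <- rbind(shifts, data.frame(channel = ch, dr = 0L, dc = 0L,
                                         ncc = 1, flag = ""))
      next
    }
    img <- channels[[ch]]$pixels
    if (stats::sd(img) == 0 || stats::sd(ref) == 0) {
      shifts <- rbind(shifts, data.frame(channel = ch, dr = 0L, dc = 0L,
                                         ncc = NA_real_,
                                         flag = "degenerate_correlation"))
      next
    }
    # candidates ordered by |dr|+|dc| so exact ties resolve to the smallest
    # shift, with (0,0) first — deterministic and safe
    cand <- expand.grid(dr = window, dc = window)
    cand <- cand[order(abs(cand$dr) + abs(cand$dc), cand$dr, cand$dc), ]
    best <- c(0L, 0L); best_v <- -Inf
    for (k in seq_len(nrow(cand))) {
      v <- ncc_at_shift(ref, img, cand$dr[k], cand$dc[k])
      if (is.na(v)) next
      if (v > best_v + 1e-12) { best_v <- v; best <- c(cand$dr[k], cand$dc[k]) }
    }
    flag <- ""
    if (!is.finite(best_v)) {
      best <- c(0L, 0L); flag <- "degenerate_correlation"
    } else if (any(abs(best) == max_shift)) flag <- "boundary"
    aligned[[ch]]$pixels <- shift_matrix(img, best[1L], best[2L])
    shifts <- rbind(shifts, data.frame(channel = ch, dr = best[1L],
                                       dc = best[2L],
                                       ncc = ifelse(is.finite(best_v), best_v, NA_real_),
                                       flag = flag))
  }
  list(map = tumor_map(aligned), shifts = shifts)
}
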