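# Linear indices of the pixels belonging to one region (artifacts excluded
# by construction: they carry label -1).
roi_pixels <- function(rois, roi_id) {
  stopifnot(inherits(rois, "roi_set"))
  if (!(roi_id %in% rois$table$id))
    stop(sprintf("ROI id %s not present", format(roi_id)))
  idx <- which(rois$labels == roi_id)
  if (!length(idx)) stop(sprintf("ROI %s is empty", format(roi_id)))
  idx
}

#' Per-ROI pixel-intensity histogram
#'
#' The distribution of ROI pixels across intensity levels 0-255, expressed as
#' percent of the total pixels in the ROI — the per-lesion readout used to
#' visualize marker heterogeneity.
#'
#' @param channel [channel_image()] (or matrix) to histogram.
#' @param rois [roi_set()] with the region labels.
#' @param roi_id Region id (must be present with positive area).
#' @return A list of class `intensity_histogram` with `bins` (length 256,
#'   percentages summing to 100), `roi_id`, `channel`, `n_pixels`.
#' @export
intensity_histogram <- function(channel, rois, roi_id) {
  px <- as_pixels(channel)
  if (!identical(dim(px), dim(rois$labels)))
    stop("channel and ROI shapes differ")
  idx <- roi_pixels(rois, roi_id)
  v <- px[idx]
  bins <- 100 * tabulate(v + 1L, nbins = 256L) / length(v)
  structure(
    list(bins = bins, roi_id = roi_id,
         channel = if (inherits(channel, "channel_image")) channel$channel else NA_character_,
         n_pixels = length(v)),
    class = "intensity_histogram"
  )
}

#' Mean pixel intensity of a ROI
#'
#' Arithmetic mean intensity over the ROI pixels; identical (to numerical
#' precision) to the histogram-weighted mean
#' `sum(v * bins[v]) / 100`.
#'
#' @inheritParams intensity_histogram
#' @return Mean intensity in \[0, 255\].
#' @export
mean_intensity <- function(channel, rois, roi_id) {
  px <- as_pixels(channel)
  if (!identical(dim(px), dim(rois$labels)))
    stop("channel and ROI shapes differ")
  mean(px[roi_pixels(rois, roi_id)])
}

#' Classify ROI pixels into weak / moderate / strong staining
#'
#' Pseudocolor heat-map classification of marker staining: ROI pixels below
#' the first cutpoint are weak, between the cutpoints moderate, at or above
#' the second strong; pixels outside every region are background. Default
#' cutpoints split the 0-255 range into equal thirds (85, 170); they are
#' configurable and always carried in the result.
#'
#' @inheritParams intensity_histogram
#' @param bin_edges Two increasing cutpoints strictly inside (0, 255).
#' @return A list of class `heatmap_image` with `classes` (integer matrix:
#'   0 background, 1 weak, 2 moderate, 3 strong), `bin_edges`, `levels`.
#' @export
heatmap_classify <- function(channel, rois, bin_edges = c(85, 170)) {
  px <- as_pixels(channel)
  if (!identical(dim(px), dim(rois$labels)))
    stop("channel and ROI shapes differ")
  if (length(bin_edges) != 2L || !(0 < bin_edges[1L]) ||
      !(bin_edges[1L] < bin_edges[2L]) || !(bin_edges[2L] < 255))
    stop("`bin_edges` must satisfy 0 < edge1 < edge2 < 255")
  cls <- matrix(0L, nrow(px), ncol(px))
  in_roi <- rois$labels > 0L
  cls[in_roi & px < bin_edges[1L]] <- 1L
  cls[in_roi & px >= bin_edges[1L] & px < bin_edges[2L]] <- 2L
  cls[in_roi & px >= bin_edges[2L]] <- 3L
  structure(
    list(classes = cls, bin_edges = bin_edges,
         levels = c("background", "weak", "moderate", "strong")),
    class = "heatmap_image"
  )
}

#' Cellularity of a ROI
#'
#' Percent of the ROI area covered by the nuclei mask, together with the mean
#' nuclear-channel intensity over the ROI.
#'
#' @param nuclei [binary_mask()] of nuclei (from [mask_nuclei()]).
#' @param hoechst [channel_image()] of the nuclear stain.
#' @inheritParams intensity_histogram
#' @return A list with `percent_area` (0-100) and `mean_intensity`.
#' @export
cellularity <- function(nuclei, hoechst, rois, roi_id) {
  nm <- as_pixels(nuclei)
  px <- as_pixels(hoechst)
  if (!identical(dim(nm), dim(rois$labels)) || !identical(dim(px), dim(rois$labels)))
    stop("mask/channel and ROI shapes differ")
  idx <- roi_pixels(rois, roi_id)
  list(percent_area = 100 * sum(nm[idx]) / length(idx),
       mean_intensity = mean(px[idx]))
}

# Exact Euclidean distance of every pixel to the nearest TRUE pixel of mask.
# wrap = TRUE computes the torus metric by 3x3 tiling (any torus-nearest
# point of a center-tile pixel has a representative within one period).
nearest_positive_distance <- function(mask, wrap = FALSE) {
  if (!any(mask)) return(NULL)
  if (!wrap) {
    d <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask), ncol(mask)))
    return(matrix(as.numeric(d), nrow(mask), ncol(mask)))
  }
  nr <- nrow(mask); nc <- ncol(mask)
  big <- matrix(FALSE, 3L * nr, 3L * nc)
  for (i in 0:2) for (j in 0:2)
    big[i * nr + seq_len(nr), j * nc + seq_len(nc)] <- mask
  d <- EBImage::distmap(matrix(as.numeric(!big), nrow(big), ncol(big)))
  d <- matrix(as.numeric(d), nrow(big), ncol(big))
  d[nr + seq_len(nr), nc + seq_len(nc)]
}

#' Vascular density of a ROI (mean distance to nearest CD31-positive pixel)
#'
#' For every ROI pixel the Euclidean distance to the nearest CD31-positive
#' pixel anywhere in the section is computed (the nearest vessel may lie
#' outside the ROI — a lesion adjacent to organ vasculature is close to
#' vessels); the ROI mean is returned in pixels and micrometres. Larger
#' values mean sparser vasculature. If the section contains no CD31-positive
#' pixel at all the density is undefined and flagged
#' `"no_vessel_in_section"` rather than imputed.
#'
#' @param cd31_mask [binary_mask()] of CD31-positive pixels/objects.
#' @inheritParams intensity_histogram
#' @param pixel_size Micrometres per pixel.
#' @param wrap Compute distances on a torus (periodic boundaries); used for
#'   boundary-free validation against the Poisson-process limit
#'   `E[d] = 1 / (2 sqrt(lambda))`.
#' @return A list with `mean_distance_px`, `mean_distance_um`, `flags`.
#' @export
vascular_density <- function(cd31_mask, rois, roi_id, pixel_size = 0.75,
                             wrap = FALSE) {
  m <- as_pixels(cd31_mask)
  if (!identical(dim(m), dim(rois$labels)))
    stop("CD31 mask and ROI shapes differ")
  idx <- roi_pixels(rois, roi_id)
  d <- nearest_positive_distance(m, wrap = wrap)
  if (is.null(d))
    return(list(mean_distance_px = NA_real_, mean_distance_um = NA_real_,
                flags = "no_vessel_in_section"))
  mu <- mean(d[idx])
  list(mean_distance_px = mu, mean_distance_um = mu * pixel_size,
       flags = character(0))
}

#' Profile every lesion of a section
#'
#' One row per lesion-kind region, ordered by region id: per-channel mean
#' intensity, cellularity (percent nuclear area + mean nuclear intensity),
#' and vascular density in px and um. Undefined vascular densities are
#' flagged, not imputed; per-metric failures are recorded in `flags` instead
#' of aborting the section.
#'
#' @param map [tumor_map()] of aligned channels.
#' @param rois [roi_set()].
#' @param nuclei [binary_mask()] of nuclei.
#' @param cd31_mask [binary_mask()] of CD31-positive objects.
#' @param nuclear_channel Name of the nuclear channel (default `"hoechst"`).
#' @return Data frame with columns `roi_id`, `organ`, `area_px`,
#'   `mean_<channel>` per channel, `cellularity_pct`,
#'   `cellularity_mean_intensity`, `vascular_density_px`,
#'   `vascular_density_um`, `flags` (`;`-separated).
#' @export
profile_lesions <- function(map, rois, nuclei, cd31_mask,
                            nuclear_channel = "hoechst") {
  stopifnot(inherits(map, "tumor_map"), inherits(rois, "roi_set"))
  lesions <- rois$table[rois$table$kind == "lesion", , drop = FALSE]
  lesions <- lesions[order(lesions$id), , drop = FALSE]
  # the global distance map is shared by all lesions of the section
  dmap <- nearest_positive_distance(as_pixels(cd31_mask))
  rows <- lapply(seq_len(nrow(lesions)), function(k) {
    id <- lesions$id[k]
    flags <- character(0)
    row <- data.frame(roi_id = id, organ = lesions$organ[k],
                      area_px = lesions$area_px[k], stringsAsFactors = FALSE)
    idx <- which(rois$labels == id)
    for (ch in names(map$channels))
      row[[paste0("mean_", ch)]] <- mean(map$channels[[ch]]$pixels[idx])
    cel <- tryCatch(cellularity(nuclei, map$channels[[nuclear_channel]], rois, id),
                    error = function(e) NULL)
    if (is.null(cel)) {
      row$cellularity_pct <- NA_real_; row$cellularity_mean_intensity <- NA_real_
      flags <- c(flags, "cellularity_failed")
    } else {
      row$cellularity_pct <- cel$percent_area
      row$cellularity_mean_intensity <- cel$mean_intensity
    }
    if (is.null(dmap)) {
      row$vascular_density_px <- NA_real_; row$vascular_density_um <- NA_real_
      flags <- c(flags, "no_vessel_in_section")
    } else {
      mu <- mean(dmap[idx])
      row$vascular_density_px <- mu
      row$vascular_density_um <- mu * map$pixel_size
    }
    row$flags <- paste(flags, collapse = ";")
    row
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(roi_id = integer(0), organ = character(0), area_px = integer(0),
               cellularity_pct = numeric(0),
               cellularity_mean_intensity = numeric(0),
               vascular_density_px = numeric(0),
               vascular_density_um = numeric(0), flags = character(0))
  rownames(out) <- NULL
  out
}

#' Correlate vascular density with marker expression across lesions
#'
#' Spearman rank correlation (mid-ranks for ties) between per-lesion vascular
#' density and mean marker intensity, with the p-value from the t
#' approximation `t = rho sqrt((n - 2) / (1 - rho^2))` on n - 2 df. Lesions
#' with undefined (flagged) vascular density are excluded and counted.
#'
#' @param profiles Data frame from [profile_lesions()].
#' @param marker Marker channel name (uses column `mean_<marker>`).
#' @return A list with `rho`, `n`, `p`, `n_excluded`, `flags`.
#' @export
correlate_density_expression <- function(profiles, marker = "her2") {
  col <- paste0("mean_", marker)
  if (!col %in% names(profiles))
    stop(sprintf("profiles lack column '%s'", col))
  ok <- is.finite(profiles$vascular_density_px) & is.finite(profiles[[col]])
  n_excluded <- sum(!ok)
  x <- profiles$vascular_density_px[ok]
  y <- profiles[[col]][ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 lesions with defined vascular density")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, n = n, p = NA_real_, n_excluded = n_excluded,
                flags = "zero_variance"))
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, n = n, p = p, n_excluded = n_excluded, flags = character(0))
}
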