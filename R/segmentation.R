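# 8-connected component labelling. EBImage::bwlabel is 4-connected, so labels
# touching diagonally are merged with a union-find pass over label adjacency.
label8 <- function(mask) {
  mask <- as_pixels(mask)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),  # down-right
    cbind(as.vector(lab[-nr, -1L]), as.vector(lab[-1L, -nc]))   # down-left
  )
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
    x
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  newid <- match(roots, sort(unique(roots)))
  pos <- lab > 0L
  lab[pos] <- newid[lab[pos]]
  lab
}

# Drop 8-connected components smaller than min_px; returns the filtered
# logical mask and the surviving component count.
filter_small_components <- function(mask, min_px) {
  lab <- label8(mask)
  if (max(lab) == 0L)
    return(list(mask = matrix(FALSE, nrow(mask), ncol(mask)), count = 0L))
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_px)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  list(mask = out, count = length(keep))
}

# Otsu threshold on the 0-255 histogram; errors on a constant image.
auto_threshold <- function(pixels) {
  if (min(pixels) == max(pixels))
    stop("degenerate histogram; supply threshold")
  th <- EBImage::otsu(EBImage::Image(pixels / 255), range = c(0, 1), levels = 256)
  th * 255
}

#' Mask nuclei by thresholding the Hoechst channel
#'
#' A pixel belongs to the nuclei mask iff its intensity is at or above the
#' threshold and its 8-connected component has at least `min_object_px`
#' pixels — the thresholding-plus-particle-filter recipe used for cellularity
#' measurement. With `threshold = "auto"`, Otsu's method on the channel
#' histogram picks the cutoff (constant images are rejected).
#'
#' @param hoechst [channel_image()] of the nuclear stain.
#' @param threshold `"auto"` or a value in 0-255.
#' @param min_object_px Minimum particle size in pixels (>= 1).
#' @return A [binary_mask()].
#' @export
mask_nuclei <- function(hoechst, threshold = "auto", min_object_px = 4L) {
  px <- as_pixels(hoechst)
  if (min_object_px < 1L) stop("`min_object_px` must be >= 1")
  th <- if (identical(threshold, "auto")) auto_threshold(px) else {
    if (!is.numeric(threshold) || threshold < 0 || threshold > 255)
      stop("`threshold` must be \"auto\" or in [0, 255]")
    threshold
  }
  raw <- px >= th
  f <- filter_small_components(raw, min_object_px)
  binary_mask(f$mask,
              source_channel = if (inherits(hoechst, "channel_image")) hoechst$channel else NA_character_,
              threshold_used = th, min_object_px = min_object_px)
}

#' Detect CD31-positive vessel objects
#'
#' Same threshold-and-particle-filter rule as [mask_nuclei()], additionally
#' returning the number of surviving 8-connected components — the
#' "CD31-positive objects" that vascular density is measured against.
#' `min_object_px = 1` recovers the raw-positive-pixel reading.
#'
#' @inheritParams mask_nuclei
#' @param cd31 [channel_image()] of the endothelial stain.
#' @return A list with `mask` ([binary_mask()]) and `object_count`.
#' @export
detect_cd31_objects <- function(cd31, threshold = "auto", min_object_px = 4L) {
  px <- as_pixels(cd31)
  if (min_object_px < 1L) stop("`min_object_px` must be >= 1")
  th <- if (identical(threshold, "auto")) auto_threshold(px) else {
    if (!is.numeric(threshold) || threshold < 0 || threshold > 255)
      stop("`threshold` must be \"auto\" or in [0, 255]")
    threshold
  }
  raw <- px >= th
  f <- filter_small_components(raw, min_object_px)
  list(mask = binary_mask(f$mask,
                          source_channel = if (inherits(cd31, "channel_image")) cd31$channel else NA_character_,
                          threshold_used = th, min_object_px = min_object_px),
       object_count = f$count)
}

#' Propose lesion ROIs from the nuclei mask
#'
#' Automated stand-in for manual screening of tumor regions: lesions appear
#' as dense clusters of nuclei, so the nuclei mask is morphologically closed
#' with a disk (bridging gaps between neighbouring nuclei), holes are filled,
#' and 8-connected components of at least `min_lesion_px` pixels become
#' lesion regions. Ids are assigned by decreasing area (ties broken by first
#' pixel position, so labelling is deterministic).
#'
#' @param nuclei [binary_mask()] from [mask_nuclei()].
#' @param min_lesion_px Minimum lesion area in pixels.
#' @param closing_radius Disk radius for morphological closing, px.
#' @return A [roi_set()] in which every region has kind `"lesion"`.
#' @export
propose_lesions <- function(nuclei, min_lesion_px = 500L, closing_radius = 10L) {
  m <- as_pixels(nuclei)
  if (!any(m)) return(roi_set(matrix(0L, nrow(m), ncol(m))))
  closed <- m
  if (closing_radius >= 1L) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, shape = "disc")
    closed <- EBImage::closing(matrix(as.numeric(m), nrow(m), ncol(m)), brush) > 0
  }
  closed <- EBImage::fillHull(matrix(as.numeric(closed), nrow(m), ncol(m))) > 0
  lab <- label8(closed)
  if (max(lab) == 0L) return(roi_set(matrix(0L, nrow(m), ncol(m))))
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_lesion_px)
  if (!length(keep)) return(roi_set(matrix(0L, nrow(m), ncol(m))))
  first_px <- vapply(keep, function(k) which(lab == k)[1L], 0L)
  keep <- keep[order(-sizes[keep], first_px)]
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  roi_set(out)
}

#' Apply manual ROI overrides to an automatic proposal
#'
#' Wherever the manual label image is non-zero it overrides the automatic
#' labels; -1 regions mark artifacts, which are excluded from every
#' downstream statistic (they are not background). Positive manual ids must
#' not collide with surviving automatic ids.
#'
#' @param auto A [roi_set()] from [propose_lesions()] (or any proposal).
#' @param manual_labels Integer label matrix of the same shape (0 keeps the
#'   automatic label, -1 marks an artifact, k > 0 assigns region k).
#' @param manual_table Optional metadata for the manual regions (columns
#'   `id`, `kind`, `organ`); manual regions default to kind `"lesion"`.
#' @return A [roi_set()] with the overrides applied.
#' @export
apply_manual_rois <- function(auto, manual_labels, manual_table = NULL) {
  stopifnot(inherits(auto, "roi_set"))
  if (!identical(dim(auto$labels), dim(manual_labels)))
    stop("manual label image shape differs from the automatic ROI set")
  storage.mode(manual_labels) <- "integer"
  manual_ids <- sort(unique(manual_labels[manual_labels > 0L]))
  out <- auto$labels
  out[manual_labels != 0L] <- manual_labels[manual_labels != 0L]
  surviving_auto <- sort(unique(out[out > 0L & manual_labels == 0L]))
  clash <- intersect(manual_ids, surviving_auto)
  if (length(clash))
    stop("manual region id(s) collide with automatic ids: ",
         paste(clash, collapse = ", "))
  ids <- sort(unique(out[out > 0L]))
  meta <- auto$table[auto$table$id %in% ids, , drop = FALSE]
  if (length(manual_ids)) {
    man <- data.frame(id = manual_ids, kind = "lesion", organ = NA_character_,
                      stringsAsFactors = FALSE)
    if (!is.null(manual_table)) {
      for (k in seq_len(nrow(man))) {
        hit <- manual_table[manual_table$id == man$id[k], , drop = FALSE]
        if (nrow(hit)) {
          if ("kind" %in% names(hit)) man$kind[k] <- hit$kind[1L]
          if ("organ" %in% names(hit)) man$organ[k] <- as.character(hit$organ[1L])
        }
      }
    }
    meta <- rbind(meta[, c("id", "kind", "organ")], man)
  } else meta <- meta[, c("id", "kind", "organ")]
  meta <- meta[order(meta$id), , drop = FALSE]
  meta$area_px <- vapply(meta$id, function(i) sum(out == i), 0L)
  meta <- meta[meta$area_px > 0L, , drop = FALSE]
  roi_set(out, meta)
}
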