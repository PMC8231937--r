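#' Lesion specification for the synthetic tumor-map generator
#'
#' Describes one disk-shaped lesion: where it sits, its per-marker mean
#' staining intensity (the ground truth for inter-metastatic heterogeneity),
#' an optional radial intensity gradient (intra-tumoral heterogeneity), and
#' its nuclear density.
#'
#' The gradient modulates the marker value linearly with distance `d` from the
#' lesion center: `mean + gradient_amplitude * (1 - 2 d / radius)`, i.e. the
#' center sits at `mean + gradient_amplitude` and the rim at
#' `mean - gradient_amplitude`.
#'
#' @param id Positive integer lesion id, unique within a section.
#' @param center Length-2 numeric, lesion center as (row, col) in pixels.
#' @param radius Lesion radius in pixels (>= 3).
#' @param marker_means Named numeric vector/list, channel -> mean intensity
#'   (0-255) inside the lesion.
#' @param gradient_amplitude Radial modulation amplitude in intensity levels;
#'   0 disables the within-lesion gradient.
#' @param nuclei_density Expected nuclei per 100x100 px of lesion area.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(id, center, radius, marker_means,
                        gradient_amplitude = 0, nuclei_density = 40) {
  id <- as.integer(id)
  if (is.na(id) || id < 1L) stop("lesion `id` must be a positive integer")
  if (length(center) != 2L || any(!is.finite(center)))
    stop("lesion `center` must be finite (row, col)")
  if (!is.numeric(radius) || radius < 3)
    stop("lesion `radius` must be >= 3 px")
  marker_means <- unlist(marker_means)
  if (is.null(names(marker_means)) || any(!nzchar(names(marker_means))))
    stop("`marker_means` must be named by channel")
  if (any(marker_means < 0 | marker_means > 255))
    stop("marker means must lie in [0, 255]")
  if (gradient_amplitude < 0)
    stop("`gradient_amplitude` must be >= 0")
  if (any(marker_means + gradient_amplitude > 255) ||
      any(marker_means - gradient_amplitude < 0))
    stop("mean +/- gradient_amplitude must stay within [0, 255]")
  if (nuclei_density < 0) stop("`nuclei_density` must be >= 0")
  structure(
    list(id = id, center = as.numeric(center), radius = as.numeric(radius),
         marker_means = marker_means,
         gradient_amplitude = as.numeric(gradient_amplitude),
         nuclei_density = as.numeric(nuclei_density)),
    class = "lesion_spec"
  )
}

#' Vessel field specification
#'
#' CD31-positive vessel cross-sections are placed by a homogeneous spatial
#' Poisson point process with intensity `rate` over the named region, and
#' rendered as filled disks. The point-process model keeps the analytic
#' nearest-distance check `E[d] = 1 / (2 sqrt(lambda))` available.
#'
#' @param rate Expected vessel objects per px^2 (Poisson intensity lambda).
#' @param object_radius Disk radius of one vessel cross-section, px (>= 1).
#' @param intensity CD31 channel intensity of vessel pixels (0-255).
#' @param region `"everywhere"`, `"normal"` (outside all lesions), or a
#'   positive lesion id restricting placement to that lesion.
#' @return An object of class `vessel_field_spec`.
#' @export
vessel_field_spec <- function(rate, object_radius = 3, intensity = 200,
                              region = "everywhere") {
  if (!is.numeric(rate) || rate < 0) stop("vessel `rate` must be >= 0")
  if (!is.numeric(object_radius) || object_radius < 1)
    stop("`object_radius` must be >= 1 px")
  if (intensity < 0 || intensity > 255)
    stop("vessel `intensity` must lie in [0, 255]")
  if (!(identical(region, "everywhere") || identical(region, "normal") ||
        (is.numeric(region) && length(region) == 1L && region >= 1)))
    stop("`region` must be \"everywhere\", \"normal\", or a lesion id")
  structure(
    list(rate = rate, object_radius = as.numeric(object_radius),
         intensity = as.numeric(intensity), region = region),
    class = "vessel_field_spec"
  )
}

#' Full parameterization of a simulated tumor-map section
#'
#' @param image_shape Length-2 integer, (rows, cols); each >= 64 unless
#'   `allow_small = TRUE` (used by small unit fixtures).
#' @param lesions List of [lesion_spec()] objects (may be empty).
#' @param vessel_fields List of [vessel_field_spec()] objects (may be empty).
#' @param background_marker_means Named vector, channel -> background mean
#'   intensity. Its names define the channel set, which must contain
#'   `"hoechst"`, `"cd31"` and at least one further marker channel.
#' @param noise_sd Standard deviation of the additive Gaussian camera noise,
#'   in intensity levels (applied to every channel, then clipped to \[0,255\]
#'   and rounded to integers).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param pixel_size Micrometres per pixel (default 0.75).
#' @param section_id,organ Labels carried into outputs and ground truth.
#' @param nuclei_intensity Hoechst level of rendered nuclei (0-255).
#' @param nucleus_radius Integer range (min, max) of nucleus disk radii, px.
#' @param background_nuclei_density Expected nuclei per 100x100 px outside
#'   lesions (sparser than lesion densities).
#' @param wrap If `TRUE`, objects are rendered on a torus (disks wrap around
#'   the image edges); used for boundary-free point-process validation.
#' @param allow_small Permit image sides < 64 px (test fixtures only).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_shape, lesions = list(), vessel_fields = list(),
                           background_marker_means = c(hoechst = 8, mkate = 5,
                                                       her2 = 5, cd31 = 3),
                           noise_sd = 10, seed = 1L, pixel_size = 0.75,
                           section_id = "synthetic", organ = "liver",
                           nuclei_intensity = 200, nucleus_radius = c(2L, 4L),
                           background_nuclei_density = 2, wrap = FALSE,
                           allow_small = FALSE) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(is.na(image_shape)))
    stop("`image_shape` must be (rows, cols)")
  if (!allow_small && any(image_shape < 64L))
    stop("`image_shape` sides must each be >= 64 px")
  if (any(image_shape < 8L)) stop("image too small")
  bg <- unlist(background_marker_means)
  if (is.null(names(bg))) stop("`background_marker_means` must be named by channel")
  if (any(bg < 0 | bg > 255)) stop("background means must lie in [0, 255]")
  chans <- names(bg)
  if (!all(c("hoechst", "cd31") %in% chans) || length(chans) < 3L)
    stop("channels must include 'hoechst', 'cd31' and at least one marker")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  lesions <- lapply(lesions, function(l) if (inherits(l, "lesion_spec")) l else do.call(lesion_spec, l))
  ids <- vapply(lesions, function(l) l$id, 0L)
  if (anyDuplicated(ids)) stop("lesion ids must be unique within a section")
  for (l in lesions) {
    unknown <- setdiff(names(l$marker_means), chans)
    if (length(unknown))
      stop(sprintf("lesion %d references channel(s) absent from the channel set: %s",
                   l$id, paste(unknown, collapse = ", ")))
  }
  vessel_fields <- lapply(vessel_fields, function(v)
    if (inherits(v, "vessel_field_spec")) v else do.call(vessel_field_spec, v))
  for (v in vessel_fields) {
    if (is.numeric(v$region) && !(v$region %in% ids))
      stop(sprintf("vessel field references unknown lesion id %d", as.integer(v$region)))
  }
  nucleus_radius <- as.integer(nucleus_radius)
  if (length(nucleus_radius) != 2L || nucleus_radius[1L] < 1L ||
      nucleus_radius[2L] < nucleus_radius[1L])
    stop("`nucleus_radius` must be an increasing integer pair >= 1")
  structure(
    list(image_shape = image_shape, lesions = lesions,
         vessel_fields = vessel_fields, background_marker_means = bg,
         noise_sd = noise_sd, seed = as.integer(seed), pixel_size = pixel_size,
         section_id = section_id, organ = organ,
         nuclei_intensity = nuclei_intensity, nucleus_radius = nucleus_radius,
         background_nuclei_density = background_nuclei_density, wrap = wrap),
    class = "synthetic_spec"
  )
}

# Integer (dr, dc) offsets of the digital disk of radius r.
disk_offsets <- function(r) {
  a <- seq.int(-floor(r), floor(r))
  g <- expand.grid(dr = a, dc = a)
  g[g$dr * g$dr + g$dc * g$dc <= r * r, , drop = FALSE]
}

# Stamp value-`val` disks of radius `r` at integer `centers` (n x 2) onto
# `mat` by maximum compositing. Returns the updated matrix. Out-of-bounds
# pixels are dropped, or wrapped when `wrap = TRUE`.
stamp_disks <- function(mat, centers, r, val, wrap = FALSE) {
  if (is.null(centers) || nrow(centers) == 0L) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  off <- disk_offsets(r)
  for (k in seq_len(nrow(centers))) {
    rr <- centers[k, 1L] + off$dr
    cc <- centers[k, 2L] + off$dc
    if (wrap) {
      rr <- ((rr - 1L) %% nr) + 1L
      cc <- ((cc - 1L) %% nc) + 1L
    } else {
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      rr <- rr[ok]; cc <- cc[ok]
      if (!length(rr)) next
    }
    idx <- (cc - 1L) * nr + rr
    mat[idx] <- pmax(mat[idx], val)
  }
  mat
}

# Uniform integer radii in [range[1], range[2]]; safe when the range is one value.
sample_radii <- function(range, n) {
  cand <- seq.int(range[1L], range[2L])
  if (length(cand) == 1L) rep(cand, n) else sample(cand, n, replace = TRUE)
}

# Uniform random integer pixel positions inside a disk (polar sampling).
runif_disk <- function(n, center, radius) {
  if (n == 0L) return(matrix(integer(0), 0L, 2L))
  rad <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(as.integer(round(center[1L] + rad * sin(th))),
        as.integer(round(center[2L] + rad * cos(th))))
}

#' Generate a synthetic multi-channel tumor map with ground truth
#'
#' Renders one simulated section per the spec: lesion disks carry
#' channel-specific mean intensities with an optional radial gradient; nuclei
#' are filled disks at Poisson-placed centers (dense inside lesions, sparse
#' outside) on the Hoechst channel; CD31 vessel cross-sections are disks at
#' spatial-Poisson-placed centers; every channel then receives additive
#' Gaussian noise, is clipped to \[0, 255\] and quantized to 8 bits.
#' Generation is bit-reproducible for a fixed spec (the seed lives in the
#' spec) and leaves the caller's RNG state untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with components:
#' \describe{
#'   \item{map}{[tumor_map()] of quantized 8-bit channels.}
#'   \item{truth}{Ground truth: `roi_labels` (lesion label matrix),
#'     `lesion_table` (per-lesion true marker means computed from the
#'     noiseless scene, nuclei area fraction of the rendered nuclei mask,
#'     vessel rate), `vessel_centers` (n x 2 matrix), and `nuclei_mask`.}
#' }
#' @export
generate_tumor_map <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
  chans <- names(spec$background_marker_means)

  # reject intersecting lesion disks up front, naming the offending pair
  les <- spec$lesions
  if (length(les) > 1L) {
    for (i in seq_len(length(les) - 1L)) for (j in seq.int(i + 1L, length(les))) {
      d <- sqrt(sum((les[[i]]$center - les[[j]]$center)^2))
      if (d < les[[i]]$radius + les[[j]]$radius)
        stop(sprintf("lesions %d and %d overlap (center distance %.1f < %.1f)",
                     les[[i]]$id, les[[j]]$id, d,
                     les[[i]]$radius + les[[j]]$radius))
    }
  }

  scene <- lapply(chans, function(ch)
    matrix(spec$background_marker_means[[ch]], nr, nc))
  names(scene) <- chans
  roi_labels <- matrix(0L, nr, nc)
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  for (l in les) {
    d2 <- (rowg - l$center[1L])^2 + (colg - l$center[2L])^2
    inside <- which(d2 <= l$radius^2)
    if (!length(inside))
      stop(sprintf("lesion %d lies entirely outside the image", l$id))
    roi_labels[inside] <- l$id
    for (ch in names(l$marker_means)) {
      v <- l$marker_means[[ch]]
      if (l$gradient_amplitude > 0)
        v <- v + l$gradient_amplitude * (1 - 2 * sqrt(d2[inside]) / l$radius)
      scene[[ch]][inside] <- v
    }
  }

  out <- with_seed(spec$seed, {
    # nuclei: lesion interiors first (id order), then sparse background
    nuclei_mask <- matrix(FALSE, nr, nc)
    hoe <- scene[["hoechst"]]
    for (l in les) {
      area <- sum(roi_labels == l$id)
      n <- stats::rpois(1L, l$nuclei_density * area / 1e4)
      if (n > 0L) {
        radii <- sample_radii(spec$nucleus_radius, n)
        for (k in seq_len(n)) {
          # centers anywhere in the lesion; rendered pixels clipped to the
          # lesion boundary (the nuclei belong to the tumor cell cluster)
          ctr <- runif_disk(1L, l$center, l$radius)
          off <- disk_offsets(radii[k])
          rr <- ctr[1L] + off$dr; cc <- ctr[2L] + off$dc
          if (spec$wrap) {
            rr <- ((rr - 1L) %% nr) + 1L; cc <- ((cc - 1L) %% nc) + 1L
          } else {
            ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
            rr <- rr[ok]; cc <- cc[ok]
          }
          idx <- (cc - 1L) * nr + rr
          idx <- idx[roi_labels[idx] == l$id]
          if (!length(idx)) next
          hoe[idx] <- pmax(hoe[idx], spec$nuclei_intensity)
          nuclei_mask[idx] <- TRUE
        }
      }
    }
    bgpix <- which(roi_labels == 0L)
    nbg <- stats::rpois(1L, spec$background_nuclei_density * length(bgpix) / 1e4)
    if (nbg > 0L) {
      pick <- bgpix[sample.int(length(bgpix), nbg, replace = TRUE)]
      ctrs <- cbind(((pick - 1L) %% nr) + 1L, ((pick - 1L) %/% nr) + 1L)
      radii <- sample_radii(spec$nucleus_radius, nbg)
      for (k in seq_len(nbg)) {
        hoe <- stamp_disks(hoe, ctrs[k, , drop = FALSE], radii[k],
                           spec$nuclei_intensity, spec$wrap)
        nuclei_mask <- stamp_disks(nuclei_mask, ctrs[k, , drop = FALSE], radii[k],
                                   TRUE, spec$wrap)
      }
    }
    scene[["hoechst"]] <- hoe

    # vessels: spatial Poisson process per field, disks max-composited on cd31
    vessel_centers <- matrix(integer(0), 0L, 2L)
    cd <- scene[["cd31"]]
    for (v in spec$vessel_fields) {
      idx <- switch(as.character(v$region[[1L]]),
                    everywhere = seq_len(nr * nc),
                    normal = which(roi_labels == 0L),
                    which(roi_labels == as.integer(v$region)))
      n <- stats::rpois(1L, v$rate * length(idx))
      if (n > 0L) {
        pick <- idx[sample.int(length(idx), n, replace = TRUE)]
        ctrs <- cbind(((pick - 1L) %% nr) + 1L, ((pick - 1L) %/% nr) + 1L)
        cd <- stamp_disks(cd, ctrs, v$object_radius, v$intensity, spec$wrap)
        vessel_centers <- rbind(vessel_centers, ctrs)
      }
    }
    scene[["cd31"]] <- cd

    # additive Gaussian noise, clip, 8-bit quantization (channel order fixed)
    channels <- list()
    for (ch in chans) {
      x <- scene[[ch]]
      if (spec$noise_sd > 0)
        x <- x + stats::rnorm(length(x), 0, spec$noise_sd)
      x <- round(pmin(pmax(x, 0), 255))
      px <- matrix(as.integer(x), nr, nc)
      channels[[ch]] <- channel_image(px, ch, spec$pixel_size, spec$section_id)
    }
    list(channels = channels, nuclei_mask = nuclei_mask,
         vessel_centers = vessel_centers, scene = scene)
  })

  # ground truth table: true means are spatial averages of the noiseless scene
  lesion_table <- do.call(rbind, lapply(les, function(l) {
    inside <- roi_labels == l$id
    row <- data.frame(id = l$id, organ = spec$organ,
                      center_row = l$center[1L], center_col = l$center[2L],
                      radius = l$radius, area_px = sum(inside),
                      nuclei_area_fraction = sum(out$nuclei_mask & inside) / sum(inside),
                      vessel_rate = sum(vapply(spec$vessel_fields, function(v) {
                        if (identical(v$region, "everywhere") ||
                            (is.numeric(v$region) && v$region == l$id)) v$rate else 0
                      }, 0)),
                      stringsAsFactors = FALSE)
    for (ch in setdiff(chans, c("hoechst", "cd31")))
      row[[paste0("mean_", ch)]] <- mean(out$scene[[ch]][inside])
    row
  }))
  if (is.null(lesion_table))
    lesion_table <- data.frame(id = integer(0), organ = character(0),
                               center_row = numeric(0), center_col = numeric(0),
                               radius = numeric(0), area_px = integer(0),
                               nuclei_area_fraction = numeric(0),
                               vessel_rate = numeric(0))

  list(
    map = tumor_map(out$channels, spec$section_id),
    truth = list(roi_labels = roi_labels, lesion_table = lesion_table,
                 vessel_centers = out$vessel_centers,
                 nuclei_mask = out$nuclei_mask)
  )
}

#' Read / write a synthetic-section spec as YAML
#'
#' The config is a flat YAML document with `image_shape`, `seed`, `noise_sd`,
#' `background_means`, a `lesions` list (`id`, `center`, `radius`, `means`,
#' `gradient`, `nuclei_density`) and a `vessels` list (`rate`, `radius`,
#' `intensity`, `region`).
#'
#' @param path File path.
#' @return For `read_synthetic_spec`, a [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  lesions <- lapply(y$lesions, function(l)
    lesion_spec(id = l$id, center = unlist(l$center), radius = l$radius,
                marker_means = l$means,
                gradient_amplitude = l$gradient %||% 0,
                nuclei_density = l$nuclei_density %||% 40))
  vessels <- lapply(y$vessels, function(v)
    vessel_field_spec(rate = v$rate, object_radius = v$radius %||% 3,
                      intensity = v$intensity %||% 200,
                      region = v$region %||% "everywhere"))
  synthetic_spec(
    image_shape = unlist(y$image_shape), lesions = lesions,
    vessel_fields = vessels,
    background_marker_means = unlist(y$background_means),
    noise_sd = y$noise_sd %||% 10, seed = y$seed %||% 1L,
    pixel_size = y$pixel_size %||% 0.75,
    section_id = y$section_id %||% "synthetic", organ = y$organ %||% "liver",
    nuclei_intensity = y$nuclei_intensity %||% 200,
    background_nuclei_density = y$background_nuclei_density %||% 2,
    wrap = isTRUE(y$wrap)
  )
}

#' @rdname read_synthetic_spec
#' @param spec A [synthetic_spec()] to serialize.
#' @export
write_synthetic_spec <- function(spec, path) {
  y <- list(
    image_shape = as.integer(spec$image_shape), pixel_size = spec$pixel_size,
    seed = spec$seed, noise_sd = spec$noise_sd,
    section_id = spec$section_id, organ = spec$organ,
    nuclei_intensity = spec$nuclei_intensity,
    background_nuclei_density = spec$background_nuclei_density,
    wrap = spec$wrap,
    background_means = as.list(spec$background_marker_means),
    lesions = lapply(spec$lesions, function(l)
      list(id = l$id, center = as.numeric(l$center), radius = l$radius,
           means = as.list(l$marker_means), gradient = l$gradient_amplitude,
           nuclei_density = l$nuclei_density)),
    vessels = lapply(spec$vessel_fields, function(v)
      list(rate = v$rate, radius = v$object_radius, intensity = v$intensity,
           region = v$region))
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
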