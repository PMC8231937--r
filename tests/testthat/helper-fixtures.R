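# Shared fixture builders. Everything is generated in code at test time.

# Minimal channel set satisfying the generator's channel invariant.
bg_means <- function(hoechst = 0, mkate = 5, her2 = 5, cd31 = 0) {
  c(hoechst = hoechst, mkate = mkate, her2 = her2, cd31 = cd31)
}

# Small two-lesion section; noise and densities overridable per test.
two_lesion_spec <- function(seed = 1L, noise_sd = 0, nuclei_density = 400,
                            shape = c(256L, 256L), vessel_rate = 0.001,
                            background_nuclei_density = 0, ...) {
  synthetic_spec(
    image_shape = shape, seed = seed, noise_sd = noise_sd,
    background_marker_means = bg_means(),
    background_nuclei_density = background_nuclei_density,
    lesions = list(
      lesion_spec(1, c(70, 70), 40, c(her2 = 100, mkate = 180),
                  nuclei_density = nuclei_density),
      lesion_spec(2, c(180, 180), 35, c(her2 = 200, mkate = 60),
                  nuclei_density = nuclei_density)),
    vessel_fields = if (vessel_rate > 0)
      list(vessel_field_spec(rate = vessel_rate, object_radius = 2)) else list(),
    ...
  )
}

# ROI set covering the full image as one region (for whole-image metrics).
full_roi <- function(shape, id = 1L) {
  roi_set(matrix(as.integer(id), shape[1L], shape[2L]))
}

# Independent flood-fill 8-connected labelling (reference implementation
# kept deliberately naive; used as the oracle for component logic).
flood_label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nrow(mask)) + 1L
      c <- ((p - 1L) %/% nrow(mask)) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > nrow(mask) || cc < 1L || cc > ncol(mask)) next
        q <- (cc - 1L) * nrow(mask) + rr
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; stack <- c(stack, q) }
      }
    }
  }
  lab
}

# Compact six-lesion "liver" pipeline config (marker means span 40-220;
# a homogeneous "brain" variant is obtained by equal her2_means).
liver_config <- function(out_dir, seed = 42L, noise_sd = 10,
                         her2_means = c(40, 76, 112, 148, 184, 220),
                         organ = "liver", section_id = "liver_a",
                         vessel_rate = 0.0015) {
  centers <- list(c(90, 90), c(90, 260), c(90, 430),
                  c(300, 90), c(300, 260), c(300, 430))
  radii <- c(45, 40, 42, 48, 38, 44)
  list(
    out_dir = out_dir, seed = seed,
    synthetic = list(
      image_shape = c(448L, 512L), seed = seed, noise_sd = noise_sd,
      section_id = section_id, organ = organ,
      background_means = list(hoechst = 8, mkate = 5, her2 = 5, cd31 = 3),
      background_nuclei_density = 2,
      lesions = lapply(1:6, function(i)
        list(id = i, center = centers[[i]], radius = radii[i],
             means = list(her2 = her2_means[i], mkate = 120),
             nuclei_density = 60)),
      vessels = list(list(rate = vessel_rate, radius = 2, intensity = 200,
                          region = "everywhere"))),
    roi_source = "manual",
    manual_roi_tiff = file.path(out_dir, "masks",
                                paste0(section_id, "_truth_labels.tif")),
    manual_roi_csv = file.path(out_dir, "tables",
                               paste0(section_id, "_truth_rois.csv"))
  )
}

# Brute-force mean nearest-positive-pixel distance over ROI pixels.
brute_force_mean_distance <- function(mask, roi_idx) {
  pos <- which(mask, arr.ind = TRUE)
  stopifnot(nrow(pos) > 0)
  nr <- nrow(mask)
  mean(vapply(roi_idx, function(p) {
    r <- ((p - 1L) %% nr) + 1L
    c <- ((p - 1L) %/% nr) + 1L
    sqrt(min((pos[, 1L] - r)^2 + (pos[, 2L] - c)^2))
  }, 0))
}
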