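test_that("a constant ROI gives a delta histogram at its value", {
  px <- matrix(100L, 16L, 16L)
  h <- intensity_histogram(channel_image(px, "her2"), full_roi(c(16L, 16L)), 1L)
  expect_equal(h$bins[101L], 100)
  expect_equal(sum(h$bins), 100)
  expect_identical(h$n_pixels, 256L)
})

test_that("a half 0 / half 255 ROI splits the histogram 50/50", {
  px <- matrix(c(rep(0L, 128), rep(255L, 128)), 16L, 16L)
  h <- intensity_histogram(channel_image(px, "her2"), full_roi(c(16L, 16L)), 1L)
  expect_equal(h$bins[1L], 50)
  expect_equal(h$bins[256L], 50)
  expect_equal(mean_intensity(channel_image(px, "her2"),
                              full_roi(c(16L, 16L)), 1L), 127.5)
})

test_that("zero-noise synthetic lesions give a ground-truth delta histogram", {
  spec <- synthetic_spec(
    image_shape = c(128L, 128L), seed = 2L, noise_sd = 0,
    background_marker_means = bg_means(),
    background_nuclei_density = 0,
    lesions = list(lesion_spec(1, c(64, 64), 30, c(her2 = 180),
                               nuclei_density = 50)))
  g <- generate_tumor_map(spec)
  rois <- roi_set(g$truth$roi_labels)
  h <- intensity_histogram(g$map$channels$her2, rois, 1L)
  expect_equal(h$bins[181L], 100)
  expect_equal(mean_intensity(g$map$channels$her2, rois, 1L), 180)
})

test_that("histogram-weighted mean equals the direct mean on random ROIs", {
  set.seed(41)
  for (rep in 1:20) {
    px <- matrix(as.integer(sample(0:255, 400, replace = TRUE)), 20L, 20L)
    lab <- matrix(0L, 20L, 20L)
    lab[sample(400L, 150L)] <- 1L
    lab[sample(which(lab == 0L), 30L)] <- -1L  # artifacts must be excluded
    rois <- roi_set(lab)
    ci <- channel_image(px, "her2")
    h <- intensity_histogram(ci, rois, 1L)
    expect_equal(sum(h$bins), 100, tolerance = 1e-12)
    expect_equal(sum((0:255) * h$bins) / 100, mean_intensity(ci, rois, 1L),
                 tolerance = 1e-9)
  }
})

test_that("empty or missing ROIs are an error", {
  px <- matrix(0L, 8L, 8L)
  rois <- full_roi(c(8L, 8L))
  expect_error(intensity_histogram(channel_image(px, "her2"), rois, 2L),
               "not present")
  expect_error(mean_intensity(channel_image(px, "her2"), rois, 99L),
               "not present")
})

test_that("heat-map classes follow the cutpoints and tile the ROI", {
  px <- matrix(0L, 3L, 3L)
  px[1L] <- 50L; px[2L] <- 120L; px[3L] <- 200L
  hm <- heatmap_classify(channel_image(px, "her2"), full_roi(c(3L, 3L)))
  expect_identical(hm$classes[1L], 1L)  # weak
  expect_identical(hm$classes[2L], 2L)  # moderate
  expect_identical(hm$classes[3L], 3L)  # strong
  expect_true(all(hm$classes %in% 1:3))  # exhaustive over ROI pixels
  hm0 <- heatmap_classify(channel_image(matrix(0L, 4L, 4L), "her2"),
                          full_roi(c(4L, 4L)))
  expect_true(all(hm0$classes == 1L))  # all-zero ROI is uniformly weak
  expect_error(heatmap_classify(channel_image(px, "her2"), full_roi(c(3L, 3L)),
                                c(170, 85)), "edge1 < edge2")
})

test_that("heat-map class counts equal histogram partial sums", {
  set.seed(42)
  px <- matrix(as.integer(sample(0:255, 1024, replace = TRUE)), 32L, 32L)
  lab <- matrix(0L, 32L, 32L)
  lab[sample(1024L, 700L)] <- 1L
  rois <- roi_set(lab)
  ci <- channel_image(px, "her2")
  hm <- heatmap_classify(ci, rois, c(85, 170))
  h <- intensity_histogram(ci, rois, 1L)
  n <- h$n_pixels
  expect_equal(sum(hm$classes == 1L), round(sum(h$bins[1:85]) * n / 100))
  expect_equal(sum(hm$classes == 2L), round(sum(h$bins[86:170]) * n / 100))
  expect_equal(sum(hm$classes == 3L), round(sum(h$bins[171:256]) * n / 100))
})

test_that("cellularity is the nuclear area fraction of the ROI", {
  shape <- c(16L, 16L)
  hoechst <- channel_image(matrix(100L, 16L, 16L), "hoechst")
  full <- binary_mask(matrix(TRUE, 16L, 16L), "hoechst", 50, 1L)
  expect_equal(cellularity(full, hoechst, full_roi(shape), 1L)$percent_area, 100)
  checker <- binary_mask(outer(1:16, 1:16, function(r, c) (r + c) %% 2L == 0L),
                         "hoechst", 50, 1L)
  res <- cellularity(checker, hoechst, full_roi(shape), 1L)
  expect_equal(res$percent_area, 50)
  expect_equal(res$mean_intensity, 100)
})

test_that("cellularity equals generator ground truth at zero noise", {
  g <- generate_tumor_map(two_lesion_spec(seed = 3L, noise_sd = 0,
                                          nuclei_density = 300))
  nuc <- mask_nuclei(g$map$channels$hoechst, threshold = 1, min_object_px = 1L)
  rois <- roi_set(g$truth$roi_labels)
  for (k in seq_len(nrow(g$truth$lesion_table))) {
    id <- g$truth$lesion_table$id[k]
    res <- cellularity(nuc, g$map$channels$hoechst, rois, id)
    expect_equal(res$percent_area,
                 100 * g$truth$lesion_table$nuclei_area_fraction[k])
  }
})

test_that("vascular density of an all-positive ROI is zero", {
  mask <- binary_mask(matrix(TRUE, 8L, 8L), "cd31", 128, 1L)
  res <- vascular_density(mask, full_roi(c(8L, 8L)), 1L)
  expect_equal(res$mean_distance_px, 0)
  expect_identical(res$flags, character(0))
})

test_that("single central vessel pixel reproduces the hand distance mean", {
  m <- matrix(FALSE, 3L, 3L)
  m[2, 2] <- TRUE
  res <- vascular_density(binary_mask(m, "cd31", 128, 1L), full_roi(c(3L, 3L)),
                          1L, pixel_size = 2)
  expected <- (4 * 1 + 4 * sqrt(2) + 0) / 9
  expect_equal(res$mean_distance_px, expected, tolerance = 1e-12)
  expect_equal(res$mean_distance_um, 2 * expected, tolerance = 1e-12)
})

test_that("distance transform matches brute force on random small masks", {
  set.seed(43)
  for (rep in 1:50) {
    n <- sample(8:32, 1L)
    mask <- matrix(stats::rbinom(n * n, 1L, 0.07) == 1L, n, n)
    if (!any(mask)) mask[sample(n * n, 1L)] <- TRUE
    lab <- matrix(0L, n, n)
    lab[sample(n * n, max(3L, n))] <- 1L
    rois <- roi_set(lab)
    res <- vascular_density(binary_mask(mask, "cd31", 128, 1L), rois, 1L)
    bf <- brute_force_mean_distance(mask, which(lab == 1L))
    expect_equal(res$mean_distance_px, bf, tolerance = 1e-9)
  }
})

test_that("vessel-free sections flag the density as undefined", {
  mask <- binary_mask(matrix(FALSE, 8L, 8L), "cd31", 128, 1L)
  res <- vascular_density(mask, full_roi(c(8L, 8L)), 1L)
  expect_true(is.na(res$mean_distance_px))
  expect_identical(res$flags, "no_vessel_in_section")
})

test_that("pixel size scales the micrometre distance and not the pixel one", {
  m <- matrix(FALSE, 12L, 12L)
  m[6, 6] <- TRUE
  rois <- full_roi(c(12L, 12L))
  bm <- binary_mask(m, "cd31", 128, 1L)
  a <- vascular_density(bm, rois, 1L, pixel_size = 0.75)
  b <- vascular_density(bm, rois, 1L, pixel_size = 1.5)
  expect_equal(a$mean_distance_px, b$mean_distance_px)
  expect_equal(2 * a$mean_distance_um, b$mean_distance_um)
})

test_that("adding CD31-positive pixels never increases the mean distance", {
  set.seed(44)
  m <- matrix(FALSE, 32L, 32L)
  m[sample(1024L, 5L)] <- TRUE
  rois <- full_roi(c(32L, 32L))
  d0 <- vascular_density(binary_mask(m, "cd31", 128, 1L), rois, 1L)$mean_distance_px
  for (rep in 1:10) {
    m[sample(which(!m), 3L)] <- TRUE
    d1 <- vascular_density(binary_mask(m, "cd31", 128, 1L), rois, 1L)$mean_distance_px
    expect_lte(d1, d0 + 1e-12)
    d0 <- d1
  }
})

test_that("profiling a two-lesion section fills every field", {
  g <- generate_tumor_map(two_lesion_spec(seed = 6L, noise_sd = 10,
                                          nuclei_density = 300))
  rois <- roi_set(g$truth$roi_labels,
                  data.frame(id = 1:2, kind = "lesion", organ = "liver",
                             area_px = g$truth$lesion_table$area_px))
  nuc <- mask_nuclei(g$map$channels$hoechst, threshold = 100, min_object_px = 4L)
  cd <- detect_cd31_objects(g$map$channels$cd31, threshold = 128,
                            min_object_px = 4L)
  prof <- profile_lesions(g$map, rois, nuc, cd$mask)
  expect_identical(nrow(prof), 2L)
  expect_identical(prof$roi_id, 1:2)
  expect_true(all(is.finite(prof$mean_her2)))
  expect_true(all(is.finite(prof$cellularity_pct)))
  expect_true(all(is.finite(prof$vascular_density_um)))
  expect_true(all(prof$flags == ""))
})

test_that("a vessel-free section flags vascular density but keeps other fields", {
  g <- generate_tumor_map(two_lesion_spec(seed = 6L, noise_sd = 10,
                                          nuclei_density = 300,
                                          vessel_rate = 0))
  rois <- roi_set(g$truth$roi_labels)
  nuc <- mask_nuclei(g$map$channels$hoechst, threshold = 100, min_object_px = 4L)
  cd <- detect_cd31_objects(g$map$channels$cd31, threshold = 128,
                            min_object_px = 4L)
  prof <- profile_lesions(g$map, rois, nuc, cd$mask)
  expect_identical(nrow(prof), 2L)
  expect_true(all(is.na(prof$vascular_density_um)))
  expect_true(all(grepl("no_vessel_in_section", prof$flags)))
  expect_true(all(is.finite(prof$mean_her2)))
})

test_that("monotone profiles give Spearman rho of +/- 1", {
  prof <- data.frame(roi_id = 1:5,
                     vascular_density_px = c(1, 2, 3, 4, 5),
                     mean_her2 = c(10, 20, 30, 40, 50))
  up <- correlate_density_expression(prof, "her2")
  expect_equal(up$rho, 1)
  prof$mean_her2 <- rev(prof$mean_her2)
  dn <- correlate_density_expression(prof, "her2")
  expect_equal(dn$rho, -1)
})

test_that("tied observations are mid-ranked in the density correlation", {
  x <- c(3.2, 1.1, 4.5, 1.1, 2.8)  # one tie in density
  y <- c(40, 10, 80, 25, 33)
  prof <- data.frame(roi_id = 1:5, vascular_density_px = x, mean_her2 = y)
  res <- correlate_density_expression(prof, "her2")
  # hand mid-rank oracle: Pearson correlation of the rank vectors
  rk <- function(v) {
    o <- sort(unique(v))
    out <- numeric(length(v))
    pos <- 0
    for (u in o) {
      hit <- which(v == u)
      out[hit] <- pos + (length(hit) + 1) / 2
      pos <- pos + length(hit)
    }
    out
  }
  rx <- rk(x); ry <- rk(y)
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$rho, hand, tolerance = 1e-12)
  # independent route: cor.test's rho agrees
  expect_equal(res$rho,
               unname(suppressWarnings(
                 stats::cor.test(x, y, method = "spearman")$estimate)),
               tolerance = 1e-12)
  expect_identical(res$n, 5L)
})

test_that("degenerate correlation inputs are flagged or rejected", {
  prof <- data.frame(roi_id = 1:2, vascular_density_px = c(1, 2),
                     mean_her2 = c(1, 2))
  expect_error(correlate_density_expression(prof, "her2"), "at least 3")
  prof3 <- data.frame(roi_id = 1:4, vascular_density_px = c(1, 1, 1, 1),
                      mean_her2 = c(1, 2, 3, 4))
  res <- correlate_density_expression(prof3, "her2")
  expect_true(is.na(res$rho))
  expect_identical(res$flags, "zero_variance")
  profx <- data.frame(roi_id = 1:5,
                      vascular_density_px = c(1, 2, NA, 4, 5),
                      mean_her2 = c(5, 4, 3, 2, 1))
  resx <- correlate_density_expression(profx, "her2")
  expect_identical(resx$n_excluded, 1L)
  expect_identical(resx$n, 4L)
})
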