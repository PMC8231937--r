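make_tile <- function(vals, shape = c(8L, 8L), channel = "hoechst") {
  channel_image(matrix(as.integer(vals), shape[1L], shape[2L]), channel)
}

test_that("montage places constant tiles in row-major blocks without blending", {
  tiles <- list(list(grid_row = 1, grid_col = 1, image = make_tile(10)),
                list(grid_row = 1, grid_col = 2, image = make_tile(20)),
                list(grid_row = 2, grid_col = 1, image = make_tile(30)),
                list(grid_row = 2, grid_col = 2, image = make_tile(40)))
  out <- assemble_montage(tile_grid(tiles))
  expect_identical(dim(out$pixels), c(16L, 16L))
  expect_true(all(out$pixels[1:8, 1:8] == 10L))
  expect_true(all(out$pixels[1:8, 9:16] == 20L))
  expect_true(all(out$pixels[9:16, 1:8] == 30L))
  expect_true(all(out$pixels[9:16, 9:16] == 40L))
})

test_that("a 1x1 grid montage is the single tile", {
  t1 <- make_tile(sample(0:255, 64, replace = TRUE))
  out <- assemble_montage(tile_grid(list(list(grid_row = 1, grid_col = 1,
                                              image = t1))))
  expect_identical(out$pixels, t1$pixels)
})

test_that("montage blocks slice back to the original tiles (round trip)", {
  set.seed(21)
  tiles <- list()
  for (i in 1:2) for (j in 1:3)
    tiles[[length(tiles) + 1L]] <- list(
      grid_row = i, grid_col = j,
      image = make_tile(sample(0:255, 35, replace = TRUE), c(5L, 7L)))
  out <- assemble_montage(tile_grid(tiles))
  expect_identical(dim(out$pixels), c(10L, 21L))
  for (t in tiles) {
    block <- out$pixels[(t$grid_row - 1L) * 5L + 1:5,
                        (t$grid_col - 1L) * 7L + 1:7]
    expect_identical(block, t$image$pixels)
  }
  # pixel multiset is conserved: the montage is a bijection on pixels
  expect_identical(sort(as.vector(out$pixels)),
                   sort(unlist(lapply(tiles, function(t) as.vector(t$image$pixels)))))
})

test_that("missing and malformed tiles are reported", {
  tiles <- list(list(grid_row = 1, grid_col = 1, image = make_tile(1)),
                list(grid_row = 2, grid_col = 2, image = make_tile(2)))
  expect_error(assemble_montage(tile_grid(tiles, c(2L, 2L))),
               "missing tile position")
  tiles2 <- list(list(grid_row = 1, grid_col = 1, image = make_tile(1)),
                 list(grid_row = 1, grid_col = 2, image = make_tile(2, c(4L, 4L))))
  expect_error(assemble_montage(tile_grid(tiles2)), "same shape")
})

test_that("8-bit TIFF write/read round-trips bit-identically", {
  set.seed(4)
  ci <- make_tile(sample(0:255, 64, replace = TRUE))
  f <- tempfile(fileext = ".tif")
  write_channel_tiff(ci, f)
  back <- read_channel_tiff(f, "hoechst")
  expect_identical(back$pixels, ci$pixels)
  # 1x1 image holding 255 is a valid channel image
  one <- channel_image(matrix(255L, 1L, 1L), "cd31")
  f1 <- tempfile(fileext = ".tif")
  write_channel_tiff(one, f1)
  expect_identical(read_channel_tiff(f1, "cd31")$pixels, one$pixels)
  unlink(c(f, f1))
})

test_that("16-bit input is max-normalized to 8-bit with half-up rounding", {
  set.seed(5)
  vals <- matrix(as.integer(sample(0:4095, 100, replace = TRUE)), 10L, 10L)
  vals[1L] <- 4095L  # pin the max
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(vals / 65535, f, bits.per.sample = 16L)
  expect_message(back <- read_channel_tiff(f, "her2"), "rescaling")
  expected <- matrix(as.integer(floor(vals * (255 / 4095) + 0.5)), 10L, 10L)
  expect_identical(back$pixels, expected)
  unlink(f)
})

test_that("RGB TIFFs are rejected with instruction to split channels", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(48), dim = c(4L, 4L, 3L)), f)
  expect_error(read_channel_tiff(f, "her2"), "grayscale file per channel")
  unlink(f)
})

test_that("read_section enforces matching channel shapes", {
  d <- tempfile(); dir.create(d)
  write_channel_tiff(make_tile(1, c(8L, 8L)), file.path(d, "a.tif"))
  write_channel_tiff(make_tile(2, c(6L, 6L)), file.path(d, "b.tif"))
  expect_error(
    read_section(c(hoechst = file.path(d, "a.tif"), cd31 = file.path(d, "b.tif"))),
    "same shape")
  unlink(d, recursive = TRUE)
})

test_that("ROI label sets round-trip through 16-bit TIFF + CSV with artifacts", {
  lab <- matrix(0L, 16L, 16L)
  lab[2:6, 2:6] <- 1L
  lab[10:14, 10:14] <- 2L
  lab[1, 10:16] <- -1L
  rois <- roi_set(lab, data.frame(id = 1:2, kind = c("lesion", "normal"),
                                  organ = c("liver", "liver"),
                                  area_px = c(25L, 25L)))
  ft <- tempfile(fileext = ".tif"); fc <- tempfile(fileext = ".csv")
  write_roi_set(rois, ft, fc)
  back <- read_roi_set(ft, fc)
  expect_identical(back$labels, rois$labels)
  expect_identical(back$table$kind, rois$table$kind)
  expect_identical(back$table$area_px, rois$table$area_px)
  unlink(c(ft, fc, paste0(fc, ".meta.json")))
})

test_that("self-alignment returns zero shift and leaves pixels untouched", {
  set.seed(6)
  a <- make_tile(sample(0:255, 4096, replace = TRUE), c(64L, 64L), "hoechst")
  b <- channel_image(a$pixels, "her2")
  res <- align_channels(list(hoechst = a, her2 = b), "hoechst", max_shift = 5L)
  expect_identical(res$shifts$dr, c(0L, 0L))
  expect_identical(res$shifts$dc, c(0L, 0L))
  expect_identical(res$map$channels$her2$pixels, a$pixels)
})

test_that("a translated copy is realigned by the recovered opposite shift", {
  set.seed(7)
  ref <- matrix(as.integer(sample(0:255, 4096, replace = TRUE)), 64L, 64L)
  shifted <- matrix(0L, 64L, 64L)
  shifted[(1 + 3):64, 1:(64 - 2)] <- ref[1:(64 - 3), (1 + 2):64]  # shift (3, -2)
  res <- align_channels(list(hoechst = channel_image(ref, "hoechst"),
                             her2 = channel_image(shifted, "her2")),
                        "hoechst", max_shift = 6L)
  row <- res$shifts[res$shifts$channel == "her2", ]
  expect_identical(c(row$dr, row$dc), c(-3L, 2L))
  realigned <- res$map$channels$her2$pixels
  core <- 4:61  # overlap region untouched by either zero fill
  expect_identical(realigned[core, core], ref[core, core])
  # exhaustive-search oracle: no other shift correlates better
  best <- -Inf; arg <- NULL
  for (dr in -6:6) for (dc in -6:6) {
    r1 <- max(1, 1 + dr):min(64, 64 + dr); c1 <- max(1, 1 + dc):min(64, 64 + dc)
    x <- ref[r1, c1]; y <- shifted[r1 - dr, c1 - dc]
    v <- suppressWarnings(stats::cor(as.numeric(x), as.numeric(y)))
    if (is.finite(v) && v > best) { best <- v; arg <- c(dr, dc) }
  }
  expect_identical(arg, c(-3L, 2L))
})

test_that("featureless channels resolve to zero shift with a degeneracy flag", {
  ref <- matrix(as.integer(sample(0:255, 1024, replace = TRUE)), 32L, 32L)
  flat <- matrix(40L, 32L, 32L)
  res <- align_channels(list(hoechst = channel_image(ref, "hoechst"),
                             cd31 = channel_image(flat, "cd31")),
                        "hoechst", max_shift = 4L)
  row <- res$shifts[res$shifts$channel == "cd31", ]
  expect_identical(c(row$dr, row$dc), c(0L, 0L))
  expect_identical(row$flag, "degenerate_correlation")
})

test_that("alignment is idempotent: re-aligning an aligned map gives zero shifts", {
  g <- generate_tumor_map(two_lesion_spec(seed = 8L, noise_sd = 10))
  chans <- g$map$channels[c("hoechst", "her2", "mkate")]
  res <- align_channels(chans, "hoechst", max_shift = 4L)
  res2 <- align_channels(res$map$channels, "hoechst", max_shift = 4L)
  expect_true(all(res2$shifts$dr == 0L))
  expect_true(all(res2$shifts$dc == 0L))
})
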