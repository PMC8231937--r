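#' Read a pipeline configuration
#'
#' A single YAML file drives the whole pipeline. Recognized keys (all
#' thresholds are echoed into the outputs so every run is reproducible from
#' its manifest):
#' \describe{
#'   \item{out_dir}{Output directory; tables under `tables/`, figures under
#'     `figures/`, masks and label images under `masks/`, simulated channels
#'     under `channels/`.}
#'   \item{seed}{Integer seed for subsampling (and the default synthetic
#'     seed).}
#'   \item{synthetic}{Inline synthetic-section spec (same keys as
#'     [read_synthetic_spec()]) — enables `simulate`.}
#'   \item{channels}{Map channel name -> TIFF path for pre-existing images.}
#'   \item{roi_source}{`"auto"` (propose from nuclei), `"manual"` (use the
#'     supplied label TIFF alone), or `"manual_over_auto"` (manual labels
#'     override the proposal). Default `"manual"` when a manual mask is
#'     configured, else `"auto"`.}
#'   \item{manual_roi_tiff, manual_roi_csv}{Manual/ground-truth ROI files.}
#'   \item{segmentation}{`nuclei_threshold`, `nuclei_min_object_px`,
#'     `cd31_threshold`, `cd31_min_object_px`, `min_lesion_px`,
#'     `closing_radius`.}
#'   \item{heatmap_channel, heatmap_edges}{Marker and cutpoints for the
#'     pseudocolor heat map.}
#'   \item{kw_channels}{Channels whose per-lesion pixel distributions enter
#'     the Kruskal-Wallis test (default: all markers).}
#'   \item{subsample_n_max}{Pixel cap per lesion for rank tests.}
#'   \item{align, align_reference, max_shift}{Channel registration controls;
#'     disabled by default (simulated channels are already aligned).}
#' }
#'
#' @param path YAML config path, or a list already in config shape.
#' @return A list of class `pipeline_config` with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  seg <- cfg$segmentation %||% list()
  out <- list(
    out_dir = cfg$out_dir %||% "tumormap_out",
    seed = as.integer(cfg$seed %||% 1L),
    synthetic = cfg$synthetic,
    channels = cfg$channels,
    pixel_size = cfg$pixel_size %||% 0.75,
    section_id = cfg$section_id %||% "section",
    roi_source = cfg$roi_source %||%
      (if (!is.null(cfg$manual_roi_tiff)) "manual" else "auto"),
    manual_roi_tiff = cfg$manual_roi_tiff,
    manual_roi_csv = cfg$manual_roi_csv,
    segmentation = list(
      nuclei_threshold = seg$nuclei_threshold %||% "auto",
      nuclei_min_object_px = as.integer(seg$nuclei_min_object_px %||% 4L),
      cd31_threshold = seg$cd31_threshold %||% "auto",
      cd31_min_object_px = as.integer(seg$cd31_min_object_px %||% 4L),
      min_lesion_px = as.integer(seg$min_lesion_px %||% 500L),
      closing_radius = as.integer(seg$closing_radius %||% 10L)
    ),
    heatmap_channel = cfg$heatmap_channel %||% "her2",
    heatmap_edges = as.numeric(unlist(cfg$heatmap_edges %||% c(85, 170))),
    kw_channels = cfg$kw_channels,
    subsample_n_max = as.integer(cfg$subsample_n_max %||% 10000L),
    align = isTRUE(cfg$align),
    align_reference = cfg$align_reference %||% "hoechst",
    max_shift = as.integer(cfg$max_shift %||% 20L)
  )
  class(out) <- "pipeline_config"
  out
}

out_paths <- function(cfg) {
  root <- cfg$out_dir
  p <- list(root = root,
            tables = file.path(root, "tables"),
            figures = file.path(root, "figures"),
            masks = file.path(root, "masks"),
            channels = file.path(root, "channels"))
  for (d in p) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  p
}

write_manifest <- function(cfg, stage, files, warnings, timings, path) {
  inv <- lapply(files, function(f)
    list(path = f, md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(
    list(stage = stage,
         package_version = as.character(utils::packageVersion("tumormapr")),
         seed = cfg$seed,
         config = cfg[setdiff(names(cfg), "synthetic_spec_obj")],
         stage_seconds = timings,
         warnings = warnings,
         files = inv),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Verify a run manifest against the files on disk
#'
#' @param manifest_path Path to a manifest JSON written by the pipeline.
#' @return `TRUE` if every listed file exists with its recorded checksum;
#'   otherwise a character vector naming the offending files.
#' @export
verify_manifest <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  bad <- character(0)
  for (f in man$files) {
    if (!file.exists(f$path)) { bad <- c(bad, paste0(f$path, " (missing)")); next }
    if (!identical(unname(tools::md5sum(f$path))[[1L]], f$md5))
      bad <- c(bad, paste0(f$path, " (checksum mismatch)"))
  }
  if (length(bad)) bad else TRUE
}

#' Simulate a synthetic section and write its files
#'
#' Generates the section described by the config's `synthetic` block and
#' writes one 8-bit grayscale TIFF per channel, the ground-truth label TIFF
#' and lesion table, the vessel-center list, and a checksummed manifest.
#'
#' @param config Path to a YAML config or a [read_pipeline_config()] result.
#' @return Invisibly, a list with the generated `map`, `truth` and the
#'   written file paths.
#' @export
tm_simulate <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  if (is.null(cfg$synthetic)) stop("config lacks a `synthetic` block")
  t0 <- proc.time()[["elapsed"]]
  syn <- cfg$synthetic
  if (is.null(syn$seed)) syn$seed <- cfg$seed
  spec <- build_synthetic_spec(syn)
  gen <- generate_tumor_map(spec)
  p <- out_paths(cfg)
  files <- unname(write_tumor_map(gen$map, p$channels))
  truth_rois <- roi_set(gen$truth$roi_labels,
                        if (nrow(gen$truth$lesion_table))
                          data.frame(id = gen$truth$lesion_table$id,
                                     kind = "lesion",
                                     organ = gen$truth$lesion_table$organ,
                                     area_px = gen$truth$lesion_table$area_px)
                        else NULL)
  lab_tif <- file.path(p$masks, sprintf("%s_truth_labels.tif", spec$section_id))
  lab_csv <- file.path(p$tables, sprintf("%s_truth_rois.csv", spec$section_id))
  write_roi_set(truth_rois, lab_tif, lab_csv)
  truth_csv <- file.path(p$tables, sprintf("%s_truth_lesions.csv", spec$section_id))
  utils::write.csv(gen$truth$lesion_table, truth_csv, row.names = FALSE)
  vc_csv <- file.path(p$tables, sprintf("%s_truth_vessel_centers.csv", spec$section_id))
  utils::write.csv(data.frame(row = gen$truth$vessel_centers[, 1L],
                              col = gen$truth$vessel_centers[, 2L]),
                   vc_csv, row.names = FALSE)
  files <- c(files, lab_tif, lab_csv, truth_csv, vc_csv)
  man <- file.path(p$root, "manifest_simulate.json")
  write_manifest(cfg, "simulate", files, character(0),
                 list(simulate = proc.time()[["elapsed"]] - t0), man)
  invisible(list(map = gen$map, truth = gen$truth, files = files,
                 manifest = man))
}

# A config `synthetic` block uses the same keys as the YAML spec file.
build_synthetic_spec <- function(syn) {
  if (inherits(syn, "synthetic_spec")) return(syn)
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(syn, tmp)
  read_synthetic_spec(tmp)
}

#' Analyze a section: segment, profile, test
#'
#' Reads the section channels (from `channels` paths, or the `simulate`
#' outputs when the config is synthetic), optionally aligns them, segments
#' nuclei and CD31 objects, resolves ROIs per `roi_source`, and writes:
#' per-lesion profiles CSV, per-lesion 256-bin histogram CSV, heat-map class
#' TIFF + paletted PNG, Kruskal-Wallis stats CSV, boxplot-summary CSV and a
#' manifest. Zero-lesion sections produce an empty profile table and a
#' warning, not an error.
#'
#' @inheritParams tm_simulate
#' @return Invisibly, a list with `profiles`, `stats`, `rois`, written
#'   `files` and the manifest path.
#' @export
tm_analyze <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  t0 <- proc.time()[["elapsed"]]
  warnings <- character(0)
  p <- out_paths(cfg)

  if (!is.null(cfg$channels)) {
    map <- read_section(unlist(cfg$channels), cfg$pixel_size, cfg$section_id)
  } else if (!is.null(cfg$synthetic)) {
    sid <- cfg$synthetic$section_id %||% "synthetic"
    chans <- names(cfg$synthetic$background_means)
    paths <- stats::setNames(
      file.path(p$channels, sprintf("%s_%s.tif", sid, chans)), chans)
    if (!all(file.exists(paths)))
      stop("simulated channels not found; run tm_simulate() first")
    map <- read_section(paths, cfg$synthetic$pixel_size %||% cfg$pixel_size, sid)
  } else stop("config must provide `channels` paths or a `synthetic` block")

  shifts <- NULL
  if (cfg$align) {
    al <- align_channels(map$channels, cfg$align_reference, cfg$max_shift)
    map <- al$map
    shifts <- al$shifts
  }

  seg <- cfg$segmentation
  nuclei <- mask_nuclei(map$channels[["hoechst"]], seg$nuclei_threshold,
                        seg$nuclei_min_object_px)
  cd31 <- detect_cd31_objects(map$channels[["cd31"]], seg$cd31_threshold,
                              seg$cd31_min_object_px)

  rois <- switch(cfg$roi_source,
    auto = propose_lesions(nuclei, seg$min_lesion_px, seg$closing_radius),
    manual = {
      if (is.null(cfg$manual_roi_tiff)) stop("roi_source 'manual' needs `manual_roi_tiff`")
      read_roi_set(cfg$manual_roi_tiff, cfg$manual_roi_csv)
    },
    manual_over_auto = {
      if (is.null(cfg$manual_roi_tiff)) stop("roi_source 'manual_over_auto' needs `manual_roi_tiff`")
      auto <- propose_lesions(nuclei, seg$min_lesion_px, seg$closing_radius)
      man <- read_roi_set(cfg$manual_roi_tiff, cfg$manual_roi_csv)
      apply_manual_rois(auto, man$labels, man$table)
    },
    stop(sprintf("unknown roi_source '%s'", cfg$roi_source))
  )

  files <- character(0)
  sid <- map$section_id

  # masks + resolved ROI labels
  nuc_tif <- file.path(p$masks, sprintf("%s_nuclei_mask.tif", sid))
  tiff::writeTIFF(nuclei$pixels * 1, nuc_tif, bits.per.sample = 8L,
                  compression = "none")
  cd_tif <- file.path(p$masks, sprintf("%s_cd31_mask.tif", sid))
  tiff::writeTIFF(cd31$mask$pixels * 1, cd_tif, bits.per.sample = 8L,
                  compression = "none")
  roi_tif <- file.path(p$masks, sprintf("%s_roi_labels.tif", sid))
  roi_csv <- file.path(p$tables, sprintf("%s_rois.csv", sid))
  write_roi_set(rois, roi_tif, roi_csv)
  files <- c(files, nuc_tif, cd_tif, roi_tif, roi_csv)

  profiles <- profile_lesions(map, rois, nuclei, cd31$mask)
  prof_csv <- file.path(p$tables, sprintf("%s_profiles.csv", sid))
  write_profiles(profiles, prof_csv)
  files <- c(files, prof_csv)

  stats_rows <- list()
  lesion_ids <- profiles$roi_id
  if (!length(lesion_ids)) {
    warnings <- c(warnings, "no lesion-kind regions; statistics skipped")
  } else {
    markers <- cfg$kw_channels %||% setdiff(names(map$channels), c("hoechst", "cd31"))
    # per-lesion histograms, one wide CSV per channel set
    hist_df <- data.frame(intensity = 0:255)
    for (ch in names(map$channels)) for (id in lesion_ids) {
      h <- intensity_histogram(map$channels[[ch]], rois, id)
      hist_df[[sprintf("%s_roi%d", ch, id)]] <- h$bins
    }
    hist_csv <- file.path(p$tables, sprintf("%s_histograms.csv", sid))
    utils::write.csv(hist_df, hist_csv, row.names = FALSE)
    files <- c(files, hist_csv)

    # heat map of the configured marker over all regions
    if (cfg$heatmap_channel %in% names(map$channels)) {
      hm <- heatmap_classify(map$channels[[cfg$heatmap_channel]], rois,
                             cfg$heatmap_edges)
      hm_tif <- file.path(p$masks, sprintf("%s_heatmap_%s.tif", sid, cfg$heatmap_channel))
      tiff::writeTIFF(hm$classes / 255, hm_tif, bits.per.sample = 8L,
                      compression = "none")
      hm_png <- file.path(p$figures, sprintf("%s_heatmap_%s.png", sid, cfg$heatmap_channel))
      write_heatmap_png(hm, hm_png)
      files <- c(files, hm_tif, hm_png)
    }

    # KW on per-lesion pixel intensities, one test per marker channel;
    # per-lesion subsample seeds derive deterministically from the run seed
    if (length(lesion_ids) >= 2L) {
      for (ch in markers) {
        groups <- lapply(lesion_ids, function(id)
          subsample_pixels(map$channels[[ch]]$pixels[rois$labels == id],
                           cfg$subsample_n_max, cfg$seed + id))
        names(groups) <- paste0("roi", lesion_ids)
        kw <- kruskal_wallis(groups)
        stats_rows[[length(stats_rows) + 1L]] <- data.frame(
          section_id = sid, grouping = paste0("pixels_", ch), k = kw$k, N = kw$N,
          H = kw$H, df = kw$df, p = kw$p, tie_correction = kw$tie_correction,
          flags = paste(kw$flags, collapse = ";"), stringsAsFactors = FALSE)
        bs <- boxplot_summary(groups)
        bs_csv <- file.path(p$tables, sprintf("%s_boxplot_%s.csv", sid, ch))
        utils::write.csv(cbind(section_id = sid, channel = ch, bs), bs_csv,
                         row.names = FALSE)
        files <- c(files, bs_csv)
      }
    } else {
      warnings <- c(warnings, "fewer than 2 lesions; Kruskal-Wallis skipped")
    }

    # KW on vascular density grouped by organ, when >= 2 organs are usable
    vd_ok <- profiles[is.finite(profiles$vascular_density_um) &
                      !is.na(profiles$organ), , drop = FALSE]
    organs <- split(vd_ok$vascular_density_um, vd_ok$organ)
    organs <- organs[lengths(organs) >= 1L]
    if (length(organs) >= 2L && sum(lengths(organs)) >= length(organs) + 1L) {
      kw <- kruskal_wallis(organs)
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        section_id = sid, grouping = "vascular_density_by_organ", k = kw$k,
        N = kw$N, H = kw$H, df = kw$df, p = kw$p,
        tie_correction = kw$tie_correction,
        flags = paste(kw$flags, collapse = ";"), stringsAsFactors = FALSE)
    }
  }

  stats_df <- if (length(stats_rows)) do.call(rbind, stats_rows) else
    data.frame(section_id = character(0), grouping = character(0),
               k = integer(0), N = integer(0), H = numeric(0), df = integer(0),
               p = numeric(0), tie_correction = numeric(0), flags = character(0))
  stats_csv <- file.path(p$tables, sprintf("%s_stats.csv", sid))
  utils::write.csv(stats_df, stats_csv, row.names = FALSE)
  files <- c(files, stats_csv)

  if (!is.null(shifts)) {
    shift_csv <- file.path(p$tables, sprintf("%s_alignment.csv", sid))
    utils::write.csv(shifts, shift_csv, row.names = FALSE)
    files <- c(files, shift_csv)
  }

  for (w in warnings) warning(w, call. = FALSE)
  man <- file.path(p$root, "manifest_analyze.json")
  write_manifest(cfg, "analyze", files, warnings,
                 list(analyze = proc.time()[["elapsed"]] - t0), man)
  invisible(list(profiles = profiles, stats = stats_df, rois = rois,
                 map = map, nuclei = nuclei, cd31 = cd31, files = files,
                 manifest = man))
}

# background black, weak blue, moderate yellow, strong red (pseudocolor
# convention for staining-strength maps)
HEATMAP_PALETTE <- matrix(c(0, 0, 0,   0, 0, 1,   1, 1, 0,   1, 0, 0),
                          nrow = 4L, byrow = TRUE)

write_heatmap_png <- function(hm, path) {
  cls <- hm$classes
  rgb <- array(0, dim = c(nrow(cls), ncol(cls), 3L))
  for (k in 0:3) {
    sel <- cls == k
    for (c in 1:3) {
      plane <- rgb[, , c]
      plane[sel] <- HEATMAP_PALETTE[k + 1L, c]
      rgb[, , c] <- plane
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Render report figures from the pipeline tables
#'
#' Produces the figure set of the analysis: per-lesion intensity-histogram
#' overlays, per-lesion boxplots (drawn from the precomputed five-number
#' summaries, so the figure and the table cannot disagree), and the vascular
#' density vs marker expression scatter (lesions with flagged/undefined
#' density are omitted and their count stated in the caption).
#'
#' @inheritParams tm_simulate
#' @param section_id Section whose tables are plotted; defaults to the
#'   config's.
#' @return Invisibly, the written figure paths.
#' @export
tm_report <- function(config, section_id = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  p <- out_paths(cfg)
  sid <- section_id %||% cfg$synthetic$section_id %||% cfg$section_id
  files <- character(0)

  need <- function(path) {
    if (!file.exists(path)) stop(sprintf("missing pipeline table: %s", path))
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  require_cols <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s lacks column(s): %s", what, paste(miss, collapse = ", ")))
  }

  hist_path <- file.path(p$tables, sprintf("%s_histograms.csv", sid))
  if (file.exists(hist_path)) {
    hist_df <- need(hist_path)
    require_cols(hist_df, "intensity", "histogram table")
    long <- do.call(rbind, lapply(setdiff(names(hist_df), "intensity"), function(cn)
      data.frame(intensity = hist_df$intensity, trace = cn,
                 percent = hist_df[[cn]], stringsAsFactors = FALSE)))
    g <- ggplot2::ggplot(long, ggplot2::aes(x = .data$intensity,
                                            y = .data$percent,
                                            colour = .data$trace)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "intensity level (0-255)", y = "% of ROI pixels",
                    title = sprintf("%s: per-ROI intensity distributions", sid)) +
      ggplot2::theme_minimal()
    f <- file.path(p$figures, sprintf("%s_histograms.png", sid))
    ggplot2::ggsave(f, g, width = 8, height = 5, dpi = 120)
    files <- c(files, f)
  }

  for (bp in list.files(p$tables, sprintf("^%s_boxplot_.*\\.csv$", sid),
                        full.names = TRUE)) {
    bs <- need(bp)
    require_cols(bs, c("group", "q1", "median", "q3", "whisker_lo", "whisker_hi"),
                 basename(bp))
    g <- ggplot2::ggplot(bs, ggplot2::aes(x = .data$group)) +
      ggplot2::geom_boxplot(ggplot2::aes(ymin = .data$whisker_lo,
                                         lower = .data$q1,
                                         middle = .data$median,
                                         upper = .data$q3,
                                         ymax = .data$whisker_hi),
                            stat = "identity") +
      ggplot2::labs(x = NULL, y = "intensity level",
                    title = sprintf("%s: %s", sid,
                                    sub("\\.csv$", "", basename(bp)))) +
      ggplot2::theme_minimal()
    f <- file.path(p$figures, sub("\\.csv$", ".png", basename(bp)))
    ggplot2::ggsave(f, g, width = 7, height = 5, dpi = 120)
    files <- c(files, f)
  }

  prof_path <- file.path(p$tables, sprintf("%s_profiles.csv", sid))
  if (file.exists(prof_path)) {
    prof <- need(prof_path)
    marker_col <- paste0("mean_", cfg$heatmap_channel)
    if (all(c("vascular_density_um", marker_col) %in% names(prof)) &&
        nrow(prof)) {
      ok <- is.finite(prof$vascular_density_um)
      n_omit <- sum(!ok)
      d <- prof[ok, , drop = FALSE]
      if (nrow(d)) {
        g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$vascular_density_um,
                                             y = .data[[marker_col]])) +
          ggplot2::geom_point(size = 3) +
          ggplot2::labs(
            x = "vascular density (mean distance to nearest CD31+ pixel, um)",
            y = sprintf("mean %s intensity", cfg$heatmap_channel),
            title = sprintf("%s: vascular density vs %s expression", sid,
                            cfg$heatmap_channel),
            caption = sprintf("%d lesion(s) with undefined vascular density omitted",
                              n_omit)) +
          ggplot2::theme_minimal()
        f <- file.path(p$figures, sprintf("%s_density_vs_%s.png", sid,
                                          cfg$heatmap_channel))
        ggplot2::ggsave(f, g, width = 6, height = 5, dpi = 120)
        files <- c(files, f)
      }
    }
  }

  man <- file.path(p$root, "manifest_report.json")
  cfg2 <- cfg
  write_manifest(cfg2, "report", files, character(0), list(), man)
  invisible(files)
}

#' Run the full pipeline: simulate, analyze, report
#'
#' @inheritParams tm_simulate
#' @return Invisibly, the [tm_analyze()] result.
#' @export
tm_run_all <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  if (!is.null(cfg$synthetic)) tm_simulate(cfg)
  res <- tm_analyze(cfg)
  tm_report(cfg, res$map$section_id)
  invisible(res)
}
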