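# Config-driven orchestration: classify -> refine -> quantify for every
# image of a folder, writing tables, intermediate rasters and the fixed
# 29-parameter morphometric summary under <image_folder>/Results.

ANALYSIS_MODES <- c("neural_projections", "soma_and_nuclei",
                    "area_number_intensity", "length_and_branching",
                    "width", "colocalization")

#' The fixed 29-parameter morphometric schema
#'
#' Every pipeline run reports exactly these parameters per image, in this
#' order; parameters whose analysis mode was not selected are marked "not
#' computed" rather than omitted. `width_histogram` is vector-valued (one
#' count per bin) and counts as a single schema entry.
#'
#' @return Character vector of the 29 parameter names.
#' @export
parameter_schema <- function() {
  c("nuclei_count", "nuclei_total_size", "nuclei_mean_shape",
    "nuclei_mean_intensity", "soma_count", "soma_total_size",
    "soma_mean_shape", "soma_mean_intensity", "projection_count",
    "projection_total_size", "projection_mean_intensity",
    "skeleton_count", "branch_count", "junction_count",
    "endpoint_voxel_count", "junction_voxel_count", "slab_voxel_count",
    "triple_point_count", "quadruple_point_count", "branch_length_mean",
    "branch_length_max", "branch_length_sum", "attachment_point_count",
    "width_mean", "width_median", "width_histogram", "manders_m_a",
    "manders_m_b", "colocalized_size")
}

#' Pipeline configuration
#'
#' Accepts a YAML file path or an equivalent named list. Recognised keys:
#'
#' * `image_folder`: directory of input TIFFs (processed in lexicographic
#'   order).
#' * `calibration`, `unit`: optional spatial scale per axis.
#' * `crop`: optional list with `lo`, `hi` (1-based inclusive bounds).
#' * `segmented_input`: when `TRUE` the TIFFs are already masks and the
#'   pipeline skips straight to quantification.
#' * `modes`: subset of `r paste(ANALYSIS_MODES, collapse = ", ")`.
#' * `channels`: named list with entries `main` and optionally `nuclei`,
#'   `soma` (cell-body candidates; defaults to the main segmentation) and
#'   `partner`; each entry has `channel` (index in multi-channel
#'   files), `classifier` (archive path), `class` (class name or index to
#'   mask) and `thresholds` (arguments to [threshold_config()]).
#' * `histogram`: arguments to [histogram_config()] (required for the
#'   `width` and `neural_projections` modes).
#' * `nuclei_dilation_radius`: halo for soma gating (default 5).
#' * `attachment_halo`: halo for attachment-point counting (default 2).
#' * `output_dir`: defaults to `<image_folder>/Results`.
#' * `seed`: RNG seed recorded with the run.
#'
#' @param config file path or named list.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a file path or a list")
  if (is.null(config$image_folder)) stopf("config needs `image_folder`")
  modes <- config$modes
  if (is.null(modes)) stopf("config needs `modes`")
  bad <- setdiff(modes, ANALYSIS_MODES)
  if (length(bad)) stopf("unknown analysis modes: %s",
                         paste(bad, collapse = ", "))
  channels <- config$channels
  if (is.null(channels$main)) stopf("config needs `channels$main`")
  needs_nuclei <- "soma_and_nuclei" %in% modes
  if (needs_nuclei && is.null(channels$nuclei))
    stopf("mode soma_and_nuclei requires `channels$nuclei`")
  if ("colocalization" %in% modes && is.null(channels$partner))
    stopf("mode colocalization requires `channels$partner`")
  if (any(c("width", "neural_projections") %in% modes) &&
      is.null(config$histogram))
    stopf("width-bearing modes require `histogram`")
  segmented <- isTRUE(config$segmented_input)
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!segmented && is.null(ch$classifier))
      stopf("channel '%s' needs a classifier (or set segmented_input)", nm)
  }
  cfg <- list(
    image_folder = config$image_folder,
    calibration = config$calibration %||% 1,
    unit = config$unit %||% "pixel",
    crop = config$crop,
    segmented_input = segmented,
    modes = modes,
    channels = channels,
    histogram = if (!is.null(config$histogram))
      do.call(histogram_config, config$histogram),
    nuclei_dilation_radius = config$nuclei_dilation_radius %||% 5,
    attachment_halo = config$attachment_halo %||% 2,
    output_dir = config$output_dir %||%
      file.path(config$image_folder, "Results"),
    seed = as.integer(config$seed %||% 1L),
    preview = isTRUE(config$preview))
  class(cfg) <- "pipeline_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' For every TIFF in the configured folder: load and optionally crop,
#' segment each required channel (classifier prediction + probability
#' threshold + mask refinement, or direct mask input), run the selected
#' analysis modes, and write per-image CSV tables, intermediate rasters
#' and the 29-parameter summary into the Results directory. Reruns with
#' an identical configuration and seed reproduce identical tables.
#'
#' @param config a [pipeline_config()], YAML path or list.
#' @param preview additionally write probability maps and other tuning
#'   rasters.
#' @return An object of class `results_bundle`: per-image results
#'   (`$images`, each holding the tables and the summary) plus the
#'   configuration.
#' @export
run_analysis <- function(config, preview = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  if (!dir.exists(cfg$image_folder))
    stopf("image folder not found: %s", cfg$image_folder)
  files <- sort(list.files(cfg$image_folder,
                           pattern = "\\.tiff?$", ignore.case = TRUE,
                           full.names = TRUE))
  if (!length(files)) stopf("no TIFF images in %s", cfg$image_folder)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  classifiers <- list()
  if (!cfg$segmented_input)
    for (nm in names(cfg$channels))
      classifiers[[nm]] <- load_pixel_classifier(cfg$channels[[nm]]$classifier)
  log_path <- file.path(cfg$output_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logln <- function(fmt, ...)
    writeLines(sprintf(fmt, ...), log_con)
  logln("run_analysis seed=%d modes=%s", cfg$seed,
        paste(cfg$modes, collapse = ","))
  images <- list()
  for (f in files) {
    img_name <- tools::file_path_sans_ext(basename(f))
    logln("image %s", img_name)
    loaded <- load_calibrated_image(f, calibration = cfg$calibration,
                                    unit = cfg$unit)
    chans <- if (inherits(loaded, "calibrated_image")) list(loaded) else loaded
    if (!is.null(cfg$crop)) {
      box <- crop_box(cfg$crop$lo, cfg$crop$hi)
      chans <- lapply(chans, crop, box = box)
    }
    get_channel <- function(spec) {
      idx <- spec$channel %||% 1L
      if (idx > length(chans))
        stopf("channel %d requested but image has %d", idx, length(chans))
      chans[[idx]]
    }
    segment <- function(nm) {
      spec <- cfg$channels[[nm]]
      image <- get_channel(spec)
      thr <- do.call(threshold_config, spec$thresholds %||% list())
      if (cfg$segmented_input) {
        mask <- mask_like(image, array(image$data > 0, dim(image$data)))
      } else {
        pm <- predict_probability_map(image, classifiers[[nm]])
        if (preview)
          save_probability_map(pm, file.path(
            cfg$output_dir, sprintf("%s_%s_probability.tif", img_name, nm)))
        mask <- extract_class_mask(pm, spec$class %||% 2L, thr$prob_min)
      }
      refined <- refine_mask(mask, image, thr)
      save_mask(refined, file.path(
        cfg$output_dir, sprintf("%s_%s_mask.tif", img_name, nm)))
      list(image = image, mask = refined)
    }
    main <- segment("main")
    res <- list(name = img_name)
    need_particles <- any(c("neural_projections", "area_number_intensity")
                          %in% cfg$modes)
    if (need_particles) {
      res$particles <- measure_particles(main$mask, main$image)
      write_table(res$particles,
                  file.path(cfg$output_dir,
                            sprintf("%s_particles.csv", img_name)))
    }
    nuclei <- bodies <- NULL
    if ("soma_and_nuclei" %in% cfg$modes) {
      nuc <- segment("nuclei")
      nuclei <- nuc$mask
      # body candidates: a dedicated soma channel when configured,
      # otherwise the main segmentation (the classical single-stain case)
      cand <- if (!is.null(cfg$channels$soma)) segment("soma")$mask
              else main$mask
      bodies <- detect_cell_bodies(cand, nuclei,
                                   cfg$nuclei_dilation_radius)
      res$nuclei_particles <- measure_particles(nuclei, nuc$image)
      res$body_particles <- measure_particles(bodies, main$image)
      write_table(res$nuclei_particles,
                  file.path(cfg$output_dir,
                            sprintf("%s_nuclei.csv", img_name)))
      write_table(res$body_particles,
                  file.path(cfg$output_dir,
                            sprintf("%s_bodies.csv", img_name)))
    }
    skel <- NULL
    if (any(c("neural_projections", "length_and_branching", "width")
            %in% cfg$modes)) {
      skel <- skeletonize_mask(main$mask)
      save_mask(skel, file.path(cfg$output_dir,
                                sprintf("%s_skeleton.tif", img_name)))
    }
    if (any(c("neural_projections", "length_and_branching") %in% cfg$modes)) {
      res$skeleton <- analyze_skeleton(skel)
      write_table(res$skeleton$skeletons,
                  file.path(cfg$output_dir,
                            sprintf("%s_skeletons.csv", img_name)))
      if (!is.null(bodies))
        res$attachment_points <- count_attachment_points(
          skel, bodies, cfg$attachment_halo)
    }
    if (any(c("neural_projections", "width") %in% cfg$modes)) {
      th <- local_thickness_map(main$mask)
      res$width <- width_along_skeleton(th, skel, cfg$histogram)
      save_thickness_map(width_map(th, skel),
                         file.path(cfg$output_dir,
                                   sprintf("%s_width.tif", img_name)))
      write_table(data.frame(bin_lo = res$width$breaks[-length(res$width$breaks)],
                             bin_hi = res$width$breaks[-1],
                             count = res$width$counts),
                  file.path(cfg$output_dir,
                            sprintf("%s_width_histogram.csv", img_name)))
    }
    if ("colocalization" %in% cfg$modes) {
      part <- segment("partner")
      res$coloc <- manders_overlap(main$mask, part$mask)
      write_table(data.frame(overlap_size = res$coloc$overlap_size,
                             m_a = res$coloc$m_a, m_b = res$coloc$m_b,
                             size_a = res$coloc$size_a,
                             size_b = res$coloc$size_b),
                  file.path(cfg$output_dir,
                            sprintf("%s_coloc.csv", img_name)))
    }
    res$summary <- summarize_image(res, cfg)
    write_table(res$summary,
                file.path(cfg$output_dir, sprintf("%s_summary.csv", img_name)))
    logln("  objects=%s skeletons=%s",
          if (!is.null(res$particles)) nrow(res$particles) else "-",
          if (!is.null(res$skeleton)) res$skeleton$n_skeletons else "-")
    images[[img_name]] <- res
  }
  structure(list(images = images, config = cfg), class = "results_bundle")
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
}

# Build the 29-entry summary table for one image's results.
summarize_image <- function(res, cfg) {
  schema <- parameter_schema()
  value <- rep(NA_real_, length(schema))
  text <- rep(NA_character_, length(schema))
  status <- rep("not computed", length(schema))
  set <- function(name, v) {
    i <- match(name, schema)
    value[i] <<- v
    status[i] <<- if (is.na(v)) "undefined" else "computed"
  }
  agg <- function(tab, prefix) {
    set(paste0(prefix, "_count"), nrow(tab))
    set(paste0(prefix, "_total_size"), sum(tab$size))
    if (prefix != "projection")
      set(paste0(prefix, "_mean_shape"),
          if (nrow(tab)) mean(tab$shape) else NA_real_)
    set(paste0(prefix, "_mean_intensity"),
        if (nrow(tab)) mean(tab$intensity_mean) else NA_real_)
  }
  if (!is.null(res$nuclei_particles)) agg(res$nuclei_particles, "nuclei")
  if (!is.null(res$body_particles)) agg(res$body_particles, "soma")
  if (!is.null(res$particles)) agg(res$particles, "projection")
  if (!is.null(res$skeleton)) {
    sk <- res$skeleton$skeletons
    set("skeleton_count", res$skeleton$n_skeletons)
    tot <- function(col) if (nrow(sk)) sum(sk[[col]]) else 0
    set("branch_count", tot("n_branches"))
    set("junction_count", tot("n_junctions"))
    set("endpoint_voxel_count", tot("n_endpoint_voxels"))
    set("junction_voxel_count", tot("n_junction_voxels"))
    set("slab_voxel_count", tot("n_slab_voxels"))
    set("triple_point_count", tot("n_triple_points"))
    set("quadruple_point_count", tot("n_quadruple_points"))
    nb <- tot("n_branches")
    set("branch_length_mean",
        if (nb > 0) tot("branch_length_sum") / nb else NA_real_)
    set("branch_length_max",
        if (nrow(sk)) max(sk$branch_length_max) else 0)
    set("branch_length_sum", tot("branch_length_sum"))
  }
  if (!is.null(res$attachment_points))
    set("attachment_point_count", res$attachment_points)
  if (!is.null(res$width)) {
    set("width_mean", res$width$width_mean)
    set("width_median", res$width$width_median)
    i <- match("width_histogram", schema)
    text[i] <- paste(res$width$counts, collapse = ";")
    status[i] <- "computed"
  }
  if (!is.null(res$coloc)) {
    set("manders_m_a", res$coloc$m_a)
    set("manders_m_b", res$coloc$m_b)
    set("colocalized_size", res$coloc$overlap_size)
  }
  data.frame(parameter = schema, value = value, text = text,
             status = status)
}

#' Ordered 29-parameter report of a results bundle
#'
#' @param bundle a [run_analysis()] result.
#' @return A data frame with one row per image and parameter: columns
#'   `image`, `parameter`, `value`, `text` (vector-valued entries such as
#'   the width histogram), `status` (`computed`, `undefined` for
#'   degenerate inputs, or `not computed` when the mode was not run).
#' @export
summarize_parameters <- function(bundle) {
  stopifnot(inherits(bundle, "results_bundle"))
  do.call(rbind, lapply(names(bundle$images), function(nm) {
    cbind(image = nm, bundle$images[[nm]]$summary)
  }))
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("<results_bundle> %d image(s), modes: %s\n",
              length(x$images), paste(x$config$modes, collapse = ", ")))
  invisible(x)
}
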