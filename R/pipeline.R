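#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].
#' Precedence is caller arguments > config file > defaults. The validated
#' configuration is echoed as JSON into the output directory so every
#' artifact is reproducible from (inputs, config, seed) alone.
#'
#' @param config_file optional path to a JSON config file whose fields
#'   override the defaults.
#' @param ... named overrides applied last (e.g. `seed = 7`,
#'   `reference_channel = "giantin"`).
#' @return a validated `run_config` list.
#' @export
run_config <- function(config_file = NULL, ...) {
  defaults <- list(
    input = NULL,                    # glob of mini-stack TIFFs
    out_dir = "golgimap-run",
    seed = NULL,
    reference_channel = "giantin",
    pixel_size_nm = NULL,            # fallback when TIFFs carry none
    background_method = "border_median",
    background_border_px = 3L,
    rolling_ball_radius_px = 25,
    normalize_intensity = TRUE,
    profile_normalize = TRUE,
    diameter_angles_deg = seq(0, 175, by = 5),
    line_width_px = 1,
    lq = list(marker = "marker", cis = "gm130", trans = "galt",
              min_axis_px = 3, plausible = c(-3, 3)),
    copynumber = list(roi_radius_px = 5, copies_per_standard = 16,
                      relative_brightness_vs_gfp = 1),
    simulate = list(n_stacks = 50)
  )
  cfg <- defaults
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop("config file not found: ", config_file)
    cfg <- utils::modifyList(cfg,
                             jsonlite::fromJSON(config_file,
                                                simplifyVector = TRUE,
                                                simplifyDataFrame = FALSE))
  }
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("config overrides must be named")
    cfg <- utils::modifyList(cfg, dots)
  }
  if (!is.null(cfg$pixel_size_nm) && cfg$pixel_size_nm <= 0)
    stop("config field pixel_size_nm must be > 0")
  if (!is.character(cfg$reference_channel))
    stop("config field reference_channel must be a string")
  structure(cfg, class = "run_config")
}

pipeline_stages <- c("simulate", "preprocess", "normalize", "average",
                     "profile", "radius", "diameter", "lq", "copynumber")

#' Run the mini-stack analysis pipeline
#'
#' Executes the requested stages in their canonical order
#' (simulate, preprocess, normalize, average, profile, radius, diameter,
#' lq, copynumber), reading mini-stack TIFFs from `config$input` (or
#' generating them with the `simulate` stage) and writing CSV/TIFF
#' artifacts plus a JSON run log into `config$out_dir`. Later stages that
#' need the output of an earlier stage not run in this invocation read it
#' from the output directory (e.g. `profile` on a precomputed
#' `average.tif`).
#'
#' @param config a [run_config()] (or list coercible to one).
#' @param stages character vector of stage names, or `"all"`.
#' @return invisibly, a list of stage results; artifacts on disk.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  if (identical(stages, "all")) stages <- pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  log <- list()
  res <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- list(...)
  }

  images <- NULL     # list of mc_image keyed by stack id
  if ("simulate" %in% stages) {
    if (is.null(config$seed)) stop("simulate stage requires a seed")
    sim_cfg <- config$simulate
    n <- sim_cfg$n_stacks %||% 50L
    sim_cfg$n_stacks <- NULL
    ds <- make_dataset(sim_cfg, n_stacks = n, seed = config$seed,
                       dir = file.path(out, "images"))
    images <- stats::setNames(lapply(ds$stacks, `[[`, "image"),
                              unique(ds$truth$stack_id))
    res$simulate <- ds
    note("simulate", n = n, seed = config$seed)
    if (is.null(config$input)) config$input <- file.path(out, "images",
                                                         "*.tif")
  }
  load_inputs <- function() {
    if (!is.null(images)) return(images)
    if (is.null(config$input)) stop("no input configured and no simulate ",
                                    "stage run")
    paths <- Sys.glob(config$input)
    if (length(paths) == 0L) stop("no mini-stacks found matching ",
                                  config$input)
    imgs <- lapply(paths, read_image,
                   pixel_size_nm = config$pixel_size_nm)
    stats::setNames(imgs, sub("\\.tiff?$", "", basename(paths)))
  }

  if ("preprocess" %in% stages) {
    images <- lapply(load_inputs(), subtract_background,
                     method = config$background_method,
                     border_px = config$background_border_px,
                     radius_px = config$rolling_ball_radius_px)
    note("preprocess", n = length(images),
         method = config$background_method)
    res$preprocess <- names(images)
  }

  aligned <- NULL
  if ("normalize" %in% stages) {
    images <- images %||% load_inputs()
    rejects <- character()
    aligned <- list()
    for (id in names(images)) {
      r <- tryCatch({
        ms <- mini_stack(images[[id]], config$reference_channel,
                         stack_id = id)
        align_ministack(
          normalize_ministack(ms,
                              normalize_intensity =
                                config$normalize_intensity))
      }, error = function(e) conditionMessage(e))
      if (inherits(r, "norm_stack")) aligned[[id]] <- r
      else rejects[id] <- r
    }
    if (length(aligned) == 0L)
      stop("normalize stage: every mini-stack was rejected")
    note("normalize", n = length(aligned), n_rejected = length(rejects),
         rejects = as.list(rejects))
    res$normalize <- names(aligned)
  }

  avg <- NULL
  if ("average" %in% stages) {
    if (is.null(aligned)) stop("average stage needs the normalize stage ",
                               "in the same invocation")
    avg <- average_ministacks(unname(aligned))
    write_image(avg$image, file.path(out, "average.tif"))
    utils::write.csv(data.frame(stack_id = avg$stack_ids),
                     file.path(out, "averaged_stacks.csv"),
                     row.names = FALSE)
    note("average", n = avg$n)
    res$average <- avg
  }
  load_average <- function() {
    if (!is.null(avg)) return(avg)
    p <- file.path(out, "average.tif")
    if (!file.exists(p)) stop("no en-face average available; run the ",
                              "average stage first")
    ids <- tryCatch(utils::read.csv(file.path(out, "averaged_stacks.csv")),
                    error = function(e) data.frame(stack_id = character()))
    structure(list(image = read_image(p), n = nrow(ids),
                   stack_ids = ids$stack_id,
                   reference_channel = config$reference_channel),
              class = "enface_average")
  }

  profile <- NULL
  if ("profile" %in% stages) {
    avg <- load_average()
    profile <- radial_mean_profile(avg$image,
                                   normalize = config$profile_normalize)
    utils::write.csv(as.data.frame(profile),
                     file.path(out, "radial_profile.csv"),
                     row.names = FALSE)
    note("profile", channels = names(avg$image$channels))
    res$profile <- profile
  }

  if ("radius" %in% stages) {
    if (is.null(profile)) {
      p <- file.path(out, "radial_profile.csv")
      if (!file.exists(p)) stop("no radial profile available; run the ",
                                "profile stage first")
      profile <- utils::read.csv(p)
      class(profile) <- c("radial_profile", "data.frame")
    }
    avg <- avg %||% load_average()
    refr <- extract_marker_radius(profile, config$reference_channel)
    chans <- setdiff(names(profile), c("radius_px"))
    radii <- lapply(chans, function(ch)
      extract_marker_radius(profile, ch,
                            reference_radius_px = refr$radius_px))
    tab <- data.frame(
      channel = chans,
      radius_px = vapply(radii, `[[`, numeric(1), "radius_px"),
      radius_nm = vapply(radii, `[[`, numeric(1), "radius_px") *
        avg$image$pixel_size_nm,
      radius_normalized = vapply(radii, `[[`, numeric(1),
                                 "radius_normalized"),
      n = avg$n)
    utils::write.csv(tab, file.path(out, "marker_radii.csv"),
                     row.names = FALSE)
    note("radius", reference_radius_px = refr$radius_px)
    res$radius <- tab
  }

  if ("diameter" %in% stages) {
    avg <- avg %||% load_average()
    dm <- measure_ring_diameter(avg$image, config$reference_channel,
                                angle_deg = config$diameter_angles_deg,
                                width_px = config$line_width_px)
    utils::write.csv(data.frame(channel = config$reference_channel,
                                diameter_px = dm$diameter_px,
                                diameter_nm = dm$diameter_nm,
                                n_angles = sum(is.finite(dm$per_angle_px))),
                     file.path(out, "ring_diameter.csv"),
                     row.names = FALSE)
    note("diameter", diameter_px = dm$diameter_px)
    res$diameter <- dm
  }

  if ("lq" %in% stages) {
    images <- images %||% load_inputs()
    lc <- config$lq
    recs <- lq_from_images(unname(images), marker = lc$marker,
                           cis = lc$cis, trans = lc$trans,
                           min_axis_px = lc$min_axis_px,
                           plausible = lc$plausible)
    tab <- data.frame(
      stack_id = names(images),
      lq = vapply(recs, `[[`, numeric(1), "lq"),
      axis_length_px = vapply(recs, `[[`, numeric(1), "axis_length_px"),
      accepted = vapply(recs, `[[`, logical(1), "accepted"))
    utils::write.csv(tab, file.path(out, "lq_records.csv"),
                     row.names = FALSE)
    summ <- summarize_lq(recs, channel = lc$marker)
    utils::write.csv(summ, file.path(out, "lq_summary.csv"),
                     row.names = FALSE)
    note("lq", n = summ$n, n_rejected = summ$n_rejected)
    res$lq <- summ
  }

  if ("copynumber" %in% stages) {
    cc <- config$copynumber
    if (is.null(cc$intensities_csv))
      stop("copynumber stage needs copynumber$intensities_csv (columns ",
           "punctum_id, i_punctum) and copynumber$i_nup")
    tab <- utils::read.csv(cc$intensities_csv)
    std <- fluor_standard(copies_per_standard = cc$copies_per_standard,
                          relative_brightness_vs_gfp =
                            cc$relative_brightness_vs_gfp)
    tab$copies <- vapply(tab$i_punctum, function(ip)
      estimate_copies(ip, cc$i_nup, std)$copies, numeric(1))
    utils::write.csv(tab, file.path(out, "copy_numbers.csv"),
                     row.names = FALSE)
    note("copynumber", n = nrow(tab), i_nup = cc$i_nup)
    res$copynumber <- tab
  }

  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
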