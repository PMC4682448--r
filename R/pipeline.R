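#' Pipeline configuration with defaults
#'
#' Collects every tunable of the workflow.  Values may be overridden by a
#' named list (e.g. parsed from YAML); unknown keys are rejected.
#'
#' @param overrides named nested list of overrides.
#' @return A `gel_config` list with components `polarity`, `strip`,
#'   `boundary`, `stitch`, `band` and `genotype`.
#' @export
gel_config <- function(overrides = NULL) {
  cfg <- list(
    polarity = "auto",
    strip = list(percentile = 75, merge_gap = 5, min_height = 8,
                 fallback_n = 4),
    boundary = list(prominence_frac = 0.05, min_lane_width = NULL),
    stitch = list(max_drift = NULL),
    band = list(percentile = 15, gate_k = 5, search_bound = NULL,
                normalized_xcorr = FALSE),
    genotype = list(ref_position = NULL, ref_window = 8, eps = NULL,
                    minpts = NULL, eps_floor = 2, var_floor = 0.25,
                    max_z = 3, search_bound = NULL)
  )
  if (!is.null(overrides)) {
    check <- function(ov, base, path = "") {
      bad <- setdiff(names(ov), names(base))
      if (length(bad) > 0) {
        stop("unknown config key(s): ",
             paste0(path, bad, collapse = ", "))
      }
      for (nm in names(ov)) {
        if (is.list(base[[nm]]) && is.list(ov[[nm]])) {
          check(ov[[nm]], base[[nm]], paste0(path, nm, "."))
        }
      }
    }
    check(overrides, cfg)
    cfg <- utils::modifyList(cfg, overrides)
  }
  structure(cfg, class = c("gel_config", "list"))
}

#' Extract lanes, profiles and bands from one gel image
#'
#' Runs polarity normalization, lane segmentation, per-lane straightening,
#' band-profile summation and band calling -- everything up to (but not
#' including) the cross-lane genotyping stage.
#'
#' @param image a [gel_image()] (any polarity).
#' @param mode lane detection mode, `"curved"` or `"straight"`.
#' @param expected_lanes optional known lane count.
#' @param config a [gel_config()].
#' @return List with `image` (normalized), `segmentation`, `lanes`
#'   (rectified + straightened), `shifts`, `profiles`, `bands`.
#' @export
extract_gel_features <- function(image, mode = c("curved", "straight"),
                                 expected_lanes = NULL,
                                 config = gel_config()) {
  mode <- match.arg(mode)
  img <- suppressMessages(normalize_polarity(image, config$polarity))
  seg <- segment_gel(img, mode = mode, expected_lanes = expected_lanes,
                     config = config)
  straightened <- lapply(seg$lanes, straighten_lane,
                         search_bound = config$band$search_bound,
                         normalized = isTRUE(config$band$normalized_xcorr))
  lanes <- lapply(straightened, `[[`, "lane")
  shifts <- lapply(straightened, `[[`, "offsets")
  profiles <- lapply(lanes, band_profile)
  bands <- lapply(profiles, function(b) {
    detect_bands(b, percentile = config$band$percentile,
                 min_intensity = band_gate(b, config$band$gate_k))
  })
  list(image = img, segmentation = seg, lanes = lanes, shifts = shifts,
       profiles = profiles, bands = bands)
}

#' Genotype the lanes of one or more feature sets
#'
#' Aligns lanes to the reference band, converts band positions to
#' reference-relative offsets, fits (or reuses) the band-cluster model and
#' emits per-lane genotype calls.  Offsets are reference-relative, so
#' features from several related gels can be pooled and a model fitted on
#' one gel can classify another.
#'
#' @param features a feature set from [extract_gel_features()], or a list
#'   of them (one per gel).
#' @param ref a [ref_spec()].
#' @param model optional previously fitted `cluster_model`; `NULL` fits
#'   one from these features.
#' @param config a [gel_config()].
#' @return List with `alignments`, `offsets`, `model`, `genotypes` --
#'   each per-gel element carries a `gel` column/index where relevant.
#' @export
genotype_gels <- function(features, ref, model = NULL,
                          config = gel_config()) {
  if (!is.null(features$profiles)) features <- list(features)
  per_gel <- lapply(features, function(f) {
    al <- align_lanes(f$profiles, f$bands, ref,
                      search_bound = config$genotype$search_bound)
    off <- band_offsets(f$bands, al)
    list(alignments = al, offsets = off)
  })
  if (is.null(model)) {
    pooled <- do.call(rbind, lapply(seq_along(per_gel), function(i) {
      o <- per_gel[[i]]$offsets
      if (nrow(o) > 0) o$gel <- i
      o
    }))
    pooled_al <- do.call(rbind, lapply(per_gel, `[[`, "alignments"))
    n_lanes <- sum(vapply(features, function(f) length(f$profiles),
                          integer(1)))
    model <- cluster_bands(pooled, n_lanes,
                           eps = config$genotype$eps,
                           minpts = config$genotype$minpts,
                           alignments = pooled_al,
                           eps_floor = config$genotype$eps_floor,
                           var_floor = config$genotype$var_floor)
  }
  genotypes <- lapply(per_gel, function(g) {
    call_genotypes(g$offsets, model, g$alignments,
                   max_z = config$genotype$max_z)
  })
  list(alignments = lapply(per_gel, `[[`, "alignments"),
       offsets = lapply(per_gel, `[[`, "offsets"),
       model = model, genotypes = genotypes)
}

boundary_to_list <- function(b) {
  list(rows = b$rows - 1, cols = b$cols - 1)  # 0-based in files
}

#' Run the full workflow over a set of images
#'
#' For each image: lane segmentation, band extraction, and overlay/table
#' outputs; across all images: a shared band-cluster model and per-lane
#' genotype calls.  All tables are CSV with a header row, geometry is JSON,
#' and pixel coordinates in files are 0-based.
#'
#' Per image the output directory receives `<stem>_lanes.json`,
#' `<stem>_bands.csv` and `<stem>_overlay.png`; across images it receives
#' `clusters.csv`, `model.json`, `genotypes.csv` and `config.yaml`.
#'
#' @param image_paths character vector of PNG/TIFF paths.
#' @param out_dir output directory.
#' @param ref a [ref_spec()]; `NULL` stops after band extraction.
#' @param mode `"curved"` or `"straight"`.
#' @param expected_lanes optional known lane count per image.
#' @param config a [gel_config()].
#' @param strict abort on the first failing image instead of skipping it.
#' @return Invisibly, a list with `features`, `genotyping` (or `NULL`) and
#'   `failures`.
#' @export
run_pipeline <- function(image_paths, out_dir, ref = NULL,
                         mode = c("curved", "straight"),
                         expected_lanes = NULL, config = gel_config(),
                         strict = FALSE) {
  mode <- match.arg(mode)
  if (length(image_paths) == 0) stop("no input images given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failures <- character(0)
  features <- list()
  for (path in image_paths) {
    stem <- tools::file_path_sans_ext(basename(path))
    f <- tryCatch({
      img <- load_gel_image(path)
      extract_gel_features(img, mode = mode,
                           expected_lanes = expected_lanes, config = config)
    }, error = function(e) {
      if (strict) stop("failed on ", path, ": ", conditionMessage(e))
      message("skipping ", path, ": ", conditionMessage(e))
      failures <<- c(failures, path)
      NULL
    })
    if (is.null(f)) next
    f$path <- path
    features[[stem]] <- f
    jsonlite::write_json(
      list(image = basename(path), coordinates = "0-based",
           mode = mode,
           strips = f$segmentation$strips,
           boundaries = lapply(f$segmentation$boundaries, boundary_to_list)),
      file.path(out_dir, paste0(stem, "_lanes.json")),
      auto_unbox = TRUE, digits = NA)
    bands_df <- do.call(rbind, lapply(seq_along(f$bands), function(i) {
      b <- f$bands[[i]]
      if (nrow(b) == 0) return(NULL)
      data.frame(image = basename(path), lane_index = i - 1L,
                 position_px = b$position - 1L, intensity = b$intensity,
                 prominence = b$prominence)
    }))
    if (is.null(bands_df)) {
      bands_df <- data.frame(image = character(0), lane_index = integer(0),
                             position_px = integer(0), intensity = numeric(0),
                             prominence = numeric(0))
    }
    utils::write.csv(bands_df,
                     file.path(out_dir, paste0(stem, "_bands.csv")),
                     row.names = FALSE)
    render_overlay(f$image, f$segmentation$boundaries, f$bands, f$lanes,
                   file.path(out_dir, paste0(stem, "_overlay.png")))
  }
  if (length(features) == 0) stop("no image could be processed")

  geno <- NULL
  if (!is.null(ref)) {
    geno <- genotype_gels(unname(features), ref, config = config)
    cl <- geno$model$clusters
    utils::write.csv(
      data.frame(cluster_id = cl$cluster_id, mean_px = cl$mean,
                 var_px2 = cl$variance, count = cl$count,
                 is_reference = cl$is_reference),
      file.path(out_dir, "clusters.csv"), row.names = FALSE)
    save_model(geno$model, file.path(out_dir, "model.json"))
    gdf <- do.call(rbind, lapply(seq_along(geno$genotypes), function(i) {
      g <- geno$genotypes[[i]]
      data.frame(image = basename(features[[i]]$path),
                 lane_index = g$calls$lane_index - 1L,
                 group_id = g$calls$group_id,
                 pattern = g$calls$pattern,
                 novel_bands = vapply(g$novel, function(v)
                   paste(v - 1L, collapse = ";"), character(1)))
    }))
    utils::write.csv(gdf, file.path(out_dir, "genotypes.csv"),
                     row.names = FALSE)
  }
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  invisible(list(features = features, genotyping = geno,
                 failures = failures))
}

#' Draw lane boundaries and band calls over a gel image
#'
#' Writes an RGB PNG with the (possibly curved) lane boundary polylines in
#' red and called band positions as green ticks at each lane centre.
#'
#' @param image a [gel_image()].
#' @param boundaries list of `lane_boundary` objects (optional).
#' @param bands list of band tables per lane (optional).
#' @param lanes list of `gel_lane` objects (needed to place band ticks).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_overlay <- function(image, boundaries = NULL, bands = NULL,
                           lanes = NULL, path) {
  px <- image$pixels / 255
  H <- nrow(px); W <- ncol(px)
  rgb <- array(rep(px, 3), dim = c(H, W, 3))
  if (!is.null(boundaries)) {
    for (b in boundaries) {
      cols <- clamp(round(boundary_col(b, seq_len(H))), 1, W)
      idx <- cbind(seq_len(H), cols)
      rgb[cbind(idx, 1)] <- 1
      rgb[cbind(idx, 2)] <- 0
      rgb[cbind(idx, 3)] <- 0
    }
  }
  if (!is.null(bands) && !is.null(lanes)) {
    for (i in seq_along(lanes)) {
      if (i > length(bands) || nrow(bands[[i]]) == 0) next
      lane <- lanes[[i]]
      cc <- round((boundary_col(lane$left, bands[[i]]$position) +
                     boundary_col(lane$right, bands[[i]]$position)) / 2)
      for (k in seq_along(cc)) {
        cols <- clamp((cc[k] - 3):(cc[k] + 3), 1, W)
        r <- clamp(bands[[i]]$position[k], 1, H)
        rgb[r, cols, 1] <- 0
        rgb[r, cols, 2] <- 1
        rgb[r, cols, 3] <- 0
      }
    }
  }
  png::writePNG(rgb, target = path)
  invisible(path)
}

#' Lane-detection accuracy
#'
#' The benchmark accuracy statistic: correctly detected lanes as a
#' percentage of true lanes, rounded to two decimals as conventionally
#' printed.
#'
#' @param detected number of correctly detected lanes.
#' @param total true number of lanes.
#' @return Percentage, rounded to 2 decimal places.
#' @export
segmentation_accuracy <- function(detected, total) {
  round(100 * detected / total, 2)
}

#' Bundled lane-detection benchmark tally
#'
#' Per-image results of automated curved-lane detection on ten
#' silver-stained PAGE images from an intron-length-polymorphism genotyping
#' study of sugarcane cultivars (433 lanes in total): image dimensions,
#' true lane count and the number of correctly detected lanes.
#'
#' @return Data frame with columns `image`, `width_px`, `height_px`,
#'   `lanes_total`, `lanes_detected`.
#' @export
lane_benchmark <- function() {
  path <- system.file("extdata", "lane_detection_benchmark.csv",
                      package = "gelcaller", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
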