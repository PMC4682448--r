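#' Specification of a synthetic gel image
#'
#' Defines a PAGE-like gel with known ground truth, reproducing the
#' artifact classes that make real gel images hard: curved (sinusoidal or
#' slanted) lanes, smiling/frowning bands, doublet bands, a vertical
#' background gradient, additive noise and contamination speckles.
#'
#' Geometry: lanes are `lane_width` px wide with `lane_gap` px between
#' them; an extra horizontal margin of `ceiling(amplitude)` px on each side
#' keeps curved lanes inside the image.  The reference band (always
#' present, near-constant mobility) sits at row `reference_mobility`;
#' every other band species is placed `band_species[s]` px below it.
#' Per-lane genotypes are presence vectors over the species, and mobility
#' errors are modelled as a whole-lane vertical offset (uniform integer in
#' `[-lane_offset_max, lane_offset_max]`, the error that inter-lane
#' alignment corrects) plus independent per-band jitter
#' (`N(0, band_jitter_sd^2)`, the residual scatter DBSCAN must absorb).
#'
#' @param n_lanes number of lanes.
#' @param lane_width,lane_gap lane geometry in pixels.
#' @param height image height (migration axis) in pixels.
#' @param curvature list with `type` (`"none"`, `"sinusoid"` or `"slant"`),
#'   `amplitude` (px), `wavelength` (px; default `3 * height`), `phase`
#'   (radians) and `slant` (px per row).
#' @param smile parabolic within-band row offset at the lane edges, px.
#' @param band_species mobilities of the non-reference species, px below
#'   the reference band.
#' @param reference_mobility row of the reference band.
#' @param genotype_patterns list of 0/1 presence vectors over
#'   `band_species`.
#' @param lane_pattern_assignment pattern index per lane.
#' @param doublet_species indices into `band_species` rendered as doublets.
#' @param doublet_gap centre-to-centre gap of doublet bands, px.
#' @param band_sigma Gaussian band thickness (sd), px.
#' @param peak_intensity band peak intensity above background.
#' @param background `c(base, gradient)`: background level and its increase
#'   per row.
#' @param noise_sd additive Gaussian pixel noise sd.
#' @param band_jitter_sd per-band mobility jitter sd, px.
#' @param lane_offset_max per-lane vertical offset bound, px.
#' @param speckle_count,speckle_radius contamination speckles.
#' @param polarity polarity of the rendered image; `bands_dark` (the
#'   silver-stain default) exercises [normalize_polarity()].
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return A `gel_spec` list.
#' @export
gel_spec <- function(n_lanes = 12, lane_width = 18, lane_gap = 8,
                     height = 400,
                     curvature = list(type = "none", amplitude = 0,
                                      wavelength = NULL, phase = 0, slant = 0),
                     smile = 0,
                     band_species = c(70, 140, 210),
                     reference_mobility = 60,
                     genotype_patterns = list(c(1, 1, 0), c(1, 0, 1),
                                              c(0, 1, 1)),
                     lane_pattern_assignment = NULL,
                     doublet_species = integer(0), doublet_gap = NA,
                     band_sigma = 2, peak_intensity = 180,
                     background = c(base = 30, gradient = 0.05),
                     noise_sd = 3, band_jitter_sd = 0, lane_offset_max = 0,
                     speckle_count = 0, speckle_radius = 2,
                     polarity = c("bands_dark", "bands_bright"),
                     seed = 1) {
  polarity <- match.arg(polarity)
  defaults <- list(type = "none", amplitude = 0, wavelength = NULL,
                   phase = 0, slant = 0)
  curvature <- utils::modifyList(defaults, curvature)
  if (is.null(curvature$wavelength)) curvature$wavelength <- 3 * height
  if (is.null(lane_pattern_assignment)) {
    lane_pattern_assignment <- rep_len(seq_along(genotype_patterns), n_lanes)
  }
  if (curvature$amplitude >= lane_gap + lane_width) {
    stop("curvature amplitude must be below lane_width + lane_gap")
  }
  if (any(vapply(genotype_patterns, length, integer(1)) !=
          length(band_species))) {
    stop("every genotype pattern must have one entry per band species")
  }
  mob <- reference_mobility + c(0, band_species)
  if (any(mob < 1 | mob > height)) {
    stop("band mobilities must lie within the image height")
  }
  if (length(doublet_species) > 0 && !is.finite(doublet_gap)) {
    stop("doublet_gap must be set when doublet_species is non-empty")
  }
  structure(list(
    n_lanes = n_lanes, lane_width = lane_width, lane_gap = lane_gap,
    height = height, curvature = curvature, smile = smile,
    band_species = band_species, reference_mobility = reference_mobility,
    genotype_patterns = genotype_patterns,
    lane_pattern_assignment = lane_pattern_assignment,
    doublet_species = doublet_species, doublet_gap = doublet_gap,
    band_sigma = band_sigma, peak_intensity = peak_intensity,
    background = background, noise_sd = noise_sd,
    band_jitter_sd = band_jitter_sd, lane_offset_max = lane_offset_max,
    speckle_count = speckle_count, speckle_radius = speckle_radius,
    polarity = polarity, seed = seed), class = "gel_spec")
}

lane_drift <- function(spec, rows) {
  cv <- spec$curvature
  switch(cv$type,
         none = rep(0, length(rows)),
         sinusoid = cv$amplitude *
           sin(2 * pi * (rows - 1) / cv$wavelength + cv$phase),
         slant = cv$slant * (rows - spec$height / 2),
         stop("unknown curvature type: ", cv$type))
}

#' Render a synthetic gel image with ground truth
#'
#' Bands are horizontal bars with a Gaussian vertical cross-section
#' (sd `band_sigma`) centred on the curved lane centreline at each
#' species' mobility, optionally bowed by the smile term and split into
#' doublets.  Background, gradient, speckles and clipped Gaussian noise
#' are then added and the image is rendered in the requested polarity.
#'
#' @param spec a [gel_spec()].
#' @return List with `image` (a [gel_image()]) and `truth`, a list holding
#'   `lane_centerlines` (`H x n_lanes` matrix of columns),
#'   `band_table` (`lane`, `species_id`, `row`, `is_reference`,
#'   `is_doublet`; species 0 is the reference), `genotype_groups`
#'   (group id per lane), `lane_offsets` and the margin-adjusted geometry.
#' @export
generate_gel <- function(spec) {
  stopifnot(inherits(spec, "gel_spec"))
  with_seed(spec$seed, {
    H <- spec$height
    pitch <- spec$lane_width + spec$lane_gap
    margin <- ceiling(abs(spec$curvature$amplitude) +
                        abs(spec$curvature$slant) * H / 2)
    W <- 2 * margin + spec$lane_gap + spec$n_lanes * pitch
    rows <- seq_len(H)
    drift <- lane_drift(spec, rows)
    centers0 <- margin + spec$lane_gap + (seq_len(spec$n_lanes) - 1) * pitch +
      spec$lane_width / 2
    centerlines <- outer(drift, rep(1, spec$n_lanes)) +
      matrix(centers0, H, spec$n_lanes, byrow = TRUE)

    img <- matrix(spec$background[[1]] + spec$background[[2]] * (rows - 1),
                  H, W)
    lane_off <- if (spec$lane_offset_max > 0) {
      sample(-spec$lane_offset_max:spec$lane_offset_max, spec$n_lanes,
             replace = TRUE)
    } else rep(0L, spec$n_lanes)

    hw <- spec$lane_width / 2
    band_rows <- list()
    add_band <- function(l, r0) {
      xc <- centerlines[clamp(round(r0), 1, H), l]
      cols <- (floor(xc - hw) + 1):floor(xc + hw)
      cols <- cols[cols >= 1 & cols <= W]
      for (col in cols) {
        u <- (col - xc) / hw
        rc <- r0 + spec$smile * u^2
        mr <- max(1, floor(rc - 4 * spec$band_sigma)):
              min(H, ceiling(rc + 4 * spec$band_sigma))
        img[mr, col] <<- img[mr, col] +
          spec$peak_intensity * exp(-(mr - rc)^2 / (2 * spec$band_sigma^2))
      }
    }
    for (l in seq_len(spec$n_lanes)) {
      pat <- spec$genotype_patterns[[spec$lane_pattern_assignment[l]]]
      for (s in 0:length(spec$band_species)) {
        present <- if (s == 0) TRUE else pat[s] == 1
        if (!present) next
        jit <- if (spec$band_jitter_sd > 0) {
          stats::rnorm(1, 0, spec$band_jitter_sd)
        } else 0
        r0 <- spec$reference_mobility +
          (if (s == 0) 0 else spec$band_species[s]) + lane_off[l] + jit
        is_doublet <- s %in% spec$doublet_species
        centers <- if (is_doublet) {
          r0 + c(-1, 1) * spec$doublet_gap / 2
        } else r0
        for (rc in centers) add_band(l, rc)
        band_rows[[length(band_rows) + 1]] <- data.frame(
          lane = l, species_id = s, row = centers,
          is_reference = s == 0, is_doublet = is_doublet)
      }
    }
    if (spec$speckle_count > 0) {
      for (i in seq_len(spec$speckle_count)) {
        sr <- stats::runif(1, 1, H); sc <- stats::runif(1, 1, W)
        rr <- max(1, floor(sr - spec$speckle_radius)):
              min(H, ceiling(sr + spec$speckle_radius))
        cc <- max(1, floor(sc - spec$speckle_radius)):
              min(W, ceiling(sc + spec$speckle_radius))
        d2 <- outer((rr - sr)^2, (cc - sc)^2, "+")
        img[rr, cc] <- img[rr, cc] +
          0.8 * spec$peak_intensity * (d2 <= spec$speckle_radius^2)
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    }
    img <- round(clamp(img, 0, 255))
    if (spec$polarity == "bands_dark") img <- 255 - img

    truth <- list(
      lane_centerlines = centerlines,
      band_table = do.call(rbind, band_rows),
      genotype_groups = match(spec$lane_pattern_assignment,
                              unique(spec$lane_pattern_assignment)),
      lane_offsets = lane_off,
      margin = margin, width = W,
      reference_mobility = spec$reference_mobility)
    list(image = gel_image(img, polarity = spec$polarity),
         truth = truth, spec = spec)
  })
}

#' Render a single distorted lane with known per-column shifts
#'
#' A direct fixture for the straightening stage: horizontal Gaussian bands
#' whose content in column `j` is displaced vertically by `shifts[j]`
#' (positive = down), e.g. smoothly for smiling bands or randomly for the
#' shift-recovery sweep.
#'
#' @param height,width lane dimensions.
#' @param band_rows undistorted band centre rows.
#' @param shifts integer vector of per-column displacements (length
#'   `width`).
#' @param band_sigma,peak_intensity,base,noise_sd rendering parameters.
#' @param seed RNG seed for the noise.
#' @return Numeric matrix `height x width`.
#' @export
generate_distorted_lane <- function(height = 120, width = 15,
                                    band_rows = c(40, 80),
                                    shifts = integer(width),
                                    band_sigma = 2, peak_intensity = 200,
                                    base = 0, noise_sd = 0, seed = 1) {
  stopifnot(length(shifts) == width)
  with_seed(seed, {
    m <- matrix(base, height, width)
    rows <- seq_len(height)
    for (j in seq_len(width)) {
      for (r in band_rows) {
        rc <- r + shifts[j]
        m[, j] <- m[, j] +
          peak_intensity * exp(-(rows - rc)^2 / (2 * band_sigma^2))
      }
    }
    if (noise_sd > 0) m <- m + matrix(stats::rnorm(height * width, 0,
                                                   noise_sd), height, width)
    clamp(m, 0, 255)
  })
}

synthetic_presets <- function(seed = 17) {
  list(
    straight_clean = gel_spec(noise_sd = 0, background = c(30, 0),
                              seed = seed),
    curved = gel_spec(curvature = list(type = "sinusoid", amplitude = 9,
                                       phase = 0.7),
                      seed = seed + 1),
    smiling = gel_spec(smile = 5, seed = seed + 2),
    doublet = gel_spec(band_species = c(70, 140), doublet_species = 2L,
                       doublet_gap = 6, band_sigma = 1,
                       genotype_patterns = list(c(1, 1)), seed = seed + 3),
    sparse = gel_spec(band_species = c(120),
                      genotype_patterns = list(c(0)), seed = seed + 4),
    noisy = gel_spec(noise_sd = 8, speckle_count = 12, seed = seed + 5)
  )
}

#' Write a suite of preset synthetic gels with ground truth
#'
#' Emits one PNG plus one ground-truth JSON per preset (straight/clean,
#' curved, smiling, doublet, sparse, noisy -- the regimes in which curved
#' lane detection succeeds or degrades) and a manifest listing files and
#' seeds.
#'
#' @param out_dir output directory (created if missing).
#' @param presets named list of [gel_spec()]s; defaults to the six built-in
#'   presets.
#' @param seed base seed for the default presets.
#' @return The manifest, invisibly (list with one entry per preset).
#' @export
generate_suite <- function(out_dir, presets = NULL, seed = 17) {
  if (is.null(presets)) presets <- synthetic_presets(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(names(presets), function(nm) {
    spec <- presets[[nm]]
    g <- generate_gel(spec)
    img_path <- file.path(out_dir, paste0(nm, ".png"))
    truth_path <- file.path(out_dir, paste0(nm, "_truth.json"))
    write_gel_image(g$image, img_path)
    jsonlite::write_json(
      list(preset = nm, seed = spec$seed, n_lanes = spec$n_lanes,
           reference_mobility = spec$reference_mobility,
           doublet_gap = spec$doublet_gap,
           band_table = g$truth$band_table,
           genotype_groups = g$truth$genotype_groups,
           lane_offsets = g$truth$lane_offsets),
      truth_path, auto_unbox = TRUE, digits = NA, na = "null")
    list(preset = nm, image = basename(img_path),
         truth = basename(truth_path), seed = spec$seed)
  })
  names(manifest) <- names(presets)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
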