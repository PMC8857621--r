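#' Specification of a synthetic OCT choroid phantom
#'
#' The phantom emulates the features of an EDI OCT B-scan that the pipeline
#' exercises: a curved inner choroidal boundary over a bright stromal band,
#' dark elliptical vessel lumina occupying a programmed area fraction, a
#' duller scleral band below the outer boundary, a thin bright RPE-like band
#' above the choroid, and multiplicative speckle. Geometry is in pixels;
#' intensities are mean 8-bit grey levels.
#'
#' @param rows,cols Image size in pixels.
#' @param icb_base Mean ICB row (depth of the choroid's inner edge).
#' @param icb_amplitude Amplitude in rows of the parabolic posterior-pole
#'   curvature of the ICB.
#' @param choroid_thickness Mean choroid band thickness in rows.
#' @param thickness_variation Peak-to-trough lateral variation of the
#'   thickness, in rows.
#' @param vessel_density Target luminal area fraction in (0, 1). Healthy
#'   choroid runs near 0.6.
#' @param vessel_radius_range Min/max ellipse semi-axis in pixels.
#' @param stroma_intensity,lumen_intensity,sclera_intensity Mean grey levels;
#'   lumen must be darker than stroma.
#' @param speckle_level Dispersion of the multiplicative gamma speckle
#'   (standard deviation of the unit-mean multiplier); 0 disables noise.
#' @param axial_scale_um,lateral_scale_um Pixel scales carried as metadata.
#' @param seed Integer seed; all generation is deterministic given the spec.
#' @param max_attempts Bound on vessel placement proposals before an
#'   unreachable `vessel_density` is reported as a generation error.
#' @return Object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(rows = 200, cols = 896,
                         icb_base = 60, icb_amplitude = 25,
                         choroid_thickness = 45, thickness_variation = 8,
                         vessel_density = 0.60,
                         vessel_radius_range = c(4, 12),
                         stroma_intensity = 180, lumen_intensity = 60,
                         sclera_intensity = 110, speckle_level = 0.15,
                         axial_scale_um = 3.9, lateral_scale_um = 14,
                         seed = 1L, max_attempts = 20000L) {
  if (vessel_density <= 0 || vessel_density >= 1) {
    abort("`vessel_density` must lie strictly between 0 and 1.")
  }
  if (lumen_intensity >= stroma_intensity) {
    abort("lumen must be darker than stroma (hypo- vs hyper-reflective).")
  }
  if (rows < 1 || cols < 1) abort("geometry must be positive.")
  structure(as.list(environment()), class = "phantom_spec")
}

# noise-free phantom structure on a canvas `cols_total` wide (>= spec$cols,
# to allow laterally jittered repeat crops); returns intensity field, truth
# labels and 0-based boundaries
phantom_structure <- function(spec, cols_total = spec$cols) {
  rows <- spec$rows
  xs <- seq(-1, 1, length.out = cols_total)
  icb <- round(spec$icb_base + spec$icb_amplitude * xs^2)
  thick <- round(spec$choroid_thickness +
                   spec$thickness_variation / 2 * sin(2 * pi * xs * 0.7))
  ocb <- icb + pmax(thick, 3L)
  if (max(ocb) >= rows) abort("choroid band does not fit below the ICB; enlarge `rows`.")

  ri <- matrix(0:(rows - 1L), rows, cols_total)
  icb_m <- matrix(icb, rows, cols_total, byrow = TRUE)
  ocb_m <- matrix(ocb, rows, cols_total, byrow = TRUE)
  in_choroid <- ri >= icb_m & ri < ocb_m
  in_sclera <- ri >= ocb_m
  in_rpe <- ri >= icb_m - 3L & ri < icb_m

  # place elliptical vessels until the luminal fraction reaches the target;
  # union counting keeps the achieved fraction exact by construction
  lumen <- matrix(FALSE, rows, cols_total)
  n_chor <- sum(in_choroid)
  target <- spec$vessel_density
  rmin <- spec$vessel_radius_range[1]; rmax <- spec$vessel_radius_range[2]
  vessels <- list()
  attempts <- 0L
  frac <- 0
  while (frac < target - 0.005 && attempts < spec$max_attempts) {
    attempts <- attempts + 1L
    # shrink proposals as the gap closes so the target is approachable
    gap <- target - frac
    rhi <- if (gap < 0.05) max(rmin, rmax / 2) else rmax
    a <- runif(1, rmin, rhi)              # lateral semi-axis
    b <- runif(1, rmin, rhi)              # axial semi-axis
    cc <- runif(1, 1, cols_total)
    cr <- icb[ceiling(cc)] + runif(1, 0, max(thick[ceiling(cc)], 1))
    c0 <- max(1L, floor(cc - a)); c1 <- min(cols_total, ceiling(cc + a))
    r0 <- max(1L, floor(cr - b)); r1 <- min(rows, ceiling(cr + b))
    if (c1 < c0 || r1 < r0) next
    sub_r <- r0:r1; sub_c <- c0:c1
    ell <- outer((sub_r - 1 - cr) / b, (sub_c - 1 - cc) / a,
                 function(y, x) x^2 + y^2 <= 1)
    added <- ell & in_choroid[sub_r, sub_c] & !lumen[sub_r, sub_c]
    n_new <- sum(added)
    if (n_new == 0L) next
    new_frac <- frac + n_new / n_chor
    if (new_frac > target + 0.01) next
    lumen[sub_r, sub_c] <- lumen[sub_r, sub_c] | added
    frac <- new_frac
    vessels[[length(vessels) + 1L]] <-
      c(row = cr, col = cc, semi_axial = b, semi_lateral = a)
  }
  if (frac < target - 0.01) {
    abort(sprintf("could not reach luminal fraction %.2f (achieved %.3f); radius range too coarse for the band",
                  target, frac))
  }

  intensity <- matrix(20, rows, cols_total)      # vitreous/retina background
  intensity[in_rpe] <- 230
  intensity[in_choroid] <- spec$stroma_intensity
  intensity[lumen] <- spec$lumen_intensity
  intensity[in_sclera] <- spec$sclera_intensity

  labels <- matrix(0L, rows, cols_total)
  labels[lumen] <- 1L
  labels[in_sclera] <- 2L

  list(intensity = intensity, labels = labels, icb = icb, ocb = ocb,
       lumen_fraction = frac,
       vessels = if (length(vessels)) as_tibble(do.call(rbind, vessels)) else
         tibble(row = numeric(), col = numeric(),
                semi_axial = numeric(), semi_lateral = numeric()))
}

apply_speckle <- function(intensity, level) {
  if (level <= 0) return(matrix(as.integer(round(intensity)), nrow(intensity)))
  shape <- 1 / level^2
  g <- matrix(rgamma(length(intensity), shape = shape, rate = shape),
              nrow(intensity))
  matrix(as.integer(pmin(pmax(round(intensity * g), 0), 255)), nrow(intensity))
}

crop_structure <- function(st, from, width) {
  cols <- (from + 1L):(from + width)
  list(intensity = st$intensity[, cols, drop = FALSE],
       labels = st$labels[, cols, drop = FALSE],
       icb = st$icb[cols], ocb = st$ocb[cols],
       lumen_fraction = st$lumen_fraction, vessels = st$vessels)
}

finish_phantom <- function(st, spec, subject = NA_character_,
                           visit = NA_integer_, repetition = NA_integer_,
                           orientation = NA_character_) {
  px <- apply_speckle(st$intensity, spec$speckle_level)
  scan <- bscan(px, axial_scale_um = spec$axial_scale_um,
                lateral_scale_um = spec$lateral_scale_um,
                subject = subject, visit = visit, repetition = repetition,
                orientation = orientation)
  bnd <- choroid_boundaries(st$icb, st$ocb)
  chor <- sweep_choroid_mask(st$icb, st$ocb, nrow(st$labels))
  truth <- structure(
    list(labels = st$labels, boundaries = bnd,
         lumen_fraction = sum(st$labels == 1L & chor) / sum(chor),
         vessels = st$vessels),
    class = "phantom_truth")
  list(scan = scan, boundaries = bnd, truth = truth)
}

# choroid-band mask from the boundaries (TRUE between ICB and OCB)
sweep_choroid_mask <- function(icb, ocb, rows) {
  ri <- matrix(0:(rows - 1L), rows, length(icb))
  ri >= matrix(icb, rows, length(icb), byrow = TRUE) &
    ri < matrix(ocb, rows, length(icb), byrow = TRUE)
}

#' Generate one synthetic B-scan with known truth
#'
#' @param spec A [phantom_spec()].
#' @param subject,visit,repetition,orientation Identity stamped on the scan.
#' @return List with `scan` (a [bscan()]), `boundaries`
#'   ([choroid_boundaries()]) and `truth` (label map, boundaries, achieved
#'   luminal fraction and the placed vessel ellipses).
#' @export
generate_phantom <- function(spec, subject = NA_character_,
                             visit = NA_integer_, repetition = NA_integer_,
                             orientation = NA_character_) {
  withr::with_seed(spec$seed, {
    st <- phantom_structure(spec)
    finish_phantom(st, spec, subject, visit, repetition, orientation)
  })
}

#' Generate a pair of repeat scans of the same eye
#'
#' Both scans share the same anatomy (boundaries and vessels); the second is
#' shifted laterally by `jitter` pixels and both carry independent speckle,
#' emulating two follow-up acquisitions registered to almost the same retinal
#' location.
#'
#' @param spec A [phantom_spec()].
#' @param jitter Lateral shift in pixels between the two scans (>= 0,
#'   < `spec$cols`).
#' @inheritParams generate_phantom
#' @return List of two phantom results (`scan`, `boundaries`, `truth` each).
#' @export
generate_repeat_pair <- function(spec, jitter = 2, subject = NA_character_,
                                 visit = NA_integer_,
                                 orientation = NA_character_) {
  jitter <- as.integer(jitter)
  if (jitter < 0) abort("`jitter` must be non-negative.")
  if (jitter >= spec$cols) abort("`jitter` must be smaller than the scan width.")
  withr::with_seed(spec$seed, {
    st <- phantom_structure(spec, cols_total = spec$cols + jitter)
    s1 <- finish_phantom(crop_structure(st, 0L, spec$cols), spec,
                         subject, visit, 1L, orientation)
    s2 <- finish_phantom(crop_structure(st, jitter, spec$cols), spec,
                         subject, visit, 2L, orientation)
    list(s1, s2)
  })
}

#' Generate a multi-subject phantom corpus
#'
#' Emulates a longitudinal study design: per subject and visit, one repeat
#' pair is generated in each of two orientations. Per-subject anatomy
#' (thickness, vessel density, curvature) is drawn once by `spec_sampler`
#' and persists across visits; only speckle and jitter vary.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param visits Visits per subject.
#' @param spec_sampler Function `(subject_index, seed)` returning a
#'   [phantom_spec()]; the default samples vessel density around 0.60 and
#'   thickness around 45 rows.
#' @param seed Corpus-level seed.
#' @param jitter Lateral shift between repeat scans, in pixels.
#' @return List with `scans` (list of phantom results) and `manifest`
#'   (tibble: subject, visit, repetition, orientation, scan index).
#' @export
generate_corpus <- function(n_subjects, visits = 4,
                            spec_sampler = default_spec_sampler,
                            seed = 1L, jitter = 2) {
  if (n_subjects < 3) abort("`n_subjects` must be at least 3.")
  scans <- list()
  rows <- list()
  withr::with_seed(seed, {
    subject_seeds <- sample.int(2^30, n_subjects)
    visit_seeds <- matrix(sample.int(2^30, n_subjects * visits * 2),
                          n_subjects)
  })
  for (s in seq_len(n_subjects)) {
    subj <- sprintf("S%03d", s)
    base_spec <- spec_sampler(s, subject_seeds[s])
    for (v in seq_len(visits)) {
      for (o in c("horizontal", "vertical")) {
        oi <- if (o == "horizontal") 0L else 1L
        sp <- base_spec
        sp$seed <- visit_seeds[s, (v - 1L) * 2L + oi + 1L]
        pair <- generate_repeat_pair(sp, jitter = jitter, subject = subj,
                                     visit = v, orientation = o)
        for (r in 1:2) {
          scans[[length(scans) + 1L]] <- pair[[r]]
          rows[[length(rows) + 1L]] <-
            tibble(subject = subj, visit = v, repetition = r,
                   orientation = o, scan = length(scans))
        }
      }
    }
  }
  list(scans = scans, manifest = dplyr::bind_rows(rows))
}

#' @rdname generate_corpus
#' @param subject_index Subject counter (unused by the default beyond
#'   documentation; anatomy comes from `seed`).
#' @export
default_spec_sampler <- function(subject_index, seed) {
  withr::with_seed(seed, {
    phantom_spec(
      icb_base = round(runif(1, 50, 70)),
      icb_amplitude = round(runif(1, 15, 30)),
      choroid_thickness = round(runif(1, 38, 52)),
      vessel_density = min(max(rnorm(1, 0.60, 0.02), 0.5), 0.7),
      seed = seed)
  })
}

#' Flattened ground-truth labels of a phantom
#'
#' Applies the same per-A-scan shift and crop as [flatten_bscan()] to the
#' phantom's truth label map and paints the sclera below the flattened OCB,
#' yielding the label map an ideal binarization of the flattened scan would
#' produce. Within the crop the CVI of these labels equals the phantom's
#' achieved luminal fraction up to boundary rasterization.
#'
#' @param ph A [generate_phantom()] result.
#' @param crop_height Rows to retain (see [compute_crop_height()]).
#' @return Integer label map `crop_height x cols`.
#' @export
phantom_flat_truth <- function(ph, crop_height) {
  fl <- flatten_bscan(ph$truth$labels, ph$boundaries, crop_height)
  mask_sclera(fl$pixels, fl$ocb_flat)
}
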