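# All generator randomness flows through one explicit seed; the global RNG
# state is saved and restored so generation never perturbs a user's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rtnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Configuration of one synthetic aneurysm case
#'
#' Describes a desk-scale stand-in for a patient case: a spherical-dome
#' aneurysm sac on a short collar of parent vessel, a pulsatile tangential
#' WSS field with a planted low-shear, direction-reversing thin-wall patch,
#' and a rendered dome image whose co-located patch is shifted along the
#' +a* (redness) axis of CIELAB.
#'
#' Defaults describe a typical mid-size aneurysm: dome radius 2.5 mm (about
#' the 5 mm mean sac diameter seen clinically), peak-normal wall shear of
#' order 1.6 Pa, an 80 % shear deficit inside the thin-wall patch
#' (`wss_deficit = 0.2`, the ratio of typical thin-wall to normal-wall WSS),
#' direction reversal over 15 % of the cycle inside the patch, and 32 time
#' samples per cycle.
#'
#' @param seed integer seed; the whole case is deterministic given it.
#' @param n_theta,n_phi mesh resolution (latitude bands from the dome pole,
#'   azimuthal divisions).
#' @param dome_radius sac radius (mm).
#' @param theta_max angular extent of the meshed surface from the pole
#'   (rad); beyond pi/2 lies below the neck plane and outside the sac.
#' @param twa_theta,twa_phi direction of the planted thin-wall patch center
#'   (polar/azimuthal angles, rad).
#' @param twa_angular_radius angular radius of the patch (rad).
#' @param wss_base normal-wall WSS scale (Pa).
#' @param wss_deficit multiplicative WSS factor inside the patch, in (0, 1).
#' @param reversal_fraction fraction of the cycle with reversed WSS
#'   direction inside the patch, in \[0, 0.5\].
#' @param background_reversal the same outside the patch (default 0).
#' @param wss_spatial_sd SD of the per-face lognormal spatial modulation of
#'   WSS magnitude.
#' @param n_times samples per cycle (>= 8).
#' @param period cardiac cycle duration (s).
#' @param waveform optional length-`n_times` positive flow-rate-like
#'   modulation; default is a two-term raised-cosine with its minimum
#'   (diastole) at the first sample.
#' @param pressure_base,pressure_sd wall pressure mean (Pa) and per-face SD.
#' @param image_width,image_height rendered image size (px).
#' @param base_lab Lab color of normally perfused wall.
#' @param patch_a_shift,patch_L_shift Lab shift inside the patch (redder,
#'   slightly darker, as a thin translucent wall appears).
#' @param image_noise_sd per-channel Lab noise SD.
#' @param annotation_radius_px radius of the generated circular annotations.
#' @return An object of class `synth_case_config`.
#' @export
synth_case_config <- function(seed = 1L,
                              n_theta = 24L, n_phi = 48L,
                              dome_radius = 2.5, theta_max = 2.2,
                              twa_theta = 0.6, twa_phi = 0.8,
                              twa_angular_radius = 0.5,
                              wss_base = 1.6, wss_deficit = 0.2,
                              reversal_fraction = 0.15,
                              background_reversal = 0,
                              wss_spatial_sd = 0.25,
                              n_times = 32L, period = 1.0,
                              waveform = NULL,
                              pressure_base = 15750, pressure_sd = 5,
                              image_width = 320L, image_height = 240L,
                              base_lab = c(52, 28, 22),
                              patch_a_shift = 15, patch_L_shift = -5,
                              image_noise_sd = 2,
                              annotation_radius_px = 10) {
  cfg <- as.list(environment())
  if (!(cfg$wss_deficit > 0 && cfg$wss_deficit < 1))
    stop("`wss_deficit` must lie in (0, 1)")
  if (cfg$reversal_fraction < 0 || cfg$reversal_fraction > 0.5)
    stop("`reversal_fraction` must lie in [0, 0.5]")
  if (cfg$background_reversal < 0 || cfg$background_reversal > 0.5)
    stop("`background_reversal` must lie in [0, 0.5]")
  if (cfg$n_times < 8L) stop("`n_times` must be >= 8")
  if (cfg$dome_radius <= 0 || cfg$theta_max <= 0 || cfg$theta_max > pi)
    stop("invalid dome geometry")
  if (cfg$twa_theta < 0 || cfg$twa_theta > cfg$theta_max)
    stop("patch center must lie on the meshed dome")
  if (!is.null(cfg$waveform)) {
    if (length(cfg$waveform) != cfg$n_times || any(cfg$waveform <= 0))
      stop("`waveform` must be ", cfg$n_times, " positive values")
  }
  structure(cfg, class = "synth_case_config")
}

#' Default pulsatile waveform
#'
#' A two-term raised-cosine flow-rate-like modulation with a systolic peak
#' at mid-cycle and its diastolic minimum at the first sample:
#' `0.6 + 0.9 * ((1 - cos(2*pi*s)) / 2)^2` for cycle fraction `s`.
#'
#' @param n_times samples per cycle.
#' @return Positive numeric vector of length `n_times`.
#' @export
default_waveform <- function(n_times) {
  s <- (seq_len(n_times) - 1) / n_times
  0.6 + 0.9 * ((1 - cos(2 * pi * s)) / 2)^2
}

# UV-sphere dome: pole at +z, rings down to theta_max; returns surface_mesh
dome_mesh <- function(radius, n_theta, n_phi, theta_max) {
  n_theta <- as.integer(n_theta); n_phi <- as.integer(n_phi)
  th <- seq_len(n_theta) * theta_max / n_theta
  ph <- (seq_len(n_phi) - 1) * 2 * pi / n_phi
  ring <- function(t) cbind(radius * sin(t) * cos(ph),
                            radius * sin(t) * sin(ph),
                            radius * cos(t))
  verts <- rbind(c(0, 0, radius), do.call(rbind, lapply(th, ring)))
  vid <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  fan <- t(vapply(seq_len(n_phi),
                  function(j) c(1L, vid(1L, j), vid(1L, j + 1L)),
                  integer(3L)))
  bands <- lapply(seq_len(n_theta - 1L), function(i) {
    do.call(rbind, lapply(seq_len(n_phi), function(j) {
      rbind(c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
            c(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
    }))
  })
  surface_mesh(verts, rbind(fan, do.call(rbind, bands)))
}

unit_dir <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# orthographic dome-to-image mapping used by the renderer
dome_projection <- function(config) {
  w <- config$image_width; h <- config$image_height
  list(cx = (w - 1) / 2, cy = (h - 1) / 2,
       r_px = 0.42 * min(w, h), dome_radius = config$dome_radius,
       width = w, height = h)
}

#' Map a surface point to image pixel coordinates (synthetic projection)
#'
#' @param point 3D point (mm) on the dome (or an `n x 3` matrix).
#' @param projection the `projection` element of a synthetic case's ground
#'   truth.
#' @return Matrix with columns `x`, `y` (0-based pixel coordinates).
#' @export
mesh_point_to_pixel <- function(point, projection) {
  p <- if (is.null(dim(point))) matrix(point, 1L, 3L) else as.matrix(point)
  s <- projection$r_px / projection$dome_radius
  cbind(x = projection$cx + p[, 1L] * s,
        y = projection$cy - p[, 2L] * s)
}

#' Map an image pixel back to the dome surface (synthetic projection)
#'
#' @param x,y 0-based pixel coordinates.
#' @param projection as in [mesh_point_to_pixel()].
#' @return 3D point (mm) on the upper dome, or `NULL` if the pixel lies
#'   outside the dome disk.
#' @export
pixel_to_mesh_point <- function(x, y, projection) {
  xn <- (x - projection$cx) / projection$r_px
  yn <- (projection$cy - y) / projection$r_px
  r2 <- xn^2 + yn^2
  if (r2 > 1) return(NULL)
  projection$dome_radius * c(xn, yn, sqrt(1 - r2))
}

render_dome_image <- function(config, twa_dir) {
  proj <- dome_projection(config)
  h <- config$image_height; w <- config$image_width
  xg <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  yg <- matrix(seq_len(h) - 1, h, w)
  xn <- (xg - proj$cx) / proj$r_px
  yn <- (proj$cy - yg) / proj$r_px
  r2 <- xn^2 + yn^2
  inside <- r2 <= 1
  zn <- sqrt(pmax(1 - r2, 0))

  light <- c(0.25, 0.25, 0.94); light <- light / sqrt(sum(light^2))
  shade <- pmax(0, xn * light[1L] + yn * light[2L] + zn * light[3L])

  lab_l <- matrix(20, h, w); lab_a <- matrix(5, h, w); lab_b <- matrix(5, h, w)
  lab_l[inside] <- config$base_lab[1L] - 5 * (1 - shade[inside])
  lab_a[inside] <- config$base_lab[2L]
  lab_b[inside] <- config$base_lab[3L]

  cosang <- xn * twa_dir[1L] + yn * twa_dir[2L] + zn * twa_dir[3L]
  patch <- inside & (cosang >= cos(config$twa_angular_radius))
  lab_a[patch] <- lab_a[patch] + config$patch_a_shift
  lab_l[patch] <- lab_l[patch] + config$patch_L_shift

  n_in <- sum(inside)
  lab_l[inside] <- lab_l[inside] + stats::rnorm(n_in, 0, config$image_noise_sd)
  lab_a[inside] <- lab_a[inside] + stats::rnorm(n_in, 0, config$image_noise_sd)
  lab_b[inside] <- lab_b[inside] + stats::rnorm(n_in, 0, config$image_noise_sd)
  lab_l <- pmin(pmax(lab_l, 0), 100)

  rgb <- farver::convert_colour(cbind(as.numeric(lab_l), as.numeric(lab_a),
                                      as.numeric(lab_b)),
                                from = "lab", to = "rgb")
  rgb <- round(pmin(pmax(rgb, 0), 255))
  img <- array(0L, c(h, w, 3L))
  img[, , 1L] <- as.integer(rgb[, 1L])
  img[, , 2L] <- as.integer(rgb[, 2L])
  img[, , 3L] <- as.integer(rgb[, 3L])
  list(image = img, pixel_mask = patch, projection = proj)
}

#' Generate one synthetic aneurysm case
#'
#' Builds the dome mesh, the pulsatile WSS field series (tangential vectors
#' whose magnitude follows the cycle waveform, attenuated by `wss_deficit`
#' and direction-reversed for `reversal_fraction` of the cycle inside the
#' planted patch), near-uniform wall pressure, the rendered intraoperative
#' style image, and the ground truth (face/pixel patch masks, circular
#' annotations, mesh/image correspondence). Deterministic given
#' `config$seed`.
#'
#' @param config a [synth_case_config()].
#' @param with_image render the dome image (set `FALSE` to generate surface
#'   data only, e.g. for large hemodynamics-only simulations).
#' @return An object of class `twa_case`: list with `series`
#'   ([wall_field_series()]), `sac` ([sac_mask()]), `image` (H x W x 3
#'   integer sRGB array or `NULL`), `ground_truth` (list: `twa_face_mask`,
#'   `twa_pixel_mask`, `annotations`, `more_face`, `less_face`,
#'   `projection`), and `config`.
#' @export
make_case <- function(config = synth_case_config(), with_image = TRUE) {
  if (!inherits(config, "synth_case_config"))
    stop("`config` must come from synth_case_config()")
  with_seed(config$seed, {
    mesh <- dome_mesh(config$dome_radius, config$n_theta, config$n_phi,
                      config$theta_max)
    m <- n_faces(mesh)
    sac <- sac_mask(mesh$face_centroids[, 3L] > 0, mesh)

    cen_dir <- mesh$face_centroids /
      sqrt(rowSums(mesh$face_centroids^2))
    twa_dir <- unit_dir(config$twa_theta, config$twa_phi)
    face_patch <- as.numeric(cen_dir %*% twa_dir) >=
      cos(config$twa_angular_radius)
    face_patch <- face_patch & unclass(sac)
    if (!any(face_patch))
      stop("planted patch covers no sac faces; enlarge twa_angular_radius")

    # tangential base direction: global +x projected onto the wall
    g <- c(1, 0, 0)
    tang <- matrix(g, m, 3L, byrow = TRUE) -
      cen_dir * as.numeric(cen_dir %*% g)
    tn <- sqrt(rowSums(tang^2))
    fallback <- tn < 1e-6
    if (any(fallback)) {       # wall normal parallel to +x: use +y instead
      g2 <- c(0, 1, 0)
      t2 <- matrix(g2, sum(fallback), 3L, byrow = TRUE) -
        cen_dir[fallback, , drop = FALSE] *
          as.numeric(cen_dir[fallback, , drop = FALSE] %*% g2)
      tang[fallback, ] <- t2
      tn[fallback] <- sqrt(rowSums(t2^2))
    }
    tang <- tang / tn

    mag <- config$wss_base * exp(stats::rnorm(m, 0, config$wss_spatial_sd))
    mag[face_patch] <- mag[face_patch] * config$wss_deficit

    nt <- config$n_times
    wave <- if (is.null(config$waveform)) default_waveform(nt) else
      config$waveform
    rev_in <- round(config$reversal_fraction * nt)
    rev_out <- round(config$background_reversal * nt)
    sign_mat <- matrix(1, nt, m)                 # reversal at cycle start
    if (rev_in > 0) sign_mat[seq_len(rev_in), face_patch] <- -1
    if (rev_out > 0) sign_mat[seq_len(rev_out), !face_patch] <- -1

    wss <- array(0, c(nt, m, 3L))
    for (k in 1:3)
      wss[, , k] <- (wave * sign_mat) * matrix(mag * tang[, k], nt, m,
                                               byrow = TRUE)
    pressure <- matrix(config$pressure_base +
                         stats::rnorm(m, 0, config$pressure_sd),
                       nt, m, byrow = TRUE)
    times <- (seq_len(nt) - 1) * config$period / nt
    series <- wall_field_series(mesh, times, wss, pressure = pressure,
                                period = config$period,
                                diastolic_index = which.min(wave))

    img <- NULL; pixel_mask <- NULL
    proj <- dome_projection(config)
    if (with_image) {
      rend <- render_dome_image(config, twa_dir)
      img <- rend$image; pixel_mask <- rend$pixel_mask
      proj <- rend$projection
    }

    less_dir <- unit_dir(config$twa_theta, config$twa_phi + pi)
    ref_dir <- unit_dir(config$twa_theta, config$twa_phi + pi / 2)
    nearest_face <- function(dir) {
      cand <- which(unclass(sac))
      cand[which.max(as.numeric(cen_dir[cand, , drop = FALSE] %*% dir))]
    }
    px_of <- function(dir)
      mesh_point_to_pixel(dir * config$dome_radius, proj)
    ann <- list(
      reference = region_annotation(px_of(ref_dir)[1L], px_of(ref_dir)[2L],
                                    config$annotation_radius_px, "reference"),
      more_dangerous = region_annotation(px_of(twa_dir)[1L],
                                         px_of(twa_dir)[2L],
                                         config$annotation_radius_px,
                                         "more_dangerous"),
      less_dangerous = region_annotation(px_of(less_dir)[1L],
                                         px_of(less_dir)[2L],
                                         config$annotation_radius_px,
                                         "less_dangerous"),
      roi = region_annotation(proj$cx, proj$cy, 0.88 * proj$r_px, "roi"))

    structure(
      list(series = series, sac = sac, image = img,
           ground_truth = list(
             twa_face_mask = face_patch,
             twa_pixel_mask = pixel_mask,
             annotations = ann,
             more_face = nearest_face(twa_dir),
             less_face = nearest_face(less_dir),
             projection = proj),
           config = config),
      class = "twa_case")
  })
}

#' @export
print.twa_case <- function(x, ...) {
  cat("synthetic aneurysm case (seed ", x$config$seed, "): ",
      n_faces(x$series$mesh), " faces, ", length(x$series$times),
      " time samples, ", sum(x$ground_truth$twa_face_mask),
      " planted patch faces",
      if (!is.null(x$image)) paste0(", image ", ncol(x$image), "x",
                                    nrow(x$image)) else "", "\n", sep = "")
  invisible(x)
}

#' Per-case jitter of the cohort generator
#'
#' Each entry is `c(mean, sd, lower, upper)` for a truncated-normal draw
#' (or a range for the uniformly drawn patch direction). The defaults plant
#' the clinically reported contrast: a strong WSS deficit at the thin-wall
#' patch, a mild and noisy OSI excess, and no pressure effect.
#'
#' @param wss_base_meanlog,wss_base_sdlog lognormal parameters of the
#'   normal-wall WSS scale (Pa).
#' @param dome_radius,wss_deficit,reversal,background_reversal,
#'   pressure_base,patch_a_shift truncated-normal jitter specs.
#' @param twa_theta_range,twa_phi_range uniform ranges for the patch
#'   direction (rad).
#' @return A list of class `cohort_effects`.
#' @export
cohort_effects <- function(wss_base_meanlog = log(1.6),
                           wss_base_sdlog = 0.5,
                           dome_radius = c(2.5, 0.5, 1.5, 4),
                           wss_deficit = c(0.2, 0.08, 0.05, 0.6),
                           reversal = c(0.15, 0.07, 0.02, 0.45),
                           background_reversal = c(0.08, 0.05, 0, 0.3),
                           pressure_base = c(15750, 740, 13000, 19000),
                           patch_a_shift = c(15, 3, 8, 25),
                           twa_theta_range = c(0.35, 0.85),
                           twa_phi_range = c(0, 2 * pi)) {
  structure(as.list(environment()), class = "cohort_effects")
}

#' Generate a synthetic cohort of aneurysm cases
#'
#' Draws per-case geometry and effect sizes from seeded jitter
#' distributions ([cohort_effects()]), generates each case with
#' [make_case()], and samples every hemodynamic parameter (pressure, WSS,
#' OSI, normalized WSS, normalized OSI) at the ground-truth more/less
#' dangerous sites, yielding the paired per-case table that the group
#' comparisons and the weighting-factor sweep consume.
#'
#' @param n_cases number of aneurysm cases (>= 2); 21 matches a typical
#'   single-center surgical series.
#' @param base_config a [synth_case_config()] supplying everything the
#'   jitter does not override.
#' @param effects a [cohort_effects()].
#' @param seed cohort-level seed; per-case seeds derive from it.
#' @param with_images render the dome images (needed for the image side of
#'   the pipeline; disable for hemodynamics-only simulations).
#' @param mesh_patch_radius radius (mm) of the site patches over which HPs
#'   are averaged.
#' @return An object of class `twa_cohort`: list with `cases`, `samples`
#'   (data.frame: `case_id`, `hp_kind`, `more`, `less`), `effects`, `seed`.
#' @export
make_cohort <- function(n_cases = 21L, base_config = synth_case_config(),
                        effects = cohort_effects(), seed = 1L,
                        with_images = TRUE, mesh_patch_radius = 0.5) {
  if (n_cases < 2L) stop("a cohort needs at least 2 cases")
  if (!inherits(effects, "cohort_effects"))
    stop("`effects` must come from cohort_effects()")
  cfgs <- with_seed(seed, {
    case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
    tn <- function(spec) rtnorm1(1L, spec[1L], spec[2L], spec[3L], spec[4L])
    lapply(seq_len(n_cases), function(i) {
      cfg <- base_config
      cfg$seed <- case_seeds[i]
      cfg$dome_radius <- tn(effects$dome_radius)
      cfg$wss_base <- exp(stats::rnorm(1L, effects$wss_base_meanlog,
                                       effects$wss_base_sdlog))
      cfg$wss_deficit <- tn(effects$wss_deficit)
      cfg$reversal_fraction <- tn(effects$reversal)
      cfg$background_reversal <- tn(effects$background_reversal)
      cfg$pressure_base <- tn(effects$pressure_base)
      cfg$patch_a_shift <- tn(effects$patch_a_shift)
      cfg$twa_theta <- stats::runif(1L, effects$twa_theta_range[1L],
                                    effects$twa_theta_range[2L])
      cfg$twa_phi <- stats::runif(1L, effects$twa_phi_range[1L],
                                  effects$twa_phi_range[2L])
      cfg
    })
  })
  cases <- lapply(cfgs, make_case, with_image = with_images)
  samples <- do.call(rbind, lapply(seq_along(cases), function(i) {
    s <- case_hp_samples(cases[[i]], mesh_patch_radius = mesh_patch_radius)
    s$case_id <- i
    s[, c("case_id", "hp_kind", "more", "less")]
  }))
  structure(list(cases = cases, samples = samples, effects = effects,
                 seed = seed),
            class = "twa_cohort")
}

#' @export
print.twa_cohort <- function(x, ...) {
  cat("synthetic cohort:", length(x$cases), "cases (seed", x$seed, ")\n")
  invisible(x)
}
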