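#' Wall shear stress from the wall shear rate
#'
#' WSS is the tangential viscous traction on the vessel wall: the product of
#' the fluid's dynamic viscosity and the shearing velocity gradient at the
#' wall.
#'
#' @param viscosity dynamic viscosity (Pa.s), > 0. Blood is typically
#'   modelled with 0.004 Pa.s.
#' @param wall_shear_rate wall shear rate (1/s), >= 0; vectorized.
#' @return WSS magnitude (Pa).
#' @examples
#' wss_from_gradient(0.004, 250)  # 1 Pa
#' @export
wss_from_gradient <- function(viscosity, wall_shear_rate) {
  if (!all(is.finite(viscosity)) || any(viscosity <= 0))
    stop("`viscosity` must be positive and finite")
  if (!all(is.finite(wall_shear_rate)) || any(wall_shear_rate < 0))
    stop("`wall_shear_rate` must be non-negative and finite")
  viscosity * wall_shear_rate
}

#' WSS magnitude field at one time sample
#'
#' @param series a [wall_field_series()].
#' @param time_index 1-based time index.
#' @return A [scalar_field()] of kind `wss_magnitude` (per-face Euclidean
#'   norm of the WSS vector at that sample).
#' @export
wss_magnitude_at <- function(series, time_index) {
  if (!inherits(series, "wall_field_series"))
    stop("`series` must be a wall_field_series")
  time_index <- as.integer(time_index)
  if (length(time_index) != 1L || is.na(time_index) ||
      time_index < 1L || time_index > length(series$times))
    stop("`time_index` out of range 1..", length(series$times))
  v <- series$wss[time_index, , , drop = FALSE]
  dim(v) <- dim(series$wss)[2:3]
  scalar_field(sqrt(rowSums(v^2)), "wss_magnitude")
}

# Trapezoidal weights for a periodic sampling of one cycle: sample i carries
# half the duration of its two adjacent segments, the closing segment running
# from the last sample back to the first sample of the next cycle.
periodic_trapezoid_weights <- function(times, period) {
  dt <- diff(times)
  dt_close <- period - diff(range(times))
  0.5 * (c(dt_close, dt) + c(dt, dt_close))
}

#' Oscillatory shear index
#'
#' OSI measures how much the WSS vector changes direction over one cardiac
#' cycle at each wall location:
#' `OSI = 0.5 * (1 - |integral(wss dt)| / integral(|wss| dt))`,
#' both integrals taken around one full cycle. It is 0 for unidirectional
#' shear and 0.5 for complete reversal. Integrals use the trapezoidal rule
#' on the sample grid with periodic closure (the final sample pairs with the
#' first). Faces where the total shear exposure `integral(|wss| dt)` falls
#' below `tol` carry no flow and are assigned OSI 0.
#'
#' @param series a [wall_field_series()].
#' @param tol threshold (Pa.s) below which a face is treated as having no
#'   flow.
#' @return A [scalar_field()] of kind `osi`.
#' @examples
#' # full reversal: +v for half the cycle, -v for the other half -> OSI 0.5
#' @export
compute_osi <- function(series, tol = 1e-12) {
  if (!inherits(series, "wall_field_series"))
    stop("`series` must be a wall_field_series")
  if (any(diff(series$times) <= 0)) stop("`times` must be strictly increasing")
  w <- periodic_trapezoid_weights(series$times, series$period)
  nt <- length(series$times)
  m <- dim(series$wss)[2L]
  # componentwise integral of the vector and integral of its magnitude
  mean_vec <- matrix(0, m, 3L)
  for (k in 1:3) {
    comp <- matrix(series$wss[, , k], nt, m)
    mean_vec[, k] <- colSums(comp * w)
  }
  mags <- sqrt(series$wss[, , 1L]^2 + series$wss[, , 2L]^2 +
               series$wss[, , 3L]^2)
  denom <- colSums(matrix(mags, nt, m) * w)
  num <- sqrt(rowSums(mean_vec^2))
  osi <- ifelse(denom < tol, 0, 0.5 * (1 - num / pmax(denom, tol)))
  scalar_field(pmin(pmax(osi, 0), 0.5), "osi")
}

#' Estimate the diastolic time index
#'
#' The diastolic sample is taken as the low-flow phase of the cycle: the
#' time index minimizing the sac-area-weighted mean WSS magnitude. Ties go
#' to the earliest index.
#'
#' @param series a [wall_field_series()].
#' @param mask a [sac_mask()].
#' @return A 1-based time index.
#' @export
diastolic_index_estimate <- function(series, mask) {
  if (!inherits(mask, "sac_mask")) stop("`mask` must be a sac_mask")
  areas <- series$mesh$face_areas[mask]
  nt <- length(series$times)
  score <- vapply(seq_len(nt), function(t) {
    v <- series$wss[t, mask, , drop = FALSE]
    dim(v) <- c(sum(mask), 3L)
    sum(sqrt(rowSums(v^2)) * areas) / sum(areas)
  }, numeric(1L))
  which.min(score)
}

#' Sac WSS extremes at the diastolic time
#'
#' Minimum and maximum WSS magnitude over the faces in the aneurysm sac
#' above its neck; these anchor the WSS normalization.
#'
#' @param field a [scalar_field()] of kind `wss_magnitude`.
#' @param mask a [sac_mask()].
#' @param tol the range `wss_max - wss_min` must exceed this (Pa), else the
#'   normalization is undefined.
#' @return An object of class `sac_extremes`: list with `wss_min`, `wss_max`.
#' @export
sac_extremes <- function(field, mask, tol = 1e-12) {
  stopifnot_kind(field, "wss_magnitude")
  if (!inherits(mask, "sac_mask")) stop("`mask` must be a sac_mask")
  if (length(field) != length(mask))
    stop("field and mask describe different numbers of faces")
  v <- as.numeric(field)[mask]
  ext <- list(wss_min = min(v), wss_max = max(v))
  if (ext$wss_max - ext$wss_min <= tol)
    stop("degenerate sac WSS range (max - min <= ", tol,
         " Pa): normalization undefined")
  structure(ext, class = "sac_extremes")
}

#' @export
print.sac_extremes <- function(x, ...) {
  cat(sprintf("sac WSS extremes: min %.4g Pa, max %.4g Pa\n",
              x$wss_min, x$wss_max))
  invisible(x)
}

#' Normalized WSS via the fourth-order ellipse scheme
#'
#' Maps WSS magnitude onto \[0, 1\] with extra weight on the dangerous
#' low-shear end. Writing `u = (WSS - WSSmax) / (WSSmax - WSSmin)` (clamped
#' to \[-1, 0\]), the normalized value is the root in \[0, 1\] of the
#' quartic ellipse relation `(WSSnorm - 1)^4 + u^4 = 1`, i.e.
#' `WSSnorm = 1 - (1 - u^4)^(1/4)`. WSSnorm is 1 at the sac minimum, 0 at
#' the sac maximum, and decreases with WSS. Values outside the sac range
#' are clamped so that the field stays in \[0, 1\].
#'
#' @param field a [scalar_field()] of kind `wss_magnitude`.
#' @param extremes a [sac_extremes()].
#' @return A [scalar_field()] of kind `wss_norm`.
#' @export
wss_norm <- function(field, extremes) {
  stopifnot_kind(field, "wss_magnitude")
  if (!inherits(extremes, "sac_extremes"))
    stop("`extremes` must come from sac_extremes()")
  rng <- extremes$wss_max - extremes$wss_min
  u <- (as.numeric(field) - extremes$wss_max) / rng
  u <- pmin(pmax(u, -1), 0)
  scalar_field(1 - (1 - u^4)^(1 / 4), "wss_norm")
}

#' Normalized OSI
#'
#' OSI already lives in \[0, 0.5\] with 0.5 the dangerous end, so the
#' normalized form is simply its double, spanning \[0, 1\].
#'
#' @param field a [scalar_field()] of kind `osi`.
#' @param tol tolerance for the input range check.
#' @return A [scalar_field()] of kind `osi_norm`.
#' @export
osi_norm <- function(field, tol = 1e-9) {
  stopifnot_kind(field, "osi")
  v <- as.numeric(field)
  if (any(v < -tol) || any(v > 0.5 + tol))
    stop("OSI values outside [0, 0.5]")
  scalar_field(pmin(pmax(2 * v, 0), 1), "osi_norm")
}

#' Weighting factors for the combined hemodynamic parameter
#'
#' @param w1 weight of the normalized WSS, in \[0, 1\].
#' @param w2 weight of the normalized OSI; defaults to `1 - w1`. The two
#'   must be non-negative and sum to 1.
#' @return An object of class `chp_weighting`.
#' @export
weighting <- function(w1, w2 = 1 - w1) {
  if (!is.finite(w1) || !is.finite(w2) || w1 < 0 || w2 < 0)
    stop("weights must be finite and non-negative")
  if (abs(w1 + w2 - 1) > 1e-9) stop("weights must sum to 1")
  structure(list(w1 = w1, w2 = w2), class = "chp_weighting")
}

#' Combined hemodynamic parameter
#'
#' The CHP is the weighted average `w1 * WSSnorm + w2 * OSInorm` of the two
#' normalized hemodynamic parameters; with `w1 + w2 = 1` it again spans
#' \[0, 1\]. High CHP flags candidate thin-walled areas.
#'
#' @param wssn a [scalar_field()] of kind `wss_norm`.
#' @param osin a [scalar_field()] of kind `osi_norm` on the same mesh.
#' @param w a [weighting()] (or a single `w1` value).
#' @return A [scalar_field()] of kind `chp`.
#' @export
chp <- function(wssn, osin, w) {
  stopifnot_kind(wssn, "wss_norm")
  stopifnot_kind(osin, "osi_norm")
  if (length(wssn) != length(osin))
    stop("wss_norm and osi_norm fields have different face counts")
  if (is.numeric(w)) w <- weighting(w)
  if (!inherits(w, "chp_weighting")) stop("`w` must come from weighting()")
  scalar_field(w$w1 * as.numeric(wssn) + w$w2 * as.numeric(osin), "chp")
}

#' Extreme-mean surface patch of a scalar field
#'
#' Locates the candidate thin-walled area as a surface patch rather than a
#' single element: for every sac face taken as a seed, the field is averaged
#' (area-weighted) over the sac faces whose centroids lie within
#' `patch_radius` of the seed centroid (Euclidean centroid distance as a
#' geodesic proxy), and the patch with the extreme mean is returned. Ties
#' break to the lowest face index.
#'
#' @param field a [scalar_field()].
#' @param mask a [sac_mask()] restricting the search (and the patch).
#' @param mesh the [surface_mesh()] carrying centroids and areas.
#' @param patch_radius patch radius in mm; 0 reduces to the single extreme
#'   face.
#' @param mode `"max"` (default) or `"min"`.
#' @return An object of class `peak_region`: list with `seed_face`,
#'   `patch_faces` (global face indices), `patch_mean`, `patch_radius`.
#' @export
peak_region <- function(field, mask, mesh, patch_radius = 0.5,
                        mode = c("max", "min")) {
  mode <- match.arg(mode)
  if (!inherits(mask, "sac_mask")) stop("`mask` must be a sac_mask")
  if (!inherits(mesh, "surface_mesh")) stop("`mesh` must be a surface_mesh")
  if (length(field) != n_faces(mesh))
    stop("field length does not match the mesh face count")
  if (!is.finite(patch_radius) || patch_radius < 0)
    stop("`patch_radius` must be >= 0")
  sac_idx <- which(unclass(mask))
  cen <- mesh$face_centroids[sac_idx, , drop = FALSE]
  areas <- mesh$face_areas[sac_idx]
  vals <- as.numeric(field)[sac_idx]
  ns <- length(sac_idx)

  if (patch_radius == 0) {
    means <- vals
    members <- as.list(seq_len(ns))
  } else {
    sq <- rowSums(cen^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(cen)
    within <- d2 <= patch_radius^2
    means <- as.numeric((within %*% (vals * areas)) / (within %*% areas))
    members <- NULL  # resolved lazily for the winner only
  }
  best <- if (mode == "max") which(means == max(means)) else
    which(means == min(means))
  seed_local <- best[which.min(sac_idx[best])]
  patch_local <- if (patch_radius == 0) seed_local else
    which(colSums((t(cen) - cen[seed_local, ])^2) <= patch_radius^2)
  structure(
    list(seed_face = sac_idx[seed_local],
         patch_faces = sac_idx[patch_local],
         patch_mean = means[seed_local],
         patch_radius = patch_radius,
         mode = mode),
    class = "peak_region")
}

#' @export
print.peak_region <- function(x, ...) {
  cat(sprintf("peak_region (%s): seed face %d, %d faces within %.3g mm, patch mean %.4g\n",
              x$mode, x$seed_face, length(x$patch_faces), x$patch_radius,
              x$patch_mean))
  invisible(x)
}
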