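#' Pulsatile wall-shear-stress field series on a surface mesh
#'
#' Container for a per-face time series of wall-shear-stress (WSS) vectors
#' sampled over one cardiac cycle, with optional per-face pressure. Sample
#' times are strictly increasing and cover one period; the series is treated
#' as periodic, the last sample pairing with the first when integrating
#' around the cycle.
#'
#' @param mesh a [surface_mesh()].
#' @param times numeric vector of sample times (s), strictly increasing,
#'   length >= 3. The samples cover one cycle; the closing segment from the
#'   last sample back to the first is implied by `period`.
#' @param wss numeric array `T x M x 3` of WSS vectors (Pa), tangent to the
#'   wall, for `T` time samples and `M` faces.
#' @param pressure optional numeric `T x M` matrix of wall pressure (Pa);
#'   gauge pressure (negative values) is allowed.
#' @param period cycle duration t (s). Defaults to
#'   `diff(range(times)) + median(diff(times))`, i.e. a uniform grid whose
#'   next sample would coincide with the first of the next cycle.
#' @param diastolic_index optional 1-based time index of the diastolic
#'   (low-flow) sample; if `NULL` it can be estimated later with
#'   [diastolic_index_estimate()].
#' @return An object of class `wall_field_series`.
#' @seealso [compute_osi()], [wss_magnitude_at()], [diastolic_index_estimate()]
#' @export
wall_field_series <- function(mesh, times, wss, pressure = NULL,
                              period = NULL, diastolic_index = NULL) {
  if (!inherits(mesh, "surface_mesh")) stop("`mesh` must be a surface_mesh")
  times <- as.numeric(times)
  nt <- length(times)
  if (nt < 3L) stop("need at least 3 time samples over the cycle")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("`times` must be finite and strictly increasing")
  wss <- unclass(wss)
  if (length(dim(wss)) != 3L ||
      !all(dim(wss) == c(nt, n_faces(mesh), 3L)))
    stop("`wss` must be a T x M x 3 array with T = ", nt,
         ", M = ", n_faces(mesh))
  if (any(!is.finite(wss))) stop("`wss` must be finite")
  if (is.null(period)) period <- diff(range(times)) + stats::median(diff(times))
  period <- as.numeric(period)
  if (!is.finite(period) || period <= diff(range(times)))
    stop("`period` must exceed the span of `times` (the closing segment ",
         "back to the first sample must have positive duration)")
  if (!is.null(pressure)) {
    pressure <- as.matrix(pressure)
    if (!all(dim(pressure) == c(nt, n_faces(mesh))))
      stop("`pressure` must be a T x M matrix")
    if (any(!is.finite(pressure))) stop("`pressure` must be finite")
  }
  if (!is.null(diastolic_index)) {
    diastolic_index <- as.integer(diastolic_index)
    if (length(diastolic_index) != 1L || is.na(diastolic_index) ||
        diastolic_index < 1L || diastolic_index > nt)
      stop("`diastolic_index` must be a single index in 1..", nt)
  }
  structure(
    list(mesh = mesh, times = times, wss = wss, pressure = pressure,
         period = period, diastolic_index = diastolic_index),
    class = "wall_field_series")
}

#' @export
print.wall_field_series <- function(x, ...) {
  cat("wall_field_series:", length(x$times), "time samples over",
      format(x$period, digits = 4), "s on", n_faces(x$mesh), "faces",
      if (!is.null(x$pressure)) "(with pressure)" else "", "\n")
  invisible(x)
}

scalar_kinds <- c("wss_magnitude", "pressure", "osi", "wss_norm",
                  "osi_norm", "chp")

#' Per-face scalar field
#'
#' A labelled vector with one finite value per face. The label fixes the
#' admissible range: `osi` lies in \[0, 0.5\], the normalized kinds
#' (`wss_norm`, `osi_norm`, `chp`) in \[0, 1\], `wss_magnitude` is
#' non-negative and `pressure` is unrestricted (gauge pressure allowed).
#'
#' @param values numeric vector, one value per face.
#' @param kind one of `r paste0('\x60', scalar_kinds, '\x60', collapse = ", ")`.
#' @param tol tolerance for range checks.
#' @return A numeric vector of class `scalar_field` with attribute `kind`.
#' @export
scalar_field <- function(values, kind = scalar_kinds, tol = 1e-9) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("scalar field values must be finite")
  rng <- switch(kind,
    osi = c(0, 0.5),
    wss_norm = , osi_norm = , chp = c(0, 1),
    wss_magnitude = c(0, Inf),
    pressure = c(-Inf, Inf))
  if (any(values < rng[1L] - tol) || any(values > rng[2L] + tol))
    stop(sprintf("'%s' values outside [%g, %g]", kind, rng[1L], rng[2L]))
  # snap roundoff back into range so downstream checks stay strict
  values <- pmin(pmax(values, rng[1L]), rng[2L])
  structure(values, kind = kind, class = "scalar_field")
}

field_kind <- function(x) attr(x, "kind")

#' @export
print.scalar_field <- function(x, ...) {
  cat("scalar_field <", field_kind(x), "> on ", length(x), " faces: ",
      sep = "")
  print(summary(as.numeric(x)))
  invisible(x)
}

stopifnot_kind <- function(x, kind) {
  if (!inherits(x, "scalar_field") || field_kind(x) != kind)
    stop("expected a scalar_field of kind '", kind, "'")
}
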