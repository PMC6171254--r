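#' Convert an 8-bit sRGB image to CIELAB
#'
#' Standard colorimetric pipeline: sRGB decoding (IEC gamma), CIE XYZ under
#' the D65 illuminant and 2 degree observer, then CIE L*a*b*. L* spans
#' 0..100; a* is the red-green axis (positive = red), b* the yellow-blue
#' axis.
#'
#' @param image integer array `H x W x 3` of sRGB values in 0..255, or an
#'   `n x 3` matrix of colors.
#' @return Numeric array (or matrix) of the same shape holding L*, a*, b*.
#' @export
srgb_to_lab <- function(image) {
  d <- dim(image)
  is_img <- length(d) == 3L && d[3L] == 3L
  if (!is_img && !(length(d) == 2L && d[2L] == 3L))
    stop("`image` must be an H x W x 3 array or an n x 3 matrix")
  v <- as.numeric(image)
  if (anyNA(v) || any(v < 0) || any(v > 255))
    stop("sRGB channel values must lie in 0..255")
  m <- if (is_img) matrix(v, d[1L] * d[2L], 3L) else matrix(v, d[1L], 3L)
  lab <- farver::convert_colour(m, from = "rgb", to = "lab")
  dimnames(lab) <- NULL
  if (is_img) {
    out <- array(0, d)
    out[, , 1L] <- lab[, 1L]; out[, , 2L] <- lab[, 2L]; out[, , 3L] <- lab[, 3L]
    out
  } else lab
}

#' CIEDE2000 color difference
#'
#' Full CIEDE2000 formula with parametric factors kL = kC = kH = 1, between
#' CIELAB colors. Symmetric and zero for identical inputs.
#'
#' @param lab_a,lab_b L*a*b* triples (length-3 vectors) or `n x 3` matrices
#'   compared row by row (one may be a single triple, which is recycled).
#' @return Numeric vector of color differences (>= 0).
#' @export
ciede2000 <- function(lab_a, lab_b) {
  a <- lab_triples(lab_a); b <- lab_triples(lab_b)
  if (nrow(a) != nrow(b)) {
    if (nrow(a) == 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
    else if (nrow(b) == 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
    else stop("`lab_a` and `lab_b` must have the same number of rows")
  }
  d <- farver::compare_colour(a, b, from_space = "lab", method = "cie2000")
  # compare_colour returns the full cross matrix; we want the paired diagonal
  as.numeric(d[cbind(seq_len(nrow(a)), seq_len(nrow(a)))])
}

lab_triples <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("a Lab color is a length-3 vector")
    x <- matrix(as.numeric(x), 1L, 3L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("Lab colors must have 3 columns")
  if (any(!is.finite(x))) stop("Lab values must be finite")
  x
}

#' Circular pixel-region annotation
#'
#' Circles marked on the intraoperative image: the reference region on
#' normal vessel, the clinically judged more/less dangerous regions, or a
#' generic region of interest. Pixel coordinates are 0-based with the
#' origin at the top-left corner and `(x, y) = (column, row)`.
#'
#' @param cx,cy center, 0-based pixel coordinates.
#' @param r radius in pixels, > 0.
#' @param role one of `reference`, `more_dangerous`, `less_dangerous`, `roi`.
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(cx, cy, r,
                              role = c("reference", "more_dangerous",
                                       "less_dangerous", "roi")) {
  role <- match.arg(role)
  if (!all(is.finite(c(cx, cy, r))) || r <= 0)
    stop("annotation needs finite center and radius > 0")
  structure(list(role = role, cx = cx, cy = cy, r = r),
            class = "region_annotation")
}

# logical H x W mask of pixels inside the circle
circle_mask <- function(h, w, ann) {
  x <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  y <- matrix(seq_len(h) - 1, h, w)
  (x - ann$cx)^2 + (y - ann$cy)^2 <= ann$r^2
}

#' Reference color of the normal-vessel patch
#'
#' Unweighted mean L*, a*, b* over the pixels inside the annotated
#' reference circle. The redness projection of the modified color metric is
#' built from this patch's `L2` and `a2`.
#'
#' @param lab CIELAB image (`H x W x 3`), from [srgb_to_lab()].
#' @param annotation a [region_annotation()] with role `reference`.
#' @return An object of class `reference_color`: list with `L2`, `a2`,
#'   `b2`, `n_pixels`.
#' @export
reference_color <- function(lab, annotation) {
  if (!inherits(annotation, "region_annotation") ||
      annotation$role != "reference")
    stop("`annotation` must be a region_annotation with role 'reference'")
  d <- dim(lab)
  if (length(d) != 3L || d[3L] != 3L) stop("`lab` must be H x W x 3")
  m <- circle_mask(d[1L], d[2L], annotation)
  if (!any(m)) stop("reference circle contains no image pixels")
  structure(list(L2 = mean(lab[, , 1L][m]),
                 a2 = mean(lab[, , 2L][m]),
                 b2 = mean(lab[, , 3L][m]),
                 n_pixels = sum(m)),
            class = "reference_color")
}

#' @export
print.reference_color <- function(x, ...) {
  cat(sprintf("reference color: L2 = %.2f, a2 = %.2f, b2 = %.2f (%d px)\n",
              x$L2, x$a2, x$b2, x$n_pixels))
  invisible(x)
}

#' Per-pixel CIEDE2000 map against the reference color
#'
#' @param lab CIELAB image (`H x W x 3`).
#' @param ref a [reference_color()].
#' @return An `H x W` matrix of class `delta_e_map` with attribute
#'   `modified = FALSE`.
#' @export
delta_e_map <- function(lab, ref) {
  if (!inherits(ref, "reference_color"))
    stop("`ref` must come from reference_color()")
  d <- dim(lab)
  if (length(d) != 3L || d[3L] != 3L) stop("`lab` must be H x W x 3")
  px <- matrix(as.numeric(lab), d[1L] * d[2L], 3L)
  de <- farver::compare_colour(px, matrix(c(ref$L2, ref$a2, ref$b2), 1L, 3L),
                               from_space = "lab", method = "cie2000")
  structure(matrix(as.numeric(de), d[1L], d[2L]),
            modified = FALSE, class = "delta_e_map")
}

#' Redness-projected modified color difference
#'
#' Rescales a raw CIEDE2000 map by the reference patch's redness fraction
#' so that color differences are credited only insofar as the reference
#' region itself is red rather than bright:
#' `dE_m = dE * a2^2 / (L2^2 + a2^2)` (the default, as printed), or the
#' geometric projection variant `dE_m = dE * a2 / sqrt(L2^2 + a2^2)`.
#' Either factor lies in \[0, 1\], so the modified map never exceeds the raw
#' map and preserves the within-image ranking of pixels.
#'
#' @param map a raw [delta_e_map()].
#' @param ref a [reference_color()].
#' @param variant `"squared"` (default) or `"projection"`.
#' @return An `H x W` matrix of class `delta_e_map` with attributes
#'   `modified = TRUE` and `factor`.
#' @export
modify_delta_e <- function(map, ref, variant = c("squared", "projection")) {
  variant <- match.arg(variant)
  if (!inherits(map, "delta_e_map") || isTRUE(attr(map, "modified")))
    stop("`map` must be a raw delta_e_map")
  if (!inherits(ref, "reference_color"))
    stop("`ref` must come from reference_color()")
  den2 <- ref$L2^2 + ref$a2^2
  if (den2 == 0)
    stop("reference has L2 = a2 = 0: redness factor undefined")
  f <- if (variant == "squared") ref$a2^2 / den2 else
    ref$a2 / sqrt(den2)
  f <- min(max(f, 0), 1)  # projection variant: negative a2 carries no redness
  structure(unclass(map) * f, modified = TRUE, factor = f, variant = variant,
            class = "delta_e_map")
}

# mask-normalized disk-mean filter by shift-and-add; pixels outside `valid`
# contribute nothing and the mean is over valid pixels only
disk_mean_filter <- function(m, radius, valid = NULL) {
  h <- nrow(m); w <- ncol(m)
  if (is.null(valid)) valid <- matrix(TRUE, h, w)
  r <- floor(radius)
  acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
  mv <- m * valid
  for (dy in -r:r) for (dx in -r:r) {
    if (dx * dx + dy * dy > radius^2) next
    sy <- max(1, 1 - dy):min(h, h - dy)   # destination rows
    sx <- max(1, 1 - dx):min(w, w - dx)
    acc[sy, sx] <- acc[sy, sx] + mv[sy + dy, sx + dx]
    cnt[sy, sx] <- cnt[sy, sx] + valid[sy + dy, sx + dx]
  }
  out <- acc / pmax(cnt, 1)
  out[cnt == 0] <- NA_real_
  out
}

#' Locate the reddest region of a modified color-difference map
#'
#' Smooths the map with a disk-mean filter (restricted to the region of
#' interest, since thin-walled areas are judged as areas rather than single
#' pixels) and returns the peak. Ties break to the smallest row, then the
#' smallest column.
#'
#' @param map a [delta_e_map()] (normally the modified one).
#' @param roi a [region_annotation()] delimiting the analysis region, or
#'   `NULL` for the whole image.
#' @param patch_radius disk radius in pixels; 0 gives the raw argmax.
#' @return List of class `reddest_region`: `x`, `y` (0-based pixel
#'   coordinates of the peak), `patch_mean`, `patch_radius`, and the
#'   `filtered` map (NA outside the ROI).
#' @export
reddest_region <- function(map, roi = NULL, patch_radius = 5) {
  if (!inherits(map, "delta_e_map")) stop("`map` must be a delta_e_map")
  if (!is.finite(patch_radius) || patch_radius < 0)
    stop("`patch_radius` must be >= 0")
  h <- nrow(map); w <- ncol(map)
  valid <- if (is.null(roi)) matrix(TRUE, h, w) else {
    if (!inherits(roi, "region_annotation")) stop("`roi` must be an annotation")
    circle_mask(h, w, roi)
  }
  if (!any(valid)) stop("region of interest contains no image pixels")
  filt <- if (patch_radius == 0) {
    f <- unclass(map); f[!valid] <- NA_real_; f
  } else disk_mean_filter(unclass(map), patch_radius, valid)
  filt[!valid] <- NA_real_
  best <- max(filt, na.rm = TRUE)
  hits <- which(filt == best, arr.ind = TRUE)   # row, col (1-based)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  structure(list(x = unname(hits[1L, 2L]) - 1L, y = unname(hits[1L, 1L]) - 1L,
                 patch_mean = best, patch_radius = patch_radius,
                 filtered = filt),
            class = "reddest_region")
}

#' @export
print.reddest_region <- function(x, ...) {
  cat(sprintf("reddest region: peak at (x = %d, y = %d), patch mean %.3f (radius %g px)\n",
              x$x, x$y, x$patch_mean, x$patch_radius))
  invisible(x)
}
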