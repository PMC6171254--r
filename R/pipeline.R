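#' Pipeline configuration
#'
#' Collects the tunable knobs of the end-to-end analysis with their
#' defaults: full weight on normalized WSS (`w1 = 1`, the best-performing
#' setting), significance level 0.05 for both the normality gate and the
#' comparisons, a 0.5 mm surface patch and a 5 px image patch for peak
#' finding, the printed form of the redness factor, and a 1.5 mm tolerance
#' for calling the surface and image peaks the same site.
#'
#' @param w1 weight of the normalized WSS in the CHP.
#' @param alpha significance level.
#' @param mesh_patch_radius surface patch radius (mm).
#' @param image_patch_radius image disk-mean radius (px).
#' @param delta_e_variant redness factor form, `"squared"` (as printed) or
#'   `"projection"`.
#' @param correspondence_mm maximum distance (mm) between the peak-CHP patch
#'   center and the surface site of the reddest pixel for a case to count
#'   as a correspondence.
#' @param diastolic_index fixed 1-based diastolic time index, or `NULL` to
#'   use the series' own / the low-flow estimate.
#' @param w1_grid weights for the sweep.
#' @param paired compare regions as paired samples.
#' @return A list of class `run_config`.
#' @export
run_config <- function(w1 = 1, alpha = 0.05, mesh_patch_radius = 0.5,
                       image_patch_radius = 5,
                       delta_e_variant = c("squared", "projection"),
                       correspondence_mm = 1.5, diastolic_index = NULL,
                       w1_grid = seq(0.5, 1, by = 0.1), paired = FALSE) {
  delta_e_variant <- match.arg(delta_e_variant)
  weighting(w1)  # validates
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  structure(as.list(environment()), class = "run_config")
}

resolve_diastolic_index <- function(series, mask, config) {
  if (!is.null(config$diastolic_index)) config$diastolic_index
  else if (!is.null(series$diastolic_index)) series$diastolic_index
  else diastolic_index_estimate(series, mask)
}

#' Hemodynamic fields of one case
#'
#' Runs the surface half of the pipeline: diastolic WSS magnitude, sac
#' extremes, normalized WSS, OSI, normalized OSI, and the CHP at the
#' configured weighting.
#'
#' @param series a [wall_field_series()].
#' @param mask a [sac_mask()].
#' @param config a [run_config()].
#' @return List of class `hemodynamic_fields`: `diastolic_index`,
#'   `wss_dia`, `extremes`, `wssn`, `osi`, `osin`, `chp` fields.
#' @export
hemodynamic_fields <- function(series, mask, config = run_config()) {
  di <- resolve_diastolic_index(series, mask, config)
  wss_dia <- wss_magnitude_at(series, di)
  ext <- sac_extremes(wss_dia, mask)
  wssn <- wss_norm(wss_dia, ext)
  osi <- compute_osi(series)
  osin <- osi_norm(osi)
  structure(list(diastolic_index = di, wss_dia = wss_dia, extremes = ext,
                 wssn = wssn, osi = osi, osin = osin,
                 chp = chp(wssn, osin, weighting(config$w1))),
            class = "hemodynamic_fields")
}

# area-weighted mean of a per-face field over the sac faces within `radius`
# mm of the centroid of `face`
patch_mean_at <- function(values, mesh, mask, face, radius) {
  cen <- mesh$face_centroids
  d2 <- colSums((t(cen) - cen[face, ])^2)
  sel <- unclass(mask) & d2 <= radius^2
  if (!any(sel)) sel[face] <- TRUE
  sum(values[sel] * mesh$face_areas[sel]) / sum(mesh$face_areas[sel])
}

#' Paired hemodynamic-parameter samples of one case
#'
#' Samples every hemodynamic parameter at the more dangerous (planted /
#' max-redness) and less dangerous ground-truth sites of a synthetic case,
#' averaging each field over the surrounding surface patch.
#'
#' @param case a [make_case()] result.
#' @param config a [run_config()].
#' @param mesh_patch_radius patch radius (mm) around each site.
#' @return data.frame with columns `hp_kind`
#'   (pressure/wss/osi/wss_norm/osi_norm/chp), `more`, `less`.
#' @export
case_hp_samples <- function(case, config = run_config(),
                            mesh_patch_radius = config$mesh_patch_radius) {
  hf <- hemodynamic_fields(case$series, case$sac, config)
  mesh <- case$series$mesh
  p_dia <- if (is.null(case$series$pressure)) NULL else
    case$series$pressure[hf$diastolic_index, ]
  fields <- list(pressure = p_dia,
                 wss = as.numeric(hf$wss_dia),
                 osi = as.numeric(hf$osi),
                 wss_norm = as.numeric(hf$wssn),
                 osi_norm = as.numeric(hf$osin),
                 chp = as.numeric(hf$chp))
  fields <- Filter(Negate(is.null), fields)
  gt <- case$ground_truth
  do.call(rbind, lapply(names(fields), function(k) {
    data.frame(
      hp_kind = k,
      more = patch_mean_at(fields[[k]], mesh, case$sac, gt$more_face,
                           mesh_patch_radius),
      less = patch_mean_at(fields[[k]], mesh, case$sac, gt$less_face,
                           mesh_patch_radius),
      stringsAsFactors = FALSE)
  }))
}

#' Analyze one intraoperative-style image
#'
#' Image half of the pipeline: CIELAB conversion, reference patch color,
#' raw CIEDE2000 map, redness-projected modified map, and its peak inside
#' the region of interest.
#'
#' @param image H x W x 3 integer sRGB array.
#' @param annotations named list of [region_annotation()]s including a
#'   `reference` and (optionally) a `roi` entry.
#' @param config a [run_config()].
#' @return List of class `image_analysis`: `ref`, `raw_map`, `mod_map`,
#'   `peak` ([reddest_region()]), and per-annotation patch means.
#' @export
analyze_image <- function(image, annotations, config = run_config()) {
  ref_ann <- annotations[["reference"]]
  if (is.null(ref_ann)) stop("annotations must include a 'reference' region")
  lab <- srgb_to_lab(image)
  ref <- reference_color(lab, ref_ann)
  raw <- delta_e_map(lab, ref)
  mod <- modify_delta_e(raw, ref, variant = config$delta_e_variant)
  peak <- reddest_region(mod, roi = annotations[["roi"]],
                         patch_radius = config$image_patch_radius)
  means <- vapply(annotations, function(a) {
    m <- circle_mask(nrow(mod), ncol(mod), a)
    if (!any(m)) return(NA_real_)
    mean(unclass(mod)[m])
  }, numeric(1L))
  structure(list(ref = ref, raw_map = raw, mod_map = mod, peak = peak,
                 annotation_means = means),
            class = "image_analysis")
}

#' Run the full pipeline on one case
#'
#' Surface scoring (CHP peak patch), image scoring (modified color metric
#' peak), and the correspondence check: the case counts as a correspondence
#' when the peak-CHP patch center lies within `config$correspondence_mm` of
#' the surface point under the reddest pixel.
#'
#' @param case a [make_case()] result (or an equivalent list with `series`,
#'   `sac`, `image`, `ground_truth$annotations`, `ground_truth$projection`).
#' @param config a [run_config()].
#' @return List of class `twa_case_report`: `fields`, `chp_peak`,
#'   `image` ([analyze_image()] result), `peak_point_mm`, `image_point_mm`,
#'   `distance_mm`, `corresponding`.
#' @export
run_case <- function(case, config = run_config()) {
  if (is.null(case$sac)) stop("case is missing the sac mask")
  hf <- hemodynamic_fields(case$series, case$sac, config)
  pk <- peak_region(hf$chp, case$sac, case$series$mesh,
                    patch_radius = config$mesh_patch_radius, mode = "max")
  if (is.null(case$image))
    stop("case has no image; regenerate with `with_image = TRUE`")
  ia <- analyze_image(case$image, case$ground_truth$annotations, config)
  peak_point <- case$series$mesh$face_centroids[pk$seed_face, ]
  image_point <- pixel_to_mesh_point(ia$peak$x, ia$peak$y,
                                     case$ground_truth$projection)
  if (is.null(image_point)) {
    dist_mm <- Inf
  } else {
    dist_mm <- sqrt(sum((peak_point - image_point)^2))
  }
  structure(list(fields = hf, chp_peak = pk, image = ia,
                 peak_point_mm = peak_point, image_point_mm = image_point,
                 distance_mm = dist_mm,
                 corresponding = is.finite(dist_mm) &&
                   dist_mm <= config$correspondence_mm,
                 config = config),
            class = "twa_case_report")
}

#' @export
print.twa_case_report <- function(x, ...) {
  cat(sprintf(
    "case report: CHP peak face %d (mean %.3f), image peak (%d, %d), distance %.2f mm -> %s\n",
    x$chp_peak$seed_face, x$chp_peak$patch_mean, x$image$peak$x,
    x$image$peak$y, x$distance_mm,
    if (x$corresponding) "correspondence" else "no correspondence"))
  invisible(x)
}

hp_order <- c("pressure", "wss", "osi", "wss_norm", "osi_norm", "chp")

#' Per-parameter comparison table from a paired samples table
#'
#' One [compare_groups()] row per hemodynamic parameter present in the
#' samples; comparisons that cannot run (fewer than 3 cases, or degenerate
#' values) are flagged `underpowered` with `NA` statistics.
#'
#' @param samples data.frame with columns `case_id`, `hp_kind`, `more`,
#'   `less` (as in `make_cohort()$samples` or [read_samples_csv()]).
#' @param alpha gate significance level.
#' @param paired compare as paired samples.
#' @return data.frame with one row per parameter: group means/SDs, the test
#'   used, its statistic and two-sided p-value.
#' @export
hp_comparison_table <- function(samples, alpha = 0.05, paired = FALSE) {
  cmp_row <- function(kind) {
    sk <- samples[samples$hp_kind == kind, ]
    res <- tryCatch(
      compare_groups(sk$more, sk$less, alpha = alpha,
                     paired = paired, hp_kind = kind),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(hp_kind = kind, mean_more = mean(sk$more),
                        sd_more = stats::sd(sk$more),
                        mean_less = mean(sk$less),
                        sd_less = stats::sd(sk$less),
                        test_used = "underpowered", statistic = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    data.frame(hp_kind = kind, mean_more = res$mean_more,
               sd_more = res$sd_more, mean_less = res$mean_less,
               sd_less = res$sd_less, test_used = res$test_used,
               statistic = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  }
  kinds <- intersect(hp_order, unique(samples$hp_kind))
  do.call(rbind, lapply(kinds, cmp_row))
}

#' Run the full pipeline on a cohort
#'
#' Aggregates the per-case analyses into the cohort-level outputs: a
#' per-parameter more/less dangerous comparison table, the
#' weighting-factor sweep of the CHP, and the fraction of cases where the
#' surface CHP peak and the image redness peak designate the same site.
#' Comparisons that cannot run (fewer than 3 cases) are flagged
#' `underpowered` with `NA` statistics rather than erroring.
#'
#' @param cohort a [make_cohort()] result.
#' @param config a [run_config()].
#' @return List of class `twa_cohort_report`: `hp_table` (data.frame, one
#'   row per hemodynamic parameter), `sweep` ([weight_sweep()] rows),
#'   `case_reports`, `correspondence` (count, n, fraction).
#' @export
run_cohort <- function(cohort, config = run_config()) {
  if (!inherits(cohort, "twa_cohort")) stop("`cohort` must be a twa_cohort")
  s <- cohort$samples
  n <- length(cohort$cases)
  hp_table <- hp_comparison_table(s, alpha = config$alpha,
                                  paired = config$paired)

  wide <- function(kind, col) s[s$hp_kind == kind, col]
  sweep <- tryCatch(
    weight_sweep(wide("wss_norm", "more"), wide("osi_norm", "more"),
                 wide("wss_norm", "less"), wide("osi_norm", "less"),
                 w1_grid = config$w1_grid, alpha = config$alpha,
                 paired = config$paired),
    error = function(e) NULL)

  with_img <- !vapply(cohort$cases, function(cs) is.null(cs$image), logical(1L))
  reports <- vector("list", n)
  flags <- rep(NA, n)
  for (i in which(with_img)) {
    reports[[i]] <- run_case(cohort$cases[[i]], config)
    flags[i] <- reports[[i]]$corresponding
  }
  n_eval <- sum(!is.na(flags))
  corr <- list(count = sum(flags, na.rm = TRUE), n = n_eval,
               fraction = if (n_eval > 0) sum(flags, na.rm = TRUE) / n_eval
                          else NA_real_)
  structure(list(hp_table = hp_table, sweep = sweep,
                 case_reports = reports, correspondence = corr,
                 config = config),
            class = "twa_cohort_report")
}

#' @export
print.twa_cohort_report <- function(x, ...) {
  cat("cohort report\n-- hemodynamic parameters (more vs less dangerous):\n")
  print(x$hp_table, row.names = FALSE, digits = 4)
  if (!is.null(x$sweep)) {
    cat("-- CHP weighting sweep:\n")
    print(as.data.frame(x$sweep), row.names = FALSE, digits = 4)
  }
  if (x$correspondence$n > 0)
    cat(sprintf("-- correspondence: %d of %d cases (%.1f%%)\n",
                x$correspondence$count, x$correspondence$n,
                100 * x$correspondence$fraction))
  invisible(x)
}
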