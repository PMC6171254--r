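#' Write a wall field series (and sac mask) as a plain-text archive
#'
#' The archive is a directory of TSV tables plus a JSON manifest:
#' `vertices.tsv` (x y z, mm), `faces.tsv` (0-based vertex index triples),
#' `times.tsv`, `wss.tsv` (long format: `time_index` 0-based, `face_id`
#' 0-based, `x y z` in Pa), optionally `pressure.tsv` and `sac_mask.tsv`,
#' and `manifest.json` recording sizes, the period and the diastolic index
#' (0-based on disk).
#'
#' @param series a [wall_field_series()].
#' @param dir output directory (created if needed).
#' @param sac optional [sac_mask()].
#' @return `dir`, invisibly.
#' @export
write_wall_fields <- function(series, dir, sac = NULL) {
  if (!inherits(series, "wall_field_series"))
    stop("`series` must be a wall_field_series")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- series$mesh
  nt <- length(series$times); m <- n_faces(mesh)
  wtsv <- function(x, file)
    utils::write.table(x, file.path(dir, file), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  wtsv(data.frame(x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                  z = mesh$vertices[, 3]), "vertices.tsv")
  wtsv(data.frame(v1 = mesh$faces[, 1] - 1L, v2 = mesh$faces[, 2] - 1L,
                  v3 = mesh$faces[, 3] - 1L), "faces.tsv")
  wtsv(data.frame(time = series$times), "times.tsv")
  long <- data.frame(
    time_index = rep(seq_len(nt) - 1L, times = m),
    face_id = rep(seq_len(m) - 1L, each = nt),
    x = as.numeric(series$wss[, , 1L]),
    y = as.numeric(series$wss[, , 2L]),
    z = as.numeric(series$wss[, , 3L]))
  wtsv(long, "wss.tsv")
  files <- c("vertices.tsv", "faces.tsv", "times.tsv", "wss.tsv")
  if (!is.null(series$pressure)) {
    wtsv(data.frame(time_index = rep(seq_len(nt) - 1L, times = m),
                    face_id = rep(seq_len(m) - 1L, each = nt),
                    pressure = as.numeric(series$pressure)),
         "pressure.tsv")
    files <- c(files, "pressure.tsv")
  }
  if (!is.null(sac)) {
    wtsv(data.frame(member = as.integer(unclass(sac))), "sac_mask.tsv")
    files <- c(files, "sac_mask.tsv")
  }
  manifest <- list(format = "twachp-wall-fields", version = 1L,
                   n_vertices = nrow(mesh$vertices), n_faces = m,
                   n_times = nt, period = series$period,
                   diastolic_index = if (is.null(series$diastolic_index))
                     NULL else series$diastolic_index - 1L,
                   files = as.list(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a wall field series archive
#'
#' @param dir directory written by [write_wall_fields()].
#' @return List with `series` ([wall_field_series()]) and `sac` (a
#'   [sac_mask()] or `NULL`).
#' @export
read_wall_fields <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  if (!identical(mf$format, "twachp-wall-fields"))
    stop("not a wall-fields archive: ", dir)
  rtsv <- function(file)
    utils::read.table(file.path(dir, file), sep = "\t", header = TRUE)
  v <- as.matrix(rtsv("vertices.tsv"))
  f <- as.matrix(rtsv("faces.tsv")) + 1L
  mesh <- surface_mesh(v, f)
  times <- rtsv("times.tsv")$time
  nt <- mf$n_times; m <- mf$n_faces
  long <- rtsv("wss.tsv")
  ord <- order(long$face_id, long$time_index)
  wss <- array(0, c(nt, m, 3L))
  wss[, , 1L] <- long$x[ord]; wss[, , 2L] <- long$y[ord]
  wss[, , 3L] <- long$z[ord]
  pressure <- NULL
  if (file.exists(file.path(dir, "pressure.tsv"))) {
    pl <- rtsv("pressure.tsv")
    pressure <- matrix(pl$pressure[order(pl$face_id, pl$time_index)], nt, m)
  }
  di <- if (is.null(mf$diastolic_index)) NULL else mf$diastolic_index + 1L
  series <- wall_field_series(mesh, times, wss, pressure = pressure,
                              period = mf$period, diastolic_index = di)
  sac <- NULL
  if (file.exists(file.path(dir, "sac_mask.tsv")))
    sac <- sac_mask(rtsv("sac_mask.tsv")$member == 1L, mesh)
  list(series = series, sac = sac)
}

#' Write a mesh and WSS series as legacy ASCII VTK polydata
#'
#' Emits `POINTS`/`POLYGONS` plus `CELL_DATA` vector arrays named
#' `WSS_t<k>` (`k` = 0-based time index) and, when a sac mask is given, an
#' integer `SCALARS sac_mask` array.
#'
#' @param series a [wall_field_series()].
#' @param file output path.
#' @param sac optional [sac_mask()].
#' @return `file`, invisibly.
#' @export
write_vtk_polydata <- function(series, file, sac = NULL) {
  mesh <- series$mesh
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  num <- function(x) paste(format(x, digits = 17, trim = TRUE),
                           collapse = " ")
  wl("# vtk DataFile Version 3.0")
  wl("aneurysm wall shear stress series")
  wl("ASCII")
  wl("DATASET POLYDATA")
  wl("POINTS ", nrow(mesh$vertices), " float")
  writeLines(apply(mesh$vertices, 1L, num), con)
  m <- n_faces(mesh)
  wl("POLYGONS ", m, " ", 4L * m)
  writeLines(apply(cbind(3L, mesh$faces - 1L), 1L, num), con)
  wl("CELL_DATA ", m)
  for (t in seq_len(length(series$times))) {
    wl("VECTORS WSS_t", t - 1L, " float")
    vmat <- series$wss[t, , , drop = FALSE]
    dim(vmat) <- c(m, 3L)
    writeLines(apply(vmat, 1L, num), con)
  }
  if (!is.null(sac)) {
    wl("SCALARS sac_mask int 1")
    wl("LOOKUP_TABLE default")
    writeLines(as.character(as.integer(unclass(sac))), con)
  }
  invisible(file)
}

#' Read legacy ASCII VTK polydata carrying WSS_t<k> cell vectors
#'
#' Minimal reader for the dialect written by [write_vtk_polydata()]:
#' triangular `POLYGONS`, per-cell `VECTORS` arrays named `WSS_t<k>`
#' (gathered in `k` order), and an optional `sac_mask` scalar array.
#' `times` are not stored in VTK, so they must be supplied to rebuild a
#' series.
#'
#' @param file VTK file path.
#' @param times sample times matching the number of `WSS_t<k>` arrays.
#' @param period optional cycle duration (s).
#' @return List with `series` and `sac` (possibly `NULL`).
#' @export
read_vtk_polydata <- function(file, times, period = NULL) {
  toks <- scan(file, what = character(), quiet = TRUE, comment.char = "",
               skip = 2L)  # skip the two header/comment lines
  i <- 1L
  eat <- function() { t <- toks[i]; i <<- i + 1L; t }
  expect <- function(word) {
    t <- eat()
    if (!identical(toupper(t), word)) stop("expected ", word, ", got ", t)
  }
  expect("ASCII"); expect("DATASET"); expect("POLYDATA")
  expect("POINTS")
  np <- as.integer(eat()); eat()  # dtype
  verts <- matrix(as.numeric(toks[i:(i + 3L * np - 1L)]), np, 3L,
                  byrow = TRUE)
  i <- i + 3L * np
  expect("POLYGONS")
  nf <- as.integer(eat()); ntot <- as.integer(eat())
  if (ntot != 4L * nf) stop("only triangular polygons are supported")
  poly <- matrix(as.integer(toks[i:(i + 4L * nf - 1L)]), nf, 4L,
                 byrow = TRUE)
  i <- i + 4L * nf
  mesh <- surface_mesh(verts, poly[, 2:4] + 1L)
  expect("CELL_DATA")
  nc <- as.integer(eat())
  if (nc != nf) stop("CELL_DATA size does not match the face count")
  wss_list <- list(); sac <- NULL
  while (i <= length(toks)) {
    kw <- toupper(eat())
    if (kw == "VECTORS") {
      name <- eat(); eat()  # dtype
      vals <- matrix(as.numeric(toks[i:(i + 3L * nc - 1L)]), nc, 3L,
                     byrow = TRUE)
      i <- i + 3L * nc
      if (grepl("^WSS_t[0-9]+$", name))
        wss_list[[name]] <- vals
    } else if (kw == "SCALARS") {
      name <- eat(); eat()
      ncomp <- suppressWarnings(as.integer(toks[i]))
      if (!is.na(ncomp)) i <- i + 1L
      expect("LOOKUP_TABLE"); eat()
      vals <- as.numeric(toks[i:(i + nc - 1L)])
      i <- i + nc
      if (name == "sac_mask") sac <- sac_mask(vals == 1, mesh)
    } else stop("unsupported VTK attribute block: ", kw)
  }
  if (length(wss_list) == 0L) stop("no WSS_t<k> vector arrays found")
  ks <- as.integer(sub("^WSS_t", "", names(wss_list)))
  wss_list <- wss_list[order(ks)]
  nt <- length(wss_list)
  if (length(times) != nt)
    stop("`times` has length ", length(times), " but the file holds ", nt,
         " WSS_t arrays")
  wss <- array(0, c(nt, nc, 3L))
  for (t in seq_len(nt)) wss[t, , ] <- wss_list[[t]]
  list(series = wall_field_series(mesh, times, wss, period = period),
       sac = sac)
}

#' Write / read circular region annotations as JSON
#'
#' The interchange format is an array of objects `{role, cx, cy, r}` with
#' 0-based pixel coordinates.
#'
#' @param annotations list of [region_annotation()]s.
#' @param file JSON path.
#' @return `file` invisibly; the reader returns a named list of
#'   annotations (named by role, `roi` kept under `roi`).
#' @export
write_annotations <- function(annotations, file) {
  rows <- lapply(annotations, function(a)
    list(role = a$role, cx = a$cx, cy = a$cy, r = a$r))
  jsonlite::write_json(unname(rows), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(file) {
  rows <- jsonlite::read_json(file, simplifyVector = FALSE)
  anns <- lapply(rows, function(r)
    region_annotation(r$cx, r$cy, r$r, role = r$role))
  names(anns) <- vapply(anns, `[[`, character(1L), "role")
  anns
}

#' Read / write 8-bit RGB images (PNG or TIFF)
#'
#' @param file image path; format chosen by extension.
#' @return `read_image`: an H x W x 3 integer array in 0..255 (an alpha
#'   channel, if present, is dropped).
#' @export
read_image <- function(file) {
  ext <- tolower(tools::file_ext(file))
  px <- switch(ext,
               png = png::readPNG(file),
               tif = , tiff = tiff::readTIFF(file),
               stop("unsupported image format: .", ext))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3L] > 3L) px <- px[, , 1:3, drop = FALSE]
  img <- array(as.integer(round(px * 255)), dim(px))
  img
}

#' @rdname read_image
#' @param image H x W x 3 integer array in 0..255.
#' @export
write_image <- function(image, file) {
  ext <- tolower(tools::file_ext(file))
  arr <- array(as.numeric(image) / 255, dim(image))
  switch(ext,
         png = png::writePNG(arr, file),
         tif = , tiff = tiff::writeTIFF(arr, file, bits.per.sample = 8L),
         stop("unsupported image format: .", ext))
  invisible(file)
}

#' Write a color-difference map as a 16-bit grayscale PNG heatmap
#'
#' Values are scaled by the map maximum to use the full 16-bit range; the
#' scale is returned so absolute values can be recovered
#' (`value = pixel * scale`).
#'
#' @param map a [delta_e_map()] (NA values render as 0).
#' @param file PNG path.
#' @return The scale factor (map maximum), invisibly.
#' @export
write_delta_e_png <- function(map, file) {
  m <- unclass(map)
  m[is.na(m)] <- 0
  top <- max(m)
  scaled <- if (top > 0) m / top else m
  write_png16(scaled, file)
  invisible(top)
}

#' Write the per-face results table of one case
#'
#' Columns: `face_id` (0-based), `osi`, `wss_dia`, `wss_norm`, `osi_norm`,
#' `chp`.
#'
#' @param fields a [hemodynamic_fields()] result.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_face_csv <- function(fields, file) {
  df <- data.frame(face_id = seq_along(fields$osi) - 1L,
                   osi = as.numeric(fields$osi),
                   wss_dia = as.numeric(fields$wss_dia),
                   wss_norm = as.numeric(fields$wssn),
                   osi_norm = as.numeric(fields$osin),
                   chp = as.numeric(fields$chp))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write the JSON report of one case
#'
#' Records the sac extremes, the weighting, the diastolic index and the
#' peak-CHP region (plus, when available, the image peak and the
#' correspondence call).
#'
#' @param report a [run_case()] result or a [hemodynamic_fields()] +
#'   [peak_region()] pair assembled manually.
#' @param file JSON path.
#' @param w1 weighting recorded in the report.
#' @return `file`, invisibly.
#' @export
write_case_json <- function(report, file, w1 = report$config$w1) {
  pk <- report$chp_peak
  out <- list(
    wss_min = report$fields$extremes$wss_min,
    wss_max = report$fields$extremes$wss_max,
    diastolic_index = report$fields$diastolic_index - 1L,
    w1 = w1, w2 = 1 - w1,
    peak = list(seed_face = pk$seed_face - 1L,
                patch_faces = as.list(pk$patch_faces - 1L),
                patch_mean = pk$patch_mean,
                patch_radius = pk$patch_radius))
  if (!is.null(report$image))
    out$image <- list(peak_x = report$image$peak$x,
                      peak_y = report$image$peak$y,
                      patch_mean = report$image$peak$patch_mean,
                      distance_mm = report$distance_mm,
                      corresponding = report$corresponding)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Read / write the per-case paired samples table
#'
#' Long CSV with columns `case_id`, `hp_kind`, `region`
#' (`more_dangerous` / `less_dangerous`), `value`.
#'
#' @param samples wide data.frame as in `make_cohort()$samples`
#'   (`case_id`, `hp_kind`, `more`, `less`).
#' @param file CSV path.
#' @return `write_samples_csv`: `file` invisibly; `read_samples_csv`: the
#'   wide data.frame.
#' @export
write_samples_csv <- function(samples, file) {
  long <- rbind(
    data.frame(case_id = samples$case_id, hp_kind = samples$hp_kind,
               region = "more_dangerous", value = samples$more),
    data.frame(case_id = samples$case_id, hp_kind = samples$hp_kind,
               region = "less_dangerous", value = samples$less))
  long <- long[order(long$case_id, long$hp_kind, long$region), ]
  utils::write.csv(long, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_samples_csv
#' @export
read_samples_csv <- function(file) {
  long <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("case_id", "hp_kind", "region", "value")
  if (!all(need %in% names(long)))
    stop("samples CSV must have columns ", paste(need, collapse = ", "))
  more <- long[long$region == "more_dangerous", ]
  less <- long[long$region == "less_dangerous", ]
  key <- function(d) paste(d$case_id, d$hp_kind)
  less <- less[match(key(more), key(less)), ]
  data.frame(case_id = more$case_id, hp_kind = more$hp_kind,
             more = more$value, less = less$value,
             stringsAsFactors = FALSE)
}

#' Write cohort-level tables
#'
#' `hp_table` and `sweep` of a [run_cohort()] report as CSV, and the
#' correspondence summary as JSON.
#'
#' @param report a [run_cohort()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$hp_table, file.path(dir, "hp_comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(report$sweep))
    utils::write.csv(as.data.frame(report$sweep),
                     file.path(dir, "weight_sweep.csv"),
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report$correspondence,
                       file.path(dir, "correspondence.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
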