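#' Triangulated vessel/aneurysm surface mesh
#'
#' Builds the surface container used by all hemodynamic post-processing:
#' vertex coordinates in millimetres and triangular faces given as 1-based
#' vertex index triples. Per-face areas, centroids and unit normals are
#' derived at construction and cached.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @return An object of class `surface_mesh`: a list with `vertices`,
#'   `faces`, `face_areas` (mm^2), `face_centroids`, `face_normals`.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
#' m <- surface_mesh(v, rbind(c(1, 2, 3), c(2, 4, 3)))
#' m$face_areas  # both 0.5 mm^2
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns (x, y, z)")
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns (triangles)")
  if (nrow(vertices) < 4L) stop("a surface mesh needs at least 4 vertices")
  if (nrow(faces) < 1L) stop("a surface mesh needs at least 1 face")
  if (anyNA(vertices) || any(!is.finite(vertices)))
    stop("`vertices` must be finite")
  if (anyNA(faces) || any(faces < 1L) || any(faces > nrow(vertices)))
    stop("`faces` contains vertex indices outside 1..", nrow(vertices))

  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c_ <- vertices[faces[, 3L], , drop = FALSE]
  cr <- cross3(b - a, c_ - a)
  areas <- 0.5 * sqrt(rowSums(cr^2))
  if (any(areas <= 0))
    stop("degenerate face(s) with zero area: ",
         paste(utils::head(which(areas <= 0), 5L), collapse = ", "))
  normals <- cr / (2 * areas)
  centroids <- (a + b + c_) / 3

  structure(
    list(vertices = vertices, faces = faces, face_areas = areas,
         face_centroids = centroids, face_normals = normals),
    class = "surface_mesh")
}

# row-wise cross product of n x 3 matrices
cross3 <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces, total area", format(sum(x$face_areas), digits = 4), "mm^2\n")
  invisible(x)
}

n_faces <- function(mesh) nrow(mesh$faces)

#' Per-face sac membership mask
#'
#' Marks the faces lying in the aneurysm sac above its neck; the sac is the
#' domain over which the wall-shear-stress normalization extremes are taken.
#'
#' @param member logical vector, one entry per face, `TRUE` inside the sac.
#' @param mesh the [surface_mesh()] the mask belongs to.
#' @return A logical vector of class `sac_mask`.
#' @export
sac_mask <- function(member, mesh) {
  member <- as.logical(member)
  if (anyNA(member)) stop("`member` must not contain NA")
  if (length(member) != n_faces(mesh))
    stop("sac mask length (", length(member), ") != number of faces (",
         n_faces(mesh), ")")
  if (!any(member)) stop("sac mask selects no faces")
  structure(member, class = "sac_mask")
}
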