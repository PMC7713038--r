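# Mesh and landmark file I/O. Binary STL, ASCII OBJ and ASCII PLY are
# written and read directly (no mesh package dependency); coordinates are
# millimetres.

#' Write a mesh to STL, OBJ or PLY
#'
#' @param mesh A mesh (list with \code{vertices}, \code{faces}).
#' @param path Output file path; the extension is ignored, the format comes
#'   from \code{format}.
#' @param format One of "stl" (binary), "obj", "ply" (ascii).
#' @return The path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("stl", "obj", "ply")) {
  format <- match.arg(tolower(format), c("stl", "obj", "ply"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  v <- mesh$vertices
  f <- mesh$faces
  if (format == "stl") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("stiflesim binary STL (mm)", width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
      n <- vcross(b - a, c3 - a)
      nn <- vnorm(n)
      if (nn > 0) n <- n / nn
      writeBin(as.numeric(c(n, a, b, c3)), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else if (format == "obj") {
    lines <- c(paste("v", fmt9(v[, 1]), fmt9(v[, 2]), fmt9(v[, 3])),
               paste("f", f[, 1], f[, 2], f[, 3]))
    writeLines(lines, path)
  } else {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    body <- c(paste(fmt9(v[, 1]), fmt9(v[, 2]), fmt9(v[, 3])),
              paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1))
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read a mesh written by \code{\link{write_mesh}} (or any standard STL,
#' OBJ, or PLY triangle mesh)
#'
#' Binary STL stores one vertex triple per triangle; identical coordinates
#' are welded back into shared vertices on read.
#'
#' @param path File path.
#' @param format Format; inferred from the extension when missing.
#' @return A mesh.
#' @export
read_mesh <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("stl", "obj", "ply"))
  if (format == "stl") {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    verts <- matrix(0, nf * 3, 3)
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      verts[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      faces[i, ] <- (3 * i - 2):(3 * i)
    }
    key <- paste(verts[, 1], verts[, 2], verts[, 3])
    uid <- match(key, unique(key))
    verts <- verts[!duplicated(key), , drop = FALSE]
    faces[] <- uid[faces]
    new_mesh(verts, faces)
  } else if (format == "obj") {
    lines <- readLines(path)
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                                   function(x) as.numeric(x[2:4])))
    faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
      as.integer(sub("/.*", "", x[2:4]))
    }))
    new_mesh(verts, faces)
  } else {
    lines <- readLines(path)
    endh <- which(lines == "end_header")
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)))
    vl <- lines[(endh + 1):(endh + nv)]
    fl <- lines[(endh + nv + 1):(endh + nv + nf)]
    verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                                   function(x) as.numeric(x[1:3])))
    faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"),
                                   function(x) as.integer(x[2:4]) + 1L))
    new_mesh(verts, faces)
  }
}

#' Export the three bone meshes of a geometry
#'
#' Writes \code{femur.<ext>}, \code{patella.<ext>}, \code{tibia.<ext>}.
#'
#' @param geom A \code{stifle_geometry}.
#' @param directory Output directory (must exist and be writable).
#' @param format "stl", "obj" or "ply".
#' @return Character vector of the three file paths.
#' @export
export_meshes <- function(geom, directory, format = c("stl", "obj", "ply")) {
  format <- match.arg(tolower(format), c("stl", "obj", "ply"))
  if (!dir.exists(directory)) stop("directory does not exist: ", directory)
  paths <- file.path(directory, paste0(c("femur", "patella", "tibia"),
                                       ".", format))
  write_mesh(geom$femur_mesh, paths[1], format)
  write_mesh(geom$patella_mesh, paths[2], format)
  write_mesh(geom$tibia_mesh, paths[3], format)
  paths
}

#' Write / read a landmark file
#'
#' Flat \code{name -> [x, y, z]} mapping in YAML or JSON (mm), for use with
#' user-supplied meshes.
#'
#' @param landmarks Named list of 3-vectors.
#' @param path File path ending in .yaml/.yml or .json.
#' @return \code{write_landmarks}: the path, invisibly;
#'   \code{read_landmarks}: a named list of numeric 3-vectors.
#' @export
write_landmarks <- function(landmarks, path) {
  ext <- tolower(tools::file_ext(path))
  lm <- lapply(landmarks, as.numeric)
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lm, path)
  } else if (ext == "json") {
    jsonlite::write_json(lm, path, digits = NA)
  } else stop("landmark file must be .yaml/.yml or .json")
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lm <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
        else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
        else stop("landmark file must be .yaml/.yml or .json")
  lapply(lm, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3 || any(!is.finite(p)))
      stop("each landmark must be a finite [x, y, z] triple")
    p
  })
}

#' Assemble a geometry from user-supplied meshes and landmarks
#'
#' Replaces the synthetic bone meshes by user meshes (STL/OBJ/PLY) aligned
#' to the package's anatomical frame, with the landmark set supplied as a
#' file. The contact model still uses the parametric trochlear profile from
#' \code{params} (the reduced contact surface), so the profile parameters
#' should be set to match the user's trochlea.
#'
#' @param femur,patella,tibia Mesh file paths.
#' @param landmarks Landmark file path (see \code{\link{read_landmarks}}).
#' @param params A \code{\link{geometry_params}} describing the contact
#'   profile and patellar dimensions.
#' @return A \code{stifle_geometry}.
#' @export
stifle_geometry_from_files <- function(femur, patella, tibia, landmarks,
                                       params = geometry_params()) {
  geom <- build_reference_stifle(params)
  geom$femur_mesh <- read_mesh(femur)
  geom$patella_mesh <- read_mesh(patella)
  geom$tibia_mesh <- read_mesh(tibia)
  lm <- read_landmarks(landmarks)
  geom$landmarks[names(lm)] <- lm
  geom
}
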