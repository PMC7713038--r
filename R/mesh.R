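# Triangle-mesh primitives. Meshes are plain lists with a numeric vertex
# matrix (n x 3, mm) and an integer face matrix (m x 3, 1-based), built so
# that every edge is shared by exactly two triangles (watertight).

new_mesh <- function(vertices, faces) {
  storage.mode(faces) <- "integer"
  structure(list(vertices = vertices, faces = faces), class = "stifle_mesh")
}

#' @export
print.stifle_mesh <- function(x, ...) {
  cat(sprintf("<stifle_mesh: %d vertices, %d triangles>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

## Signed volume via the divergence theorem (mm^3); positive for outward
## normals.
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Mesh volume
#' @param mesh A mesh as found in a \code{stifle_geometry} object.
#' @return Enclosed volume in mm^3.
#' @export
mesh_volume <- function(mesh) abs(mesh_signed_volume(mesh))

## Flip winding if the signed volume is negative so normals point outward.
mesh_orient <- function(mesh) {
  if (mesh_signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Check that a mesh is watertight
#'
#' Every undirected edge must be used by exactly two triangles.
#'
#' @param mesh A mesh.
#' @return TRUE/FALSE.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

## Closed tube through a stack of cross-section rings (same vertex count per
## ring), capped with triangle fans at both ends.
tube_mesh <- function(rings) {
  k <- nrow(rings[[1]])
  nr <- length(rings)
  verts <- do.call(rbind, rings)
  idx <- function(r, i) (r - 1L) * k + ((i - 1L) %% k) + 1L
  faces <- vector("list", nr - 1)
  for (r in seq_len(nr - 1)) {
    i <- seq_len(k)
    faces[[r]] <- rbind(cbind(idx(r, i), idx(r, i + 1), idx(r + 1, i + 1)),
                        cbind(idx(r, i), idx(r + 1, i + 1), idx(r + 1, i)))
  }
  c0 <- colMeans(rings[[1]])
  c1 <- colMeans(rings[[nr]])
  verts <- rbind(verts, c0, c1)
  i0 <- nrow(verts) - 1L
  i1 <- nrow(verts)
  i <- seq_len(k)
  cap0 <- cbind(rep(i0, k), idx(1, i + 1), idx(1, i))
  cap1 <- cbind(rep(i1, k), idx(nr, i), idx(nr, i + 1))
  mesh_orient(new_mesh(verts, do.call(rbind, c(faces, list(cap0, cap1)))))
}

## Pillow shell over a rectangular (x, z) grid: a lower sheet y = f_low(x, z)
## and an upper sheet y = f_low + bulge(x, z), sharing rim vertices where the
## bulge vanishes.
pillow_mesh <- function(xs, zs, f_low, f_bulge) {
  nx <- length(xs); nz <- length(zs)
  grid <- expand.grid(ix = seq_len(nx), iz = seq_len(nz))
  low <- cbind(xs[grid$ix],
               f_low(xs[grid$ix], zs[grid$iz]),
               zs[grid$iz])
  bot_id <- matrix(seq_len(nx * nz), nx, nz)
  interior <- grid$ix > 1 & grid$ix < nx & grid$iz > 1 & grid$iz < nz
  up <- low[interior, , drop = FALSE]
  up[, 2] <- up[, 2] + f_bulge(up[, 1], up[, 3])
  top_id <- bot_id
  top_id[cbind(grid$ix[interior], grid$iz[interior])] <-
    nx * nz + seq_len(sum(interior))
  verts <- rbind(low, up)
  fcs <- list()
  for (j in seq_len(nz - 1)) {
    for (i in seq_len(nx - 1)) {
      b <- c(bot_id[i, j], bot_id[i + 1, j], bot_id[i + 1, j + 1],
             bot_id[i, j + 1])
      t <- c(top_id[i, j], top_id[i + 1, j], top_id[i + 1, j + 1],
             top_id[i, j + 1])
      fcs[[length(fcs) + 1]] <- rbind(c(b[1], b[2], b[3]), c(b[1], b[3], b[4]))
      if (!all(t == b)) {
        ## avoid duplicating the bottom diagonal in corner cells whose
        ## top diagonal endpoints both lie on the shared rim
        if (t[1] == b[1] && t[3] == b[3])
          fcs[[length(fcs) + 1]] <- rbind(c(t[1], t[4], t[2]),
                                          c(t[2], t[4], t[3]))
        else
          fcs[[length(fcs) + 1]] <- rbind(c(t[1], t[3], t[2]),
                                          c(t[1], t[4], t[3]))
      }
    }
  }
  mesh_orient(new_mesh(verts, do.call(rbind, fcs)))
}

## Oriented rectangular box: center, three orthonormal axes (columns of R),
## and half-extents.
box_mesh <- function(center, axes, half) {
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  verts <- t(apply(s, 1, function(u) center + axes %*% (u * half)))
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z-
    c(5, 6, 8), c(5, 8, 7),   # z+
    c(1, 2, 6), c(1, 6, 5),   # y-
    c(3, 7, 8), c(3, 8, 4),   # y+
    c(1, 5, 7), c(1, 7, 3),   # x-
    c(2, 4, 8), c(2, 8, 6))   # x+
  mesh_orient(new_mesh(verts, f))
}

## Apply a function to all vertices (n x 3 -> n x 3).
mesh_transform <- function(mesh, fn) {
  mesh$vertices <- fn(mesh$vertices)
  mesh
}
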