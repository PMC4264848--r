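#' Triangulated surface mesh in physical coordinates
#'
#' @param vertices N x 3 numeric matrix of points in mm.
#' @param faces M x 3 integer matrix of vertex indices (1-based),
#'   counter-clockwise seen from outside.
#' @param label `"tissue"` or `"scaffold"`.
#' @param spacing the `(pixel_size, pixel_size, slice_thickness)` of
#'   the source volume, in mm (physical-frame metadata; meshes built
#'   from the same scan share it whatever their resample factor).
#' @param resample_factor the downsampling factor the mesh was built
#'   with.
#' @return a `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces, label = "tissue",
                         spacing = c(1, 1, 1), resample_factor = 1L) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, label = label,
                 spacing = spacing, resample_factor = as.integer(resample_factor)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh '%s': %d vertices, %d faces\n",
              x$label, nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$vertices) > 0) {
    bb <- apply(x$vertices, 2, range)
    cat(sprintf("  bbox [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g] mm\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
    cat(sprintf("  enclosed volume %.4g mm^3\n", mesh_volume(x)))
  }
  invisible(x)
}

## block-mean downsampling by an integer factor (trailing remainder cropped)
downsample_volume <- function(v, f) {
  if (f == 1L) return(v)
  d <- dim(v); nd <- d %/% f
  if (any(nd < 1)) stop("resample factor larger than the volume")
  v <- v[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f),
         drop = FALSE]
  dim(v) <- c(f, nd[1], f, nd[2], f, nd[3])
  out <- apply(v, c(2, 4, 6), mean)
  out
}

## Kuhn decomposition: 6 tetrahedra per cube around the (0,0,0)-(1,1,1)
## diagonal, one per axis-order path; faces match across neighbouring
## cubes, so the extracted surface is watertight.
kuhn_tets <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(seq_len(6), function(p) {
    e <- diag(3)
    rbind(c(0, 0, 0),
          e[perms[p, 1], ],
          e[perms[p, 1], ] + e[perms[p, 2], ],
          c(1, 1, 1))
  })
}

#' Extract an isosurface from a (binary) volume
#'
#' Marching isosurface extraction at the given level (0.5 for binary
#' masks): the volume is optionally block-mean downsampled by
#' `resample_factor`, padded with one empty voxel shell so every
#' surface is closed, and triangulated by marching tetrahedra (Kuhn
#' 6-tetrahedron cube decomposition — a marching-cubes variant with no
#' ambiguous cases). Vertices are returned in physical mm; triangles
#' are oriented with outward normals.
#'
#' @param volume 3D logical or numeric array (rows x cols x slices).
#' @param resample_factor integer >= 1; `f` downsamples the volume by
#'   `f` along each axis before surfacing (1 = full resolution).
#' @param spacing physical voxel size `(pixel, pixel, slice)` in mm.
#' @param level iso level (default 0.5).
#' @param label mesh label.
#' @return a [surface_mesh()]; an empty volume yields an empty mesh.
#' @export
marching_cubes <- function(volume, resample_factor = 1L,
                           spacing = c(1, 1, 1), level = 0.5,
                           label = "tissue") {
  f <- as.integer(resample_factor)
  if (is.na(f) || f < 1L) stop("resample_factor must be an integer >= 1")
  v <- volume * 1
  if (is.matrix(v)) v <- array(v, c(dim(v), 1L))
  if (!any(v > level))
    return(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3), label,
                        spacing, f))
  v <- downsample_volume(v, f)
  sp <- spacing * f
  d0 <- dim(v)
  V <- array(0, d0 + 2L)
  V[2:(d0[1] + 1), 2:(d0[2] + 1), 2:(d0[3] + 1)] <- v
  rng <- max(V) - min(V)
  V[V == level] <- level - 1e-6 * (rng + 1)   # keep nodes off the level
  n <- dim(V)
  ## physical position of node (i,j,k): centre of its source block
  node_pos <- function(nid) {
    nid0 <- nid - 1L
    i <- nid0 %% n[1] + 1L
    j <- (nid0 %/% n[1]) %% n[2] + 1L
    k <- nid0 %/% (n[1] * n[2]) + 1L
    cbind((i - 1.5) * sp[1], (j - 1.5) * sp[2], (k - 1.5) * sp[3])
  }
  S <- V > level
  idx1 <- seq_len(n[1] - 1); idx2 <- seq_len(n[2] - 1); idx3 <- seq_len(n[3] - 1)
  csum <- array(0L, n - 1L)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1)
    csum <- csum + S[idx1 + di, idx2 + dj, idx3 + dk, drop = FALSE]
  act <- which(csum > 0L & csum < 8L, arr.ind = TRUE)
  if (nrow(act) == 0)
    return(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3), label, spacing, f))
  nid_of <- function(i, j, k) i + (j - 1) * n[1] + (k - 1) * n[1] * n[2]
  Vv <- as.vector(V)
  tets <- kuhn_tets()
  tri_e1 <- tri_e2 <- tri_e3 <- list()   # edge keys per triangle corner
  tri_ref <- list()                      # inside-side reference points
  edge_key_all <- edge_in_all <- edge_out_all <- list()
  KEYM <- prod(n) + 1
  gi <- 0L
  emit <- function(eid_in, eid_out, tris, ref_pos) {
    ## eid_in/eid_out: list of (inside, outside) node-id vectors per edge slot
    keys <- lapply(seq_along(eid_in), function(s) {
      a <- eid_in[[s]]; b <- eid_out[[s]]
      pmin(a, b) * KEYM + pmax(a, b)
    })
    for (tr in tris) {
      gi <<- gi + 1L
      tri_e1[[gi]] <<- keys[[tr[1]]]
      tri_e2[[gi]] <<- keys[[tr[2]]]
      tri_e3[[gi]] <<- keys[[tr[3]]]
      tri_ref[[gi]] <<- ref_pos
    }
    for (s in seq_along(eid_in)) {
      edge_key_all[[length(edge_key_all) + 1L]] <<- keys[[s]]
      edge_in_all[[length(edge_in_all) + 1L]] <<- eid_in[[s]]
      edge_out_all[[length(edge_out_all) + 1L]] <<- eid_out[[s]]
    }
  }
  for (tet in tets) {
    nids <- sapply(seq_len(4), function(c_)
      nid_of(act[, 1] + tet[c_, 1], act[, 2] + tet[c_, 2],
             act[, 3] + tet[c_, 3]))
    if (is.null(dim(nids))) nids <- matrix(nids, nrow = 1)
    ins <- matrix(S[nids], nrow(nids), 4)
    code <- ins[, 1] + 2L * ins[, 2] + 4L * ins[, 3] + 8L * ins[, 4]
    for (cd in 1:14) {
      sel <- which(code == cd)
      if (length(sel) == 0) next
      inside <- which(bitwAnd(cd, c(1L, 2L, 4L, 8L)) > 0L)
      outside <- setdiff(1:4, inside)
      nin <- nids[sel, , drop = FALSE]
      refm <- matrix(0, length(sel), 3)
      for (ic in inside) refm <- refm + node_pos(nin[, ic])
      refm <- refm / length(inside)
      if (length(inside) == 1L) {
        A <- nin[, inside]
        emit(list(A, A, A),
             list(nin[, outside[1]], nin[, outside[2]], nin[, outside[3]]),
             list(c(1, 2, 3)), refm)
      } else if (length(inside) == 3L) {
        D <- nin[, outside]
        emit(list(nin[, inside[1]], nin[, inside[2]], nin[, inside[3]]),
             list(D, D, D), list(c(1, 2, 3)), refm)
      } else {
        A <- nin[, inside[1]]; B <- nin[, inside[2]]
        C <- nin[, outside[1]]; D <- nin[, outside[2]]
        emit(list(A, A, B, B), list(C, D, D, C),
             list(c(1, 2, 3), c(1, 3, 4)), refm)
      }
    }
  }
  e1 <- unlist(tri_e1); e2 <- unlist(tri_e2); e3 <- unlist(tri_e3)
  refp <- do.call(rbind, tri_ref)
  ekey <- unlist(edge_key_all)
  ein <- unlist(edge_in_all); eout <- unlist(edge_out_all)
  keep <- !duplicated(ekey)
  ukey <- ekey[keep]; uin <- ein[keep]; uout <- eout[keep]
  ord <- order(ukey)
  ukey <- ukey[ord]; uin <- uin[ord]; uout <- uout[ord]
  ## interpolate each unique crossing edge once
  pin <- node_pos(uin); pout <- node_pos(uout)
  t <- (level - Vv[uin]) / (Vv[uout] - Vv[uin])
  verts <- pin + t * (pout - pin)
  f1 <- findInterval(e1, ukey); f2 <- findInterval(e2, ukey)
  f3 <- findInterval(e3, ukey)
  faces <- cbind(f1, f2, f3)
  ## orient every triangle with its normal away from the inside
  P1 <- verts[faces[, 1], , drop = FALSE]
  P2 <- verts[faces[, 2], , drop = FALSE]
  P3 <- verts[faces[, 3], , drop = FALSE]
  u <- P2 - P1; w <- P3 - P1
  nx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  ny <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  nz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  cen <- (P1 + P2 + P3) / 3
  dir <- cen - refp
  dp <- nx * dir[, 1] + ny * dir[, 2] + nz * dir[, 3]
  flip <- dp < 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]
  area2 <- nx^2 + ny^2 + nz^2
  faces <- faces[area2 > 1e-24, , drop = FALSE]
  ## drop unreferenced vertices
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  surface_mesh(verts[used, , drop = FALSE],
               matrix(remap[faces], ncol = 3), label, spacing, f)
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(matrix(0L, 0, 2))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  k <- pmin(e[, 1], e[, 2]) * (nrow(mesh$vertices) + 1) +
    pmax(e[, 1], e[, 2])
  e[!duplicated(k), , drop = FALSE]
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh a [surface_mesh()].
#' @return integer Euler characteristic (2 per closed sphere-topology
#'   component).
#' @export
mesh_euler <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' Is every mesh edge shared by exactly two faces?
#' @param mesh a [surface_mesh()].
#' @return logical.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(TRUE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  k <- pmin(e[, 1], e[, 2]) * (nrow(mesh$vertices) + 1) +
    pmax(e[, 1], e[, 2])
  all(table(k) == 2L)
}

#' Enclosed volume of a closed mesh
#'
#' Signed sum of origin-tetrahedron volumes over all faces (divergence
#' theorem); the absolute value is returned.
#'
#' @param mesh a [surface_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(0)
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  s <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
    a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(s)) / 6
}

#' Taubin non-shrinking mesh smoothing
#'
#' Alternating Laplacian steps with positive factor `lambda` and
#' negative factor `mu` (pass-band condition `0 < lambda < -mu < 1`),
#' which smooths surface faceting without the volume shrinkage of
#' plain Laplacian smoothing. Uniform neighbour weights; connectivity
#' and vertex/face counts are unchanged.
#'
#' @param mesh a [surface_mesh()].
#' @param lambda positive smoothing factor (default 0.5).
#' @param mu negative inflation factor (default -0.53, the filter's
#'   canonical pass-band pairing; `mu = 0` degenerates to plain
#'   Laplacian smoothing and is allowed for comparison).
#' @param iterations number of lambda/mu passes (>= 0).
#' @return the smoothed [surface_mesh()].
#' @export
taubin_smooth <- function(mesh, lambda = 0.5, mu = -0.53, iterations = 10) {
  if (iterations < 0) stop("iterations must be >= 0")
  if (!(lambda > 0)) stop("lambda must be > 0")
  if (mu != 0 && !(lambda < -mu && -mu < 1))
    stop("pass-band condition 0 < lambda < -mu < 1 violated")
  if (iterations == 0 || nrow(mesh$faces) == 0) return(mesh)
  e <- mesh_edges(mesh)
  both <- rbind(e, e[, c(2, 1)])
  ord <- order(both[, 1])
  src <- both[ord, 1]; dst <- both[ord, 2]
  nv <- nrow(mesh$vertices)
  deg <- tabulate(src, nv)
  v <- mesh$vertices
  lap_step <- function(v, fac) {
    s <- rowsum(v[dst, , drop = FALSE], src, reorder = TRUE)
    g <- as.integer(rownames(s))
    delta <- v
    delta[] <- 0
    delta[g, ] <- s / deg[g] - v[g, , drop = FALSE]
    v + fac * delta
  }
  for (it in seq_len(iterations)) {
    v <- lap_step(v, lambda)
    if (mu != 0) v <- lap_step(v, mu)
  }
  out <- mesh
  out$vertices <- v
  out
}

#' Combine tissue and scaffold meshes into one scene
#'
#' @param tissue_mesh,scaffold_mesh [surface_mesh()] objects in the
#'   same physical frame (equal `spacing` metadata).
#' @return a `mesh_scene`: named list of the non-empty meshes with a
#'   shared bounding box.
#' @export
assemble_model <- function(tissue_mesh, scaffold_mesh) {
  if (!isTRUE(all.equal(tissue_mesh$spacing, scaffold_mesh$spacing)) &&
      nrow(tissue_mesh$vertices) > 0 && nrow(scaffold_mesh$vertices) > 0)
    stop("meshes come from different physical frames (spacing mismatch)")
  objs <- list(tissue = tissue_mesh, scaffold = scaffold_mesh)
  objs <- objs[vapply(objs, function(m) nrow(m$vertices) > 0, logical(1))]
  bbox <- if (length(objs) == 0) NULL else
    apply(do.call(rbind, lapply(objs, `[[`, "vertices")), 2, range)
  structure(list(objects = objs, bbox = bbox), class = "mesh_scene")
}

#' @export
print.mesh_scene <- function(x, ...) {
  cat(sprintf("mesh_scene: %d object(s)%s\n", length(x$objects),
              if (length(x$objects))
                paste0(" (", paste(names(x$objects), collapse = ", "), ")")
              else ""))
  if (!is.null(x$bbox))
    cat(sprintf("  bbox %.3g x %.3g x %.3g mm\n",
                diff(x$bbox[, 1]), diff(x$bbox[, 2]), diff(x$bbox[, 3])))
  invisible(x)
}

#' Write a mesh as ASCII PLY
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("comment label", mesh$label),
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  if (nrow(mesh$vertices) > 0)
    writeLines(apply(format(mesh$vertices, trim = TRUE, digits = 9), 1,
                     paste, collapse = " "), con)
  if (nrow(mesh$faces) > 0)
    writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Write a mesh as ASCII STL
#' @inheritParams write_ply
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", mesh$label), con)
  f <- mesh$faces
  if (nrow(f) > 0) {
    v <- mesh$vertices
    p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]
    p3 <- v[f[, 3], , drop = FALSE]
    u <- p2 - p1; w <- p3 - p1
    nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                 u[, 3] * w[, 1] - u[, 1] * w[, 3],
                 u[, 1] * w[, 2] - u[, 2] * w[, 1])
    len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
    nrm <- nrm / len
    fmt <- function(m) apply(format(m, trim = TRUE, digits = 9), 1, paste,
                             collapse = " ")
    writeLines(paste0("facet normal ", fmt(nrm), "\n outer loop\n  vertex ",
                      fmt(p1), "\n  vertex ", fmt(p2), "\n  vertex ",
                      fmt(p3), "\n endloop\nendfacet"), con)
  }
  writeLines(paste("endsolid", mesh$label), con)
  invisible(path)
}

#' Write a mesh scene as a multi-object Wavefront OBJ
#'
#' Each mesh becomes a named `o` object in one file, so labels survive
#' the export.
#'
#' @param scene a [assemble_model()] scene.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scene_obj <- function(scene, path) {
  con <- file(path, "w")
  on.exit(close(con))
  off <- 0L
  for (nm in names(scene$objects)) {
    m <- scene$objects[[nm]]
    writeLines(paste("o", nm), con)
    if (nrow(m$vertices) > 0)
      writeLines(paste("v",
                       apply(format(m$vertices, trim = TRUE, digits = 9), 1,
                             paste, collapse = " ")), con)
    if (nrow(m$faces) > 0)
      writeLines(paste("f", m$faces[, 1] + off, m$faces[, 2] + off,
                       m$faces[, 3] + off), con)
    off <- off + nrow(m$vertices)
  }
  invisible(path)
}
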