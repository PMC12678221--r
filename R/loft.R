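# Lofting: join stacks of cross-section rings into watertight triangle
# meshes. Rings are N x 3 coordinate matrices ordered along the vessel;
# points within a ring must run counter-clockwise in the y-z plane and be
# index-aligned between consecutive rings (generator correspondence).

# counter-clockwise in (y,z)? signed shoelace area of columns 2:3
ring_is_ccw <- function(ring) {
  y <- ring[, 2L]; z <- ring[, 3L]
  y2 <- c(y[-1L], y[1L]); z2 <- c(z[-1L], z[1L])
  sum(y * z2 - y2 * z) > 0
}

ensure_ccw <- function(ring) if (ring_is_ccw(ring)) ring else
  ring[c(1L, nrow(ring):2L), , drop = FALSE]

# quad-strip faces between nsec stacked rings of N vertices starting at
# vertex index `base + 1`; two triangles per quad
tube_strip_faces <- function(nsec, N, base = 0L) {
  if (nsec < 2L) return(matrix(0L, 0L, 3L))
  i <- rep(seq_len(N), times = nsec - 1L)
  ip1 <- ifelse(i == N, 1L, i + 1L)
  j <- rep(seq_len(nsec - 1L) - 1L, each = N)
  A <- base + j * N + i
  A1 <- base + j * N + ip1
  B <- base + (j + 1L) * N + i
  B1 <- base + (j + 1L) * N + ip1
  rbind(cbind(A, A1, B1), cbind(A, B1, B))
}

# centroid fan over a ring; `start = TRUE` for the upstream end (fan wound
# against the ring direction so the cap faces away from the tube)
cap_fan_faces <- function(ring_idx, center_idx, start = TRUE) {
  n <- length(ring_idx)
  nxt <- c(ring_idx[-1L], ring_idx[1L])
  if (start) cbind(center_idx, nxt, ring_idx)
  else cbind(center_idx, ring_idx, nxt)
}

# march a triangle band between two closed vertex loops (indices into V);
# `ip` is the upstream loop, `im` the downstream loop
zipper_cyclic <- function(ip, im, V) {
  n1 <- length(ip); n2 <- length(im)
  d0 <- colSums((t(V[im, , drop = FALSE]) - V[ip[1L], ])^2)
  j0 <- which.min(d0)
  im <- im[c(j0:n2, if (j0 > 1L) 1:(j0 - 1L))]
  faces <- matrix(0L, n1 + n2, 3L)
  i <- 1L; j <- 1L; ci <- 0L; cj <- 0L; k <- 0L
  while (ci < n1 || cj < n2) {
    i1 <- if (i == n1) 1L else i + 1L
    j1 <- if (j == n2) 1L else j + 1L
    adv_i <- if (ci >= n1) FALSE else if (cj >= n2) TRUE else
      sum((V[ip[i1], ] - V[im[j], ])^2) <= sum((V[ip[i], ] - V[im[j1], ])^2)
    k <- k + 1L
    if (adv_i) {
      faces[k, ] <- c(ip[i], ip[i1], im[j])
      i <- i1; ci <- ci + 1L
    } else {
      faces[k, ] <- c(ip[i], im[j1], im[j])
      j <- j1; cj <- cj + 1L
    }
  }
  faces
}

# single tube: stacked rings, optional end caps
ring_tube_mesh <- function(rings, cap_start = TRUE, cap_end = TRUE) {
  rings <- lapply(rings, ensure_ccw)
  N <- nrow(rings[[1L]])
  if (any(vapply(rings, nrow, 1L) != N))
    stop("all rings must have the same point count")
  nsec <- length(rings)
  if (nsec < 2L) stop("need at least two rings")
  V <- do.call(rbind, rings)
  faces <- tube_strip_faces(nsec, N)
  if (cap_start) {
    V <- rbind(V, colMeans(rings[[1L]]))
    faces <- rbind(faces, cap_fan_faces(seq_len(N), nrow(V), start = TRUE))
  }
  if (cap_end) {
    V <- rbind(V, colMeans(rings[[nsec]]))
    faces <- rbind(faces,
                   cap_fan_faces((nsec - 1L) * N + seq_len(N), nrow(V),
                                 start = FALSE))
  }
  finish_mesh(V, faces)
}

# one parent tube branching into two child tubes: parent and children are
# lofted as quad strips; the junction is closed by a cyclic zipper from the
# last parent ring to the two first child rings merged at their
# nearest-vertex bridge, plus a saddle quad at the bridge
pants_mesh <- function(parent_rings, child2_rings, child3_rings) {
  parent_rings <- lapply(parent_rings, ensure_ccw)
  child2_rings <- lapply(child2_rings, ensure_ccw)
  child3_rings <- lapply(child3_rings, ensure_ccw)
  n1 <- nrow(parent_rings[[1L]])
  n2 <- nrow(child2_rings[[1L]])
  n3 <- nrow(child3_rings[[1L]])
  np <- length(parent_rings); nc2 <- length(child2_rings)
  nc3 <- length(child3_rings)
  if (np < 2L || nc2 < 2L || nc3 < 2L)
    stop("each branch needs at least two sections")
  V <- rbind(do.call(rbind, parent_rings),
             do.call(rbind, child2_rings),
             do.call(rbind, child3_rings))
  b2 <- np * n1
  b3 <- b2 + nc2 * n2
  faces <- rbind(tube_strip_faces(np, n1),
                 tube_strip_faces(nc2, n2, base = b2),
                 tube_strip_faces(nc3, n3, base = b3))
  P <- (np - 1L) * n1 + seq_len(n1)
  C2 <- b2 + seq_len(n2)
  C3 <- b3 + seq_len(n3)
  dm <- outer(seq_len(n2), seq_len(n3), function(a, b)
    rowSums((V[C2[a], , drop = FALSE] - V[C3[b], , drop = FALSE])^2))
  hit <- arrayInd(which.min(dm), dim(dm))
  iu <- hit[1L]; iv <- hit[2L]
  rot <- function(idx, s) idx[c(s:length(idx), if (s > 1L) 1:(s - 1L))]
  C2r <- rot(C2, iu)
  C3r <- rot(C3, iv)
  M <- c(C2r, C3r)
  u <- C2r[1L]; u_prev <- C2r[n2]
  v <- C3r[1L]; v_prev <- C3r[n3]
  faces <- rbind(faces,
                 zipper_cyclic(P, M, V),
                 rbind(c(u, u_prev, v), c(v, v_prev, u)))
  # caps: parent inlet, child outlets
  V <- rbind(V, colMeans(parent_rings[[1L]]),
             colMeans(child2_rings[[nc2]]),
             colMeans(child3_rings[[nc3]]))
  nv <- nrow(V)
  faces <- rbind(faces,
                 cap_fan_faces(seq_len(n1), nv - 2L, start = TRUE),
                 cap_fan_faces(b2 + (nc2 - 1L) * n2 + seq_len(n2), nv - 1L,
                               start = FALSE),
                 cap_fan_faces(b3 + (nc3 - 1L) * n3 + seq_len(n3), nv,
                               start = FALSE))
  finish_mesh(V, faces)
}

finish_mesh <- function(V, faces) {
  # weld exactly-coincident vertices (filtered generator curves can touch),
  # so collapsed quads degenerate cleanly instead of opening pinholes
  dd <- dedup_vertices(V, tol = 1e-9)
  faces <- matrix(dd$map[faces], ncol = 3L)
  mesh <- surface_mesh(dd$vertices, faces)
  if (!isTRUE(mesh$closed))
    stop("loft produced a non-watertight mesh (",
         nrow(mesh$vertices), " vertices, ", nrow(mesh$faces), " faces)")
  if (!mesh_orientation_consistent(mesh))
    stop("loft produced inconsistently oriented faces")
  mesh <- orient_outward(mesh)
  attr(mesh, "vertex_map") <- dd$map
  mesh
}
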