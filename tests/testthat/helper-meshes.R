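# reference solids built in code: unit cube, regular tetrahedron, icosphere

cube_mesh <- function(edge = 1) {
  v <- as.matrix(expand.grid(x = c(0, edge), y = c(0, edge), z = c(0, edge)))
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = 0
    c(5, 6, 8), c(5, 8, 7),   # z = edge
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 7, 8), c(3, 8, 4),   # y = edge
    c(1, 5, 7), c(1, 7, 3),   # x = 0
    c(2, 4, 8), c(2, 8, 6))   # x = edge
  orient_all_outward(surface_mesh(v, f))
}

tetra_mesh <- function(edge = 1) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v <- v * edge / (2 * sqrt(2))     # edge length of this layout is 2*sqrt(2)
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  orient_all_outward(surface_mesh(v, f))
}

icosphere <- function(subdiv = 2, radius = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v); key <- new.env()
    mid <- function(i, j) {
      k <- paste(min(i, j), max(i, j))
      if (!is.null(key[[k]])) return(key[[k]])
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      key[[k]] <- nrow(v)
      nrow(v)
    }
    f2 <- matrix(0L, 0, 3)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; c <- f[r, 3]
      ab <- mid(a, b); bc <- mid(b, c); ca <- mid(c, a)
      f2 <- rbind(f2, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                  c(ab, bc, ca))
    }
    f <- f2
  }
  v <- v * radius / sqrt(rowSums(v^2))
  orient_all_outward(surface_mesh(v, f))
}

# flat hexagonal fan: center vertex 1 surrounded by a symmetric ring
hex_patch_mesh <- function() {
  th <- 2 * pi * (0:5) / 6
  v <- rbind(c(0, 0, 0), cbind(cos(th), sin(th), 0))
  f <- cbind(1, 2:7, c(3:7, 2))
  surface_mesh(v, f)
}

# winding fixed so the signed volume is positive (test meshes only)
orient_all_outward <- function(mesh) {
  vol <- sum(apply(mesh$faces, 1, function(fr) {
    a <- mesh$vertices[fr[1], ]; b <- mesh$vertices[fr[2], ]
    c <- mesh$vertices[fr[3], ]
    (a[1] * (b[2] * c[3] - b[3] * c[2]) +
       a[2] * (b[3] * c[1] - b[1] * c[3]) +
       a[3] * (b[1] * c[2] - b[2] * c[1])) / 6
  }))
  if (vol < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

std_phantom <- function() phantom_spec("bifurcating", diameter = 7.1,
                                       length = 50)
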