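#' Mesh primitives
#'
#' Constructors for the closed solids the lattice builders are assembled
#' from. All return outward-oriented watertight [tri_mesh()] objects in mm.
#'
#' @name primitives
NULL

#' Axis-aligned box
#' @param lo,hi numeric length-3 corners (mm).
#' @return A [tri_mesh()] with 12 faces.
#' @export
mesh_box <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(all(hi > lo))
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order: 1:(---) 2:(+--) 3:(-+-) 4:(++-) 5:(--+) 6:(+-+) 7:(-++) 8:(+++)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # bottom (z-)
    c(5, 6, 8), c(5, 8, 7),   # top (z+)
    c(1, 2, 6), c(1, 6, 5),   # front (y-)
    c(3, 7, 8), c(3, 8, 4),   # back (y+)
    c(1, 5, 7), c(1, 7, 3),   # left (x-)
    c(2, 4, 8), c(2, 8, 6)    # right (x+)
  )
  mesh_orient_outward(tri_mesh(v, f))
}

#' Extruded convex polygon
#'
#' Extrudes a counter-clockwise convex 2D polygon from `z0` to `z1`.
#'
#' @param poly n x 2 matrix of CCW vertices (mm).
#' @param z0,z1 extrusion limits (mm), `z1 > z0`.
#' @return A closed [tri_mesh()].
#' @export
mesh_extrude_polygon <- function(poly, z0, z1) {
  poly <- as.matrix(poly); n <- nrow(poly)
  stopifnot(n >= 3, z1 > z0)
  v <- rbind(cbind(poly, z0), cbind(poly, z1))
  nxt <- c(2:n, 1)
  sides <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(c(i, nxt[i], n + nxt[i]), c(i, n + nxt[i], n + i))
  }))
  bottom <- do.call(rbind, lapply(2:(n - 1), function(i) c(1, i + 1, i)))
  top <- do.call(rbind, lapply(2:(n - 1), function(i) c(n + 1, n + i, n + i + 1)))
  mesh_orient_outward(tri_mesh(v, rbind(sides, bottom, top)))
}

#' Extruded polygonal annulus
#'
#' Extrudes the region between two concentric CCW polygons with the same
#' vertex count (outer strictly containing inner). Used for closed chain
#' links with a square strut cross-section.
#'
#' @param outer,inner n x 2 CCW polygons (mm).
#' @param z0,z1 extrusion limits (mm).
#' @return A closed [tri_mesh()] with a through hole.
#' @export
mesh_extrude_annulus <- function(outer, inner, z0, z1) {
  outer <- as.matrix(outer); inner <- as.matrix(inner)
  n <- nrow(outer)
  stopifnot(n >= 3, nrow(inner) == n, z1 > z0)
  # vertex blocks: outer@z0, inner@z0, outer@z1, inner@z1
  v <- rbind(cbind(outer, z0), cbind(inner, z0), cbind(outer, z1), cbind(inner, z1))
  ob <- 0L; ib <- n; ot <- 2L * n; it <- 3L * n
  nxt <- c(2:n, 1)
  fs <- vector("list", 4 * n)
  k <- 1
  for (i in seq_len(n)) {
    j <- nxt[i]
    # outer wall (outward)
    fs[[k]] <- rbind(c(ob + i, ob + j, ot + j), c(ob + i, ot + j, ot + i)); k <- k + 1
    # inner wall (faces the hole)
    fs[[k]] <- rbind(c(ib + i, it + j, ib + j), c(ib + i, it + i, it + j)); k <- k + 1
    # bottom cap (z-)
    fs[[k]] <- rbind(c(ob + i, ib + j, ob + j), c(ob + i, ib + i, ib + j)); k <- k + 1
    # top cap (z+)
    fs[[k]] <- rbind(c(ot + i, ot + j, it + j), c(ot + i, it + j, it + i)); k <- k + 1
  }
  mesh_orient_outward(tri_mesh(v, do.call(rbind, fs)))
}

#' Swept circular tube along a polyline
#'
#' Sweeps a circular cross-section along an open or closed 3D path using
#' parallel-transport frames. Open tubes are closed with flat end caps;
#' closed paths distribute the frame holonomy so the seam matches.
#'
#' @param path k x 3 matrix of centreline points (mm).
#' @param radius tube radius (mm).
#' @param n_seg number of cross-section segments (default 12).
#' @param closed is the path a closed loop (last point connects to first)?
#' @return A closed [tri_mesh()].
#' @export
mesh_sweep_tube <- function(path, radius, n_seg = 12, closed = FALSE) {
  path <- as.matrix(path)
  k <- nrow(path)
  stopifnot(k >= 2, radius > 0, n_seg >= 3)
  tang <- function(i) {
    if (closed) {
      a <- path[if (i == 1) k else i - 1, ]; b <- path[if (i == k) 1 else i + 1, ]
    } else {
      a <- path[max(1, i - 1), ]; b <- path[min(k, i + 1), ]
    }
    d <- b - a; d / sqrt(sum(d^2))
  }
  tangents <- t(vapply(seq_len(k), tang, numeric(3)))
  # initial frame
  t1 <- tangents[1, ]
  ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * t1) * t1; u <- u / sqrt(sum(u^2))
  frames_u <- matrix(0, k, 3); frames_u[1, ] <- u
  for (i in 2:k) {
    ti <- tangents[i, ]
    u <- frames_u[i - 1, ]
    u <- u - sum(u * ti) * ti
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12) { # degenerate: pick any perpendicular
      ref <- if (abs(ti[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- ref - sum(ref * ti) * ti; nu <- sqrt(sum(u^2))
    }
    frames_u[i, ] <- u / nu
  }
  twist <- rep(0, k)
  if (closed) {
    # holonomy: transport u_k one more step to station 1 and measure the angle
    # mismatch with u_1, then unwind it linearly along the path
    ti <- tangents[1, ]
    u_end <- frames_u[k, ] - sum(frames_u[k, ] * ti) * ti
    u_end <- u_end / sqrt(sum(u_end^2))
    w <- frames_u[1, ]
    v2 <- pracma_cross(ti, w)
    ang <- atan2(sum(u_end * v2), sum(u_end * w))
    twist <- ang * (seq_len(k) - 1) / k
  }
  theta <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  verts <- matrix(0, k * n_seg, 3)
  for (i in seq_len(k)) {
    ti <- tangents[i, ]
    ui <- frames_u[i, ]
    vi <- pracma_cross(ti, ui)
    a <- theta + twist[i]
    ring <- sweep(outer(cos(a), ui) + outer(sin(a), vi), 1, radius, "*")
    verts[(i - 1) * n_seg + seq_len(n_seg), ] <- sweep(ring, 2, path[i, ], "+")
  }
  idx <- function(i, j) (i - 1) * n_seg + ((j - 1) %% n_seg) + 1
  n_ring <- if (closed) k else k - 1
  fs <- vector("list", n_ring + 2)
  for (i in seq_len(n_ring)) {
    i2 <- if (i == k) 1 else i + 1
    j <- seq_len(n_seg)
    fs[[i]] <- rbind(cbind(idx(i, j), idx(i, j + 1), idx(i2, j + 1)),
                     cbind(idx(i, j), idx(i2, j + 1), idx(i2, j)))
  }
  nv <- k * n_seg
  if (!closed) {
    # end caps: fans about the path end points
    verts <- rbind(verts, path[1, ], path[k, ])
    c1 <- nv + 1L; c2 <- nv + 2L
    j <- seq_len(n_seg)
    fs[[n_ring + 1]] <- cbind(rep(c1, n_seg), idx(1, j + 1), idx(1, j))
    fs[[n_ring + 2]] <- cbind(rep(c2, n_seg), idx(k, j), idx(k, j + 1))
  }
  mesh_orient_outward(tri_mesh(verts, do.call(rbind, fs)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Cylinder between two points
#' @param p0,p1 end points (mm).
#' @param radius cylinder radius (mm).
#' @param n_seg cross-section segments.
#' @return A closed [tri_mesh()].
#' @export
mesh_cylinder <- function(p0, p1, radius, n_seg = 10) {
  mesh_sweep_tube(rbind(p0, p1), radius, n_seg = n_seg, closed = FALSE)
}

#' Solid slab under a height-field surface patch
#'
#' Builds the closed solid between `z = zmid - t/2` and `z = zmid + t/2`
#' where `zmid(x, y)` is sampled on a rectangular grid: a folded sheet
#' thickened by vertical offset. The volume is exactly
#' (plan area) x `thickness`, independent of the folds.
#'
#' @param xg,yg strictly increasing grid coordinates (mm).
#' @param zmid matrix `length(xg)` x `length(yg)` of mid-surface heights (mm).
#' @param thickness vertical thickness (mm).
#' @return A closed [tri_mesh()].
#' @export
mesh_sheet_solid <- function(xg, yg, zmid, thickness) {
  nx <- length(xg); ny <- length(yg)
  stopifnot(nrow(zmid) == nx, ncol(zmid) == ny, thickness > 0, nx >= 2, ny >= 2)
  gx <- rep(xg, times = ny); gy <- rep(yg, each = nx)
  zt <- as.vector(zmid) + thickness / 2
  zb <- as.vector(zmid) - thickness / 2
  v <- rbind(cbind(gx, gy, zt), cbind(gx, gy, zb))
  nvert <- nx * ny
  id <- function(i, j) (j - 1) * nx + i
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  a <- id(i, j); b <- id(i + 1, j); cc <- id(i + 1, j + 1); d <- id(i, j + 1)
  top <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  bot <- rbind(cbind(a + nvert, cc + nvert, b + nvert),
               cbind(a + nvert, d + nvert, cc + nvert))
  # side walls along the four boundary edges
  wall <- function(tid) { # tid: top vertex ids along a boundary, ordered
    m <- length(tid)
    do.call(rbind, lapply(seq_len(m - 1), function(k) {
      rbind(c(tid[k], tid[k] + nvert, tid[k + 1] + nvert),
            c(tid[k], tid[k + 1] + nvert, tid[k + 1]))
    }))
  }
  south <- id(seq_len(nx), 1)
  north <- id(rev(seq_len(nx)), ny)
  east <- id(nx, seq_len(ny))
  west <- id(1, rev(seq_len(ny)))
  sides <- rbind(wall(south), wall(east), wall(north), wall(west))
  mesh_orient_outward(tri_mesh(v, rbind(top, bot, sides)))
}

#' Latitude-longitude sphere
#' @param center centre (mm).
#' @param radius radius (mm).
#' @param n_lon,n_lat resolution.
#' @return A closed [tri_mesh()].
#' @export
mesh_sphere <- function(center = c(0, 0, 0), radius = 1, n_lon = 48, n_lat = 24) {
  stopifnot(radius > 0, n_lon >= 3, n_lat >= 2)
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 1)[-c(1, n_lat + 1)]
  lon <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  ring <- function(phi) cbind(cos(phi) * cos(lon), cos(phi) * sin(lon),
                              rep(sin(phi), n_lon))
  v <- do.call(rbind, lapply(lat, ring)) * radius
  v <- rbind(v, c(0, 0, -radius), c(0, 0, radius))
  nv <- length(lat) * n_lon
  south <- nv + 1L; north <- nv + 2L
  idx <- function(r, j) (r - 1) * n_lon + ((j - 1) %% n_lon) + 1
  j <- seq_len(n_lon)
  fs <- list(cbind(rep(south, n_lon), idx(1, j + 1), idx(1, j)),
             cbind(rep(north, n_lon), idx(length(lat), j), idx(length(lat), j + 1)))
  for (r in seq_len(length(lat) - 1)) {
    fs[[length(fs) + 1]] <- rbind(cbind(idx(r, j), idx(r, j + 1), idx(r + 1, j + 1)),
                                  cbind(idx(r, j), idx(r + 1, j + 1), idx(r + 1, j)))
  }
  m <- mesh_orient_outward(tri_mesh(sweep(v, 2, as.numeric(center), "+"),
                                    do.call(rbind, fs)))
  m
}

#' Capped parametric tube (vessel segment)
#'
#' Surface of a tube around a polyline centreline with a per-station radius,
#' closed with flat end caps, e.g. a blood-pool segment.
#'
#' @param centerline k x 3 matrix (mm).
#' @param radii scalar or length-k vector of radii (mm).
#' @param n_seg circumferential segments.
#' @return A closed [tri_mesh()].
#' @export
mesh_tube_solid <- function(centerline, radii, n_seg = 48) {
  centerline <- as.matrix(centerline)
  k <- nrow(centerline)
  radii <- rep_len(as.numeric(radii), k)
  stopifnot(k >= 2, all(radii > 0))
  # reuse the sweep machinery with varying radius
  m <- mesh_sweep_tube(centerline, 1, n_seg = n_seg, closed = FALSE)
  # rescale each ring: vertices are ring-major, caps appended last
  for (i in seq_len(k)) {
    rows <- (i - 1) * n_seg + seq_len(n_seg)
    ctr <- centerline[i, ]
    m$vertices[rows, ] <- sweep(sweep(m$vertices[rows, , drop = FALSE], 2, ctr, "-") * radii[i],
                                2, ctr, "+")
  }
  m
}
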