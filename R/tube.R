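#' Tubular vessel-wall specification
#'
#' A parametric stand-in for a segmented vessel: a centreline polyline with a
#' per-station inner (blood-pool) radius. The wall is synthesised by
#' offsetting the inner surface outwards by `wall_offset` (default 2 mm),
#' and a lattice is tessellated onto the mid-wall via a UV map whose u/v
#' scale factors are `uv_factor` millimetres per cell (default 2.75 mm).
#'
#' @param centerline k x 3 matrix of stations (mm), k >= 2.
#' @param inner_radius scalar or length-k inner radius profile (mm).
#' @param wall_offset wall thickness in mm (default 2).
#' @param uv_factor UV-map scale, mm of surface per unit cell (default 2.75).
#' @param lattice_thickness strut thickness of the conformal lattice (mm,
#'   default 0.5).
#' @param height_offset radial placement of the lattice within the wall,
#'   0 = inner surface, 1 = outer surface (default 0.5, mid-wall).
#' @return A `tube_wall_spec`.
#' @export
tube_wall_spec <- function(centerline, inner_radius, wall_offset = 2,
                           uv_factor = 2.75, lattice_thickness = 0.5,
                           height_offset = 0.5) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2) stop("centerline needs >= 2 stations", call. = FALSE)
  inner_radius <- rep_len(as.numeric(inner_radius), nrow(centerline))
  if (any(inner_radius <= 0) || wall_offset <= 0 || uv_factor <= 0 ||
      lattice_thickness <= 0 || height_offset < 0 || height_offset > 1) {
    stop("invalid tube wall parameters", call. = FALSE)
  }
  structure(list(centerline = centerline, inner_radius = inner_radius,
                 wall_offset = wall_offset, uv_factor = uv_factor,
                 lattice_thickness = lattice_thickness,
                 height_offset = height_offset),
            class = "tube_wall_spec")
}

# area-weighted outward vertex normals of a closed mesh
vertex_normals <- function(mesh) {
  f <- mesh$faces
  a <- mesh$vertices[f[, 2], , drop = FALSE] - mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 3], , drop = FALSE] - mesh$vertices[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1]) # face normal, |.| = 2 area
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (j in 1:3) {
    for (c in 1:3) {
      vn[, c] <- vn[, c] + unname(tapply(fn[, c], factor(f[, j], levels = seq_len(nrow(vn))),
                                         sum, default = 0))
    }
  }
  vn[is.na(vn)] <- 0
  len <- sqrt(rowSums(vn^2)); len[len == 0] <- 1
  vn / len
}

#' Offset a closed inner surface into a wall solid
#'
#' Pushes every vertex of the (closed, outward-oriented) inner surface along
#' its vertex normal by `offset` and returns the wall solid bounded by the
#' outer surface and the reversed inner surface. Errors if the offset folds
#' the surface over itself (offset exceeding the minimum radius of
#' curvature), detected as flipped outer triangles.
#'
#' @param inner_surface a closed [tri_mesh()] (e.g. a blood-pool model).
#' @param offset wall thickness in mm, > 0.
#' @return A watertight [tri_mesh()] wall solid (outer + inner cavity).
#' @export
offset_wall <- function(inner_surface, offset) {
  if (!is.numeric(offset) || offset <= 0) stop("offset must be > 0", call. = FALSE)
  if (!mesh_is_watertight(inner_surface)) {
    stop("inner surface must be a closed mesh", call. = FALSE)
  }
  vn <- vertex_normals(inner_surface)
  outer <- inner_surface
  outer$vertices <- inner_surface$vertices + offset * vn
  # self-intersection guard: face normals must not flip
  dotn <- function(m) {
    f <- m$faces
    a <- m$vertices[f[, 2], ] - m$vertices[f[, 1], ]
    b <- m$vertices[f[, 3], ] - m$vertices[f[, 1], ]
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  if (any(rowSums(dotn(outer) * dotn(inner_surface)) <= 0)) {
    stop("geometry error: offset exceeds the minimum radius of curvature",
         call. = FALSE)
  }
  inner_rev <- mesh_reverse(inner_surface)
  wall <- mesh_combine(outer, inner_rev)
  wall
}

# arc lengths along a polyline, starting at 0
polyline_arclength <- function(p) {
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}

#' Conformally tessellate the diamond-crystal cell onto a vessel wall
#'
#' Builds a UV map of the mid-wall surface (u = circumferential arc length /
#' `uv_factor`, v = centreline arc length / `uv_factor`), tiles the
#' diamond-crystal skeleton over the whole-cell UV grid and maps every strut
#' end point through (u, v, w) -> (surface point + radial offset), with w
#' spanning the wall interior around `height_offset`. Struts are cylinders of
#' diameter `lattice_thickness`; the lattice lies strictly between the inner
#' and outer wall surfaces.
#'
#' @param cell a diamond-crystal unit cell from [build_unit_cell()] (used for
#'   its spec; the skeleton is rebuilt in UV space).
#' @param wall a [tube_wall_spec()].
#' @return A `lattice_mesh` with attributes `cell_count` and `counts`
#'   (`c(n_u, n_v)`).
#' @export
conformal_tessellate <- function(cell, wall) {
  stopifnot(inherits(wall, "tube_wall_spec"))
  spec <- attr(cell, "spec")
  if (is.null(spec) || spec$kind != "diamond_crystal") {
    stop("conformal tessellation uses the symmetric diamond-crystal cell",
         call. = FALSE)
  }
  cl <- wall$centerline
  s <- polyline_arclength(cl)
  len <- s[length(s)]
  r_mid <- wall$inner_radius + wall$wall_offset / 2
  mean_circ <- 2 * pi * mean(r_mid)
  c_uv <- wall$uv_factor
  n_u <- floor(mean_circ / c_uv + 1e-9)
  n_v <- floor(len / c_uv + 1e-9)
  if (n_u < 1 || n_v < 1) {
    stop("empty lattice: uv_factor larger than the tube dimensions", call. = FALSE)
  }
  if (wall$wall_offset <= wall$lattice_thickness) {
    stop("geometry error: lattice thickness does not fit inside the wall",
         call. = FALSE)
  }

  # diamond-cubic skeleton bonds in the unit cube
  base <- rbind(as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1))),
                c(.5, .5, 0), c(.5, .5, 1), c(.5, 0, .5), c(.5, 1, .5),
                c(0, .5, .5), c(1, .5, .5),
                c(.25, .25, .25), c(.75, .75, .25), c(.75, .25, .75), c(.25, .75, .75))
  colnames(base) <- NULL
  bonds <- list()
  for (i in 15:18) {
    d2 <- rowSums(sweep(base, 2, base[i, ])^2)
    for (j in which(abs(d2 - 3 / 16) < 1e-9)) bonds[[length(bonds) + 1]] <- c(i, j)
  }

  # frames along the centreline (parallel transport, like the tube sweep)
  k <- nrow(cl)
  tangents <- t(vapply(seq_len(k), function(i) {
    a <- cl[max(1, i - 1), ]; b <- cl[min(k, i + 1), ]
    d <- b - a; d / sqrt(sum(d^2))
  }, numeric(3)))
  u0 <- c(0, 0, 1); t1 <- tangents[1, ]
  if (abs(sum(u0 * t1)) > 0.9) u0 <- c(1, 0, 0)
  u0 <- u0 - sum(u0 * t1) * t1; u0 <- u0 / sqrt(sum(u0^2))
  U <- matrix(0, k, 3); U[1, ] <- u0
  for (i in 2:k) {
    ti <- tangents[i, ]
    uu <- U[i - 1, ]; uu <- uu - sum(uu * ti) * ti
    U[i, ] <- uu / sqrt(sum(uu^2))
  }
  map_point <- function(uf, vf, wf) {
    # uf in [0, n_u) cells (wraps), vf in [0, n_v], wf in [0, 1]
    sv <- vf / n_v * len
    i <- findInterval(sv, s, all.inside = TRUE)
    f <- (sv - s[i]) / max(s[i + 1] - s[i], 1e-12)
    ctr <- cl[i, ] * (1 - f) + cl[i + 1, ] * f
    ui <- U[i, ] * (1 - f) + U[i + 1, ] * f; ui <- ui / sqrt(sum(ui^2))
    ti <- tangents[i, ] * (1 - f) + tangents[i + 1, ] * f
    ti <- ti / sqrt(sum(ti^2))
    vi <- pracma_cross(ti, ui)
    rin <- wall$inner_radius[i] * (1 - f) + wall$inner_radius[i + 1] * f
    th <- 2 * pi * uf / n_u
    # radial band available to the lattice mid-line, keeping strut surfaces
    # strictly inside the wall
    band <- wall$wall_offset - wall$lattice_thickness
    r <- rin + wall$lattice_thickness / 2 +
      band * (wall$height_offset + 0.98 * (wf - 0.5))
    ctr + r * (cos(th) * ui + sin(th) * vi)
  }

  cells <- expand.grid(iu = seq_len(n_u) - 1, iv = seq_len(n_v) - 1)
  struts <- vector("list", nrow(cells) * length(bonds))
  idx <- 1
  for (ci in seq_len(nrow(cells))) {
    for (b in bonds) {
      p <- base[b[1], ]; q <- base[b[2], ]
      a1 <- map_point(cells$iu[ci] + p[1], cells$iv[ci] + p[2], p[3])
      a2 <- map_point(cells$iu[ci] + q[1], cells$iv[ci] + q[2], q[3])
      struts[[idx]] <- mesh_cylinder(a1, a2, wall$lattice_thickness / 2, n_seg = 8)
      idx <- idx + 1
    }
  }
  lat <- mesh_combine(struts)
  structure(lat,
            class = c("lattice_mesh", class(lat)),
            cell_count = as.integer(n_u * n_v),
            counts = c(n_u = n_u, n_v = n_v),
            overlap_free = FALSE,
            provenance = list(spec = spec, wall = wall))
}
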