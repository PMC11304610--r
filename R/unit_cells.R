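#' Unit-cell specification
#'
#' Describes one lattice-reinforcement unit cell. The chain and knitted cells
#' derive from a regular hexagonal prism of 5 mm radius and 5 mm height split
#' at mid-height, the origami (Miura-ori) cell from a 5 mm cube, and the
#' diamond crystal from a unit cube; these native sizes set the cell's aspect
#' ratio, which tessellation preserves when it resizes the cell.
#'
#' @param kind one of `"chain"`, `"knitted"`, `"diamond_crystal"`, `"origami"`.
#' @param strut_thickness full strut thickness/diameter in mm (the design
#'   table "Thickness").
#' @param link_gap_ratio chain only: clearance between links over link
#'   length (d/L); default 1/3.
#' @param fold_angle origami only: in-plane herringbone fold angle in
#'   degrees, strictly between 0 and 90; default 60.
#' @param base_dims named list of native dimensions (mm); defaults follow the
#'   construction above.
#' @return An object of class `unit_cell_spec`.
#' @export
unit_cell_spec <- function(kind = c("chain", "knitted", "diamond_crystal", "origami"),
                           strut_thickness = 0.5,
                           link_gap_ratio = 1 / 3,
                           fold_angle = 60,
                           base_dims = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(strut_thickness) || strut_thickness <= 0) {
    stop("strut_thickness must be > 0", call. = FALSE)
  }
  if (kind == "chain" && (link_gap_ratio <= 0 || link_gap_ratio >= 1)) {
    stop("link_gap_ratio must be in (0, 1)", call. = FALSE)
  }
  if (kind == "origami" && (fold_angle <= 0 || fold_angle >= 90)) {
    stop("fold_angle must be in (0, 90) degrees", call. = FALSE)
  }
  if (is.null(base_dims)) {
    base_dims <- switch(kind,
      chain = list(prism_radius = 5, prism_height = 5),
      knitted = list(prism_radius = 5, prism_height = 5),
      origami = list(cube_side = 5),
      diamond_crystal = list(cube_side = 1))
  }
  if (any(unlist(base_dims) <= 0)) stop("base_dims must be positive", call. = FALSE)
  structure(list(kind = kind, strut_thickness = strut_thickness,
                 link_gap_ratio = link_gap_ratio, fold_angle = fold_angle,
                 base_dims = base_dims),
            class = "unit_cell_spec")
}

# regular hexagon, circumradius R; rot = 0 puts vertices on the x axis
hexagon2d <- function(R, rot = 0) {
  th <- rot + 2 * pi * (0:5) / 6
  cbind(R * cos(th), R * sin(th))
}

#' @keywords internal
#' Chain cell: two flat hexagonal links stacked with clearance, the upper one
#' shifted along x so the pair reads as two interlocked links in projection
#' (a flattened chain). size_z is the overall thickened height; the link
#' outer circumradius follows the native prism aspect (radius = height), so
#' it equals size_z. The in-projection clearance between the two links is
#' gap_ratio * L with L the link length (outer flat-to-flat extent).
build_chain_cell <- function(size_z, thickness, gap_ratio) {
  t <- thickness
  if (2 * t >= size_z) stop("thickness too large for chain cell height", call. = FALSE)
  R_out <- size_z                       # native prism radius == height
  R_in <- R_out - 2 * t / sqrt(3)       # perpendicular strut width == t
  if (R_in <= 0) stop("thickness too large for chain link", call. = FALSE)
  zoff <- (size_z - t) / 2              # link mid-planes at +/- zoff
  L <- sqrt(3) * R_out                  # link length (flat-to-flat, x extent)
  d <- gap_ratio * L
  cshift <- 2 * R_in * sqrt(3) / 2 - d  # upper link into the lower one's opening
  rot <- pi / 6                         # flat sides face +/- x
  link <- function(xc, zc) {
    m <- mesh_extrude_annulus(hexagon2d(R_out, rot), hexagon2d(R_in, rot),
                              zc - t / 2, zc + t / 2)
    mesh_translate(m, c(xc, 0, 0))
  }
  mesh_combine(link(0, -zoff), link(cshift, zoff))
}

#' @keywords internal
#' Knitted cell: one jersey (stockinette) loop lying in the slab plane with
#' an out-of-plane undulation, swept with a circular yarn cross-section.
#' Native proportions follow the hexagonal prism: loop width = prism radius,
#' loop height = flat-to-flat span, undulation = prism height.
build_knitted_cell <- function(size_z, thickness, n_path = 72, n_seg = 10) {
  t <- thickness
  if (t >= size_z) stop("thickness too large for knitted cell height", call. = FALSE)
  s <- size_z / 5                       # native prism height 5 -> size_z
  w <- 5 * s - t                        # centreline loop width (x)
  h <- 5 * sqrt(3) * s - t              # centreline loop height (y)
  az <- (size_z - t) / 2                # undulation amplitude (z)
  if (w <= 0 || h <= 0) stop("thickness too large for knitted loop", call. = FALSE)
  th <- 2 * pi * (seq_len(n_path) - 1) / n_path
  path <- cbind((w / 2) * sin(th), (h / 2) * (1 - cos(th)), az * cos(2 * th))
  mesh_sweep_tube(path, t / 2, n_seg = n_seg, closed = TRUE)
}

#' @keywords internal
#' Diamond-crystal cell: the diamond-cubic beam lattice in a cube -- 16
#' tetrahedral bonds between the 18 lattice sites of the conventional cell --
#' with cylindrical struts. size_z is the thickened cube extent.
build_diamond_cell <- function(size_z, thickness, n_seg = 10) {
  t <- thickness
  a <- size_z - t                       # skeleton cube side
  if (a <= 0) stop("thickness too large for diamond cell", call. = FALSE)
  base <- rbind(                        # fractional sites of diamond cubic
    expand.grid(c(0, 1), c(0, 1), c(0, 1)),                    # corners
    c(.5, .5, 0), c(.5, .5, 1), c(.5, 0, .5), c(.5, 1, .5),    # faces
    c(0, .5, .5), c(1, .5, .5),
    c(.25, .25, .25), c(.75, .75, .25), c(.75, .25, .75), c(.25, .75, .75))
  base <- as.matrix(base)
  colnames(base) <- NULL
  interior <- 15:18
  bonds <- list()
  for (i in interior) {
    d2 <- rowSums(sweep(base, 2, base[i, ])^2)
    nb <- which(abs(d2 - 3 / 16) < 1e-9)   # bond length sqrt(3)/4 in fractional units
    for (j in nb) bonds[[length(bonds) + 1]] <- c(i, j)
  }
  pts <- sweep(base, 2, 0.5) * a          # centred skeleton
  struts <- lapply(bonds, function(b) {
    mesh_cylinder(pts[b[1], ], pts[b[2], ], t / 2, n_seg = n_seg)
  })
  m <- mesh_combine(struts)
  # cells tile with pitch = cube side so corner struts of neighbours meet
  attr(m, "nominal_extent") <- rep(size_z, 3)
  m
}

#' @keywords internal
#' Origami cell: Miura-ori folded sheet as a height-field (herringbone
#' arrangement so the cell stays square in plan), thickened vertically. The
#' fold amplitude fills the cell height; fold_angle sets the in-plane zigzag
#' of the fold lines.
build_origami_cell <- function(size_z, thickness, fold_angle = 60, n_grid = 16) {
  t <- thickness
  a <- (size_z - t) / 2                 # fold amplitude
  if (a < 0) stop("thickness larger than cell for origami", call. = FALSE)
  L <- size_z                           # square plan, native cube aspect
  shear <- tan((90 - fold_angle) * pi / 180)
  tri_wave <- function(u) 2 * abs(u - floor(u + 0.5))  # period-1 triangle in [0,1]
  g <- seq(0, L, length.out = n_grid + 1)
  zm <- outer(g, g, function(x, y) {
    # fold lines zigzag in y (herringbone) with slope `shear`
    u <- x / L + 0.5 * shear * tri_wave(y / L)
    a * (2 * tri_wave(u) - 1)
  })
  if (a == 0) zm[] <- 0
  mesh_sheet_solid(g, g, zm, t)
}

#' Build one lattice unit cell
#'
#' Constructs the watertight mesh of one unit cell at its native scale (5 mm
#' prism/cube; unit cube for the diamond crystal), thickened with the spec's
#' strut thickness. The returned mesh carries a `generator` attribute so
#' [tessellate()] can rebuild the cell at the configured size and thickness
#' instead of scaling struts down with the skeleton.
#'
#' @param spec a [unit_cell_spec()].
#' @return A [tri_mesh()] with attributes `spec` and `generator`.
#' @examples
#' cell <- build_unit_cell(unit_cell_spec("origami", strut_thickness = 0.75))
#' mesh_bbox(cell)
#' @export
build_unit_cell <- function(spec) {
  if (!inherits(spec, "unit_cell_spec")) stop("spec must be a unit_cell_spec", call. = FALSE)
  native_z <- switch(spec$kind,
    chain = spec$base_dims$prism_height,
    knitted = spec$base_dims$prism_height,
    origami = spec$base_dims$cube_side,
    diamond_crystal = spec$base_dims$cube_side)
  if (spec$strut_thickness >= native_z) {
    stop("degenerate thickness: strut thickness must be smaller than the cell",
         call. = FALSE)
  }
  gen <- switch(spec$kind,
    chain = function(size_z, thickness) {
      build_chain_cell(size_z, thickness, spec$link_gap_ratio)
    },
    knitted = function(size_z, thickness) build_knitted_cell(size_z, thickness),
    diamond_crystal = function(size_z, thickness) build_diamond_cell(size_z, thickness),
    origami = function(size_z, thickness) {
      build_origami_cell(size_z, thickness, spec$fold_angle)
    })
  mesh <- gen(native_z, spec$strut_thickness)
  attr(mesh, "spec") <- spec
  attr(mesh, "generator") <- gen
  attr(mesh, "overlap_free") <- spec$kind != "diamond_crystal"
  mesh
}

# cell extent used for grid pitch: the generator's declared tiling extent if
# any, otherwise the mesh bounding-box extent
cell_extent <- function(mesh) {
  nom <- attr(mesh, "nominal_extent")
  if (!is.null(nom)) return(nom)
  bb <- mesh_bbox(mesh)
  bb[2, ] - bb[1, ]
}
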