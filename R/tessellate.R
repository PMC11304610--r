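#' Tessellation configuration and matrix slab
#'
#' `tessellation_config()` mirrors the design-table controls: the unit cell
#' is uniformly resized so its z extent equals `size_z` (aspect ratio
#' preserved), struts are thickened to `thickness`, and copies are placed on
#' a regular grid with pitch = cell extent + `spacing` per axis.
#' `matrix_slab()` is the rectangular base body the lattice reinforces; the
#' default dimensions are the printed tensile specimen (64.10 x 10.13 x
#' 2.60 mm).
#'
#' @param size_z target cell height in mm.
#' @param spacing numeric length-3, empty space between cells (mm).
#' @param thickness strut thickness in mm.
#' @param keep_aspect_ratio must be `TRUE` (uniform resize); kept explicit to
#'   mirror the design-table switch.
#' @return A `tessellation_config` / `matrix_slab` object.
#' @export
tessellation_config <- function(size_z, spacing = c(0, 0, 0), thickness,
                                keep_aspect_ratio = TRUE) {
  spacing <- rep_len(as.numeric(spacing), 3)
  if (size_z <= 0 || thickness <= 0 || any(spacing < 0)) {
    stop("size_z and thickness must be > 0 and spacing >= 0", call. = FALSE)
  }
  if (!isTRUE(keep_aspect_ratio)) {
    stop("only keep_aspect_ratio = TRUE resizing is supported", call. = FALSE)
  }
  structure(list(size_z = size_z, spacing = spacing, thickness = thickness,
                 keep_aspect_ratio = TRUE),
            class = "tessellation_config")
}

#' @rdname tessellation_config
#' @param length,width,height slab dimensions in mm.
#' @param material_id matrix material label (e.g. `"SHA30"`, `"T600"`).
#' @export
matrix_slab <- function(length = 64.10, width = 10.13, height = 2.60,
                        material_id = "SHA30") {
  if (any(c(length, width, height) <= 0)) stop("slab dimensions must be > 0", call. = FALSE)
  structure(list(length = length, width = width, height = height,
                 material_id = material_id),
            class = "matrix_slab")
}

slab_dims <- function(slab) c(slab$length, slab$width, slab$height)

#' @rdname tessellation_config
#' @param slab a [matrix_slab()].
#' @export
slab_mesh <- function(slab) {
  mesh_box(c(0, 0, 0), slab_dims(slab))
}

#' @rdname tessellation_config
#' @export
slab_volume <- function(slab) prod(slab_dims(slab))

#' Analytic tessellation cell counts
#'
#' Number of whole cells per axis: the largest n with
#' n * cell + (n - 1) * spacing <= slab, i.e.
#' `floor((slab + spacing) / (cell + spacing))` -- trailing inter-cell
#' spacing does not need to fit.
#'
#' @param cell_extent,spacing,slab_extent numeric length-3 (mm).
#' @return Integer length-3 counts.
#' @export
tessellation_counts <- function(cell_extent, spacing, slab_extent) {
  n <- floor((slab_extent + spacing) / (cell_extent + spacing) + 1e-9)
  as.integer(pmax(0, n))
}

#' Tessellate a unit cell into a matrix slab
#'
#' Resizes the cell so its z extent equals `config$size_z` (keeping aspect
#' ratio; when the cell carries its parametric generator the skeleton is
#' rebuilt at target size and the struts are thickened to `config$thickness`
#' in final millimetres), then places copies on a regular grid. Only cells
#' that fit entirely inside the slab are kept; the grid is centred.
#'
#' @param cell a unit-cell mesh from [build_unit_cell()] (or any watertight
#'   mesh, which is then purely rescaled).
#' @param config a [tessellation_config()].
#' @param slab a [matrix_slab()].
#' @return A `lattice_mesh`: a [tri_mesh()] with attributes `cell_count`,
#'   `counts` (per axis), `cell_volume` (union volume of one cell, mm^3),
#'   `overlap_free` and `provenance`.
#' @export
tessellate <- function(cell, config, slab) {
  stopifnot(inherits(config, "tessellation_config"), inherits(slab, "matrix_slab"))
  gen <- attr(cell, "generator")
  if (!is.null(gen)) {
    unit <- gen(config$size_z, config$thickness)
  } else {
    if (!mesh_is_watertight(cell)) stop("cell mesh must be watertight", call. = FALSE)
    bb <- mesh_bbox(cell)
    s <- config$size_z / (bb[2, 3] - bb[1, 3])
    unit <- mesh_scale(cell, s)
  }
  bb <- mesh_bbox(unit)
  ext <- cell_extent(unit)
  S <- slab_dims(slab)
  n <- tessellation_counts(ext, config$spacing, S)
  if (any(n < 1)) {
    stop("empty lattice: no unit cell fits inside the slab with this configuration",
         call. = FALSE)
  }
  pitch <- ext + config$spacing
  span <- n * ext + (n - 1) * config$spacing
  # centre the grid; each copy sits centred in its nominal cell box
  origin <- (S - span) / 2 + (ext - (bb[2, ] - bb[1, ])) / 2 - bb[1, ]
  overlap_free <- isTRUE(attr(cell, "overlap_free"))
  cell_volume <- if (overlap_free) mesh_volume(unit) else mesh_volume_voxel(unit, 0.02)

  offs <- as.matrix(expand.grid(x = seq_len(n[1]) - 1, y = seq_len(n[2]) - 1,
                                z = seq_len(n[3]) - 1))
  copies <- lapply(seq_len(nrow(offs)), function(i) {
    mesh_translate(unit, origin + offs[i, ] * pitch)
  })
  lat <- mesh_combine(copies)
  structure(lat,
            class = c("lattice_mesh", class(lat)),
            cell_count = as.integer(nrow(offs)),
            counts = n,
            cell_volume = cell_volume,
            overlap_free = overlap_free,
            provenance = list(spec = attr(cell, "spec"), config = config, slab = slab))
}

#' Lattice volume
#'
#' Volume of the union of all lattice cells (mm^3). For overlap-free cell
#' kinds this is the exact divergence-theorem volume; for cells with struts
#' meeting at shared nodes (diamond crystal) it is the per-cell column-ray
#' union volume times the cell count (cells of a tessellation are disjoint
#' translates).
#'
#' @param lattice a `lattice_mesh` from [tessellate()].
#' @return Volume in mm^3.
#' @export
lattice_volume <- function(lattice) {
  cv <- attr(lattice, "cell_volume")
  n <- attr(lattice, "cell_count")
  if (!is.null(cv) && !is.null(n)) return(cv * n)
  mesh_volume(lattice)
}

#' Lattice volume fraction
#'
#' Lattice volume over full slab volume, as a fraction in `[0, 1]`
#' (multiply by 100 for the design-table percentage).
#'
#' @param lattice a `lattice_mesh`.
#' @param slab a [matrix_slab()]; defaults to the lattice's provenance slab.
#' @return Fraction in `[0, 1]`.
#' @export
volume_fraction <- function(lattice, slab = NULL) {
  if (is.null(slab)) slab <- attr(lattice, "provenance")$slab
  stopifnot(inherits(slab, "matrix_slab"))
  if (nrow(lattice$faces) == 0) return(0)
  v <- lattice_volume(lattice)
  if (v < 0) stop("negative mesh volume: orientation flipped", call. = FALSE)
  v / slab_volume(slab)
}

#' Embed a lattice in its matrix slab
#'
#' Boolean difference of the slab and the lattice: because every lattice
#' cell lies strictly inside the slab, the difference is represented exactly
#' as the slab boundary plus the reversed lattice boundary (internal
#' cavities). Volumes are additive: matrix + lattice = slab.
#'
#' @param lattice a `lattice_mesh`.
#' @param slab a [matrix_slab()].
#' @param matrix_material,lattice_material material labels.
#' @return A `composite_sample` list with `matrix_mesh`, `lattice_mesh`,
#'   material labels and the computed volumes (mm^3).
#' @export
embed_lattice <- function(lattice, slab, matrix_material = "T600",
                          lattice_material = "SHA85") {
  stopifnot(inherits(slab, "matrix_slab"))
  S <- slab_dims(slab)
  if (nrow(lattice$faces) > 0) {
    bb <- mesh_bbox(lattice)
    if (any(bb[1, ] < -1e-9) || any(bb[2, ] > S + 1e-9)) {
      stop("lattice does not fit inside the slab", call. = FALSE)
    }
    if (!mesh_is_watertight(lattice)) {
      stop("mesh error: lattice is not watertight, cannot take Boolean difference",
           call. = FALSE)
    }
  }
  lat_vol <- if (nrow(lattice$faces) == 0) 0 else lattice_volume(lattice)
  matrix_mesh <- mesh_combine(slab_mesh(slab), mesh_reverse(lattice))
  structure(list(matrix_mesh = matrix_mesh,
                 lattice_mesh = lattice,
                 matrix_material = matrix_material,
                 lattice_material = lattice_material,
                 slab = slab,
                 matrix_volume = slab_volume(slab) - lat_vol,
                 lattice_volume = lat_vol),
            class = "composite_sample")
}

#' @export
print.composite_sample <- function(x, ...) {
  cat(sprintf("<composite_sample> matrix %s (%.2f mm^3) + lattice %s (%.2f mm^3)\n",
              x$matrix_material, x$matrix_volume, x$lattice_material, x$lattice_volume))
  invisible(x)
}

#' Bundled tessellation design table
#'
#' The four lattice-reinforcement designs with their tessellation settings
#' and the reported percentage of slab volume each occupies.
#'
#' @return A tibble with one row per design.
#' @export
lattice_design_table <- function() {
  tibble::tibble(
    kind = c("chain", "knitted", "diamond_crystal", "origami"),
    size_z = c(1.5, 2.0, 2.0, 1.5),
    spacing_x = c(0, 0, 0, 0),
    spacing_y = c(1, 0, 0, 0),
    spacing_z = c(1, 1, 0, 1),
    thickness = c(0.6, 0.3, 0.3, 0.75),
    reported_volume_pct = c(12.81, 3.19, 7.58, 25.33)
  )
}

#' Build one design-table lattice end to end
#'
#' Convenience wrapper: spec -> unit cell -> tessellation for one row of
#' [lattice_design_table()].
#'
#' @param kind design kind (row of the table).
#' @param slab a [matrix_slab()].
#' @return A `lattice_mesh`.
#' @export
build_design_lattice <- function(kind, slab = matrix_slab()) {
  row <- dplyr::filter(lattice_design_table(), .data$kind == .env$kind)
  if (nrow(row) != 1) stop("unknown design kind: ", kind, call. = FALSE)
  spec <- unit_cell_spec(kind, strut_thickness = row$thickness)
  cfg <- tessellation_config(row$size_z,
                             c(row$spacing_x, row$spacing_y, row$spacing_z),
                             row$thickness)
  tessellate(build_unit_cell(spec), cfg, slab)
}
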