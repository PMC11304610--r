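test_that("origami design tessellates to the analytic (42, 6, 1) grid", {
  slab <- matrix_slab()                  # 64.10 x 10.13 x 2.60
  cell <- build_unit_cell(unit_cell_spec("origami", strut_thickness = 0.75))
  cfg <- tessellation_config(1.5, c(0, 0, 1), 0.75)
  lat <- tessellate(cell, cfg, slab)
  expect_equal(unname(attr(lat, "counts")), c(42L, 6L, 1L))
  expect_equal(attr(lat, "cell_count"), 252L)
})

test_that("diamond-crystal design uses grid pitch 2.0 mm in all axes", {
  cell <- build_unit_cell(unit_cell_spec("diamond_crystal", strut_thickness = 0.3))
  lat <- tessellate(cell, tessellation_config(2.0, c(0, 0, 0), 0.3), matrix_slab())
  expect_equal(unname(attr(lat, "counts")),
               unname(tessellation_counts(c(2, 2, 2), c(0, 0, 0),
                                          c(64.10, 10.13, 2.60))))
  # neighbouring cells are translates by exactly 2.0 mm along x
  v1 <- lat$vertices[lat$faces[lat$part %in% 1:16, ], ]
  v2 <- lat$vertices[lat$faces[lat$part %in% 17:32, ], ]
  expect_equal(unname(v2), unname(sweep(v1, 2, c(2, 0, 0), "+")), tolerance = 1e-9)
  expect_equal(unname(attr(lat, "counts"))[1], 32L)
})

test_that("cell counts equal the floor-division formula across configurations", {
  slab_ext <- c(64.10, 10.13, 2.60)
  cases <- expand.grid(ext = c(1.3, 2.0, 3.7), sp = c(0, 0.5, 1))
  for (i in seq_len(nrow(cases))) {
    ext <- rep(cases$ext[i], 3); sp <- rep(cases$sp[i], 3)
    n <- tessellation_counts(ext, sp, slab_ext)
    # oracle: largest n such that n*ext + (n-1)*sp fits
    oracle <- vapply(1:3, function(k) {
      n_try <- 0
      while ((n_try + 1) * ext[k] + n_try * sp[k] <= slab_ext[k] + 1e-9) {
        n_try <- n_try + 1
      }
      n_try
    }, numeric(1))
    expect_equal(unname(n), as.integer(oracle))
  }
})

test_that("a cell filling the slab tessellates to a single copy", {
  slab <- matrix_slab(10, 5, 2)
  cell <- mesh_box(c(0, 0, 0), c(10, 5, 2))
  lat <- tessellate(cell, tessellation_config(2, c(0, 0, 0), 0.5), slab)
  expect_equal(attr(lat, "cell_count"), 1L)
  expect_equal(volume_fraction(lat, slab), 1, tolerance = 1e-6)
})

test_that("tessellation that fits no cell raises the empty-lattice error", {
  cell <- build_unit_cell(unit_cell_spec("knitted", strut_thickness = 0.3))
  expect_error(
    tessellate(cell, tessellation_config(5.0, c(0, 0, 0), 0.3), matrix_slab()),
    "empty lattice")
})

test_that("all placed cells lie inside the slab", {
  slab <- matrix_slab()
  for (k in c("chain", "origami")) {
    lat <- build_design_lattice(k, slab)
    bb <- mesh_bbox(lat)
    expect_true(all(bb[1, ] >= -1e-9))
    expect_true(all(bb[2, ] <= c(slab$length, slab$width, slab$height) + 1e-9))
  }
})

test_that("embedding conserves volume: matrix + lattice = slab", {
  slab <- matrix_slab()
  lat <- build_design_lattice("chain", slab)
  cs <- embed_lattice(lat, slab)
  rel_err <- abs(mesh_volume(cs$matrix_mesh) + mesh_volume(lat) -
                 slab_volume(slab)) / slab_volume(slab)
  expect_lt(rel_err, 1e-4)
  expect_true(mesh_is_watertight(cs$matrix_mesh))
  # matrix volume = slab * (1 - volume fraction)
  expect_equal(cs$matrix_volume,
               slab_volume(slab) * (1 - volume_fraction(lat, slab)),
               tolerance = 1e-9)
})

test_that("degenerate embeddings behave: empty lattice and slab-filling lattice", {
  slab <- matrix_slab(10, 5, 2)
  empty <- structure(tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)),
                     class = c("lattice_mesh", "tri_mesh"))
  cs <- embed_lattice(empty, slab)
  expect_equal(cs$matrix_volume, slab_volume(slab))
  expect_equal(volume_fraction(empty, slab), 0)

  full <- tessellate(mesh_box(c(0, 0, 0), c(10, 5, 2)),
                     tessellation_config(2, c(0, 0, 0), 0.5), slab)
  cs2 <- embed_lattice(full, slab)
  expect_equal(cs2$matrix_volume, 0, tolerance = 1e-4)
})

test_that("a lattice poking out of the slab is rejected", {
  slab <- matrix_slab(10, 5, 2)
  big <- tessellate(mesh_box(c(0, 0, 0), c(12, 5, 2)),
                    tessellation_config(2, c(0, 0, 0), 0.5), matrix_slab(12, 5, 2))
  expect_error(embed_lattice(big, slab), "does not fit")
})

test_that("volume fraction is monotone in strut thickness for each design", {
  slab <- matrix_slab()
  for (k in c("chain", "knitted", "diamond_crystal", "origami")) {
    row <- lattice_design_table()[lattice_design_table()$kind == k, ]
    vfs <- vapply(c(0.85, 1, 1.15) * row$thickness, function(th) {
      spec <- unit_cell_spec(k, strut_thickness = th)
      cfg <- tessellation_config(row$size_z,
                                 c(row$spacing_x, row$spacing_y, row$spacing_z), th)
      volume_fraction(tessellate(build_unit_cell(spec), cfg, slab), slab)
    }, numeric(1))
    expect_true(all(diff(vfs) > 0), label = paste(k, "fraction monotone"))
  }
})
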