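#' Write a mesh to STL
#'
#' Writes binary (default) or ASCII STL in millimetres with facet normals
#' recomputed from the right-hand winding. A non-watertight mesh is written
#' with a warning and flagged in the returned metadata.
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @param ascii write ASCII STL instead of binary.
#' @return Invisibly, a list with `path`, `n_facets` and `watertight`.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  wt <- mesh_is_watertight(mesh)
  if (!wt) warning("mesh is not watertight; STL written anyway", call. = FALSE)
  f <- mesh$faces
  v1 <- mesh$vertices[f[, 1], , drop = FALSE]
  v2 <- mesh$vertices[f[, 2], , drop = FALSE]
  v3 <- mesh$vertices[f[, 3], , drop = FALSE]
  a <- v2 - v1; b <- v3 - v1
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  n <- nrow(f)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid aortamimic", con)
    for (i in seq_len(n)) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e", v1[i, 1], v1[i, 2], v1[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", v2[i, 1], v2[i, 2], v2[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", v3[i, 1], v3[i, 2], v3[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid aortamimic", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("aortamimic binary STL (mm)", width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    # interleave: normal, v1, v2, v3 (floats), attribute count (uint16)
    block <- t(cbind(nrm, v1, v2, v3))
    for (i in seq_len(n)) {
      writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(list(path = path, n_facets = n, watertight = wt))
}

#' Read an STL file
#'
#' Reads binary or ASCII STL (auto-detected). Vertices are not merged; each
#' facet contributes three vertices, which preserves the facet count exactly.
#'
#' @param path STL file path.
#' @return A [tri_mesh()].
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 512)
  close(con)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    grepl("facet", rawToChar(head[head != as.raw(0)]), fixed = TRUE)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) {
      as.numeric(x[2:4])
    }))
    v <- nums
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    rec <- readBin(con, "raw", n * 50)
    # each record: 12 floats (48 bytes) + uint16
    keep <- rep(rep(c(TRUE, FALSE), c(48, 2)), n)
    vals <- readBin(rec[keep], "numeric", n * 12, size = 4, endian = "little")
    m <- matrix(vals, ncol = 12, byrow = TRUE)
    v <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE], m[, 10:12, drop = FALSE])
    v <- v[rep(seq_len(n), each = 3) + c(0, n, 2 * n), , drop = FALSE]
    v <- matrix(0, 3 * n, 3)
    v[seq(1, 3 * n, 3), ] <- m[, 4:6, drop = FALSE]
    v[seq(2, 3 * n, 3), ] <- m[, 7:9, drop = FALSE]
    v[seq(3, 3 * n, 3), ] <- m[, 10:12, drop = FALSE]
  }
  nf <- nrow(v) / 3
  tri_mesh(v, matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
}
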