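#' Read an STL surface mesh
#'
#' Handles both the binary and ASCII dialects. STL stores three explicit
#' vertices per facet; identical coordinates are welded back into shared
#' vertices deterministically (first-occurrence order), so a
#' write-then-read round trip preserves coordinates to 32-bit float
#' precision and face topology up to that canonical de-duplication.
#'
#' @param path STL file path.
#' @return a [triangle_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("STL file does not exist: ", path)
  size <- file.size(path)
  is_binary <- FALSE
  if (size >= 84) {
    con <- file(path, "rb")
    invisible(readBin(con, "raw", 80L))
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    close(con)
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  mesh <- if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
  message(sprintf("read STL %s: %d vertices, %d faces", path,
                  nrow(mesh$vertices), nrow(mesh$faces)))
  mesh
}

read_stl_binary <- function(path) {
  size <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  expected <- 84 + 50 * as.numeric(ntri)
  if (size < expected)
    stop(sprintf("malformed binary STL %s: expected %.0f bytes, file truncated at byte %.0f",
                 path, expected, size))
  payload <- readBin(con, "raw", 50L * ntri)
  rec <- matrix(payload, nrow = 50L)
  floats <- readBin(as.raw(rec[1:48, ]), "double", n = 12L * ntri,
                    size = 4L, endian = "little")
  fm <- matrix(floats, nrow = 12L)       # per facet: normal, v1, v2, v3
  tri_vertices <- matrix(as.numeric(fm[4:12, ]), ncol = 3L, byrow = TRUE)
  weld_tri_soup(tri_vertices)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^\\s*solid", lines[1]))
    stop("malformed STL ", path, ": not binary-sized and no ASCII 'solid' header at byte 0")
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
    stop("malformed ASCII STL ", path, ": vertex count not a multiple of 3")
  nums <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  if (any(!is.finite(nums))) stop("malformed ASCII STL ", path,
                                  ": non-numeric vertex coordinates")
  weld_tri_soup(nums)
}

# triangle soup (3 rows per facet) -> welded triangle_mesh; first-occurrence
# vertex order, facet order preserved
weld_tri_soup <- function(tri_vertices) {
  key <- paste(tri_vertices[, 1], tri_vertices[, 2], tri_vertices[, 3],
               sep = "|")
  first <- !duplicated(key)
  vertices <- tri_vertices[first, , drop = FALSE]
  idx <- match(key, key[first])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  keep <- faces[, 1L] != faces[, 2L] & faces[, 2L] != faces[, 3L] &
    faces[, 1L] != faces[, 3L]
  triangle_mesh(vertices, faces[keep, , drop = FALSE])
}

#' Write a mesh to STL
#'
#' Binary by default; `binary = FALSE` writes the ASCII dialect. Facet
#' normals are recomputed from the winding.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param binary write binary STL (default `TRUE`).
#' @return the path, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  stopifnot(is_triangle_mesh(mesh))
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c3 - a
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(nrow(f), con, size = 4L, endian = "little")
    # per facet: normal, v1, v2, v3 as float32 then a zero attribute word
    block <- t(cbind(n, a, b, c3))          # 12 floats per facet, by column
    fl <- writeBin(as.numeric(block), raw(), size = 4L, endian = "little")
    fl <- matrix(fl, nrow = 48L)
    out <- rbind(fl, matrix(as.raw(0L), nrow = 2L, ncol = nrow(f)))
    writeBin(as.vector(out), con)
  } else {
    fmt_pt <- function(m) sprintf("      vertex %.9g %.9g %.9g",
                                  m[, 1], m[, 2], m[, 3])
    txt <- c("solid kneeval",
             as.vector(rbind(sprintf("  facet normal %.9g %.9g %.9g",
                                     n[, 1], n[, 2], n[, 3]),
                             "    outer loop",
                             fmt_pt(a), fmt_pt(b), fmt_pt(c3),
                             "    endloop",
                             "  endfacet")),
             "endsolid kneeval")
    writeLines(txt, path)
  }
  message(sprintf("wrote STL %s: %d vertices, %d faces (%s)", path,
                  nrow(v), nrow(f), if (binary) "binary" else "ascii"))
  invisible(path)
}
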