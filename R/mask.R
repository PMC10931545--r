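#' Binary volumetric segmentation mask
#'
#' A 3D voxel grid with physical spacing and origin. Grid values are
#' binarized on construction: any nonzero voxel is foreground. Grid axis i
#' advances along patient axis i (x, y, z) at `spacing[i]` mm per voxel;
#' `origin` is the physical position of voxel (1, 1, 1).
#'
#' @param grid 3D array (logical or numeric; nonzero = foreground).
#' @param spacing length-3 voxel size in mm, all components > 0.
#' @param origin length-3 position of the first voxel centre (mm).
#' @param orientation axis-orientation label carried from file headers
#'   (default "RAS"-style identity mapping).
#' @return an object of class `volumetric_mask`.
#' @export
volumetric_mask <- function(grid, spacing, origin = c(0, 0, 0),
                            orientation = "RAS") {
  stopifnot(length(dim(grid)) == 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive voxel sizes in mm")
  stopifnot(length(origin) == 3L)
  g <- array(grid != 0, dim = dim(grid))
  structure(list(grid = g, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "volumetric_mask")
}

#' @export
print.volumetric_mask <- function(x, ...) {
  cat(sprintf("volumetric_mask: %s voxels, spacing (%.3g, %.3g, %.3g) mm, %d foreground\n",
              paste(dim(x$grid), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3], sum(x$grid)))
  invisible(x)
}

#' Count of foreground voxels
#' @param mask a [volumetric_mask()].
#' @return integer count.
#' @export
mask_foreground_count <- function(mask) sum(mask$grid)

#' Load a volumetric segmentation mask
#'
#' Reads NIfTI (`.nii`, `.nii.gz`) through RNifti or NRRD (`.nrrd`,
#' `.nhdr` with attached data) through the built-in reader. Header spacing
#' and origin are honored; files whose headers carry no voxel-size
#' information are rejected rather than silently assumed isotropic.
#'
#' @param path file path.
#' @return a [volumetric_mask()].
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("mask file does not exist: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  mask <- if (ext == "nii") {
    load_mask_nifti(path)
  } else if (tolower(tools::file_ext(path)) %in% c("nrrd", "nhdr")) {
    load_mask_nrrd(path)
  } else {
    stop("unrecognized volumetric format (expected NIfTI or NRRD): ", path)
  }
  message(sprintf("loaded mask %s: %s voxels, %d foreground", path,
                  paste(dim(mask$grid), collapse = "x"),
                  mask_foreground_count(mask)))
  mask
}

load_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3L || any(!is.finite(spacing[1:3])) ||
        any(spacing[1:3] <= 0))
    stop("NIfTI header carries no usable voxel spacing (anisotropy unknown): ",
         path)
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- c(0, 0, 0)
  orientation <- "RAS"
  if (!inherits(xf, "try-error") && is.matrix(xf) && all(dim(xf) == c(4L, 4L))) {
    origin <- as.numeric(xf[1:3, 4])
    orientation <- tryCatch(RNifti::orientation(xf), error = function(e) "RAS")
  }
  volumetric_mask(array(as.array(img) != 0, dim = dim(img)),
                  spacing = spacing[1:3], origin = origin,
                  orientation = orientation)
}

#' Write a mask to NIfTI
#'
#' @param mask a [volumetric_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  arr <- array(as.integer(mask$grid), dim = dim(mask$grid))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- mask$spacing
  xf <- diag(4)
  diag(xf)[1:3] <- mask$spacing
  xf[1:3, 4] <- mask$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  message(sprintf("wrote mask %s: %s voxels", path,
                  paste(dim(arr), collapse = "x")))
  invisible(path)
}

# Minimal NRRD reader: detached headers are not supported; encodings raw,
# gzip and ascii are. Written against the NRRD0004 field set actually used
# by segmentation tools (type/dimension/sizes/encoding/endian/spacings or
# space directions/space origin).
load_mask_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("NRRD header ended without data: ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  dimn <- as.integer(fields[["dimension"]])
  if (is.na(dimn) || dimn != 3L) stop("expected a 3D NRRD volume: ", path)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  stopifnot(length(sizes) == 3L)
  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    spacing <- vapply(vecs, function(v) {
      comp <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
      sqrt(sum(comp^2))
    }, numeric(1), USE.NAMES = FALSE)
  }
  if (is.null(spacing) || length(spacing) != 3L || any(!is.finite(spacing)))
    stop("NRRD header carries no voxel spacing (anisotropy unknown): ", path)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]),
                                  ",")[[1]])
  typ <- tolower(fields[["type"]])
  enc <- tolower(fields[["encoding"]])
  n <- prod(sizes)
  read_typed <- function(raw_vec) {
    endian <- if (identical(fields[["endian"]], "big")) "big" else "little"
    if (typ %in% c("uchar", "unsigned char", "uint8", "uint8_t")) {
      as.integer(raw_vec)
    } else if (typ %in% c("short", "int16", "int16_t", "signed short")) {
      readBin(raw_vec, "integer", n = n, size = 2L, signed = TRUE,
              endian = endian)
    } else if (typ %in% c("ushort", "uint16", "uint16_t", "unsigned short")) {
      readBin(raw_vec, "integer", n = n, size = 2L, signed = FALSE,
              endian = endian)
    } else if (typ %in% c("int", "int32", "int32_t", "signed int")) {
      readBin(raw_vec, "integer", n = n, size = 4L, endian = endian)
    } else if (typ %in% c("float")) {
      readBin(raw_vec, "double", n = n, size = 4L, endian = endian)
    } else if (typ %in% c("double")) {
      readBin(raw_vec, "double", n = n, size = 8L, endian = endian)
    } else {
      stop("unsupported NRRD type: ", typ)
    }
  }
  type_size <- if (typ %in% c("uchar", "unsigned char", "uint8", "uint8_t")) 1L
    else if (typ %in% c("short", "int16", "int16_t", "signed short",
                        "ushort", "uint16", "uint16_t", "unsigned short")) 2L
    else if (typ %in% c("int", "int32", "int32_t", "signed int", "float")) 4L
    else 8L
  vals <- if (enc %in% c("raw")) {
    read_typed(readBin(con, "raw", n = n * type_size))
  } else if (enc %in% c("gzip", "gz")) {
    rest <- readBin(con, "raw", n = file.size(path))
    read_typed(memDecompress(rest, type = "gzip"))
  } else if (enc %in% c("ascii", "text", "txt")) {
    scan(con, what = numeric(), n = n, quiet = TRUE)
  } else {
    stop("unsupported NRRD encoding: ", enc)
  }
  if (length(vals) < n) stop("NRRD data truncated: ", path)
  volumetric_mask(array(vals[seq_len(n)], dim = sizes), spacing = spacing,
                  origin = origin, orientation = "RAS")
}

# Separable Gaussian filter on a 3D array, replicate-padded borders.
# Kernel radius 3*sigma (min 1); sigma in voxels.
smooth_field_gaussian <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  w <- w / sum(w)
  shift_axis <- function(a, s, axis) {
    n <- dim(a)[axis]
    idx <- pmin(pmax(seq_len(n) + s, 1L), n)
    switch(axis,
           a[idx, , , drop = FALSE],
           a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  for (axis in 1:3) {
    out <- array(0, dim = dim(arr))
    for (s in seq(-r, r)) out <- out + w[s + r + 1L] * shift_axis(arr, s, axis)
    arr <- out
  }
  arr
}

#' Voxelize a closed mesh into a binary mask
#'
#' Parity counting along z columns of a regular grid. Used by the synthetic
#' cohort generator to produce ground-truth segmentation volumes from
#' generated surfaces.
#'
#' @param mesh a closed [triangle_mesh()].
#' @param spacing voxel size in mm (scalar or length 3).
#' @param padding voxels of empty margin around the mesh bounding box.
#' @return a [volumetric_mask()].
#' @export
voxelize_mesh <- function(mesh, spacing = 0.5, padding = 2L) {
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  bb <- mesh_bbox(mesh)
  origin <- bb[1L, ] - padding * spacing
  dims <- as.integer(ceiling((bb[2L, ] - origin) / spacing)) + padding + 1L
  grid <- .voxelize_mesh_cpp(mesh$vertices, mesh$faces, origin, spacing, dims)
  volumetric_mask(grid, spacing = spacing, origin = origin)
}
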