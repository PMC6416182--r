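#' Colored point cloud
#'
#' A minimal container for one scan scene or one plant: an `n x 3` matrix of
#' positions (meters, z up) and an `n x 3` matrix of RGB colors in 0--255.
#'
#' @param positions numeric `n x 3` matrix of xyz coordinates (meters).
#' @param colors numeric `n x 3` matrix of RGB values in `[0, 255]`.
#' @return An object of class `point_cloud` with elements `positions`,
#'   `colors` and `n`.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), 10), matrix(128, 10, 3))
#' pc
#' @export
point_cloud <- function(positions, colors) {
  positions <- as.matrix(positions)
  colors <- as.matrix(colors)
  storage.mode(positions) <- "double"
  storage.mode(colors) <- "double"
  if (nrow(positions) < 1) stop("a point cloud needs at least one point")
  if (ncol(positions) != 3) stop("positions must have three columns")
  if (!all(dim(colors) == dim(positions)))
    stop("colors must match positions: one RGB triple per point")
  if (any(!is.finite(positions))) stop("positions contain non-finite values")
  if (any(colors < 0 | colors > 255 | !is.finite(colors)))
    stop("colors must lie in [0, 255]")
  dimnames(positions) <- NULL
  dimnames(colors) <- NULL
  structure(list(positions = positions, colors = colors, n = nrow(positions)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  rng <- apply(x$positions, 2, range)
  cat(sprintf("point_cloud: %d points\n", x$n))
  cat(sprintf("  bbox  x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f] (m)\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  cat(sprintf("  bbox diagonal %.3f m\n", bbox_diagonal(x)))
  invisible(x)
}

#' @export
plot.point_cloud <- function(x, which = c("xz", "xy", "yz"), cex = 0.2, ...) {
  which <- match.arg(which)
  ax <- strsplit(which, "")[[1]]
  idx <- match(ax, c("x", "y", "z"))
  col <- grDevices::rgb(x$colors[, 1], x$colors[, 2], x$colors[, 3],
                        maxColorValue = 255)
  plot(x$positions[, idx[1]], x$positions[, idx[2]], col = col, pch = 16,
       cex = cex, asp = 1, xlab = ax[1], ylab = ax[2], ...)
  invisible(x)
}

# subset a cloud by point index
cloud_subset <- function(cloud, idx) {
  if (length(idx) == 0) {
    return(structure(list(positions = matrix(0, 0, 3),
                          colors = matrix(0, 0, 3), n = 0L),
                     class = "point_cloud"))
  }
  point_cloud(cloud$positions[idx, , drop = FALSE],
              cloud$colors[idx, , drop = FALSE])
}

#' Length of the main bounding-box diagonal
#'
#' Euclidean length of the axis-aligned bounding-box diagonal of a cloud;
#' used as the scale reference for radius parameters throughout the pipeline.
#'
#' @param cloud a [point_cloud], or a bare `n x 3` coordinate matrix.
#' @return Length in meters; 0 for a single point.
#' @export
bbox_diagonal <- function(cloud) {
  P <- as_xyz_matrix(cloud)
  if (nrow(P) < 1) stop("empty cloud")
  sqrt(sum((apply(P, 2, max) - apply(P, 2, min))^2))
}

# ---------------------------------------------------------------------------
# readers / writers

#' Read a colored point cloud
#'
#' Reads PLY (ASCII or binary little-endian with `x y z red green blue`
#' vertex properties), PCD (ASCII, `FIELDS x y z rgb`) or whitespace-delimited
#' `x y z r g b` text. Files without color are rejected unless `default_color`
#' supplies an RGB triple.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"ply"`, `"pcd"`, `"xyzrgb"`; `"auto"`
#'   infers from the file extension.
#' @param default_color optional RGB triple assigned to colorless files.
#' @param axis_order a permutation of `c("x","y","z")` naming which file
#'   columns map to the package's x/y/z (z vertical) convention.
#' @return a [point_cloud].
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "pcd", "xyzrgb"),
                             default_color = NULL,
                             axis_order = c("x", "y", "z")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", pcd = "pcd", "xyzrgb")
  }
  cloud <- switch(format,
                  ply = read_ply(path, default_color),
                  pcd = read_pcd(path, default_color),
                  xyzrgb = read_xyzrgb(path, default_color))
  perm <- match(axis_order, c("x", "y", "z"))
  if (any(is.na(perm)) || length(perm) != 3)
    stop("axis_order must be a permutation of c('x','y','z')")
  if (!identical(perm, 1:3))
    cloud$positions <- cloud$positions[, perm, drop = FALSE]
  cloud
}

#' Write a colored point cloud
#'
#' @param cloud a [point_cloud].
#' @param path output file path.
#' @param format `"ply"`, `"pcd"` or `"xyzrgb"`.
#' @param binary write binary little-endian PLY instead of ASCII
#'   (PLY only). Positions are stored as 32-bit floats in every format.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path,
                              format = c("ply", "pcd", "xyzrgb"),
                              binary = FALSE) {
  format <- match.arg(format)
  switch(format,
         ply = write_ply(cloud, path, binary),
         pcd = write_pcd(cloud, path),
         xyzrgb = write_xyzrgb(cloud, path))
  invisible(path)
}

read_ply <- function(path, default_color) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("malformed PLY: header not terminated")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 500) stop("malformed PLY: runaway header")
  }
  if (trimws(header[1]) != "ply") stop("malformed PLY: missing magic line 1")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1) stop("malformed PLY: missing format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  # vertex element and its properties
  el_idx <- grep("^element ", header)
  if (length(el_idx) == 0) stop("malformed PLY: no element declaration")
  el <- do.call(rbind, lapply(strsplit(trimws(header[el_idx]), "\\s+"),
                              function(t) t[2:3]))
  vert_row <- which(el[, 1] == "vertex")
  if (length(vert_row) != 1) stop("malformed PLY: need one vertex element")
  n <- as.integer(el[vert_row, 2])
  if (is.na(n) || n < 1) stop("malformed PLY: bad vertex count")
  if (length(el_idx) > 1 && vert_row != 1)
    stop("unsupported PLY layout: vertex must be the first element")
  prop_idx <- el_idx[vert_row] +
    seq_len((c(el_idx, length(header))[vert_row + 1] - el_idx[vert_row]) - 1)
  props <- header[prop_idx]
  props <- props[grepl("^property ", trimws(props))]
  pp <- strsplit(trimws(props), "\\s+")
  ptype <- vapply(pp, `[`, "", 2)
  pname <- vapply(pp, function(t) t[length(t)], "")
  if (any(ptype == "list")) stop("unsupported PLY: list property in vertex")
  need <- c("x", "y", "z")
  if (!all(need %in% pname)) stop("malformed PLY: missing x/y/z properties")
  has_color <- all(c("red", "green", "blue") %in% pname)
  if (!has_color && is.null(default_color))
    stop("no color: PLY lacks red/green/blue vertex properties")
  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2,
                 ushort = 2, int16 = 2, uint16 = 2, int = 4, uint = 4,
                 int32 = 4, uint32 = 4, float = 4, float32 = 4, double = 8,
                 float64 = 8)
  if (fmt == "ascii") {
    body <- readLines(path)[-seq_along(header)]
    dat <- tryCatch(
      read.table(text = body, nrows = n, colClasses = "numeric"),
      error = function(e) stop("malformed PLY data records: ",
                               conditionMessage(e)))
    if (nrow(dat) < n)
      stop("malformed PLY: expected ", n, " records, found ", nrow(dat))
    if (ncol(dat) != length(pname))
      stop("malformed PLY: record width does not match properties")
    colnames(dat) <- pname
  } else {
    sizes <- unname(type_size[ptype])
    if (any(is.na(sizes))) stop("unsupported PLY property type")
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = n * rec)
    if (length(raw) < n * rec) stop("malformed PLY: truncated binary data")
    offs <- cumsum(c(0, sizes[-length(sizes)]))
    dat <- matrix(0, n, length(pname))
    colnames(dat) <- pname
    for (j in seq_along(pname)) {
      sel <- rep((0:(n - 1)) * rec, each = sizes[j]) + offs[j] +
        seq_len(sizes[j])
      what <- if (ptype[j] %in% c("float", "float32", "double", "float64"))
        "double" else "integer"
      signed <- !grepl("^u", ptype[j])
      dat[, j] <- readBin(raw[sel], what, n = n, size = sizes[j],
                          signed = if (sizes[j] < 4) signed else TRUE,
                          endian = "little")
    }
    dat <- as.data.frame(dat)
  }
  pos <- as.matrix(dat[, c("x", "y", "z")])
  cols <- if (has_color) as.matrix(dat[, c("red", "green", "blue")])
          else matrix(rep(default_color, each = n), n)
  point_cloud(pos, cols)
}

write_ply <- function(cloud, path, binary = FALSE) {
  n <- cloud$n
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           "end_header")
  if (!binary) {
    co <- round(cloud$colors)
    lines <- sprintf("%.9g %.9g %.9g %d %d %d",
                     cloud$positions[, 1], cloud$positions[, 2],
                     cloud$positions[, 3], co[, 1], co[, 2], co[, 3])
    writeLines(c(hdr, lines), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    rec <- 15L  # 3 float32 + 3 uint8
    raw <- raw(n * rec)
    for (j in 1:3) {
      b <- writeBin(as.numeric(cloud$positions[, j]), raw(), size = 4,
                    endian = "little")
      raw[rep((0:(n - 1)) * rec, each = 4) + (j - 1) * 4 + 1:4] <- b
    }
    for (j in 1:3) {
      b <- as.raw(round(cloud$colors[, j]))
      raw[(0:(n - 1)) * rec + 12 + j] <- b
    }
    writeBin(raw, con)
  }
  invisible(path)
}

# pack / unpack PCL-style 24-bit rgb
pack_rgb <- function(colors) {
  co <- round(colors)
  co[, 1] * 65536 + co[, 2] * 256 + co[, 3]
}

unpack_rgb <- function(packed) {
  cbind(packed %/% 65536 %% 256, packed %/% 256 %% 256, packed %% 256)
}

read_pcd <- function(path, default_color) {
  lines <- readLines(path)
  hdr_end <- grep("^DATA\\s", lines)
  if (length(hdr_end) != 1) stop("malformed PCD: missing DATA line")
  hdr <- lines[seq_len(hdr_end)]
  get <- function(key) {
    ln <- grep(paste0("^", key, "\\s"), hdr, value = TRUE)
    if (length(ln) != 1) return(NULL)
    strsplit(trimws(ln), "\\s+")[[1]][-1]
  }
  mode <- strsplit(trimws(lines[hdr_end]), "\\s+")[[1]][2]
  if (mode != "ascii") stop("unsupported PCD: only DATA ascii is handled")
  fields <- get("FIELDS")
  types <- get("TYPE")
  n <- as.integer(get("POINTS")[1])
  if (is.na(n) || n < 1) stop("malformed PCD: bad POINTS")
  if (!all(c("x", "y", "z") %in% fields))
    stop("malformed PCD: missing x/y/z fields")
  dat <- tryCatch(
    read.table(text = lines[-(seq_len(hdr_end))], nrows = n),
    error = function(e) stop("malformed PCD data records: ",
                             conditionMessage(e)))
  if (nrow(dat) < n)
    stop("malformed PCD: expected ", n, " records, found ", nrow(dat))
  if (ncol(dat) != length(fields))
    stop("malformed PCD: record width does not match FIELDS")
  colnames(dat) <- fields
  pos <- as.matrix(dat[, c("x", "y", "z")])
  if ("rgb" %in% fields) {
    rgb_type <- types[match("rgb", fields)]
    v <- dat[, "rgb"]
    packed <- if (identical(rgb_type, "F")) float_bits_to_int(v)
              else as.numeric(v)
    cols <- unpack_rgb(packed)
  } else if (!is.null(default_color)) {
    cols <- matrix(rep(default_color, each = n), n)
  } else {
    stop("no color: PCD lacks an rgb field")
  }
  point_cloud(pos, cols)
}

# reinterpret float32 bit patterns as unsigned 24-bit color integers
float_bits_to_int <- function(x) {
  b <- writeBin(as.numeric(x), raw(), size = 4, endian = "little")
  as.numeric(readBin(b, "integer", n = length(x), size = 4,
                     endian = "little")) %% 2^24
}

write_pcd <- function(cloud, path) {
  n <- cloud$n
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           "FIELDS x y z rgb",
           "SIZE 4 4 4 4",
           "TYPE F F F U",
           "COUNT 1 1 1 1",
           sprintf("WIDTH %d", n),
           "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0",
           sprintf("POINTS %d", n),
           "DATA ascii")
  lines <- sprintf("%.9g %.9g %.9g %d",
                   cloud$positions[, 1], cloud$positions[, 2],
                   cloud$positions[, 3], pack_rgb(cloud$colors))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

read_xyzrgb <- function(path, default_color) {
  dat <- tryCatch(read.table(path, comment.char = "#"),
                  error = function(e) stop("malformed xyzrgb file: ",
                                           conditionMessage(e)))
  if (ncol(dat) == 3) {
    if (is.null(default_color))
      stop("no color: file has xyz columns only")
    cols <- matrix(rep(default_color, each = nrow(dat)), nrow(dat))
  } else if (ncol(dat) >= 6) {
    cols <- as.matrix(dat[, 4:6])
  } else {
    stop("malformed xyzrgb file: expected 3 or 6 columns, found ", ncol(dat))
  }
  point_cloud(as.matrix(dat[, 1:3]), cols)
}

write_xyzrgb <- function(cloud, path) {
  co <- round(cloud$colors)
  writeLines(sprintf("%.9g %.9g %.9g %d %d %d",
                     cloud$positions[, 1], cloud$positions[, 2],
                     cloud$positions[, 3], co[, 1], co[, 2], co[, 3]),
             path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# uniform density reduction

# voxel keys on a fixed global grid (origin 0), as strings
voxel_keys <- function(P, voxel) {
  k <- floor(P / voxel)
  paste(k[, 1], k[, 2], k[, 3])
}

#' Voxel-grid downsampling at a fixed voxel size
#'
#' Keeps, for each occupied voxel of a fixed global grid, the input point
#' nearest the voxel centroid. No interpolation: retained points keep their
#' original coordinates and colors, so the operation is idempotent at a fixed
#' voxel size.
#'
#' @param cloud a [point_cloud].
#' @param voxel voxel edge length (meters).
#' @return a [point_cloud] with one point per occupied voxel.
#' @export
voxel_downsample <- function(cloud, voxel) {
  stopifnot(voxel > 0)
  P <- cloud$positions
  key <- voxel_keys(P, voxel)
  ctr <- (floor(P / voxel) + 0.5) * voxel
  d <- rowSums((P - ctr)^2)
  ord <- order(key, d, seq_len(nrow(P)))
  keep <- ord[!duplicated(key[ord])]
  cloud_subset(cloud, sort(keep))
}

#' Uniform point-cloud simplification to a target size
#'
#' Reduces density to approximately `target_n` points by voxel-grid
#' subsampling, bisecting the voxel edge length until the retained count is
#' within 10% of the target. Dense scans of a grown maize plant are typically
#' reduced to about ten thousand points before skeletonization; below the
#' target the cloud is returned unchanged.
#'
#' @param cloud a [point_cloud].
#' @param target_n requested number of points (>= 1).
#' @return a [point_cloud] whose size is within `[0.9, 1.1] * target_n`
#'   whenever the input is larger than the target.
#' @export
uniform_simplify <- function(cloud, target_n) {
  if (length(target_n) != 1 || !is.finite(target_n) || target_n < 1)
    stop("target_n must be a positive integer")
  target_n <- as.integer(target_n)
  if (cloud$n <= target_n) return(cloud)
  diag <- bbox_diagonal(cloud)
  if (diag <= 0) {
    # all points coincident: any subset is uniform
    return(cloud_subset(cloud, seq_len(target_n)))
  }
  count_at <- function(v) length(unique(voxel_keys(cloud$positions, v)))
  lo <- diag / (2 * cloud$n^(1 / 3) * 10)  # finer than needed
  hi <- diag
  while (count_at(lo) < target_n) lo <- lo / 2
  best_v <- NA
  best_err <- Inf
  for (it in 1:60) {
    mid <- sqrt(lo * hi)
    cnt <- count_at(mid)
    err <- abs(cnt - target_n)
    if (err < best_err) {
      best_err <- err
      best_v <- mid
    }
    if (cnt >= 0.9 * target_n && cnt <= 1.1 * target_n) break
    if (cnt > target_n) lo <- mid else hi <- mid
  }
  out <- voxel_downsample(cloud, best_v)
  if (out$n < 0.9 * target_n || out$n > 1.1 * target_n)
    warning(sprintf(
      "uniform_simplify: reached %d points for target %d (grid plateau)",
      out$n, target_n))
  out
}
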