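#' Pinhole camera intrinsics
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels; must lie inside the image.
#' @param width,height image size in pixels.
#' @return A \code{camera_intrinsics} object.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  if (fx <= 0 || fy <= 0) stop("focal lengths fx, fy must be positive")
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point (cx, cy) must lie within the image")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = "ply", pcd = "pcd",
         csv = "xyz_csv", xyz = "xyz_csv", txt = "xyz_csv",
         stop("cannot infer point-cloud format from extension '.", ext,
              "'; pass 'format' explicitly"))
}

#' Read a point cloud from file
#'
#' Supports ASCII and binary little-endian PLY, PCD v0.7 ASCII and
#' headerless "x,y,z" CSV.  Coordinates are taken verbatim as millimetres
#' (no unit autodetection or rescaling).  Non-finite coordinates are
#' dropped; the dropped count is recorded in \code{meta$dropped_nonfinite}.
#'
#' @param path file to read.
#' @param format one of \code{"auto"} (by extension), \code{"ply"},
#'   \code{"pcd"}, \code{"xyz_csv"}.
#' @return A \code{\link{point_cloud}} with \code{meta$source} set to
#'   \code{path}.
#' @seealso \code{\link{write_point_cloud}}
#' @export
read_point_cloud <- function(path,
                             format = c("auto", "ply", "pcd", "xyz_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read point cloud: no such file: ", path)
  if (format == "auto") format <- .guess_format(path)
  xyz <- switch(format,
                ply = .read_ply(path),
                pcd = .read_pcd(path),
                xyz_csv = .read_xyz_csv(path))
  n_raw <- nrow(xyz)
  finite <- rowSums(is.finite(xyz)) == 3L
  xyz <- xyz[finite, , drop = FALSE]
  meta <- list(source = path, format = format)
  if (n_raw > nrow(xyz))
    meta$dropped_nonfinite <- n_raw - nrow(xyz)
  point_cloud(xyz, meta = meta)
}

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply"))
    stop("parse error in ", path, ": missing 'ply' magic on line 1")
  fmt <- NULL
  elements <- list()   # name -> list(count, prop_names, prop_types)
  cur <- NULL
  lineno <- 1L
  repeat {
    ln <- readLines(con, n = 1L)
    lineno <- lineno + 1L
    if (length(ln) == 0L)
      stop("parse error in ", path, ": header ended before 'end_header'")
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "comment") next
    if (tok[1L] == "end_header") break
    if (tok[1L] == "format") {
      fmt <- tok[2L]
    } else if (tok[1L] == "element") {
      cur <- tok[2L]
      elements[[cur]] <- list(count = as.integer(tok[3L]),
                              prop_names = character(0),
                              prop_types = character(0))
    } else if (tok[1L] == "property") {
      if (is.null(cur))
        stop("parse error in ", path, ": property before element (line ",
             lineno, ")")
      if (tok[2L] == "list")
        stop("unsupported PLY in ", path, ": list properties on element '",
             cur, "'")
      elements[[cur]]$prop_names <- c(elements[[cur]]$prop_names, tok[3L])
      elements[[cur]]$prop_types <- c(elements[[cur]]$prop_types, tok[2L])
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format '", fmt, "' in ", path)
  if (!"vertex" %in% names(elements))
    stop("parse error in ", path, ": no 'vertex' element")
  vtx <- elements$vertex
  ixyz <- match(c("x", "y", "z"), vtx$prop_names)
  if (anyNA(ixyz))
    stop("parse error in ", path, ": vertex element lacks x/y/z properties")
  n <- vtx$count
  if (n == 0L) return(matrix(numeric(0), ncol = 3L))
  nprop <- length(vtx$prop_names)
  if (fmt == "ascii") {
    if (which(names(elements) == "vertex") != 1L)
      stop("unsupported PLY in ", path, ": 'vertex' is not the first element")
    lines <- readLines(con, n = n)
    if (length(lines) < n)
      stop("parse error in ", path, ": expected ", n, " vertex lines, got ",
           length(lines))
    vals <- strsplit(trimws(lines), "\\s+")
    bad <- which(lengths(vals) < nprop)
    if (length(bad))
      stop("parse error in ", path, ": vertex record ", bad[1L],
           " has too few values")
    m <- matrix(suppressWarnings(as.numeric(unlist(vals, use.names = FALSE))),
                nrow = n, byrow = TRUE)
    m[, ixyz, drop = FALSE]
  } else {
    if (which(names(elements) == "vertex") != 1L)
      stop("unsupported binary PLY in ", path,
           ": 'vertex' is not the first element")
    types <- vtx$prop_types
    sizes <- .ply_type_size[types]
    if (anyNA(sizes))
      stop("parse error in ", path, ": unknown property type")
    if (length(unique(types)) == 1L && types[1L] %in%
        c("float", "float32", "double", "float64")) {
      sz <- sizes[1L]
      vals <- readBin(con, "double", n = n * nprop, size = sz,
                      endian = "little")
      if (length(vals) < n * nprop)
        stop("parse error in ", path, ": truncated binary vertex data")
      m <- matrix(vals, nrow = n, byrow = TRUE)
      m[, ixyz, drop = FALSE]
    } else {
      # mixed property types: walk the record layout per column
      rec <- sum(sizes)
      raw <- readBin(con, "raw", n = n * rec)
      if (length(raw) < n * rec)
        stop("parse error in ", path, ": truncated binary vertex data")
      offs <- cumsum(c(0L, sizes))[seq_len(nprop)]
      out <- matrix(NA_real_, n, 3L)
      for (j in seq_len(3L)) {
        k <- ixyz[j]
        idx <- as.vector(outer(seq_len(sizes[k]), (seq_len(n) - 1L) * rec +
                                 offs[k], `+`))
        what <- if (types[k] %in% c("float", "float32", "double", "float64"))
          "double" else "integer"
        sgn <- !types[k] %in% c("uchar", "uint8", "ushort", "uint16",
                                "uint", "uint32")
        out[, j] <- readBin(raw[idx], what, n = n, size = sizes[k],
                            signed = sgn, endian = "little")
      }
      out
    }
  }
}

.read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  data_line <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(tok) == 0L || startsWith(tok[1L], "#")) next
    key <- toupper(tok[1L])
    hdr[[key]] <- tok[-1L]
    if (key == "DATA") { data_line <- i; break }
  }
  if (is.na(data_line)) stop("parse error in ", path, ": no DATA line")
  if (tolower(hdr$DATA[1L]) != "ascii")
    stop("unsupported PCD in ", path, ": only DATA ascii is supported")
  fields <- hdr$FIELDS
  ixyz <- match(c("x", "y", "z"), fields)
  if (anyNA(ixyz))
    stop("parse error in ", path, ": FIELDS lacks x/y/z")
  n <- as.integer(hdr$POINTS[1L])
  if (is.na(n)) stop("parse error in ", path, ": bad POINTS count")
  if (n == 0L) return(matrix(numeric(0), ncol = 3L))
  body <- lines[(data_line + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    stop("parse error in ", path, ": expected ", n, " points, got ",
         length(body))
  vals <- strsplit(trimws(body[seq_len(n)]), "\\s+")
  bad <- which(lengths(vals) < length(fields))
  if (length(bad))
    stop("parse error in ", path, ": point record ", bad[1L],
         " has too few values")
  m <- matrix(suppressWarnings(as.numeric(unlist(vals, use.names = FALSE))),
              nrow = n, byrow = TRUE)
  m[, ixyz, drop = FALSE]
}

.read_xyz_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(matrix(numeric(0), ncol = 3L))
  vals <- strsplit(trimws(lines), ",")
  bad <- which(lengths(vals) != 3L)
  if (length(bad))
    stop("parse error in ", path, ": line ", bad[1L],
         " does not have exactly 3 comma-separated values")
  m <- matrix(suppressWarnings(as.numeric(unlist(vals, use.names = FALSE))),
              ncol = 3L, byrow = TRUE)
  nab <- which(rowSums(is.na(m)) > 0L & rowSums(is.finite(m)) < 3L)
  # NA from non-numeric text is a parse error; NaN/Inf handled by caller
  txt_bad <- which(vapply(seq_len(nrow(m)), function(i)
    anyNA(m[i, ]) && !any(vapply(vals[[i]], function(v)
      toupper(trimws(v)) %in% c("NA", "NAN", "INF", "-INF"), logical(1L))),
    logical(1L)))
  if (length(txt_bad))
    stop("parse error in ", path, ": non-numeric value on line ", txt_bad[1L])
  m
}

#' Write a point cloud to file
#'
#' Coordinates are written at full working precision so that a
#' write-then-read round trip preserves every coordinate to within
#' 1e-6 mm (PLY binary uses 64-bit floats; text formats print 6 decimal
#' places of a millimetre).
#'
#' @param pc a \code{\link{point_cloud}}.
#' @param path output file.
#' @param format \code{"auto"} (by extension), \code{"ply"}, \code{"pcd"}
#'   or \code{"xyz_csv"}.
#' @param binary for PLY only: write binary little-endian instead of ASCII.
#' @return \code{path}, invisibly.
#' @export
write_point_cloud <- function(pc, path,
                              format = c("auto", "ply", "pcd", "xyz_csv"),
                              binary = FALSE) {
  stopifnot(inherits(pc, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  p <- pc$points
  n <- nrow(p)
  ok <- switch(format,
    ply = {
      hdr <- c("ply",
               if (binary) "format binary_little_endian 1.0"
               else "format ascii 1.0",
               "comment written by berrybias (units: mm, camera frame)",
               sprintf("element vertex %d", n),
               "property double x", "property double y", "property double z",
               "end_header")
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(hdr, con)
      if (n > 0L) {
        if (binary) {
          writeBin(as.vector(t(p)), con, size = 8L, endian = "little")
        } else {
          writeLines(sprintf("%.6f %.6f %.6f", p[, 1L], p[, 2L], p[, 3L]),
                     con)
        }
      }
      TRUE
    },
    pcd = {
      hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
               "VERSION 0.7", "FIELDS x y z", "SIZE 8 8 8", "TYPE F F F",
               "COUNT 1 1 1", sprintf("WIDTH %d", n), "HEIGHT 1",
               "VIEWPOINT 0 0 0 1 0 0 0", sprintf("POINTS %d", n),
               "DATA ascii")
      writeLines(c(hdr, if (n > 0L)
        sprintf("%.6f %.6f %.6f", p[, 1L], p[, 2L], p[, 3L])), path)
      TRUE
    },
    xyz_csv = {
      writeLines(if (n > 0L)
        sprintf("%.6f,%.6f,%.6f", p[, 1L], p[, 2L], p[, 3L])
        else character(0), path)
      TRUE
    })
  if (!isTRUE(ok)) stop("failed to write ", path)
  invisible(path)
}

#' Back-project a depth image to a point cloud
#'
#' Standard pinhole back-projection: pixel (u, v) (0-based column/row)
#' with depth z > 0 mm maps to
#' \eqn{((u - c_x) z / f_x,\; -(v - c_y) z / f_y,\; z)}.
#' The Y sign flip converts image rows (down) to the camera frame's Y-up
#' convention.  Zero or negative depths mark sensor dropouts and are
#' omitted; the omitted count is recorded in
#' \code{meta$dropped_invalid_depth}.
#'
#' @param depth numeric matrix of depths in mm, \code{height} rows by
#'   \code{width} columns (row-major grid; 0 = invalid).
#' @param intr a \code{\link{camera_intrinsics}}.
#' @return A \code{\link{point_cloud}}; points ordered row-major (by image
#'   row, then column).
#' @export
depth_image_to_cloud <- function(depth, intr) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  if (!is.matrix(depth) || nrow(depth) != intr$height ||
      ncol(depth) != intr$width)
    stop(sprintf(
      "depth grid is %d x %d but intrinsics declare %d x %d (rows x cols)",
      nrow(depth), ncol(depth), intr$height, intr$width))
  # row-major pixel order: v (row) outer, u (col) inner
  v <- rep(seq_len(nrow(depth)) - 1L, each = ncol(depth))
  u <- rep(seq_len(ncol(depth)) - 1L, times = nrow(depth))
  z <- as.vector(t(depth))
  valid <- is.finite(z) & z > 0
  n_drop <- sum(!valid)
  u <- u[valid]; v <- v[valid]; z <- z[valid]
  pts <- cbind(x = (u - intr$cx) * z / intr$fx,
               y = -(v - intr$cy) * z / intr$fy,
               z = z)
  meta <- list(source = "depth_image")
  if (n_drop > 0L) meta$dropped_invalid_depth <- n_drop
  point_cloud(pts, meta = meta)
}
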