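#' Construct a point cloud
#'
#' A point cloud is the set of 3D points (in metres) to which alpha-shapes
#' are fitted: typically a LiDAR or photogrammetry scan of an articulated
#' skeleton.
#'
#' @param points numeric matrix with three columns (x, y, z), in metres.
#' @param id non-empty character label for the specimen.
#' @param source_format one of `"xyz"`, `"ply"`, `"obj"`, or `NA`.
#' @return an object of class `point_cloud` with fields `id`, `points`
#'   (an N x 3 matrix) and `source_format`.
#' @seealso [read_cloud()], [write_cloud()], [downsample_cloud()],
#'   [size_metrics()]
#' @export
#' @examples
#' pc <- point_cloud(matrix(runif(30), ncol = 3), id = "demo")
#' n_points(pc)
point_cloud <- function(points, id = "cloud", source_format = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("`points` must have exactly 3 columns")
  if (!is.numeric(points)) stop("`points` must be numeric")
  if (!all(is.finite(points))) stop("all coordinates must be finite")
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("`id` must be a single non-empty string")
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(id = id, points = points,
                 source_format = source_format),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' @export
print.point_cloud <- function(x, ...) {
  rng <- apply(x$points, 2, range)
  cat(sprintf("<point_cloud> '%s': %d points (%s)\n", x$id, n_points(x),
              if (is.na(x$source_format)) "in memory" else x$source_format))
  cat(sprintf("  extent x: [%.4g, %.4g]  y: [%.4g, %.4g]  z: [%.4g, %.4g] m\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

check_cloud <- function(cloud, min_points = 4L) {
  if (!inherits(cloud, "point_cloud")) stop("not a point_cloud")
  if (n_points(cloud) < min_points)
    stop(sprintf("degenerate cloud '%s': %d points, need at least %d",
                 cloud$id, n_points(cloud), min_points))
  invisible(cloud)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         xyz = , txt = , pts = , csv = "xyz",
         ply = "ply",
         obj = "obj",
         stop("cannot guess point-cloud format from extension '.", ext,
              "'; pass `format` explicitly"))
}

#' Read a point cloud from disk
#'
#' Supported formats: plain XYZ ASCII (whitespace- or comma-separated,
#' `#` comment lines allowed, first three numeric columns used), PLY
#' (ascii and binary little-endian; only the vertex element is read) and
#' OBJ (only `v` records are read). Faces and all non-vertex content are
#' discarded: the alpha-shape machinery consumes points only.
#'
#' @param path file to read.
#' @param format `"auto"` (extension-based), `"xyz"`, `"ply"` or `"obj"`.
#' @param id specimen label; defaults to the file name without extension.
#' @return a [point_cloud()].
#' @export
read_cloud <- function(path, format = c("auto", "xyz", "ply", "obj"),
                       id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  id <- id %||% tools::file_path_sans_ext(basename(path))
  pts <- switch(format,
                xyz = read_xyz(path),
                ply = read_ply_vertices(path),
                obj = read_obj_vertices(path))
  if (nrow(pts) < 4L)
    stop(sprintf("degenerate cloud in '%s': only %d points (need >= 4)",
                 path, nrow(pts)))
  point_cloud(pts, id = id, source_format = format)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data rows in ", path)
  toks <- strsplit(trimws(lines), "[,[:space:]]+")
  nt <- lengths(toks)
  if (any(nt < 3L)) {
    bad <- lineno[which(nt < 3L)[1L]]
    stop(sprintf("parse error in '%s' at line %d: fewer than 3 columns",
                 path, bad))
  }
  xyz <- vapply(toks, function(t) as.numeric(t[1:3]), numeric(3))
  if (anyNA(xyz)) {
    bad <- lineno[which(colSums(is.na(xyz)) > 0L)[1L]]
    stop(sprintf("parse error in '%s' at line %d: non-numeric coordinate",
                 path, bad))
  }
  t(xyz)
}

ply_type_size <- function(type) {
  switch(type,
         char = , int8 = , uchar = , uint8 = 1L,
         short = , int16 = , ushort = , uint16 = 2L,
         int = , int32 = , uint = , uint32 = 4L,
         float = , float32 = 4L,
         double = , float64 = 8L,
         stop("unsupported PLY property type: ", type))
}

read_ply_vertices <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  # header is ASCII; locate end_header at the byte level (the body may be
  # binary and contain nul bytes)
  pos <- grepRaw("end_header", raw, fixed = TRUE)
  if (!length(pos)) stop("not a PLY file (no end_header): ", path)
  pos <- pos[1]
  nl <- which(raw[pos:length(raw)] == as.raw(10L))[1]
  if (is.na(nl)) stop("malformed PLY header: ", path)
  body_off <- pos + nl - 1L  # body starts at raw[body_off + 1]
  header <- strsplit(rawToChar(raw[seq_len(pos - 1L)]), "\r?\n")[[1]]
  if (!length(header) || trimws(header[1]) != "ply")
    stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  if (!length(fmt_line)) stop("PLY header missing format line: ", path)
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format '", fmt, "' (ascii or binary_little_endian)")
  # parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (ln in header[-1]) {
    t <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(t)) next
    if (t[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = t[2], count = as.integer(t[3]), props = list())
    } else if (t[1] == "property" && !is.null(cur)) {
      if (t[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = t[5], list = TRUE, count_type = t[3], type = t[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = t[3], list = FALSE, type = t[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop("PLY file has no vertex element: ", path)
  if (fmt == "ascii") {
    return(read_ply_ascii_vertices(raw, body_off, elements, path))
  }
  read_ply_binary_vertices(raw, body_off, elements, path)
}

read_ply_ascii_vertices <- function(raw, body_off, elements, path) {
  body <- rawToChar(raw[(body_off + 1L):length(raw)])
  toks <- scan(text = body, what = character(), quiet = TRUE)
  pos <- 1L
  for (el in elements) {
    pnames <- vapply(el$props, `[[`, "", "name")
    has_list <- any(vapply(el$props, `[[`, TRUE, "list"))
    if (el$name == "vertex") {
      if (has_list) stop("list properties on the vertex element: ", path)
      np <- length(el$props)
      need <- el$count * np
      if (pos + need - 1L > length(toks))
        stop("truncated PLY vertex data: ", path)
      vals <- suppressWarnings(as.numeric(toks[pos:(pos + need - 1L)]))
      if (anyNA(vals)) stop("non-numeric PLY vertex record in: ", path)
      m <- matrix(vals, ncol = np, byrow = TRUE)
      ix <- match(c("x", "y", "z"), pnames)
      if (anyNA(ix)) stop("PLY vertex element lacks x/y/z properties: ", path)
      return(m[, ix, drop = FALSE])
    }
    # skip a non-vertex element (faces etc.)
    if (!has_list) {
      pos <- pos + el$count * length(el$props)
    } else {
      for (i in seq_len(el$count)) {
        for (p in el$props) {
          if (p$list) {
            cnt <- suppressWarnings(as.integer(toks[pos]))
            if (is.na(cnt)) stop("malformed PLY list record in: ", path)
            pos <- pos + 1L + cnt
          } else pos <- pos + 1L
        }
      }
    }
  }
  stop("PLY vertex element not found in body: ", path)
}

read_ply_binary_vertices <- function(raw, body_off, elements, path) {
  off <- body_off  # 0-based offset into raw
  for (el in elements) {
    if (el$name != "vertex") {
      if (any(vapply(el$props, `[[`, TRUE, "list")))
        stop("cannot skip a binary PLY list element declared before the ",
             "vertex element: ", path)
      rs <- sum(vapply(el$props, function(p) ply_type_size(p$type), 1L))
      off <- off + el$count * rs
      next
    }
    if (any(vapply(el$props, `[[`, TRUE, "list")))
      stop("list properties on the vertex element: ", path)
    sizes <- vapply(el$props, function(p) ply_type_size(p$type), 1L)
    rs <- sum(sizes)
    n <- el$count
    if (off + as.double(n) * rs > length(raw))
      stop("truncated binary PLY vertex data: ", path)
    offsets <- cumsum(c(0L, sizes))[seq_along(sizes)]
    pnames <- vapply(el$props, `[[`, "", "name")
    out <- matrix(NA_real_, n, 3)
    for (j in seq_len(3)) {
      pi <- match(c("x", "y", "z")[j], pnames)
      if (is.na(pi)) stop("PLY vertex element lacks x/y/z properties: ", path)
      sz <- sizes[pi]
      type <- el$props[[pi]]$type
      idx <- rep(seq_len(sz), n) +
        rep(seq.int(0L, by = rs, length.out = n), each = sz) +
        offsets[pi] + off
      bytes <- raw[idx]
      out[, j] <- switch(type,
        float = , float32 = , double = , float64 =
          readBin(bytes, "double", n = n, size = sz, endian = "little"),
        readBin(bytes, "integer", n = n, size = sz, endian = "little"))
    }
    return(out)
  }
  stop("PLY vertex element not found: ", path)
}

read_obj_vertices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vix <- grep("^v\\s", lines)
  if (!length(vix)) stop("no vertex ('v') records in OBJ file: ", path)
  toks <- strsplit(trimws(lines[vix]), "\\s+")
  nt <- lengths(toks)
  if (any(nt < 4L))
    stop(sprintf("parse error in '%s' at line %d: short vertex record",
                 path, vix[which(nt < 4L)[1L]]))
  xyz <- vapply(toks, function(t) suppressWarnings(as.numeric(t[2:4])),
                numeric(3))
  if (anyNA(xyz))
    stop(sprintf("parse error in '%s' at line %d: non-numeric coordinate",
                 path, vix[which(colSums(is.na(xyz)) > 0L)[1L]]))
  t(xyz)
}

#' Write a point cloud to disk
#'
#' Coordinates are written with enough digits that a read/write round trip
#' reproduces them to better than 6 significant figures, in the original
#' point order.
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @param format `"xyz"`, `"ply"` (ascii) or `"obj"`.
#' @export
write_cloud <- function(cloud, path, format = c("xyz", "ply", "obj")) {
  format <- match.arg(format)
  check_cloud(cloud, min_points = 1L)
  p <- cloud$points
  fmtrow <- function(m) sprintf("%.10g %.10g %.10g", m[, 1], m[, 2], m[, 3])
  txt <- switch(format,
    xyz = fmtrow(p),
    obj = paste("v", fmtrow(p)),
    ply = c("ply", "format ascii 1.0",
            paste("element vertex", nrow(p)),
            "property double x", "property double y", "property double z",
            "end_header", fmtrow(p)))
  writeLines(txt, path)
  invisible(path)
}

#' Randomly downsample a point cloud
#'
#' Draws a uniform random sample of exactly `n` points *without*
#' replacement, reproducibly for a given seed. Sampling to a common point
#' count across a comparative sample removes the dependence of point
#' density on specimen size that LiDAR scans of differently sized
#' skeletons carry.
#'
#' @param cloud a [point_cloud()].
#' @param n target point count (>= 4).
#' @param seed integer seed; the same (cloud, n, seed) always returns the
#'   identical subsample.
#' @return a [point_cloud()] with `n` points; if `n` exceeds the cloud
#'   size the full cloud is returned unchanged with a warning.
#' @export
downsample_cloud <- function(cloud, n, seed = 1L) {
  check_cloud(cloud)
  if (n < 4L) stop("`n` must be at least 4")
  N <- n_points(cloud)
  if (n > N) {
    warning(sprintf("cloud '%s' has %d points, fewer than requested %d; %s",
                    cloud$id, N, n, "returning the full cloud"))
    return(cloud)
  }
  idx <- with_seed(seed, sample.int(N, n))
  point_cloud(cloud$points[idx, , drop = FALSE], id = cloud$id,
              source_format = cloud$source_format)
}

#' Size-normalization metrics of a point cloud
#'
#' Computes the specimen-size metrics used to normalize alpha across
#' differently sized skeletons. The reference length `l_ref` is the mean
#' Euclidean distance of the points from their centroid; the alpha radius
#' for a refinement coefficient `k` is then `l_ref * k` (see
#' [alpha_for()]). Alternative metrics (maximum height along the vertical
#' axis, maximum axis-aligned extent and bounding-box diagonal) are also
#' reported.
#'
#' @param cloud a [point_cloud()] with at least 2 distinct points.
#' @param vertical_axis which coordinate is "up" (default 3 = z); museum
#'   scans differ in mounting convention.
#' @return an object of class `size_metrics`: `centroid`, `l_ref`,
#'   `max_height`, `max_length`, `bbox_diagonal` (all metres).
#' @export
#' @examples
#' cube <- point_cloud(as.matrix(expand.grid(0:1, 0:1, 0:1)), "cube")
#' size_metrics(cube)$l_ref  # sqrt(3)/2
size_metrics <- function(cloud, vertical_axis = 3L) {
  check_cloud(cloud, min_points = 2L)
  stopifnot(vertical_axis %in% 1:3)
  p <- cloud$points
  ctr <- colMeans(p)
  centered <- sweep(p, 2, ctr)
  d <- sqrt(rowSums(centered^2))
  if (max(d) == 0) stop("degenerate cloud: all points identical")
  ext <- apply(p, 2, function(v) diff(range(v)))
  structure(list(centroid = ctr,
                 l_ref = mean(d),
                 max_height = unname(ext[vertical_axis]),
                 max_length = unname(max(ext)),
                 bbox_diagonal = unname(sqrt(sum(ext^2)))),
            class = "size_metrics")
}

#' @export
print.size_metrics <- function(x, ...) {
  cat(sprintf(paste0("<size_metrics> l_ref=%.6g  max_height=%.6g  ",
                     "max_length=%.6g  bbox_diagonal=%.6g m\n"),
              x$l_ref, x$max_height, x$max_length, x$bbox_diagonal))
  invisible(x)
}
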