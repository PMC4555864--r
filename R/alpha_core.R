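#' Build the alpha-complex of a point cloud
#'
#' Computes the Delaunay tetrahedralization of the cloud once, together
#' with each tetrahedron's circumradius and volume, and preprocesses them
#' (sort by circumradius + prefix sums) so that the enclosed volume of the
#' alpha-shape at *any* radius `alpha` afterwards costs a single binary
#' search ([alpha_volume()]). An alpha-shape retains exactly the Delaunay
#' tetrahedra whose circumsphere is smaller than `alpha`: conceptually, a
#' sphere of radius `alpha` burrows through the cloud and excavates every
#' region it can reach, including voids completely interior to the points.
#'
#' Near-flat tetrahedra (volume below `1e-12 * bbox_diagonal^3`) carry an
#' infinite circumradius sentinel and are never retained at finite alpha.
#' Exactly degenerate inputs (grids, cube corners and other cospherical
#' configurations) are resolved by a seeded uniform jitter of magnitude
#' `1e-9 * bbox_diagonal`, applied only when the tetrahedralizer reports a
#' degeneracy; real scan data never trigger it.
#'
#' @param cloud a [point_cloud()] with at least 4 non-coplanar points.
#' @param jitter_seed seed for the degeneracy-breaking jitter.
#' @return an object of class `alpha_complex` with fields `tets`,
#'   `circumradius`, `tet_volume`, `sorted_radii`, `cum_volume`,
#'   `hull_volume`, `vertices`, `l_ref`, `bbox_diagonal`, `jittered`.
#' @seealso [alpha_volume()], [boundary_mesh()], [convex_hull_volume()]
#' @export
#' @examples
#' ball <- make_primitive("ball", radius = 1, n_points = 2000, seed = 1)
#' ac <- alpha_complex(ball$cloud)
#' alpha_volume(ac, c(0.5, Inf))
alpha_complex <- function(cloud, jitter_seed = 1L) {
  check_cloud(cloud)
  pts <- unique(cloud$points)
  if (nrow(pts) < 4L)
    stop(sprintf("degenerate cloud '%s': fewer than 4 distinct points",
                 cloud$id))
  ext <- apply(pts, 2, function(v) diff(range(v)))
  diag_len <- sqrt(sum(ext^2))
  qh <- cpp_quickhull(pts)
  if (!isTRUE(qh$ok))
    stop(sprintf("degenerate geometry in cloud '%s': %s", cloud$id,
                 qh$reason))
  build <- function(p) {
    d <- cpp_delaunay(p)
    if (!isTRUE(d$ok)) return(d)
    m <- cpp_tet_metrics(p, d$tets, 1e-12 * diag_len^3)
    hv <- cpp_quickhull(p)$volume
    d$bad <- isTRUE(d$degenerate) ||
      abs(sum(m$volume) - hv) > 1e-9 * hv
    d$metrics <- m
    d
  }
  jittered <- FALSE
  d <- build(pts)
  if (!isTRUE(d$ok) || d$bad) {
    # escalating jitter ladder: the smallest magnitude that resolves the
    # degeneracy wins (validated by hull-volume conservation); magnitudes
    # are relative to the bounding-box diagonal
    jittered <- TRUE
    jit <- with_seed(jitter_seed,
                     matrix(runif(length(pts), -1, 1), ncol = 3))
    orig <- pts
    for (mag in c(1e-9, 1e-7, 1e-5)) {
      pts <- orig + mag * diag_len * jit
      d <- build(pts)
      if (isTRUE(d$ok) && !d$bad) break
    }
    if (!isTRUE(d$ok))
      stop(sprintf("degenerate geometry in cloud '%s': %s", cloud$id,
                   d$reason %||% "tetrahedralization failed"))
    if (d$bad)
      stop(sprintf("degenerate geometry in cloud '%s': %s", cloud$id,
                   "tetrahedralization inconsistent even after jitter"))
  }
  m <- d$metrics
  ord <- order(m$circumradius)
  structure(list(
    tets = d$tets,
    circumradius = m$circumradius,
    tet_volume = m$volume,
    sorted_order = ord,
    sorted_radii = m$circumradius[ord],
    cum_volume = cumsum(m$volume[ord]),
    hull_volume = qh$volume,
    vertices = pts,
    n_points = nrow(pts),
    l_ref = size_metrics(cloud)$l_ref,
    bbox_diagonal = diag_len,
    jittered = jittered,
    id = cloud$id), class = "alpha_complex")
}

#' @export
print.alpha_complex <- function(x, ...) {
  cat(sprintf("<alpha_complex> '%s': %d points, %d tetrahedra%s\n", x$id,
              x$n_points, nrow(x$tets), if (x$jittered) " (jittered)" else ""))
  fin <- is.finite(x$circumradius)
  cat(sprintf("  circumradii: %.4g .. %.4g m (%d degenerate)\n",
              min(x$circumradius), max(x$circumradius[fin]), sum(!fin)))
  cat(sprintf("  hull volume: %.6g m^3   l_ref: %.4g m\n",
              x$hull_volume, x$l_ref))
  invisible(x)
}

#' Circumradius of a tetrahedron
#'
#' Radius of the unique sphere through four points, by the circumcenter
#' closed form in double precision. Returns `Inf` when the tetrahedron is
#' degenerate (volume not above `degenerate_tol`), the sentinel used
#' throughout the alpha-complex: such tetrahedra are never retained at
#' finite alpha.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @param degenerate_tol volume at or below which the tetrahedron counts
#'   as flat (default 0: only exactly degenerate input).
#' @return circumradius in the input units, or `Inf`.
#' @export
#' @examples
#' # regular tetrahedron with edge 1: circumradius sqrt(6)/4
#' circumradius(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
#'              c(0.5, sqrt(3) / 6, sqrt(6) / 3))
circumradius <- function(p1, p2, p3, p4, degenerate_tol = 0) {
  q <- rbind(p1, p2, p3, p4)
  stopifnot(ncol(q) == 3L, is.numeric(q))
  vol <- abs(det(rbind(q[2, ] - q[1, ], q[3, ] - q[1, ], q[4, ] - q[1, ]))) / 6
  if (!is.finite(vol) || vol <= degenerate_tol) return(Inf)
  A <- 2 * (q[2:4, ] - matrix(q[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(q[2:4, ]^2) - sum(q[1, ]^2)
  ctr <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(ctr)) return(Inf)
  sqrt(sum((ctr - q[1, ])^2))
}

#' Alpha-shape volume at one or more radii
#'
#' Sums the volumes of the Delaunay tetrahedra whose circumradius is below
#' `alpha` (strictly, by default, matching the usual alpha-complex
#' convention; the choice only matters on exact ties). `alpha = Inf`
#' returns the convex-hull volume. Interior excavated voids need no
#' special handling: their large-circumradius tetrahedra are simply not
#' retained.
#'
#' @param complex an [alpha_complex()].
#' @param alpha positive radius (metres); may be a vector, and `Inf` is
#'   allowed.
#' @param strict retain circumradius `< alpha` (default) or `<= alpha`.
#' @return numeric vector of enclosed volumes (cubic metres).
#' @export
alpha_volume <- function(complex, alpha, strict = TRUE) {
  stopifnot(inherits(complex, "alpha_complex"))
  if (length(alpha) == 0L || anyNA(alpha) || any(alpha <= 0))
    stop("`alpha` must be positive (Inf allowed)")
  k <- findInterval(alpha, complex$sorted_radii, left.open = strict)
  ifelse(k == 0L, 0, complex$cum_volume[pmax(k, 1L)])
}

#' Number of tetrahedra retained at a given alpha
#' @inheritParams alpha_volume
#' @return integer count of retained Delaunay tetrahedra.
#' @export
n_retained <- function(complex, alpha, strict = TRUE) {
  stopifnot(inherits(complex, "alpha_complex"))
  findInterval(alpha, complex$sorted_radii, left.open = strict)
}

#' Convex-hull volume of a point cloud
#'
#' The convex hull is the alpha-shape limit at infinite alpha; its volume
#' is computed independently of the Delaunay machinery (QuickHull), which
#' makes it a useful cross-check on [alpha_volume()] at `alpha = Inf`.
#'
#' @param cloud a [point_cloud()] with at least 4 non-coplanar points.
#' @return hull volume in cubic metres.
#' @export
convex_hull_volume <- function(cloud) {
  check_cloud(cloud)
  qh <- cpp_quickhull(cloud$points)
  if (!isTRUE(qh$ok))
    stop(sprintf("degenerate geometry in cloud '%s': %s", cloud$id,
                 qh$reason))
  qh$volume
}

#' Boundary mesh of an alpha-shape
#'
#' Extracts the triangular facets that bound the retained tetrahedra (each
#' boundary facet belongs to exactly one retained tetrahedron) with
#' outward orientation, suitable for export ([write_mesh()]) and visual
#' inspection of the fit.
#'
#' @inheritParams alpha_volume
#' @param alpha single positive radius.
#' @return an object of class `triangle_mesh` with fields `vertices`
#'   (N x 3) and `faces` (F x 3, 1-based, outward-oriented); zero retained
#'   tetrahedra yield a valid empty mesh.
#' @export
boundary_mesh <- function(complex, alpha, strict = TRUE) {
  stopifnot(inherits(complex, "alpha_complex"), length(alpha) == 1L)
  if (is.na(alpha) || alpha <= 0) stop("`alpha` must be positive")
  keep <- if (strict) complex$circumradius < alpha
          else complex$circumradius <= alpha
  tets <- complex$tets[keep, , drop = FALSE]
  if (!nrow(tets)) {
    return(structure(list(vertices = complex$vertices,
                          faces = matrix(integer(), 0, 3)),
                     class = "triangle_mesh"))
  }
  # four faces per tet; a facet on the boundary appears exactly once
  fidx <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
                tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  opp <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  key3 <- t(apply(fidx, 1, sort))
  n1 <- as.double(complex$n_points) + 1
  key <- (key3[, 1] * n1 + key3[, 2]) * n1 + key3[, 3]
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  faces <- fidx[!dup, , drop = FALSE]
  opp <- opp[!dup]
  # orient each facet outward: the owning tet's fourth vertex must lie on
  # the negative side
  v <- complex$vertices
  a <- v[faces[, 1], , drop = FALSE]
  b <- v[faces[, 2], , drop = FALSE]
  cc <- v[faces[, 3], , drop = FALSE]
  d <- v[opp, , drop = FALSE]
  u1 <- b - a; u2 <- cc - a; u3 <- d - a
  o <- u1[, 1] * (u2[, 2] * u3[, 3] - u2[, 3] * u3[, 2]) -
       u1[, 2] * (u2[, 1] * u3[, 3] - u2[, 3] * u3[, 1]) +
       u1[, 3] * (u2[, 1] * u3[, 2] - u2[, 2] * u3[, 1])
  flip <- o > 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]
  structure(list(vertices = v, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Enclosed volume of a closed triangle mesh
#'
#' Divergence-theorem volume of an outward-oriented closed mesh; an
#' independent check on the tetrahedron-sum volume of [alpha_volume()].
#'
#' @param mesh a `triangle_mesh` from [boundary_mesh()].
#' @return volume in cubic metres (0 for an empty mesh).
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!nrow(mesh$faces)) return(0)
  ctr <- colMeans(mesh$vertices)
  v <- sweep(mesh$vertices, 2, ctr)
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  cc <- v[mesh$faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Write a triangle mesh to PLY (ascii) or OBJ
#' @param mesh a `triangle_mesh`.
#' @param path output file.
#' @param format `"ply"` or `"obj"` (guessed from the extension when
#'   omitted).
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "obj")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), ply = "ply",
                     obj = "obj", stop("cannot guess mesh format for ", path))
  }
  v <- mesh$vertices
  f <- mesh$faces
  vrow <- sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3])
  txt <- if (format == "ply") {
    c("ply", "format ascii 1.0",
      paste("element vertex", nrow(v)),
      "property double x", "property double y", "property double z",
      paste("element face", nrow(f)),
      "property list uchar int vertex_indices",
      "end_header", vrow,
      sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  } else {
    c(paste("v", vrow), sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  }
  writeLines(txt, path)
  invisible(path)
}
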