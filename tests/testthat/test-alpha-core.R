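test_that("circumradius matches closed forms, scales linearly, flags coplanarity", {
  v <- regular_tetra(1)
  expect_equal(circumradius(v[1, ], v[2, ], v[3, ], v[4, ]), sqrt(6) / 4,
               tolerance = 1e-12)
  v2 <- regular_tetra(2)
  expect_equal(circumradius(v2[1, ], v2[2, ], v2[3, ], v2[4, ]), sqrt(6) / 2,
               tolerance = 1e-12)
  expect_identical(circumradius(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                c(1, 1, 0)), Inf)
})

test_that("single-tetrahedron complex: retention threshold, hull, boundary mesh", {
  ac <- alpha_complex(tetra_cloud())
  expect_equal(nrow(ac$tets), 1L)
  expect_equal(ac$circumradius, sqrt(6) / 4, tolerance = 1e-12)
  expect_equal(ac$tet_volume, 1 / (6 * sqrt(2)), tolerance = 1e-12)
  expect_equal(alpha_volume(ac, 0.7), 1 / (6 * sqrt(2)), tolerance = 1e-12)
  expect_equal(alpha_volume(ac, 0.5), 0)
  expect_equal(n_retained(ac, 0.7), 1L)
  expect_equal(alpha_volume(ac, Inf), convex_hull_volume(tetra_cloud()),
               tolerance = 1e-12)
  # strictness only matters exactly at the circumradius
  r <- sqrt(6) / 4
  expect_equal(alpha_volume(ac, ac$circumradius, strict = TRUE), 0)
  expect_gt(alpha_volume(ac, ac$circumradius, strict = FALSE), 0)
  expect_equal(nrow(boundary_mesh(ac, 0.7)$faces), 4L)
  empty <- boundary_mesh(ac, 0.5)
  expect_equal(nrow(empty$faces), 0L)
  expect_equal(mesh_volume(empty), 0)
})

test_that("exactly cospherical clouds take the jitter path and conserve volume", {
  ac <- alpha_complex(cube_cloud())
  expect_true(ac$jittered)
  expect_equal(alpha_volume(ac, Inf), 1, tolerance = 1e-6)
  acg <- alpha_complex(make_primitive("grid", m = 4, spacing = 0.25)$cloud)
  expect_true(acg$jittered)
  expect_equal(alpha_volume(acg, Inf), 0.75^3, tolerance = 1e-6)
})

test_that("degenerate clouds raise geometry errors", {
  flat <- point_cloud(cbind(runif(10), runif(10), 0), id = "flat")
  expect_error(alpha_complex(flat), "degenerate|coplanar")
  expect_error(convex_hull_volume(flat), "degenerate|coplanar")
  line <- point_cloud(cbind(1:5, 2 * (1:5), 3 * (1:5)), id = "line")
  expect_error(alpha_complex(line), "degenerate|collinear|coplanar")
})

test_that("alpha volume is monotone in alpha, zero below and hull above the radii", {
  for (seed in 1:4) {
    pc <- rand_cloud(300, seed)
    ac <- alpha_complex(pc)
    alphas <- sort(c(10^seq(-3, 1, length.out = 40), Inf))
    v <- alpha_volume(ac, alphas)
    expect_true(all(diff(v) >= 0))
    expect_gte(min(v), 0)
    fin <- is.finite(ac$circumradius)
    expect_equal(alpha_volume(ac, min(ac$circumradius[fin])), 0)
    expect_equal(alpha_volume(ac, max(ac$circumradius[fin]) * 1.0001),
                 ac$hull_volume, tolerance = 1e-9)
    expect_equal(alpha_volume(ac, Inf), convex_hull_volume(pc),
                 tolerance = 1e-9)
    # conservation: finite tetrahedra partition the hull
    expect_equal(sum(ac$tet_volume[fin]), ac$hull_volume, tolerance = 1e-9)
  }
})

test_that("prefix-sum queries equal the brute-force circumradius filter", {
  pc <- rand_cloud(800, seed = 6)
  ac <- alpha_complex(pc)
  set.seed(60)
  alphas <- exp(runif(20, log(0.01), log(2)))
  brute <- vapply(alphas,
                  function(a) sum(ac$tet_volume[ac$circumradius < a]),
                  numeric(1))
  expect_equal(alpha_volume(ac, alphas), brute, tolerance = 1e-13)
  brute_le <- vapply(alphas,
                     function(a) sum(ac$tet_volume[ac$circumradius <= a]),
                     numeric(1))
  expect_equal(alpha_volume(ac, alphas, strict = FALSE), brute_le,
               tolerance = 1e-13)
})

test_that("alpha volumes are invariant under rigid motion and covariant under scaling", {
  pc <- rand_cloud(400, seed = 8)
  ac <- alpha_complex(pc)
  alphas <- c(0.08, 0.15, 0.3, 1)
  v0 <- alpha_volume(ac, alphas)
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  moved <- point_cloud(pc$points %*% t(R) +
                         matrix(c(5, -2, 11), 400, 3, byrow = TRUE),
                       id = "moved")
  vr <- alpha_volume(alpha_complex(moved), alphas)
  expect_equal(vr, v0, tolerance = 1e-6)
  s <- 3.7
  vs <- alpha_volume(alpha_complex(point_cloud(s * pc$points, id = "s")),
                     s * alphas)
  expect_equal(vs, s^3 * v0, tolerance = 1e-9)
})

test_that("boundary meshes are closed and their divergence volume matches the tet sum", {
  ball <- make_primitive("ball", n_points = 3000, seed = 5)
  acb <- alpha_complex(ball$cloud)
  quad <- make_quadruped(1, n_points = 5000, seed = 4)
  acq <- alpha_complex(quad$cloud)
  cases <- list(list(ac = acb, alpha = 0.3),
                list(ac = acb, alpha = 0.6),
                list(ac = acq, alpha = acq$l_ref * 0.427))
  for (cs in cases) {
    mesh <- boundary_mesh(cs$ac, cs$alpha)
    expect_gt(nrow(mesh$faces), 0)
    # closedness: every edge is shared by an even number of boundary facets
    e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
    ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    expect_true(all(table(ekey) %% 2 == 0))
    expect_equal(mesh_volume(mesh), alpha_volume(cs$ac, cs$alpha),
                 tolerance = 1e-6)
  }
})

test_that("meshes export to PLY and OBJ and re-import as their vertex clouds", {
  ac <- alpha_complex(tetra_cloud())
  mesh <- boundary_mesh(ac, 0.7)
  for (fmt in c("ply", "obj")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(mesh, f)
    back <- read_cloud(f)  # vertices only; faces ignored by design
    expect_equal(unname(back$points), unname(mesh$vertices), tolerance = 1e-9)
  }
})
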