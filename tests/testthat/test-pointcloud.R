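test_that("XYZ parsing handles comments, separators, extra columns and bad rows", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("# LiDAR export", "0 0 0", "1,0,0  ", "0 1 0 99 intensity",
               "0.5 0.5 1.25"), f)
  pc <- read_cloud(f)
  expect_s3_class(pc, "point_cloud")
  expect_equal(n_points(pc), 4L)
  expect_equal(pc$points[2, ], c(x = 1, y = 0, z = 0))
  expect_equal(pc$points[3, ], c(x = 0, y = 1, z = 0))  # extra cols dropped

  writeLines(c("0 0 0", "1 0 0", "0 1 0", "1.0 2.0"), f)
  expect_error(read_cloud(f), "line 4")
  writeLines(c("0 0 0", "1 0 x", "0 1 0", "0 0 1"), f)
  expect_error(read_cloud(f), "line 2")
  writeLines(c("0 0 0", "1 0 0", "0 1 0"), f)
  expect_error(read_cloud(f), "degenerate")
})

test_that("PLY ascii vertices are read and faces discarded", {
  f <- withr::local_tempfile(fileext = ".ply")
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  writeLines(c("ply", "format ascii 1.0", "comment unit cube",
               "element vertex 8",
               "property float x", "property float y", "property float z",
               "element face 2",
               "property list uchar int vertex_indices",
               "end_header",
               apply(v, 1, paste, collapse = " "),
               "3 0 1 2", "4 4 5 7 6"), f)
  pc <- read_cloud(f)
  expect_equal(n_points(pc), 8L)
  expect_equal(unname(pc$points), unname(v) * 1.0)
})

test_that("PLY binary little-endian vertices are read, mixed property types", {
  f <- withr::local_tempfile(fileext = ".ply")
  set.seed(11)
  v <- matrix(runif(24), ncol = 3)
  con <- file(f, "wb")
  writeChar(paste0("ply\nformat binary_little_endian 1.0\n",
                   "element vertex 8\n",
                   "property float x\nproperty float y\nproperty float z\n",
                   "property uchar red\n",
                   "end_header\n"), con, eos = NULL)
  for (i in 1:8) {
    writeBin(as.numeric(v[i, ]), con, size = 4, endian = "little")
    writeBin(as.integer(127), con, size = 1)
  }
  close(con)
  pc <- read_cloud(f)
  expect_equal(n_points(pc), 8L)
  expect_equal(unname(pc$points), unname(v), tolerance = 1e-6)
})

test_that("OBJ vertex records are read, everything else ignored", {
  f <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("# comment", "v 0 0 0", "v 1 0 0", "vn 0 0 1", "v 0 1 0",
               "v 0 0 1", "f 1 2 3"), f)
  pc <- read_cloud(f)
  expect_equal(n_points(pc), 4L)
  expect_equal(pc$points[4, ], c(x = 0, y = 0, z = 1))
})

test_that("write/read round trips preserve coordinates and order in all formats", {
  pc <- rand_cloud(57, seed = 4)
  for (fmt in c("xyz", "ply", "obj")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_cloud(pc, f, fmt)
    back <- read_cloud(f)
    expect_equal(back$points, pc$points, tolerance = 1e-9,
                 info = paste("format", fmt))
  }
  expect_error(write_cloud(pc, tempfile(), "stl"))
})

test_that("downsampling is a deterministic subsample honouring the n > N contract", {
  pc <- rand_cloud(1000, seed = 9)
  s1 <- downsample_cloud(pc, 100, seed = 1)
  s2 <- downsample_cloud(pc, 100, seed = 1)
  expect_identical(s1$points, s2$points)
  expect_equal(n_points(s1), 100L)
  expect_equal(anyDuplicated(s1$points), 0L)
  # every sampled point is a member of the input
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(key(s1$points) %in% key(pc$points)))
  expect_false(identical(downsample_cloud(pc, 100, seed = 2)$points,
                         s1$points))
  small <- rand_cloud(50, seed = 3)
  expect_warning(full <- downsample_cloud(small, 100, seed = 1),
                 "fewer than requested")
  expect_identical(full$points, small$points)
  expect_error(downsample_cloud(pc, 3), "at least 4")
})

test_that("size metrics match closed forms", {
  m <- size_metrics(cube_cloud())
  expect_equal(m$l_ref, sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(m$bbox_diagonal, sqrt(3), tolerance = 1e-12)
  expect_equal(m$max_length, 1)
  expect_equal(unname(m$centroid), c(0.5, 0.5, 0.5))

  two <- point_cloud(rbind(c(0, 0, 0), c(0, 0, 2)), id = "pair")
  m2 <- size_metrics(two)
  expect_equal(unname(m2$centroid), c(0, 0, 1))
  expect_equal(m2$l_ref, 1)
  expect_equal(m2$max_height, 2)
  expect_equal(size_metrics(two, vertical_axis = 1)$max_height, 0)

  expect_error(size_metrics(point_cloud(matrix(1, 4, 3), id = "same")),
               "identical")
})

test_that("size metrics are translation invariant and scale equivariantly", {
  for (seed in 1:3) {
    pc <- rand_cloud(120, seed)
    m0 <- size_metrics(pc)
    shifted <- point_cloud(sweep(pc$points, 2, c(-3, 7, 0.5), "+"), id = "t")
    mt <- size_metrics(shifted)
    for (f in c("l_ref", "max_height", "max_length", "bbox_diagonal"))
      expect_equal(mt[[f]], m0[[f]], tolerance = 1e-12)
    s <- 2.5
    ms <- size_metrics(point_cloud(s * pc$points, id = "s"))
    for (f in c("l_ref", "max_height", "max_length", "bbox_diagonal"))
      expect_equal(ms[[f]], s * m0[[f]], tolerance = 1e-12)
  }
})
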