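# fixtures are built in code; nothing is read from disk

# vertices of a regular tetrahedron with the given edge length
regular_tetra <- function(edge = 1) {
  edge * rbind(c(0, 0, 0), c(1, 0, 0),
               c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(6) / 3))
}

tetra_cloud <- function(edge = 1, id = "tetra")
  point_cloud(regular_tetra(edge), id = id)

cube_cloud <- function(side = 1, id = "cube")
  point_cloud(side * as.matrix(expand.grid(0:1, 0:1, 0:1)), id = id)

# uniform random cloud in the unit box, locally seeded
rand_cloud <- function(n, seed, id = paste0("rand", seed)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  point_cloud(matrix(runif(3 * n), ncol = 3), id = id)
}

# Rodrigues rotation matrix: angle (rad) about a (non-unit) axis
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

with_seed_test <- function(seed, code) alphamass:::with_seed(seed, code)

# small synthetic calibration sample shared by calibration/prediction tests
small_family <- function(n_spec = 4, n_points = 6000, seed = 2)
  make_family(scales = seq(0.6, 1.8, length.out = n_spec),
              n_points = n_points, seed = seed)

family_inputs <- function(fam) {
  list(clouds = lapply(fam, `[[`, "cloud"),
       masses = data.frame(
         specimen_id = vapply(fam, `[[`, "", "specimen_id"),
         mass_kg = vapply(fam, `[[`, 1, "assigned_mass")))
}
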