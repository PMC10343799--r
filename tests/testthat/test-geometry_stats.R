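# synthetic cylinder: full rings of points at several heights, so the
# centroid lies exactly on the axis and the principal direction is exact
cylinder_points <- function(n_ang = 24, n_z = 10, radius = 9.08,
                            length = 30) {
  th <- seq(0, 2 * pi, length.out = n_ang + 1)[-(n_ang + 1)]
  zz <- seq(0, length, length.out = n_z)
  g <- expand.grid(th = th, z = zz)
  cbind(radius * cos(g$th), radius * sin(g$th), g$z)
}

as_assembly <- function(P, name = "C") {
  n <- nrow(P)
  Assembly(data.frame(index = seq_len(n), name = name, element = "C",
                      unit_id = seq_len(n), residue_id = 1L,
                      x = P[, 1], y = P[, 2], z = P[, 3], mass = 12,
                      charge = NA_real_, stringsAsFactors = FALSE))
}

test_that("fit_axis recovers cylinder axes, rotated axes and lines", {
  P <- cylinder_points()
  ax <- fit_axis(as_assembly(P))
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-8)
  set.seed(11)
  for (i in 1:5) {
    R <- random_rotation()
    ax2 <- fit_axis(as_assembly(P %*% t(R)))
    want <- as.vector(R %*% c(0, 0, 1))
    expect_equal(abs(sum(ax2$direction * want)), 1, tolerance = 1e-6)
  }
  line <- cbind(seq_len(10), 2 * seq_len(10), -seq_len(10))
  axl <- fit_axis(as_assembly(line))
  expect_equal(abs(sum(axl$direction * c(1, 2, -1) / sqrt(6))), 1,
               tolerance = 1e-10)
  expect_error(fit_axis(as_assembly(matrix(0, 5, 3))), "degenerate")
})

test_that("radial_stats matches brute force and is rigid-motion invariant", {
  P <- cylinder_points(radius = 9.08)
  a <- as_assembly(P)
  ax <- fit_axis(a)
  rs <- radial_stats(a, ax)
  expect_equal(rs$mean_radius, 9.08, tolerance = 1e-6)
  expect_lt(rs$layer_thickness, 1e-6)
  # outlier arithmetic: ring radius r plus one atom at 2r
  r0 <- 5; n <- 60
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ring <- rbind(cbind(r0 * cos(th), r0 * sin(th), 0), c(2 * r0, 0, 0))
  axz <- structure(list(point = c(0, 0, 0), direction = c(0, 0, 1),
                        method = "principal_component"), class = "AxisFit")
  rs2 <- radial_stats(as_assembly(ring), axz)
  expect_equal(rs2$max_radius, 2 * r0, tolerance = 1e-12)
  expect_equal(rs2$mean_radius, (n * r0 + 2 * r0) / (n + 1),
               tolerance = 1e-12)
  # brute-force oracle for point-to-line distances on random fixtures
  set.seed(21)
  Q <- matrix(rnorm(90, sd = 5), 30, 3)
  p0 <- rnorm(3); d0 <- rnorm(3); d0 <- d0 / sqrt(sum(d0^2))
  axr <- structure(list(point = p0, direction = d0,
                        method = "principal_component"), class = "AxisFit")
  brute <- apply(Q, 1, function(q) {
    v <- q - p0
    sqrt(sum(v^2) - sum(v * d0)^2)
  })
  expect_equal(radial_stats(as_assembly(Q), axr)$mean_radius, mean(brute),
               tolerance = 1e-10)
  # consistent rigid motion leaves the report unchanged
  R <- random_rotation(); tr <- c(3, -2, 7)
  a2 <- as_assembly(sweep(P %*% t(R), 2, tr, "+"))
  ax2 <- structure(list(point = as.vector(R %*% ax$point) + tr,
                        direction = as.vector(R %*% ax$direction),
                        method = "principal_component"), class = "AxisFit")
  rs3 <- radial_stats(a2, ax2)
  expect_equal(rs3$mean_radius, rs$mean_radius, tolerance = 1e-9)
  expect_equal(rs3$layer_thickness, rs$layer_thickness, tolerance = 1e-9)
})

test_that("pair_fit recovers rigid motions and never reflects", {
  h <- build_parametric_helix(params = HelixParams(n_units = 12))
  npairs <- 21
  idx <- which(h$atoms$name == "N")[seq_len(npairs)]
  pairs <- cbind(idx, idx)
  self <- pair_fit(h, h, pairs)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  set.seed(31)
  R <- random_rotation(); tr <- c(10, -4, 2)
  hm <- pnthelix:::set_coords(h, sweep(as.matrix(h) %*% t(R), 2, tr, "+"))
  fit <- pair_fit(hm, h, pairs)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # aligning the mirror image must NOT reflect: det stays +1, rmsd > 0
  fitm <- pair_fit(mirror(h), h, pairs)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-9)
  expect_gt(fitm$rmsd, 0.5)
  expect_error(pair_fit(h, h, pairs[1:2, ]), ">= 3")
})

test_that("noisy pair_fit RMSD matches the isotropic-noise expectation", {
  # closed form: superposition removes 6 of 3n dof, so
  # E[RMSD^2] ~ sigma^2 (3n - 6) / n for small isotropic noise
  h <- build_parametric_helix(params = HelixParams(n_units = 12))
  idx <- which(h$atoms$name == "N")[1:21]
  pairs <- cbind(idx, idx)
  sigma <- 1; n <- 21
  want <- sigma * sqrt((3 * n - 6) / n)
  set.seed(41)
  got <- replicate(40, {
    noisy <- h
    noisy$atoms[, c("x", "y", "z")] <-
      noisy$atoms[, c("x", "y", "z")] + rnorm(3 * nrow(noisy$atoms), 0, sigma)
    pair_fit(noisy, h, pairs)$rmsd
  })
  expect_equal(mean(got), want, tolerance = 0.08) # Monte-Carlo tolerance
})

test_that("cylindrical maps: constant cylinder, protrusion, mirror flip", {
  P <- cylinder_points(n_ang = 36, n_z = 12, radius = 7)
  a <- as_assembly(P)
  axz <- structure(list(point = c(0, 0, 15), direction = c(0, 0, 1),
                        method = "principal_component"), class = "AxisFit")
  m <- cylindrical_map(a, axz, n_angular = 12, n_axial = 6)
  expect_equal(max(abs(m$outer - 7), na.rm = TRUE), 0, tolerance = 1e-9)
  # one protruding atom raises exactly one bin above r
  Pp <- rbind(P, c(14, 0, 15))
  mp <- cylindrical_map(as_assembly(Pp), axz, n_angular = 12, n_axial = 6)
  expect_equal(sum(mp$outer > 7 + 1e-6, na.rm = TRUE), 1)
  # mirror reverses the angular coordinate of the occupied pattern
  hx <- build_parametric_helix(params = HelixParams(n_units = 12))
  ax <- structure(list(point = colMeans(as.matrix(hx)),
                       direction = c(0, 0, 1),
                       method = "principal_component"), class = "AxisFit")
  axm <- ax; axm$point <- ax$point * c(-1, 1, 1)
  m1 <- cylindrical_map(hx, ax, n_angular = 18, n_axial = 6)
  m2 <- cylindrical_map(mirror(hx), axm, n_angular = 18, n_axial = 6)
  # same multiset of outer radii per z slab, mirrored arrangement
  for (j in 1:6)
    expect_equal(sort(m2$outer[, j]), sort(m1$outer[, j]), tolerance = 1e-9)
})
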