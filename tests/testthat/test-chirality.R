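test_that("component triple product equals the determinant oracle", {
  expect_identical(triple_product(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 1)
  expect_identical(triple_product(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  set.seed(101)
  for (i in 1:1000) {
    v <- matrix(rnorm(9, sd = 10^runif(1, -2, 2)), 3, 3)
    got <- triple_product(v[, 1], v[, 2], v[, 3])
    want <- det(v)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("calpha_vectors orders, counts and translates correctly", {
  ch <- build_linear_chain("L", 24, 10)
  sv <- calpha_vectors(ch)
  expect_equal(nrow(sv$calpha), 48)   # 2 Calpha per unit
  expect_equal(nrow(sv$vectors), 47)
  sh <- ch; sh$atoms$x <- sh$atoms$x + 5; sh$atoms$z <- sh$atoms$z - 3
  expect_lt(max(abs(calpha_vectors(sh)$vectors - sv$vectors)), 1e-9)
  one <- build_ff_unit("L")
  expect_error(calpha_vectors(one), "insufficient")
  # collinear Calphas give X_total exactly 0
  P <- cbind(0, 0, seq_len(10))
  expect_identical(calpha_chirality(points_as_calpha(P))$x_total, 0)
})

test_that("Calpha index: sign, parity, rigid motion, scaling law", {
  P <- helix_points(24, radius = 2, pitch = 3)
  a <- points_as_calpha(P)
  rep_ <- calpha_chirality(a)
  expect_gt(rep_$x_total, 0)
  expect_equal(rep_$sign_label, "D")
  expect_equal(rep_$x_total, oracle_x_total(P), tolerance = 1e-10)
  # parity: mirror negates x_total and chi_norm exactly
  m <- calpha_chirality(mirror(a))
  expect_equal(m$x_total, -rep_$x_total, tolerance = 0)
  expect_equal(m$chi_norm, -rep_$chi_norm, tolerance = 0)
  expect_equal(m$sign_label, "L")
  # rigid motion invariance
  set.seed(7)
  for (i in 1:5) {
    R <- random_rotation()
    Pm <- sweep(P %*% t(R), 2, rnorm(3, sd = 20), "+")
    r2 <- calpha_chirality(points_as_calpha(Pm))
    expect_equal(r2$x_total, rep_$x_total, tolerance = 1e-8)
    expect_equal(r2$chi_norm, rep_$chi_norm, tolerance = 1e-8)
  }
  # scaling: x_total ~ s^3, chi_norm ~ s^(3-k)
  for (s in c(0.5, 2)) {
    rs <- calpha_chirality(points_as_calpha(P * s))
    expect_equal(rs$x_total, rep_$x_total * s^3, tolerance = 1e-10)
    expect_equal(rs$chi_norm, rep_$chi_norm * s^(3 - 5), tolerance = 1e-10)
  }
  # k is configurable and enters the normalization
  rk <- calpha_chirality(a, CalphaChiralityParams(k = 3))
  expect_equal(calpha_chirality(points_as_calpha(P * 2),
                                CalphaChiralityParams(k = 3))$chi_norm,
               rk$chi_norm, tolerance = 1e-10) # s^(3-3) = 1
  # degenerate geometry is reported with the offending pair
  Pd <- P; Pd[3, ] <- Pd[2, ]
  expect_error(calpha_chirality(points_as_calpha(Pd)), "Calpha 2 and 3")
})

test_that("unit dipoles: point dipole, neutrality, COM invariance", {
  a <- Assembly(data.frame(
    index = 1:2, name = c("P", "M"), element = "C", unit_id = 1L,
    residue_id = 1L, x = 0, y = 0, z = c(0.5, -0.5), mass = 12,
    charge = c(1, -1), stringsAsFactors = FALSE))
  expect_equal(unit_dipole(a, 1), c(0, 0, 1), tolerance = 1e-12)
  a0 <- a; a0$atoms$charge <- 0
  expect_equal(unit_dipole(a0, 1), c(0, 0, 0))
  at <- a; at$atoms$x <- at$atoms$x + 7; at$atoms$z <- at$atoms$z + 3
  expect_equal(unit_dipole(at, 1), unit_dipole(a, 1), tolerance = 1e-12)
  am <- a; am$atoms$charge <- NA_real_
  expect_error(unit_dipole(am, 1), "missing charge")
})

test_that("dipole index: tangent construction sign, homogeneity, parity", {
  a <- tangent_dipole_assembly(n = 6, handed = 1) # one full right turn
  rep_ <- dipole_chirality(a)
  expect_gt(rep_$c_total, 0)
  expect_equal(rep_$sign_label, "D")
  # brute-force oracle on the explicitly constructed dipole vectors
  D <- t(vapply(1:6, function(u) unit_dipole(a, u), numeric(3)))
  s <- 0
  for (i in 1:4) s <- s + det(cbind(D[i, ], D[i + 1, ], D[i + 2, ]))
  expect_equal(rep_$c_total, s, tolerance = 1e-12)
  left <- dipole_chirality(tangent_dipole_assembly(n = 6, handed = -1))
  expect_lt(left$c_total, 0)
  expect_equal(left$sign_label, "L")
  # mirror flips c_total and c_norm exactly
  m <- dipole_chirality(mirror(a))
  expect_equal(m$c_total, -rep_$c_total, tolerance = 0)
  expect_equal(m$c_norm, -rep_$c_norm, tolerance = 0)
  # scaling every dipole by s > 0 leaves c_norm unchanged
  a3 <- a; a3$atoms$charge <- a3$atoms$charge * 3.7
  r3 <- dipole_chirality(a3)
  expect_equal(r3$c_total, rep_$c_total * 3.7^3, tolerance = 1e-9)
  expect_equal(r3$c_norm, rep_$c_norm, tolerance = 1e-9)
  # reversing every dipole negates c_total
  arev <- a; arev$atoms$charge <- -arev$atoms$charge
  expect_equal(dipole_chirality(arev)$c_total, -rep_$c_total, tolerance = 0)
  # works for any n >= 3, not just one coil
  expect_gt(dipole_chirality(tangent_dipole_assembly(n = 17))$c_total, 0)
  expect_error(dipole_chirality(tangent_dipole_assembly(n = 2)), ">= 3")
  # zero dipoles: c_total reported, normalization flagged
  az <- tangent_dipole_assembly(4); az$atoms$charge <- 0
  expect_warning(rz <- dipole_chirality(az), "normalization")
  expect_identical(rz$c_total, 0)
})

test_that("windowed profile separates single-handed from composite", {
  P <- helix_points(40, radius = 2, pitch = 3)
  prof <- chirality_profile(points_as_calpha(P), window = 8)
  expect_equal(prof$frac_positive, 1)
  expect_equal(prof$frac_negative, 0)
  expect_equal(prof$label, "D")
  # composite: right-handed half continued by its mirror continuation
  P2 <- helix_points(20, radius = 2, pitch = 3)
  Pm <- cbind(-P2[, 1], P2[, 2], P2[, 3])          # left-handed half
  Pm <- sweep(Pm, 2, Pm[1, ] - P2[20, ], "-")      # continue from the join
  comp <- points_as_calpha(rbind(P2, Pm[-1, , drop = FALSE]))
  pc <- chirality_profile(comp, window = 8)
  expect_gt(pc$frac_positive, 0.25)
  expect_gt(pc$frac_negative, 0.25)
  expect_equal(pc$label, "mixed")
  # mirror flips every window value
  pm <- chirality_profile(mirror(comp), window = 8)
  expect_equal(pm$values, -pc$values, tolerance = 0)
  expect_error(chirality_profile(points_as_calpha(P), window = 3), "window")
})
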