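# shared fixtures and independent oracles

# random proper rotation (det = +1) via QR decomposition
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# brute-force oracle for the summed mixed product of consecutive difference
# vectors: base-R determinants, independent of the package's component code
oracle_x_total <- function(points) {
  V <- diff(points)
  s <- 0
  for (i in seq_len(nrow(V) - 2))
    s <- s + det(cbind(V[i, ], V[i + 1, ], V[i + 2, ]))
  s
}

# ideal helix of bare points: right-handed for omega > 0
helix_points <- function(n, radius = 2, pitch = 3, omega = 2 * pi / 6) {
  t <- (seq_len(n) - 1) * omega
  cbind(radius * cos(t), radius * sin(t), pitch * t / (2 * pi))
}

# wrap a point matrix into an Assembly of one-Calpha "units"
points_as_calpha <- function(P) {
  n <- nrow(P)
  Assembly(data.frame(
    index = seq_len(n), name = "CA", element = "C", unit_id = seq_len(n),
    residue_id = 1L, x = P[, 1], y = P[, 2], z = P[, 3], mass = 12.011,
    charge = NA_real_, stringsAsFactors = FALSE))
}

# assembly of two-atom units whose dipoles are exactly the helix tangents
# (charge +1 offset +0.5 t, charge -1 offset -0.5 t about each centre)
tangent_dipole_assembly <- function(n = 6, radius = 2, pitch = 3,
                                    omega = 2 * pi / 6, handed = 1) {
  t_par <- (seq_len(n) - 1) * omega * handed
  ctr <- cbind(radius * cos(t_par), radius * sin(t_par),
               pitch * abs(t_par) / (2 * pi))
  tan_v <- cbind(-radius * omega * handed * sin(t_par),
                 radius * omega * handed * cos(t_par),
                 rep(pitch * omega / (2 * pi), n))
  tan_v <- tan_v / sqrt(rowSums(tan_v^2))
  rows <- lapply(seq_len(n), function(i) {
    data.frame(index = c(2L * i - 1L, 2L * i), name = c("QP", "QM"),
               element = "C", unit_id = i, residue_id = 1L,
               x = ctr[i, 1] + c(0.5, -0.5) * tan_v[i, 1],
               y = ctr[i, 2] + c(0.5, -0.5) * tan_v[i, 2],
               z = ctr[i, 3] + c(0.5, -0.5) * tan_v[i, 3],
               mass = 12, charge = c(1, -1), stringsAsFactors = FALSE)
  })
  Assembly(do.call(rbind, rows))
}

# short scaled-down protocol for engine tests (full stages take minutes)
tiny_schedule <- function() SpringSchedule(c(0.001, 0.01, 0.1, 1.1),
                                           c(0.2, 0.2, 0.3, 0.3))
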