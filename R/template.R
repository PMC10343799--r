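# Idealized internal-coordinate template for one zwitterionic FF unit.
#
# The unit is the complete zwitterionic diphenylalanine dipeptide,
# C18 H20 N2 O3 = 43 atoms: a protonated N-terminal amino group (NH3+), a
# deprotonated C-terminal carboxylate (CO2-), two phenyl side chains, and an
# extended backbone.  Geometry comes from standard bond lengths and angles,
# not from any crystal structure; the template is a self-contained synthetic
# stand-in whose only structural claims are connectivity, atom count, and
# the L configuration at both alpha carbons.

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)

# Place atom d given positions of a (dihedral ref), b (angle ref), c (parent),
# with |d-c| = bond, angle(d,c,b) = ang (deg), torsion(d,c,b,a) = dih (deg).
.nerf_place <- function(a, b, c, bond, ang, dih) {
  ang <- ang * pi / 180
  dih <- dih * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Z-matrix rows: name, element, residue, parent, angle-ref, dihedral-ref,
# bond (A), angle (deg), torsion (deg).  Chirality at both CA atoms follows
# the L convention det[N-CA, C-CA, CB-CA] > 0 (frozen in the test suite
# against an external cheminformatics oracle).
.ff_zmatrix <- function() {
  s <- 1 # L configuration switch; mirroring is done in cartesian space
  z <- rbind.data.frame(
    # name element res  p  b  a   bond  angle   dih
    list("N",  "N", 1L,  0L, 0L, 0L, NA,    NA,    NA),
    list("CA", "C", 1L,  1L, 0L, 0L, 1.47,  NA,    NA),
    list("C",  "C", 1L,  2L, 1L, 0L, 1.53,  111,   NA),
    list("O",  "O", 1L,  3L, 2L, 1L, 1.23,  121,   -30),
    list("CB", "C", 1L,  2L, 1L, 3L, 1.53,  110.5, -s * 120),
    list("CG", "C", 1L,  5L, 2L, 1L, 1.51,  114,   180),
    list("CD1","C", 1L,  6L, 5L, 2L, 1.39,  120.9, 90),
    list("CD2","C", 1L,  6L, 5L, 2L, 1.39,  120.9, -90),
    list("CE1","C", 1L,  7L, 6L, 5L, 1.39,  120,   180),
    list("CE2","C", 1L,  8L, 6L, 5L, 1.39,  120,   180),
    list("CZ", "C", 1L,  9L, 7L, 6L, 1.39,  120,   0),
    list("H1", "H", 1L,  1L, 2L, 3L, 1.03,  109.5, 60),
    list("H2", "H", 1L,  1L, 2L, 3L, 1.03,  109.5, 180),
    list("H3", "H", 1L,  1L, 2L, 3L, 1.03,  109.5, -60),
    list("HA", "H", 1L,  2L, 1L, 3L, 1.09,  108,   s * 120),
    list("HB2","H", 1L,  5L, 2L, 1L, 1.09,  109,   60),
    list("HB3","H", 1L,  5L, 2L, 1L, 1.09,  109,   -60),
    list("HD1","H", 1L,  7L, 6L, 5L, 1.08,  120,   0),
    list("HD2","H", 1L,  8L, 6L, 5L, 1.08,  120,   0),
    list("HE1","H", 1L,  9L, 7L, 6L, 1.08,  120,   180),
    list("HE2","H", 1L, 10L, 8L, 6L, 1.08,  120,   180),
    list("HZ", "H", 1L, 11L, 9L, 7L, 1.08,  120,   180),
    # residue 2 (C-terminal, carboxylate)
    list("N",  "N", 2L,  3L, 2L, 1L, 1.33,  114,   150),  # psi_1
    list("CA", "C", 2L, 23L, 3L, 2L, 1.46,  122,   180),  # omega trans
    list("C",  "C", 2L, 24L, 23L, 3L, 1.53, 111,   -150), # phi_2
    list("O",  "O", 2L, 25L, 24L, 23L, 1.25, 117,  -30),
    list("OXT","O", 2L, 25L, 24L, 23L, 1.25, 117,  150),
    list("CB", "C", 2L, 24L, 23L, 25L, 1.53, 110.5, -s * 120),
    list("CG", "C", 2L, 28L, 24L, 23L, 1.51, 114,  180),
    list("CD1","C", 2L, 29L, 28L, 24L, 1.39, 120.9, 90),
    list("CD2","C", 2L, 29L, 28L, 24L, 1.39, 120.9, -90),
    list("CE1","C", 2L, 30L, 29L, 28L, 1.39, 120,  180),
    list("CE2","C", 2L, 31L, 29L, 28L, 1.39, 120,  180),
    list("CZ", "C", 2L, 32L, 30L, 29L, 1.39, 120,  0),
    list("H",  "H", 2L, 23L, 3L, 2L, 1.02,  119,   0),    # amide H, anti to CA2
    list("HA", "H", 2L, 24L, 23L, 25L, 1.09, 108,  s * 120),
    list("HB2","H", 2L, 28L, 24L, 23L, 1.09, 109,  60),
    list("HB3","H", 2L, 28L, 24L, 23L, 1.09, 109,  -60),
    list("HD1","H", 2L, 30L, 29L, 28L, 1.08, 120,  0),
    list("HD2","H", 2L, 31L, 29L, 28L, 1.08, 120,  0),
    list("HE1","H", 2L, 32L, 30L, 29L, 1.08, 120,  180),
    list("HE2","H", 2L, 33L, 31L, 29L, 1.08, 120,  180),
    list("HZ", "H", 2L, 34L, 32L, 30L, 1.08, 120,  180)
  )
  names(z) <- c("name", "element", "residue_id", "p", "b", "a",
                "bond", "angle", "dih")
  z$name <- as.character(z$name)
  z$element <- as.character(z$element)
  z
}

# Cartesian coordinates of the L template in a canonical frame:
# centre of mass at origin, CA1 -> CA2 along +z, CB1 in the +x half plane.
.ff_template_coords <- function(z) {
  n <- nrow(z)
  xyz <- matrix(NA_real_, n, 3)
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(0, 0, z$bond[2])
  # angle(N, CA, C): vector CA->N is (0,0,-1); choose C in the xz plane
  ang3 <- z$angle[3] * pi / 180
  xyz[3, ] <- xyz[2, ] + z$bond[3] * c(sin(ang3), 0, -cos(ang3))
  for (i in 4:n) {
    xyz[i, ] <- .nerf_place(xyz[z$a[i], ], xyz[z$b[i], ], xyz[z$p[i], ],
                            z$bond[i], z$angle[i], z$dih[i])
  }
  mass <- .element_masses[z$element]
  com <- colSums(xyz * mass) / sum(mass)
  xyz <- sweep(xyz, 2, com)
  # rotate CA1 -> CA2 onto +z
  ax <- xyz[24, ] - xyz[2, ]
  ax <- ax / sqrt(sum(ax^2))
  xyz <- xyz %*% t(.rotation_between(ax, c(0, 0, 1)))
  # rotate about z so CB1 (atom 5) relative to CA1 points into +x
  v <- xyz[5, ] - xyz[2, ]
  th <- atan2(v[2], v[1])
  rz <- matrix(c(cos(-th), -sin(-th), 0, sin(-th), cos(-th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  xyz %*% t(rz)
}

# proper rotation taking unit vector u onto unit vector v (Rodrigues)
.rotation_between <- function(u, v) {
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  cth <- sum(u * v)
  if (abs(cth + 1) < 1e-12) { # antiparallel: rotate pi about any orthogonal
    o <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- o - sum(o * u) * u
    w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3))
  }
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + cth)
}

# bond list (1-2 connectivity) of the template: z-matrix parents + the two
# phenyl ring closures
.ff_template_bonds <- function(z) {
  b <- cbind(seq_len(nrow(z))[-1], z$p[-1])
  rbind(b, c(11L, 10L), c(34L, 33L))
}

.ff_template_cache <- new.env(parent = emptyenv())

ff_template <- function() {
  if (is.null(.ff_template_cache$tpl)) {
    z <- .ff_zmatrix()
    xyz <- .ff_template_coords(z)
    .ff_template_cache$tpl <- list(z = z, xyz = xyz,
                                   bonds = .ff_template_bonds(z))
  }
  .ff_template_cache$tpl
}
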