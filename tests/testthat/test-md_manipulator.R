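test_that("free particle moves uniformly without forces or thermostat", {
  s <- particle_system(matrix(0, 1, 3), mass = 12,
                       velocities = matrix(c(0.1, 0.2, 0.3), 1, 3))
  r <- md_step(s, nsteps = 1000, dt = 0.001)
  expect_equal(as.vector(r$system$coords), c(0.1, 0.2, 0.3),
               tolerance = 1e-12)
})

test_that("harmonic pair conserves energy and matches the analytic period", {
  k_pn <- 100; m <- 12
  s <- particle_system(rbind(c(0, 0, 0), c(0, 0, 2.2)), mass = c(m, m),
                       bonds = data.frame(atom_a = 1, atom_b = 2,
                                          k = k_pn, r0 = 2.0))
  r <- md_step(s, nsteps = 10000, dt = 0.001, save_every = 5)
  E <- unlist(r$potential) + unlist(r$kinetic)
  expect_lt((max(E) - min(E)) / E[1], 1e-4)
  # closed-form oracle: omega = sqrt(k_internal / mu), mu = m/2
  k_int <- k_pn / pnt_units$pN_per_internal_force
  period <- 2 * pi / sqrt(k_int / (m / 2))
  sep <- vapply(r$frames, function(f) f[2, 3] - f[1, 3], numeric(1))
  crossings <- which(diff(sign(sep - 2.0)) < 0)
  measured <- mean(diff(unlist(r$times)[crossings]))
  expect_equal(measured, period, tolerance = 0.02)
})

test_that("NVE on a thermalized FF unit shows no secular energy drift", {
  sys <- ff_system(build_ff_unit("L"))
  warm <- md_step(sys, nsteps = 5000, dt = 0.001,
                  thermostat = ThermostatParams(seed = 5))
  r <- md_step(warm$system, nsteps = 10000, dt = 0.001, save_every = 100)
  E <- unlist(r$potential) + unlist(r$kinetic)
  n <- length(E)
  drift <- abs(mean(E[(n - 9):n]) - mean(E[1:10])) / abs(mean(E[1:10]))
  expect_lt(drift, 1e-4)
})

test_that("collisional thermostat equilibrates to the target temperature", {
  set.seed(3)
  s <- particle_system(matrix(runif(120) * 20, 40, 3), mass = rep(12, 40))
  th <- ThermostatParams(lambda_rate = 5, m0 = 1, temperature = 300,
                         seed = 42)
  r <- md_step(s, nsteps = 40000, dt = 0.001, thermostat = th,
               save_every = 20)
  ke <- unlist(r$kinetic); tm <- unlist(r$times)
  Tmeas <- mean(ke[tm > 8]) / (0.5 * pnt_units$kB * 3 * 40) # > 20 ps window
  expect_lt(abs(Tmeas - 300) / 300, 0.05)
})

test_that("trajectories are bitwise deterministic in the seed", {
  ch <- build_linear_chain("L", 2, 10)
  sys <- ff_system(ch)
  th <- ThermostatParams(seed = 7)
  a <- md_step(sys, nsteps = 2000, dt = 0.001, thermostat = th,
               fixed_atoms = 1)
  b <- md_step(sys, nsteps = 2000, dt = 0.001, thermostat = th,
               fixed_atoms = 1)
  expect_identical(a$system$coords, b$system$coords)
  expect_identical(a$system$velocities, b$system$velocities)
  c_ <- md_step(sys, nsteps = 2000, dt = 0.001,
                thermostat = ThermostatParams(seed = 8), fixed_atoms = 1)
  expect_false(identical(a$system$coords, c_$system$coords))
  # fixed atom never moves, exactly
  expect_identical(unname(a$system$coords[1, ]), unname(sys$coords[1, ]))
})

test_that("mirrored run with mirrored impulses is the mirrored trajectory", {
  ch <- build_linear_chain("L", 2, 10)
  th <- ThermostatParams(seed = 11)
  a <- md_step(ff_system(ch), nsteps = 10000, dt = 0.001, thermostat = th,
               fixed_atoms = 1)
  m <- md_step(ff_system(mirror(ch)), nsteps = 10000, dt = 0.001,
               thermostat = th, fixed_atoms = 1, mirror_impulses = TRUE)
  dev <- max(abs(m$system$coords -
                 cbind(-a$system$coords[, 1], a$system$coords[, 2:3])))
  expect_lt(dev, 1e-6) # bitwise mirror in practice
})

test_that("scaffold emits the four spring kinds with stated counts", {
  ch <- build_linear_chain("L", 24, 10)
  hp <- HelixParams(units_per_turn = 6, rise_per_turn = 6, radius = 9,
                    n_units = 24)
  sc <- build_scaffold(ch, hp)
  counts <- table(sc$kind)
  expect_equal(unname(counts["contact_NH3_CO2"]), 23)  # consecutive pairs
  expect_equal(unname(counts["helix_pitch"]), 18)      # (1,7)...(18,24)
  expect_equal(unname(counts["inner_diameter"]), 48)
  expect_equal(unname(counts["outer_diameter_even"] +
                      counts["outer_diameter_odd"]), 48)
  expect_equal(unique(sc$rest_length[sc$kind == "helix_pitch"]), 6)
  # inner rest length with target 4 A and default 2 A offset is 2 A
  sc2 <- build_scaffold(ch, hp, inner_radius = 4)
  expect_equal(unique(sc2$rest_length[sc2$kind == "inner_diameter"]), 2)
  expect_true(all(sc$atom_a != sc$atom_b, na.rm = TRUE))
})

test_that("staged run is reproducible and parity-equivariant end to end", {
  ch <- build_linear_chain("L", 3, 10)
  hp <- HelixParams(n_units = 3)
  sc <- build_scaffold(ch, hp)
  th <- ThermostatParams(seed = 3)
  ip <- IntegratorParams(relaxation_duration = 0.5, save_every_ps = 0.25)
  r1 <- run_assembly(ch, sc, tiny_schedule(), th, ip)
  r2 <- run_assembly(ch, sc, tiny_schedule(), th, ip)
  expect_identical(as.matrix(r1$final), as.matrix(r2$final))
  expect_equal(length(r1$trajectory$frames) > 3, TRUE)
  expect_true(all(diff(r1$trajectory$times) > 0))
  # total steered time of the default schedule is 80 ps
  expect_equal(sum(SpringSchedule()$duration), 80)
  # mirrored chain + mirrored impulses => mirrored final structure
  rm_ <- run_assembly(mirror(ch), sc2 <- build_scaffold(mirror(ch), hp),
                      tiny_schedule(), th, ip, mirror_impulses = TRUE)
  A <- as.matrix(r1$final); M <- as.matrix(rm_$final)
  expect_lt(max(abs(M - cbind(-A[, 1], A[, 2:3]))), 1e-6)
  # chirality outcome flips sign exactly
  x1 <- calpha_chirality(r1$final)$x_total
  xm <- calpha_chirality(rm_$final)$x_total
  expect_equal(xm, -x1, tolerance = 1e-9)
})

test_that("stability check distinguishes frozen from melted structures", {
  ch <- build_linear_chain("L", 4, 10)
  hp <- HelixParams(n_units = 4)
  sc <- build_scaffold(ch, hp)
  ip <- IntegratorParams(relaxation_duration = 1, save_every_ps = 0.25)
  sched <- SpringSchedule(0.001, 0.5)
  cold <- run_assembly(ch, sc, sched,
                       ThermostatParams(lambda_rate = 10,
                                        temperature = 1e-4, seed = 1), ip)
  sc_cold <- stability_check(cold$trajectory, cold$final)
  expect_lt(sc_cold$rmsd_core, 0.2)
  expect_true(sc_cold$retained)
  hot <- run_assembly(ch, sc, sched,
                      ThermostatParams(temperature = 5000, seed = 1), ip)
  sc_hot <- stability_check(hot$trajectory, hot$final)
  expect_false(sc_hot$retained)
  expect_length(sc_cold$per_unit_drift, 4)
})

test_that("run_batch differs only in the RNG stream and records failures", {
  ch <- build_linear_chain("L", 2, 10)
  hp <- HelixParams(n_units = 2)
  sc <- build_scaffold(ch, hp)
  ip <- IntegratorParams(relaxation_duration = 0.3, save_every_ps = 0.3)
  sched <- SpringSchedule(c(0.01, 0.1), c(0.3, 0.3))
  # 2 Calphas per unit x 2 units: window must fit 4 Calphas
  b1 <- run_batch(ch, sc, sched, ThermostatParams(), ip, n_runs = 3,
                  base_seed = 5, window = 4)
  b2 <- run_batch(ch, sc, sched, ThermostatParams(), ip, n_runs = 3,
                  base_seed = 5, window = 4)
  expect_identical(b1, b2)
  expect_equal(b1$seed, 5:7)
  expect_false(any(duplicated(b1$chirality_value)))
  expect_true(all(is.na(b1$error)))
  expect_error(run_batch(ch, sc, sched, n_runs = 0), "n_runs")
})
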