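test_that("activation energy converts and validates correctly", {
  qw <- quartic_double_well_backend(1, 2)
  r <- minimize(geometry("X", c(-1.2, 0, 0)), qw)
  ts <- dimer_ts_search(geometry("X", c(-0.2, 0, 0)), qw)
  ## barrier b^2 / (4a) = 1 hartree
  expect_equal(activation_energy(r, ts), fmpes_units$hartree_kcal_mol,
               tolerance = 1e-7)
  expect_identical(activation_energy(r, r), 0)

  pes_k <- compose_modified_pes(bead_spring_flex_backend(),
                                list(uniaxial_term(5)))
  r2 <- minimize(bead_spring_flex_geometry("reactant"), pes_k)
  expect_error(activation_energy(r2, ts), "different surfaces")
})

test_that("Mueller-Brown lowest barrier matches the grid-refined oracle", {
  mb <- muller_brown_backend()
  oracle <- mb_stationary_oracle()
  r <- minimize(geometry("X", c(0.6, 0, 0)), mb)        # shallow basin
  ts <- dimer_ts_search(geometry("X", c(0.3, 0.25, 0)), mb)
  va <- activation_energy(r, ts)
  va_oracle <- (oracle$saddles[[1]]$e - oracle$minima[[2]]$e) *
    fmpes_units$hartree_kcal_mol
  expect_equal(va, va_oracle, tolerance = 1e-8)
})

test_that("pulling-force scan matches the tilted double-well closed form over the full grid", {
  qw <- quartic_double_well_backend(1, 2)
  settings <- opt_settings(gradient_convergence = 1e-7)
  scan <- scan_pulling_force(
    geometry("X", c(-1.0, 0, 0)), geometry("X", c(0.2, 0, 0)), qw,
    forces = seq(0, 4, by = 0.5), settings = settings,
    term_factory = function(f) linear_tilt_term(f))
  expect_true(all(scan$reactant_converged & scan$ts_converged &
                    scan$ts_is_saddle))
  va_hartree <- scan$activation_kcal / fmpes_units$hartree_kcal_mol
  va_oracle <- vapply(scan$force_nN, function(f) {
    tilted_quartic_barrier(f / fmpes_units$au_force_nN)
  }, numeric(1))
  expect_lt(max(abs(va_hartree - va_oracle)), 1e-8)
  ## a pulling force lowers the barrier monotonically here
  expect_true(all(diff(scan$activation_kcal) < 0))
})

test_that("zero-perturbation rows equal the unperturbed barrier", {
  inp <- bsf_inputs()
  b0_kcal <- inp$backend$params$B0 * fmpes_units$hartree_kcal_mol
  sk <- scan_uniaxial_k(inp$reactant, inp$ts, inp$backend, ks = c(0, 10))
  sf <- scan_pulling_force(inp$reactant, inp$ts, inp$backend,
                           forces = c(0, 1))
  expect_equal(sk$activation_kcal[sk$k_N_m == 0], b0_kcal, tolerance = 1e-6)
  expect_equal(sf$activation_kcal[sf$force_nN == 0], b0_kcal,
               tolerance = 1e-6)
})

test_that("two-atom closed-form compression scan matches exactly", {
  ## harmonic bond along z: E = kb/2 (d - d0)^2 with d = z1 - z2 (atoms
  ## symmetric about the plane at +/- z); adding k/2 (z1^2 + z2^2) gives
  ## the modified minimum at z* = kb d0 / (2 kb + k_au) per atom.
  kb <- 0.3
  d0 <- 2 / fmpes_units$bohr_angstrom
  be <- potential_backend(
    "harmonic_dimer",
    energy = function(x) 0.5 * kb * (sqrt(sum((x[1, ] - x[2, ])^2)) - d0)^2,
    gradient = function(x) {
      d <- sqrt(sum((x[1, ] - x[2, ])^2))
      u <- (x[1, ] - x[2, ]) / d
      f <- kb * (d - d0)
      rbind(f * u, -f * u)
    },
    n_atoms = 2)
  start <- geometry(c("C", "C"), rbind(c(0, 0, 1.1), c(0, 0, -1.1)))
  ks <- c(0, 10, 25, 50)
  scan <- scan_uniaxial_k(start, NULL, be, ks = ks, alignment = "none",
                          settings = opt_settings(gradient_convergence = 1e-8))
  z_expected <- kb * d0 / (2 * kb + ks / fmpes_units$au_force_constant_N_m)
  e_expected <- 0.5 * kb * (2 * z_expected - d0)^2 +
    (ks / fmpes_units$au_force_constant_N_m) * z_expected^2
  expect_lt(max(abs(scan$e_reactant - e_expected)), 1e-8)
  expect_true(all(diff(scan$reactant_sum_z2) < 0))
})

test_that("flex toy: compression activates, pulling does not", {
  inp <- bsf_inputs()
  sk <- scan_uniaxial_k(inp$reactant, inp$ts, inp$backend)
  expect_true(all(sk$reactant_converged & sk$ts_converged & sk$ts_is_saddle))
  expect_true(all(diff(sk$activation_kcal) < 0))       # strictly decreasing
  expect_true(all(diff(sk$reactant_sum_z2) < 1e-6))    # monotone flattening

  sf <- scan_pulling_force(inp$reactant, inp$ts, inp$backend)
  expect_true(all(sf$reactant_converged & sf$ts_converged & sf$ts_is_saddle))
  va0 <- sf$activation_kcal[sf$force_nN == 0]
  ## attachment-orthogonal pulling leaves the barrier within 2% of V_A(0),
  ## while the same k-grid compresses it by more than a third
  expect_lt(max(abs(sf$activation_kcal - va0)), 0.02 * va0)
  expect_lt(min(sk$activation_kcal), (2 / 3) * va0)
})

test_that("warm-start continuation agrees with cold starts", {
  ## cold starts honour the saddle search's precondition (a guess near the
  ## barrier region) only while the compressed saddle stays close to the
  ## unperturbed one, so the audit grid stays in that regime
  inp <- bsf_inputs()
  ks <- c(0, 5, 10, 15)
  ## tight convergence so the comparison probes path dependence, not the
  ## second-order energy error of the default stopping criterion
  tight <- opt_settings(gradient_convergence = 1e-7)
  warm <- scan_uniaxial_k(inp$reactant, inp$ts, inp$backend, ks = ks,
                          settings = tight)
  cold <- scan_uniaxial_k(inp$reactant, inp$ts, inp$backend, ks = ks,
                          settings = tight, warm_start = FALSE)
  expect_lt(max(abs(warm$activation_kcal - cold$activation_kcal)), 1e-6)
})

test_that("scan tables round-trip through CSV with metadata", {
  inp <- bsf_inputs()
  scan <- scan_uniaxial_k(inp$reactant, inp$ts, inp$backend, ks = c(0, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_scan_csv(scan, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# backend: bead_spring_flex", lines)))
  back <- read_scan_csv(path)
  expect_equal(back$activation_kcal, scan$activation_kcal, tolerance = 1e-12)
  expect_equal(back$k_N_m, scan$k_N_m)
  expect_identical(attr(back, "metadata")$value_unit, "N/m")
})
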