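test_that("uniaxial compression energy matches the hand unit-conversion oracle", {
  # two atoms at z = +/- 1 Angstrom, k = 50 N/m:
  # V = 2 * (50/2) * (1e-10 m)^2 = 5.0e-19 J -> * N_A / 4184 kcal/mol
  g <- geometry(c("C", "C"), rbind(c(0, 0, 1), c(0, 0, -1)))
  hand <- 5.0e-19 * 6.02214076e23 / 4184
  expect_equal(uniaxial_energy(g, 50), hand, tolerance = 1e-6)
  expect_equal(round(uniaxial_energy(g, 50), 2), 71.97)

  expect_identical(uniaxial_energy(g, 0), 0)
  planar <- generate_fixture("planar_ring")$geometry
  expect_identical(uniaxial_energy(planar, 50), 0)
  expect_error(uniaxial_term(-1), "non-negative")
})

test_that("uniaxial force is (0, 0, -k z_i) exactly and matches finite differences", {
  k <- 35
  k_au <- k / fmpes_units$au_force_constant_N_m
  g0 <- geometry("C", c(0.3, -0.8, 0))
  expect_identical(max(abs(uniaxial_force(g0, k))), 0)

  gb <- geometry("C", c(0, 0, fmpes_units$bohr_angstrom))  # z = 1 bohr
  f <- uniaxial_force(gb, k)
  expect_identical(f[1, 1:2], c(0, 0))
  expect_equal(f[1, 3], -k_au, tolerance = 1e-12)

  set.seed(3)
  g10 <- geometry(rep("C", 10), matrix(rnorm(30), 10, 3))
  term <- uniaxial_term(k)
  xb <- fmpes:::.ang_to_bohr(g10$coords)
  g_fd <- fmpes:::.fd_gradient(term$energy, xb, 1e-4)
  expect_lt(max(abs(term$gradient(xb) - g_fd)), 1e-8)
  expect_identical(max(abs(term$gradient(xb)[, 1:2])), 0)
})

test_that("pulling energy is -F * d with support restricted to the pair", {
  g <- geometry(c("C", "C", "C"),
                rbind(c(0, 0, 0), c(2, 0, 0), c(0.5, 1, 0)),
                attachment_pair = c(1, 2))
  # 1 nN over 2.0 Angstrom = -2e-19 J
  hand <- -2e-19 * 6.02214076e23 / 4184
  expect_equal(pulling_energy(g, 1), hand, tolerance = 1e-6)
  expect_identical(pulling_energy(g, 0), 0)

  term <- pulling_term(1.7, c(1, 2))
  xb <- fmpes:::.ang_to_bohr(g$coords)
  gr <- term$gradient(xb)
  expect_identical(gr[3, ], c(0, 0, 0))
  expect_equal(gr[1, ], -gr[2, ])  # antiparallel collinear pair
  u <- (xb[1, ] - xb[2, ]) / sqrt(sum((xb[1, ] - xb[2, ])^2))
  expect_lt(max(abs(gr[1, ] - sum(gr[1, ] * u) * u)), 1e-14)
  g_fd <- fmpes:::.fd_gradient(term$energy, xb, 1e-4)
  expect_lt(max(abs(gr - g_fd)), 1e-8)

  coincident <- geometry(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(pulling_energy(coincident, 1, c(1, 2)), "coincident")
})

test_that("modified PES is exactly additive term by term", {
  be <- bead_spring_flex_backend()
  g <- bead_spring_flex_geometry("reactant")
  xb <- fmpes:::.ang_to_bohr(g$coords)
  t1 <- uniaxial_term(20)
  t2 <- pulling_term(1.5, c(1, 2))

  empty <- compose_modified_pes(be, list())
  expect_identical(evaluate_energy(g, empty), evaluate_energy(g, be))

  both <- compose_modified_pes(be, list(t1, t2))
  e_sum <- evaluate_energy(g, be) + t1$energy(xb) + t2$energy(xb)
  expect_equal(evaluate_energy(g, both), e_sum, tolerance = 1e-12)
  g_sum <- evaluate_gradient(g, be) + t1$gradient(xb) + t2$gradient(xb)
  expect_lt(max(abs(evaluate_gradient(g, both) - g_sum)), 1e-14)

  planar <- generate_fixture("planar_ring")$geometry
  pes_k <- compose_modified_pes(potential_backend(
    "flat", function(x) 0, function(x) 0 * x), list(uniaxial_term(50)))
  expect_identical(evaluate_energy(planar, pes_k), 0)
})

test_that("uniaxial symmetry: invariant under z-rotations and xy-translations, increasing in |z|", {
  set.seed(5)
  g <- geometry(rep("C", 6), matrix(rnorm(18), 6, 3))
  e0 <- uniaxial_energy(g, 30)
  for (phi in c(0.3, 2.1)) {
    rz <- matrix(c(cos(phi), -sin(phi), 0, sin(phi), cos(phi), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    g2 <- set_coords(g, sweep(g$coords %*% t(rz), 2, -c(4, -7, 0)))
    expect_lt(abs(uniaxial_energy(g2, 30) - e0), 1e-10)
  }
  g_higher <- set_coords(g, g$coords %*% diag(c(1, 1, 1.5)))
  expect_gt(uniaxial_energy(g_higher, 30), e0)
})

test_that("align_to_frame orients without distorting", {
  g <- bead_spring_flex_geometry("reactant")
  d0 <- as.matrix(dist(g$coords))

  expect_identical(align_to_frame(g, "none")$coords, g$coords)

  lin <- geometry(c("C", "C", "C"),
                  rbind(c(0, 0, -1.2), c(0, 0, 0), c(0, 0, 1.3)),
                  attachment_pair = c(1, 3))
  al <- align_to_frame(lin, "attachment_in_plane")
  av <- al$coords[3, ] - al$coords[1, ]
  expect_lt(abs(av[3]), 1e-10)

  for (mode in c("attachment_in_plane", "principal_axes")) {
    ag <- align_to_frame(g, mode)
    expect_lt(max(abs(as.matrix(dist(ag$coords)) - d0)), 1e-10)
    expect_lt(max(abs(colMeans(ag$coords))), 1e-10)
  }

  ## the identical frame can be applied to a companion structure
  ts <- bead_spring_flex_geometry("ts")
  ar <- align_to_frame(g, "attachment_in_plane")
  ats <- apply_frame(ts, attr(ar, "transform"))
  expect_lt(max(abs(as.matrix(dist(ats$coords)) - as.matrix(dist(ts$coords)))),
            1e-10)

  no_pair <- geometry(c("C", "C"), rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_error(align_to_frame(no_pair, "attachment_in_plane"),
               "attachment_pair")
})

test_that("k -> 0 and F -> 0 reproduce the unperturbed stationary points", {
  be <- bead_spring_flex_backend()
  start <- set_coords(bead_spring_flex_geometry("reactant"),
                      bead_spring_flex_geometry("reactant")$coords + 0.05)
  sp_base <- minimize(start, be, characterize = FALSE)
  for (terms in list(list(uniaxial_term(0)),
                     list(pulling_term(0, c(1, 2))))) {
    sp_mod <- minimize(start, compose_modified_pes(be, terms),
                       characterize = FALSE)
    dev <- fmpes:::.ang_to_bohr(abs(sp_mod$geometry$coords -
                                      sp_base$geometry$coords))
    expect_lt(max(dev), 1e-5)
  }
})
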