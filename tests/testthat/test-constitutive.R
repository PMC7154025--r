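test_that("kinematic invariants handle identity, compression and isochoric stretch", {
  st <- compute_invariants(diag(3))
  expect_equal(st$J, 1)
  expect_equal(st$i1bar, 3)
  expect_equal(st$i4bar_star, 1)

  # volume-preserving compression along the fiber: the fiber invariant
  # clamps at 1, so the reinforcement is inactive in compression
  st2 <- compute_invariants(diag(c(0.8, 1.118, 1.118)), c(1, 0, 0))
  expect_lt(st2$i4bar, 1)
  expect_equal(st2$i4bar_star, 1)

  st3 <- compute_invariants(diag(c(1.2, 1.2, 1 / 1.44)), c(1, 0, 0))
  expect_equal(st3$J, 1, tolerance = 1e-12)
  expect_equal(st3$i1bar, 2 * 1.2^2 + 1.2^-4, tolerance = 1e-12)
  expect_equal(st3$i4bar_star, 1.44, tolerance = 1e-12)

  expect_error(compute_invariants(diag(c(-1, 1, 1))), "det")
})

test_that("strain energy vanishes at the reference state and matches direct arithmetic", {
  for (nm in c("porcine", "pericardial")) {
    p <- material_preset(nm)
    expect_equal(strain_energy(p, diag(3)), 0)
  }
  # independent arithmetic evaluation of the three energy terms for the
  # porcine parameters at an isochoric equibiaxial stretch
  p <- material_preset("porcine")
  lam <- 1.1
  F <- diag(c(lam, lam, lam^-2))
  i1b <- 2 * lam^2 + lam^-4
  i4 <- lam^2
  E <- i4 - 1  # kappa = 0
  expected <- 0.302 * (exp(3.25 * (i1b - 3)) - 1) +
    197 / (2 * 0.001) * (exp(0.001 * E^2) - 1)
  got <- strain_energy(p, F)
  expect_gt(got, 0)
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("strain energy is frame indifferent", {
  set.seed(42)
  p <- material_preset("pericardial")
  for (i in 1:10) {
    F <- random_isochoric_F()
    Q <- random_rotation()
    expect_equal(strain_energy(p, Q %*% F), strain_energy(p, F),
                 tolerance = 1e-12)
  }
})

test_that("kappa = 1/3 gives an isotropic response invariant under fiber rotation", {
  p <- material_params(c10 = 0.302, c01 = 3.25, k1 = 0.197, k2 = 0.5,
                       kappa = 1 / 3)
  set.seed(7)
  F <- random_isochoric_F(0.12)
  w_ref <- strain_energy(p, compute_invariants(F, p$e0))
  s_ref <- pk1_stress(p, F)$pk1
  for (i in 1:8) {
    e_new <- stats::rnorm(3)
    p2 <- p
    p2$e0 <- e_new / sqrt(sum(e_new^2))
    expect_equal(strain_energy(p2, compute_invariants(F, p2$e0)), w_ref,
                 tolerance = 1e-13)
    expect_equal(pk1_stress(p2, F)$pk1, s_ref, tolerance = 1e-13)
  }
})

test_that("fiber term is inactive in compression when kappa = 0", {
  p <- material_preset("porcine")  # kappa = 0
  p0 <- p
  p0$k1 <- 0
  F <- diag(c(0.8, 1.118, 1.118))  # fiber along x in compression
  expect_equal(strain_energy(p, F), strain_energy(p0, F))
  expect_equal(pk1_stress(p, F)$pk1, pk1_stress(p0, F)$pk1)
})

test_that("analytic stress matches the finite-difference energy gradient", {
  set.seed(1)
  for (nm in c("porcine", "pericardial")) {
    p <- material_preset(nm)
    for (i in 1:4) {
      F <- random_isochoric_F()
      P <- pk1_stress(p, F)$pk1
      Pfd <- fd_pk1(p, F)
      expect_lt(max(abs(P - Pfd)) / max(abs(Pfd)), 1e-6)
    }
  }
})

test_that("reference state is stress free and small-k2 evaluation is well conditioned", {
  for (nm in c("porcine", "pericardial")) {
    p <- material_preset(nm)
    res <- pk1_stress(p, diag(3))
    expect_equal(res$pk1, matrix(0, 3, 3), tolerance = 1e-12)
    expect_equal(res$von_mises, 0, tolerance = 1e-12)
  }
  # porcine k2 = 0.001: expm1 evaluation agrees with the analytic series
  # (k1/2) E^2 (1 + k2 E^2/2 + ...) with no cancellation
  p <- material_preset("porcine")
  lam <- 1.2
  E <- lam^2 - 1
  w_an <- strain_energy(p, diag(c(lam, lam, lam^-2))) -
    strain_energy(material_params(p$c10, p$c01, k1 = 0, k2 = 0.001),
                  diag(c(lam, lam, lam^-2)))
  series <- p$k1 / 2 * E^2 * (1 + 0.001 * E^2 / 2 + 0.001^2 * E^4 / 6)
  expect_equal(w_an, series, tolerance = 1e-10)
  expect_true(is.finite(pk1_stress(p, diag(c(lam, lam, lam^-2)))$von_mises))
})

test_that("runaway fiber stretch raises an overflow error naming the invariant", {
  p <- material_preset("pericardial")  # k2 = 149.8
  F <- diag(c(3, 1, 1 / 3))
  expect_error(strain_energy(p, F), "I4bar")
  expect_error(pk1_stress(p, F), "overflow")
})

test_that("plane-stress biaxial response matches the energy-derivative oracle", {
  expect_equal(unname(plane_stress_biaxial(material_preset("porcine"), 1, 1)),
               c(0, 0, 0), tolerance = 1e-12)

  # isotropy symmetry at kappa = 1/3: equibiaxial stresses equal for any angle
  iso <- material_params(0.2, 5, 0.5, 20, kappa = 1 / 3)
  for (ang in c(0, 0.3, 1.1)) {
    s <- plane_stress_biaxial(iso, 1.1, 1.1, ang)
    expect_equal(s[["sigma11"]], s[["sigma22"]], tolerance = 1e-10)
  }

  # principal-stretch oracle sigma_ii = lam_i dW/dlam_i at lam3 = 1/(lam1 lam2),
  # on aligned-fiber protocols (fibers along axis 1 for both materials);
  # five-point stencil keeps the oracle's truncation error below the
  # comparison tolerance for the stiff pericardial exponentials
  h <- 1e-4
  d5 <- function(f, x) {
    (-f(x + 2 * h) + 8 * f(x + h) - 8 * f(x - h) + f(x - 2 * h)) / (12 * h)
  }
  for (nm in c("porcine", "pericardial")) {
    p <- material_preset(nm)
    p$e0 <- c(1, 0, 0)
    W <- function(l1, l2) {
      strain_energy(p, compute_invariants(diag(c(l1, l2, 1 / (l1 * l2))),
                                          p$e0))
    }
    for (ll in list(c(1.1, 1.1), c(1.15, 1.02), c(1.05, 1.12))) {
      s <- plane_stress_biaxial(p, ll[1], ll[2], fiber_angle = 0)
      o1 <- ll[1] * d5(function(x) W(x, ll[2]), ll[1])
      o2 <- ll[2] * d5(function(x) W(ll[1], x), ll[2])
      expect_equal(s[["sigma11"]], o1, tolerance = 1e-8)
      expect_equal(s[["sigma22"]], o2, tolerance = 1e-8)
      expect_equal(s[["sigma12"]], 0, tolerance = 1e-10)
    }
  }
})

test_that("wall tether force is a linear restoring spring", {
  w <- wall_params()
  X <- c(1, 2, 3)
  expect_equal(wall_tether_force(w, X, X), c(0, 0, 0))
  d <- c(0.1, 0, 0)
  f <- wall_tether_force(w, X, X + d)
  expect_equal(f, -852 * d)
  expect_equal(wall_tether_force(w, X, X + 2 * d), 2 * f)
  expect_equal(wall_energy(w, diag(3)), 0)
})
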