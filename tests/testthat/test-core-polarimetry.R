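test_that("Stokes validity follows the polarization inequality", {
  expect_true(stokes_is_valid(stokes(1, 1, 0, 0)))   # fully polarized
  expect_true(stokes_is_valid(stokes(1, 0, 0, 0)))   # unpolarized
  expect_false(stokes_is_valid(c(1, 0.8, 0.8, 0)))   # sqrt(1.28) > 1
  expect_error(stokes_is_valid(c(1 + 0i, 0, 0, 0)), "SFD")
})

test_that("Cloude covariance reproduces the canonical spectra", {
  ev_id <- Re(ordered_eigenvalues(cloude_covariance(diag(4))))
  expect_equal(ev_id, c(1, 0, 0, 0), tolerance = 1e-12)

  ev_dep <- Re(ordered_eigenvalues(cloude_covariance(diag(c(1, 0, 0, 0)))))
  expect_equal(ev_dep, rep(0.25, 4), tolerance = 1e-12)

  m_hv <- (mm_linear_polarizer(0) + mm_linear_polarizer(90)) / 2
  ev_hv <- Re(ordered_eigenvalues(cloude_covariance(m_hv)))
  expect_equal(ev_hv / sum(ev_hv), c(0.5, 0.5, 0, 0), tolerance = 1e-12)
})

test_that("covariance map is linear, invertible, trace-normalized, rank 1 on Jones matrices", {
  set.seed(11)
  for (rep in 1:20) {
    m1 <- matrix(rnorm(16), 4, 4)
    m2 <- matrix(rnorm(16), 4, 4)
    a <- rnorm(1); b <- rnorm(1)
    lin <- cloude_covariance(a * m1 + b * m2) -
      (a * cloude_covariance(m1) + b * cloude_covariance(m2))
    expect_lt(max(abs(lin)), 1e-12)
    h <- cloude_covariance(m1)
    expect_equal(Re(sum(diag(h))), m1[1, 1], tolerance = 1e-12)
    expect_lt(max(abs(mueller_from_covariance(h) - m1)), 1e-11)
  }
  for (rep in 1:20) {
    mj <- mueller_from_jones(rand_jones())
    ev <- Re(ordered_eigenvalues(cloude_covariance(mj)))
    expect_lt(max(abs(ev[2:4])) / ev[1], 1e-10)   # rank 1
  }
})

test_that("ordered eigenvalues agree with a characteristic-polynomial oracle", {
  expect_equal(ordered_eigenvalues(diag(c(0.1, 0.7, 0.2, 0.0)) + 0i),
               c(0.7, 0.2, 0.1, 0.0))
  set.seed(12)
  for (rep in 1:10) {
    a <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
    h <- (a + Conj(t(a))) / 2                      # random Hermitian
    got <- ordered_eigenvalues(h)
    want <- sort(Re(charpoly_eigenvalues(h)), decreasing = TRUE)
    expect_equal(Re(got), want, tolerance = 1e-8)
  }
})

test_that("purity indices evaluate the eigenvalue formulas without clipping", {
  expect_equal(unlist(purity_indices(c(1, 0, 0, 0))), c(p1 = 1, p2 = 1, p3 = 1))
  expect_equal(unlist(purity_indices(rep(0.25, 4))), c(p1 = 0, p2 = 0, p3 = 0))
  expect_equal(unlist(purity_indices(c(0.5, 0.5, 0, 0))), c(p1 = 0, p2 = 1, p3 = 1))
  expect_true(all(is.nan(unlist(purity_indices(c(0, 0, 0, 0))))))
  # an SFD-style negative eigenvalue drives P3 over unity, unclipped
  p <- purity_indices(c(0.6, 0.3, 0.2, -0.1))
  expect_gt(p$p3, 1)
})

test_that("purity inequality holds for convex sums of Jones-derived matrices", {
  set.seed(13)
  for (rep in 1:300) {
    p <- purity_indices(rand_physical_mueller())
    expect_true(-1e-10 <= p$p1 && p$p1 <= p$p2 + 1e-10 &&
                  p$p2 <= p$p3 + 1e-10 && p$p3 <= 1 + 1e-10)
  }
})

test_that("realizability is the covariance eigenvalue test", {
  expect_true(is_realizable(diag(4)))
  expect_false(is_realizable(diag(c(1, 1, 1, -1))))
  # oracle: H of diag(1,1,1,-1) has an explicit negative eigenvalue
  ev <- Re(ordered_eigenvalues(cloude_covariance(diag(c(1, 1, 1, -1)))))
  expect_lt(min(ev), -0.1)
  set.seed(14)
  for (rep in 1:100) expect_true(is_realizable(rand_physical_mueller()))
})

test_that("Lu-Chipman handles the canonical limiting cases", {
  lc_id <- lu_chipman(diag(4))
  expect_equal(lc_id$m_delta, diag(4), tolerance = 1e-12)
  expect_equal(lc_id$m_r, diag(4), tolerance = 1e-12)
  expect_equal(lc_id$m_d, diag(4), tolerance = 1e-12)
  expect_equal(lc_id$diattenuation, 0)
  expect_equal(lc_id$linear_retardance, 0)
  expect_equal(lc_id$depolarization_power, 0)

  lc_pol <- lu_chipman(mm_linear_polarizer(0))
  expect_equal(lc_pol$diattenuation, 1, tolerance = 1e-12)
  expect_lt(lc_pol$residual, 1e-10)

  # ideal depolarizer: zero 3x3 block, identity retarder
  lc_dep <- lu_chipman(diag(c(1, 0, 0, 0)))
  expect_equal(lc_dep$depolarization_power, 1)
  expect_lt(lc_dep$residual, 1e-10)

  expect_error(lu_chipman(diag(c(1, 1, 1, -1))), class = "sfdmueller_nonrealizable")
})

test_that("Lu-Chipman recovers a constructed depolarizer-retarder-diattenuator product", {
  m_delta <- mm_depolarizer(0.5, 0.5, 0.5)
  m_r <- linear_retarder_mueller(0, 30)
  m_d <- mm_linear_diattenuator(0.3, 0)
  lc <- lu_chipman(m_delta %*% m_r %*% m_d)
  expect_lt(max(abs(lc$m_delta - m_delta)), 1e-8)
  expect_lt(max(abs(lc$m_r - m_r)), 1e-8)
  expect_lt(max(abs(lc$m_d - m_d)), 1e-8)
  expect_equal(lc$diattenuation, 0.3, tolerance = 1e-10)
  expect_equal(lc$linear_retardance, 30, tolerance = 1e-8)
  expect_equal(lc$retardance_orientation, 0, tolerance = 1e-8)
  expect_equal(lc$depolarization_power, 0.5, tolerance = 1e-10)
})

test_that("Lu-Chipman round-trips random constructed products", {
  set.seed(15)
  for (rep in 1:60) {
    d <- runif(1, 0, 0.9)
    th_d <- runif(1, -90, 90)
    ret <- runif(1, 5, 170)
    th_r <- runif(1, -85, 85)
    dep <- rand_depolarizer(0.2)
    m_d <- mm_linear_diattenuator(d, th_d)
    m_r <- linear_retarder_mueller(th_r, ret)
    m <- dep %*% m_r %*% m_d
    lc <- lu_chipman(m)
    expect_lt(lc$residual, 1e-8)
    expect_lt(max(abs(lc$m_delta %*% lc$m_r %*% lc$m_d - m)), 1e-8)
    expect_equal(lc$diattenuation, d, tolerance = 1e-6)
    expect_equal(lc$linear_retardance, ret, tolerance = 1e-6)
  }
})

test_that("diattenuation is invariant under transverse-frame rotation", {
  set.seed(16)
  m <- mm_depolarizer(0.7, 0.7, 0.6) %*% linear_retarder_mueller(20, 45) %*%
    mm_linear_diattenuator(0.4, 10)
  d0 <- lu_chipman(m)$diattenuation
  for (ang in c(-63, -20, 15, 48, 90)) {
    expect_equal(lu_chipman(rotate_mueller(m, ang))$diattenuation, d0,
                 tolerance = 1e-10)
  }
})

test_that("displaced-kernel SFD fixture pushes P3 above unity at high frequency", {
  reg <- matrix(1L, 4, 4)
  sc <- sfd_scene(reg, list(`1` = list(
    kernel_component("local", 0.6 * mm_depolarizer(0.1, 0.1, 0.05)),
    kernel_component("displaced", 0.4 * mm_linear_polarizer(0),
                     displacement = 0.1, axis = "x"))), pitch = 0.05)
  m5 <- Re(analytic_sfd_brdf(sc, 5, "x")[1, 1, , ])
  expect_gt(purity_indices(m5)$p3, 1)
  expect_false(is_realizable(m5))
  # the same composition at f = 0 is an ordinary convex sum: realizable
  m0 <- Re(analytic_sfd_brdf(sc, 0, "x")[1, 1, , ])
  expect_true(is_realizable(m0))
  expect_lte(purity_indices(m0)$p3, 1 + 1e-12)
})
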