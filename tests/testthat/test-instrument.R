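test_that("linear retarder matrix matches the rotation-sandwich construction", {
  expect_equal(linear_retarder_mueller(0, 0), diag(4))
  expect_equal(linear_retarder_mueller(0, 180), diag(c(1, 1, -1, -1)),
               tolerance = 1e-12)
  # explicit rotation-matrix product oracle
  th <- 27.4 * pi / 180; d <- pi / 2
  rot <- function(t) matrix(c(1, 0, 0, 0,
                              0, cos(2 * t), sin(2 * t), 0,
                              0, -sin(2 * t), cos(2 * t), 0,
                              0, 0, 0, 1), 4, 4, byrow = TRUE)
  wp <- matrix(c(1, 0, 0, 0, 0, 1, 0, 0,
                 0, 0, cos(d), sin(d), 0, 0, -sin(d), cos(d)),
               4, 4, byrow = TRUE)
  expect_equal(linear_retarder_mueller(27.4, 90), rot(-th) %*% wp %*% rot(th),
               tolerance = 1e-12)
  expect_equal(det(linear_retarder_mueller(33, 77)), 1, tolerance = 1e-12)
})

test_that("the 16-state model reconstructs arbitrary Mueller matrices exactly", {
  ins <- default_instrument()
  set.seed(21)
  for (rep in 1:100) {
    m <- matrix(rnorm(16), 4, 4)
    i16 <- simulate_intensities(ins, m)
    expect_lt(max(abs(reduce_intensities(ins, i16) - m)), 1e-12)
  }
  # complex (SFD) matrices reduce just as exactly
  mc <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  expect_lt(max(abs(reduce_intensities(ins, simulate_intensities(ins, mc)) - mc)),
            1e-12)
})

test_that("generator states are fully polarized unit-intensity Stokes vectors", {
  g <- default_instrument()$psg_states
  expect_equal(g[1, ], rep(1, 16))
  expect_equal(sqrt(colSums(g[2:4, ]^2)), rep(1, 16), tolerance = 1e-12)
})

test_that("degenerate LC configurations are rejected", {
  expect_error(build_states(arm_spec(lc1 = retarder_spec(27.4, c(135, 135)))),
               "degenerate")
})

test_that("the default axes are near the grid-search conditioning optimum", {
  # coarse grid here; the 1-degree scan runs in the acceptance suite
  ins <- default_instrument()
  gr <- condition_grid_search(step = 5)
  expect_lt(ins$condition, 1.05 * gr$best)
})

test_that("acquisition plans enumerate frequencies x phases x 16 states", {
  p <- plan_acquisition(c(0, 1.2, 1.7, 2.5, 3.3, 5.0, 5.0), n_phases = 6)
  expect_equal(p$frame_count, 672L)
  expect_equal(nrow(p$frames), 672L)
  expect_equal(plan_acquisition(0, n_phases = 3)$frame_count, 48L)
  # double oversampling of the 3-phase minimum
  expect_equal(plan_acquisition(0, oversampling = 2)$n_phases, 6L)
  expect_error(plan_acquisition(0, n_phases = 2), "3 phases")
  # deterministic manifest order: frequency slowest, state fastest
  p2 <- plan_acquisition(c(0, 5), n_phases = 3)
  expect_equal(p2$frames$state[1:17], c(1:16, 1L))
  expect_equal(p2$frames$freq_index, rep(1:2, each = 48))
})

test_that("projector periods map to the canonical frequency list", {
  expect_equal(period_to_frequency(Inf, 0.5), 0)
  expect_equal(period_to_frequency(6), 5.0)
  expect_equal(period_to_frequency(12), 2.5)
  got <- period_to_frequency(c(Inf, 24, 18, 12, 9, 6))
  expect_equal(got, c(0, 1.2, 1.7, 2.5, 3.3, 5.0), tolerance = 0.05)
  expect_error(period_to_frequency(6, -1), "pitch")
  expect_error(period_to_frequency(0), "period")
})

test_that("reduction matrices survive a CSV round trip and still reduce", {
  ins <- default_instrument()
  path <- withr::local_tempfile(fileext = ".csv")
  write_reduction_csv(ins, path)
  ext <- read_reduction_csv(path)
  expect_equal(ext$w, ins$w, tolerance = 1e-12)
  set.seed(22)
  m <- matrix(rnorm(16), 4, 4)
  expect_lt(max(abs(reduce_intensities(ext, simulate_intensities(ins, m)) - m)),
            1e-10)
  expect_error(simulate_intensities(ext, m), "optical model")
})
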