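test_that("analytic kernel transforms match a discretized Fourier integral", {
  freqs <- c(0, 1.2, 1.7, 2.5, 3.3, 5.0)
  w <- diag(4)
  for (f in freqs) {
    for (kind in c("local", "gaussian", "exponential", "displaced")) {
      comp <- switch(kind,
        local = kernel_component("local", w),
        gaussian = kernel_component("gaussian", w, width = 0.12),
        exponential = kernel_component("exponential", w, width = 0.15),
        displaced = kernel_component("displaced", w, displacement = 0.07))
      sc <- sfd_scene(matrix(1L, 1, 1), list(`1` = list(comp)), pitch = 0.01)
      got <- analytic_sfd_brdf(sc, f, "x")[1, 1, 1, 1]
      want <- numeric_kernel_transform(kind, width = comp$width,
                                       displacement = comp$displacement, f = f)
      expect_lt(abs(got - want) / abs(want), 1e-6)
    }
  }
})

test_that("f = 0 response is the sum of component weights (Mueller BRDF)", {
  set.seed(31)
  sc <- rand_scene(4, 4)
  f0 <- analytic_sfd_brdf(sc, 0, "x")
  for (lab in names(sc$components)) {
    px <- which(sc$regions == as.integer(lab), arr.ind = TRUE)[1, ]
    want <- Reduce(`+`, lapply(sc$components[[lab]], `[[`, "weight"))
    expect_equal(Re(f0[px[1], px[2], , ]), want, tolerance = 1e-12)
    expect_equal(max(abs(Im(f0))), 0)
  }
})

test_that("gaussian modulus ratio and displaced phase follow the closed forms", {
  sig <- 0.1
  sc <- sfd_scene(matrix(1L, 1, 1),
                  list(`1` = list(kernel_component("gaussian", diag(4), width = sig))),
                  pitch = 0.01)
  for (f in c(1.2, 2.5, 5)) {
    ratio <- Mod(analytic_sfd_brdf(sc, f, "x")[1, 1, 1, 1]) /
      Mod(analytic_sfd_brdf(sc, 0, "x")[1, 1, 1, 1])
    expect_equal(ratio, exp(-2 * pi^2 * sig^2 * f^2), tolerance = 1e-12)
  }
  dl <- 0.06
  scd <- sfd_scene(matrix(1L, 1, 1),
                   list(`1` = list(kernel_component("displaced", diag(4),
                                                    displacement = dl))),
                   pitch = 0.01)
  for (f in c(1.2, 2.5, 5)) {
    v <- analytic_sfd_brdf(scd, f, "x")[1, 1, 1, 1]
    expect_equal(Arg(v), (2 * pi * f * dl) %% (2 * pi), tolerance = 1e-12)
    expect_equal(Mod(v), 1, tolerance = 1e-12)
    # displacement perpendicular to the modulation: no phase
    expect_equal(Arg(analytic_sfd_brdf(scd, f, "y")[1, 1, 1, 1]), 0)
  }
})

test_that("symmetric kernels give exactly real SFD responses", {
  set.seed(32)
  sc <- rand_symmetric_scene(6, 6)
  for (f in c(1.2, 2.5, 5)) {
    expect_equal(max(abs(Im(analytic_sfd_brdf(sc, f, "x")))), 0)
  }
  # displaced pairs +-delta with equal weights are symmetric too
  w <- rand_physical_mueller()
  scp <- sfd_scene(matrix(1L, 2, 2), list(`1` = list(
    kernel_component("displaced", w, displacement = 0.08),
    kernel_component("displaced", w, displacement = -0.08))), pitch = 0.01)
  expect_lt(max(abs(Im(analytic_sfd_brdf(scp, 5, "x")))), 1e-15)
})

test_that("local-only scenes render exact sinusoids with the analytic modulation", {
  ins <- default_instrument()
  set.seed(33)
  w <- 0.5 * rand_physical_mueller()
  sc <- sfd_scene(matrix(1L, 3, 8),
                  list(`1` = list(kernel_component("local", w))),
                  pitch = 0.04)
  plan <- plan_acquisition(c(0, 2.5), n_phases = 6)
  stack <- render_frames(sc, plan, ins, sim_config(exposure_scale = 100))
  # at every pixel and state, frames over phase are A + B cos(phi + theta)
  for (k in c(1, 7, 16)) for (cc in c(1, 5)) {
    y <- stack$frames[2, , k, 2, cc]
    fit <- sinusoid_fit(y, plan$phases)
    expect_equal(fit$dc, mean(stack$frames[1, , k, 2, cc]), tolerance = 1e-9)
    resid <- y - (fit$dc + fit$amplitude * cos(plan$phases + fit$theta))
    expect_lt(max(abs(resid)), 1e-9)
    # delta kernel: modulation depth equals the DC projection (flat response)
    expect_equal(fit$amplitude, fit$dc, tolerance = 1e-9)
  }
})

test_that("gaussian scenes attenuate modulation by the analytic factor", {
  ins <- default_instrument()
  sig <- 0.09
  sc <- sfd_scene(matrix(1L, 2, 6),
                  list(`1` = list(kernel_component("gaussian",
                                                   0.5 * mm_depolarizer(0.3),
                                                   width = sig))),
                  pitch = 0.05)
  plan <- plan_acquisition(c(0, 3.3), n_phases = 6)
  stack <- render_frames(sc, plan, ins, sim_config(exposure_scale = 100))
  y <- stack$frames[2, , 1, 1, 3]
  fit <- sinusoid_fit(y, plan$phases)
  expect_equal(fit$amplitude / fit$dc, exp(-2 * pi^2 * sig^2 * 3.3^2),
               tolerance = 1e-9)
})

test_that("displaced scenes shift the rendered sinusoid phase by 2 pi f delta", {
  ins <- default_instrument()
  dl <- 0.06; f <- 2.5
  base <- list(kernel_component("local", 0.5 * mm_depolarizer(0.2)))
  disp <- list(kernel_component("displaced", 0.5 * mm_depolarizer(0.2),
                                displacement = dl))
  plan <- plan_acquisition(f, n_phases = 6)
  cfg <- sim_config(exposure_scale = 100)
  s0 <- render_frames(sfd_scene(matrix(1L, 2, 2), list(`1` = base),
                                pitch = 0.05), plan, ins, cfg)
  s1 <- render_frames(sfd_scene(matrix(1L, 2, 2), list(`1` = disp),
                                pitch = 0.05), plan, ins, cfg)
  f0 <- sinusoid_fit(s0$frames[1, , 1, 1, 1], plan$phases)
  f1 <- sinusoid_fit(s1$frames[1, , 1, 1, 1], plan$phases)
  dphi <- (f1$theta - f0$theta) %% (2 * pi)
  expect_equal(dphi, (-2 * pi * f * dl) %% (2 * pi), tolerance = 1e-9)
})

test_that("rendering is bit-for-bit deterministic under a fixed seed", {
  ins <- default_instrument()
  set.seed(34)
  sc <- rand_scene(6, 6)
  plan <- plan_acquisition(c(0, 2.5), n_phases = 6)
  cfg <- sim_config(noise = "shot_read", seed = 77, exposure_scale = 3000)
  a <- render_frames(sc, plan, ins, cfg)
  b <- render_frames(sc, plan, ins, cfg)
  expect_identical(a$frames, b$frames)
  d <- render_frames(sc, plan, ins, sim_config(noise = "shot_read", seed = 78,
                                               exposure_scale = 3000))
  expect_false(identical(a$frames, d$frames))
})

test_that("demodulated noise tracks the shot-noise prediction", {
  ins <- default_instrument()
  sc <- sfd_scene(matrix(1L, 2, 2),
                  list(`1` = list(kernel_component("local",
                                                   0.5 * mm_depolarizer(0.2)))),
                  pitch = 0.05)
  plan <- plan_acquisition(2.5, n_phases = 6)
  mu <- render_frames(sc, plan, ins,
                      sim_config(exposure_scale = 5000))$frames[1, , 1, 1, 1]
  vals <- complex(80)
  for (i in seq_along(vals)) {
    cfg <- sim_config(noise = "shot_read", seed = 500 + i,
                      exposure_scale = 5000)
    vals[i] <- demodulate(render_frames(sc, plan, ins, cfg), 2.5, 1)[1, 1]
  }
  pred <- predict_demod_sd(mu, sim_config(noise = "shot_read"), "re")
  expect_lt(abs(sd(Re(vals)) / pred - 1), 0.25)   # 80 reps; acceptance uses 200
})

test_that("reference set encodes scale and MTF as designed", {
  ins <- default_instrument()
  plan <- plan_acquisition(c(0, 1.2, 5), n_phases = 6)
  frd <- 1 / pi
  flat <- make_references(frd, plan, ins, sim_config(exposure_scale = 200))
  # unit MTF: mirror |M11| identical at all nonzero f
  expect_equal(flat$mirror_m11[[2]], flat$mirror_m11[[3]], tolerance = 1e-12)
  expect_gt(flat$diffuse_m0[1, 1], 0)

  mtf <- function(f) ifelse(f == 0, 1, 0.8)
  dimmed <- make_references(frd, plan, ins,
                            sim_config(exposure_scale = 200, mtf = mtf))
  # demodulation halves the modulated channel; the MTF shows up on top of that
  expect_equal(dimmed$mirror_m11[[1]] / dimmed$mirror_m11[[2]], 2 / 0.8,
               tolerance = 1e-9)
  expect_error(make_references(-1, plan, ins), "positive")
})

test_that("phantom presets build valid scenes with their signature structure", {
  for (nm in c("fiber_gradient", "fiber_bundle", "two_region_brain")) {
    sc <- phantom_preset(nm, nr = 32, nc = 32)
    expect_s3_class(sc, "sfd_scene")
    f0 <- analytic_sfd_brdf(sc, 0, "x")
    expect_equal(max(abs(Im(f0))), 0)
  }
  expect_error(phantom_preset("nope"), "arg")
})
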