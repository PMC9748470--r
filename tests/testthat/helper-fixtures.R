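# shared generators for the test suite; everything is built in code,
# under fixed seeds supplied by the individual tests

rand_jones <- function() {
  matrix(complex(real = stats::rnorm(4), imaginary = stats::rnorm(4)), 2, 2)
}

# random physical Mueller matrix: convex sum of up to four Jones-derived
# matrices, normalized to unit throughput
rand_physical_mueller <- function(n_terms = sample(1:4, 1)) {
  w <- stats::runif(n_terms)
  w <- w / sum(w)
  m <- matrix(0, 4, 4)
  for (i in seq_len(n_terms)) {
    mi <- mueller_from_jones(rand_jones())
    m <- m + w[i] * mi / mi[1, 1]
  }
  m
}

# random physically valid diagonal depolarizer diag(1, a, b, c): the Cloude
# eigenvalues (1 +/- a +/- b +/- c)/4 (even sign products) must be nonnegative
rand_depolarizer <- function(lo = 0.15, hi = 1) {
  repeat {
    v <- stats::runif(3, lo, hi)
    ev <- c(1 + v[1] + v[2] + v[3], 1 + v[1] - v[2] - v[3],
            1 - v[1] + v[2] - v[3], 1 - v[1] - v[2] + v[3])
    if (all(ev >= 1e-6)) return(diag(c(1, v)))
  }
}

# random analytic scene with every kernel kind and physical weights
rand_scene <- function(nr, nc, n_regions = 3, seedless_axis = c("x", "y")) {
  reg <- matrix(1L, nr, nc)
  if (n_regions >= 2) reg[, seq_len(max(1, nc %/% 2))] <- 2L
  if (n_regions >= 3) reg[seq_len(max(1, nr %/% 3)), ] <- 3L
  mk <- function(scale) scale * rand_physical_mueller()
  comps <- lapply(seq_len(n_regions), function(i) list(
    kernel_component("local", mk(0.3)),
    kernel_component("gaussian", mk(0.25), width = stats::runif(1, .05, .2)),
    kernel_component("exponential", mk(0.2), width = stats::runif(1, .05, .2)),
    kernel_component("displaced", mk(0.15),
                     displacement = stats::runif(1, -.1, .1),
                     axis = sample(seedless_axis, 1))))
  names(comps) <- as.character(seq_len(n_regions))
  sfd_scene(reg, comps, pitch = 1.1 / nc)
}

# symmetric variant: no displaced kernels (even line-spread functions)
rand_symmetric_scene <- function(nr, nc) {
  reg <- matrix(1L, nr, nc)
  reg[, seq_len(max(1, nc %/% 2))] <- 2L
  mk <- function(scale) scale * rand_physical_mueller()
  comps <- list(
    `1` = list(kernel_component("local", mk(0.4)),
               kernel_component("gaussian", mk(0.3), width = 0.1)),
    `2` = list(kernel_component("exponential", mk(0.35), width = 0.12),
               kernel_component("local", mk(0.2))))
  sfd_scene(reg, comps, pitch = 1.1 / nc)
}

default_instrument <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_states()
    cache
  }
})

# characteristic-polynomial eigenvalue oracle (Faddeev-LeVerrier),
# independent of eigen()
charpoly_eigenvalues <- function(h) {
  n <- nrow(h)
  coefs <- complex(n + 1)
  coefs[1] <- 1           # lambda^n
  m <- diag(n) + 0i
  for (k in 1:n) {
    m <- h %*% m
    ck <- -sum(diag(m)) / k
    coefs[k + 1] <- ck
    m <- m + ck * diag(n)
  }
  polyroot(rev(coefs))    # polyroot wants ascending powers
}

# least-squares sinusoid fit oracle: A + B cos(phi + theta) over phases
sinusoid_fit <- function(y, phi) {
  x1 <- cos(phi); x2 <- sin(phi)
  fit <- stats::lm(y ~ x1 + x2)
  b <- stats::coef(fit)
  # B cos(phi + theta) = B cos(theta) cos(phi) - B sin(theta) sin(phi)
  list(dc = unname(b[1]),
       amplitude = unname(sqrt(b[2]^2 + b[3]^2)),
       theta = unname(atan2(-b[3], b[2])))
}

# discretized Fourier-integral oracle for the kernel transforms
numeric_kernel_transform <- function(kind, width = NULL, displacement = NULL,
                                     f, half_width = 3, du = 1e-4) {
  u <- seq(-half_width, half_width, by = du)
  dens <- switch(kind,
    local = NULL,
    displaced = NULL,
    gaussian = stats::dnorm(u, sd = width),
    exponential = exp(-abs(u) / width) / (2 * width))
  if (kind == "local") return(1 + 0i)
  if (kind == "displaced") return(exp(2i * pi * f * displacement))
  sum(dens * exp(2i * pi * f * u)) * du
}
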