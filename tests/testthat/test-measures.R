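# Estimator checks against closed-form Gaussian oracles and hand-enumerable
# histograms.

test_that("information rate vanishes for a stationary density", {
  g <- build_grid(c(-4, 4), 50)
  p0 <- gaussian_pdf_on_grid(0, 1, g, t = 0)
  p1 <- gaussian_pdf_on_grid(0, 1, g, t = 1e-4)
  expect_equal(information_rate(p0, p1), 0)
})

test_that("information rate matches the drifting-Gaussian closed form", {
  # mean drifts at v = 1, unit variance: Gamma = |v|/sigma = 1
  dt <- 1e-4
  g <- build_grid(c(-8, 8 + dt), 4000)
  p0 <- gaussian_pdf_on_grid(0, 1, g, t = 0)
  p1 <- gaussian_pdf_on_grid(dt, 1, g, t = dt)
  expect_equal(information_rate(p0, p1), gaussian_gamma(1, 1),
               tolerance = 1e-3)
  # pure width growth sigma(t) = 1 + t at t = 0: Gamma = sqrt(2)
  q0 <- gaussian_pdf_on_grid(0, 1, g, t = 0)
  q1 <- gaussian_pdf_on_grid(0, 1 + dt, g, t = dt)
  expect_equal(information_rate(q0, q1), sqrt(2), tolerance = 1e-3)
})

test_that("square-root-difference estimator agrees with (dp/dt)^2/p quadrature", {
  # both are discretizations of the same Fisher-metric integrand; at small
  # dt and fine bins they coincide to high order
  dt <- 1e-8
  g <- build_grid(c(-8, 8), 16000)
  p0 <- gaussian_pdf_on_grid(0, 1, g, t = 0)
  p1 <- gaussian_pdf_on_grid(dt, 1, g, t = dt)
  simplified <- information_rate(p0, p1)
  w <- diff(g$edges)
  pos <- p0$mass > 0
  direct <- sqrt(sum(((p1$mass[pos] - p0$mass[pos]) / dt)^2 /
                     p0$mass[pos]))
  expect_equal(simplified, direct, tolerance = 1e-6)
})

test_that("information rate enforces grid and cadence contracts", {
  g1 <- build_grid(c(-4, 4), 50)
  g2 <- build_grid(c(-5, 5), 50)
  p0 <- gaussian_pdf_on_grid(0, 1, g1, t = 0)
  pbad <- gaussian_pdf_on_grid(0, 1, g2, t = 1e-4)
  expect_error(information_rate(p0, pbad), "grid")
  pback <- gaussian_pdf_on_grid(0, 1, g1, t = -1e-4)
  expect_error(information_rate(p0, pback), "later")
})

test_that("every estimated rate respects the Hellinger bound 2*sqrt(2)/dt", {
  set.seed(77)
  g <- build_grid(c(0, 1), 30)
  dt <- 1e-4
  for (k in 1:20) {
    m0 <- estimate_pdf(runif(300), g, t = 0)
    m1 <- estimate_pdf(runif(300)^2, g, t = dt)
    expect_lte(information_rate(m0, m1), 2 * sqrt(2) / dt)
  }
})

test_that("information length accumulates the rate series", {
  z <- make_series(rep(0, 10))
  expect_equal(information_length(z)$value, rep(0, 10))
  cst <- make_series(rep(3, 5), delta_t = 0.01)
  expect_equal(information_length(cst)$value, 3 * 0.01 * (1:5))
  expect_error(information_length(make_series(c(1, -1, 1))),
               "non-negative")
  # drifting Gaussian: L(t) = |v| t / sigma
  dt <- 1e-4
  g <- build_grid(c(-8, 9), 4000)
  k <- 0:99
  gam <- vapply(k, function(j) {
    information_rate(gaussian_pdf_on_grid(j * dt, 1, g, t = j * dt),
                     gaussian_pdf_on_grid((j + 1) * dt, 1, g,
                                          t = (j + 1) * dt))
  }, 0)
  L <- information_length(make_series(gam, delta_t = dt))
  expect_equal(L$value[100], 100 * dt / 1, tolerance = 1e-3)
})

test_that("auto-conditional rate reduces to the marginal rate under independence", {
  gb <- build_grid(c(-8, 8.1), 500)
  ga <- build_grid(c(-6, 6), 80)
  dt <- 1e-3
  pa <- gaussian_pdf_on_grid(0, 1, ga)$mass
  pb0 <- gaussian_pdf_on_grid(0, 1, gb, t = 0)
  pb1 <- gaussian_pdf_on_grid(0.05, 1, gb, t = dt)
  j0 <- product_joint(list(pb0$mass, pa), list(gb, ga), times = c(0, 0))
  j1 <- product_joint(list(pb1$mass, pa), list(gb, ga), times = c(dt, 0))
  expect_equal(auto_conditional_rate(j0, j1),
               information_rate(pb0, pb1), tolerance = 1e-12)
  # identical joints: zero
  expect_equal(auto_conditional_rate(j0, j0, delta_t = dt), 0)
})

test_that("auto-conditional rate on a 2x2 hand enumeration", {
  # two bins per axis; conditioning value a in {0,1} with mass 1/2 each;
  # given a, b sits in bin a at t and moves to the other bin at t + dt:
  # joint_now = diag(1/2), joint_next = antidiag(1/2).
  gb <- build_grid(c(0, 1), 2); ga <- build_grid(c(0, 1), 2)
  dt <- 0.1
  j0 <- structure(list(grids = list(gb, ga),
                       mass = matrix(c(0.5, 0, 0, 0.5), 2),
                       times = c(0, 0), n_samples = NA_integer_),
                  class = "joint_hist")
  j1 <- structure(list(grids = list(gb, ga),
                       mass = matrix(c(0, 0.5, 0.5, 0), 2),
                       times = c(dt, 0), n_samples = NA_integer_),
                  class = "joint_hist")
  # Hellinger^2 = sum over 4 cells of (sqrt(0.5)-0)^2 = 2
  expect_equal(auto_conditional_rate(j0, j1), (2 / dt) * sqrt(2))
  # the b-marginal never moves (1/2, 1/2 both times) so the whole
  # conditional rate is attributed to the causal term
  expect_equal(causal_information_rate(j0, j1), (2 / dt) * sqrt(2))
})

test_that("causal rate is zero for independent signals and antisymmetric nets", {
  gb <- build_grid(c(-8, 8.1), 400)
  ga <- build_grid(c(-6, 6), 60)
  dt <- 1e-3
  pa <- gaussian_pdf_on_grid(0.2, 1, ga)$mass
  pb0 <- gaussian_pdf_on_grid(0, 1, gb)$mass
  pb1 <- gaussian_pdf_on_grid(0.03, 1.01, gb)$mass
  j0 <- product_joint(list(pb0, pa), list(gb, ga), times = c(0, 0))
  j1 <- product_joint(list(pb1, pa), list(gb, ga), times = c(dt, 0))
  expect_equal(causal_information_rate(j0, j1), 0, tolerance = 1e-9)
  # stationary joint: both terms vanish
  expect_equal(causal_information_rate(j0, j0, delta_t = dt), 0)
  # net rate: identical inputs cancel; antisymmetry holds
  s1 <- make_series(c(1, 2, 3)); s2 <- make_series(c(3, 1, 2))
  expect_equal(net_causal_rate(s1, s1)$value, rep(0, 3))
  expect_equal(net_causal_rate(s1, s2)$value,
               -net_causal_rate(s2, s1)$value)
})

test_that("causal rate increases with the cross-coupling strength", {
  # b's increment depends on a through coupling c; the estimated causal
  # rate must grow monotonically with c and sit near zero at c = 0
  set.seed(99)
  n <- 1e5
  dt <- 0.1
  a <- rnorm(n); b <- rnorm(n); eps <- rnorm(n)
  est <- vapply(c(0, 0.5, 1), function(cpl) {
    b1 <- b + 10 * cpl * a * dt + 0.5 * sqrt(dt) * eps
    nb <- joint_bins(n, 2)
    gb <- build_grid(list(b, b1), nb)
    ga <- build_grid(a, nb)
    j0 <- estimate_joint(list(b, a), list(gb, ga), times = c(0, 0))
    j1 <- estimate_joint(list(b1, a), list(gb, ga), times = c(dt, 0))
    causal_information_rate(j0, j1)
  }, 0)
  expect_true(all(diff(est) > 0))
  expect_lt(est[1], 0.25 * est[3])
})

test_that("differential entropy matches closed forms", {
  # uniform on [0,1]: zero in every binning
  g <- build_grid(c(0, 1), 17)
  u <- structure(list(grid = g, mass = rep(1 / 17, 17), t = 0,
                      n_samples = NA_integer_), class = "hist_pdf")
  expect_equal(differential_entropy(u), 0, tolerance = 1e-8)
  # uniform on [0,2]: log 2
  g2 <- build_grid(c(0, 2), 8)
  u2 <- structure(list(grid = g2, mass = rep(1 / 8, 8), t = 0,
                       n_samples = NA_integer_), class = "hist_pdf")
  expect_equal(differential_entropy(u2), log(2), tolerance = 1e-8)
  # standard Gaussian: 0.5 * log(2*pi*e)
  gg <- build_grid(c(-8, 8), 4000)
  expect_equal(differential_entropy(gaussian_pdf_on_grid(0, 1, gg)),
               0.5 * log(2 * pi * exp(1)), tolerance = 1e-3)
  u$mass <- u$mass * 0.9
  expect_error(differential_entropy(u), "sum to 1")
})

test_that("transfer entropy: exact product null and 1-bit copy channel", {
  g2 <- build_grid(c(0, 1), 2)
  # independent a: exact zero
  q <- matrix(c(0.3, 0.2, 0.1, 0.4), 2)  # joint of (b', b)
  pa <- c(0.6, 0.4)
  m <- array(0, c(2, 2, 2))
  for (k in 1:2) m[, , k] <- q * pa[k]
  tri <- structure(list(grids = list(g2, g2, g2), mass = m,
                        times = c(0.1, 0, 0), n_samples = NA_integer_),
                   class = "joint_hist")
  expect_equal(transfer_entropy(tri), 0)
  # copy channel b' = a with b independent uniform: exactly 1 bit
  m2 <- array(0, c(2, 2, 2))
  for (b in 1:2) for (a in 1:2) m2[a, b, a] <- 0.25
  tri2 <- structure(list(grids = list(g2, g2, g2), mass = m2,
                         times = c(0.1, 0, 0), n_samples = NA_integer_),
                    class = "joint_hist")
  expect_identical(transfer_entropy(tri2), 1)
  tri2$mass[1, 1, 1] <- 0.5
  expect_error(transfer_entropy(tri2), "sum to 1")
})

test_that("transfer entropy tracks the Gaussian AR closed form", {
  # b' = phi*b + c*a + e: TE = 0.5*log2(1 + c^2 var(a)/var(e)). The
  # histogram plug-in carries a known upward bias of order
  # K_cells/(2 n ln 2) and a discretization loss, so the tolerance is set
  # from those terms rather than Monte-Carlo error alone.
  set.seed(123)
  n <- 1e6
  phi <- 0.5; cpl <- 0.8; se <- 0.6
  a <- rnorm(n); b <- rnorm(n)
  b1 <- phi * b + cpl * a + se * rnorm(n)
  closed <- 0.5 * log2(1 + cpl^2 / se^2)
  nb <- joint_bins(n, 3)
  gb <- build_grid(list(b, b1), nb)
  ga <- build_grid(a, nb)
  tri <- estimate_joint(list(b1, b, a), list(gb, gb, ga),
                        times = c(1, 0, 0))
  te <- transfer_entropy(tri)
  bias_bound <- nb^3 / (2 * n * log(2))
  expect_lt(abs(te - closed), 0.05 * closed + bias_bound)
})

test_that("measure series enforce the uniform time base", {
  expect_error(measure_series("x", c(0, 1, 1.5), c(1, 2, 3), 1),
               "spacing")
  s <- make_series(1:5, delta_t = 0.5)
  expect_s3_class(s, "measure_series")
  expect_equal(as.data.frame(s)$value, 1:5)
})
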