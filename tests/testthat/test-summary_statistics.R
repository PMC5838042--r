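test_that("isotropic edge weights match geometry and numeric integration", {
  win <- window_rect()
  expect_equal(ripley_weight(50, 50, 5, win), 1)
  expect_equal(ripley_weight(0, 50, 5, win), 2)   # half circle inside
  expect_equal(ripley_weight(0, 0, 5, win), 4)    # quarter circle inside
  expect_equal(ripley_weight(50, 0, 10, win), 2)
  expect_error(ripley_weight(50, 50, -1, win), "positive")
  expect_error(ripley_weight(150, 50, 5, win), "inside")

  # numeric arc-length oracle across interior, edge, corner and large radii
  set.seed(21)
  cases <- rbind(
    cbind(runif(10, 0, 100), runif(10, 0, 100), runif(10, 0.5, 40)),
    c(1, 1, 30), c(0.2, 50, 12), c(99, 99, 60), c(50, 2, 70)
  )
  for (k in seq_len(nrow(cases))) {
    w <- ripley_weight(cases[k, 1], cases[k, 2], cases[k, 3], win)
    frac <- numeric_inside_fraction(cases[k, 1], cases[k, 2], cases[k, 3], win)
    expect_equal(1 / w, frac, tolerance = 1e-6)
    expect_gte(w, 1)
  }
})

test_that("K estimate equals the brute-force double-loop oracle", {
  win <- window_rect()
  # worked two-point case: both ordered pairs interior, weights 1
  p2 <- marked_pattern(c(50, 51), c(50, 50), "a", win)
  expect_equal(estimate_K(p2, c(0.5, 2))$K, c(0, 5000))
  set.seed(22)
  rg <- c(1, 3, 7, 15, 25)
  for (n in c(2, 5, 10)) {
    p <- random_pattern(n, win)
    est <- estimate_K(p, rg)
    expect_equal(est$K, brute_force_K(p, rg), tolerance = 1e-12)
    expect_true(all(diff(est$K) >= 0))
    expect_true(all(est$K >= 0))
  }
  expect_error(estimate_K(random_pattern(1, win)), "at least 2")
  # r below the minimum interpoint distance counts nothing
  p <- marked_pattern(c(10, 90), c(10, 90), "a", win)
  expect_equal(estimate_K(p, 5)$K, 0)
})

test_that("mean K under CSR tracks pi r^2 within the Monte-Carlo CI", {
  win <- window_rect()
  set.seed(23)
  rg <- c(2, 5, 10, 20)
  reps <- 150
  Ks <- replicate(reps, estimate_K(sample_csr(100, win), rg)$K)
  m <- rowMeans(Ks)
  se <- apply(Ks, 1, sd) / sqrt(reps)
  expect_true(all(abs(m - pi * rg^2) <= 2.576 * se))
})

test_that("pcf of CSR is flat at 1 and respects bandwidth guards", {
  win <- window_rect()
  set.seed(24)
  rg <- c(2, 5, 10)
  gs <- replicate(60, estimate_pcf(sample_csr(200, win), rg)$g)
  expect_true(all(abs(rowMeans(gs) - 1) < 0.06))
  expect_error(estimate_pcf(random_pattern(1, win)), "at least 2")
  p <- random_pattern(100, win)
  est <- estimate_pcf(p, c(0, 0.5, 5), bandwidth = 2)
  expect_true(is.nan(est$g[1]))       # r = 0 flagged, not an exception
  expect_true(is.na(est$g[2]))        # r < h/2 reported missing
  expect_true(is.finite(est$g[3]))
  expect_equal(est$bandwidth, 2)
  # default bandwidth is Stoyan's rule
  expect_equal(estimate_pcf(p, 5)$bandwidth, 0.26 / sqrt(100 / 1e4))
})

test_that("pcf agrees with the numeric derivative of K", {
  win <- window_rect()
  spec <- species_spec("t", "thomas", n = 500, kappa = 0.005, sigma = 2, mu = 10)
  set.seed(9)
  pat <- generate_thomas(spec, win)
  rfine <- seq(0.25, 17, by = 0.25)
  rg <- seq(1, 16, by = 0.25)
  K <- estimate_K(pat, rfine)$K
  g <- estimate_pcf(pat, rg, bandwidth = 1.2)$g
  idx <- match(rg, rfine)
  fd <- (K[idx + 1L] - K[idx - 1L]) / (2 * 0.25) / (2 * pi * rg)
  expect_lt(mean(abs(g - fd)), 0.15)
  expect_gt(cor(g, fd), 0.98)
})

test_that("cross pcf detects independence, separation and shared clustering", {
  win <- window_rect()
  set.seed(25)
  g5 <- replicate(40, {
    a <- sample_csr(300, win); b <- sample_csr(300, win)
    estimate_pcf_cross(a, b, 5, bandwidth = 1.5)$g
  })
  expect_lt(abs(mean(g5) - 1), 0.05)

  # pattern_b = pattern_a translated far away: no cross pairs within reach
  a <- marked_pattern(runif(50, 0, 25), runif(50, 0, 100), "a", win)
  b <- marked_pattern(a$x + 50, a$y, "b", win)
  expect_equal(estimate_pcf_cross(a, b, 1, bandwidth = 0.5)$g, 0)

  # shared Thomas parents force cross-attraction at small r
  set.seed(26)
  hits <- replicate(30, {
    par <- cbind(runif(40, 0, 100), runif(40, 0, 100))
    off <- function() {
      k <- rep(seq_len(40), rpois(40, 8))
      ox <- par[k, 1] + rnorm(length(k), sd = 2)
      oy <- par[k, 2] + rnorm(length(k), sd = 2)
      keep <- ox >= 0 & ox <= 100 & oy >= 0 & oy <= 100
      marked_pattern(ox[keep], oy[keep], "s", win)
    }
    estimate_pcf_cross(off(), off(), 1, bandwidth = 1)$g > 1
  })
  expect_gte(sum(hits), 27)

  expect_error(estimate_pcf_cross(a, random_pattern(5, window_rect(0, 50, 0, 50))),
               "share one window")
  empty <- marked_pattern(numeric(0), numeric(0), character(0), win)
  expect_error(estimate_pcf_cross(a, empty), "non-empty")
})

test_that("cross pcf is symmetric in its arguments up to edge centering", {
  set.seed(10)
  f <- generate_fixture("plot2_like", 3)
  a <- subset_species(f, "QS"); b <- subset_species(f, "QA")
  rg <- seq(1, 16, by = 0.5)
  ga <- estimate_pcf_cross(a, b, rg, bandwidth = 1.5)$g
  gb <- estimate_pcf_cross(b, a, rg, bandwidth = 1.5)$g
  expect_lt(mean(abs(ga - gb)) / mean(ga), 0.15)
})

test_that("intensity surfaces integrate to n and track density", {
  win <- window_rect()
  set.seed(27)
  p <- sample_csr(1000, win)
  surf <- estimate_intensity(p)
  expect_true(all(surf$lambda >= 0))
  expect_lt(abs(intensity_integral(surf) - 1000) / 1000, 0.01)
  # flat truth recovered within 20% over the central subwindow
  central <- surf$lambda[surf$xs > 25 & surf$xs < 75, surf$ys > 25 & surf$ys < 75]
  expect_true(all(abs(central - 0.1) / 0.1 < 0.2))

  single <- marked_pattern(40, 60, "a", win)
  expect_lt(abs(intensity_integral(estimate_intensity(single)) - 1), 0.01)

  left <- marked_pattern(runif(200, 0, 50), runif(200, 0, 100), "a", win)
  sl <- estimate_intensity(left)
  expect_gt(mean(sl$lambda[sl$xs < 50, ]), mean(sl$lambda[sl$xs > 50, ]))

  expect_error(estimate_intensity(p, bandwidth = 0), "positive")
  empty <- marked_pattern(numeric(0), numeric(0), character(0), win)
  expect_error(estimate_intensity(empty), "at least 1")
})
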