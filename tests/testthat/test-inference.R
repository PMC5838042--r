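csr_stat <- function(p) estimate_pcf(p, c(2, 5, 10), bandwidth = 2)$g

test_that("envelope construction brackets the simulations", {
  win <- window_rect()
  obs <- sample_csr(80, win, seed = 51)
  env1 <- build_envelope(obs, csr_stat, function(p) sample_csr(80, win),
                         rgrid = c(2, 5, 10), s = 1, seed = 52)
  expect_identical(env1$lo, env1$hi)           # one simulation: lo = hi
  expect_identical(env1$lo, as.numeric(env1$sims[1, ]))

  env <- build_envelope(obs, csr_stat, function(p) sample_csr(80, win),
                        rgrid = c(2, 5, 10), s = 19, seed = 53)
  expect_true(all(env$lo <= env$hi))
  expect_equal(env$lo, apply(env$sims, 2, min))
  expect_equal(env$hi, apply(env$sims, 2, max))

  # degenerate null returning the observed pattern: obs sits on both envelopes
  envd <- build_envelope(obs, csr_stat, function(p) p,
                         rgrid = c(2, 5, 10), s = 9)
  expect_equal(envd$lo, envd$obs)
  expect_equal(envd$hi, envd$obs)

  # a statistic failing on a simulated pattern names the replicate
  fragile <- function(p) {
    if (npoints(p) < 50) stop("too sparse") else estimate_pcf(p, 2)$g
  }
  expect_error(build_envelope(obs, fragile, function(p) sample_csr(3, win),
                              c(2), s = 3),
               "replicate 1")
})

test_that("goodness-of-fit p-values follow the rank arithmetic", {
  set.seed(54)
  r <- 1:10
  sims <- matrix(rnorm(199 * 10, 1, 0.1), 199)
  # observed curve far above every simulation: largest deviation, p = 1/200
  gof_hi <- gof_test(rep(5, 10), sims, r)
  expect_equal(gof_hi$p, 0.005)
  expect_equal(gof_hi$rank, 1L)
  # observed equal to the null mean: smallest deviation, p = 1
  gof_lo <- gof_test(colMeans(sims), sims, r)
  expect_equal(gof_lo$p, 1)
  expect_equal(gof_lo$rank, 200L)

  # literal-oracle agreement and rank/p consistency on random curve sets
  for (k in 1:5) {
    s <- sample(4:12, 1)
    curves <- matrix(rnorm((s + 1) * 6), s + 1)
    got <- gof_test(curves[1, ], curves[-1, , drop = FALSE], 1:6)
    want <- brute_force_gof(curves)
    expect_equal(got$p, want$p)
    expect_equal(got$u0, want$u0)
    expect_equal(got$rank, want$rank)
    expect_equal(got$p, 1 - (s + 1 - got$rank) / (s + 1))
  }

  # permuting simulated curves changes nothing
  perm <- sample(199)
  gof_p <- gof_test(rep(5, 10), sims[perm, ], r)
  expect_equal(gof_p$p, gof_hi$p)

  expect_error(gof_test(rep(1, 10), sims, r, interval = c(30, 40)), "empty")
  expect_error(gof_test(rep(1, 10), sims[0, , drop = FALSE], r), "at least 1")
  # a single simulation always ties under the leave-one-out expectation
  expect_equal(gof_test(rep(5, 10), sims[1, , drop = FALSE], r)$p, 1)
})

test_that("association classifier implements the three-outcome logic", {
  mk_env <- function(obs, lo, hi) {
    structure(list(r = seq_along(obs), obs = obs, lo = lo, hi = hi,
                   sims = rbind(lo, hi), s = 2L, seed = NULL,
                   statistic = "test"),
              class = "envelope_result")
  }
  mk_gof <- function(p) structure(list(u0 = 1, u = 1, rank = 1L, p = p, s = 2L,
                                       interval = c(1, 10), r_used = 1:10),
                                  class = "gof_result")
  lo <- rep(0.8, 10); hi <- rep(1.2, 10)
  expect_equal(classify_association(mk_env(rep(0.5, 10), lo, hi), mk_gof(0.01))$sign,
               "negative")
  expect_equal(classify_association(mk_env(c(rep(2, 3), rep(1, 7)), lo, hi),
                                    mk_gof(0.02))$sign, "positive")
  expect_equal(classify_association(mk_env(rep(1, 10), lo, hi), mk_gof(0.42))$sign,
               "none")
  # significant GoF but no excursion still reads as no association
  expect_equal(classify_association(mk_env(rep(1, 10), lo, hi), mk_gof(0.01))$sign,
               "none")
  # mixed excursions: the larger squared excursion wins
  obs <- c(rep(0.5, 5), rep(1.25, 5))
  expect_equal(classify_association(mk_env(obs, lo, hi), mk_gof(0.01))$sign,
               "negative")
})

test_that("case-control difference is calibrated under exchangeable labels", {
  win <- window_rect()
  rg <- seq(1, 10, by = 1)
  set.seed(55)
  ps <- replicate(20, {
    pool <- sample_csr(200, win)
    pool$species <- sample(rep(c("ctl", "cas"), c(110, 90)))
    jp <- joint_pattern(pool, "ctl", "cas")
    env <- diff_case_control(jp, "ctl", "cas", rg, s = 39)
    gof_test(env)$p
  })
  expect_gte(sum(ps > 0.05), 17)  # ~95% expected at the 5% level

  # exchangeable case: observed difference stays inside the envelopes at
  # nearly all scales
  set.seed(56)
  frac_in <- replicate(5, {
    pool <- sample_csr(240, win)
    pool$species <- sample(rep(c("ctl", "cas"), 120))
    env <- diff_case_control(joint_pattern(pool, "ctl", "cas"), "ctl", "cas",
                             rg, s = 99)
    mean(env$obs >= env$lo & env$obs <= env$hi, na.rm = TRUE)
  })
  expect_gte(mean(frac_in), 0.95)
})

test_that("case-control difference detects case clustering around controls", {
  win <- window_rect()
  rg <- seq(1, 10, by = 1)
  set.seed(57)
  ps <- replicate(20, {
    ctl <- sample_csr(150, win)
    k <- sample.int(150, 100, replace = TRUE)
    cx <- pmin(pmax(ctl$x[k] + rnorm(100), 0), 100)
    cy <- pmin(pmax(ctl$y[k] + rnorm(100), 0), 100)
    cas <- marked_pattern(cx, cy, "cas", win)
    pool <- merge_patterns(ctl, cas)
    jp <- joint_pattern(pool, "sim", "cas")   # csr sampler labels "sim"
    env <- diff_case_control(jp, "sim", "cas", rg, s = 39)
    gof <- gof_test(env)
    excursion_up <- any(env$obs > env$hi, na.rm = TRUE)
    gof$p <= 0.05 && excursion_up
  })
  expect_gte(sum(ps), 15)
})

test_that("shared-species difference is centered under exchangeability and detects asymmetry", {
  win <- window_rect()
  rg <- seq(1, 8, by = 1)
  set.seed(58)
  # exchangeable congeners: mean simulated difference ~ 0 at every scale
  pool <- sample_csr(240, win)
  pool$species <- sample(rep(c("c1", "c2"), 120))
  jp <- joint_pattern(pool, "c1", "c2")
  third <- sample_csr(90, win)
  env <- diff_shared_species(jp, third, "congener_to_third", rg, s = 200)
  ok <- apply(env$sims, 2, function(v) all(is.finite(v)))
  m <- colMeans(env$sims[, ok, drop = FALSE])
  se <- apply(env$sims[, ok, drop = FALSE], 2, sd) / sqrt(nrow(env$sims))
  expect_true(all(abs(m) <= pmax(4.7 * se, 0.05)))
  expect_true(all(abs(m) < 0.2))

  # congener 1 repelled from the third species, congener 2 independent
  set.seed(59)
  hits <- replicate(15, {
    third <- sample_csr(90, win)
    cand <- sample_csr(600, win)
    md <- sapply(seq_len(600), function(i) {
      min(sqrt((third$x - cand$x[i])^2 + (third$y - cand$y[i])^2))
    })
    keep <- which(md > 3)[1:130]
    c1 <- marked_pattern(cand$x[keep], cand$y[keep], "c1", win)
    c2 <- sample_csr(130, win, species = "c2")
    jp <- joint_pattern(merge_patterns(c1, c2), "c1", "c2")
    env <- diff_shared_species(jp, third, "congener_to_third", rg, s = 39)
    gof <- gof_test(env)
    gof$p <= 0.05 && any(env$obs < env$lo, na.rm = TRUE)
  })
  expect_gte(sum(hits), 11)
})

test_that("difference statistics validate their inputs", {
  win <- window_rect()
  p <- random_pattern(20, win, species = rep(c("a", "b"), c(19, 1)))
  jp <- joint_pattern(p, "a", "b")
  expect_error(diff_case_control(jp, "a", "b", 1:5), "at least 2")
  expect_error(diff_case_control(jp, "a", "zz", 1:5), "two labels")
  third_far <- random_pattern(5, window_rect(0, 50, 0, 50))
  good <- random_pattern(20, win, species = rep(c("a", "b"), 10))
  jg <- joint_pattern(good, "a", "b")
  expect_error(diff_shared_species(jg, third_far, "congener_to_third", 1:5),
               "share one window")
})
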