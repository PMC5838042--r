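test_that("species and link specifications validate their parameters", {
  expect_error(species_spec("a", "thomas", n = 10), "kappa")
  expect_error(species_spec("a", "thomas", kappa = -1, sigma = 2, mu = 5),
               "kappa > 0")
  expect_error(association_link("a", "b", "thinning", radius = 0), "radius")
  expect_error(association_link("a", "b", "shared_parents", fraction = 2),
               "fraction")
  sp <- list(species_spec("a", "csr", n = 5), species_spec("b", "csr", n = 5))
  expect_error(community_config(species = c(sp, sp[1])), "unique")
  expect_error(community_config(species = sp,
                                links = list(association_link("a", "zz", "thinning"))),
               "undeclared")
  cyc <- list(association_link("a", "b", "thinning"),
              association_link("b", "a", "thinning"))
  expect_error(community_config(species = sp, links = cyc), "cycle")
})

test_that("Thomas generator honors mu = 0, fixed n and the seed contract", {
  win <- window_rect()
  sterile <- species_spec("t", "thomas", kappa = 0.01, sigma = 2, mu = 0)
  expect_equal(npoints(generate_thomas(sterile, win, seed = 71)), 0L)

  fixed <- species_spec("t", "thomas", n = 500, kappa = 0.005, sigma = 2, mu = 10)
  p <- generate_thomas(fixed, win, seed = 72)
  expect_equal(npoints(p), 500L)
  expect_true(all(p$x >= 0 & p$x <= 100 & p$y >= 0 & p$y <= 100))
  expect_identical(generate_thomas(fixed, win, seed = 72)$x, p$x)
  # clustering visible at short range
  expect_gt(estimate_pcf(p, 2)$g, 2)
})

test_that("independent species show no cross-correlation, thinning removes close pairs", {
  win <- window_rect()
  cfg <- community_config(win, list(
    species_spec("a", "csr", n = 150), species_spec("b", "csr", n = 150)))
  set.seed(73)
  g5 <- replicate(30, {
    com <- generate_community(cfg)
    estimate_pcf_cross(subset_species(com, "a"), subset_species(com, "b"),
                       5, bandwidth = 2)$g
  })
  expect_lt(abs(mean(g5) - 1), 0.1)

  close_cross <- function(cfg) {
    com <- generate_community(cfg)
    a <- subset_species(com, "a"); b <- subset_species(com, "b")
    sum(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 < 9)
  }
  thin_cfg <- community_config(win, list(
    species_spec("a", "csr", n = 150), species_spec("b", "csr", n = 150)),
    list(association_link("a", "b", "thinning", radius = 3, retention = 0.1)))
  set.seed(74)
  unthinned <- mean(replicate(30, close_cross(cfg)))
  thinned <- mean(replicate(30, close_cross(thin_cfg)))
  expect_gte(unthinned / thinned, 5)
})

test_that("shared parents induce positive cross-association", {
  win <- window_rect()
  cfg <- community_config(win, list(
    species_spec("a", "thomas", n = 250, kappa = 0.004, sigma = 2, mu = 7),
    species_spec("b", "thomas", n = 250, kappa = 0.004, sigma = 2, mu = 7)),
    list(association_link("a", "b", "shared_parents", fraction = 1)))
  set.seed(75)
  hits <- replicate(20, {
    com <- generate_community(cfg)
    estimate_pcf_cross(subset_species(com, "a"), subset_species(com, "b"),
                       1, bandwidth = 1)$g > 1
  })
  expect_gte(sum(hits), 18)
})

test_that("plot fixtures reproduce the configured composition exactly", {
  f1 <- generate_fixture("plot1_like", seed = 5)
  tab1 <- table(f1$species)
  expect_equal(unname(tab1[["QS"]]), 543)
  expect_equal(unname(tab1[["QV"]]), 214)
  expect_equal(length(tab1), 12L)  # 2 congeners + 10 heterospecifics
  expect_true(all(f1$x >= 0 & f1$x <= 100 & f1$y >= 0 & f1$y <= 100))
  expect_true(all(f1$dbh >= 1))

  f2 <- generate_fixture("plot2_like", seed = 5)
  tab2 <- table(f2$species)
  expect_equal(as.numeric(tab2[c("QS", "QV", "QA")]), c(340, 169, 170))
  expect_identical(generate_fixture("plot2_like", seed = 5)$x, f2$x)
  expect_error(generate_fixture("plot9_like", 1))
})

test_that("aggregated species read as aggregated under CSR, gradient-only species as random under HP", {
  win <- window_rect()
  rg <- seq(0.5, 10, by = 0.5)
  thom <- species_spec("t", "thomas", n = 300, kappa = 0.005, sigma = 2.5, mu = 6)
  agg <- vapply(1:5, function(seed) {
    p <- generate_thomas(thom, win, seed = seed)
    env <- pattern_envelope(p, "csr", rg, s = 99)
    any(env$obs > env$hi & env$r <= 10, na.rm = TRUE)
  }, logical(1))
  expect_equal(sum(agg), 5L)

  grad_cfg <- community_config(win, list(
    species_spec("g", "inhomogeneous", n = 300, gradient = c(0.015, 0))))
  rnd <- vapply(1:5, function(seed) {
    p <- subset_species(generate_community(grad_cfg, seed = seed), "g")
    env <- pattern_envelope(p, "hp", rg, s = 99)
    gof_test(env)$p > 0.05
  }, logical(1))
  expect_gte(sum(rnd), 4L)
})

test_that("community configurations round-trip through YAML", {
  cfg <- plot_cfg <- community_config(
    window_rect(0, 50, 0, 80),
    list(species_spec("a", "thomas", n = 40, kappa = 0.01, sigma = 1.5, mu = 4,
                      gradient = c(0.01, -0.02)),
         species_spec("b", "csr", n = 25)),
    list(association_link("a", "b", "thinning", radius = 2.5, retention = 0.4)),
    seed = 99)
  tf <- tempfile(fileext = ".yaml")
  write_community_config(cfg, tf)
  back <- read_community_config(tf)
  expect_equal(back$window, cfg$window)
  expect_equal(back$seed, 99)
  expect_equal(back$species[[1]]$kappa, 0.01)
  expect_equal(back$species[[1]]$gradient, c(0.01, -0.02))
  expect_equal(back$links[[1]]$retention, 0.4)
  # identical generative law: same seed, same community
  expect_identical(generate_community(cfg, seed = 3)$x,
                   generate_community(back, seed = 3)$x)
})
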