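test_that("neighborhood counts match manual enumeration", {
  win <- window_rect()
  # A(0,0), B(3,0), C(4,4), B'(20,20): C sits at 5.657 m from A, outside 5 m
  p <- marked_pattern(c(0, 3, 4, 20), c(0, 0, 4, 20), c("A", "B", "C", "B"),
                      win, dbh = c(10, 10, 10, 10))
  ns <- neighborhood_stats(p, radius = 5)
  a <- ns[ns$species == "A", ]
  expect_equal(a$mean_neighbor_species, 1)
  expect_equal(a$mean_neighbor_individuals, 1)
  expect_equal(a$n, 1L)
  expect_equal(a$basal_area, basal_area(10))

  single <- marked_pattern(50, 50, "A", win, dbh = 12)
  ns1 <- neighborhood_stats(single, 5)
  expect_equal(ns1$mean_neighbor_species, 0)
  expect_equal(ns1$mean_neighbor_individuals, 0)

  nodbh <- marked_pattern(c(1, 2), c(1, 2), "A", win)
  expect_error(neighborhood_stats(nodbh, 5), "dbh missing")
  expect_error(neighborhood_stats(single, -1), "positive")
})

test_that("neighborhood counts agree with the brute-force oracle", {
  win <- window_rect(0, 40, 0, 40)
  set.seed(61)
  p <- random_pattern(50, win, species = sample(c("a", "b", "c", "d"), 50, TRUE),
                      with_dbh = TRUE)
  ns <- neighborhood_stats(p, radius = 7)
  bf <- brute_force_neighbors(p, 7)
  for (s in ns$species) {
    sel <- p$species == s
    expect_equal(ns$mean_neighbor_species[ns$species == s], mean(bf$species[sel]))
    expect_equal(ns$mean_neighbor_individuals[ns$species == s],
                 mean(bf$individuals[sel]))
  }
  # total stems conserved across per-species rows
  expect_equal(sum(ns$n), npoints(p))
})

test_that("duplicating every stem doubles individual counts, not species counts", {
  win <- window_rect()
  set.seed(62)
  p <- random_pattern(30, win, species = sample(c("a", "b"), 30, TRUE),
                      with_dbh = TRUE)
  dup <- merge_patterns(p, p)
  bf <- brute_force_neighbors(p, 5)
  bd <- brute_force_neighbors(dup, 5)
  # each stem gains its own duplicate plus every neighbor's duplicate ...
  expect_equal(bd$individuals[seq_len(30)], 2L * bf$individuals + 1L)
  # ... and its species list gains only its own species (when not already there)
  had_conspecific <- vapply(seq_len(30), function(i) {
    d2 <- (p$x - p$x[i])^2 + (p$y - p$y[i])^2
    any(d2 <= 25 & p$species == p$species[i] & seq_len(30) != i)
  }, logical(1))
  expect_equal(bd$species[seq_len(30)], bf$species + !had_conspecific)
  nd <- neighborhood_stats(dup, 5)
  expect_equal(sum(nd$n), 2L * npoints(p))
  # implementation agrees with the oracle on the duplicated community
  for (s in nd$species) {
    sel <- dup$species == s
    expect_equal(nd$mean_neighbor_individuals[nd$species == s],
                 mean(bd$individuals[sel]))
  }
})

test_that("focal regression reproduces closed-form OLS", {
  df <- data.frame(basal_area = c(1, 2, 3),
                   mean_neighbor_species = c(2, 3, 5),
                   mean_neighbor_individuals = c(4, 4, 4))
  fit <- fit_focal_regression(df, "species")
  expect_equal(fit$slope, 1.5)
  expect_equal(fit$r, 1.5 / sqrt(7 / 3), tolerance = 1e-6)
  expect_equal(round(fit$r, 3), 0.982)

  # perfect line
  df2 <- data.frame(basal_area = 1:5, mean_neighbor_species = 2 * (1:5),
                    mean_neighbor_individuals = 1:5)
  fit2 <- fit_focal_regression(df2, "species")
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$r, 1)

  # constant response degenerates gracefully
  expect_warning(fit0 <- fit_focal_regression(df, "individuals"), "constant")
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$r, 0)

  expect_error(fit_focal_regression(df[1:2, ], "species"), "at least 3")
})

test_that("diversity indices follow the basal-area share formulas", {
  win <- window_rect()
  one <- marked_pattern(c(1, 2), c(1, 2), "a", win, dbh = c(10, 20))
  d1 <- diversity_indices(one)
  expect_equal(d1$H, 0)
  expect_equal(d1$D, 0)

  # equal basal areas: H = ln 2, D = 1/2
  eq <- marked_pattern(c(1, 2), c(1, 2), c("a", "b"), win, dbh = c(15, 15))
  d2 <- diversity_indices(eq)
  expect_equal(d2$H, log(2))
  expect_equal(d2$D, 0.5)

  # shares 0.8 / 0.2 via dbh 20 and 10
  sh <- marked_pattern(c(1, 2), c(1, 2), c("a", "b"), win, dbh = c(20, 10))
  d3 <- diversity_indices(sh)
  expect_equal(unname(d3$p[order(-d3$p)]), c(0.8, 0.2))
  expect_equal(d3$H, -(0.8 * log(0.8) + 0.2 * log(0.2)))
  expect_equal(round(d3$H, 4), 0.5004)
  expect_equal(d3$D, 0.32)
  expect_equal(sum(d3$p), 1)
})

test_that("diversity is invariant to species order and dbh rescaling, maximal at even shares", {
  win <- window_rect()
  set.seed(63)
  p <- random_pattern(80, win, species = sample(letters[1:5], 80, TRUE),
                      with_dbh = TRUE)
  d <- diversity_indices(p)
  # relabel species by a permutation
  perm <- setNames(letters[sample(5)], letters[1:5])
  q <- p; q$species <- unname(perm[p$species])
  dq <- diversity_indices(q)
  expect_equal(dq$H, d$H)
  expect_equal(dq$D, d$D)
  # rescale all dbh: shares are scale-free
  ps <- p; ps$dbh <- p$dbh * 3.7
  dsc <- diversity_indices(ps)
  expect_equal(dsc$H, d$H)
  expect_equal(dsc$D, d$D)
  # even shares maximize H among random perturbations
  k <- d$n_species
  expect_lte(d$H, log(k))
  for (i in 1:20) {
    pp <- abs(rnorm(k)) + 0.01
    pp <- pp / sum(pp)
    expect_lte(-sum(pp * log(pp)), log(k) + 1e-12)
  }
})

test_that("quadrat handling restricts the diversity computation", {
  win <- window_rect()
  p <- marked_pattern(c(10, 10, 90), c(10, 20, 90), c("a", "b", "c"), win,
                      dbh = c(10, 10, 10))
  q <- diversity_indices(p, quadrat = window_rect(0, 50, 0, 50))
  expect_equal(q$n_species, 2L)
  expect_equal(q$H, log(2))
  expect_error(diversity_indices(p, quadrat = window_rect(40, 60, 40, 60)),
               "no stems")
  expect_error(diversity_indices(p, quadrat = window_rect(-10, 50, 0, 50)),
               "inside")
})
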