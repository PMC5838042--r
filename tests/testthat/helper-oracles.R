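# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: plain double loops and numerical
# integration, so agreement is evidence, not tautology.

# fraction of the circumference of circle (x, y, d) inside a rectangular
# window, by grid + bisection of the inside indicator along the circle
numeric_inside_fraction <- function(x, y, d, win, ngrid = 4096L) {
  inside <- function(t) {
    px <- x + d * cos(t); py <- y + d * sin(t)
    px >= win$xmin & px <= win$xmax & py >= win$ymin & py <= win$ymax
  }
  th <- seq(0, 2 * pi, length.out = ngrid + 1L)
  ins <- inside(th)
  total <- 0
  for (k in seq_len(ngrid)) {
    a <- th[k]; b <- th[k + 1L]
    if (ins[k] && ins[k + 1L]) {
      total <- total + (b - a)
    } else if (ins[k] || ins[k + 1L]) {
      lo <- a; hi <- b
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        if (inside(mid) == ins[k]) lo <- mid else hi <- mid
      }
      cross <- (lo + hi) / 2
      total <- total + if (ins[k]) (cross - a) else (b - cross)
    }
  }
  total / (2 * pi)
}

# literal double-loop Ripley K per the ordered-sum definition
brute_force_K <- function(pattern, rgrid) {
  n <- length(pattern$x)
  A <- window_area(pattern$window)
  vapply(rgrid, function(r) {
    tot <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d <- sqrt((pattern$x[i] - pattern$x[j])^2 +
                    (pattern$y[i] - pattern$y[j])^2)
        if (d < r) {
          tot <- tot + ripley_weight(pattern$x[i], pattern$y[i], d,
                                     pattern$window)
        }
      }
    }
    A / n^2 * tot
  }, numeric(1))
}

# literal per-stem neighborhood counts
brute_force_neighbors <- function(pattern, radius) {
  n <- length(pattern$x)
  sp_counts <- integer(n); ind_counts <- integer(n)
  for (i in seq_len(n)) {
    seen <- character(0); m <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((pattern$x[i] - pattern$x[j])^2 +
                  (pattern$y[i] - pattern$y[j])^2)
      if (d <= radius) {
        m <- m + 1L
        seen <- union(seen, pattern$species[j])
      }
    }
    ind_counts[i] <- m; sp_counts[i] <- length(seen)
  }
  list(species = sp_counts, individuals = ind_counts)
}

# literal evaluation of the rank-based goodness-of-fit p-value from a
# (s+1) x m curve matrix (row 1 = observed), leave-one-out expectation
brute_force_gof <- function(curves) {
  nr <- nrow(curves)
  u <- numeric(nr)
  for (i in seq_len(nr)) {
    expected <- colMeans(curves[-i, , drop = FALSE])
    u[i] <- sum((curves[i, ] - expected)^2)
  }
  exceed <- sum(u[1L] > u[-1L])
  list(u0 = u[1L], u = u[-1L], p = 1 - exceed / nr,
       rank = nr - exceed)
}

# closed-form Thomas-process pair correlation function
thomas_pcf <- function(r, kappa, sigma) {
  1 + exp(-r^2 / (4 * sigma^2)) / (4 * pi * sigma^2 * kappa)
}

random_pattern <- function(n, win = window_rect(), species = "sp",
                           with_dbh = FALSE) {
  marked_pattern(stats::runif(n, win$xmin, win$xmax),
                 stats::runif(n, win$ymin, win$ymax),
                 species = species, window = win,
                 dbh = if (with_dbh) stats::runif(n, 5, 40) else NULL)
}
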