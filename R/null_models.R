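#' Complete spatial randomness (CSR) sampler
#'
#' Draws exactly `n` points independently and uniformly over a rectangular
#' window: the homogeneous Poisson null conditioned on the observed count,
#' so that envelopes compare patterns of identical abundance.
#'
#' All samplers in the package use base R's RNG; passing `seed` makes the
#' draw reproducible (identical seed, identical pattern) without touching
#' the caller's RNG state otherwise.
#'
#' @param n Number of points (`>= 0`).
#' @param window A [window_rect()].
#' @param species Label attached to the sampled points.
#' @param seed Optional integer seed.
#' @return A [marked_pattern()].
#' @export
sample_csr <- function(n, window = window_rect(), species = "sim", seed = NULL) {
  stopifnot(inherits(window, "ppwindow"))
  if (length(n) != 1L || !is.finite(n) || n < 0) {
    stop("n must be a single nonnegative count", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  marked_pattern(stats::runif(n, window$xmin, window$xmax),
                 stats::runif(n, window$ymin, window$ymax),
                 species = if (n) species else character(0), window = window)
}

#' Heterogeneous Poisson (HP) sampler
#'
#' Draws exactly `n` points i.i.d. from an [estimate_intensity()] surface,
#' normalized (conditional-on-n heterogeneous Poisson). Sampling is by
#' rejection against the surface maximum, with bilinear interpolation of
#' the gridded intensity between nodes, so the spatial law follows the
#' surface rather than the grid. With a constant surface this reduces to
#' [sample_csr()].
#'
#' @param intensity An `"intensity_surface"`; must be nonnegative and not
#'   identically zero.
#' @param n Number of points (`>= 0`); defaults to the count the surface
#'   was estimated from.
#' @param species Label attached to the sampled points.
#' @param seed Optional integer seed.
#' @return A [marked_pattern()].
#' @export
sample_hp <- function(intensity, n = NULL, species = "sim", seed = NULL) {
  stopifnot(inherits(intensity, "intensity_surface"))
  if (any(intensity$lambda < 0)) stop("intensity must be nonnegative", call. = FALSE)
  lmax <- max(intensity$lambda)
  if (lmax <= 0) stop("intensity is identically zero", call. = FALSE)
  if (is.null(n)) n <- intensity$n
  if (length(n) != 1L || !is.finite(n) || n < 0) {
    stop("n must be a single nonnegative count", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  win <- intensity$window
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 64L)
    cx <- stats::runif(m, win$xmin, win$xmax)
    cy <- stats::runif(m, win$ymin, win$ymax)
    acc <- stats::runif(m) * lmax < interp_intensity(intensity, cx, cy)
    xs <- c(xs, cx[acc]); ys <- c(ys, cy[acc])
  }
  marked_pattern(xs[seq_len(n)], ys[seq_len(n)],
                 species = if (n) species else character(0), window = win)
}

#' Two-label joint pattern for random labeling
#'
#' Restricts a marked pattern to exactly two focal species labels and
#' records their counts `n1`, `n2`. Random labeling permutes the labels
#' over these fixed joint locations.
#'
#' @param pattern A [marked_pattern()].
#' @param label1,label2 The two focal species labels; both must occur.
#' @return Object of class `"joint_pattern"`: a `"marked_pattern"` with
#'   extra fields `label1`, `label2`, `n1`, `n2`.
#' @export
joint_pattern <- function(pattern, label1, label2) {
  stopifnot(inherits(pattern, "marked_pattern"))
  sub <- subset_species(pattern, c(label1, label2))
  n1 <- sum(sub$species == label1)
  n2 <- sum(sub$species == label2)
  if (n1 == 0L || n2 == 0L) {
    stop("both labels must be present in the pattern", call. = FALSE)
  }
  sub$label1 <- label1; sub$label2 <- label2
  sub$n1 <- n1; sub$n2 <- n2
  class(sub) <- c("joint_pattern", "marked_pattern")
  sub
}

#' Random labeling (RL) null
#'
#' Returns a copy of a two-label [joint_pattern()] whose positions (and any
#' dbh/status marks attached to positions) are unchanged, while the two
#' species labels are reassigned by a uniform random permutation preserving
#' the label counts `n1` and `n2`. If one label is absent (`n2 = 0` never
#' happens for a valid joint pattern, but a degenerate single-label input is
#' returned unchanged).
#'
#' @param joint A `"joint_pattern"`.
#' @param seed Optional integer seed.
#' @return A `"joint_pattern"` with permuted labels.
#' @export
relabel <- function(joint, seed = NULL) {
  stopifnot(inherits(joint, "joint_pattern"))
  if (!is.null(seed)) set.seed(seed)
  n <- npoints(joint)
  out <- joint
  if (joint$n1 == 0L || joint$n2 == 0L || n == 0L) return(out)
  lab <- rep(joint$label2, n)
  lab[sample.int(n, joint$n1)] <- joint$label1
  out$species <- lab
  out
}
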