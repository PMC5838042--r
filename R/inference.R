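#' Pointwise Monte-Carlo simulation envelope
#'
#' Simulates `s` replicates of a null model, evaluates a functional summary
#' statistic on each, and returns the pointwise minimum/maximum envelopes
#' together with the observed curve and all simulated curves (retained for
#' the goodness-of-fit test). With `s = 199` the pointwise probability that
#' an exchangeable realization falls outside the min/max band is
#' `2/(s+1) = 1%`, i.e. an approximately 99% envelope.
#'
#' @param observed The observed input (any object the two closures accept,
#'   typically a [marked_pattern()] or [joint_pattern()]).
#' @param statistic Function mapping such an input to a numeric curve
#'   evaluated on `rgrid` (missing values allowed and propagated).
#' @param null Function mapping the observed input to one simulated
#'   replicate under the null model.
#' @param rgrid Distance grid the statistic is evaluated on.
#' @param s Number of simulations (`>= 1`).
#' @param seed Optional integer seed (set once before the simulation loop).
#' @param label Short description of the statistic, kept in the result.
#' @return Object of class `"envelope_result"`: list with `r`, `obs`, `lo`,
#'   `hi`, `sims` (an `s` by `length(r)` matrix), `s`, `seed`, `statistic`.
#' @export
build_envelope <- function(observed, statistic, null, rgrid = default_rgrid(),
                           s = 199, seed = NULL, label = "statistic") {
  stopifnot(is.function(statistic), is.function(null))
  validate_rgrid(rgrid)
  if (length(s) != 1L || !is.finite(s) || s < 1) {
    stop("s must be a single count >= 1", call. = FALSE)
  }
  s <- as.integer(s)
  if (!is.null(seed)) set.seed(seed)
  obs <- as.numeric(statistic(observed))
  if (length(obs) != length(rgrid)) {
    stop("statistic must return one value per grid point", call. = FALSE)
  }
  sims <- matrix(NA_real_, nrow = s, ncol = length(rgrid))
  for (i in seq_len(s)) {
    sims[i, ] <- tryCatch(
      as.numeric(statistic(null(observed))),
      error = function(e) stop(sprintf("statistic failed on replicate %d: %s",
                                       i, conditionMessage(e)), call. = FALSE)
    )
  }
  lo <- apply(sims, 2L, function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  hi <- apply(sims, 2L, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  structure(list(r = rgrid, obs = obs, lo = lo, hi = hi, sims = sims,
                 s = s, seed = seed, statistic = label),
            class = "envelope_result")
}

#' @export
print.envelope_result <- function(x, ...) {
  out <- sum(x$obs < x$lo | x$obs > x$hi, na.rm = TRUE)
  cat(sprintf("Monte-Carlo envelope of %s: s = %d simulations, %d scales, %d excursions\n",
              x$statistic, x$s, length(x$r), out))
  invisible(x)
}

#' Goodness-of-fit test for a functional summary statistic
#'
#' Computes, for the observed curve (index 0) and each of `s` simulated
#' curves, the total squared deviation over a distance interval between the
#' curve and its expectation under the null, the expectation being taken as
#' the mean of the *other* curves (leave-one-out, which makes all `s + 1`
#' deviations exchangeable under the null). The p-value is
#' `p = 1 - sum(I(u0 > ui)) / (s + 1)` with a strict inequality, so ties
#' count toward non-significance; tied deviations are reported via a
#' message. The rank of the observed deviation (1 = largest, most extreme)
#' satisfies `p = 1 - (s + 1 - rank) / (s + 1)`.
#'
#' Grid points where any curve is missing (e.g. pcf values below half a
#' bandwidth) are excluded from the deviation sum.
#'
#' @param x An `"envelope_result"`, or a numeric observed curve.
#' @param sims Simulated curves (`s` by `length(r)` matrix) when `x` is a
#'   numeric curve.
#' @param r Distance grid when `x` is a numeric curve.
#' @param interval Length-2 numeric range of scales to include; default the
#'   whole positive grid.
#' @return Object of class `"gof_result"`: list with `u0`, `u` (the
#'   simulated deviations), `rank`, `p`, `s`, `interval`, `r_used`.
#' @export
gof_test <- function(x, sims = NULL, r = NULL, interval = NULL) {
  if (inherits(x, "envelope_result")) {
    obs <- x$obs; sims <- x$sims; r <- x$r
  } else {
    obs <- as.numeric(x)
    if (is.null(sims) || is.null(r)) {
      stop("sims and r are required when passing a raw curve", call. = FALSE)
    }
    sims <- as.matrix(sims)
  }
  s <- nrow(sims)
  if (s < 1L) stop("at least 1 simulated curve is required", call. = FALSE)
  if (is.null(interval)) interval <- c(min(r[r > 0]), max(r))
  use <- r >= interval[1L] & r <= interval[2L] & r > 0
  use <- use & is.finite(obs) & apply(sims, 2L, function(v) all(is.finite(v)))
  if (!any(use)) stop("empty distance interval for the goodness-of-fit test",
                      call. = FALSE)
  curves <- rbind(obs[use], sims[, use, drop = FALSE])  # (s+1) x m
  tot <- colSums(curves)
  u <- vapply(seq_len(s + 1L), function(i) {
    expected <- (tot - curves[i, ]) / s
    sum((curves[i, ] - expected)^2)
  }, numeric(1))
  u0 <- u[1L]
  ui <- u[-1L]
  # with a single simulation the two leave-one-out deviations always tie
  if (s >= 2L && any(ui == u0)) {
    message("goodness-of-fit: tied deviations broken toward non-significance")
  }
  exceed <- sum(u0 > ui)
  # algebraically 1 - exceed/(s+1); this form avoids float drift at the
  # attainable p levels (e.g. 2/40 compares equal to a 0.05 cutoff)
  p <- (s + 1 - exceed) / (s + 1)
  structure(list(u0 = u0, u = ui, rank = s + 1L - exceed, p = p, s = s,
                 interval = interval, r_used = r[use]),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf(
    "goodness-of-fit: u0 = %.4g, rank %d of %d, p = %.4g on r in [%g, %g] m\n",
    x$u0, x$rank, x$s + 1L, x$p, x$interval[1L], x$interval[2L]))
  invisible(x)
}

# fixed pcf bandwidth for a two-label joint pattern: Stoyan's rule at the
# geometric-mean intensity of the two labels; invariant under relabeling
joint_bandwidth <- function(n1, n2, A) stoyan_bandwidth(sqrt(n1 * n2) / A)

#' Case-control difference of pair correlation functions
#'
#' Tests whether a "case" species shows spatial structure beyond that of a
#' "control" species occupying the same habitat, using random labeling over
#' the fixed joint locations. The observed statistic is
#' `D(r) = g_cc'(r) - g_cc(r)`: the bivariate pcf from control to case
#' minus the univariate pcf of the control. Under exchangeable labels
#' D is centered at zero; `D(r) > 0` indicates additional aggregation of
#' the case that is independent of the control. Envelopes come from `s`
#' random relabelings; the kernel bandwidth is computed once from the
#' observed label counts and reused for every replicate.
#'
#' @param joint A [joint_pattern()] holding both species.
#' @param control,case The two labels; each must have at least 2 points.
#' @param rgrid Distance grid.
#' @param bandwidth Kernel half-width; default [stoyan_bandwidth()] at the
#'   geometric-mean intensity of the two labels.
#' @param s Number of relabelings.
#' @param seed Optional integer seed.
#' @return An `"envelope_result"` for the difference statistic.
#' @export
diff_case_control <- function(joint, control, case, rgrid = default_rgrid(),
                              bandwidth = NULL, s = 199, seed = NULL) {
  stopifnot(inherits(joint, "joint_pattern"))
  if (!all(c(control, case) %in% c(joint$label1, joint$label2))) {
    stop("control and case must be the joint pattern's two labels", call. = FALSE)
  }
  n_ctrl <- sum(joint$species == control)
  n_case <- sum(joint$species == case)
  if (n_ctrl < 2L || n_case < 2L) {
    stop("both labels need at least 2 points for the case-control statistic",
         call. = FALSE)
  }
  A <- window_area(joint$window)
  h <- if (is.null(bandwidth)) joint_bandwidth(n_ctrl, n_case, A) else bandwidth
  stat <- function(jp) {
    ctrl <- subset_species(jp, control)
    cs <- subset_species(jp, case)
    estimate_pcf_cross(ctrl, cs, rgrid, bandwidth = h)$g -
      estimate_pcf(ctrl, rgrid, bandwidth = h)$g
  }
  build_envelope(joint, stat, function(jp) relabel(jp), rgrid, s = s,
                 seed = seed,
                 label = sprintf("g[%s,%s] - g[%s,%s] under random labeling",
                                 control, case, control, control))
}

#' Shared-heterospecific difference of cross pair correlation functions
#'
#' Compares how two congeneric species relate to the same third
#' (heterospecific) species: the observed statistic is
#' `D(r) = g_13(r) - g_23(r)` (congener-to-third direction) or
#' `D(r) = g_31(r) - g_32(r)` (third-to-congener direction), where 1 and 2
#' are the two congener labels of the joint pattern and 3 the third
#' species. Envelopes come from `s` random relabelings of the congener pair
#' only; the third species is never moved. Under labels exchangeable with
#' respect to the third species, `E[D] = 0` exactly; `D < 0` indicates the
#' first congener has the stronger negative influence on (or association
#' with) the third species.
#'
#' @param joint A [joint_pattern()] of the two congeners (each `>= 2`
#'   points).
#' @param third A [marked_pattern()] of the heterospecific species, same
#'   window, at least 1 point.
#' @param direction `"congener_to_third"` (g13 - g23) or
#'   `"third_to_congener"` (g31 - g32).
#' @param rgrid Distance grid.
#' @param bandwidth Kernel half-width; default Stoyan's rule at the
#'   geometric mean of the mean congener intensity and the third species'
#'   intensity (fixed across replicates).
#' @param s Number of relabelings.
#' @param seed Optional integer seed.
#' @return An `"envelope_result"` for the difference statistic.
#' @export
diff_shared_species <- function(joint, third,
                                direction = c("congener_to_third",
                                              "third_to_congener"),
                                rgrid = default_rgrid(), bandwidth = NULL,
                                s = 199, seed = NULL) {
  stopifnot(inherits(joint, "joint_pattern"), inherits(third, "marked_pattern"))
  direction <- match.arg(direction)
  if (!window_equal(joint$window, third$window)) {
    stop("joint and third-species patterns must share one window", call. = FALSE)
  }
  if (joint$n1 < 2L || joint$n2 < 2L) {
    stop("both congeners need at least 2 points", call. = FALSE)
  }
  n3 <- npoints(third)
  if (n3 < 1L) stop("third-species pattern is empty", call. = FALSE)
  A <- window_area(joint$window)
  h <- if (is.null(bandwidth)) {
    stoyan_bandwidth(sqrt(sqrt(joint$n1 * joint$n2) * n3) / A)
  } else bandwidth
  lab1 <- joint$label1; lab2 <- joint$label2
  stat <- function(jp) {
    c1 <- subset_species(jp, lab1)
    c2 <- subset_species(jp, lab2)
    if (direction == "congener_to_third") {
      estimate_pcf_cross(c1, third, rgrid, bandwidth = h)$g -
        estimate_pcf_cross(c2, third, rgrid, bandwidth = h)$g
    } else {
      estimate_pcf_cross(third, c1, rgrid, bandwidth = h)$g -
        estimate_pcf_cross(third, c2, rgrid, bandwidth = h)$g
    }
  }
  lbl <- if (direction == "congener_to_third") {
    sprintf("g[%s,3] - g[%s,3] under random labeling", lab1, lab2)
  } else {
    sprintf("g[3,%s] - g[3,%s] under random labeling", lab1, lab2)
  }
  build_envelope(joint, stat, function(jp) relabel(jp), rgrid, s = s,
                 seed = seed, label = lbl)
}

#' Classify an association as negative, positive or absent
#'
#' Combines a simulation envelope and its goodness-of-fit test into the
#' three-outcome call used for association tables: `"none"` when the GoF
#' p-value exceeds `alpha` or the observed curve never leaves the envelope;
#' otherwise the sign of the direction (below the lower or above the upper
#' envelope) with the larger summed squared excursion over the interval.
#'
#' @param env An `"envelope_result"`.
#' @param gof The matching `"gof_result"` (same curves and interval).
#' @param alpha Significance level (default .05).
#' @param interval Optional scale range over which excursions are summed;
#'   default the GoF interval.
#' @return Object of class `"association_call"`: list with `sign` (one of
#'   `"negative"`, `"positive"`, `"none"`), `p`, `below`, `above`.
#' @export
classify_association <- function(env, gof, alpha = 0.05, interval = NULL) {
  stopifnot(inherits(env, "envelope_result"), inherits(gof, "gof_result"))
  if (is.null(interval)) interval <- gof$interval
  use <- env$r >= interval[1L] & env$r <= interval[2L] &
    is.finite(env$obs) & is.finite(env$lo) & is.finite(env$hi)
  below <- sum(pmax(0, env$lo[use] - env$obs[use])^2)
  above <- sum(pmax(0, env$obs[use] - env$hi[use])^2)
  sign <- if (gof$p > alpha || (below == 0 && above == 0)) {
    "none"
  } else if (below > above) "negative" else "positive"
  structure(list(sign = sign, p = gof$p, below = below, above = above),
            class = "association_call")
}

#' @export
print.association_call <- function(x, ...) {
  code <- switch(x$sign, negative = "-", positive = "+", none = "r")
  cat(sprintf("association call: %s (p = %.3g)\n", code, x$p))
  invisible(x)
}

#' Univariate pattern envelope under CSR or heterogeneous Poisson
#'
#' Analysis of one species' spatial pattern: envelope of the univariate
#' pair correlation function under either complete spatial randomness or a
#' heterogeneous Poisson null whose intensity surface is kernel-estimated
#' from the observed pattern itself (once; the surface is not re-estimated
#' per replicate). Both nulls condition on the observed stem count.
#'
#' @param pattern A [marked_pattern()] of one species (`>= 2` points).
#' @param null `"csr"` or `"hp"`.
#' @param rgrid Distance grid.
#' @param bandwidth pcf kernel half-width (default Stoyan's rule).
#' @param intensity_bandwidth Gaussian bandwidth of the HP intensity
#'   surface, meters.
#' @param s Number of simulations.
#' @param seed Optional integer seed.
#' @return An `"envelope_result"` for g(r).
#' @export
pattern_envelope <- function(pattern, null = c("csr", "hp"),
                             rgrid = default_rgrid(), bandwidth = NULL,
                             intensity_bandwidth = 20, s = 199, seed = NULL) {
  stopifnot(inherits(pattern, "marked_pattern"))
  null <- match.arg(null)
  n <- npoints(pattern)
  if (n < 2L) stop("at least 2 points are required", call. = FALSE)
  A <- window_area(pattern$window)
  h <- if (is.null(bandwidth)) stoyan_bandwidth(n / A) else bandwidth
  stat <- function(p) estimate_pcf(p, rgrid, bandwidth = h)$g
  sim <- if (null == "csr") {
    function(p) sample_csr(n, p$window)
  } else {
    surface <- estimate_intensity(pattern, bandwidth = intensity_bandwidth)
    function(p) sample_hp(surface, n = n)
  }
  build_envelope(pattern, stat, sim, rgrid, s = s, seed = seed,
                 label = sprintf("g under %s", toupper(null)))
}

#' Bivariate association envelope under the heterogeneous Poisson null
#'
#' Analysis of the association between a fixed species and a second species
#' whose locations are randomized: the observed statistic is the cross pcf
#' `g_fixed,moving(r)`; null replicates redraw the moving species from a
#' heterogeneous Poisson process with its own kernel-estimated intensity
#' surface (estimated once from the observed moving pattern), keeping the
#' fixed species in place. An observed curve above (below) the envelope
#' indicates positive (negative) interspecific association at that scale.
#'
#' @param fixed A [marked_pattern()] kept in place (`>= 1` point).
#' @param moving A [marked_pattern()] randomized under HP (`>= 2` points),
#'   same window.
#' @param rgrid Distance grid.
#' @param bandwidth pcf kernel half-width (default Stoyan's rule at the
#'   geometric-mean intensity).
#' @param intensity_bandwidth Gaussian bandwidth of the HP surface, meters.
#' @param s Number of simulations.
#' @param seed Optional integer seed.
#' @return An `"envelope_result"` for g_ab(r).
#' @export
hp_association <- function(fixed, moving, rgrid = default_rgrid(),
                           bandwidth = NULL, intensity_bandwidth = 20,
                           s = 199, seed = NULL) {
  stopifnot(inherits(fixed, "marked_pattern"), inherits(moving, "marked_pattern"))
  if (!window_equal(fixed$window, moving$window)) {
    stop("patterns must share one window", call. = FALSE)
  }
  na <- npoints(fixed); nb <- npoints(moving)
  if (na < 1L || nb < 2L) {
    stop("fixed needs >= 1 and moving >= 2 points", call. = FALSE)
  }
  A <- window_area(fixed$window)
  h <- if (is.null(bandwidth)) stoyan_bandwidth(sqrt(na * nb) / A) else bandwidth
  surface <- estimate_intensity(moving, bandwidth = intensity_bandwidth)
  stat <- function(mv) estimate_pcf_cross(fixed, mv, rgrid, bandwidth = h)$g
  build_envelope(moving, stat, function(mv) sample_hp(surface, n = nb),
                 rgrid, s = s, seed = seed,
                 label = "cross pcf under HP randomization of the second species")
}

#' Serialize an envelope as a tidy table
#'
#' @param env An `"envelope_result"`.
#' @return Data frame with columns `r`, `value`, `lo`, `hi`, `statistic`.
#' @export
as_envelope_table <- function(env) {
  stopifnot(inherits(env, "envelope_result"))
  data.frame(r = env$r, value = env$obs, lo = env$lo, hi = env$hi,
             statistic = env$statistic)
}
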