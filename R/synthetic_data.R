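#' Species specification for the community generator
#'
#' Describes one species' generating process: complete spatial randomness,
#' an inhomogeneous (log-linear habitat gradient) Poisson pattern, or a
#' Thomas cluster process (Poisson parents, Gaussian-scattered Poisson
#' offspring), plus a lognormal dbh law. A Thomas species may additionally
#' carry gradient coefficients, in which case its parents follow the
#' gradient. When `n` is given the generator conditions on exactly that
#' abundance.
#'
#' @param label Species label (unique within a community).
#' @param process `"csr"`, `"inhomogeneous"` or `"thomas"`.
#' @param n Abundance (`>= 0`), or `NULL` for a random-size Thomas draw.
#' @param kappa Thomas parent intensity, parents per m^2.
#' @param sigma Thomas offspring displacement standard deviation, meters.
#' @param mu Thomas mean offspring per parent.
#' @param gradient Length-2 log-linear intensity coefficients `(bx, by)`:
#'   intensity proportional to `exp(bx * x + by * y)`.
#' @param dbh_meanlog,dbh_sdlog Lognormal dbh parameters (cm scale); draws
#'   are floored at 0.1 cm.
#' @return Object of class `"species_spec"`.
#' @export
species_spec <- function(label, process = c("csr", "inhomogeneous", "thomas"),
                         n = NULL, kappa = NULL, sigma = NULL, mu = NULL,
                         gradient = c(0, 0), dbh_meanlog = log(10),
                         dbh_sdlog = 0.5) {
  process <- match.arg(process)
  if (!is.null(n) && (length(n) != 1L || n < 0)) {
    stop("n must be a single nonnegative count", call. = FALSE)
  }
  if (process == "thomas") {
    if (is.null(kappa) || is.null(sigma) || is.null(mu)) {
      stop("a thomas species needs kappa, sigma and mu", call. = FALSE)
    }
    if (kappa <= 0 || sigma <= 0 || mu < 0) {
      stop("thomas parameters must satisfy kappa > 0, sigma > 0, mu >= 0",
           call. = FALSE)
    }
  }
  stopifnot(length(gradient) == 2L, is.numeric(gradient), dbh_sdlog >= 0)
  structure(list(label = as.character(label), process = process,
                 n = if (is.null(n)) NULL else as.integer(n),
                 kappa = kappa, sigma = sigma, mu = mu,
                 gradient = as.numeric(gradient),
                 dbh_meanlog = dbh_meanlog, dbh_sdlog = dbh_sdlog),
            class = "species_spec")
}

#' Interspecific association link for the community generator
#'
#' Two mechanisms are available. `"shared_parents"`: the target species
#' reuses a fraction of the source species' Thomas parent points, which
#' induces positive cross-species association at the cluster scale.
#' `"thinning"`: target candidates within `radius` meters of any source
#' point are retained with probability `retention`, which induces negative
#' association at scales up to the radius.
#'
#' @param from,to Source and target species labels.
#' @param mechanism `"shared_parents"` or `"thinning"`.
#' @param fraction Shared-parent fraction in `[0, 1]`.
#' @param radius Thinning radius, meters (`> 0`).
#' @param retention Retention probability in `[0, 1]` inside the radius.
#' @return Object of class `"association_link"`.
#' @export
association_link <- function(from, to, mechanism = c("shared_parents", "thinning"),
                             fraction = 0.5, radius = 5, retention = 0.2) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "shared_parents") {
    if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]", call. = FALSE)
  } else {
    if (radius <= 0) stop("thinning radius must be positive", call. = FALSE)
    if (retention < 0 || retention > 1) stop("retention must be in [0, 1]", call. = FALSE)
  }
  structure(list(from = as.character(from), to = as.character(to),
                 mechanism = mechanism, fraction = fraction,
                 radius = radius, retention = retention),
            class = "association_link")
}

#' Community configuration
#'
#' Bundles a window, a list of [species_spec()]s and a list of
#' [association_link()]s into a validated generative description of a
#' multi-species stem map. Labels must be unique, links must reference
#' declared labels, and the directed graph of links must be acyclic (each
#' link's source species is generated before its target).
#'
#' @param window A [window_rect()].
#' @param species List of [species_spec()]s.
#' @param links List of [association_link()]s (possibly empty).
#' @param seed Optional default seed recorded in the config.
#' @return Object of class `"community_config"`.
#' @export
community_config <- function(window = window_rect(), species = list(),
                             links = list(), seed = NULL) {
  stopifnot(inherits(window, "ppwindow"))
  lapply(species, function(s) stopifnot(inherits(s, "species_spec")))
  lapply(links, function(l) stopifnot(inherits(l, "association_link")))
  labels <- vapply(species, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("species labels must be unique", call. = FALSE)
  for (l in links) {
    if (!all(c(l$from, l$to) %in% labels)) {
      stop(sprintf("link %s -> %s references an undeclared species",
                   l$from, l$to), call. = FALSE)
    }
  }
  order_species_labels(labels, links)  # errors on cycles
  structure(list(window = window, species = species, links = links,
                 seed = seed),
            class = "community_config")
}

# topological order of species labels under the directed link graph
order_species_labels <- function(labels, links) {
  edges <- lapply(links, function(l) c(l$from, l$to))
  remaining <- labels
  ordered <- character(0)
  while (length(remaining)) {
    has_incoming <- vapply(remaining, function(lab) {
      any(vapply(edges, function(e) e[2L] == lab && e[1L] %in% remaining,
                 logical(1)))
    }, logical(1))
    ready <- remaining[!has_incoming]
    if (!length(ready)) {
      stop("association links contain a cycle; generation order is undefined",
           call. = FALSE)
    }
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

# rejection sampler from a log-linear gradient exp(bx*x + by*y) on a window
sample_gradient_points <- function(m, window, gradient) {
  bx <- gradient[1L]; by <- gradient[2L]
  lmax <- exp(max(bx * c(window$xmin, window$xmax)) +
                max(by * c(window$ymin, window$ymax)))
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < m) {
    k <- max(2L * (m - length(xs)), 64L)
    cx <- stats::runif(k, window$xmin, window$xmax)
    cy <- stats::runif(k, window$ymin, window$ymax)
    acc <- stats::runif(k) * lmax < exp(bx * cx + by * cy)
    xs <- c(xs, cx[acc]); ys <- c(ys, cy[acc])
  }
  cbind(xs[seq_len(m)], ys[seq_len(m)])
}

# one round of offspring from a fixed parent set
thomas_offspring <- function(parents, mu, sigma, window) {
  if (!nrow(parents) || mu <= 0) return(cbind(numeric(0), numeric(0)))
  counts <- stats::rpois(nrow(parents), mu)
  if (sum(counts) == 0L) return(cbind(numeric(0), numeric(0)))
  px <- rep(parents[, 1L], counts)
  py <- rep(parents[, 2L], counts)
  ox <- px + stats::rnorm(length(px), sd = sigma)
  oy <- py + stats::rnorm(length(py), sd = sigma)
  keep <- points_inside(ox, oy, window)
  cbind(ox[keep], oy[keep])
}

# minimum distance from each candidate to a source point set
min_dist_to <- function(cand, src) {
  if (!nrow(cand)) return(numeric(0))
  if (!nrow(src)) return(rep(Inf, nrow(cand)))
  dx <- outer(cand[, 1L], src[, 1L], "-")
  dy <- outer(cand[, 2L], src[, 2L], "-")
  sqrt(apply(dx * dx + dy * dy, 1L, min))
}

apply_thinning <- function(cand, thin_specs) {
  keep <- rep(TRUE, nrow(cand))
  for (ts in thin_specs) {
    md <- min_dist_to(cand, ts$points)
    inside <- md <= ts$radius
    keep <- keep & (!inside | stats::runif(nrow(cand)) < ts$retention)
  }
  cand[keep, , drop = FALSE]
}

# core generator for one species; thin_specs: list of (points, radius,
# retention); shared_parents: matrix of parent points to reuse, or NULL
generate_species_points <- function(spec, window, thin_specs = list(),
                                    shared = NULL) {
  buffer <- if (spec$process == "thomas") 4 * spec$sigma else 0
  bufwin <- window_rect(window$xmin - buffer, window$xmax + buffer,
                        window$ymin - buffer, window$ymax + buffer)
  parents <- NULL
  if (spec$process == "thomas") {
    n_par <- stats::rpois(1L, spec$kappa * window_area(bufwin))
    n_shared <- if (is.null(shared)) 0L else min(round(shared$fraction * n_par),
                                                 nrow(shared$parents))
    fresh <- n_par - n_shared
    par_fresh <- if (fresh > 0) {
      if (any(spec$gradient != 0)) {
        sample_gradient_points(fresh, bufwin, spec$gradient)
      } else {
        cbind(stats::runif(fresh, bufwin$xmin, bufwin$xmax),
              stats::runif(fresh, bufwin$ymin, bufwin$ymax))
      }
    } else cbind(numeric(0), numeric(0))
    par_shared <- if (n_shared > 0) {
      shared$parents[sample.int(nrow(shared$parents), n_shared), , drop = FALSE]
    } else cbind(numeric(0), numeric(0))
    parents <- rbind(par_shared, par_fresh)
  }
  draw_batch <- function(m) {
    switch(spec$process,
      thomas = thomas_offspring(parents, spec$mu, spec$sigma, window),
      csr = cbind(stats::runif(m, window$xmin, window$xmax),
                  stats::runif(m, window$ymin, window$ymax)),
      inhomogeneous = sample_gradient_points(m, window, spec$gradient))
  }
  fixed_n <- !is.null(spec$n)
  if (spec$process == "thomas" && (spec$mu <= 0 || !nrow(parents))) {
    if (fixed_n && spec$n > 0L) {
      stop(sprintf("species '%s': no offspring can be generated (mu = 0 or no parents)",
                   spec$label), call. = FALSE)
    }
    return(list(points = cbind(numeric(0), numeric(0)), parents = parents))
  }
  if (!fixed_n) {
    pts <- apply_thinning(draw_batch(0L), thin_specs)
    return(list(points = pts, parents = parents))
  }
  target <- spec$n
  acc <- cbind(numeric(0), numeric(0))
  for (iter in seq_len(500L)) {
    if (nrow(acc) >= target) break
    batch <- draw_batch(max(target - nrow(acc), 16L))
    acc <- rbind(acc, apply_thinning(batch, thin_specs))
  }
  if (nrow(acc) < target) {
    stop(sprintf("species '%s': could not reach n = %d under the configured thinning",
                 spec$label, target), call. = FALSE)
  }
  list(points = acc[sample.int(nrow(acc), target), , drop = FALSE],
       parents = parents)
}

#' Simulate a Thomas cluster process
#'
#' Poisson(`kappa * A`) parent points, uniform (or gradient-weighted) over
#' the window extended by a 4-sigma guard buffer to avoid edge deficits;
#' each parent receives Poisson(`mu`) offspring displaced by an isotropic
#' Gaussian of standard deviation `sigma`; offspring are clipped to the
#' window. If the spec carries an abundance `n`, offspring rounds are drawn
#' from the same parent set until `n` points are available and exactly `n`
#' are kept. The process has the closed-form pair correlation function
#' `g(r) = 1 + exp(-r^2 / (4 sigma^2)) / (4 pi sigma^2 kappa)`.
#'
#' @param spec A [species_spec()] with `process = "thomas"`.
#' @param window A [window_rect()].
#' @param seed Optional integer seed.
#' @return A [marked_pattern()] (no dbh attached; see
#'   [generate_community()] for marked draws).
#' @export
generate_thomas <- function(spec, window = window_rect(), seed = NULL) {
  stopifnot(inherits(spec, "species_spec"))
  if (spec$process != "thomas") stop("spec must have process = 'thomas'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- generate_species_points(spec, window)
  marked_pattern(res$points[, 1L], res$points[, 2L],
                 species = if (nrow(res$points)) spec$label else character(0),
                 window = window)
}

#' Generate a multi-species community
#'
#' Draws every species of a [community_config()] in link (topological)
#' order: shared-parent links are honored when the target's Thomas parents
#' are drawn, thinning links are applied to the target's candidate points
#' against the already-generated source species, and each stem receives a
#' lognormal dbh floored at 1 cm (the usual census mapping threshold).
#' Returns one merged marked pattern.
#'
#' @param config A [community_config()].
#' @param seed Optional integer seed (falls back to `config$seed`).
#' @return A [marked_pattern()] with dbh marks.
#' @export
generate_community <- function(config, seed = NULL) {
  stopifnot(inherits(config, "community_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  labels <- vapply(config$species, `[[`, character(1), "label")
  specs <- stats::setNames(config$species, labels)
  gen_order <- order_species_labels(labels, config$links)
  pts <- list(); parents <- list()
  for (lab in gen_order) {
    spec <- specs[[lab]]
    thin_specs <- list(); shared <- NULL
    for (l in config$links) {
      if (l$to != lab) next
      if (l$mechanism == "thinning") {
        thin_specs <- c(thin_specs, list(list(points = pts[[l$from]],
                                              radius = l$radius,
                                              retention = l$retention)))
      } else {
        src_par <- parents[[l$from]]
        if (is.null(src_par) || !nrow(src_par)) {
          stop(sprintf("shared-parents link %s -> %s: source has no parent points",
                       l$from, l$to), call. = FALSE)
        }
        shared <- list(parents = src_par, fraction = l$fraction)
      }
    }
    res <- generate_species_points(spec, config$window, thin_specs, shared)
    pts[[lab]] <- res$points
    parents[[lab]] <- res$parents
  }
  parts <- lapply(labels, function(lab) {
    p <- pts[[lab]]
    spec <- specs[[lab]]
    m <- nrow(p)
    # emulates a census with a 1 cm dbh threshold
    dbh <- pmax(1, stats::rlnorm(m, spec$dbh_meanlog, spec$dbh_sdlog))
    marked_pattern(p[, 1L], p[, 2L],
                   species = if (m) spec$label else character(0),
                   window = config$window, dbh = dbh)
  })
  if (!length(parts)) {
    return(marked_pattern(numeric(0), numeric(0), character(0),
                          config$window, dbh = numeric(0)))
  }
  merge_patterns(parts)
}

# fixture constants: two emulated 1-hm^2 plots. Parameter values are package
# constants chosen so the qualitative contrasts (positive congener
# association in the two-congener plot, negative associations among the
# thinned congener pairs in the three-congener plot) are robust across
# seeds; they are an emulation, not estimates from any census.
plot1_config <- function() {
  het_n <- c(80, 66, 55, 47, 40, 35, 31, 27, 24, 20)
  hets <- lapply(seq_along(het_n), function(i) {
    species_spec(sprintf("SP%02d", i), "thomas", n = het_n[i],
                 kappa = 0.002, sigma = 3, mu = 4,
                 dbh_meanlog = log(6), dbh_sdlog = 0.6)
  })
  het_links <- unlist(lapply(seq_along(het_n), function(i) {
    list(association_link("QS", sprintf("SP%02d", i), "thinning",
                          radius = 4, retention = 0.3),
         association_link("QV", sprintf("SP%02d", i), "thinning",
                          radius = 4, retention = 0.3))
  }), recursive = FALSE)
  community_config(
    window = window_rect(0, 100, 0, 100),
    species = c(list(
      species_spec("QS", "thomas", n = 543, kappa = 0.005, sigma = 2.5,
                   mu = 11, gradient = c(0.02, 0),
                   dbh_meanlog = log(15), dbh_sdlog = 0.6),
      species_spec("QV", "thomas", n = 214, kappa = 0.005, sigma = 2.5,
                   mu = 5, gradient = c(0.02, 0),
                   dbh_meanlog = log(18), dbh_sdlog = 0.6)),
      hets),
    links = c(list(
      association_link("QS", "QV", "shared_parents", fraction = 0.75)),
      het_links)
  )
}

plot2_config <- function() {
  het_n <- c(75, 62, 52, 45, 39, 34, 30, 26, 23, 20)
  hets <- lapply(seq_along(het_n), function(i) {
    species_spec(sprintf("SP%02d", i), "thomas", n = het_n[i],
                 kappa = 0.002, sigma = 3, mu = 4,
                 dbh_meanlog = log(6), dbh_sdlog = 0.6)
  })
  het_links <- lapply(seq_along(het_n), function(i) {
    association_link(c("QS", "QV", "QA")[1L + (i %% 3L)],
                     sprintf("SP%02d", i), "thinning",
                     radius = 3, retention = 0.5)
  })
  community_config(
    window = window_rect(0, 100, 0, 100),
    species = c(list(
      species_spec("QS", "thomas", n = 340, kappa = 0.005, sigma = 2.5,
                   mu = 7, gradient = c(0.02, 0),
                   dbh_meanlog = log(16), dbh_sdlog = 0.6),
      species_spec("QV", "thomas", n = 169, kappa = 0.004, sigma = 2.5,
                   mu = 5, gradient = c(-0.02, 0),
                   dbh_meanlog = log(18), dbh_sdlog = 0.6),
      species_spec("QA", "thomas", n = 170, kappa = 0.004, sigma = 2.5,
                   mu = 5, gradient = c(0, 0.02),
                   dbh_meanlog = log(17), dbh_sdlog = 0.6)),
      hets),
    links = c(list(
      association_link("QS", "QV", "thinning", radius = 5, retention = 0.15),
      association_link("QS", "QA", "thinning", radius = 5, retention = 0.15)),
      het_links)
  )
}

#' Named synthetic plot fixtures
#'
#' Two reproducible synthetic stem maps emulating the structure of a
#' two-congener and a three-congener 100 m x 100 m study plot.
#' `"plot1_like"`: congeners QS (n = 543) and QV (n = 214), Thomas
#' clustering on a shared habitat gradient with a shared-parents positive
#' link, plus 10 rarer heterospecifics (n = 20-80) thinned around both
#' congeners. `"plot2_like"`: congeners QS (n = 340), QV (n = 169) and
#' QA (n = 170) with divergent gradients, QV and QA thinned around QS
#' (negative links), plus 10 heterospecifics with weaker thinning links.
#' Counts are exact (fixed-n generation); the same name and seed always
#' yield the identical pattern.
#'
#' @param name `"plot1_like"` or `"plot2_like"`.
#' @param seed Integer seed.
#' @return A [marked_pattern()] with dbh marks.
#' @export
generate_fixture <- function(name = c("plot1_like", "plot2_like"), seed = 1L) {
  name <- match.arg(name)
  config <- switch(name, plot1_like = plot1_config(), plot2_like = plot2_config())
  generate_community(config, seed = seed)
}

#' Read and write community configurations
#'
#' Round-trip a [community_config()] through a structured YAML file.
#'
#' @param config A `"community_config"`.
#' @param path File path.
#' @export
write_community_config <- function(config, path) {
  stopifnot(inherits(config, "community_config"))
  obj <- list(
    window = unclass(config$window),
    seed = config$seed,
    species = lapply(config$species, function(s) unclass(s)),
    links = lapply(config$links, function(l) unclass(l))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_community_config
#' @return `read_community_config()`: a `"community_config"`.
#' @export
read_community_config <- function(path) {
  obj <- yaml::read_yaml(path)
  win <- do.call(window_rect, obj$window[c("xmin", "xmax", "ymin", "ymax")])
  species <- lapply(obj$species, function(s) {
    species_spec(s$label, s$process, n = s$n, kappa = s$kappa,
                 sigma = s$sigma, mu = s$mu,
                 gradient = if (is.null(s$gradient)) c(0, 0) else unlist(s$gradient),
                 dbh_meanlog = s$dbh_meanlog, dbh_sdlog = s$dbh_sdlog)
  })
  links <- lapply(obj$links, function(l) {
    association_link(l$from, l$to, l$mechanism, fraction = l$fraction,
                     radius = l$radius, retention = l$retention)
  })
  community_config(win, species, links, seed = obj$seed)
}
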