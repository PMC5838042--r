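#' Neighborhood richness around focal species
#'
#' Individual-based neighborhood analysis: for every stem in the community,
#' the neighbors within `radius` meters (the focal stem excluded) are
#' counted, both as distinct species and as individuals. These per-stem
#' values are averaged per focal species and paired with the species'
#' total basal area. No edge correction is applied; focal stems closer to
#' the plot boundary than the radius are included and their count is
#' reported in the `n_edge` column.
#'
#' @param community A [marked_pattern()] with dbh present for every stem.
#' @param radius Neighborhood radius, meters (default 5).
#' @return A data frame of class `"neighborhood_summary"` with one row per
#'   species: `species`, `n` (focal stems), `basal_area` (total, m^2),
#'   `mean_neighbor_species`, `mean_neighbor_individuals`, `n_edge`.
#' @export
neighborhood_stats <- function(community, radius = 5) {
  stopifnot(inherits(community, "marked_pattern"))
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  n <- npoints(community)
  if (n < 1L) stop("community pattern is empty", call. = FALSE)
  if (is.null(community$dbh) || anyNA(community$dbh)) {
    missing <- if (is.null(community$dbh)) seq_len(n) else which(is.na(community$dbh))
    stop(sprintf("dbh missing for stems: %s",
                 paste(utils::head(missing, 20L), collapse = ", ")),
         call. = FALSE)
  }
  x <- community$x; y <- community$y; sp <- community$species
  neigh_sp <- integer(n); neigh_ind <- integer(n)
  for (i in seq_len(n)) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    nb <- which(d2 <= radius^2)
    nb <- nb[nb != i]
    neigh_ind[i] <- length(nb)
    neigh_sp[i] <- length(unique(sp[nb]))
  }
  win <- community$window
  edge <- pmin(x - win$xmin, win$xmax - x, y - win$ymin, win$ymax - y) < radius
  ba <- basal_area(community$dbh)
  species <- sort(unique(sp))
  out <- data.frame(
    species = species,
    n = vapply(species, function(s) sum(sp == s), integer(1)),
    basal_area = vapply(species, function(s) sum(ba[sp == s]), numeric(1)),
    mean_neighbor_species = vapply(species, function(s) mean(neigh_sp[sp == s]), numeric(1)),
    mean_neighbor_individuals = vapply(species, function(s) mean(neigh_ind[sp == s]), numeric(1)),
    n_edge = vapply(species, function(s) sum(edge[sp == s]), integer(1)),
    row.names = NULL
  )
  class(out) <- c("neighborhood_summary", "data.frame")
  out
}

#' Regression of neighborhood richness on focal basal area
#'
#' Ordinary least squares of a per-species neighborhood response (mean
#' neighbor species count or mean neighbor individual count) on the
#' species' total basal area, with the Pearson correlation coefficient and
#' its two-sided p-value. Species are the observational units. A constant
#' response has zero slope and the correlation is reported as 0 with a
#' warning (its usual definition degenerates).
#'
#' @param summaries A [neighborhood_stats()] table (or any data frame with
#'   `basal_area` and the response column), at least 3 rows.
#' @param response `"species"` (mean neighbor species count) or
#'   `"individuals"` (mean neighbor individual count).
#' @return Object of class `"focal_regression"`: list with `slope`,
#'   `intercept`, `r` (Pearson), `p` (two-sided), `n`, `response`.
#' @export
fit_focal_regression <- function(summaries, response = c("species", "individuals")) {
  response <- match.arg(response)
  col <- switch(response, species = "mean_neighbor_species",
                individuals = "mean_neighbor_individuals")
  stopifnot(is.data.frame(summaries), all(c("basal_area", col) %in% names(summaries)))
  xv <- summaries$basal_area
  yv <- summaries[[col]]
  n <- length(xv)
  if (n < 3L) stop("at least 3 species points are required", call. = FALSE)
  if (stats::sd(xv) == 0) stop("basal area is constant across species", call. = FALSE)
  if (stats::sd(yv) == 0) {
    warning("constant response: correlation undefined, reported as 0", call. = FALSE)
    fit <- stats::lm(yv ~ xv)
    res <- list(slope = 0, intercept = unname(stats::coef(fit)[1L]), r = 0,
                p = 1, n = n, response = response)
  } else {
    fit <- stats::lm(yv ~ xv)
    ct <- stats::cor.test(xv, yv, method = "pearson")
    res <- list(slope = unname(stats::coef(fit)[2L]),
                intercept = unname(stats::coef(fit)[1L]),
                r = unname(ct$estimate), p = ct$p.value, n = n,
                response = response)
  }
  structure(res, class = "focal_regression")
}

#' @export
print.focal_regression <- function(x, ...) {
  cat(sprintf(
    "neighborhood %s ~ basal area: slope %.4g, Pearson r = %.3f, p = %.3g (n = %d species)\n",
    x$response, x$slope, x$r, x$p, x$n))
  invisible(x)
}

#' Basal-area Shannon and Simpson diversity
#'
#' Species diversity of a quadrat weighted by basal area: with `p_i` the
#' share of species i in the total basal area of the quadrat,
#' Shannon `H = -sum(p_i * log(p_i))` (natural log, nats) and
#' Simpson `D = 1 - sum(p_i^2)`. The quadrat defaults to the whole plot.
#' Both indices are invariant to relabeling species and to rescaling all
#' dbh by a common factor.
#'
#' @param community A [marked_pattern()] with dbh for every stem.
#' @param quadrat A [window_rect()] contained in the community window;
#'   default the whole window. Must contain at least one stem.
#' @return Object of class `"diversity_result"`: list with `H`, `D`,
#'   `p` (named shares), `n_species`, `quadrat`.
#' @export
diversity_indices <- function(community, quadrat = NULL) {
  stopifnot(inherits(community, "marked_pattern"))
  if (is.null(community$dbh) || anyNA(community$dbh)) {
    stop("dbh is required for basal-area diversity", call. = FALSE)
  }
  win <- community$window
  if (is.null(quadrat)) quadrat <- win
  stopifnot(inherits(quadrat, "ppwindow"))
  if (quadrat$xmin < win$xmin - 1e-9 || quadrat$xmax > win$xmax + 1e-9 ||
      quadrat$ymin < win$ymin - 1e-9 || quadrat$ymax > win$ymax + 1e-9) {
    stop("quadrat must lie inside the community window", call. = FALSE)
  }
  inq <- points_inside(community$x, community$y, quadrat)
  if (!any(inq)) stop("quadrat contains no stems", call. = FALSE)
  ba <- tapply(basal_area(community$dbh[inq]), community$species[inq], sum)
  p <- as.numeric(ba) / sum(ba)
  names(p) <- names(ba)
  H <- -sum(p * log(p))
  D <- 1 - sum(p^2)
  structure(list(H = H, D = D, p = p, n_species = length(p), quadrat = quadrat),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("basal-area diversity over %d species: Shannon H = %.3f nats, Simpson D = %.3f\n",
              x$n_species, x$H, x$D))
  invisible(x)
}
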