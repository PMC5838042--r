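#' Analysis configuration
#'
#' Settings for the full three-part workflow over one stem map: the
#' congener roster (the focal species compared against each other), the
#' heterospecific roster (defaults to the 10 most abundant non-congener
#' species in the data), the distance grid, kernel bandwidths, simulation
#' count, significance level, seed and the neighborhood radius.
#'
#' @param congeners Character vector of at least 2 focal species labels.
#' @param heterospecifics Character vector of non-congener labels, or
#'   `NULL` to pick the 10 most abundant at run time.
#' @param rgrid Distance grid for all functional statistics.
#' @param pcf_bandwidth Kernel half-width for pcf estimates; `NULL` for
#'   Stoyan's rule per statistic.
#' @param intensity_bandwidth Gaussian bandwidth of heterogeneous Poisson
#'   intensity surfaces, meters.
#' @param s Simulations per envelope (default 199, giving approximately
#'   99% min/max envelopes).
#' @param alpha Significance level for association calls.
#' @param seed Integer seed; the whole pipeline is deterministic given it.
#' @param radius Neighborhood radius, meters.
#' @param gof_interval Optional scale range for goodness-of-fit tests;
#'   default the full positive grid.
#' @return Object of class `"analysis_config"`.
#' @export
analysis_config <- function(congeners, heterospecifics = NULL,
                            rgrid = default_rgrid(), pcf_bandwidth = NULL,
                            intensity_bandwidth = 20, s = 199, alpha = 0.05,
                            seed = 1L, radius = 5, gof_interval = NULL) {
  congeners <- as.character(congeners)
  if (length(congeners) < 2L) {
    stop("at least 2 congener species are required", call. = FALSE)
  }
  if (s < 1) stop("s must be >= 1", call. = FALSE)
  validate_rgrid(rgrid)
  structure(list(congeners = congeners, heterospecifics = heterospecifics,
                 rgrid = rgrid, pcf_bandwidth = pcf_bandwidth,
                 intensity_bandwidth = intensity_bandwidth, s = as.integer(s),
                 alpha = alpha, seed = as.integer(seed), radius = radius,
                 gof_interval = gof_interval),
            class = "analysis_config")
}

sign_code <- function(call) switch(call$sign, negative = "-", positive = "+", "r")

#' Run the full analysis workflow
#'
#' Executes, on one stem map: (1) per-congener spatial patterns — pcf
#' envelopes under CSR and under a heterogeneous Poisson null, plus
#' case-control random-labeling similarity of every congener pair in both
#' orderings; (2) interspecific associations — cross-pcf envelopes under HP
#' randomization for every congener pair and every congener-heterospecific
#' pair in both directions, plus shared-heterospecific difference
#' statistics for every congener pair and heterospecific in both
#' directions; (3) neighborhood richness regressions and basal-area
#' diversity. Species with too few stems for a stage are skipped with a
#' logged reason, never silently dropped. The run is deterministic given
#' the config seed.
#'
#' @param pattern A [marked_pattern()] with dbh marks.
#' @param config An [analysis_config()].
#' @return Object of class `"report_bundle"`: list of result tables (see
#'   [export_tables()]), envelope objects, a run log and provenance.
#' @export
run_pipeline <- function(pattern, config) {
  stopifnot(inherits(pattern, "marked_pattern"),
            inherits(config, "analysis_config"))
  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]
  log <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("[%7.1fs] %s", proc.time()[["elapsed"]] - t0,
                    sprintf(fmt, ...))
    log <<- c(log, line)
    invisible(line)
  }
  counts <- table(pattern$species)
  missing <- setdiff(config$congeners, names(counts))
  if (length(missing)) {
    stop(sprintf("congener species absent from the stem map: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  hets <- config$heterospecifics
  if (is.null(hets)) {
    non <- counts[setdiff(names(counts), config$congeners)]
    hets <- names(sort(non, decreasing = TRUE))[seq_len(min(10L, length(non)))]
    note("heterospecific roster (10 most abundant): %s", paste(hets, collapse = " "))
  } else {
    absent <- setdiff(hets, names(counts))
    if (length(absent)) {
      stop(sprintf("heterospecific species absent: %s",
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
  }
  note("stem map: %d stems, %d species; congeners: %s; s = %d; seed = %d",
       npoints(pattern), length(counts), paste(config$congeners, collapse = " "),
       config$s, config$seed)
  rg <- config$rgrid
  interval <- config$gof_interval
  usable <- function(sp, need) counts[[sp]] >= need
  skips <- data.frame(stage = character(0), species = character(0),
                      reason = character(0))
  skip <- function(stage, sp, reason) {
    skips <<- rbind(skips, data.frame(stage = stage, species = sp,
                                      reason = reason))
    note("skip [%s] %s: %s", stage, sp, reason)
  }

  ## Analysis 1a: spatial pattern of each congener under CSR and HP
  pattern_envs <- list()
  pattern_rows <- list()
  for (sp in config$congeners) {
    if (!usable(sp, 2L)) { skip("pattern", sp, "fewer than 2 stems"); next }
    sub <- subset_species(pattern, sp)
    for (null in c("csr", "hp")) {
      env <- pattern_envelope(sub, null, rg, config$pcf_bandwidth,
                              config$intensity_bandwidth, s = config$s)
      gof <- gof_test(env, interval = interval)
      call <- classify_association(env, gof, config$alpha)
      pattern_envs[[paste(sp, null, sep = ".")]] <- env
      pattern_rows[[paste(sp, null)]] <- data.frame(
        species = sp, null = toupper(null), n = counts[[sp]],
        u0 = gof$u0, rank = gof$rank, p = gof$p,
        call = switch(call$sign, positive = "aggregated",
                      negative = "regular", "random"))
    }
    note("pattern envelopes done for %s", sp)
  }

  ## Analysis 1b: case-control similarity, both orderings per congener pair
  sim_rows <- list(); sim_envs <- list()
  pairs <- utils::combn(config$congeners, 2L, simplify = FALSE)
  for (pr in pairs) {
    if (!usable(pr[1L], 2L) || !usable(pr[2L], 2L)) {
      skip("similarity", paste(pr, collapse = "-"), "a label has fewer than 2 stems")
      next
    }
    jp <- joint_pattern(pattern, pr[1L], pr[2L])
    for (ord in list(pr, rev(pr))) {
      env <- diff_case_control(jp, control = ord[1L], case = ord[2L],
                               rgrid = rg, bandwidth = config$pcf_bandwidth,
                               s = config$s)
      gof <- gof_test(env, interval = interval)
      call <- classify_association(env, gof, config$alpha)
      key <- sprintf("%s_as_control.%s_as_case", ord[1L], ord[2L])
      sim_envs[[key]] <- env
      sim_rows[[key]] <- data.frame(control = ord[1L], case = ord[2L],
                                    u0 = gof$u0, rank = gof$rank, p = gof$p,
                                    different = gof$p <= config$alpha,
                                    sign = sign_code(call))
    }
    note("similarity done for pair %s", paste(pr, collapse = "-"))
  }

  ## Analysis 2a: HP associations between congeners (both directions)
  cc_rows <- list(); assoc_envs <- list()
  assoc_one <- function(from, to) {
    env <- hp_association(subset_species(pattern, from),
                          subset_species(pattern, to), rg,
                          config$pcf_bandwidth, config$intensity_bandwidth,
                          s = config$s)
    gof <- gof_test(env, interval = interval)
    call <- classify_association(env, gof, config$alpha)
    list(env = env, row = data.frame(from = from, to = to,
                                     sign = sign_code(call), p = gof$p,
                                     rank = gof$rank))
  }
  for (pr in pairs) {
    for (ord in list(pr, rev(pr))) {
      if (!usable(ord[1L], 1L) || !usable(ord[2L], 2L)) {
        skip("association", paste(ord, collapse = "->"), "too few stems")
        next
      }
      res <- assoc_one(ord[1L], ord[2L])
      key <- paste(ord, collapse = "_to_")
      assoc_envs[[key]] <- res$env
      cc_rows[[key]] <- res$row
    }
  }
  note("congener-congener associations done")

  ## Analysis 2b: HP associations congener <-> heterospecific, both directions
  het_rows <- list()
  for (het in hets) {
    for (cg in config$congeners) {
      for (dir in c("congener_to_het", "het_to_congener")) {
        from <- if (dir == "congener_to_het") cg else het
        to <- if (dir == "congener_to_het") het else cg
        if (!usable(from, 1L) || !usable(to, 2L)) {
          skip("association", paste(from, to, sep = "->"), "too few stems")
          next
        }
        res <- assoc_one(from, to)
        het_rows[[paste(het, cg, dir)]] <- cbind(
          data.frame(heterospecific = het, congener = cg, direction = dir),
          res$row[c("sign", "p", "rank")])
      }
    }
    note("heterospecific associations done for %s", het)
  }

  ## Analysis 2c: shared-heterospecific differences per congener pair
  diff_rows <- list()
  for (pr in pairs) {
    if (!usable(pr[1L], 2L) || !usable(pr[2L], 2L)) {
      skip("difference", paste(pr, collapse = "-"), "a congener has fewer than 2 stems")
      next
    }
    jp <- joint_pattern(pattern, pr[1L], pr[2L])
    for (het in hets) {
      if (!usable(het, 1L)) { skip("difference", het, "no stems"); next }
      third <- subset_species(pattern, het)
      for (dir in c("congener_to_third", "third_to_congener")) {
        env <- diff_shared_species(jp, third, dir, rg,
                                   config$pcf_bandwidth, s = config$s)
        gof <- gof_test(env, interval = interval)
        diff_rows[[paste(pr[1L], pr[2L], het, dir)]] <- data.frame(
          pair = paste(pr, collapse = "-"), heterospecific = het,
          direction = dir, u0 = gof$u0, rank = gof$rank, p = gof$p,
          different = gof$p <= config$alpha)
      }
    }
    note("shared-heterospecific differences done for pair %s",
         paste(pr, collapse = "-"))
  }

  ## Analysis 3: neighborhood richness and diversity
  neighborhood <- NULL; fits <- NULL; diversity <- NULL
  if (is.null(pattern$dbh)) {
    skip("neighborhood", "all", "dbh marks absent")
  } else {
    neighborhood <- neighborhood_stats(pattern, radius = config$radius)
    fit_sp <- fit_focal_regression(neighborhood, "species")
    fit_ind <- fit_focal_regression(neighborhood, "individuals")
    fits <- data.frame(
      response = c("species", "individuals"),
      slope = c(fit_sp$slope, fit_ind$slope),
      intercept = c(fit_sp$intercept, fit_ind$intercept),
      pearson_r = c(fit_sp$r, fit_ind$r),
      p = c(fit_sp$p, fit_ind$p),
      n_species = c(fit_sp$n, fit_ind$n))
    div <- diversity_indices(pattern)
    diversity <- data.frame(shannon_H = div$H, simpson_D = div$D,
                            n_species = div$n_species, basis = "basal-area")
    note("neighborhood and diversity done (H = %.3f, D = %.3f)", div$H, div$D)
  }

  bind_or_empty <- function(lst, proto) {
    if (length(lst)) do.call(rbind, c(lst, list(make.row.names = FALSE))) else proto
  }
  structure(list(
    spatial_patterns = bind_or_empty(pattern_rows, data.frame(
      species = character(0), null = character(0), n = integer(0),
      u0 = numeric(0), rank = integer(0), p = numeric(0), call = character(0))),
    similarity = bind_or_empty(sim_rows, data.frame(
      control = character(0), case = character(0), u0 = numeric(0),
      rank = integer(0), p = numeric(0), different = logical(0),
      sign = character(0))),
    congener_associations = bind_or_empty(cc_rows, data.frame(
      from = character(0), to = character(0), sign = character(0),
      p = numeric(0), rank = integer(0))),
    het_associations = bind_or_empty(het_rows, data.frame(
      heterospecific = character(0), congener = character(0),
      direction = character(0), sign = character(0), p = numeric(0),
      rank = integer(0))),
    differences = bind_or_empty(diff_rows, data.frame(
      pair = character(0), heterospecific = character(0),
      direction = character(0), u0 = numeric(0), rank = integer(0),
      p = numeric(0), different = logical(0))),
    neighborhood = neighborhood, fits = fits, diversity = diversity,
    pattern_envelopes = pattern_envs, similarity_envelopes = sim_envs,
    association_envelopes = assoc_envs,
    skips = skips, log = log,
    provenance = list(seed = config$seed, s = config$s, alpha = config$alpha,
                      rgrid = range(rg), congeners = config$congeners,
                      heterospecifics = hets, n_stems = npoints(pattern),
                      package_version = as.character(utils::packageVersion("stemspat")))),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("analysis report bundle\n")
  cat(sprintf("  spatial patterns: %d rows | similarity: %d | associations: %d + %d | differences: %d\n",
              nrow(x$spatial_patterns), nrow(x$similarity),
              nrow(x$congener_associations), nrow(x$het_associations),
              nrow(x$differences)))
  if (!is.null(x$diversity)) {
    cat(sprintf("  diversity: H = %.3f, D = %.3f over %d species\n",
                x$diversity$shannon_H, x$diversity$simpson_D,
                x$diversity$n_species))
  }
  if (nrow(x$skips)) cat(sprintf("  %d comparisons skipped (see $skips)\n", nrow(x$skips)))
  invisible(x)
}

# wide association matrix in the layout of the published association
# tables: one row per heterospecific, sign + p per congener per direction
association_matrix <- function(het_associations, congeners) {
  hets <- unique(het_associations$heterospecific)
  out <- data.frame(heterospecific = hets, stringsAsFactors = FALSE)
  for (dir in c("congener_to_het", "het_to_congener")) {
    for (cg in congeners) {
      sel <- het_associations$direction == dir & het_associations$congener == cg
      m <- het_associations[sel, ]
      idx <- match(hets, m$heterospecific)
      prefix <- if (dir == "congener_to_het") "influence_of" else "influence_on"
      out[[sprintf("%s_%s_sign", prefix, cg)]] <- m$sign[idx]
      out[[sprintf("%s_%s_p", prefix, cg)]] <- m$p[idx]
    }
  }
  out
}

# wide difference matrix: rows heterospecifics, columns pair x direction
difference_matrix <- function(differences) {
  hets <- unique(differences$heterospecific)
  out <- data.frame(heterospecific = hets, stringsAsFactors = FALSE)
  for (pr in unique(differences$pair)) {
    for (dir in unique(differences$direction)) {
      sel <- differences$pair == pr & differences$direction == dir
      m <- differences[sel, ]
      idx <- match(hets, m$heterospecific)
      col <- sprintf("%s.%s_p", gsub("-", "_", pr),
                     if (dir == "congener_to_third") "to_het" else "from_het")
      out[[col]] <- m$p[idx]
    }
  }
  out
}

#' Export a report bundle as tidy CSV tables
#'
#' Writes the bundle's tables under `outdir`: spatial-pattern calls,
#' similarity results, association calls in long form and as a wide matrix
#' (rows = heterospecifics, sign and p per congener and direction),
#' shared-heterospecific difference results in long form and as a wide
#' p-value matrix (rows = heterospecifics, columns = congener pair and
#' direction), envelope curves, neighborhood and diversity tables, the
#' skip table and a plain-text run log.
#'
#' @param bundle A `"report_bundle"`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
export_tables <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory", call. = FALSE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  put(bundle$spatial_patterns, "spatial_patterns.csv")
  put(bundle$similarity, "similarity.csv")
  put(bundle$congener_associations, "congener_associations.csv")
  put(bundle$het_associations, "het_associations.csv")
  put(association_matrix(bundle$het_associations,
                         bundle$provenance$congeners),
      "association_matrix.csv")
  put(bundle$differences, "differences.csv")
  put(difference_matrix(bundle$differences), "difference_matrix.csv")
  env_tab <- do.call(rbind, c(lapply(names(bundle$pattern_envelopes), function(k) {
    cbind(comparison = k, as_envelope_table(bundle$pattern_envelopes[[k]]))
  }), lapply(names(bundle$similarity_envelopes), function(k) {
    cbind(comparison = k, as_envelope_table(bundle$similarity_envelopes[[k]]))
  })))
  if (!is.null(env_tab)) put(env_tab, "envelope_curves.csv")
  if (!is.null(bundle$neighborhood)) put(bundle$neighborhood, "neighborhood.csv")
  if (!is.null(bundle$fits)) put(bundle$fits, "neighborhood_fits.csv")
  if (!is.null(bundle$diversity)) put(bundle$diversity, "diversity.csv")
  put(bundle$skips, "skipped_comparisons.csv")
  writeLines(bundle$log, file.path(outdir, "run_log.txt"))
  files <- c(files, file.path(outdir, "run_log.txt"))
  invisible(files)
}
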