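#' Rectangular observation window
#'
#' Axis-aligned rectangle in which a stem map was recorded. Coordinates are
#' continuous, in meters, with the origin conventionally at the lower-left
#' corner of the plot.
#'
#' @param xmin,xmax,ymin,ymax Window limits in meters; `xmax > xmin` and
#'   `ymax > ymin` are required.
#' @return An object of class `"ppwindow"`: a list with fields `xmin`,
#'   `xmax`, `ymin`, `ymax`.
#' @examples
#' win <- window_rect(0, 100, 0, 100)
#' window_area(win)  # 10000 m^2
#' @export
window_rect <- function(xmin = 0, xmax = 100, ymin = 0, ymax = 100) {
  stopifnot(is.numeric(xmin), is.numeric(xmax), is.numeric(ymin), is.numeric(ymax))
  if (!(xmax > xmin) || !(ymax > ymin)) {
    stop("invalid window: require xmax > xmin and ymax > ymin", call. = FALSE)
  }
  structure(
    list(xmin = as.numeric(xmin), xmax = as.numeric(xmax),
         ymin = as.numeric(ymin), ymax = as.numeric(ymax)),
    class = "ppwindow"
  )
}

#' @rdname window_rect
#' @param window A `"ppwindow"` object.
#' @export
window_area <- function(window) {
  stopifnot(inherits(window, "ppwindow"))
  (window$xmax - window$xmin) * (window$ymax - window$ymin)
}

#' @export
print.ppwindow <- function(x, ...) {
  cat(sprintf("rectangular window [%g, %g] x [%g, %g] m, area %g m^2\n",
              x$xmin, x$xmax, x$ymin, x$ymax, window_area(x)))
  invisible(x)
}

window_equal <- function(a, b, tol = 1e-9) {
  all(abs(c(a$xmin - b$xmin, a$xmax - b$xmax,
            a$ymin - b$ymin, a$ymax - b$ymax)) <= tol)
}

points_inside <- function(x, y, window, tol = 1e-9) {
  x >= window$xmin - tol & x <= window$xmax + tol &
    y >= window$ymin - tol & y <= window$ymax + tol
}

#' Marked point pattern of mapped stems
#'
#' A stem map: point locations inside a rectangular window, with a species
#' label per stem and optionally a diameter at breast height (dbh, cm) and a
#' living/dead status flag. This is the universal input of every analysis in
#' the package.
#'
#' Stems with dbh below 1 cm trigger a warning (typical census threshold),
#' not an error, so that synthetic communities need not honor it. Points on
#' the window boundary are accepted.
#'
#' @param x,y Numeric coordinate vectors, meters.
#' @param species Character vector of species labels, recycled if length 1.
#' @param window A [window_rect()] object containing every point.
#' @param dbh Optional numeric vector of diameters at breast height, cm.
#' @param status Optional character vector, values `"living"` or `"dead"`.
#' @return An object of class `"marked_pattern"`.
#' @examples
#' p <- marked_pattern(c(10, 20), c(30, 40), c("QS", "QV"), window_rect())
#' npoints(p)
#' @export
marked_pattern <- function(x, y, species = "sp1", window = window_rect(),
                           dbh = NULL, status = NULL) {
  stopifnot(inherits(window, "ppwindow"))
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  if (length(species) == 1L) species <- rep(as.character(species), n)
  species <- as.character(species)
  if (length(species) != n) stop("species length must match point count", call. = FALSE)
  if (!is.null(dbh)) {
    dbh <- as.numeric(dbh)
    if (length(dbh) != n) stop("dbh length must match point count", call. = FALSE)
    if (any(is.finite(dbh) & dbh <= 0)) stop("dbh must be positive", call. = FALSE)
    if (any(is.finite(dbh) & dbh < 1)) {
      warning("some stems have dbh < 1 cm (below the usual census threshold)",
              call. = FALSE)
    }
  }
  if (!is.null(status)) {
    status <- as.character(status)
    if (length(status) == 1L) status <- rep(status, n)
    if (length(status) != n) stop("status length must match point count", call. = FALSE)
    bad <- !status %in% c("living", "dead")
    if (any(bad)) stop("status values must be 'living' or 'dead'", call. = FALSE)
  }
  inside <- points_inside(x, y, window)
  if (any(!inside)) {
    stop(sprintf("points outside the window at rows: %s",
                 paste(which(!inside), collapse = ", ")), call. = FALSE)
  }
  structure(
    list(x = x, y = y, species = species, dbh = dbh, status = status,
         window = window),
    class = "marked_pattern"
  )
}

#' @rdname marked_pattern
#' @param pattern A `"marked_pattern"` object.
#' @export
npoints <- function(pattern) {
  stopifnot(inherits(pattern, "marked_pattern"))
  length(pattern$x)
}

#' @export
print.marked_pattern <- function(x, ...) {
  tab <- sort(table(x$species), decreasing = TRUE)
  cat(sprintf("marked point pattern: %d stems, %d species\n",
              length(x$x), length(tab)))
  print(x$window)
  if (length(tab)) {
    head_tab <- utils::head(tab, 8L)
    cat("  ", paste(sprintf("%s=%d", names(head_tab), head_tab), collapse = " "),
        if (length(tab) > 8L) "..." else "", "\n")
  }
  invisible(x)
}

#' Subset and combine marked patterns
#'
#' `subset_species()` keeps the stems of the given species (same window);
#' `subset_status()` keeps stems with the given status flag;
#' `merge_patterns()` concatenates patterns sharing one window. Subsetting a
#' pattern by species and re-merging the pieces preserves stem count and
#' total basal area exactly.
#'
#' @param pattern A [marked_pattern()].
#' @param species Character vector of labels to keep.
#' @return A `"marked_pattern"`.
#' @export
subset_species <- function(pattern, species) {
  stopifnot(inherits(pattern, "marked_pattern"))
  keep <- pattern$species %in% species
  subset_index(pattern, keep)
}

#' @rdname subset_species
#' @param status `"living"` or `"dead"`.
#' @export
subset_status <- function(pattern, status) {
  stopifnot(inherits(pattern, "marked_pattern"))
  if (is.null(pattern$status)) stop("pattern has no status marks", call. = FALSE)
  subset_index(pattern, pattern$status %in% status)
}

subset_index <- function(pattern, keep) {
  structure(
    list(x = pattern$x[keep], y = pattern$y[keep],
         species = pattern$species[keep],
         dbh = if (is.null(pattern$dbh)) NULL else pattern$dbh[keep],
         status = if (is.null(pattern$status)) NULL else pattern$status[keep],
         window = pattern$window),
    class = "marked_pattern"
  )
}

#' @rdname subset_species
#' @param ... Two or more `"marked_pattern"` objects with identical windows.
#' @export
merge_patterns <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "marked_pattern")) {
    parts <- parts[[1]]
  }
  stopifnot(length(parts) >= 1L)
  lapply(parts, function(p) stopifnot(inherits(p, "marked_pattern")))
  win <- parts[[1]]$window
  for (p in parts) {
    if (!window_equal(win, p$window)) stop("window mismatch in merge", call. = FALSE)
  }
  has_dbh <- all(vapply(parts, function(p) !is.null(p$dbh), logical(1)))
  has_status <- all(vapply(parts, function(p) !is.null(p$status), logical(1)))
  structure(
    list(x = unlist(lapply(parts, `[[`, "x"), use.names = FALSE),
         y = unlist(lapply(parts, `[[`, "y"), use.names = FALSE),
         species = unlist(lapply(parts, `[[`, "species"), use.names = FALSE),
         dbh = if (has_dbh) unlist(lapply(parts, `[[`, "dbh"), use.names = FALSE) else NULL,
         status = if (has_status) unlist(lapply(parts, `[[`, "status"), use.names = FALSE) else NULL,
         window = win),
    class = "marked_pattern"
  )
}

#' Stem-table dialect
#'
#' Describes how a delimited stem table is laid out: the field delimiter and
#' the column names holding coordinates, species, dbh and status. `x`, `y`
#' and `species` columns are mandatory; coordinates are meters and dbh is cm.
#'
#' @param delimiter Single field-separator character.
#' @param x,y,species,dbh,status Column names in the file.
#' @return An object of class `"stem_dialect"`.
#' @export
stem_dialect <- function(delimiter = ",", x = "x", y = "y",
                         species = "species", dbh = "dbh", status = "status") {
  stopifnot(nchar(delimiter) == 1L)
  structure(list(delimiter = delimiter, x = x, y = y, species = species,
                 dbh = dbh, status = status),
            class = "stem_dialect")
}

#' Read a stem table
#'
#' Reads a delimited stem map into a [marked_pattern()]. Rows outside the
#' window are an error (listing the offending row numbers), never silently
#' dropped; non-numeric coordinates are reported with their row index.
#'
#' @param source Path or connection readable by [utils::read.table()].
#' @param dialect A [stem_dialect()].
#' @param window A [window_rect()] the stems must fall in.
#' @return A `"marked_pattern"`.
#' @export
read_stem_table <- function(source, dialect = stem_dialect(),
                            window = window_rect()) {
  stopifnot(inherits(dialect, "stem_dialect"), inherits(window, "ppwindow"))
  df <- utils::read.table(source, header = TRUE, sep = dialect$delimiter,
                          colClasses = "character", stringsAsFactors = FALSE,
                          check.names = FALSE)
  for (col in c(dialect$x, dialect$y, dialect$species)) {
    if (!col %in% names(df)) {
      stop(sprintf("stem table is missing mandatory column '%s'", col),
           call. = FALSE)
    }
  }
  n <- nrow(df)
  if (n == 0L) return(marked_pattern(numeric(0), numeric(0), character(0), window))
  parse_num <- function(col, what) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) & !(is.na(df[[col]]) | df[[col]] %in% c("", "NA"))
    if (any(bad)) {
      stop(sprintf("non-numeric %s in column '%s' at rows: %s", what, col,
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    }
    v
  }
  x <- parse_num(dialect$x, "coordinate")
  y <- parse_num(dialect$y, "coordinate")
  if (anyNA(x) || anyNA(y)) {
    stop(sprintf("missing coordinates at rows: %s",
                 paste(which(is.na(x) | is.na(y)), collapse = ", ")),
         call. = FALSE)
  }
  inside <- points_inside(x, y, window)
  if (any(!inside)) {
    stop(sprintf("stems outside the declared window at rows: %s",
                 paste(which(!inside), collapse = ", ")), call. = FALSE)
  }
  dbh <- if (dialect$dbh %in% names(df)) parse_num(dialect$dbh, "dbh") else NULL
  status <- if (dialect$status %in% names(df)) df[[dialect$status]] else NULL
  marked_pattern(x, y, df[[dialect$species]], window, dbh = dbh, status = status)
}

#' Write a stem table
#'
#' Serializes a [marked_pattern()] as delimited text; reading the result
#' back with the same dialect and window reproduces the pattern up to
#' 6-decimal coordinate formatting. Optional columns absent from the
#' pattern are omitted from the file.
#'
#' @param pattern A `"marked_pattern"`.
#' @param file Path or connection; `""` returns the text invisibly via
#'   [utils::write.table()]'s default behaviour of printing.
#' @param dialect A [stem_dialect()].
#' @export
write_stem_table <- function(pattern, file, dialect = stem_dialect()) {
  stopifnot(inherits(pattern, "marked_pattern"), inherits(dialect, "stem_dialect"))
  df <- data.frame(x = sprintf("%.6f", pattern$x),
                   y = sprintf("%.6f", pattern$y),
                   species = pattern$species,
                   stringsAsFactors = FALSE)
  names(df) <- c(dialect$x, dialect$y, dialect$species)
  if (!is.null(pattern$dbh)) df[[dialect$dbh]] <- sprintf("%.6f", pattern$dbh)
  if (!is.null(pattern$status)) df[[dialect$status]] <- pattern$status
  if (nrow(df) == 0L) {
    # keep the header even for an empty pattern
    cols <- c(dialect$x, dialect$y, dialect$species)
    df <- as.data.frame(matrix(character(0), 0, length(cols),
                               dimnames = list(NULL, cols)))
  }
  utils::write.table(df, file, sep = dialect$delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Basal area of a stem
#'
#' Cross-sectional trunk area at breast height, in square meters, from the
#' diameter at breast height in centimeters: `pi * (dbh / 200)^2`.
#'
#' @param dbh Diameter(s) at breast height, cm; must be positive.
#' @return Basal area(s), m^2.
#' @examples
#' basal_area(10)  # ~7.854e-3 m^2
#' @export
basal_area <- function(dbh) {
  dbh <- as.numeric(dbh)
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("dbh must be positive and finite", call. = FALSE)
  }
  pi * (dbh / 200)^2
}
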