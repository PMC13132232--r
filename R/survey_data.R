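# Survey data model: observation and transect tables, study-area polygons,
# and the observation-inclusion rules that reduce raw sightings to
# indicated-pair units.

OBS_UNITS <- c("single_male", "pair", "lone_female", "open_group")

obs_required_cols <- c("survey_id", "year", "x", "y", "unit", "on_transect")
tr_required_cols  <- c("transect_id", "survey_id", "year", "stratum",
                       "design_width", "vertex", "x", "y")

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

# Coordinates that all fit inside the lon/lat box are almost certainly
# unprojected; the pipeline requires planar km.
check_projected <- function(x, y, what) {
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stop(sprintf("%s: non-finite coordinates", what), call. = FALSE)
  if (length(x) > 0 && all(abs(x) <= 180) && all(abs(y) <= 90))
    stop(sprintf(paste0("%s: coordinates look geographic (lon/lat); ",
                        "supply planar projected coordinates in km"), what),
         call. = FALSE)
  invisible(TRUE)
}

#' Validate an observation table
#'
#' Checks the documented schema: `survey_id`, `year`, `x`, `y`, `unit`
#' (one of `single_male`, `pair`, `lone_female`, `open_group`), `on_transect`;
#' optional `group_size`, `observer`, `side`. Coordinates must be planar km.
#'
#' @param obs data.frame of observations.
#' @param year_range optional length-2 integer vector of admissible years.
#' @return the validated table (invisibly classed `obs_table`).
#' @export
validate_observations <- function(obs, year_range = NULL) {
  check_columns(obs, obs_required_cols, "observations")
  if (nrow(obs) > 0) {
    check_projected(obs$x, obs$y, "observations")
    if (!all(obs$unit %in% OBS_UNITS))
      stop("observations: unknown unit value(s): ",
           paste(setdiff(unique(obs$unit), OBS_UNITS), collapse = ", "),
           call. = FALSE)
    if (!is.numeric(obs$year) || any(obs$year != round(obs$year)))
      stop("observations: year must be integer calendar years", call. = FALSE)
    if (!is.null(year_range) &&
        any(obs$year < year_range[1] | obs$year > year_range[2]))
      stop("observations: year outside configured range", call. = FALSE)
    if (!is.logical(obs$on_transect))
      obs$on_transect <- as.logical(obs$on_transect)
    if (anyNA(obs$on_transect))
      stop("observations: on_transect must be TRUE/FALSE", call. = FALSE)
    if ("group_size" %in% names(obs)) {
      bad <- obs$unit == "open_group" &
        (is.na(obs$group_size) | obs$group_size < 1)
      if (any(bad))
        stop("observations: open_group rows need group_size >= 1", call. = FALSE)
    } else if (any(obs$unit == "open_group")) {
      stop("observations: open_group rows need a group_size column", call. = FALSE)
    }
  }
  class(obs) <- unique(c("obs_table", class(obs)))
  invisible(obs)
}

#' Validate a transect table
#'
#' Long format: one row per polyline vertex, ordered by `vertex` within
#' `transect_id`. Each transect needs at least two vertices, positive length
#' and a positive strip `design_width` (km, both sides combined unless
#' observer-specific).
#'
#' @param tr data.frame of transect vertices.
#' @return the validated table (invisibly classed `transect_table`).
#' @export
validate_transects <- function(tr) {
  check_columns(tr, tr_required_cols, "transects")
  if (nrow(tr) > 0) {
    check_projected(tr$x, tr$y, "transects")
    if (any(tr$design_width <= 0))
      stop("transects: design_width must be > 0", call. = FALSE)
    for (id in unique(tr$transect_id)) {
      v <- tr[tr$transect_id == id, ]
      v <- v[order(v$vertex), ]
      if (nrow(v) < 2)
        stop(sprintf("transects: transect %s has < 2 vertices", id), call. = FALSE)
      if (polyline_length(cbind(v$x, v$y)) <= 0)
        stop(sprintf("transects: transect %s has zero length", id), call. = FALSE)
    }
  }
  class(tr) <- unique(c("transect_table", class(tr)))
  invisible(tr)
}

#' Read observation / transect CSV files
#'
#' @param path CSV file path.
#' @param ... passed to [validate_observations()] / [validate_transects()].
#' @return validated table.
#' @export
read_observations <- function(path, ...) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("on_transect" %in% names(obs)) obs$on_transect <- as.logical(obs$on_transect)
  validate_observations(obs, ...)
}

#' @rdname read_observations
#' @export
read_transects <- function(path) {
  validate_transects(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a table back to CSV
#' @param x table; @param path destination.
#' @export
write_survey_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Construct a study area from stratum polygons
#'
#' @param polygons named list of two-column vertex matrices (km), one per
#'   stratum.
#' @return `study_area` object with per-stratum and total areas (km^2).
#' @export
study_area <- function(polygons) {
  if (is.null(names(polygons)) || any(names(polygons) == ""))
    names(polygons) <- paste0("stratum_", seq_along(polygons))
  polygons <- lapply(polygons, function(v) open_ring(as.matrix(v)))
  for (s in names(polygons)) {
    poly_validate(polygons[[s]], label = sprintf("stratum '%s'", s))
    check_projected(polygons[[s]][, 1], polygons[[s]][, 2],
                    sprintf("stratum '%s'", s))
  }
  areas <- vapply(polygons, poly_area, numeric(1))
  structure(list(polygons = polygons, areas = areas, total_area = sum(areas)),
            class = "study_area")
}

#' @export
print.study_area <- function(x, ...) {
  cat("Study area:", length(x$polygons), "stratum polygon(s), total",
      format(x$total_area, digits = 6), "km^2\n")
  for (s in names(x$polygons))
    cat(sprintf("  %-12s %10.3f km^2 (%d vertices)\n", s, x$areas[[s]],
                nrow(x$polygons[[s]])))
  invisible(x)
}

#' Read / write a study area as GeoJSON
#'
#' Polygons must be in a planar projected CRS (km); a `FeatureCollection`
#' with one `Polygon` feature per stratum and a `stratum` property. Writing
#' records the planar units in a top-level `planar_units` member.
#'
#' @param path GeoJSON file path.
#' @return `study_area` object.
#' @export
read_study_area <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("GeoJSON: expected a FeatureCollection", call. = FALSE)
  polys <- list()
  for (f in gj$features) {
    if (is.null(f$geometry) || !identical(f$geometry$type, "Polygon"))
      stop("GeoJSON: every feature must be a Polygon", call. = FALSE)
    ring <- f$geometry$coordinates[[1]]
    v <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    nm <- if (!is.null(f$properties$stratum)) f$properties$stratum
          else paste0("stratum_", length(polys) + 1)
    polys[[nm]] <- open_ring(v)
  }
  study_area(polys)
}

#' @rdname read_study_area
#' @param area `study_area` object to write.
#' @export
write_study_area <- function(area, path) {
  feats <- lapply(names(area$polygons), function(s) {
    ring <- close_ring(area$polygons[[s]])
    list(type = "Feature",
         properties = list(stratum = s),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.list(unname(ring[i, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", planar_units = "km",
                            features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a full survey data set
#'
#' @param obs_path,transect_path,area_path CSV / CSV / GeoJSON paths.
#' @param year_range optional admissible year range.
#' @return list with `observations`, `transects`, `area`.
#' @export
read_survey <- function(obs_path, transect_path, area_path, year_range = NULL) {
  obs <- read_observations(obs_path, year_range = year_range)
  tr <- read_transects(transect_path)
  area <- read_study_area(area_path)
  message(sprintf("read %d observations, %d transect vertices, %d strata",
                  nrow(obs), nrow(tr), length(area$polygons)))
  list(observations = obs, transects = tr, area = area)
}

#' Apply the observation-inclusion rules
#'
#' Reduces raw sightings to the units the density model uses: lone females
#' (females outside male-female pairs) are dropped, off-transect rows are
#' dropped, and size-1 "open" groups (unknown sex/pair status) are recoded as
#' single males. Open groups larger than 1 are an error. Idempotent. The drops
#' and recodes are recorded in an `audit` attribute.
#'
#' @param obs validated observation table.
#' @return filtered table with an `audit` attribute (data.frame of rule, n).
#' @export
apply_inclusion_rules <- function(obs) {
  obs <- validate_observations(as.data.frame(obs))
  big_open <- obs$unit == "open_group" & obs$group_size > 1
  if (any(big_open))
    stop(sprintf("unsupported unit: open_group with size > 1 (%d row(s))",
                 sum(big_open)), call. = FALSE)
  audit <- data.frame(rule = character(0), n = integer(0))
  log_rule <- function(rule, n) {
    if (n > 0) audit <<- rbind(audit, data.frame(rule = rule, n = n))
  }
  drop_off <- !obs$on_transect
  log_rule("drop_off_transect", sum(drop_off))
  obs <- obs[!drop_off, , drop = FALSE]
  drop_f <- obs$unit == "lone_female"
  log_rule("drop_lone_female", sum(drop_f))
  obs <- obs[!drop_f, , drop = FALSE]
  recode <- obs$unit == "open_group"
  log_rule("recode_open1_single_male", sum(recode))
  obs$unit[recode] <- "single_male"
  rownames(obs) <- NULL
  structure(validate_observations(obs), audit = audit)
}

#' Audit log of the last inclusion-rule application
#' @param obs table returned by [apply_inclusion_rules()].
#' @export
inclusion_audit <- function(obs) attr(obs, "audit")

#' Count indicated pairs
#'
#' Each retained single male and each pair contributes one indicated pair
#' (a single male is assumed to indicate a nesting female). Indicated
#' breeding birds are `2 *` indicated pairs and are computed downstream,
#' never stored here.
#'
#' @param obs table already passed through [apply_inclusion_rules()].
#' @return the table with a `count` column (1 per row).
#' @export
indicated_units <- function(obs) {
  if (nrow(obs) > 0 && !all(obs$unit %in% c("single_male", "pair")))
    stop("indicated_units: apply inclusion rules first", call. = FALSE)
  obs$count <- rep(1L, nrow(obs))
  obs
}
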