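# Chop transects into fixed-length segments with centroids and strip areas,
# then assign observation counts to nearest segments. The resulting segment
# table is the response table for both the design-based estimator (after
# aggregation back to transects) and the density GAM.

#' Partition transects into fixed-length segments
#'
#' Each transect polyline is cut into consecutive segments of
#' `target_length` km with one shorter remainder segment at the end (boundary
#' segments are kept, not merged; their smaller area flows into the model's
#' area offset). Centroid is the mid-arc-length point of the segment
#' polyline; `area = length * effective_width`.
#'
#' In pooled mode the strip covers both observer sides
#' (`effective_width = 0.4` km for two 200 m half-strips). With
#' `by_observer = TRUE` each recorded side is emitted as its own segment row
#' of half the width, so observer-specific models see 200 m strips.
#'
#' @param transects validated transect table (long vertex format).
#' @param target_length segment length in km (> 0).
#' @param effective_width full strip width in km (> 0).
#' @param by_observer emit one row per observer side (width halved).
#' @return `segment_table` data.frame: segment_id, transect_id, survey_id,
#'   year, stratum, observer, x_c, y_c, x0, y0, x1, y1, length, area, count
#'   (NA until [assign_counts()]); segment polylines in a `geometry`
#'   attribute.
#' @export
segment_transects <- function(transects, target_length, effective_width,
                              by_observer = FALSE) {
  stopifnot(target_length > 0, effective_width > 0)
  transects <- validate_transects(as.data.frame(transects))
  acc <- list()
  geoms <- list()
  for (id in unique(transects$transect_id)) {
    tv <- transects[transects$transect_id == id, ]
    tv <- tv[order(tv$vertex), ]
    v <- cbind(tv$x, tv$y)
    L <- polyline_length(v)
    if (L < 1e-3) {
      warning(sprintf("transect %s shorter than 1 m; skipped", id))
      next
    }
    breaks <- if (L > target_length) seq(target_length, L, by = target_length)
              else numeric(0)
    breaks <- breaks[breaks < L - 1e-12]
    pieces <- split_polyline(v, breaks)
    for (k in seq_along(pieces)) {
      p <- pieces[[k]]
      plen <- polyline_length(p)
      mid <- polyline_point_at(p, plen / 2)
      sides <- if (by_observer) c("left", "right") else NA_character_
      w <- if (by_observer) effective_width / 2 else effective_width
      for (sd in sides) {
        seg_id <- if (by_observer) sprintf("%s_%03d_%s", id, k, sd)
                  else sprintf("%s_%03d", id, k)
        acc[[length(acc) + 1]] <- list(
          seg_id, id, tv$survey_id[1], tv$year[1], tv$stratum[1],
          if ("observer" %in% names(tv)) tv$observer[1] else NA_character_,
          sd, mid[1], mid[2], p[1, 1], p[1, 2],
          p[nrow(p), 1], p[nrow(p), 2], plen, plen * w)
        geoms[[seg_id]] <- p
      }
    }
  }
  col <- function(i, f) vapply(acc, function(r) f(r[[i]]), f(NA))
  seg <- data.frame(
    segment_id = col(1, as.character), transect_id = col(2, as.character),
    survey_id = col(3, as.character), year = col(4, as.integer),
    stratum = col(5, as.character), observer = col(6, as.character),
    side = col(7, as.character),
    x_c = col(8, as.numeric), y_c = col(9, as.numeric),
    x0 = col(10, as.numeric), y0 = col(11, as.numeric),
    x1 = col(12, as.numeric), y1 = col(13, as.numeric),
    length = col(14, as.numeric), area = col(15, as.numeric),
    count = NA_integer_, stringsAsFactors = FALSE)
  structure(seg, geometry = geoms,
            class = c("segment_table", class(seg)))
}

segment_geometry <- function(segments, seg_id) {
  g <- attr(segments, "geometry")
  if (!is.null(g) && !is.null(g[[seg_id]])) return(g[[seg_id]])
  r <- segments[segments$segment_id == seg_id, ][1, ]
  rbind(c(r$x0, r$y0), c(r$x1, r$y1))
}

#' Assign observations to their nearest segment
#'
#' Every observation increments the count of the nearest segment (perpendicular
#' distance to the segment polyline) among segments of the same survey and
#' year. Ties break deterministically to the lexicographically smaller
#' `segment_id`. Observations farther than `gate_km` from every candidate
#' segment are excluded with a warning and recorded in an `orphans` attribute.
#' All segments are retained in the output, including zero-count segments.
#'
#' @param segments `segment_table` from [segment_transects()].
#' @param obs observation table with a `count` column ([indicated_units()]).
#' @param gate_km maximum allowed observation-to-segment distance (default 1).
#' @return the segment table with `count` filled in.
#' @export
assign_counts <- function(segments, obs, gate_km = 1) {
  seg <- segments
  seg$count <- 0L
  orphans <- integer(0)
  if (nrow(obs) > 0 && !"count" %in% names(obs))
    stop("assign_counts: observations need a count column (indicated_units)",
         call. = FALSE)
  if (nrow(obs) > 0) {
    geoms <- lapply(seg$segment_id, function(id) segment_geometry(segments, id))
    key <- paste(seg$survey_id, seg$year)
    ord <- order(seg$segment_id)
    for (i in seq_len(nrow(obs))) {
      cand <- which(key == paste(obs$survey_id[i], obs$year[i]))
      if (length(cand) == 0) { orphans <- c(orphans, i); next }
      d <- vapply(cand, function(j)
        dist_point_polyline(obs$x[i], obs$y[i], geoms[[j]]), numeric(1))
      dmin <- min(d)
      if (dmin > gate_km) { orphans <- c(orphans, i); next }
      best <- cand[d <= dmin + 1e-9]
      if (length(best) > 1) best <- best[order(seg$segment_id[best])][1]
      seg$count[best] <- seg$count[best] + obs$count[i]
    }
  }
  if (length(orphans) > 0)
    warning(sprintf("%d observation(s) farther than %g km from any segment; excluded",
                    length(orphans), gate_km))
  structure(seg, geometry = attr(segments, "geometry"), orphans = orphans,
            class = class(segments))
}
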