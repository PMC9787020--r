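#' Proportion of overlapping search area
#'
#' The team's division-of-labor measure: the area covered by at least two
#' players' search polygons (the union of all pairwise intersections, so
#' triply covered ground counts once), divided by the total search area
#' (the union of all polygons). 0 means the team cleanly partitioned the
#' search space; 1 means everyone searched the same locations.
#'
#' @param polygons List of two or more polygons: `herd_search_polygon`
#'   objects or plain ring lists (each ring a `list(x, y)`).
#' @return A `herd_overlap` object: `proportion` (in `[0, 1]`, `NA` with
#'   `degenerate = TRUE` when the total area is zero), `overlap_area`,
#'   `total_area`, `per_player_areas`.
#' @export
overlap_proportion <- function(polygons) {
  if (length(polygons) < 2L) {
    stop("overlap_proportion: need at least two polygons", call. = FALSE)
  }
  regions <- lapply(polygons, function(p) {
    if (inherits(p, "herd_search_polygon")) p$rings else p
  })
  areas <- vapply(regions, region_area, numeric(1L))

  inter <- function(a, b) {
    if (!length(a) || !length(b)) return(list())
    polyclip::polyclip(a, b, op = "intersection",
                       fillA = "nonzero", fillB = "nonzero")
  }
  uni <- function(a, b) {
    if (!length(a)) return(b)
    if (!length(b)) return(a)
    polyclip::polyclip(a, b, op = "union",
                       fillA = "nonzero", fillB = "nonzero")
  }

  k <- length(regions)
  ov <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      ov <- uni(ov, inter(regions[[i]], regions[[j]]))
    }
  }
  total <- Reduce(uni, regions)
  total_area <- region_area(total)
  overlap_area <- region_area(ov)
  degenerate <- total_area <= 0
  structure(list(
    proportion = if (degenerate) NA_real_ else overlap_area / total_area,
    overlap_area = overlap_area,
    total_area = total_area,
    per_player_areas = areas,
    degenerate = degenerate
  ), class = "herd_overlap")
}

#' @export
print.herd_overlap <- function(x, ...) {
  cat("<herd_overlap> proportion:",
      if (x$degenerate) "NA (degenerate)" else format(x$proportion, digits = 4),
      "| overlap:", format(x$overlap_area, digits = 6),
      "| total:", format(x$total_area, digits = 6), "\n")
  invisible(x)
}

#' Trial-level overlap from a log
#'
#' Convenience wrapper: alpha-shape search polygons of all players
#' ([search_polygons()]) followed by [overlap_proportion()].
#'
#' @param log A `herd_trial_log`.
#' @param to_hz Analysis rate, Hz.
#' @return A `herd_overlap` object.
#' @export
trial_overlap <- function(log, to_hz = 5) {
  overlap_proportion(search_polygons(log, to_hz))
}

#' Export search polygons as GeoJSON
#'
#' Writes each polygon's rings as a GeoJSON `Polygon` feature (planar game
#' coordinates, not geographic) for external inspection and plotting.
#'
#' @param polygons List of `herd_search_polygon` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polygons, path) {
  features <- lapply(polygons, function(p) {
    coords <- lapply(p$rings, function(r) {
      xs <- c(r$x, r$x[1L])
      ys <- c(r$y, r$y[1L])
      lapply(seq_along(xs), function(i) c(xs[i], ys[i]))
    })
    list(
      type = "Feature",
      properties = list(player = p$player, method = p$method, area = p$area),
      geometry = list(type = "Polygon", coordinates = coords)
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
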