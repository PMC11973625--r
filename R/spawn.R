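#' Release polygon with live coral cover
#'
#' A mapped reef polygon from which virtual spawn or larvae are seeded,
#' carrying its live-coral cover, planar area, relative propagule weight and
#' (after allocation) the particle count assigned to it.
#'
#' @param id Identifier string.
#' @param vertices `m x 2` matrix of vertices in metres (local frame), in
#'   order, unclosed.
#' @param cover_pct Live coral cover percent in `[0, 100]`.
#' @param weight Relative propagule output (default `NA`, filled by
#'   [allocate_release_polygons()]).
#' @param n_particles Allocated particle count (default `NA`).
#' @param parent_id Id of the polygon this one was split from, if any.
#'
#' @return An object of class `release_polygon` (list with the above fields
#'   plus `area` in square metres, from the shoelace formula).
#' @export
release_polygon <- function(id, vertices, cover_pct, weight = NA_real_,
                            n_particles = NA_integer_, parent_id = NA_character_) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2, nrow(vertices) >= 3)
  if (cover_pct < 0 || cover_pct > 100) stop("cover_pct must be in [0, 100]")
  a <- polygon_area(vertices)
  if (a <= 0) stop("polygon area must be > 0")
  structure(list(id = id, vertices = vertices, cover_pct = cover_pct,
                 area = a, weight = weight,
                 n_particles = as.integer(n_particles), parent_id = parent_id),
            class = "release_polygon")
}

#' Planar polygon area (shoelace formula)
#' @param vertices `m x 2` vertex matrix. @return Area in the square of the
#'   coordinate unit.
#' @export
polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman clip of a polygon against the half-plane
# axis <= cut (side = "low") or axis >= cut (side = "high"); axis 1 = x, 2 = y.
.clip_halfplane <- function(verts, axis, cut, side) {
  inside <- function(p) if (side == "low") p[axis] <= cut else p[axis] >= cut
  n <- nrow(verts)
  out <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n)) {
    a <- verts[k, ]; b <- verts[if (k == n) 1 else k + 1, ]
    ain <- inside(a); bin <- inside(b)
    if (ain) out <- rbind(out, a)
    if (xor(ain, bin)) {
      t <- (cut - a[axis]) / (b[axis] - a[axis])
      out <- rbind(out, a + t * (b - a))
    }
  }
  out
}

# Split a polygon into k pieces by recursive bisection along its longer
# bounding-box axis; piece counts balance as floor/ceiling of k/2.
.split_polygon <- function(verts, k) {
  if (k <= 1) return(list(verts))
  xr <- range(verts[, 1]); yr <- range(verts[, 2])
  axis <- if (diff(xr) >= diff(yr)) 1L else 2L
  rng <- if (axis == 1L) xr else yr
  k1 <- floor(k / 2); k2 <- k - k1
  cut <- rng[1] + diff(rng) * k1 / k
  lo <- .clip_halfplane(verts, axis, cut, "low")
  hi <- .clip_halfplane(verts, axis, cut, "high")
  c(.split_polygon(lo, k1), .split_polygon(hi, k2))
}

#' Allocate spawn releases across coral polygons
#'
#' Collection-phase allocation: polygons with live coral cover below
#' `min_cover_pct` are dropped; each remaining polygon gets a relative
#' propagule weight (by default `area * cover_pct / 100`, a documented
#' stand-in for a full cover-to-fecundity workflow and pluggable via
#' `weight_fun`); polygons are then split along their longer axis into enough
#' sub-polygons that each sub-polygon carries about `target_per_subpolygon`
#' particles, with the weight-per-subpolygon scale chosen so the whole domain
#' totals `total_budget` particles.
#'
#' @param polygons List of [release_polygon()].
#' @param target_per_subpolygon Particles per sub-polygon (default 5000).
#' @param total_budget Total particle budget across the domain (default
#'   450000, i.e. 90 sub-polygons of 5000).
#' @param min_cover_pct Cover filter threshold in percent (default 10).
#' @param weight_fun Function `(area_m2, cover_pct) -> weight`; default
#'   `area * cover/100`.
#'
#' @return List of sub-polygons ([release_polygon()]) with `weight`,
#'   `n_particles` and `parent_id` filled in.
#' @export
allocate_release_polygons <- function(polygons, target_per_subpolygon = 5000,
                                      total_budget = 450000,
                                      min_cover_pct = 10,
                                      weight_fun = NULL) {
  if (is.null(weight_fun))
    weight_fun <- function(area, cover) area * cover / 100
  keep <- Filter(function(p) p$cover_pct >= min_cover_pct, polygons)
  if (!length(keep))
    stop("no polygons with cover >= ", min_cover_pct, "% remain")
  w <- vapply(keep, function(p) weight_fun(p$area, p$cover_pct), numeric(1))
  # weight carried by one 'target' sub-polygon so the domain totals the budget
  w_unit <- sum(w) * target_per_subpolygon / total_budget
  out <- list()
  for (k in seq_along(keep)) {
    p <- keep[[k]]
    nsub <- max(1L, ceiling(w[k] / w_unit))
    pieces <- .split_polygon(p$vertices, nsub)
    for (s in seq_along(pieces)) {
      id <- if (nsub == 1L) p$id else sprintf("%s_%02d", p$id, s)
      out[[id]] <- release_polygon(
        id = id, vertices = pieces[[s]], cover_pct = p$cover_pct,
        weight = w[k] / nsub,
        n_particles = as.integer(target_per_subpolygon), parent_id = p$id)
    }
  }
  out
}

#' Run a surface spawn-slick dispersal scenario
#'
#' Releases the allocated particles of every sub-polygon near the surface
#' (0.25 m) during the two-hour evening spawn window and tracks them for 16 h,
#' once per requested windage setting (typically 0% and 3% of the wind speed).
#'
#' @param field A [current_field()] spanning the release plus `duration_h`.
#' @param wind Wind series data frame (`time_s`, `wind_u`, `wind_v`);
#'   required for non-zero drag settings.
#' @param polygons Allocated sub-polygons from [allocate_release_polygons()].
#' @param release_start_s Start of the release window on the field time axis
#'   (seconds; e.g. 19:00 of the spawning night).
#' @param drag_pcts Windage percentages to run (default `c(0, 3)`).
#' @param duration_h Tracking duration (default 16).
#' @param release_window_h Length of the release window (default 2, i.e.
#'   19:00--21:00).
#' @param seed Master seed; each sub-polygon uses a derived sub-seed.
#'
#' @return Named list (one element per drag setting, e.g. `"drag0"`) of lists
#'   of [advect_ensemble()] results, one per sub-polygon.
#' @export
run_slick_scenario <- function(field, wind, polygons, release_start_s,
                               drag_pcts = c(0, 3), duration_h = 16,
                               release_window_h = 2, seed = 1L) {
  stopifnot(length(polygons) >= 1)
  win <- c(release_start_s, release_start_s + release_window_h * 3600)
  out <- list()
  for (dp in drag_pcts) {
    ens <- vector("list", length(polygons))
    names(ens) <- names(polygons)
    for (k in seq_along(polygons)) {
      p <- polygons[[k]]
      sub_seed <- (seed + 7919L * k) %% .Machine$integer.max
      cfg <- tracking_config(duration_h = duration_h, release_depth = 0.25,
                             wind_drag_pct = dp,
                             n_particles = p$n_particles, seed = sub_seed)
      seeds <- seed_particles(p, p$n_particles, release_window = win,
                              seed = sub_seed, field = field)
      ens[[k]] <- advect_ensemble(field, seeds, cfg,
                                  wind = if (dp > 0) wind else NULL,
                                  polygon_id = p$id)
    }
    out[[paste0("drag", dp)]] <- ens
  }
  out
}

#' Particle density raster from track ensembles
#'
#' Sums particle-timepoint samples per grid cell over all ensembles of one
#' scenario, the quantity whose cellwise maxima identify spawn-slick
#' convergence zones. Every stored timepoint of every particle contributes
#' one count to the cell containing it.
#'
#' @param ensembles List of [advect_ensemble()] results (or a single one).
#' @param grid A [grid_spec()] defining the raster.
#' @param scenario Optional metadata list stored on the result.
#'
#' @return An object of class `density_raster`: list with `grid`, integer
#'   matrix `counts` (`ny x nx`), `total` and `scenario`.
#' @export
slick_density <- function(ensembles, grid, scenario = list()) {
  if (inherits(ensembles, "track_ensemble")) ensembles <- list(ensembles)
  counts <- matrix(0L, grid$ny, grid$nx)
  for (ens in ensembles) {
    ci <- cell_index(grid, as.vector(ens$x), as.vector(ens$y))
    ok <- !is.na(ci$i)
    tab <- tabulate(ci$j[ok] + grid$ny * (ci$i[ok] - 1L),
                    nbins = grid$ny * grid$nx)
    counts <- counts + matrix(tab, grid$ny, grid$nx)
  }
  structure(list(grid = grid, counts = counts, total = sum(counts),
                 scenario = scenario),
            class = "density_raster")
}

#' @export
print.density_raster <- function(x, ...) {
  cat(sprintf("<density_raster> %d x %d cells, %d particle-timepoints\n",
              x$grid$ny, x$grid$nx, x$total))
  invisible(x)
}

#' Top convergence cells of a density raster
#' @param raster A [slick_density()] result. @param n Number of cells.
#' @return Data frame with `i`, `j`, `x`, `y`, `count`, strongest first.
#' @export
top_density_cells <- function(raster, n = 10) {
  ord <- order(raster$counts, decreasing = TRUE)[seq_len(n)]
  j <- (ord - 1L) %% raster$grid$ny + 1L
  i <- (ord - 1L) %/% raster$grid$ny + 1L
  cs <- raster$grid$cell_size
  data.frame(i = i, j = j, x = (i - 0.5) * cs, y = (j - 0.5) * cs,
             count = raster$counts[ord])
}
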