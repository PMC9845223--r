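#' Transform an arrival displacement into the velocity frame
#'
#' The heat maps are accumulated in the "velocity frame": each player's
#' position at time `t` is moved to the origin and the frame rotated so the
#' current velocity points along +x. This function applies that rigid
#' transform to the displacement `pos_later - pos`; it preserves norms
#' exactly.
#'
#' @param pos Position at `t`: length-2 vector or n x 2 matrix (m).
#' @param vel Velocity at `t`: same shape (m/s); rows must be non-zero.
#' @param pos_later Position at `t + delta_t`: same shape (m).
#' @return Velocity-frame coordinates, n x 2 matrix (or length-2 vector if
#'   the inputs were vectors).
#' @examples
#' velocity_frame_point(c(10, 5), c(0, 2), c(10, 9))  # c(4, 0)
#' @export
velocity_frame_point <- function(pos, vel, pos_later) {
  vec_in <- is.null(dim(pos))
  to_mat <- function(z) if (is.null(dim(z))) matrix(z, ncol = 2) else as.matrix(z)
  pos <- to_mat(pos); vel <- to_mat(vel); pos_later <- to_mat(pos_later)
  stopifnot(ncol(pos) == 2, nrow(pos) == nrow(vel),
            nrow(pos) == nrow(pos_later))
  spd <- sqrt(vel[, 1]^2 + vel[, 2]^2)
  if (any(spd == 0)) {
    stop("zero velocity: the velocity frame is undefined; exclude such points.",
         call. = FALSE)
  }
  ct <- vel[, 1] / spd
  st <- vel[, 2] / spd
  dx <- pos_later[, 1] - pos[, 1]
  dy <- pos_later[, 2] - pos[, 2]
  out <- cbind(ct * dx + st * dy, -st * dx + ct * dy)
  colnames(out) <- c("ax", "ay")
  if (vec_in) out[1, ] else out
}

#' Velocity-frame arrival points for a given interval
#'
#' For every (player, frame) with a defined velocity and a frame
#' `delta_t` seconds later inside the same segment, computes the arrival
#' point in the velocity frame. All overlapping windows at the native frame
#' rate are used. Goalkeepers are excluded when a `role` column is present
#' (sprint analyses are about outfield players), and zero-speed frames —
#' where the frame is undefined — are dropped with a count attached as
#' attribute `n_zero_speed`.
#'
#' @param records Output of [compute_velocity()].
#' @param delta_t Arrival interval, s; positive multiple of the sampling
#'   interval.
#' @return A tibble with columns `segment_id`, `player_id`, `time_s`,
#'   `v0` (speed at the window start, m/s), `ax`, `ay` (velocity-frame
#'   arrival coordinates, m).
#' @export
arrival_points <- function(records, delta_t) {
  check_tracking_cols(records, c("segment_id", "time_s", "player_id",
                                 "x_m", "y_m", "vx", "vy", "speed"))
  si <- infer_interval(records)
  k <- delta_t / si
  if (delta_t <= 0 || abs(k - round(k)) > 1e-6) {
    stop(sprintf("`delta_t` (%g s) must be a positive multiple of the sampling interval (%g s).",
                 delta_t, si), call. = FALSE)
  }
  k <- as.integer(round(k))
  if ("role" %in% names(records)) {
    records <- dplyr::filter(records, .data$role != "GK")
  }
  pts <- records |>
    dplyr::arrange(.data$segment_id, .data$player_id, .data$time_s) |>
    dplyr::group_by(.data$segment_id, .data$player_id) |>
    dplyr::mutate(x_next = dplyr::lead(.data$x_m, k),
                  y_next = dplyr::lead(.data$y_m, k)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$x_next))
  n_zero <- sum(pts$speed == 0)
  pts <- dplyr::filter(pts, .data$speed > 0)
  vf <- velocity_frame_point(cbind(pts$x_m, pts$y_m),
                             cbind(pts$vx, pts$vy),
                             cbind(pts$x_next, pts$y_next))
  out <- tibble::tibble(segment_id = pts$segment_id,
                        player_id = pts$player_id,
                        time_s = pts$time_s,
                        v0 = pts$speed,
                        ax = vf[, "ax"], ay = vf[, "ay"])
  attr(out, "n_zero_speed") <- n_zero
  attr(out, "delta_t") <- delta_t
  out
}

#' Build an arrival-point heat map for one initial-speed bin
#'
#' Accumulates velocity-frame arrival points whose initial speed falls in
#' the half-open bin `[v0_bin[1], v0_bin[2])` onto a square grid. The cell
#' side defaults to `0.2 * delta_t` metres, scaling the resolution with the
#' size of the reachable region. Cells are half-open,
#' `[i s, (i+1) s) x [j s, (j+1) s)`, anchored at the origin of the velocity
#' frame; boundary points go to the higher index.
#'
#' @param points Arrival points ([arrival_points()] or
#'   [generate_sprint_ensemble()] output: columns `v0`, `ax`, `ay`).
#' @param delta_t Arrival interval the points were built with, s.
#' @param v0_bin Length-2 numeric: the initial-speed bin `[lo, hi)`, m/s.
#' @param cell_size Cell side, m; default `0.2 * delta_t`.
#' @return An object of class `heatmap_grid`: a list with the integer count
#'   matrix `counts` (rows indexing x cells, columns y cells), the index
#'   offsets `ix0`, `iy0` of the first row/column, `cell_size`, `delta_t`,
#'   `v0_bin` and `n_points`. Empty selections yield a valid grid with
#'   `n_points = 0`.
#' @export
build_heatmap <- function(points, delta_t, v0_bin,
                          cell_size = 0.2 * delta_t) {
  check_tracking_cols(points, c("v0", "ax", "ay"))
  stopifnot(is.numeric(v0_bin), length(v0_bin) == 2L, v0_bin[1] < v0_bin[2],
            cell_size > 0, delta_t > 0)
  sel <- points$v0 >= v0_bin[1] & points$v0 < v0_bin[2]
  x <- points$ax[sel]
  y <- points$ay[sel]
  if (length(x) == 0) {
    return(structure(list(counts = matrix(0L, 0, 0), ix0 = 0L, iy0 = 0L,
                          cell_size = cell_size, delta_t = delta_t,
                          v0_bin = v0_bin, n_points = 0L),
                     class = "heatmap_grid"))
  }
  ix <- floor(x / cell_size)
  iy <- floor(y / cell_size)
  ix0 <- min(ix); iy0 <- min(iy)
  nx <- max(ix) - ix0 + 1L
  ny <- max(iy) - iy0 + 1L
  counts <- matrix(tabulate((iy - iy0) * nx + (ix - ix0 + 1L),
                            nbins = nx * ny),
                   nx, ny)
  structure(list(counts = counts, ix0 = as.integer(ix0), iy0 = as.integer(iy0),
                 cell_size = cell_size, delta_t = delta_t, v0_bin = v0_bin,
                 n_points = length(x)),
            class = "heatmap_grid")
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf(
    "<heatmap_grid> delta_t = %g s, v0 in [%g, %g) m/s, cell = %g m, %d points in %d x %d cells (%d occupied)\n",
    x$delta_t, x$v0_bin[1], x$v0_bin[2], x$cell_size, x$n_points,
    nrow(x$counts), ncol(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Default isolated-cell threshold
#'
#' Threshold `c` on the number of occupied Moore neighbours a cell needs to
#' be kept: 8 for `delta_t < 1` s, 6 for `1 <= delta_t <= 3` s, 4 for
#' `delta_t > 3` s. Short intervals produce dense compact maps where a
#' strict threshold removes noise; long intervals produce sparser maps that
#' need a looser one.
#'
#' @param delta_t Arrival interval, s; positive (vectorised).
#' @return Integer threshold(s).
#' @export
default_c <- function(delta_t) {
  stopifnot(is.numeric(delta_t), all(delta_t > 0))
  ifelse(delta_t < 1, 8L, ifelse(delta_t <= 3, 6L, 4L))
}

#' Remove isolated heat-map cells
#'
#' Keeps an occupied cell only if at least `c` of its 8 Moore neighbours are
#' occupied, in a single pass over the input occupancy (the neighbour counts
#' are all taken from the unfiltered grid; the filter is not iterated).
#' This strips isolated outlier cells — typically tracking-noise artifacts —
#' before extent-based circle estimation. Blank cells are unchanged, so the
#' survivor set is always a subset of the input occupancy.
#'
#' With `strict = TRUE` the test becomes "more than `c`" neighbours, which
#' is only satisfiable for `c <= 7` (a Moore neighbourhood has 8 cells).
#'
#' @param grid A [build_heatmap()] result.
#' @param c Neighbour threshold in `[0, 8]`; defaults to
#'   [default_c()]`(grid$delta_t)`.
#' @param strict Use strictly-more-than `c` instead of at-least `c`.
#' @return A `heatmap_grid` with isolated cells blanked.
#' @export
filter_isolated_cells <- function(grid, c = default_c(grid$delta_t),
                                  strict = FALSE) {
  stopifnot(inherits(grid, "heatmap_grid"))
  if (!is.numeric(c) || length(c) != 1L || c < 0 || c > 8) {
    stop("`c` must be in [0, 8]: a cell has only 8 Moore neighbours.",
         call. = FALSE)
  }
  if (strict && c > 7) {
    stop("strict adjacency with c > 7 can never be satisfied.", call. = FALSE)
  }
  if (grid$n_points == 0L || length(grid$counts) == 0L) return(grid)
  occ <- grid$counts > 0
  nx <- nrow(occ); ny <- ncol(occ)
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- occ
  nb <- matrix(0L, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- nb + pad[(2 + dx):(nx + 1 + dx), (2 + dy):(ny + 1 + dy)]
  }
  keep <- occ & (if (strict) nb > c else nb >= c)
  grid$counts[!keep] <- 0L
  grid$n_points <- sum(grid$counts)
  grid
}

#' Estimate the boundary circle of a heat map from its extents
#'
#' Approximates the heat map's boundary as a circle using the extreme
#' coordinates of the surviving occupied cells (cell centres):
#' \deqn{(x_c, y_c) = ((x_{max}+x_{min})/2,\; (y_{max}+y_{min})/2), \quad
#'       r_c = (x_{max}-x_{min}+y_{max}-y_{min})/4.}
#' Under the FS model this recovers centre `(A v0, 0)` and radius `B`. Cell
#' centres (not edges) are used: edges would bias `r_c` by half a cell.
#'
#' @param grid A (typically filtered) `heatmap_grid`.
#' @return A one-row tibble: `v0_lo`, `v0_hi`, `v0_mid`, `x_c`, `y_c`,
#'   `r_c` (m), `n_cells`, `n_points`, `delta_t`.
#' @export
circle_from_extent <- function(grid) {
  stopifnot(inherits(grid, "heatmap_grid"))
  occ <- which(grid$counts > 0, arr.ind = TRUE)
  if (nrow(occ) == 0) {
    stop("empty heat map: no occupied cells to estimate a circle from.",
         call. = FALSE)
  }
  s <- grid$cell_size
  cx <- (occ[, 1] - 1 + grid$ix0 + 0.5) * s
  cy <- (occ[, 2] - 1 + grid$iy0 + 0.5) * s
  tibble::tibble(
    v0_lo = grid$v0_bin[1], v0_hi = grid$v0_bin[2],
    v0_mid = mean(grid$v0_bin),
    x_c = (max(cx) + min(cx)) / 2,
    y_c = (max(cy) + min(cy)) / 2,
    r_c = (max(cx) - min(cx) + max(cy) - min(cy)) / 4,
    n_cells = nrow(occ),
    n_points = as.integer(grid$n_points),
    delta_t = grid$delta_t
  )
}

#' Per-bin circle estimates for one arrival interval
#'
#' Runs the heat-map chain — bin by initial speed, accumulate, filter
#' isolated cells, estimate the boundary circle — for every speed bin of
#' width `delta_v0` whose lower edge lies in `v0_range`.
#'
#' @param points Arrival points (see [build_heatmap()]).
#' @param delta_t Arrival interval, s.
#' @param v0_range Lower-edge range of bins, m/s; default `c(0, 6)` gives
#'   bins starting at 0, 0.3, ..., 6.
#' @param delta_v0 Bin width, m/s; default 0.3.
#' @param cell_size Cell side, m; default `0.2 * delta_t`.
#' @param c Isolated-cell threshold; default [default_c()]`(delta_t)`.
#' @param strict Passed to [filter_isolated_cells()].
#' @return A tibble with one row per bin that survives filtering (see
#'   [circle_from_extent()]); bins whose filtered map is empty are skipped
#'   with a warning.
#' @export
estimate_circles <- function(points, delta_t, v0_range = c(0, 6),
                             delta_v0 = 0.3, cell_size = 0.2 * delta_t,
                             c = default_c(delta_t), strict = FALSE) {
  stopifnot(is.numeric(v0_range), length(v0_range) == 2L,
            v0_range[1] <= v0_range[2], delta_v0 > 0)
  edges <- seq(v0_range[1], v0_range[2] + 1e-9, by = delta_v0)
  rows <- purrr::map(edges, function(lo) {
    g <- build_heatmap(points, delta_t, c(lo, lo + delta_v0), cell_size)
    g <- filter_isolated_cells(g, c = c, strict = strict)
    if (g$n_points == 0L || all(g$counts == 0L)) return(NULL)
    circle_from_extent(g)
  })
  empty <- sum(vapply(rows, is.null, logical(1)))
  if (empty > 0) {
    warning(sprintf("%d of %d speed bins had no cells after filtering and were skipped.",
                    empty, length(edges)))
  }
  dplyr::bind_rows(rows)
}
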