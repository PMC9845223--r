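tracking_schema_cols <- c("segment_id", "time_s", "player_id", "team",
                          "role", "x_m", "y_m")

#' Read tracking data from CSV
#'
#' Reads the package's plain tracking format: a header row
#' `segment_id,time_s,player_id,team,role,x_m,y_m`, with `role` one of
#' `GK`/`OUT`, times in seconds and positions in metres (pitch-centred).
#' The file is validated: missing columns, non-numeric or missing values
#' (reported with line numbers), unknown roles, and non-uniform timestamps
#' within a (segment, player) series are all errors.
#'
#' @param path Path to a CSV file.
#' @return A tracking tibble (see [generate_tracking()]) with attribute
#'   `sample_interval`.
#' @export
read_tracking <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    segment_id = readr::col_character(),
    time_s = readr::col_double(),
    player_id = readr::col_character(),
    team = readr::col_character(),
    role = readr::col_character(),
    x_m = readr::col_double(),
    y_m = readr::col_double()
  ), progress = FALSE)
  miss <- setdiff(tracking_schema_cols, names(raw))
  if (length(miss) > 0) {
    stop("tracking file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    p <- prob[1, ]
    stop(sprintf("malformed value in column %s at line %d (expected %s).",
                 names(raw)[p$col], p$row + 1L, p$expected), call. = FALSE)
  }
  if (nrow(raw) == 0) stop("tracking file has no data rows: ", path,
                           call. = FALSE)
  for (col in c("time_s", "x_m", "y_m")) {
    bad <- which(!is.finite(raw[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("missing/non-finite `%s` at line %d.", col, bad[1] + 1L),
           call. = FALSE)
    }
  }
  bad_role <- which(!raw$role %in% c("GK", "OUT"))
  if (length(bad_role) > 0) {
    stop(sprintf("unknown `role` '%s' at line %d (expected GK or OUT).",
                 raw$role[bad_role[1]], bad_role[1] + 1L), call. = FALSE)
  }
  raw <- dplyr::arrange(raw, .data$segment_id, .data$player_id, .data$time_s)
  steps <- raw |>
    dplyr::group_by(.data$segment_id, .data$player_id) |>
    dplyr::summarise(d = list(diff(.data$time_s)), .groups = "drop")
  all_d <- unlist(steps$d)
  if (length(all_d) == 0) stop("each series needs at least two frames.",
                               call. = FALSE)
  si <- stats::median(all_d)
  off <- vapply(seq_len(nrow(steps)),
                function(i) any(abs(steps$d[[i]] - si) > 1e-6), logical(1))
  if (any(off)) {
    stop("non-uniform timestamps in segment ",
         steps$segment_id[which(off)[1]], ", player ",
         steps$player_id[which(off)[1]], ".", call. = FALSE)
  }
  attr(raw, "sample_interval") <- si
  raw
}

#' Write tracking data to CSV
#'
#' Writes the schema of [read_tracking()] with a deterministic column and
#' row order, so a write/read round trip is the identity and identical
#' inputs produce byte-identical files.
#'
#' @param tracks A tracking tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(tracks, path) {
  check_tracking_cols(tracks, tracking_schema_cols)
  out <- tracks[, tracking_schema_cols] |>
    dplyr::arrange(.data$segment_id, .data$player_id, .data$time_s)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Export a heat-map grid as a CSV matrix
#'
#' Writes the dense count matrix preceded by a small `#`-prefixed header
#' block recording `delta_t`, the speed bin, the cell size and the grid
#' origin, so the file is self-describing.
#'
#' @param grid A `heatmap_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(grid, path) {
  stopifnot(inherits(grid, "heatmap_grid"))
  hdr <- c(
    sprintf("# delta_t: %g", grid$delta_t),
    sprintf("# v0_bin: %g %g", grid$v0_bin[1], grid$v0_bin[2]),
    sprintf("# cell_size: %g", grid$cell_size),
    sprintf("# origin_index: %d %d", grid$ix0, grid$iy0),
    sprintf("# n_points: %d", grid$n_points)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(grid$counts, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a validation report bundle
#'
#' Writes the tables of a [run_validation()] result as CSV files in a
#' directory: speed distribution, averaged MSD with fitted exponents,
#' per-bin circle estimates, and per-interval kinetic fits.
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$speed_distribution,
                   file.path(dir, "speed_distribution.csv"), progress = FALSE)
  readr::write_csv(report$msd, file.path(dir, "msd.csv"), progress = FALSE)
  readr::write_csv(report$msd_exponents, file.path(dir, "msd_exponents.csv"),
                   progress = FALSE)
  readr::write_csv(report$circles, file.path(dir, "circle_estimates.csv"),
                   progress = FALSE)
  readr::write_csv(dplyr::select(report$fits, -dplyr::any_of("fit")),
                   file.path(dir, "kinetic_fits.csv"), progress = FALSE)
  invisible(dir)
}
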