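#' Write a walking dataset to a directory of plain-text files
#'
#' Layout: `trajectory.csv` (t, x, z), `footfalls.csv` (leg, t_down,
#' t_up, x_foot, y_foot), `leg_tracks.csv` (t, leg, y_body, stance,
#' optional), `meta.json`, and `truth.json` when ground truth is
#' present.  Every CSV starts with a `#` comment naming the units (SI:
#' seconds and metres).  Numbers are written with 17 significant
#' digits, so a read-back reproduces them bit for bit.
#'
#' @param bundle A `walking_dataset` (see [generate_fly_dataset()]) or
#'   a list with compatible elements (`com`, `footfalls`, `meta`,
#'   optionally `leg_tracks`, `truth`).
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_unit_csv(bundle$com, file.path(path, "trajectory.csv"),
                 "# CoM trajectory; t [s], x [m], z [m]")
  write_unit_csv(as.data.frame(bundle$footfalls),
                 file.path(path, "footfalls.csv"),
                 "# footfalls; t_down/t_up [s], x_foot/y_foot [m]")
  if (!is.null(bundle$leg_tracks))
    write_unit_csv(bundle$leg_tracks, file.path(path, "leg_tracks.csv"),
                   "# leg tracks; t [s], y_body [m] (anterior positive)")
  jsonlite::write_json(bundle$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$truth))
    jsonlite::write_json(bundle$truth, file.path(path, "truth.json"),
                         digits = NA, dataframe = "columns")
  invisible(path)
}

write_unit_csv <- function(df, file, header) {
  fmt <- function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }
  out <- as.data.frame(lapply(df, fmt), stringsAsFactors = FALSE)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.csv(out, con, row.names = FALSE, quote = FALSE)
}

#' Read a walking dataset written by [write_dataset()]
#'
#' Validates the schema: the trajectory needs columns `t`, `x`, `z`
#' with strictly increasing time (a duplicated timestamp is reported
#' with its value), footfall rows must carry the six canonical leg
#' labels with lift-off after touch-down, and metadata must identify
#' the fly (mass, measured leg length, frame rate).
#'
#' @param path Directory produced by [write_dataset()].
#' @return A `walking_dataset` list (without `com_clean`).
#' @export
read_dataset <- function(path) {
  traj_file <- file.path(path, "trajectory.csv")
  if (!file.exists(traj_file))
    stop("read_dataset: no trajectory.csv under ", path, call. = FALSE)
  com <- read.csv(traj_file, comment.char = "#")
  need <- c("t", "x", "z")
  miss <- setdiff(need, names(com))
  if (length(miss))
    stop("read_dataset: trajectory.csv missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  d <- diff(com$t)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1]
    stop(sprintf("read_dataset: non-increasing timestamp %.9g in trajectory.csv",
                 com$t[i + 1]), call. = FALSE)
  }
  footfalls <- footfall_sequence(
    read.csv(file.path(path, "footfalls.csv"), comment.char = "#"))
  lt_file <- file.path(path, "leg_tracks.csv")
  leg_tracks <- NULL
  if (file.exists(lt_file)) {
    leg_tracks <- read.csv(lt_file, comment.char = "#")
    leg_tracks$stance <- as.logical(leg_tracks$stance)
    bad <- !leg_tracks$leg %in% LEG_LABELS
    if (any(bad))
      stop(sprintf("read_dataset: unknown leg label '%s' in leg_tracks.csv row %d",
                   leg_tracks$leg[which(bad)[1]], which(bad)[1]),
           call. = FALSE)
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  for (fld in c("m", "R_real", "frame_rate"))
    if (is.null(meta[[fld]]))
      stop("read_dataset: meta.json missing field ", fld, call. = FALSE)
  truth_file <- file.path(path, "truth.json")
  truth <- if (file.exists(truth_file))
    jsonlite::read_json(truth_file, simplifyVector = TRUE)
  structure(list(com = com, footfalls = footfalls,
                 leg_tracks = leg_tracks, truth = truth, meta = meta),
            class = "walking_dataset")
}
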