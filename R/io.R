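.fmt_num <- function(x) sprintf("%.17g", x)

.write_delim <- function(df, path, num_cols) {
  out <- df
  for (nm in num_cols) out[[nm]] <- .fmt_num(df[[nm]])
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Read and write trajectory tables
#'
#' Tracks are stored as delimited text with header
#' `track_id,frame,t_s,x_um,y_um[,state]`, one row per frame.  Numeric columns
#' are written with 17 significant digits, so a write/read round trip is
#' lossless at double precision.  On reading, rows are grouped by track id and
#' sorted by frame, malformed rows are rejected with their line numbers, and
#' each track is checked for uniform frame spacing.
#'
#' @param path CSV file path.
#' @param tracks Tracks data.frame (for writing).
#' @return `read_tracks` returns the tracks data.frame; `write_tracks` returns
#'   `path` invisibly.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, colClasses = list(character = "track_id"))
  req <- c("track_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("tracks file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!stats::complete.cases(df[, req, with = FALSE]) |
                 !is.finite(df$t_s) | !is.finite(df$x_um) | !is.finite(df$y_um))
  if (length(bad))
    stop("malformed rows (data lines): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  data.table::setorderv(df, c("track_id", "frame"))
  df <- as.data.frame(df)
  for (id in unique(df$track_id))
    .frame_interval(df$t_s[df$track_id == id], id)
  df
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  .check_tracks(tracks)
  .write_delim(tracks, path, c("t_s", "x_um", "y_um"))
}

#' Read and write jump-event tables
#'
#' Events are stored as delimited text with header
#' `track_id,t_start_s,t_end_s,length_um,duration_s,theta_rad`.
#'
#' @param path CSV file path.
#' @param events Events data.frame (for writing).
#' @return `read_events` returns the events data.frame; `write_events` returns
#'   `path` invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, colClasses = list(character = "track_id"))
  req <- c("track_id", "t_start_s", "t_end_s", "length_um", "duration_s",
           "theta_rad")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("events file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  as.data.frame(df[order(df$track_id, df$t_start_s), ])
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  .write_delim(events, path,
               c("t_start_s", "t_end_s", "length_um", "duration_s",
                 "theta_rad"))
}

#' Read and write binned density profiles
#'
#' Profiles are stored as delimited text with header
#' `bin_center_um,count[,time_s][,N_c]`.
#'
#' @param path CSV file path.
#' @param profiles Profiles data.frame (for writing).
#' @return `read_profiles` returns the profiles data.frame; `write_profiles`
#'   returns `path` invisibly.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- data.table::fread(path)
  miss <- setdiff(c("bin_center_um", "count"), names(df))
  if (length(miss))
    stop("profiles file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  as.data.frame(df)
}

#' @rdname read_profiles
#' @export
write_profiles <- function(profiles, path) {
  .write_delim(profiles, path, "bin_center_um")
}

#' Structured analysis report
#'
#' Collects fit results into a stable JSON-serializable structure with
#' provenance: package version, seed, and an MD5 digest of the configuration.
#' Missing optional fields are serialized as nulls, never omitted, and
#' identical runs produce identical reports (no timestamps).
#'
#' @param results Named list of analysis results (numbers, vectors, or the
#'   fit objects produced by this package).
#' @param seed Seed used for the run (or `NA`).
#' @param config Configuration object or list to digest (or `NULL`).
#' @param path Optional file to write the JSON to.
#' @return The report list, invisibly when `path` is given.
#' @export
run_report <- function(results, seed = NA_integer_, config = NULL,
                       path = NULL) {
  canon <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                            force = TRUE, null = "null")
  tmp <- tempfile()
  writeLines(canon, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  report <- list(
    package = "entrainr",
    version = as.character(utils::packageVersion("entrainr")),
    seed = if (is.na(seed)) NULL else as.integer(seed),
    config_hash = cfg_hash,
    results = strip(results))
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE, force = TRUE)
    return(invisible(report))
  }
  report
}
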