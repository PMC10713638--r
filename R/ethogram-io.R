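#' Read bout annotations and recording metadata from CSV
#'
#' Consumes the annotator-style event tables: one row per bout with the fly
#' identifier, behaviour label and inclusive 0-based frame interval. The CSV
#' dialect is comma-separated UTF-8 with a header row; extra columns in the
#' events file are preserved as bout attributes (as character, so that a
#' write/read cycle is byte-identical).
#'
#' @param events_path Path to the events CSV (`fly_id`, `behaviour`,
#'   `start_frame`, `end_frame`, optional attribute columns).
#' @param recordings_path Path to the recordings CSV (`fly_id`, `fps`,
#'   `n_frames`, optional `group`, `protocol_id`).
#' @param protocol_path Optional path to a protocols CSV.
#' @inheritParams ethogram_dataset
#' @return A validated [ethogram_dataset()].
#' @seealso [write_annotations()]
#' @export
read_annotations <- function(events_path, recordings_path,
                             protocol_path = NULL,
                             on_overlap = c("error", "merge")) {
  for (p in c(events_path, recordings_path, protocol_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  # everything is read as character (attribute columns must survive a
  # write/read cycle byte-identically); the constructors coerce the typed
  # columns
  events <- readr::read_csv(
    events_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  miss <- setdiff(c("fly_id", "behaviour", "start_frame", "end_frame"),
                  names(events))
  if (length(miss) > 0) {
    stop("events file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  recordings <- readr::read_csv(
    recordings_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  miss <- setdiff(c("fly_id", "fps", "n_frames"), names(recordings))
  if (length(miss) > 0) {
    stop("recordings file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  protocols <- if (!is.null(protocol_path)) {
    readr::read_csv(
      protocol_path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  } else {
    NULL
  }
  ethogram_dataset(events, recordings, protocols, on_overlap = on_overlap)
}

#' Write an ethogram dataset to CSV
#'
#' Serialises the dataset into the documented CSV dialect:
#' `events.csv` (`fly_id`, `behaviour`, `start_frame`, `end_frame`, attribute
#' columns), `recordings.csv` (`fly_id`, `fps`, `n_frames`, `group`,
#' `protocol_id`) and `protocols.csv` (`protocol_id`, `kind`, `baseline_s`,
#' `n_stimuli`, `stim_s`, `isi_s`, `pre_s`, `constant_s`, `post_s`).
#' `read_annotations()` on the written files reproduces the dataset, and a
#' second write of the re-read dataset is byte-identical.
#'
#' @param x An `ethogram_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_annotations <- function(x, out_dir) {
  stopifnot(inherits(x, "ethogram_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir,
                                 call. = FALSE)
  paths <- c(
    events = file.path(out_dir, "events.csv"),
    recordings = file.path(out_dir, "recordings.csv"),
    protocols = file.path(out_dir, "protocols.csv")
  )
  readr::write_csv(x$bouts, paths[["events"]], progress = FALSE)
  readr::write_csv(x$recordings, paths[["recordings"]], progress = FALSE)
  readr::write_csv(x$protocols, paths[["protocols"]], progress = FALSE)
  invisible(paths)
}
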