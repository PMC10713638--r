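#' Construct an ethogram dataset
#'
#' Bundles bout annotations, per-fly recording metadata and (optionally)
#' stimulation-protocol parameters into a single validated object. Frames are
#' 0-based and bout intervals are inclusive on both ends: a one-frame bout has
#' `start_frame == end_frame`. Bouts of the *same* behaviour for the same fly
#' must not overlap or touch (frame-adjacent bouts are one bout); bouts of
#' *different* behaviours may co-occur freely (e.g. ovipositor extrusion during
#' abdominal contortions).
#'
#' @param bouts Data frame with columns `fly_id`, `behaviour`, `start_frame`,
#'   `end_frame`; any further columns are kept as bout attributes (e.g.
#'   `buried` on egg-expulsion bouts, with values `"yes"`, `"no"`,
#'   `"unknown"`).
#' @param recordings Data frame with columns `fly_id`, `fps`, `n_frames` and
#'   optionally `group` (defaults to `"all"`) and `protocol_id`.
#' @param protocols Optional data frame of stimulation-protocol parameters
#'   (see [write_annotations()] for the columns); may be `NULL`.
#' @param on_overlap What to do with overlapping or adjacent same-behaviour
#'   bouts: `"error"` (default) treats them as a data error, `"merge"` unions
#'   them into a single bout (attributes taken from the earliest bout).
#' @param validate If `TRUE` (default), run [validate_ethogram()] and abort on
#'   any violation.
#'
#' @return An object of class `ethogram_dataset`: a list with tibbles `bouts`
#'   (sorted by fly, behaviour, start frame), `recordings` and `protocols`.
#' @examples
#' d <- ethogram_dataset(
#'   bouts = data.frame(fly_id = "fly1", behaviour = "egg_expulsion",
#'                      start_frame = 100L, end_frame = 105L),
#'   recordings = data.frame(fly_id = "fly1", fps = 20, n_frames = 54000L)
#' )
#' d
#' @export
ethogram_dataset <- function(bouts, recordings, protocols = NULL,
                             on_overlap = c("error", "merge"),
                             validate = TRUE) {
  on_overlap <- match.arg(on_overlap)
  bouts <- as_bout_tbl(bouts)
  recordings <- as_recording_tbl(recordings)
  protocols <- as_protocol_tbl(protocols)

  if (on_overlap == "merge") {
    bouts <- merge_overlapping_bouts(bouts)
  }
  bouts <- dplyr::arrange(bouts, .data$fly_id, .data$behaviour,
                          .data$start_frame)

  x <- structure(
    list(bouts = bouts, recordings = recordings, protocols = protocols),
    class = "ethogram_dataset"
  )
  if (validate) {
    rep <- validate_ethogram(x)
    errs <- dplyr::filter(rep, .data$severity == "error")
    if (nrow(errs) > 0) {
      stop("invalid ethogram dataset:\n  ",
           paste(utils::head(errs$message, 10), collapse = "\n  "),
           if (nrow(errs) > 10) sprintf("\n  ... and %d more", nrow(errs) - 10),
           call. = FALSE)
    }
  }
  x
}

as_bout_tbl <- function(bouts) {
  bouts <- tibble::as_tibble(bouts)
  req <- c("fly_id", "behaviour", "start_frame", "end_frame")
  miss <- setdiff(req, names(bouts))
  if (length(miss) > 0) {
    stop("events table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bouts$fly_id <- as.character(bouts$fly_id)
  bouts$behaviour <- as.character(bouts$behaviour)
  bouts$start_frame <- as.integer(bouts$start_frame)
  bouts$end_frame <- as.integer(bouts$end_frame)
  dplyr::relocate(bouts, dplyr::all_of(req))
}

as_recording_tbl <- function(recordings) {
  recordings <- tibble::as_tibble(recordings)
  req <- c("fly_id", "fps", "n_frames")
  miss <- setdiff(req, names(recordings))
  if (length(miss) > 0) {
    stop("recordings table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  recordings$fly_id <- as.character(recordings$fly_id)
  recordings$fps <- as.numeric(recordings$fps)
  recordings$n_frames <- as.integer(recordings$n_frames)
  if (!"group" %in% names(recordings)) recordings$group <- "all"
  recordings$group <- as.character(recordings$group)
  if (!"protocol_id" %in% names(recordings)) {
    recordings$protocol_id <- NA_character_
  }
  recordings$protocol_id <- as.character(recordings$protocol_id)
  dplyr::relocate(recordings,
                  dplyr::all_of(c(req, "group", "protocol_id")))
}

protocol_tbl_cols <- c("protocol_id", "kind", "baseline_s", "n_stimuli",
                       "stim_s", "isi_s", "pre_s", "constant_s", "post_s")

as_protocol_tbl <- function(protocols) {
  if (is.null(protocols)) {
    return(tibble::tibble(
      protocol_id = character(), kind = character(),
      baseline_s = numeric(), n_stimuli = integer(), stim_s = numeric(),
      isi_s = numeric(), pre_s = numeric(), constant_s = numeric(),
      post_s = numeric()
    ))
  }
  protocols <- tibble::as_tibble(protocols)
  if (!"protocol_id" %in% names(protocols)) {
    stop("protocols table is missing required column(s): protocol_id",
         call. = FALSE)
  }
  for (col in setdiff(protocol_tbl_cols, names(protocols))) {
    protocols[[col]] <- if (col %in% c("protocol_id", "kind")) {
      NA_character_
    } else if (col == "n_stimuli") NA_integer_ else NA_real_
  }
  protocols$protocol_id <- as.character(protocols$protocol_id)
  protocols$kind <- as.character(protocols$kind)
  protocols$n_stimuli <- as.integer(protocols$n_stimuli)
  for (col in c("baseline_s", "stim_s", "isi_s", "pre_s", "constant_s",
                "post_s")) {
    protocols[[col]] <- as.numeric(protocols[[col]])
  }
  dplyr::select(protocols, dplyr::all_of(protocol_tbl_cols))
}

merge_overlapping_bouts <- function(bouts) {
  if (nrow(bouts) == 0) return(bouts)
  bouts <- dplyr::arrange(bouts, .data$fly_id, .data$behaviour,
                          .data$start_frame)
  out <- bouts |>
    dplyr::group_by(.data$fly_id, .data$behaviour) |>
    dplyr::mutate(
      # a new run starts when this bout does not overlap/touch the running end
      run = cumsum(c(TRUE, .data$start_frame[-1] >
                       cummax(.data$end_frame)[-dplyr::n()] + 1L))
    ) |>
    dplyr::group_by(.data$fly_id, .data$behaviour, .data$run) |>
    dplyr::summarise(
      start_frame = min(.data$start_frame),
      end_frame = max(.data$end_frame),
      dplyr::across(
        !dplyr::any_of(c("start_frame", "end_frame")),
        dplyr::first
      ),
      .groups = "drop"
    ) |>
    dplyr::select(-"run")
  dplyr::relocate(out, "fly_id", "behaviour", "start_frame", "end_frame")
}

#' Validate an ethogram dataset
#'
#' Checks every structural invariant of the annotation data model and returns
#' a report instead of raising conditions, so that defects are data the caller
#' can inspect. A dataset is valid iff the report contains no row with
#' `severity == "error"`. Unknown (non-canonical) behaviour labels are
#' permitted and reported with `severity == "note"`.
#'
#' Checked invariants: frame intervals well-formed (`0 <= start <= end`),
#' bouts within their recording (`end_frame < n_frames`), no overlapping or
#' frame-adjacent same-behaviour bouts per fly, every bout's `fly_id` resolves
#' to exactly one recording, every non-missing `protocol_id` resolves to a
#' protocol row, and recording metadata sane (`fps > 0`, `n_frames >= 1`).
#'
#' @param x An `ethogram_dataset` (it may have been built with
#'   `validate = FALSE`).
#' @return A tibble with columns `severity` (`"error"` or `"note"`), `rule`,
#'   `fly_id`, `behaviour`, `start_frame`, `end_frame` and `message`; zero
#'   error rows iff the dataset is valid.
#' @examples
#' d <- ethogram_dataset(
#'   data.frame(fly_id = "f1", behaviour = "burrowing",
#'              start_frame = 0L, end_frame = 10L),
#'   data.frame(fly_id = "f1", fps = 20, n_frames = 1000L)
#' )
#' validate_ethogram(d)
#' @export
validate_ethogram <- function(x) {
  stopifnot(inherits(x, "ethogram_dataset"))
  bouts <- x$bouts
  recs <- x$recordings
  rows <- list()
  add <- function(severity, rule, fly_id = NA_character_,
                  behaviour = NA_character_, start_frame = NA_integer_,
                  end_frame = NA_integer_, message) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      severity = severity, rule = rule, fly_id = fly_id,
      behaviour = behaviour, start_frame = as.integer(start_frame),
      end_frame = as.integer(end_frame), message = message
    )
  }

  dup <- recs$fly_id[duplicated(recs$fly_id)]
  for (f in unique(dup)) {
    add("error", "duplicate_recording", fly_id = f,
        message = sprintf("fly '%s' has more than one recording row", f))
  }
  bad_rec <- recs[!is.na(recs$fps) & !is.na(recs$n_frames) &
                    (recs$fps <= 0 | recs$n_frames < 1), , drop = FALSE]
  for (i in seq_len(nrow(bad_rec))) {
    add("error", "bad_recording", fly_id = bad_rec$fly_id[i],
        message = sprintf("recording for fly '%s' has fps %s, n_frames %s",
                          bad_rec$fly_id[i], bad_rec$fps[i],
                          bad_rec$n_frames[i]))
  }

  # per-bout checks, vectorised; each bout is reported under at most one rule
  nf <- recs$n_frames[match(bouts$fly_id, recs$fly_id)]
  bad_iv <- is.na(bouts$start_frame) | is.na(bouts$end_frame) |
    bouts$start_frame < 0L | bouts$start_frame > bouts$end_frame
  dangling <- !bad_iv & !bouts$fly_id %in% recs$fly_id
  out_of_range <- !bad_iv & !dangling & !is.na(nf) & bouts$end_frame >= nf
  for (i in which(bad_iv)) {
    add("error", "bad_interval", bouts$fly_id[i], bouts$behaviour[i],
        bouts$start_frame[i], bouts$end_frame[i],
        sprintf("fly '%s' %s bout [%s, %s] is not a valid frame interval",
                bouts$fly_id[i], bouts$behaviour[i], bouts$start_frame[i],
                bouts$end_frame[i]))
  }
  for (i in which(dangling)) {
    add("error", "dangling_fly", bouts$fly_id[i], bouts$behaviour[i],
        bouts$start_frame[i], bouts$end_frame[i],
        sprintf("bout references unknown fly '%s'", bouts$fly_id[i]))
  }
  for (i in which(out_of_range)) {
    add("error", "out_of_range", bouts$fly_id[i], bouts$behaviour[i],
        bouts$start_frame[i], bouts$end_frame[i],
        sprintf("fly '%s' %s bout [%d, %d] exceeds recording length %d",
                bouts$fly_id[i], bouts$behaviour[i], bouts$start_frame[i],
                bouts$end_frame[i], nf[i]))
  }

  # overlapping / frame-adjacent same-behaviour bouts (one report per pair)
  well <- bouts[!is.na(bouts$start_frame) & !is.na(bouts$end_frame) &
                  bouts$start_frame >= 0L &
                  bouts$start_frame <= bouts$end_frame, , drop = FALSE]
  if (nrow(well) > 1) {
    ov <- well |>
      dplyr::arrange(.data$fly_id, .data$behaviour, .data$start_frame,
                     .data$end_frame) |>
      dplyr::group_by(.data$fly_id, .data$behaviour) |>
      dplyr::filter(dplyr::row_number() > 1,
                    .data$start_frame <=
                      dplyr::lag(cummax(.data$end_frame)) + 1L) |>
      dplyr::ungroup()
    for (i in seq_len(nrow(ov))) {
      add("error", "overlapping_bouts", ov$fly_id[i], ov$behaviour[i],
          ov$start_frame[i], ov$end_frame[i],
          sprintf(
            "fly '%s' has overlapping or adjacent %s bouts at [%d, %d]",
            ov$fly_id[i], ov$behaviour[i], ov$start_frame[i],
            ov$end_frame[i]))
    }
  }

  known_prot <- x$protocols$protocol_id
  dang <- recs[!is.na(recs$protocol_id) &
                 !recs$protocol_id %in% known_prot, , drop = FALSE]
  for (i in seq_len(nrow(dang))) {
    add("error", "dangling_protocol", fly_id = dang$fly_id[i],
        message = sprintf("recording for fly '%s' references unknown protocol '%s'",
                          dang$fly_id[i], dang$protocol_id[i]))
  }

  unk <- unique(bouts$behaviour[!bouts$behaviour %in% canonical_behaviours])
  for (b in unk) {
    add("note", "unknown_behaviour", behaviour = b,
        message = sprintf("behaviour label '%s' is not canonical", b))
  }

  if (length(rows) == 0) {
    tibble::tibble(severity = character(), rule = character(),
                   fly_id = character(), behaviour = character(),
                   start_frame = integer(), end_frame = integer(),
                   message = character())
  } else {
    dplyr::bind_rows(rows)
  }
}

#' @export
print.ethogram_dataset <- function(x, ...) {
  cat(sprintf(
    "<ethogram_dataset: %d bouts, %d recordings, %d protocols>\n",
    nrow(x$bouts), nrow(x$recordings), nrow(x$protocols)))
  grp <- table(x$recordings$group)
  if (length(grp) > 0) {
    cat("  groups:", paste(sprintf("%s (%d)", names(grp), grp),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

# fps of one fly, with existence check
fps_of <- function(x, fly_id) {
  i <- match(fly_id, x$recordings$fly_id)
  if (is.na(i)) stop(sprintf("unknown fly '%s'", fly_id), call. = FALSE)
  x$recordings$fps[i]
}

# single fps shared by the given flies, error on mixture
pooled_fps <- function(x, fly_ids = x$recordings$fly_id) {
  fps <- unique(x$recordings$fps[x$recordings$fly_id %in% fly_ids])
  if (length(fps) != 1) {
    stop("recordings mix different fps values (",
         paste(fps, collapse = ", "),
         "); analyses pooling flies on a time axis need a single fps",
         call. = FALSE)
  }
  fps
}

fly_bouts <- function(x, fly_id, behaviour = NULL) {
  b <- x$bouts[x$bouts$fly_id == fly_id, , drop = FALSE]
  if (!is.null(behaviour)) b <- b[b$behaviour %in% behaviour, , drop = FALSE]
  dplyr::arrange(b, .data$start_frame)
}
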