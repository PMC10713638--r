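#' Inter-egg expulsion intervals
#'
#' For each fly, the interval between consecutive egg expulsions: the first
#' frame of an expulsion bout minus the last frame of the previous expulsion
#' bout. A fly with `n` expulsions contributes `n - 1` intervals; flies with
#' one or zero expulsions contribute none.
#'
#' @param x An [ethogram_dataset()].
#' @param fly Optional fly id (default: all flies).
#' @param unit `"frames"` or `"seconds"` (frames divided by the recording
#'   fps).
#' @return A tibble with columns `fly_id`, `interval_index`, `interval`.
#' @examples
#' d <- ethogram_dataset(
#'   data.frame(fly_id = "f1", behaviour = "egg_expulsion",
#'              start_frame = c(100L, 2500L, 5000L),
#'              end_frame = c(105L, 2510L, 5004L)),
#'   data.frame(fly_id = "f1", fps = 20, n_frames = 54000L)
#' )
#' inter_egg_intervals(d, unit = "seconds")
#' @export
inter_egg_intervals <- function(x, fly = NULL,
                                unit = c("frames", "seconds")) {
  stopifnot(inherits(x, "ethogram_dataset"))
  unit <- match.arg(unit)
  flies <- resolve_flies(x, fly)
  purrr::map_dfr(flies, function(f) {
    exp <- fly_bouts(x, f, "egg_expulsion")
    if (nrow(exp) <= 1) {
      return(tibble::tibble(fly_id = character(), interval_index = integer(),
                            interval = numeric()))
    }
    iv <- exp$start_frame[-1] - exp$end_frame[-nrow(exp)]
    if (unit == "seconds") iv <- iv / fps_of(x, f)
    tibble::tibble(fly_id = f, interval_index = seq_along(iv),
                   interval = as.numeric(iv))
  })
}

#' Per-bin bout or event counts
#'
#' Counts bouts of a behaviour in consecutive time bins aligned to the start
#' of each recording (e.g. eggs per 5 min, bouts per 5 min). A bout is
#' assigned to the bin containing its start frame, so a bout straddling a bin
#' boundary counts once, in its start bin. Only complete bins are returned; a
#' trailing partial bin is excluded. With `count_frames = TRUE` the literal
#' frames reading of the binned-rate formula is used instead: the number of
#' frames of the behaviour falling inside each bin.
#'
#' @inheritParams inter_egg_intervals
#' @param behaviour A behaviour label (e.g. `"egg_expulsion"` for eggs per
#'   bin).
#' @param bin_length_s Bin length in seconds (default 300, i.e. 5 min).
#' @param count_frames Count behaviour frames per bin instead of bout onsets.
#' @return A tibble with columns `fly_id`, `bin_index` (1-based),
#'   `bin_start_s`, `bin_end_s`, `count`.
#' @export
counts_per_bin <- function(x, behaviour, bin_length_s = 300, fly = NULL,
                           count_frames = FALSE) {
  stopifnot(inherits(x, "ethogram_dataset"), bin_length_s > 0)
  flies <- resolve_flies(x, fly)
  purrr::map_dfr(flies, function(f) {
    fps <- fps_of(x, f)
    n_frames <- x$recordings$n_frames[match(f, x$recordings$fly_id)]
    bin_frames <- bin_length_s * fps
    n_bins <- floor(n_frames / bin_frames)
    if (n_bins < 1) {
      stop(sprintf(
        "bin length %gs exceeds the duration of fly '%s' recording (%gs)",
        bin_length_s, f, n_frames / fps), call. = FALSE)
    }
    b <- fly_bouts(x, f, behaviour)
    counts <- if (count_frames) {
      vapply(seq_len(n_bins), function(k) {
        lo <- (k - 1) * bin_frames
        hi <- k * bin_frames - 1      # inclusive frame range of bin k
        sum(pmax(0, pmin(b$end_frame, hi) - pmax(b$start_frame, lo) + 1))
      }, numeric(1))
    } else {
      bin_of <- floor(b$start_frame / bin_frames) + 1
      vapply(seq_len(n_bins), function(k) sum(bin_of == k), numeric(1))
    }
    tibble::tibble(
      fly_id = f, bin_index = seq_len(n_bins),
      bin_start_s = (seq_len(n_bins) - 1) * bin_length_s,
      bin_end_s = seq_len(n_bins) * bin_length_s,
      count = counts
    )
  })
}

#' Behaviour bouts per egg laid
#'
#' Number of bouts of a behaviour divided by the number of egg expulsions of
#' the same fly over the whole recording (the per-egg normalisation used when
#' comparing motor-element counts between genotypes). Undefined (`NA`, with a
#' warning) for flies that laid no egg; such flies should be excluded from
#' group summaries.
#'
#' @inheritParams counts_per_bin
#' @return A tibble with columns `fly_id`, `n_bouts`, `n_eggs`, `value`.
#' @export
bouts_per_egg <- function(x, behaviour, fly = NULL, count_frames = FALSE) {
  stopifnot(inherits(x, "ethogram_dataset"))
  flies <- resolve_flies(x, fly)
  out <- purrr::map_dfr(flies, function(f) {
    b <- fly_bouts(x, f, behaviour)
    n_bouts <- if (count_frames) {
      sum(b$end_frame - b$start_frame + 1)
    } else {
      nrow(b)
    }
    n_eggs <- nrow(fly_bouts(x, f, "egg_expulsion"))
    tibble::tibble(
      fly_id = f, n_bouts = as.numeric(n_bouts), n_eggs = n_eggs,
      value = if (n_eggs > 0) n_bouts / n_eggs else NA_real_
    )
  })
  if (any(is.na(out$value))) {
    warning(sprintf(
      "%d fly(s) laid zero eggs; their per-egg values are undefined (NA): %s",
      sum(is.na(out$value)),
      paste(out$fly_id[is.na(out$value)], collapse = ", ")), call. = FALSE)
  }
  out
}

#' Mean bout duration in seconds
#'
#' Mean over a fly's bouts of the bout duration, where the duration of a bout
#' is the last frame minus the first frame, converted to seconds. (Under this
#' subtraction convention a one-frame bout has duration 0 s.) Undefined
#' (`NA`) when the fly has no bout of that behaviour.
#'
#' @inheritParams counts_per_bin
#' @return A tibble with columns `fly_id`, `n_bouts`, `value` (seconds).
#' @export
mean_bout_duration <- function(x, behaviour, fly = NULL) {
  stopifnot(inherits(x, "ethogram_dataset"))
  flies <- resolve_flies(x, fly)
  purrr::map_dfr(flies, function(f) {
    b <- fly_bouts(x, f, behaviour)
    fps <- fps_of(x, f)
    tibble::tibble(
      fly_id = f, n_bouts = nrow(b),
      value = if (nrow(b) > 0) {
        mean((b$end_frame - b$start_frame) / fps)
      } else {
        NA_real_
      }
    )
  })
}

#' Proportion of eggs not buried
#'
#' Per fly, the number of eggs not buried over the total number of eggs whose
#' burial status could be determined. Egg-expulsion bouts carry the status in
#' a `buried` attribute column with values `"yes"`, `"no"` or `"unknown"`;
#' unknown-status expulsions are excluded from both numerator and denominator.
#' Undefined (`NA`) when no expulsion has a determined status.
#'
#' @inheritParams inter_egg_intervals
#' @return A tibble with columns `fly_id`, `n_not_buried`, `n_determined`,
#'   `value`.
#' @export
proportion_eggs_not_buried <- function(x, fly = NULL) {
  stopifnot(inherits(x, "ethogram_dataset"))
  flies <- resolve_flies(x, fly)
  purrr::map_dfr(flies, function(f) {
    exp <- fly_bouts(x, f, "egg_expulsion")
    status <- if ("buried" %in% names(exp)) exp$buried else
      rep("unknown", nrow(exp))
    status[is.na(status)] <- "unknown"
    det <- status[status %in% c("yes", "no")]
    tibble::tibble(
      fly_id = f,
      n_not_buried = sum(det == "no"),
      n_determined = length(det),
      value = if (length(det) > 0) sum(det == "no") / length(det) else
        NA_real_
    )
  })
}

#' Population-level proportion of flagged counts
#'
#' Shared helper for population proportions such as the percentage of females
#' laying eggs, or of dissected reproductive systems with eggs jammed in the
#' lateral oviducts: `n_flagged / n_total`, returned in `[0, 1]` (multiply by
#' 100 for reporting as a percentage). Vectorised over pairs.
#'
#' @param n_flagged Non-negative count(s) with the property of interest.
#' @param n_total Positive total count(s); must be `>= n_flagged`.
#' @return Numeric proportion(s) in `[0, 1]`.
#' @examples
#' proportion_with_flag(17, 17)
#' proportion_with_flag(0, 24)
#' @export
proportion_with_flag <- function(n_flagged, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive", call. = FALSE)
  if (any(n_flagged < 0) || any(n_flagged > n_total)) {
    stop("n_flagged must lie in [0, n_total]", call. = FALSE)
  }
  n_flagged / n_total
}

#' Per-fly metric table
#'
#' Computes the standard per-fly metrics for a set of behaviours and returns
#' them in one tidy table: eggs per bin, bouts per bin, bouts per egg, mean
#' bout duration and proportion of eggs not buried. Undefined values are kept
#' as explicit rows with `defined = FALSE`, never dropped.
#'
#' @inheritParams counts_per_bin
#' @param behaviours Behaviours to tabulate (default: all canonical labels).
#' @return A tibble with columns `fly_id`, `group`, `metric`, `window`,
#'   `value`, `defined`. `window` is a bin label (`"bin1"`, ...) for binned
#'   metrics and `"whole"` otherwise.
#' @export
bout_metric_table <- function(x, behaviours = canonical_behaviours,
                              bin_length_s = 300, count_frames = FALSE) {
  stopifnot(inherits(x, "ethogram_dataset"))
  if (nrow(x$recordings) == 0) {
    stop("dataset contains no recordings; no metrics to compute",
         call. = FALSE)
  }
  grp <- setNames(x$recordings$group, x$recordings$fly_id)
  row_tbl <- function(tbl, metric, window) {
    tibble::tibble(
      fly_id = tbl$fly_id, group = unname(grp[tbl$fly_id]),
      metric = metric, window = window,
      value = tbl$value, defined = !is.na(tbl$value)
    )
  }
  pieces <- list()
  eggs <- counts_per_bin(x, "egg_expulsion", bin_length_s,
                         count_frames = FALSE)
  pieces[[length(pieces) + 1]] <- tibble::tibble(
    fly_id = eggs$fly_id, group = unname(grp[eggs$fly_id]),
    metric = "eggs_per_bin", window = paste0("bin", eggs$bin_index),
    value = eggs$count, defined = TRUE
  )
  for (beh in setdiff(behaviours, "egg_expulsion")) {
    bins <- counts_per_bin(x, beh, bin_length_s, count_frames = count_frames)
    pieces[[length(pieces) + 1]] <- tibble::tibble(
      fly_id = bins$fly_id, group = unname(grp[bins$fly_id]),
      metric = paste0("bouts_per_bin_", beh),
      window = paste0("bin", bins$bin_index),
      value = bins$count, defined = TRUE
    )
    pieces[[length(pieces) + 1]] <- row_tbl(
      suppressWarnings(bouts_per_egg(x, beh, count_frames = count_frames)),
      paste0("bouts_per_egg_", beh), "whole")
    pieces[[length(pieces) + 1]] <- row_tbl(
      mean_bout_duration(x, beh), paste0("mean_bout_duration_", beh),
      "whole")
  }
  pieces[[length(pieces) + 1]] <- row_tbl(
    proportion_eggs_not_buried(x), "proportion_eggs_not_buried", "whole")
  iei <- inter_egg_intervals(x, unit = "seconds") |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::summarise(value = median(.data$interval), .groups = "drop")
  all_flies <- tibble::tibble(fly_id = x$recordings$fly_id)
  iei <- dplyr::left_join(all_flies, iei, by = "fly_id")
  pieces[[length(pieces) + 1]] <- row_tbl(
    iei, "median_inter_egg_interval_s", "whole")
  dplyr::bind_rows(pieces)
}

resolve_flies <- function(x, fly) {
  if (is.null(fly)) return(x$recordings$fly_id)
  bad <- setdiff(fly, x$recordings$fly_id)
  if (length(bad) > 0) {
    stop("unknown fly id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  fly
}
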