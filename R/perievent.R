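#' Peri-event behaviour probability around egg expulsion
#'
#' For each frame offset in `-window .. +window` around the last frame of
#' every egg-expulsion bout, the probability that a bout of `behaviour` covers
#' that frame. Offset 0 is the expulsion bout's last frame (the moment the egg
#' leaves); the expulsion's own earlier frames appear at negative offsets.
#' Expulsions whose reference frame lies within `window` frames of the start
#' or end of their recording are excluded, so every included event has a full
#' window. By default events are pooled across flies before normalising by the
#' total number of included expulsions; `per_fly = TRUE` instead computes one
#' curve per fly and averages them, reporting the across-fly standard error of
#' the mean.
#'
#' @inheritParams counts_per_bin
#' @param window Half-width of the window in frames (default 1200, i.e. 1 min
#'   at 20 fps).
#' @param per_fly Average per-fly curves instead of pooling events.
#' @return A tibble of class `perievent_curve` with columns `offset`
#'   (frames), `offset_s` (seconds), `probability` and, for `per_fly = TRUE`,
#'   `sem`. Attributes: `behaviour`, `window`, `n_events`, `fps` and (per
#'   fly) `n_flies`.
#' @examples
#' d <- ethogram_dataset(
#'   data.frame(fly_id = "f1",
#'              behaviour = c("egg_expulsion", "grooming_terminalia"),
#'              start_frame = c(2000L, 2010L), end_frame = c(2005L, 2050L)),
#'   data.frame(fly_id = "f1", fps = 20, n_frames = 54000L)
#' )
#' cv <- perievent_probability(d, "grooming_terminalia", window = 100)
#' range(cv$probability)
#' @export
perievent_probability <- function(x, behaviour, window = 1200,
                                  fly = NULL, per_fly = FALSE) {
  stopifnot(inherits(x, "ethogram_dataset"), window >= 1)
  window <- as.integer(window)
  flies <- resolve_flies(x, fly)
  fps <- pooled_fps(x, flies)
  offsets <- seq.int(-window, window)

  per_fly_counts <- purrr::map(flies, function(f) {
    nf <- x$recordings$n_frames[match(f, x$recordings$fly_id)]
    refs <- fly_bouts(x, f, "egg_expulsion")$end_frame
    refs <- refs[refs >= window & refs <= nf - 1L - window]
    if (length(refs) == 0) {
      return(list(n = 0L, counts = numeric(length(offsets))))
    }
    beh <- fly_bouts(x, f, behaviour)
    counts <- numeric(length(offsets))
    for (r in refs) {
      hit <- beh[beh$end_frame >= r - window &
                   beh$start_frame <= r + window, , drop = FALSE]
      covered <- logical(length(offsets))
      for (i in seq_len(nrow(hit))) {
        lo <- max(hit$start_frame[i] - r, -window)
        hi <- min(hit$end_frame[i] - r, window)
        covered[(lo + window + 1L):(hi + window + 1L)] <- TRUE
      }
      counts <- counts + covered
    }
    list(n = length(refs), counts = counts)
  })

  n_events <- sum(purrr::map_int(per_fly_counts, "n"))
  if (n_events == 0) {
    stop("no egg expulsion lies at least `window` frames from both ",
         "recording ends; every event fell in the edge-exclusion zones",
         call. = FALSE)
  }

  if (!per_fly) {
    total <- Reduce(`+`, purrr::map(per_fly_counts, "counts"))
    out <- tibble::tibble(
      offset = offsets, offset_s = offsets / fps,
      probability = total / n_events
    )
  } else {
    keep <- purrr::keep(per_fly_counts, ~ .x$n > 0)
    mat <- do.call(rbind, purrr::map(keep, ~ .x$counts / .x$n))
    out <- tibble::tibble(
      offset = offsets, offset_s = offsets / fps,
      probability = colMeans(mat),
      sem = apply(mat, 2, sd) / sqrt(nrow(mat))
    )
    attr(out, "n_flies") <- nrow(mat)
  }
  attr(out, "behaviour") <- behaviour
  attr(out, "window") <- window
  attr(out, "n_events") <- n_events
  attr(out, "fps") <- fps
  class(out) <- c("perievent_curve", class(out))
  out
}

#' @export
print.perievent_curve <- function(x, ...) {
  cat(sprintf(
    "<perievent_curve: %s, window +/-%d frames, %d events>\n",
    attr(x, "behaviour"), attr(x, "window"), attr(x, "n_events")))
  NextMethod()
}

#' Plot a peri-event probability curve
#'
#' Probability of the behaviour as a function of time relative to egg
#' expulsion (vertical line at 0). Per-fly curves get a shaded across-fly
#' s.e.m. ribbon.
#'
#' @param object A `perievent_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perievent_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$offset_s / 60,
                                    y = .data$probability)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time from egg expulsion (min)", y = "Probability",
      title = attr(object, "behaviour"),
      subtitle = sprintf("n = %d egg expulsions", attr(object, "n_events"))
    ) +
    ggplot2::theme_minimal()
  if ("sem" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$probability - .data$sem),
                   ymax = pmin(1, .data$probability + .data$sem)),
      alpha = 0.25, fill = "#2166ac")
  }
  p
}
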