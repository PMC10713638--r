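#' Build a pulsed optogenetic stimulation protocol
#'
#' A baseline (light-OFF) period followed by `n_stimuli` light-ON stimuli
#' separated by inter-stimulus intervals (ISIs). The default values are the
#' standard activation protocol: 1 min baseline, six 10-s stimuli, 20-s ISIs.
#' There is no trailing ISI after the last stimulus unless requested, so the
#' total duration is `baseline_s + n * stim_s + (n - 1) * isi_s` by default.
#'
#' @param baseline_s Baseline duration in seconds.
#' @param n_stimuli Number of light-ON stimuli.
#' @param stim_s Stimulus duration in seconds.
#' @param isi_s Inter-stimulus interval in seconds.
#' @param trailing_isi Append an ISI after the last stimulus.
#' @param protocol_id Identifier used when serialising.
#' @return An object of class `stim_protocol`: a tibble of epochs with
#'   columns `epoch_index`, `kind` (`"pre"`, `"stim"`, `"isi"`, `"post"`),
#'   `stimulus_index` (`NA` for OFF epochs), `start_s`, `end_s`; attributes
#'   `protocol_id`, `style` and the constructor parameters.
#' @examples
#' p <- build_protocol(60, 6, 10, 20)
#' stim_windows(p, fps = 20)   # stimulus 1 is ON at frames [1200, 1400)
#' @export
build_protocol <- function(baseline_s = 60, n_stimuli = 6, stim_s = 10,
                           isi_s = 20, trailing_isi = FALSE,
                           protocol_id = "pulsed") {
  stopifnot(baseline_s > 0, n_stimuli >= 1, stim_s > 0, isi_s > 0)
  kinds <- c("pre")
  stim_idx <- c(NA_integer_)
  durs <- c(baseline_s)
  for (k in seq_len(n_stimuli)) {
    kinds <- c(kinds, "stim")
    stim_idx <- c(stim_idx, k)
    durs <- c(durs, stim_s)
    if (k < n_stimuli || trailing_isi) {
      kinds <- c(kinds, "isi")
      stim_idx <- c(stim_idx, k)   # ISI k follows stimulus k
      durs <- c(durs, isi_s)
    }
  }
  new_stim_protocol(kinds, stim_idx, durs, protocol_id, style = "pulsed",
                    params = list(baseline_s = baseline_s,
                                  n_stimuli = as.integer(n_stimuli),
                                  stim_s = stim_s, isi_s = isi_s))
}

#' Build a constant-light silencing protocol
#'
#' A pre-stimulation period, one constant light-ON period and a
#' post-stimulation period. The defaults are the standard acute-silencing
#' protocol: 10 min pre, 15 min constant stimulation, 5 min post.
#'
#' @param pre_s,constant_s,post_s Epoch durations in seconds.
#' @inheritParams build_protocol
#' @return A `stim_protocol` with epochs `pre`, `stim`, `post`.
#' @export
build_constant_protocol <- function(pre_s = 600, constant_s = 900,
                                    post_s = 300,
                                    protocol_id = "constant") {
  stopifnot(pre_s > 0, constant_s > 0, post_s > 0)
  new_stim_protocol(
    kinds = c("pre", "stim", "post"),
    stim_idx = c(NA_integer_, 1L, NA_integer_),
    durs = c(pre_s, constant_s, post_s),
    protocol_id = protocol_id, style = "constant",
    params = list(pre_s = pre_s, constant_s = constant_s, post_s = post_s)
  )
}

new_stim_protocol <- function(kinds, stim_idx, durs, protocol_id, style,
                              params) {
  ends <- cumsum(durs)
  epochs <- tibble::tibble(
    epoch_index = seq_along(kinds),
    kind = kinds,
    stimulus_index = as.integer(stim_idx),
    start_s = c(0, ends[-length(ends)]),
    end_s = ends
  )
  structure(epochs,
            protocol_id = protocol_id, style = style, params = params,
            class = c("stim_protocol", class(epochs)))
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol '%s' (%s): %d epochs, %.0f s total>\n",
              attr(x, "protocol_id"), attr(x, "style"), nrow(x),
              max(x$end_s)))
  NextMethod()
}

#' Epoch and stimulus frame windows of a protocol
#'
#' Converts the protocol's epoch boundaries from seconds to half-open frame
#' windows `[start_frame, end_frame_excl)` at a given frame rate. Boundaries
#' are `round(cumulative_seconds * fps)`, so the windows tile the protocol
#' without gap or overlap.
#'
#' @param protocol A `stim_protocol`.
#' @param fps Frames per second of the recording.
#' @return `epoch_windows()`: the epoch tibble plus `start_frame`,
#'   `end_frame_excl`; `stim_windows()`: only the light-ON rows, keyed by
#'   `stimulus_index`.
#' @export
epoch_windows <- function(protocol, fps) {
  stopifnot(inherits(protocol, "stim_protocol"), fps > 0)
  bnd <- round(c(0, protocol$end_s) * fps)
  out <- tibble::as_tibble(protocol)
  out$start_frame <- as.integer(bnd[-length(bnd)])
  out$end_frame_excl <- as.integer(bnd[-1])
  out
}

#' @rdname epoch_windows
#' @export
stim_windows <- function(protocol, fps) {
  w <- epoch_windows(protocol, fps)
  dplyr::select(w[w$kind == "stim", , drop = FALSE],
                "stimulus_index", "start_frame", "end_frame_excl")
}

#' Percentage of stimulations with a behaviour
#'
#' A stimulus "has" the behaviour when at least `min_overlap_frames` frames
#' of some bout of that behaviour overlap the stimulus's light-ON window
#' (optionally requiring the bout onset to fall inside the window). The
#' proportion pools stimuli across all flies of the group.
#'
#' @inheritParams counts_per_bin
#' @param protocol A `stim_protocol`.
#' @param group Optional recording group to restrict to (default: all flies).
#' @param min_overlap_frames Minimum bout/window overlap, in frames.
#' @param require_onset_inside Require the bout to *start* inside the ON
#'   window.
#' @return A list with `proportion` (in `[0, 1]`), `n_stimuli`,
#'   `n_responded` and `outcomes`, a tibble with one row per (fly, stimulus):
#'   `fly_id`, `stimulus_index`, `responded`, `response_onset_frame` (first
#'   overlapping frame, `NA` when no response).
#' @export
pct_stimulations_with_behaviour <- function(x, behaviour, protocol,
                                            group = NULL,
                                            min_overlap_frames = 1,
                                            require_onset_inside = FALSE) {
  stopifnot(inherits(x, "ethogram_dataset"))
  flies <- group_flies(x, group)
  outcomes <- purrr::map_dfr(flies, function(f) {
    fps <- fps_of(x, f)
    sw <- stim_windows(protocol, fps)
    b <- fly_bouts(x, f, behaviour)
    purrr::map_dfr(seq_len(nrow(sw)), function(k) {
      a <- sw$start_frame[k]
      z <- sw$end_frame_excl[k]
      ov <- pmin(b$end_frame, z - 1L) - pmax(b$start_frame, a) + 1L
      hit <- ov >= min_overlap_frames
      if (require_onset_inside) hit <- hit & b$start_frame >= a &
          b$start_frame < z
      responded <- any(hit)
      tibble::tibble(
        fly_id = f, stimulus_index = sw$stimulus_index[k],
        responded = responded,
        response_onset_frame = if (responded) {
          as.integer(min(pmax(b$start_frame[hit], a)))
        } else {
          NA_integer_
        }
      )
    })
  })
  list(
    proportion = mean(outcomes$responded),
    n_stimuli = nrow(outcomes),
    n_responded = sum(outcomes$responded),
    outcomes = outcomes
  )
}

#' Allocation of egg expulsions to protocol epochs
#'
#' Assigns each egg expulsion to the protocol epoch whose half-open frame
#' window contains the expulsion's end frame (the expulsion moment), and
#' reports the percentage of eggs per epoch. Percentages are over all eggs
#' expelled within the protocol period and sum to 100. Eggs expelled after
#' the protocol ended are excluded and counted in the `n_outside` attribute.
#'
#' @inheritParams pct_stimulations_with_behaviour
#' @return A tibble with one row per epoch: `epoch_index`, `kind`,
#'   `stimulus_index`, `n_eggs`, `pct`.
#' @export
egg_allocation <- function(x, protocol, group = NULL) {
  stopifnot(inherits(x, "ethogram_dataset"))
  flies <- group_flies(x, group)
  fps <- pooled_fps(x, flies)
  ew <- epoch_windows(protocol, fps)
  ends <- x$bouts$end_frame[x$bouts$fly_id %in% flies &
                              x$bouts$behaviour == "egg_expulsion"]
  epoch_of <- findInterval(ends, ew$start_frame)   # 0 = before protocol
  inside <- epoch_of >= 1 & ends < max(ew$end_frame_excl)
  if (sum(inside) == 0) {
    stop("no egg expulsion falls within the protocol period", call. = FALSE)
  }
  n_eggs <- vapply(ew$epoch_index,
                   function(k) sum(epoch_of[inside] == k), numeric(1))
  out <- tibble::tibble(
    epoch_index = ew$epoch_index, kind = ew$kind,
    stimulus_index = ew$stimulus_index,
    n_eggs = as.integer(n_eggs),
    pct = 100 * n_eggs / sum(n_eggs)
  )
  attr(out, "n_outside") <- sum(!inside)
  out
}

#' Latency from first stimulus onset to first egg expulsion
#'
#' Per fly: the start frame of the first egg expulsion at or after the first
#' stimulus onset, minus that onset frame, converted to seconds. `NA` when
#' the fly expels no egg after the stimulus onset.
#'
#' @inheritParams pct_stimulations_with_behaviour
#' @return A tibble with columns `fly_id`, `latency_s`.
#' @export
latency_to_expulsion <- function(x, protocol, fly = NULL) {
  stopifnot(inherits(x, "ethogram_dataset"))
  flies <- resolve_flies(x, fly)
  purrr::map_dfr(flies, function(f) {
    fps <- fps_of(x, f)
    onset <- stim_windows(protocol, fps)$start_frame[1]
    starts <- fly_bouts(x, f, "egg_expulsion")$start_frame
    starts <- starts[starts >= onset]
    tibble::tibble(
      fly_id = f,
      latency_s = if (length(starts) > 0) (min(starts) - onset) / fps else
        NA_real_
    )
  })
}

group_flies <- function(x, group) {
  flies <- if (is.null(group)) {
    x$recordings$fly_id
  } else {
    x$recordings$fly_id[x$recordings$group %in% group]
  }
  if (length(flies) == 0) {
    stop("no fly in group ",
         if (is.null(group)) "(dataset is empty)" else
           paste0("'", paste(group, collapse = ","), "'"),
         call. = FALSE)
  }
  flies
}

# serialise protocols into the dataset's protocols table
protocol_param_row <- function(protocol) {
  p <- attr(protocol, "params")
  tibble::tibble(
    protocol_id = attr(protocol, "protocol_id"),
    kind = attr(protocol, "style"),
    baseline_s = p$baseline_s %||% NA_real_,
    n_stimuli = p$n_stimuli %||% NA_integer_,
    stim_s = p$stim_s %||% NA_real_,
    isi_s = p$isi_s %||% NA_real_,
    pre_s = p$pre_s %||% NA_real_,
    constant_s = p$constant_s %||% NA_real_,
    post_s = p$post_s %||% NA_real_
  )
}

#' @importFrom rlang %||%
NULL
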