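#' Configuration for the egg-laying ethogram simulator
#'
#' Parameters of the seeded semi-Markov generator. The defaults encode the
#' qualitative structure of wild-type egg-laying: a three-phase cycle in
#' which egg deposition is always followed by abdominal contortions,
#' contortions are followed by deposition or exploration with equal
#' probability, and exploration always returns to deposition; a fixed motor
#' sequence within each deposition (ovipositor contact, burrowing, egg
#' pushing, egg expulsion, abdomen curling, optional grooming of the
#' terminalia); 94% of eggs buried; and dwell/duration parameters calibrated
#' so that the per-fly median inter-egg expulsion interval falls in the 2-3
#' minute band over 45-min recordings at 20 fps.
#'
#' All duration and dwell distributions are log-normal (positive and
#' right-skewed, matching the long-tailed scatter of real inter-event
#' intervals); `meanlog` is the log of the median in seconds. Inter-element
#' gaps inside a deposition sequence are capped at `max_gap_s` so the
#' sequence is genuinely continuous and always chains to its expulsion under
#' the default linkage gap; phases are separated by a buffer of at least
#' `min_buffer_s` so that exploration contacts never chain into the next
#' deposition.
#'
#' @param transition 3x3 row-stochastic matrix with zero diagonal; rows and
#'   columns ordered deposition, contortions, exploration.
#' @param dwell Named list of `c(meanlog, sdlog)` for the `contortions` and
#'   `exploration` phase dwell times (seconds).
#' @param template Tibble with columns `element`, `meanlog`, `sdlog`: the
#'   deposition-sequence elements, in order, with their duration
#'   distributions.
#' @param gap `c(meanlog, sdlog)` of the within-deposition inter-element gap.
#' @param max_gap_s Hard cap on within-deposition gaps (seconds).
#' @param buffer `c(meanlog, sdlog)` of the between-phase buffer.
#' @param min_buffer_s Hard floor on the between-phase buffer (seconds).
#' @param exploration_contact,exploration_gap `c(meanlog, sdlog)` of
#'   exploration ovipositor-contact durations and inter-contact gaps; gaps
#'   are floored at `min_exploration_gap_s`.
#' @param min_exploration_gap_s Floor on exploration inter-contact gaps.
#' @param p_grooming_after_expulsion Probability that a deposition ends with
#'   grooming of the terminalia (grooming is optional).
#' @param p_burrow_in_exploration Probability that an exploration contact is
#'   accompanied by burrowing.
#' @param p_buried Probability that an expelled egg is buried.
#' @param proboscis_rate_per_min Rate of background proboscis-extension
#'   bouts (per minute), generated as a Poisson-like renewal process over the
#'   whole recording.
#' @param proboscis_duration `c(meanlog, sdlog)` of proboscis bout durations.
#' @param fps Frames per second.
#' @param recording_length_s Recording length in seconds.
#' @param n_flies Number of flies per dataset.
#' @param group Group label written into the recordings table.
#' @param start_phase Phase in which each fly starts.
#' @param seed Master seed; per-fly seeds are derived from it.
#' @return A validated list of class `simulator_config`.
#' @export
simulator_config <- function(
    transition = default_transition_matrix(),
    dwell = list(contortions = c(meanlog = log(75), sdlog = 0.35),
                 exploration = c(meanlog = log(40), sdlog = 0.45)),
    template = default_deposition_template(),
    gap = c(meanlog = log(0.8), sdlog = 0.3),
    max_gap_s = 1.8,
    buffer = c(meanlog = log(3), sdlog = 0.2),
    min_buffer_s = 2.5,
    exploration_contact = c(meanlog = log(5), sdlog = 0.4),
    exploration_gap = c(meanlog = log(8), sdlog = 0.4),
    min_exploration_gap_s = 3,
    p_grooming_after_expulsion = 0.5,
    p_burrow_in_exploration = 0.5,
    p_buried = 0.94,
    proboscis_rate_per_min = 1,
    proboscis_duration = c(meanlog = log(2), sdlog = 0.4),
    fps = 20,
    recording_length_s = 2700,
    n_flies = 10,
    group = "simulated",
    start_phase = "exploration",
    seed = 1L) {
  cfg <- structure(
    list(transition = transition, dwell = dwell, template = template,
         gap = gap, max_gap_s = max_gap_s, buffer = buffer,
         min_buffer_s = min_buffer_s,
         exploration_contact = exploration_contact,
         exploration_gap = exploration_gap,
         min_exploration_gap_s = min_exploration_gap_s,
         p_grooming_after_expulsion = p_grooming_after_expulsion,
         p_burrow_in_exploration = p_burrow_in_exploration,
         p_buried = p_buried,
         proboscis_rate_per_min = proboscis_rate_per_min,
         proboscis_duration = proboscis_duration,
         fps = fps, recording_length_s = recording_length_s,
         n_flies = as.integer(n_flies), group = group,
         start_phase = start_phase, seed = as.integer(seed)),
    class = "simulator_config"
  )
  validate_simulator_config(cfg)
  cfg
}

#' @rdname simulator_config
#' @export
default_transition_matrix <- function() {
  m <- matrix(c(0, 1, 0,
                0.5, 0, 0.5,
                1, 0, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(egg_laying_phases, egg_laying_phases))
  m
}

#' @rdname simulator_config
#' @export
default_deposition_template <- function() {
  tibble::tibble(
    element = c("ovipositor_contact", "burrowing", "egg_pushing",
                "egg_expulsion", "abdomen_curling"),
    meanlog = log(c(5, 10, 8, 1.5, 5)),
    sdlog = c(0.4, 0.4, 0.35, 0.3, 0.35)
  )
}

validate_simulator_config <- function(cfg) {
  tm <- cfg$transition
  if (!is.matrix(tm) || !all(dim(tm) == c(3, 3))) {
    stop("transition must be a 3x3 matrix", call. = FALSE)
  }
  if (any(abs(rowSums(tm) - 1) > 1e-9)) {
    stop("transition rows must sum to 1", call. = FALSE)
  }
  if (any(diag(tm) != 0)) {
    stop("transition diagonal must be zero (phases are run-length ",
         "collapsed, so self-transitions cannot occur)", call. = FALSE)
  }
  if (any(tm < 0 | tm > 1)) {
    stop("transition entries must be probabilities in [0, 1]", call. = FALSE)
  }
  probs <- c(cfg$p_grooming_after_expulsion, cfg$p_burrow_in_exploration,
             cfg$p_buried)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  pos <- c(cfg$fps, cfg$recording_length_s, cfg$n_flies, cfg$max_gap_s,
           cfg$min_buffer_s, cfg$min_exploration_gap_s,
           cfg$gap[["sdlog"]], cfg$buffer[["sdlog"]],
           unlist(lapply(cfg$dwell, `[[`, "sdlog")), cfg$template$sdlog)
  if (any(pos <= 0)) {
    stop("fps, lengths, counts and sdlog parameters must be positive",
         call. = FALSE)
  }
  if (!cfg$start_phase %in% egg_laying_phases) {
    stop("start_phase must be one of: ",
         paste(egg_laying_phases, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

rln <- function(p) rlnorm(1, p[["meanlog"]], p[["sdlog"]])

#' Simulate one fly's egg-laying ethogram
#'
#' Runs the semi-Markov generator for a single fly: phases alternate by
#' sampling the transition matrix and dwell-time distributions; each
#' deposition phase instantiates the template elements in order, always
#' ending in one egg expulsion; each contortions phase emits one
#' abdominal-contortions bout spanning its dwell; each exploration phase
#' emits ovipositor-contact bouts (optionally accompanied by burrowing) that
#' never chain to an expulsion. A deposition whose expulsion would start at
#' or after the end of the recording is dropped wholesale, so the emitted
#' annotations and the ground-truth phase sequence stay consistent. Identical
#' `(config, fly_seed)` gives identical output.
#'
#' @param config A [simulator_config()].
#' @param fly_seed Integer seed for this fly.
#' @param fly_id Identifier written into the bout rows.
#' @return A list with `bouts` (tibble: `fly_id`, `behaviour`,
#'   `start_frame`, `end_frame`, `buried`), `phases` (ground-truth phase
#'   sequence: `fly_id`, `phase`, `onset_frame`) and `eggs` (`fly_id`,
#'   `start_frame`, `end_frame`, `buried`).
#' @export
simulate_fly <- function(config, fly_seed, fly_id = "fly1") {
  stopifnot(inherits(config, "simulator_config"))
  validate_simulator_config(config)
  withr::local_seed(as.integer(fly_seed))

  fps <- config$fps
  T_s <- config$recording_length_s
  n_frames <- as.integer(round(T_s * fps))
  to_frames <- function(ts, dur) {
    s <- as.integer(round(ts * fps))
    e <- s + max(1L, as.integer(round(dur * fps))) - 1L
    c(s, min(e, n_frames - 1L))
  }

  bouts <- list()
  phases <- list()
  eggs <- list()
  emit <- function(behaviour, ts, dur, buried = NA_character_) {
    if (ts >= T_s) return(invisible(NULL))
    fr <- to_frames(ts, dur)
    bouts[[length(bouts) + 1]] <<- list(
      behaviour = behaviour, start_frame = fr[1], end_frame = fr[2],
      buried = buried)
    invisible(fr)
  }
  gap_s <- function() min(rln(config$gap), config$max_gap_s)
  buffer_s <- function() max(rln(config$buffer), config$min_buffer_s)

  phase <- config$start_phase
  t <- buffer_s()          # settling time before the first phase
  t_free <- 0              # latest end of any emitted bout

  while (t < T_s) {
    if (phase == "deposition") {
      # pre-sample the whole sequence so a truncated deposition (expulsion
      # at/after the recording end) can be dropped without emitting anything
      tpl <- config$template
      durs <- vapply(seq_len(nrow(tpl)), function(i)
        rln(c(meanlog = tpl$meanlog[i], sdlog = tpl$sdlog[i])), numeric(1))
      gaps <- vapply(seq_len(nrow(tpl) - 1), function(i) gap_s(), numeric(1))
      starts <- t + cumsum(c(0, durs[-length(durs)] + gaps))
      i_exp <- match("egg_expulsion", tpl$element)
      if (starts[i_exp] >= T_s) break
      buried <- if (runif(1) < config$p_buried) "yes" else "no"
      for (i in seq_len(nrow(tpl))) {
        emit(tpl$element[i], starts[i],
             durs[i], buried = if (i == i_exp) buried else NA_character_)
      }
      exp_fr <- to_frames(starts[i_exp], durs[i_exp])
      eggs[[length(eggs) + 1]] <- list(start_frame = exp_fr[1],
                                       end_frame = exp_fr[2],
                                       buried = buried)
      phases[[length(phases) + 1]] <- list(phase = "deposition",
                                           onset_frame = exp_fr[1])
      t <- starts[length(starts)] + durs[length(durs)]
      if (runif(1) < config$p_grooming_after_expulsion) {
        g <- gap_s()
        d <- rln(c(meanlog = log(10), sdlog = 0.4))
        emit("grooming_terminalia", t + g, d)
        t <- t + g + d
      }
      t_free <- max(t_free, t)
    } else if (phase == "contortions") {
      d <- rln(config$dwell$contortions)
      fr <- emit("abdominal_contortions", t, d)
      if (!is.null(fr)) {
        phases[[length(phases) + 1]] <- list(phase = "contortions",
                                             onset_frame = fr[1])
      }
      t <- t + d
      t_free <- max(t_free, t)
    } else { # exploration
      dwell <- rln(config$dwell$exploration)
      t_stop <- t + dwell
      first <- TRUE
      while (t < t_stop && t < T_s) {
        cdur <- rln(config$exploration_contact)
        fr <- emit("ovipositor_contact", t, cdur)
        if (!is.null(fr) && first) {
          phases[[length(phases) + 1]] <- list(phase = "exploration",
                                               onset_frame = fr[1])
          first <- FALSE
        }
        t_free <- max(t_free, t + cdur)
        if (runif(1) < config$p_burrow_in_exploration) {
          bstart <- t + 0.5 * cdur
          # cap so the burrow ends well before the next contact's burrow
          bdur <- min(rln(c(meanlog = log(4), sdlog = 0.4)),
                      0.5 * cdur + 2.5)
          emit("burrowing", bstart, bdur)
          t_free <- max(t_free, bstart + bdur)
        }
        t <- t + cdur + max(rln(config$exploration_gap),
                            config$min_exploration_gap_s)
      }
      t <- max(t, t_free)
    }
    t <- max(t, t_free) + buffer_s()
    phase <- sample(egg_laying_phases, 1,
                    prob = config$transition[phase, ])
  }

  # background proboscis extension: renewal process across all phases
  rate_s <- config$proboscis_rate_per_min / 60
  if (rate_s > 0) {
    tp <- rexp(1, rate_s)
    while (tp < T_s) {
      d <- rln(config$proboscis_duration)
      emit("proboscis_extension", tp, d)
      tp <- tp + d + max(rexp(1, rate_s), 0.5)
    }
  }

  pluck_chr <- function(lst, fld) vapply(lst, `[[`, character(1), fld)
  pluck_int <- function(lst, fld) vapply(lst, `[[`, integer(1), fld)
  list(
    bouts = tibble::tibble(
      fly_id = rep(fly_id, length(bouts)),
      behaviour = pluck_chr(bouts, "behaviour"),
      start_frame = pluck_int(bouts, "start_frame"),
      end_frame = pluck_int(bouts, "end_frame"),
      buried = pluck_chr(bouts, "buried")
    ),
    phases = tibble::tibble(
      fly_id = rep(fly_id, length(phases)),
      phase = pluck_chr(phases, "phase"),
      onset_frame = pluck_int(phases, "onset_frame")
    ),
    eggs = tibble::tibble(
      fly_id = rep(fly_id, length(eggs)),
      start_frame = pluck_int(eggs, "start_frame"),
      end_frame = pluck_int(eggs, "end_frame"),
      buried = pluck_chr(eggs, "buried")
    )
  )
}

#' Simulate a multi-fly ethogram dataset with ground truth
#'
#' Runs [simulate_fly()] for `config$n_flies` flies, with per-fly seeds
#' derived deterministically from the master seed, and assembles a validated
#' [ethogram_dataset()] plus the generator's ground truth.
#'
#' @param config A [simulator_config()].
#' @param protocol Optional `stim_protocol` attached to every recording (its
#'   parameters are stored in the dataset's protocols table).
#' @return A list of class `ethogram_simulation` with elements `dataset` (an
#'   `ethogram_dataset`) and `ground_truth` (list of tibbles `phases` and
#'   `eggs`).
#' @examples
#' sim <- simulate_ethogram(simulator_config(n_flies = 2,
#'                                           recording_length_s = 600))
#' sim$dataset
#' @export
simulate_ethogram <- function(config = simulator_config(), protocol = NULL) {
  stopifnot(inherits(config, "simulator_config"))
  validate_simulator_config(config)
  fly_seeds <- withr::with_seed(
    config$seed, sample.int(.Machine$integer.max - 1L, config$n_flies))
  fly_ids <- sprintf("fly%03d", seq_len(config$n_flies))
  sims <- purrr::map2(fly_seeds, fly_ids,
                      function(s, id) simulate_fly(config, s, id))
  bouts <- dplyr::bind_rows(purrr::map(sims, "bouts"))
  recordings <- tibble::tibble(
    fly_id = fly_ids, fps = config$fps,
    n_frames = as.integer(round(config$recording_length_s * config$fps)),
    group = config$group,
    protocol_id = if (is.null(protocol)) NA_character_ else
      attr(protocol, "protocol_id")
  )
  protocols <- if (is.null(protocol)) NULL else protocol_param_row(protocol)
  dataset <- ethogram_dataset(bouts, recordings, protocols)
  structure(
    list(dataset = dataset,
         ground_truth = list(
           phases = dplyr::bind_rows(purrr::map(sims, "phases")),
           eggs = dplyr::bind_rows(purrr::map(sims, "eggs")))),
    class = "ethogram_simulation"
  )
}

#' @export
print.ethogram_simulation <- function(x, ...) {
  cat(sprintf(
    "<ethogram_simulation: %d flies, %d bouts, %d eggs, %d phase entries>\n",
    nrow(x$dataset$recordings), nrow(x$dataset$bouts),
    nrow(x$ground_truth$eggs), nrow(x$ground_truth$phases)))
  invisible(x)
}

#' Overlay planted optogenetic responses on a dataset
#'
#' For each fly carrying the protocol and each light-ON stimulus, inserts a
#' response bout with probability `p_respond`, starting at the stimulus onset
#' plus a sampled latency. A planted response whose latency is at least the
#' stimulus duration is dropped (with a message). With `clip = TRUE` the
#' response bout is truncated at the end of the ON window. Planted responses
#' are recorded so that stimulus-locked metrics can be checked against ground
#' truth. Overlapping or adjacent response bouts of the same behaviour are
#' merged.
#'
#' @param x An `ethogram_dataset` or `ethogram_simulation`.
#' @param protocol A `stim_protocol`.
#' @param behaviour Behaviour label of the planted response bouts.
#' @param p_respond Per-stimulus response probability.
#' @param latency `c(meanlog, sdlog)` of the response latency (seconds).
#' @param duration `c(meanlog, sdlog)` of the response bout duration.
#' @param clip Truncate response bouts at the end of the ON window.
#' @param seed Seed for the overlay's randomness.
#' @return A list with `dataset` (augmented, response bouts merged in) and
#'   `responses` (tibble: `fly_id`, `stimulus_index`, `planted`,
#'   `latency_s`, `start_frame`; `planted` is `FALSE` for non-responding or
#'   dropped stimuli).
#' @export
overlay_stimulation <- function(x, protocol, behaviour = "egg_pushing",
                                p_respond = 1,
                                latency = c(meanlog = log(1), sdlog = 0.3),
                                duration = c(meanlog = log(3), sdlog = 0.3),
                                clip = TRUE, seed = 1L) {
  if (inherits(x, "ethogram_simulation")) x <- x$dataset
  stopifnot(inherits(x, "ethogram_dataset"), p_respond >= 0, p_respond <= 1)
  withr::local_seed(as.integer(seed))
  fps <- pooled_fps(x)
  sw <- stim_windows(protocol, fps)
  stim_s <- (sw$end_frame_excl[1] - sw$start_frame[1]) / fps
  n_dropped <- 0L
  rows <- list()
  new_bouts <- list()
  for (f in x$recordings$fly_id) {
    nf <- x$recordings$n_frames[match(f, x$recordings$fly_id)]
    for (k in seq_len(nrow(sw))) {
      responds <- runif(1) < p_respond
      lat <- NA_real_
      start <- NA_integer_
      if (responds) {
        lat <- rln(latency)
        if (lat >= stim_s) {
          n_dropped <- n_dropped + 1L
          responds <- FALSE
        } else {
          start <- sw$start_frame[k] + as.integer(round(lat * fps))
          dur <- rln(duration)
          end <- start + max(1L, as.integer(round(dur * fps))) - 1L
          if (clip) end <- min(end, sw$end_frame_excl[k] - 1L)
          end <- min(end, nf - 1L)
          new_bouts[[length(new_bouts) + 1]] <- tibble::tibble(
            fly_id = f, behaviour = behaviour,
            start_frame = start, end_frame = end)
        }
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        fly_id = f, stimulus_index = sw$stimulus_index[k],
        planted = responds, latency_s = lat, start_frame = start)
    }
  }
  if (n_dropped > 0) {
    message(sprintf(
      "%d planted response(s) dropped: latency exceeded the %gs stimulus",
      n_dropped, stim_s))
  }
  bouts <- dplyr::bind_rows(c(list(x$bouts), new_bouts))
  dataset <- ethogram_dataset(bouts, x$recordings, x$protocols,
                              on_overlap = "merge")
  list(dataset = dataset, responses = dplyr::bind_rows(rows))
}
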