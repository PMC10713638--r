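#' Classify ovipositor contacts as progressing or non-progressing
#'
#' An ovipositor contact "progresses" to egg expulsion when it is connected to
#' a subsequent egg-expulsion bout through a chain of deposition-sequence
#' bouts (ovipositor contact, burrowing, egg pushing, egg expulsion) in which
#' consecutive bouts are separated by at most `linkage_gap` frames and no
#' abdominal-contortions bout intervenes. Contacts that do not reach an
#' expulsion this way are exploration-phase probing.
#'
#' @inheritParams inter_egg_intervals
#' @param linkage_gap Maximum gap, in frames, between consecutive bouts of a
#'   deposition chain. Default `NULL` means 2 seconds at the fly's fps.
#' @return A tibble with columns `fly_id`, `start_frame`, `end_frame`,
#'   `progressing` (logical), one row per ovipositor-contact bout.
#' @export
classify_ovipositor_contacts <- function(x, fly = NULL, linkage_gap = NULL) {
  stopifnot(inherits(x, "ethogram_dataset"))
  flies <- resolve_flies(x, fly)
  purrr::map_dfr(flies, function(f) {
    gap <- if (is.null(linkage_gap)) round(2 * fps_of(x, f)) else linkage_gap
    chain <- fly_bouts(x, f, deposition_chain_behaviours)
    breakers <- fly_bouts(x, f, "abdominal_contortions")$start_frame
    contacts <- chain[chain$behaviour == "ovipositor_contact", , drop = FALSE]
    if (nrow(contacts) == 0) {
      return(tibble::tibble(fly_id = character(), start_frame = integer(),
                            end_frame = integer(), progressing = logical()))
    }
    prog <- vapply(seq_len(nrow(contacts)), function(i) {
      chain_progresses(contacts$start_frame[i], chain, breakers, gap)
    }, logical(1))
    tibble::tibble(fly_id = f, start_frame = contacts$start_frame,
                   end_frame = contacts$end_frame, progressing = prog)
  })
}

# Forward scan from the contact that starts at `start`: extend the reached
# chain coverage bout by bout (in start order) while the gap to the next
# chain bout is <= linkage gap and no contortions bout starts inside the gap.
chain_progresses <- function(start, chain, breaker_starts, gap) {
  i0 <- which(chain$start_frame == start &
                chain$behaviour == "ovipositor_contact")[1]
  reach_end <- chain$end_frame[i0]
  j <- i0
  while (j < nrow(chain)) {
    j <- j + 1
    s <- chain$start_frame[j]
    if (s - reach_end > gap) return(FALSE)
    if (any(breaker_starts > reach_end & breaker_starts <= s)) return(FALSE)
    if (chain$behaviour[j] == "egg_expulsion") return(TRUE)
    reach_end <- max(reach_end, chain$end_frame[j])
  }
  FALSE
}

#' Extract the per-fly egg-laying phase sequence
#'
#' Maps bouts onto the three egg-laying phases through their representative
#' elements: egg expulsions mark the `deposition` phase, abdominal-contortion
#' bouts mark the `contortions` phase, and ovipositor contacts that do not
#' progress to an expulsion (see [classify_ovipositor_contacts()]) mark the
#' `exploration` phase. Proboscis extension and burrowing never contribute:
#' the former occurs throughout egg-laying and beyond, and the latter
#' accompanies ovipositor contact at lower frequency. Consecutive same-phase
#' events are collapsed into a single entry keeping the earliest onset.
#'
#' @inheritParams classify_ovipositor_contacts
#' @return A tibble with columns `fly_id`, `phase` (one of
#'   [egg_laying_phases]), `onset_frame`; onsets strictly increasing within a
#'   fly, consecutive phases always distinct.
#' @export
extract_phase_sequence <- function(x, fly = NULL, linkage_gap = NULL) {
  stopifnot(inherits(x, "ethogram_dataset"))
  flies <- resolve_flies(x, fly)
  purrr::map_dfr(flies, function(f) {
    dep <- fly_bouts(x, f, "egg_expulsion")
    con <- fly_bouts(x, f, "abdominal_contortions")
    expl <- classify_ovipositor_contacts(x, f, linkage_gap)
    expl <- expl[!expl$progressing, , drop = FALSE]
    ev <- tibble::tibble(
      phase = c(rep("deposition", nrow(dep)),
                rep("contortions", nrow(con)),
                rep("exploration", nrow(expl))),
      onset_frame = c(dep$start_frame, con$start_frame, expl$start_frame)
    )
    ev <- dplyr::arrange(ev, .data$onset_frame)
    keep <- c(TRUE, ev$phase[-1] != ev$phase[-nrow(ev)])
    if (nrow(ev) == 0) keep <- logical(0)
    ev <- ev[keep, , drop = FALSE]
    tibble::tibble(fly_id = f, phase = ev$phase,
                   onset_frame = ev$onset_frame)
  })
}

#' First-order Markov transition matrix between egg-laying phases
#'
#' Counts adjacent phase pairs in the extracted sequences, pooled over flies
#' but never across fly boundaries, and row-normalises the counts into
#' transition probabilities. Self-transitions are structurally impossible
#' because sequences are run-length collapsed, so the diagonal is zero. Rows
#' with no outgoing transition have undefined (NaN) probabilities.
#'
#' @param sequences A phase-sequence tibble as returned by
#'   [extract_phase_sequence()] (columns `fly_id`, `phase`, `onset_frame`),
#'   or an `ethogram_dataset` (the sequences are extracted first).
#' @param linkage_gap Passed to [extract_phase_sequence()] when `sequences`
#'   is a dataset.
#' @return An object of class `phase_transitions`: a list with the 3x3
#'   `counts` and `probabilities` matrices (rows = from-phase, columns =
#'   to-phase, in the order deposition, contortions, exploration) and
#'   `n_transitions`.
#' @examples
#' seqs <- tibble::tibble(
#'   fly_id = "f1",
#'   phase = c("deposition", "contortions", "deposition", "contortions",
#'             "exploration", "deposition"),
#'   onset_frame = c(0L, 10L, 20L, 30L, 40L, 50L)
#' )
#' transition_matrix(seqs)
#' @export
transition_matrix <- function(sequences, linkage_gap = NULL) {
  if (inherits(sequences, "ethogram_dataset")) {
    sequences <- extract_phase_sequence(sequences, linkage_gap = linkage_gap)
  }
  stopifnot(all(c("fly_id", "phase") %in% names(sequences)))
  bad <- setdiff(unique(sequences$phase), egg_laying_phases)
  if (length(bad) > 0) {
    stop("unknown phase label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- matrix(0L, 3, 3,
                   dimnames = list(egg_laying_phases, egg_laying_phases))
  for (f in unique(sequences$fly_id)) {
    ph <- sequences$phase[sequences$fly_id == f]
    if (length(ph) < 2) next
    for (i in seq_len(length(ph) - 1)) {
      counts[ph[i], ph[i + 1]] <- counts[ph[i], ph[i + 1]] + 1L
    }
  }
  n <- sum(counts)
  if (n == 0) {
    stop("no phase transitions: every sequence has fewer than 2 entries",
         call. = FALSE)
  }
  probs <- counts / rowSums(counts)   # rows without outgoing counts -> NaN
  structure(
    list(counts = counts, probabilities = probs, n_transitions = n),
    class = "phase_transitions"
  )
}

#' @export
print.phase_transitions <- function(x, ...) {
  cat(sprintf("<phase_transitions: %d transitions>\n", x$n_transitions))
  print(round(x$probabilities, 3))
  invisible(x)
}

#' @rdname transition_matrix
#' @param x A `phase_transitions` object.
#' @param ... Unused.
#' @return `tidy()` returns a tibble with one row per ordered phase pair:
#'   `from`, `to`, `count`, `probability`.
#' @export
tidy.phase_transitions <- function(x, ...) {
  tibble::tibble(
    from = rep(egg_laying_phases, each = 3),
    to = rep(egg_laying_phases, times = 3),
    count = as.integer(t(x$counts)),
    probability = as.numeric(t(x$probabilities))
  )
}

#' @rdname transition_matrix
#' @export
glance.phase_transitions <- function(x, ...) {
  tibble::tibble(
    n_transitions = x$n_transitions,
    n_from_deposition = sum(x$counts["deposition", ]),
    n_from_contortions = sum(x$counts["contortions", ]),
    n_from_exploration = sum(x$counts["exploration", ])
  )
}

#' Plot a phase-transition matrix
#'
#' Heat-map of transition probabilities between the three egg-laying phases,
#' annotated with the probability and the underlying count.
#'
#' @param object A `phase_transitions` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_transitions <- function(object, ...) {
  td <- tidy(object)
  td$from <- factor(td$from, rev(egg_laying_phases))
  td$to <- factor(td$to, egg_laying_phases)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$probability)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(
      is.nan(.data$probability), "-",
      sprintf("%.2f\n(n=%d)", .data$probability, .data$count)))) +
    ggplot2::scale_fill_gradient(low = "grey95", high = "#b2182b",
                                 limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = "To phase", y = "From phase",
                  fill = "P(transition)") +
    ggplot2::theme_minimal()
}

#' Sensitivity of the transition matrix to the linkage gap
#'
#' The chain rule that separates progressing from non-progressing ovipositor
#' contacts depends on the `linkage_gap` parameter. This helper recomputes
#' the transition matrix over a grid of gaps so the stability of the estimate
#' can be inspected.
#'
#' @inheritParams transition_matrix
#' @param x An `ethogram_dataset`.
#' @param gaps_s Numeric vector of candidate gaps in seconds.
#' @return A tibble with columns `linkage_gap_s`, `from`, `to`, `count`,
#'   `probability`, `n_transitions`.
#' @export
linkage_gap_sensitivity <- function(x, gaps_s = c(0.5, 1, 2, 4, 8)) {
  stopifnot(inherits(x, "ethogram_dataset"))
  fps <- pooled_fps(x)
  purrr::map_dfr(gaps_s, function(g) {
    tm <- transition_matrix(x, linkage_gap = round(g * fps))
    out <- tidy(tm)
    out$linkage_gap_s <- g
    out$n_transitions <- tm$n_transitions
    dplyr::relocate(out, "linkage_gap_s")
  })
}
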