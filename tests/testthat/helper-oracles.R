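# Fixture builders and independently coded brute-force oracles.
# The oracles deliberately use naive per-frame / per-pair enumeration and
# share no code with the package internals they check.

rand_bout_frames <- function(k, n_frames) {
  # k non-overlapping, non-adjacent [start, end] intervals within [0, n_frames)
  while (k > 0) {
    durs <- sample(1:30, k, replace = TRUE)
    gaps <- sample(2:250, k, replace = TRUE)
    starts <- cumsum(gaps) + c(0, cumsum(durs[-k]))
    ends <- starts + durs - 1L
    if (max(ends) < n_frames) {
      return(data.frame(start_frame = as.integer(starts),
                        end_frame = as.integer(ends)))
    }
    k <- k - 1
  }
  NULL
}

random_small_dataset <- function(n_flies = 2, n_frames = 4000, fps = 20,
                                 behaviours = canonical_behaviours,
                                 max_bouts = 6, group = "all") {
  rows <- list()
  for (f in seq_len(n_flies)) {
    id <- paste0("fly", f)
    for (beh in behaviours) {
      k <- sample(0:max_bouts, 1)
      fr <- if (k > 0) rand_bout_frames(k, n_frames) else NULL
      if (is.null(fr)) next
      buried <- if (beh == "egg_expulsion") {
        sample(c("yes", "no", "unknown"), nrow(fr), replace = TRUE)
      } else {
        rep(NA_character_, nrow(fr))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        fly_id = id, behaviour = beh, start_frame = fr$start_frame,
        end_frame = fr$end_frame, buried = buried)
    }
  }
  bouts <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(fly_id = character(), behaviour = character(),
                   start_frame = integer(), end_frame = integer(),
                   buried = character())
  recs <- tibble::tibble(fly_id = paste0("fly", seq_len(n_flies)),
                         fps = fps, n_frames = as.integer(n_frames),
                         group = group)
  ethogram_dataset(bouts, recs)
}

coupled_dataset <- function(n_events = 30, spacing = 3000, fps = 20,
                            n_frames = 200000L, lo = 10L, hi = 50L) {
  # a grooming bout covers frames r+lo .. r+hi after every expulsion end r
  refs <- as.integer(seq(spacing, by = spacing, length.out = n_events))
  bouts <- dplyr::bind_rows(
    tibble::tibble(fly_id = "f1", behaviour = "egg_expulsion",
                   start_frame = refs - 5L, end_frame = refs),
    tibble::tibble(fly_id = "f1", behaviour = "grooming_terminalia",
                   start_frame = refs + lo, end_frame = refs + hi))
  ethogram_dataset(bouts, tibble::tibble(fly_id = "f1", fps = fps,
                                         n_frames = n_frames))
}

# ---- oracles ---------------------------------------------------------------

oracle_inter_egg <- function(bouts, fly, fps = NULL) {
  b <- bouts[bouts$fly_id == fly & bouts$behaviour == "egg_expulsion", ]
  b <- b[order(b$start_frame), ]
  if (nrow(b) <= 1) return(numeric(0))
  out <- numeric(nrow(b) - 1)
  for (i in seq_len(nrow(b) - 1)) {
    out[i] <- b$start_frame[i + 1] - b$end_frame[i]
  }
  if (!is.null(fps)) out <- out / fps
  out
}

oracle_counts_per_bin <- function(bouts, fly, beh, bin_frames, n_bins) {
  b <- bouts[bouts$fly_id == fly & bouts$behaviour == beh, ]
  counts <- numeric(n_bins)
  for (i in seq_len(nrow(b))) {
    k <- b$start_frame[i] %/% bin_frames + 1
    if (k <= n_bins) counts[k] <- counts[k] + 1
  }
  counts
}

oracle_perievent <- function(bouts, recs, beh, W) {
  # probability per offset by scanning every (event, offset) pair
  probs <- numeric(2 * W + 1)
  n_ev <- 0
  for (f in recs$fly_id) {
    nf <- recs$n_frames[recs$fly_id == f]
    exps <- bouts[bouts$fly_id == f & bouts$behaviour == "egg_expulsion", ]
    bb <- bouts[bouts$fly_id == f & bouts$behaviour == beh, ]
    for (r in exps$end_frame) {
      if (r < W || r > nf - 1 - W) next
      n_ev <- n_ev + 1
      for (o in -W:W) {
        fr <- r + o
        if (any(bb$start_frame <= fr & fr <= bb$end_frame)) {
          probs[o + W + 1] <- probs[o + W + 1] + 1
        }
      }
    }
  }
  list(probability = if (n_ev > 0) probs / n_ev else probs, n_events = n_ev)
}

oracle_progressing <- function(bouts, fly, contact_start, gap) {
  # BFS over the bout adjacency relation among deposition-chain bouts
  chain <- bouts[bouts$fly_id == fly &
                   bouts$behaviour %in% c("ovipositor_contact", "burrowing",
                                          "egg_pushing", "egg_expulsion"), ]
  chain <- chain[order(chain$start_frame), ]
  brk <- bouts$start_frame[bouts$fly_id == fly &
                             bouts$behaviour == "abdominal_contortions"]
  n <- nrow(chain)
  start_idx <- which(chain$start_frame == contact_start &
                       chain$behaviour == "ovipositor_contact")
  reached <- rep(FALSE, n)
  reached[start_idx] <- TRUE
  queue <- start_idx
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    if (chain$behaviour[i] == "egg_expulsion") return(TRUE)
    for (j in seq_len(n)) {
      if (reached[j] || chain$start_frame[j] < chain$start_frame[i]) next
      if (chain$start_frame[j] - chain$end_frame[i] > gap) next
      if (any(brk > chain$end_frame[i] & brk <= chain$start_frame[j])) next
      reached[j] <- TRUE
      queue <- c(queue, j)
    }
  }
  FALSE
}

oracle_transition_counts <- function(seqs) {
  counts <- matrix(0, 3, 3, dimnames = list(egg_laying_phases,
                                            egg_laying_phases))
  for (f in unique(seqs$fly_id)) {
    ph <- seqs$phase[seqs$fly_id == f]
    if (length(ph) >= 2) {
      for (i in 2:length(ph)) counts[ph[i - 1], ph[i]] <-
          counts[ph[i - 1], ph[i]] + 1
    }
  }
  counts
}

oracle_stim_responded <- function(bouts, fly, beh, windows) {
  # per stimulus: does any behaviour frame fall inside the ON window?
  vapply(seq_len(nrow(windows)), function(k) {
    frames <- windows$start_frame[k]:(windows$end_frame_excl[k] - 1)
    b <- bouts[bouts$fly_id == fly & bouts$behaviour == beh, ]
    any(vapply(frames, function(fr)
      any(b$start_frame <= fr & fr <= b$end_frame), logical(1)))
  }, logical(1))
}

oracle_fisher_p <- function(tab) {
  # full hypergeometric enumeration: sum P(tables) <= P(observed)
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
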