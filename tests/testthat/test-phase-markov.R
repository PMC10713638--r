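phase_fixture <- function() {
  # contortions(0,100), contact(500,520) with no expulsion chain,
  # contortions(900,1000), expulsion(1500,1505)
  bouts <- tibble::tibble(
    fly_id = "f1",
    behaviour = c("abdominal_contortions", "ovipositor_contact",
                  "abdominal_contortions", "egg_expulsion"),
    start_frame = c(0L, 500L, 900L, 1500L),
    end_frame = c(100L, 520L, 1000L, 1505L))
  ethogram_dataset(bouts, tibble::tibble(fly_id = "f1", fps = 20,
                                         n_frames = 54000L))
}

test_that("representative elements map onto the three phases", {
  ps <- extract_phase_sequence(phase_fixture())
  expect_equal(ps$phase,
               c("contortions", "exploration", "contortions", "deposition"))
  expect_equal(ps$onset_frame, c(0L, 500L, 900L, 1500L))
})

test_that("consecutive same-phase events collapse to the earliest onset", {
  bouts <- tibble::tibble(
    fly_id = "f1", behaviour = "egg_expulsion",
    start_frame = c(100L, 300L, 500L), end_frame = c(105L, 305L, 505L))
  d <- ethogram_dataset(bouts, tibble::tibble(fly_id = "f1", fps = 20,
                                              n_frames = 54000L))
  ps <- extract_phase_sequence(d)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$phase, "deposition")
  expect_equal(ps$onset_frame, 100L)
})

test_that("proboscis extension and burrowing never contribute phases", {
  bouts <- tibble::tibble(
    fly_id = "f1",
    behaviour = c("proboscis_extension", "burrowing", "proboscis_extension"),
    start_frame = c(0L, 500L, 1000L), end_frame = c(50L, 600L, 1100L))
  d <- ethogram_dataset(bouts, tibble::tibble(fly_id = "f1", fps = 20,
                                              n_frames = 54000L))
  expect_equal(nrow(extract_phase_sequence(d)), 0)
})

test_that("a canonical deposition chain classifies as progressing", {
  # contact -> burrowing (gap 5) -> egg pushing (gap 3) -> expulsion (gap 0)
  bouts <- tibble::tibble(
    fly_id = "f1",
    behaviour = c("ovipositor_contact", "burrowing", "egg_pushing",
                  "egg_expulsion"),
    start_frame = c(100L, 155L, 208L, 261L),
    end_frame = c(150L, 205L, 260L, 270L))
  d <- ethogram_dataset(bouts, tibble::tibble(fly_id = "f1", fps = 20,
                                              n_frames = 54000L))
  cls <- classify_ovipositor_contacts(d)
  expect_true(cls$progressing)
})

test_that("an intervening contortions bout breaks the chain", {
  bouts <- tibble::tibble(
    fly_id = "f1",
    behaviour = c("ovipositor_contact", "abdominal_contortions",
                  "egg_expulsion"),
    start_frame = c(100L, 160L, 180L),
    end_frame = c(150L, 175L, 190L))
  d <- ethogram_dataset(bouts, tibble::tibble(fly_id = "f1", fps = 20,
                                              n_frames = 54000L))
  expect_false(classify_ovipositor_contacts(d)$progressing)
})

test_that("gaps larger than the linkage gap break the chain", {
  bouts <- tibble::tibble(
    fly_id = "f1",
    behaviour = c("ovipositor_contact", "egg_expulsion"),
    start_frame = c(100L, 200L), end_frame = c(150L, 210L))
  d <- ethogram_dataset(bouts, tibble::tibble(fly_id = "f1", fps = 20,
                                              n_frames = 54000L))
  expect_true(classify_ovipositor_contacts(d, linkage_gap = 50)$progressing)
  expect_false(classify_ovipositor_contacts(d, linkage_gap = 49)$progressing)
})

test_that("classification matches a BFS reachability oracle", {
  withr::local_seed(701)
  for (rep in 1:40) {
    d <- random_small_dataset(
      n_flies = 1, n_frames = 3000,
      behaviours = c("ovipositor_contact", "burrowing", "egg_pushing",
                     "egg_expulsion", "abdominal_contortions"),
      max_bouts = 5)
    gap <- sample(c(10, 40, 120), 1)
    cls <- classify_ovipositor_contacts(d, linkage_gap = gap)
    for (i in seq_len(nrow(cls))) {
      expect_equal(
        cls$progressing[i],
        oracle_progressing(d$bouts, cls$fly_id[i], cls$start_frame[i], gap),
        info = sprintf("rep %d contact %d gap %d", rep, i, gap))
    }
  }
})

test_that("transition counts match the hand-worked single-sequence example", {
  seqs <- tibble::tibble(
    fly_id = "f1",
    phase = c("deposition", "contortions", "deposition", "contortions",
              "exploration", "deposition"),
    onset_frame = c(0L, 10L, 20L, 30L, 40L, 50L))
  tm <- transition_matrix(seqs)
  expect_equal(tm$counts["deposition", "contortions"], 2L)
  expect_equal(tm$counts["contortions", "deposition"], 1L)
  expect_equal(tm$counts["contortions", "exploration"], 1L)
  expect_equal(tm$counts["exploration", "deposition"], 1L)
  expect_equal(tm$n_transitions, 5L)
  expect_equal(tm$probabilities["deposition", "contortions"], 1.0)
  expect_equal(tm$probabilities["contortions", "deposition"], 0.5)
  expect_equal(tm$probabilities["contortions", "exploration"], 0.5)
  expect_equal(tm$probabilities["exploration", "deposition"], 1.0)
})

test_that("transitions never cross fly boundaries", {
  seqs <- tibble::tibble(
    fly_id = c("a", "a", "b", "b"),
    phase = c("deposition", "contortions", "contortions", "deposition"),
    onset_frame = c(0L, 10L, 0L, 10L))
  tm <- transition_matrix(seqs)
  expect_equal(tm$n_transitions, 2L)
  expect_equal(tm$counts["contortions", "contortions"], 0L)
})

test_that("rows are stochastic and the diagonal is structurally zero", {
  withr::local_seed(702)
  sim <- simulate_ethogram(simulator_config(n_flies = 5,
                                            recording_length_s = 1200,
                                            seed = 31))
  tm <- transition_matrix(sim$dataset)
  expect_equal(unname(diag(tm$counts)), c(0L, 0L, 0L))
  rs <- rowSums(tm$probabilities)
  out_deg <- rowSums(tm$counts)
  expect_equal(rs[out_deg > 0], rep(1, sum(out_deg > 0)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(is.nan(tm$probabilities[out_deg == 0, ])))
  # counts agree with the enumeration oracle on the extracted sequences
  seqs <- extract_phase_sequence(sim$dataset)
  expect_equal(unname(tm$counts), unname(oracle_transition_counts(seqs)),
               ignore_attr = TRUE)
})

test_that("no transitions at all is an error", {
  seqs <- tibble::tibble(fly_id = "a", phase = "deposition",
                         onset_frame = 0L)
  expect_error(transition_matrix(seqs), "fewer than 2")
})

test_that("tidy and glance summarise the matrix faithfully", {
  seqs <- tibble::tibble(
    fly_id = "f1", phase = c("deposition", "contortions", "exploration"),
    onset_frame = c(0L, 10L, 20L))
  tm <- transition_matrix(seqs)
  td <- tidy(tm)
  expect_equal(nrow(td), 9)
  expect_equal(td$count[td$from == "deposition" & td$to == "contortions"],
               1L)
  expect_equal(glance(tm)$n_transitions, 2L)
})
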