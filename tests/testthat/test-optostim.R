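test_that("the pulsed protocol tiles and places stimulus 1 at [1200,1400)", {
  p <- build_protocol(60, 6, 10, 20)
  sw <- stim_windows(p, fps = 20)
  expect_equal(sw$start_frame[1], 1200L)
  expect_equal(sw$end_frame_excl[1], 1400L)
  expect_equal(nrow(sw), 6)
  expect_equal(max(p$end_s), 60 + 6 * 10 + 5 * 20)
  ew <- epoch_windows(p, 20)
  expect_equal(ew$start_frame[-1], ew$end_frame_excl[-nrow(ew)])
  # single stimulus: total 70 s
  p1 <- build_protocol(60, 1, 10, 20)
  expect_equal(max(p1$end_s), 70)
  expect_equal(nrow(stim_windows(p1, 20)), 1)
})

test_that("random protocol parameters tile to the analytic total", {
  withr::local_seed(801)
  for (rep in 1:25) {
    b <- runif(1, 10, 120); n <- sample(1:8, 1)
    s <- runif(1, 2, 30); i <- runif(1, 2, 40)
    p <- build_protocol(b, n, s, i)
    expect_equal(max(p$end_s), b + n * s + (n - 1) * i)
    expect_equal(p$end_s, cumsum(c(p$end_s[1], diff(p$end_s))))
  }
  pc <- build_constant_protocol(600, 900, 300)
  expect_equal(pc$kind, c("pre", "stim", "post"))
  expect_equal(max(pc$end_s), 1800)
})

stim_fixture <- function(bouts, n_flies = 1, fps = 20, n_frames = 6000L) {
  recs <- tibble::tibble(fly_id = unique(bouts$fly_id), fps = fps,
                         n_frames = n_frames)
  ethogram_dataset(bouts, recs)
}

test_that("percentage of stimulations with behaviour counts ON overlaps", {
  p <- build_protocol(60, 6, 10, 20)
  # behaviour overlapping stimuli 1 and 3 only
  d <- stim_fixture(tibble::tibble(
    fly_id = "f1", behaviour = "egg_pushing",
    start_frame = c(1300L, 2450L), end_frame = c(1350L, 2500L)))
  res <- pct_stimulations_with_behaviour(d, "egg_pushing", p)
  expect_equal(res$proportion, 2 / 6)
  expect_equal(res$outcomes$responded, c(TRUE, FALSE, TRUE, FALSE, FALSE,
                                         FALSE))
  # behaviour only during ISIs -> 0
  d2 <- stim_fixture(tibble::tibble(
    fly_id = "f1", behaviour = "egg_pushing",
    start_frame = 1450L, end_frame = 1700L))
  expect_equal(pct_stimulations_with_behaviour(d2, "egg_pushing",
                                               p)$proportion, 0)
  expect_error(pct_stimulations_with_behaviour(d, "egg_pushing", p,
                                               group = "nope"), "group")
})

test_that("stimulus response detection matches per-frame enumeration", {
  withr::local_seed(802)
  p <- build_protocol(20, 4, 5, 8)
  for (rep in 1:25) {
    d <- random_small_dataset(n_flies = 1, n_frames = 3000,
                              behaviours = "egg_pushing", max_bouts = 6)
    sw <- stim_windows(p, 20)
    res <- pct_stimulations_with_behaviour(d, "egg_pushing", p)
    orc <- oracle_stim_responded(d$bouts, d$recordings$fly_id[1],
                                 "egg_pushing", sw)
    expect_equal(res$outcomes$responded, orc)
  }
})

test_that("adding bouts never decreases the response proportion", {
  withr::local_seed(803)
  p <- build_protocol(20, 4, 5, 8)
  d <- random_small_dataset(n_flies = 1, n_frames = 3000,
                            behaviours = "egg_pushing", max_bouts = 3)
  base <- pct_stimulations_with_behaviour(d, "egg_pushing", p)$proportion
  extra <- dplyr::bind_rows(
    d$bouts,
    tibble::tibble(fly_id = d$recordings$fly_id[1],
                   behaviour = "egg_pushing",
                   start_frame = 2801L, end_frame = 2900L))
  d2 <- ethogram_dataset(extra, d$recordings, on_overlap = "merge")
  expect_gte(pct_stimulations_with_behaviour(d2, "egg_pushing",
                                             p)$proportion, base)
})

test_that("egg allocation assigns by end frame and sums to 100%", {
  p <- build_protocol(60, 6, 10, 20)
  d <- stim_fixture(tibble::tibble(
    fly_id = "f1", behaviour = "egg_expulsion",
    start_frame = c(1250L, 1300L, 1380L), end_frame = c(1260L, 1310L, 1390L)))
  al <- egg_allocation(d, p)
  expect_equal(sum(al$pct), 100)
  expect_equal(al$pct[al$kind == "stim" & al$stimulus_index == 1], 100)
  # an expulsion ending exactly on an epoch boundary belongs to the
  # half-open window that starts there
  d2 <- stim_fixture(tibble::tibble(
    fly_id = "f1", behaviour = "egg_expulsion",
    start_frame = 1395L, end_frame = 1400L))
  al2 <- egg_allocation(d2, p)
  expect_equal(al2$n_eggs[al2$kind == "isi"][1], 1L)
  expect_equal(al2$n_eggs[al2$kind == "stim"][1], 0L)
  expect_error(egg_allocation(stim_fixture(tibble::tibble(
    fly_id = "f1", behaviour = "burrowing",
    start_frame = 10L, end_frame = 20L)), p), "no egg")
})

test_that("egg allocation matches epoch-membership enumeration", {
  withr::local_seed(804)
  p <- build_protocol(30, 5, 8, 12)
  for (rep in 1:20) {
    d <- random_small_dataset(n_flies = 2, n_frames = 4000,
                              behaviours = "egg_expulsion", max_bouts = 5)
    ew <- epoch_windows(p, 20)
    ends <- d$bouts$end_frame
    inside <- ends < max(ew$end_frame_excl)
    if (sum(inside) == 0) {
      expect_error(egg_allocation(d, p))
      next
    }
    al <- egg_allocation(d, p)
    for (k in seq_len(nrow(ew))) {
      expect_equal(al$n_eggs[k],
                   sum(ends >= ew$start_frame[k] &
                         ends < ew$end_frame_excl[k]))
    }
    expect_equal(sum(al$pct), 100, tolerance = 1e-9)
  }
})

test_that("latency runs from first stimulus onset to first expulsion", {
  p <- build_protocol(60, 6, 10, 20)
  d <- stim_fixture(tibble::tibble(
    fly_id = "f1", behaviour = "egg_expulsion",
    start_frame = 1300L, end_frame = 1310L))
  expect_equal(latency_to_expulsion(d, p)$latency_s, 5.0)
  # expulsion before the first stimulus does not count; none after -> NA
  d2 <- stim_fixture(tibble::tibble(
    fly_id = "f1", behaviour = "egg_expulsion",
    start_frame = 500L, end_frame = 510L))
  expect_true(is.na(latency_to_expulsion(d2, p)$latency_s))
  withr::local_seed(805)
  for (rep in 1:20) {
    d3 <- random_small_dataset(n_flies = 1, n_frames = 5000,
                               behaviours = "egg_expulsion", max_bouts = 6)
    got <- latency_to_expulsion(d3, p)$latency_s
    starts <- d3$bouts$start_frame[d3$bouts$start_frame >= 1200L]
    if (length(starts) == 0) expect_true(is.na(got)) else
      expect_equal(got, (min(starts) - 1200L) / 20)
  }
})
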