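test_that("a single-bout events file round-trips through read", {
  dir <- withr::local_tempdir()
  writeLines(c("fly_id,behaviour,start_frame,end_frame",
               "fly1,egg_expulsion,100,105"),
             file.path(dir, "events.csv"))
  writeLines(c("fly_id,fps,n_frames", "fly1,20,54000"),
             file.path(dir, "recordings.csv"))
  d <- read_annotations(file.path(dir, "events.csv"),
                        file.path(dir, "recordings.csv"))
  expect_s3_class(d, "ethogram_dataset")
  expect_equal(nrow(d$bouts), 1)
  expect_equal(nrow(d$recordings), 1)
  expect_equal(d$bouts$start_frame, 100L)
  expect_equal(d$recordings$fps, 20)
})

test_that("missing required columns are reported by name", {
  dir <- withr::local_tempdir()
  writeLines(c("fly_id,behaviour,start_frame", "fly1,burrowing,10"),
             file.path(dir, "events.csv"))
  writeLines(c("fly_id,fps,n_frames", "fly1,20,1000"),
             file.path(dir, "recordings.csv"))
  expect_error(
    read_annotations(file.path(dir, "events.csv"),
                     file.path(dir, "recordings.csv")),
    "end_frame")
})

test_that("overlapping same-behaviour bouts error unless merged", {
  bouts <- tibble::tibble(
    fly_id = "fly1", behaviour = "burrowing",
    start_frame = c(10L, 15L), end_frame = c(20L, 25L))
  recs <- tibble::tibble(fly_id = "fly1", fps = 20, n_frames = 1000L)
  expect_error(ethogram_dataset(bouts, recs), "overlapping")
  merged <- ethogram_dataset(bouts, recs, on_overlap = "merge")
  expect_equal(nrow(merged$bouts), 1)
  expect_equal(merged$bouts$start_frame, 10L)
  expect_equal(merged$bouts$end_frame, 25L)
  # frame-adjacent bouts are one bout too
  adj <- ethogram_dataset(
    tibble::tibble(fly_id = "fly1", behaviour = "burrowing",
                   start_frame = c(10L, 21L), end_frame = c(20L, 30L)),
    recs, on_overlap = "merge")
  expect_equal(nrow(adj$bouts), 1)
  # different behaviours may co-occur freely
  expect_no_error(ethogram_dataset(
    tibble::tibble(fly_id = "fly1",
                   behaviour = c("burrowing", "ovipositor_contact"),
                   start_frame = c(10L, 12L), end_frame = c(20L, 25L)),
    recs))
})

test_that("write/read round-trips arbitrary datasets identically", {
  withr::local_seed(401)
  for (rep in 1:100) {
    d <- random_small_dataset(n_flies = sample(1:3, 1),
                              n_frames = sample(2000:6000, 1))
    dir <- file.path(tempdir(), sprintf("rt%d", rep))
    paths <- write_annotations(d, dir)
    d2 <- read_annotations(paths[["events"]], paths[["recordings"]],
                           paths[["protocols"]])
    expect_equal(d2$bouts, d$bouts)
    expect_equal(d2$recordings, d$recordings)
    unlink(dir, recursive = TRUE)
  }
})

test_that("a write/read/write cycle is byte-identical", {
  withr::local_seed(77)
  d <- random_small_dataset(n_flies = 3)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- write_annotations(d, dir1)
  d2 <- read_annotations(p1[["events"]], p1[["recordings"]],
                         p1[["protocols"]])
  p2 <- write_annotations(d2, dir2)
  for (nm in names(p1)) {
    expect_identical(readBin(p1[[nm]], "raw", file.size(p1[[nm]])),
                     readBin(p2[[nm]], "raw", file.size(p2[[nm]])))
  }
})

test_that("an empty dataset writes header-only files", {
  d <- ethogram_dataset(
    tibble::tibble(fly_id = character(), behaviour = character(),
                   start_frame = integer(), end_frame = integer()),
    tibble::tibble(fly_id = character(), fps = numeric(),
                   n_frames = integer()))
  dir <- withr::local_tempdir()
  paths <- write_annotations(d, dir)
  for (p in paths) {
    expect_equal(length(readLines(p)), 1)
  }
})

test_that("validation reports each planted violation exactly once", {
  withr::local_seed(402)
  base_recs <- tibble::tibble(fly_id = c("fly1", "fly2"), fps = 20,
                              n_frames = 20000L)
  for (k in 1:10) {
    bouts <- tibble::tibble(
      fly_id = "fly1", behaviour = "grooming_terminalia",
      start_frame = 0L, end_frame = 10L, buried = NA_character_)
    planted <- 0
    kinds <- sample(c("range", "interval", "dangle", "overlap"), k,
                    replace = TRUE)
    offset <- 100L
    for (kind in kinds) {
      row <- switch(kind,
        range = tibble::tibble(fly_id = "fly2", behaviour = "burrowing",
                               start_frame = 20000L + offset,
                               end_frame = 20005L + offset,
                               buried = NA_character_),
        interval = tibble::tibble(fly_id = "fly2",
                                  behaviour = "egg_pushing",
                                  start_frame = offset + 50L,
                                  end_frame = offset,
                                  buried = NA_character_),
        dangle = tibble::tibble(fly_id = paste0("ghost", offset),
                                behaviour = "burrowing",
                                start_frame = offset, end_frame = offset + 5L,
                                buried = NA_character_),
        overlap = tibble::tibble(fly_id = "fly1",
                                 behaviour = "abdominal_contortions",
                                 start_frame = c(offset, offset + 3L),
                                 end_frame = c(offset + 10L, offset + 12L),
                                 buried = NA_character_)
      )
      bouts <- dplyr::bind_rows(bouts, row)
      planted <- planted + 1
      offset <- offset + 1000L   # keep planted defects independent
    }
    d <- ethogram_dataset(bouts, base_recs, validate = FALSE)
    rep_tbl <- validate_ethogram(d)
    expect_equal(sum(rep_tbl$severity == "error"), planted)
  }
})

test_that("valid datasets yield empty reports; unknown labels are notes", {
  withr::local_seed(403)
  d <- random_small_dataset()
  expect_equal(nrow(validate_ethogram(d)), 0)
  d2 <- ethogram_dataset(
    tibble::tibble(fly_id = "fly1", behaviour = "wing_grooming",
                   start_frame = 0L, end_frame = 10L),
    tibble::tibble(fly_id = "fly1", fps = 20, n_frames = 100L))
  rep_tbl <- validate_ethogram(d2)
  expect_equal(rep_tbl$severity, "note")
  expect_equal(rep_tbl$rule, "unknown_behaviour")
})

test_that("bouts past the recording end are flagged with their location", {
  d <- ethogram_dataset(
    tibble::tibble(fly_id = "fly1", behaviour = "burrowing",
                   start_frame = 90L, end_frame = 120L),
    tibble::tibble(fly_id = "fly1", fps = 20, n_frames = 100L),
    validate = FALSE)
  rep_tbl <- validate_ethogram(d)
  expect_equal(nrow(rep_tbl), 1)
  expect_equal(rep_tbl$rule, "out_of_range")
  expect_match(rep_tbl$message, "fly1")
})
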