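test_that("a single persistent object yields one constant-label track", {
  masks <- lapply(0:9, function(i) {
    m <- matrix(0L, 40, 40)
    m[(10 + i):(15 + i), 12:17] <- sample(1:50, 1) # arbitrary input label
    m
  })
  res <- track_masks(masks)
  expect_equal(nrow(res$tracks), 1)
  expect_equal(res$tracks$birth, 0L)
  expect_equal(res$tracks$death, 9L)
  expect_equal(res$tracks$origin, "first_frame")
  expect_equal(res$tracks$end, "last_frame")
  labs <- unique(unlist(lapply(res$masks, function(m) m[m > 0])))
  expect_equal(labs, 1L)
})

test_that("a division produces three tracks and one lineage edge", {
  sim <- simulate_cells(n_cells = 1, n_frames = 12, n_divisions = 1,
                        field = c(120, 120), radius = 12,
                        step_sigma = 0.6, seed = 2)
  res <- track_masks(sim$masks)
  expect_equal(nrow(res$tracks), 3)
  expect_equal(nrow(res$divisions), 1)
  d <- res$divisions
  mother <- res$tracks[res$tracks$label == d$mother, ]
  expect_equal(mother$end, "divided")
  expect_equal(mother$death, d$frame)
  for (dd in c(d$daughter1, d$daughter2)) {
    tr <- res$tracks[res$tracks$label == dd, ]
    expect_equal(tr$birth, d$frame + 1L)
    expect_equal(tr$origin, "division")
  }
  # matches the simulator's reference lineage timing
  expect_equal(d$frame, sim$divisions$frame)
})

test_that("colony fusions build a merged-branch lineage", {
  sim <- simulate_cells(n_cells = 3, n_frames = 25, fusion = TRUE,
                        field = c(220, 220), radius = 18,
                        step_sigma = 0.8, min_separation = 60,
                        drift_to_center = 2.5, seed = 4)
  expect_equal(nrow(sim$fusions), 2) # the scenario's two merges
  res <- track_masks(sim$masks, tracking_config(enable_fusion = TRUE))
  expect_equal(nrow(res$fusions), 2)
  expect_equal(nrow(res$tracks), 5)
  expect_equal(res$fusions$frame, sim$fusions$frame)
  expect_equal(lapply(res$fusions$parents, length),
               lapply(sim$fusions$parents, length))
  # masks are never split in fusion mode: object counts match input
  for (i in seq_along(sim$masks)) {
    expect_equal(length(unique(res$masks[[i]][res$masks[[i]] > 0])),
                 length(unique(sim$masks[[i]][sim$masks[[i]] > 0])))
  }
})

test_that("border exits/entries and interior deaths/births are classified", {
  mk <- function(objs) {
    m <- matrix(0L, 30, 30)
    for (o in objs) m[o$r, o$c] <- o$l
    m
  }
  sq <- function(r0, c0) list(r = r0:(r0 + 3), c = c0:(c0 + 3))
  # object A interior persists; B starts at border then leaves;
  # C appears at border at frame 1; D dies mid-field after frame 1
  f0 <- mk(list(c(sq(12, 12), l = 1L), c(sq(1, 20), l = 2L),
                c(sq(20, 20), l = 3L)))
  f1 <- mk(list(c(sq(12, 12), l = 5L), c(sq(27, 1), l = 6L),
                c(sq(20, 20), l = 7L)))
  f2 <- mk(list(c(sq(12, 12), l = 1L), c(sq(27, 1), l = 2L)))
  # d_max small enough that disjoint corners cannot be linked across the
  # 30x30 toy field
  res <- track_masks(list(f0, f1, f2), tracking_config(d_max = 8))
  tr <- res$tracks
  expect_equal(sum(tr$end == "left_fov"), 1) # B
  expect_equal(sum(tr$origin == "entered_fov"), 1) # C
  expect_equal(sum(tr$end == "died"), 1) # D
  expect_equal(nrow(tr), 4)
})

test_that("track count balances origins and labels stay in their interval", {
  sim <- simulate_cells(n_cells = 10, n_frames = 15, n_divisions = 3,
                        field = c(300, 300), radius = 10, step_sigma = 1,
                        min_separation = 50, seed = 9)
  res <- track_masks(sim$masks)
  tr <- res$tracks
  n0 <- sum(tr$birth == 0)
  expect_equal(nrow(tr), n0 + sum(tr$birth > 0))
  expect_equal(sum(tr$origin == "first_frame"), n0)
  for (i in seq_along(res$masks)) {
    f <- i - 1L
    present <- unique(res$masks[[i]][res$masks[[i]] > 0])
    for (g in present) {
      expect_gte(f, tr$birth[tr$label == g])
      expect_lte(f, tr$death[tr$label == g])
    }
  }
})

test_that("paths, lists and generator input give identical results", {
  sim <- simulate_particles(n_particles = 6, n_frames = 8, seed = 12)
  d <- withr::local_tempdir()
  write_tracked_masks(sim$masks, d, prefix = "in_")
  res_list <- track_masks(sim$masks)
  res_path <- track_masks(file.path(d, sprintf("in_%03d.tif", 0:7)))
  res_fun <- track_masks(function(i) sim$masks[[i]], n_frames = 8)
  expect_equal(res_list$tracks, res_path$tracks)
  expect_equal(res_list$tracks, res_fun$tracks)
  for (i in 1:8) {
    expect_equal(unclass(res_list$masks[[i]])[, ],
                 unclass(res_path$masks[[i]])[, ])
  }
})

test_that("streamed output to disk matches in-memory masks", {
  sim <- simulate_particles(n_particles = 5, n_frames = 6, seed = 8)
  d <- withr::local_tempdir()
  res <- track_masks(sim$masks, output_dir = d, keep_masks = TRUE)
  back <- read_mask_sequence(file.path(d, sprintf("mask_%03d.tif", 0:5)))
  for (i in 1:6) {
    expect_equal(unclass(back[[i]])[, ], unclass(res$masks[[i]])[, ])
  }
})

test_that("confidence index rewards long, isolated, interior tracks", {
  # long interior isolated track with near-zero link costs
  masks <- lapply(0:7, function(i) disk_mask(50, 50, 25, 25 + i %% 2, 8))
  res <- track_masks(masks)
  expect_equal(res$tracks$confidence, 1)
  # short track touching the border fails lifespan + border indicators
  m1 <- matrix(0L, 30, 30)
  m1[1:4, 10:13] <- 1L
  m2 <- matrix(0L, 30, 30)
  m2[1:4, 11:14] <- 1L
  res2 <- track_masks(list(m1, m2))
  expect_lte(res2$tracks$confidence, 0.5)
  expect_equal(res2$tracks$c_lifespan, 0)
  expect_equal(res2$tracks$c_interior, 0)
  # a track passing through a collision split loses the isolation point
  sim <- simulate_cells(n_cells = 12, n_frames = 8,
                        merge_on_contact = TRUE, field = c(120, 120),
                        radius = 9, step_sigma = 3, min_separation = 19,
                        seed = 1)
  res3 <- track_masks(sim$masks)
  expect_true(any(res3$tracks$c_isolated == 0))
})

test_that("lineage CSV export round-trips", {
  sim <- simulate_cells(n_cells = 4, n_frames = 12, n_divisions = 2,
                        field = c(200, 200), radius = 11, step_sigma = 0.8,
                        min_separation = 60, seed = 6)
  res <- track_masks(sim$masks)
  d <- withr::local_tempdir()
  export_lineage(res, d)
  tr <- utils::read.csv(file.path(d, "tracks.csv"))
  expect_equal(nrow(tr), nrow(res$tracks))
  dv <- utils::read.csv(file.path(d, "divisions.csv"))
  expect_equal(nrow(dv), 2)
  fu <- utils::read.csv(file.path(d, "fusions.csv"))
  expect_equal(nrow(fu), 0)
})

test_that("tidy, glance and autoplot summarize a result", {
  sim <- simulate_cells(n_cells = 3, n_frames = 10, n_divisions = 1,
                        field = c(150, 150), radius = 10, step_sigma = 0.8,
                        min_separation = 45, seed = 13)
  res <- track_masks(sim$masks)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("label", "birth", "death", "confidence") %in%
                    names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_divisions, 1L)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
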