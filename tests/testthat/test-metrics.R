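ts <- function(...) {
  # quick track-set constructor: list of c(track, frame, row, col) rows
  rows <- list(...)
  tibble::tibble(
    track = vapply(rows, `[`, numeric(1), 1),
    frame = as.integer(vapply(rows, `[`, numeric(1), 2)),
    row = vapply(rows, `[`, numeric(1), 3),
    col = vapply(rows, `[`, numeric(1), 4)
  )
}

test_that("identical track sets pair perfectly at distance zero", {
  ref <- ts(c(1, 0, 5, 5), c(1, 1, 6, 5), c(2, 0, 20, 20), c(2, 1, 20, 21))
  p <- map_tracks_by_distance(ref, ref)
  expect_equal(nrow(p$pairs), 4)
  expect_equal(max(p$pairs$dist), 0)
  expect_equal(alpha_metric(p), 1)
  expect_equal(beta_metric(p), 1)
})

test_that("the tolerance gate forbids pairs at or beyond epsilon", {
  ref <- ts(c(1, 0, 10, 10))
  est <- ts(c(7, 0, 10, 16)) # 6 px away
  p <- map_tracks_by_distance(ref, est, epsilon = 5)
  expect_equal(nrow(p$pairs), 0)
  p2 <- map_tracks_by_distance(ref, est, epsilon = 7)
  expect_equal(nrow(p2$pairs), 1)
})

test_that("optimal per-frame pairing beats greedy nearest-first", {
  # greedy pairs ref1-est1 (dist 1) forcing ref2-est2 (dist 3.9), total 4.9;
  # the assignment picks ref1-est2 (1.9) + ref2-est1 (1.1), total 3.0
  ref <- ts(c(1, 0, 0, 10), c(2, 0, 0, 12.1))
  est <- ts(c(5, 0, 0, 11), c(6, 0, 0, 8.2))
  p <- map_tracks_by_distance(ref, est, epsilon = 5)
  expect_equal(nrow(p$pairs), 2)
  greedy_total <- 1 + 3.9
  expect_lt(sum(p$pairs$dist), greedy_total)
})

test_that("overlap mapping pairs only mutual maxima", {
  # identical sequences: everything pairs with itself
  sim <- simulate_cells(n_cells = 5, n_frames = 3, field = c(96, 96),
                        radius = 9, step_sigma = 1, seed = 2)
  p <- map_tracks_by_overlap(sim$true_masks, sim$true_masks)
  expect_equal(p$pairs$ref_track, p$pairs$est_track)
  # counterexample: est object B overlaps ref X (60) and ref Y (40); X
  # prefers est A. B and Y are each other's best -> B-Y paired, X-A paired,
  # and nothing pairs twice
  ref <- matrix(0L, 12, 30)
  ref[2:6, 1:12] <- 1L # X
  ref[2:6, 13:20] <- 2L # Y
  est <- matrix(0L, 12, 30)
  est[2:6, 1:7] <- 5L # A: overlaps X by 35
  est[2:6, 8:20] <- 6L # B: overlaps X by 25, Y by 40
  p2 <- map_tracks_by_overlap(list(ref), list(est))
  expect_equal(nrow(p2$pairs), 2)
  expect_equal(p2$pairs$est_track[p2$pairs$ref_track == 1L], 5L)
  expect_equal(p2$pairs$est_track[p2$pairs$ref_track == 2L], 6L)
  # zero overlap: no pairs
  far1 <- matrix(0L, 10, 10)
  far1[1:2, 1:2] <- 1L
  far2 <- matrix(0L, 10, 10)
  far2[8:9, 8:9] <- 1L
  expect_equal(nrow(map_tracks_by_overlap(list(far1),
                                          list(far2))$pairs), 0)
})

test_that("an ambiguous (tied) maximum overlap stays unpaired", {
  ref <- matrix(0L, 10, 20)
  ref[2:5, 3:10] <- 1L
  est <- matrix(0L, 10, 20)
  est[2:5, 3:6] <- 7L # overlaps ref 1 by 16
  est[2:5, 7:10] <- 8L # overlaps ref 1 by 16 (tie)
  p <- map_tracks_by_overlap(list(ref), list(est))
  expect_equal(nrow(p$pairs), 0)
})

test_that("decision and track counts follow the counting rules", {
  # ref: track 1 over frames 0..9 (9 links); est: empty
  ref <- tibble::tibble(track = 1, frame = 0:9, row = 5, col = 5)
  est <- ref[0, ]
  p <- map_tracks_by_distance(ref, est)
  dec <- count_tp_fp_fn(p, "decisions")
  expect_equal(dec, list(tp = 0L, fn = 9L, fp = 0L))
  whole <- count_tp_fp_fn(p, "whole_track")
  expect_equal(whole, list(tp = 0L, fn = 1L, fp = 0L))
  # a spurious 4-frame est track adds 3 FP links and 1 FP track
  est2 <- tibble::tibble(track = 9, frame = 0:3, row = 50, col = 50)
  p2 <- map_tracks_by_distance(ref, est2)
  dec2 <- count_tp_fp_fn(p2, "decisions")
  expect_equal(dec2$fp, 3L)
  expect_equal(count_tp_fp_fn(p2, "whole_track")$fp, 1L)
  # perfect agreement: TP = all links, no FP/FN
  p3 <- map_tracks_by_distance(ref, ref)
  dec3 <- count_tp_fp_fn(p3, "decisions")
  expect_equal(dec3, list(tp = 9L, fn = 0L, fp = 0L))
})

test_that("jaccard follows its ratio exactly", {
  expect_equal(jaccard(6, 0, 0), 1)
  expect_equal(jaccard(0, 3, 4), 0)
  expect_equal(jaccard(3, 1, 2), 0.5)
  expect_message(expect_equal(jaccard(0, 0, 0), 1), "agreement")
})

test_that("alpha ignores spurious tracks while beta penalizes them", {
  ref <- tibble::tibble(track = rep(1:2, each = 6),
                        frame = rep(0:5, 2),
                        row = rep(c(10, 30), each = 6),
                        col = rep(0:5, 2) * 2)
  # perfect estimate
  p0 <- map_tracks_by_distance(ref, ref)
  a0 <- alpha_metric(p0)
  b0 <- beta_metric(p0)
  expect_equal(a0, 1)
  expect_equal(b0, 1)
  # add one spurious track far away
  est <- dplyr::bind_rows(
    ref, tibble::tibble(track = 99, frame = 0:5, row = 80, col = 80)
  )
  p1 <- map_tracks_by_distance(ref, est)
  expect_equal(alpha_metric(p1), a0) # unchanged
  expect_lt(beta_metric(p1), b0) # strictly penalized
  expect_lte(beta_metric(p1), alpha_metric(p1))
  # empty estimate: worst case on both
  p2 <- map_tracks_by_distance(ref, ref[0, ])
  expect_equal(alpha_metric(p2), 0)
  expect_equal(beta_metric(p2), 0)
})

test_that("all four metrics live in [0,1] on random noisy estimates", {
  set.seed(17)
  for (i in 1:10) {
    sim <- simulate_particles(n_particles = 8, n_frames = 6,
                              step_sigma = 2, seed = i, render = FALSE)
    ref <- sim$tracks
    est <- ref
    est$row <- est$row + rnorm(nrow(est), 0, 3)
    est$col <- est$col + rnorm(nrow(est), 0, 3)
    drop <- sample(nrow(est), round(nrow(est) * 0.2))
    est <- est[-drop, ]
    ev <- evaluate_tracking(ref, est)
    for (mname in c("alpha", "beta", "jaccard", "jaccard_theta")) {
      expect_gte(ev[[mname]], 0)
      expect_lte(ev[[mname]], 1)
    }
    expect_lte(ev$beta, ev$alpha)
  }
})

test_that("a single broken link hurts jaccard_theta more than jaccard", {
  # 10-frame track whose estimate switches identity once mid-way
  ref <- tibble::tibble(track = 1, frame = 0:9, row = 10, col = 10)
  est <- tibble::tibble(track = c(rep(5, 5), rep(6, 5)), frame = 0:9,
                        row = 10, col = 10)
  ev <- evaluate_tracking(ref, est)
  expect_lt(ev$jaccard_theta, ev$jaccard)
  expect_equal(ev$jaccard_theta, 0) # the whole-track unit is all-or-nothing
  expect_equal(ev$jaccard, 8 / 9) # 8 of 9 ref links kept, no spurious ones
})

test_that("track-set CSV round-trips through the readers", {
  tr <- ts(c(1, 0, 5.5, 6.5), c(1, 1, 6, 7), c(2, 0, 1, 2))
  p <- file.path(withr::local_tempdir(), "tracks.csv")
  write_track_set(tr, p)
  back <- read_track_set(p)
  expect_equal(back$track, tr$track)
  expect_equal(back$row, tr$row)
  suppressWarnings(
    expect_error(read_track_set(write_tmp_tiff(matrix(0L, 4, 4))))
  )
})
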