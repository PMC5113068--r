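test_that("the same seed reproduces sequences bit-exactly", {
  a <- simulate_particles(n_particles = 8, n_frames = 6, seed = 33)
  b <- simulate_particles(n_particles = 8, n_frames = 6, seed = 33)
  expect_identical(a$masks, b$masks)
  expect_identical(a$tracks, b$tracks)
  c1 <- simulate_cells(n_cells = 6, n_frames = 8, n_divisions = 2,
                       field = c(160, 160), seed = 5)
  c2 <- simulate_cells(n_cells = 6, n_frames = 8, n_divisions = 2,
                       field = c(160, 160), seed = 5)
  expect_identical(c1$masks, c2$masks)
  expect_identical(c1$tracks, c2$tracks)
  # and the simulator does not disturb the caller's RNG stream
  set.seed(1)
  x1 <- runif(1)
  set.seed(1)
  invisible(simulate_particles(n_particles = 3, n_frames = 2, seed = 99))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("static objects track perfectly (all metrics 1)", {
  sim <- simulate_particles(n_particles = 10, n_frames = 8,
                            step_sigma = 0, seed = 2)
  res <- track_masks(sim$masks)
  ev <- evaluate_tracking(mask_track_set(sim$masks),
                          mask_track_set(res$masks))
  expect_equal(ev$alpha, 1)
  expect_equal(ev$beta, 1)
  expect_equal(ev$jaccard, 1)
  expect_equal(ev$jaccard_theta, 1)
})

test_that("brownian tracks obey the 2D diffusion law", {
  sigma <- 1.5
  sim <- simulate_particles(n_particles = 500, n_frames = 21,
                            step_sigma = sigma, radius = 3,
                            field = c(3000, 3000), seed = 7,
                            render = FALSE)
  tr <- sim$tracks
  start <- tr[tr$frame == 0, ]
  for (t in c(5, 10, 20)) {
    at_t <- tr[tr$frame == t, ]
    msd <- mean((at_t$row - start$row)^2 + (at_t$col - start$col)^2)
    expect_equal(msd, 2 * sigma^2 * t, tolerance = 0.15)
  }
})

test_that("directed motion outruns brownian at equal step scale", {
  sim_b <- simulate_particles(n_particles = 60, n_frames = 15,
                              motion = "brownian", step_sigma = 2,
                              field = c(2000, 2000), seed = 3,
                              render = FALSE)
  sim_d <- simulate_particles(n_particles = 60, n_frames = 15,
                              motion = "directed", step_sigma = 2,
                              field = c(2000, 2000), seed = 3,
                              render = FALSE)
  disp <- function(tr) {
    s <- tr[tr$frame == 0, ]
    e <- tr[tr$frame == 14, ]
    mean(sqrt((e$row - s$row)^2 + (e$col - s$col)^2))
  }
  expect_gt(disp(sim_d$tracks), 2 * disp(sim_b$tracks))
})

test_that("an over-dense placement request fails cleanly", {
  expect_error(
    simulate_particles(n_particles = 200, n_frames = 2, radius = 10,
                       field = c(64, 64), seed = 1),
    "density"
  )
})

test_that("without divisions or contact the degraded sequence is the truth", {
  sim <- simulate_cells(n_cells = 6, n_frames = 6, division_rate = 0,
                        field = c(256, 256), radius = 9, step_sigma = 0.5,
                        min_separation = 60, seed = 11)
  for (i in seq_along(sim$masks)) {
    # same objects, same pixels, up to the per-frame relabeling
    ov <- overlap_table(sim$true_masks[[i]], sim$masks[[i]])
    expect_equal(nrow(ov), 6)
    expect_equal(sum(ov$pixels), sum(sim$true_masks[[i]] > 0))
  }
  expect_equal(sim$n_merge_events, 0)
})

test_that("a forced division writes a consistent reference lineage", {
  sim <- simulate_cells(n_cells = 1, n_frames = 10, n_divisions = 1,
                        field = c(120, 120), radius = 12, step_sigma = 0.5,
                        seed = 8)
  expect_equal(nrow(sim$divisions), 1)
  expect_equal(nrow(sim$tracks), 3)
  d <- sim$divisions
  tr <- sim$tracks
  expect_equal(tr$death[tr$label == d$mother], d$frame)
  expect_equal(tr$end[tr$label == d$mother], "divided")
  for (dd in c(d$daughter1, d$daughter2)) {
    expect_equal(tr$birth[tr$label == dd], d$frame + 1L)
  }
  # daughters satisfy the similarity indicators with margin at birth
  m <- sim$true_masks[[d$frame + 2L]]
  f <- extract_features(m)
  dts <- f[f$label %in% c(d$daughter1, d$daughter2), ]
  expect_gte(min(dts$area) / max(dts$area), 0.8)
  expect_gte(min(dts$aspect_ratio) / max(dts$aspect_ratio), 0.8)
  # the mother is round just before splitting
  fm <- extract_features(sim$true_masks[[d$frame + 1L]])
  expect_gte(fm$circularity[fm$label == d$mother], 0.9)
})

test_that("merged-label frames lose exactly the merged count of labels", {
  sim <- simulate_cells(n_cells = 10, n_frames = 10,
                        merge_on_contact = TRUE, field = c(110, 110),
                        radius = 9, step_sigma = 2.5, min_separation = 19,
                        seed = 14)
  expect_gt(sim$n_merge_events, 0)
  recount <- 0L
  for (i in seq_along(sim$masks)) {
    truth <- sim$true_masks[[i]]
    degr <- sim$masks[[i]]
    n_true <- length(unique(truth[truth > 0]))
    n_degr <- length(unique(degr[degr > 0]))
    ov <- overlap_table(degr, truth)
    per_comp <- table(ov$label_t)
    merges <- sum(per_comp - 1L)
    expect_equal(n_degr, n_true - merges)
    recount <- recount + sum(per_comp >= 2)
  }
  expect_equal(recount, sim$n_merge_events)
})

test_that("the reference lineage satisfies the structural invariants", {
  sim <- simulate_cells(n_cells = 8, n_frames = 16, n_divisions = 3,
                        field = c(300, 300), radius = 11, step_sigma = 0.8,
                        min_separation = 55, seed = 21)
  tr <- sim$tracks
  expect_false(any(duplicated(tr$label)))
  expect_true(all(tr$birth <= tr$death))
  dv <- sim$divisions
  for (i in seq_len(nrow(dv))) {
    expect_equal(tr$birth[tr$label == dv$daughter1[i]], dv$frame[i] + 1L)
    expect_equal(tr$birth[tr$label == dv$daughter2[i]], dv$frame[i] + 1L)
  }
  # time-directed acyclicity: every child is born after its mother
  expect_true(all(tr$birth[match(dv$daughter1, tr$label)] >
                    tr$birth[match(dv$mother, tr$label)]))
})
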