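# All randomness in the simulators goes through R's RNG under a caller-given
# seed, with the caller's RNG state restored afterwards.
with_sim_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Render a set of blob-shaped objects into an integer label matrix. `df` has
# columns label, r, c (continuous centers, 1-based pixel space), radius, and
# amp2..amp4 / ph2..ph4 (radial Fourier perturbation of the disk boundary:
# rho(theta) = radius * (1 + sum_k amp_k cos(k theta + ph_k))). A pixel
# claimed by several objects goes to the one whose normalized radial
# distance is smallest, so touching objects stay individually labeled.
render_objects <- function(df, nr, nc) {
  lab <- matrix(0L, nr, nc)
  if (nrow(df) == 0) return(lab)
  best <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(df))) {
    R <- df$radius[k]
    amp <- c(df$amp2[k], df$amp3[k], df$amp4[k])
    ph <- c(df$ph2[k], df$ph3[k], df$ph4[k])
    reach <- R * (1 + sum(abs(amp))) + 1
    r0 <- max(1L, floor(df$r[k] - reach))
    r1 <- min(nr, ceiling(df$r[k] + reach))
    c0 <- max(1L, floor(df$c[k] - reach))
    c1 <- min(nc, ceiling(df$c[k] + reach))
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1
    cols <- c0:c1
    DR <- matrix(rows - df$r[k], length(rows), length(cols))
    DC <- matrix(cols - df$c[k], length(rows), length(cols), byrow = TRUE)
    dist <- sqrt(DR^2 + DC^2)
    theta <- atan2(DC, DR)
    rho <- R * (1 + amp[1] * cos(2 * theta + ph[1]) +
                  amp[2] * cos(3 * theta + ph[2]) +
                  amp[3] * cos(4 * theta + ph[3]))
    nd <- dist / pmax(rho, 1e-9)
    sel <- nd <= 1 & nd < best[rows, cols]
    if (any(sel)) {
      sub_l <- lab[rows, cols]
      sub_b <- best[rows, cols]
      sub_l[sel] <- df$label[k]
      sub_b[sel] <- nd[sel]
      lab[rows, cols] <- sub_l
      best[rows, cols] <- sub_b
    }
  }
  lab
}

reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

place_separated <- function(n, lo_r, hi_r, lo_c, hi_c, min_sep,
                            max_tries = 4000) {
  rs <- numeric(0)
  cs <- numeric(0)
  tries <- 0
  while (length(rs) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop("could not place ", n, " objects at separation ", min_sep,
           " in the field; lower the density", call. = FALSE)
    }
    r <- stats::runif(1, lo_r, hi_r)
    c <- stats::runif(1, lo_c, hi_c)
    if (length(rs) == 0 ||
        min((rs - r)^2 + (cs - c)^2) >= min_sep^2) {
      rs <- c(rs, r)
      cs <- c(cs, c)
    }
  }
  list(r = rs, c = cs)
}

#' Simulate moving particles with exact ground-truth tracks
#'
#' Disks of fixed radius move through a rectangular field under one of three
#' motion models: `brownian` (isotropic Gaussian steps of standard deviation
#' `step_sigma` per axis per frame), `directed` (a constant per-particle
#' heading at speed `step_sigma` plus Gaussian noise of `step_sigma / 4`),
#' or `switching` (directed motion whose heading is resampled with
#' probability 0.2 each frame). Boundaries are reflective. Initial positions
#' are rejection-sampled at pairwise separation of at least
#' `2 * radius + 2`; an over-dense request fails after bounded retries.
#'
#' @param n_particles Number of particles.
#' @param n_frames Number of frames.
#' @param motion `"brownian"`, `"directed"` or `"switching"`.
#' @param step_sigma Motion scale in pixels per frame (see above).
#' @param radius Disk radius in pixels.
#' @param field `(rows, cols)` of the field.
#' @param seed Integer seed; the same seed reproduces the sequence exactly.
#' @param render Render label masks (`TRUE`) or return only the ground-truth
#'   table plus a per-frame renderer (`FALSE`, for streaming use).
#' @return A list of class `"particle_sim"`: `masks` (list of labeled masks,
#'   labels = particle ids, or `NULL`), `tracks` (tibble `track`, `frame`,
#'   `row`, `col`; 0-based, true disk centers), `render_frame` (function of
#'   a 1-based frame number returning that frame's mask), and the
#'   parameters.
#' @export
simulate_particles <- function(n_particles = 20, n_frames = 20,
                               motion = c("brownian", "directed",
                                          "switching"),
                               step_sigma = 2, radius = 5,
                               field = c(256, 256), seed = 1,
                               render = TRUE) {
  motion <- match.arg(motion)
  nr <- field[1]
  nc <- field[2]
  margin <- radius + 1
  with_sim_seed(seed, {
    pos <- place_separated(n_particles, margin, nr - margin,
                           margin, nc - margin, 2 * radius + 2)
    r <- pos$r
    c <- pos$c
    heading <- stats::runif(n_particles, 0, 2 * pi)
    rows_out <- matrix(0, n_frames, n_particles)
    cols_out <- matrix(0, n_frames, n_particles)
    for (f in seq_len(n_frames)) {
      if (f > 1) {
        if (motion == "brownian") {
          r <- r + stats::rnorm(n_particles, 0, step_sigma)
          c <- c + stats::rnorm(n_particles, 0, step_sigma)
        } else {
          if (motion == "switching") {
            flip <- stats::runif(n_particles) < 0.2
            heading[flip] <- stats::runif(sum(flip), 0, 2 * pi)
          }
          r <- r + step_sigma * cos(heading) +
            stats::rnorm(n_particles, 0, step_sigma / 4)
          c <- c + step_sigma * sin(heading) +
            stats::rnorm(n_particles, 0, step_sigma / 4)
        }
        r <- reflect_into(r, margin, nr - margin)
        c <- reflect_into(c, margin, nc - margin)
      }
      rows_out[f, ] <- r
      cols_out[f, ] <- c
    }
  })
  tracks <- tibble(
    track = rep(seq_len(n_particles), each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, n_particles),
    row = as.vector(rows_out) - 1,
    col = as.vector(cols_out) - 1
  )
  render_frame <- function(i) {
    df <- tibble(
      label = seq_len(n_particles),
      r = rows_out[i, ], c = cols_out[i, ],
      radius = radius,
      amp2 = 0, amp3 = 0, amp4 = 0, ph2 = 0, ph3 = 0, ph4 = 0
    )
    render_objects(df, nr, nc)
  }
  masks <- if (render) {
    lapply(seq_len(n_frames),
           function(i) new_labeled_mask(render_frame(i), i - 1L))
  }
  structure(list(
    masks = masks, tracks = tracks, render_frame = render_frame,
    n_frames = n_frames, field = field, radius = radius,
    motion = motion, step_sigma = step_sigma, seed = seed
  ), class = "particle_sim")
}

#' Simulate deformable cells with divisions, contacts and fusions
#'
#' Cells are deformable blobs — disks with a low-order radial Fourier
#' perturbation, so circularity and aspect ratio are controllable — whose
#' centers follow Brownian motion (optionally with a drift toward the field
#' center, used to force encounters). The simulator produces a *true* mask
#' sequence (every cell individually labeled with its lineage id, even while
#' touching) and a *degraded* sequence that emulates what a per-frame
#' segmentation would deliver: labels renumbered per frame, and — with
#' `merge_on_contact = TRUE` — touching cells collapsed into a single label
#' (an under-segmentation error). With `fusion = TRUE`, touching objects
#' genuinely merge in both sequences (colony fusion): the parents' tracks
#' end and a new merged object is born, recorded as a fusion edge.
#'
#' A division is announced two frames ahead: the mother sheds its shape
#' perturbation (rounding up), then splits into two equal-radius daughters
#' of half its area, displaced symmetrically so both overlap the mother's
#' footprint — satisfying the four mitosis indicators the tracker tests.
#'
#' @param n_cells Initial number of cells.
#' @param n_frames Number of frames.
#' @param division_rate Per-cell per-frame probability of announcing a
#'   division.
#' @param n_divisions Alternatively, schedule exactly this many divisions at
#'   evenly spaced frames (overrides `division_rate`).
#' @param fusion Merge touching objects into genuine fusion events.
#' @param merge_on_contact Collapse touching cells into one label in the
#'   degraded sequence only (segmentation error emulation).
#' @param step_sigma Brownian step, pixels per frame per axis.
#' @param radius Mean initial cell radius, pixels.
#' @param shape_amp Scale of the radial perturbation (0 = perfect disks).
#' @param min_separation Minimum initial center separation; default
#'   `2 * radius + 4`.
#' @param drift_to_center Radial drift toward the field center, pixels per
#'   frame.
#' @param field `(rows, cols)` of the field.
#' @param seed Integer seed.
#' @return A list of class `"cell_sim"`: `masks` (degraded sequence — the
#'   tracker's input), `true_masks` (lineage-labeled truth), `tracks`,
#'   `divisions`, `fusions` (reference lineage tables in the same layout as
#'   [track_masks()] output), `n_merge_events` (count of (frame, merged
#'   component) under-segmentation instances), and the parameters.
#' @export
simulate_cells <- function(n_cells = 12, n_frames = 20,
                           division_rate = 0, n_divisions = NULL,
                           fusion = FALSE, merge_on_contact = FALSE,
                           step_sigma = 1, radius = 10,
                           shape_amp = 0.12,
                           min_separation = NULL,
                           drift_to_center = 0,
                           field = c(256, 256), seed = 1) {
  nr <- field[1]
  nc <- field[2]
  if (is.null(min_separation)) min_separation <- 2 * radius + 4
  margin <- radius * 1.6 + 2

  with_sim_seed(seed, {
    pos <- place_separated(n_cells, margin, nr - margin,
                           margin, nc - margin, min_separation)
    cells <- tibble(
      label = seq_len(n_cells),
      r = pos$r, c = pos$c,
      radius = radius * stats::runif(n_cells, 0.85, 1.15),
      amp2 = stats::runif(n_cells, 0, shape_amp),
      amp3 = stats::runif(n_cells, 0, shape_amp / 2),
      amp4 = stats::runif(n_cells, 0, shape_amp / 2),
      ph2 = stats::runif(n_cells, 0, 2 * pi),
      ph3 = stats::runif(n_cells, 0, 2 * pi),
      ph4 = stats::runif(n_cells, 0, 2 * pi),
      group = seq_len(n_cells),
      divide_in = NA_integer_
    )
    next_label <- n_cells + 1L
    group_label <- seq_len(n_cells) # lineage label of each group
    birth <- rep(0L, n_cells)
    death <- rep(0L, n_cells)
    origin <- rep("first_frame", n_cells)
    end <- rep("last_frame", n_cells)
    divisions <- list()
    fusions <- list()
    true_masks <- vector("list", n_frames)
    degraded <- vector("list", n_frames)
    n_merge_events <- 0L

    sched <- NULL
    if (!is.null(n_divisions) && n_divisions > 0) {
      if (n_divisions > n_cells) {
        stop("n_divisions cannot exceed n_cells", call. = FALSE)
      }
      split_frames <- round(seq(4, max(4, n_frames - 3),
                                length.out = n_divisions))
      sched <- tibble(label = seq_len(n_divisions),
                      announce = as.integer(split_frames) - 2L)
    }

    new_track <- function(label, f, orig) {
      # state vectors are indexed by lineage label
      birth[label] <<- f
      death[label] <<- f
      origin[label] <<- orig
      end[label] <<- "last_frame"
    }
    grow <- function(v, upto, fill) {
      if (length(v) < upto) v[(length(v) + 1):upto] <- fill
      v
    }

    for (f in seq_len(n_frames) - 1L) { # 0-based frame index
      if (f > 0) {
        # motion
        dr <- stats::rnorm(nrow(cells), 0, step_sigma)
        dc <- stats::rnorm(nrow(cells), 0, step_sigma)
        if (drift_to_center > 0) {
          vr <- (nr + 1) / 2 - cells$r
          vc <- (nc + 1) / 2 - cells$c
          nrm <- pmax(sqrt(vr^2 + vc^2), 1e-9)
          dr <- dr + drift_to_center * vr / nrm
          dc <- dc + drift_to_center * vc / nrm
        }
        if (fusion) {
          # members of one group move together
          for (g in unique(cells$group)) {
            i <- which(cells$group == g)
            cells$r[i] <- cells$r[i] + dr[i[1]]
            cells$c[i] <- cells$c[i] + dc[i[1]]
          }
        } else {
          cells$r <- cells$r + dr
          cells$c <- cells$c + dc
        }
        cells$r <- reflect_into(cells$r, margin, nr - margin)
        cells$c <- reflect_into(cells$c, margin, nc - margin)

        # division lifecycle
        if (!is.null(sched)) {
          due <- sched$label[sched$announce == f]
          for (lb in due) {
            i <- which(cells$label == lb)
            if (length(i) == 1 && is.na(cells$divide_in[i])) {
              cells$divide_in[i] <- 2L
            }
          }
        } else if (division_rate > 0) {
          cand <- which(is.na(cells$divide_in))
          trig <- cand[stats::runif(length(cand)) < division_rate]
          cells$divide_in[trig] <- 2L
        }
        rounding <- !is.na(cells$divide_in)
        if (any(rounding)) {
          shrink <- ifelse(cells$divide_in == 2L, 0.3, 0)
          for (col_a in c("amp2", "amp3", "amp4")) {
            cells[[col_a]][rounding] <-
              cells[[col_a]][rounding] * shrink[rounding]
          }
        }
        split_now <- which(!is.na(cells$divide_in) & cells$divide_in == 0L)
        for (i in rev(split_now)) {
          mother <- cells$label[i]
          Rm <- cells$radius[i]
          ang <- stats::runif(1, 0, 2 * pi)
          off <- 0.62 * Rm
          Rd <- Rm / sqrt(2)
          d_amp <- 0.04
          kids <- tibble(
            label = c(next_label, next_label + 1L),
            r = cells$r[i] + c(off, -off) * cos(ang),
            c = cells$c[i] + c(off, -off) * sin(ang),
            radius = Rd,
            amp2 = d_amp, amp3 = 0, amp4 = 0,
            ph2 = stats::runif(1, 0, 2 * pi), ph3 = 0, ph4 = 0,
            group = c(max(cells$group) + 1L, max(cells$group) + 2L),
            divide_in = NA_integer_
          )
          birth <- grow(birth, next_label + 1L, NA_integer_)
          death <- grow(death, next_label + 1L, NA_integer_)
          origin <- grow(origin, next_label + 1L, NA_character_)
          end <- grow(end, next_label + 1L, NA_character_)
          new_track(next_label, f, "division")
          new_track(next_label + 1L, f, "division")
          end[mother] <- "divided"
          divisions[[length(divisions) + 1]] <- tibble(
            mother = mother, daughter1 = next_label,
            daughter2 = next_label + 1L, frame = f - 1L
          )
          group_label <- grow(group_label, max(kids$group), NA_integer_)
          group_label[kids$group] <- kids$label
          cells <- dplyr::bind_rows(cells[-i, ], kids)
          next_label <- next_label + 2L
        }
        cells$divide_in <- cells$divide_in - 1L
      }

      # render with per-cell labels first (needed for contact detection)
      rend <- cells
      rend$label <- if (fusion) group_label[cells$group] else cells$label
      m_true <- render_objects(rend, nr, nc)

      if (fusion) {
        tp <- touching_pairs(m_true)
        if (nrow(tp) > 0) {
          # union-find over group lineage labels
          repeat {
            merged_any <- FALSE
            for (k in seq_len(nrow(tp))) {
              la <- tp$a[k]
              lb <- tp$b[k]
              ga <- unique(cells$group[group_label[cells$group] == la])
              gb <- unique(cells$group[group_label[cells$group] == lb])
              if (length(ga) == 0 || length(gb) == 0) next
              parents <- c(la, lb)
              child <- next_label
              next_label <- next_label + 1L
              birth <- grow(birth, child, NA_integer_)
              death <- grow(death, child, NA_integer_)
              origin <- grow(origin, child, NA_character_)
              end <- grow(end, child, NA_character_)
              new_track(child, f, "fusion")
              for (p in parents) end[p] <- "fused"
              fusions[[length(fusions) + 1]] <- tibble(
                child = child, parents = list(sort(parents)), frame = f
              )
              newg <- min(ga, gb)
              cells$group[cells$group %in% c(ga, gb)] <- newg
              group_label[newg] <- child
              merged_any <- TRUE
              break
            }
            if (!merged_any) break
            rend$label <- group_label[cells$group]
            m_true <- render_objects(rend, nr, nc)
            tp <- touching_pairs(m_true)
            if (nrow(tp) == 0) break
          }
        }
      }

      # lineage bookkeeping: everything alive is present this frame
      present <- unique(rend$label)
      present <- if (fusion) unique(group_label[cells$group]) else
        cells$label
      death[present] <- f

      true_masks[[f + 1L]] <- new_labeled_mask(m_true, f)

      # degraded sequence: per-frame relabeling, optional contact merging
      if (merge_on_contact && !fusion) {
        comp <- label_components(m_true > 0L)
        fg <- which(comp > 0L)
        # count components swallowing >= 2 true labels
        swallowed <- tibble(component = comp[fg], lab = m_true[fg]) %>%
          dplyr::distinct() %>%
          dplyr::count(.data$component)
        n_merge_events <- n_merge_events + sum(swallowed$n >= 2)
        degraded[[f + 1L]] <- new_labeled_mask(comp, f)
      } else {
        degraded[[f + 1L]] <- new_labeled_mask(relabel_raster(m_true), f)
      }
    }

    valid <- which(!is.na(birth))
    tracks <- tibble(
      label = valid, birth = birth[valid], death = death[valid],
      origin = origin[valid], end = end[valid]
    )
    structure(list(
      masks = degraded, true_masks = true_masks,
      tracks = tracks,
      divisions = if (length(divisions)) dplyr::bind_rows(divisions) else
        tibble(mother = integer(), daughter1 = integer(),
               daughter2 = integer(), frame = integer()),
      fusions = if (length(fusions)) dplyr::bind_rows(fusions) else
        tibble(child = integer(), parents = list(), frame = integer()),
      n_merge_events = n_merge_events,
      n_frames = n_frames, field = field, seed = seed
    ), class = "cell_sim")
  })
}

# unordered pairs of distinct positive labels with 8-adjacent pixels
touching_pairs <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    r1 <- seq_len(nr - abs(s[1]))
    c1 <- if (s[2] >= 0) seq_len(nc - s[2]) else seq.int(1 - s[2], nc)
    a <- mask[r1, c1, drop = FALSE]
    b <- mask[r1 + s[1], c1 + s[2], drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      lo <- pmin(a[sel], b[sel])
      hi <- pmax(a[sel], b[sel])
      out[[length(out) + 1]] <- tibble(a = lo, b = hi)
    }
  }
  if (length(out) == 0) {
    return(tibble(a = integer(), b = integer()))
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

# renumber the positive labels of one frame to 1..k in raster order of each
# label's first pixel (what an independent per-frame segmentation would do)
relabel_raster <- function(mask) {
  idx <- which(mask > 0L)
  if (length(idx) == 0) return(mask)
  first <- idx[!duplicated(mask[idx])]
  old <- mask[first]
  lut <- integer(max(old) + 1L)
  lut[old + 1L] <- seq_along(old)
  out <- mask
  out[idx] <- lut[mask[idx] + 1L]
  out
}
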