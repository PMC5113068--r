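#' Centroid track set of a labeled mask sequence
#'
#' Collapses a mask sequence to one centroid sample per (track label, frame),
#' the representation consumed by the tracking accuracy metrics.
#'
#' @param masks List of labeled masks (globally labeled: one label = one
#'   track).
#' @return A tibble `track`, `frame` (0-based), `row`, `col` (0-based
#'   centroid coordinates), sorted by track then frame.
#' @export
mask_track_set <- function(masks) {
  purrr::imap_dfr(masks, function(m, i) {
    f <- extract_features(m)
    if (nrow(f) == 0) return(NULL)
    tibble(track = f$label, frame = i - 1L, row = f$row, col = f$col)
  }) %>% dplyr::arrange(.data$track, .data$frame)
}

#' Read / write point-track tables
#'
#' Plain CSV with columns `track`, `frame`, `row`, `col` (0-based frames and
#' coordinates).
#'
#' @param path CSV file path.
#' @return `read_track_set()`: the track tibble.
#' @export
read_track_set <- function(path) {
  x <- utils::read.csv(path)
  need <- c("track", "frame", "row", "col")
  if (!all(need %in% names(x))) {
    stop("track CSV must have columns track, frame, row, col",
         call. = FALSE)
  }
  as_tibble(x[, need]) %>% dplyr::arrange(.data$track, .data$frame)
}

#' @rdname read_track_set
#' @param tracks Track tibble to write.
#' @export
write_track_set <- function(tracks, path) {
  utils::write.csv(tracks[, c("track", "frame", "row", "col")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Map estimated tracks to reference tracks by gated centroid distance
#'
#' Within each frame, reference and estimated positions are paired by an
#' optimal one-to-one assignment minimizing total distance; a pair further
#' apart than the tolerance `epsilon` is forbidden. A track-level pairing is
#' then derived by an optimal assignment maximizing the number of per-frame
#' co-pairings accumulated between each (reference track, estimated track)
#' couple.
#'
#' @param ref,est Track tibbles (`track`, `frame`, `row`, `col`).
#' @param epsilon Gating distance in pixels; default 5, the customary
#'   tolerance for simulated particle data.
#' @return A list of class `"track_pairing"`: `pairs` (tibble `frame`,
#'   `ref_track`, `est_track`, `dist`), `track_pairs` (tibble `ref_track`,
#'   `est_track`, `n`), `epsilon`, and the two inputs.
#' @export
map_tracks_by_distance <- function(ref, est, epsilon = 5) {
  stopifnot(epsilon > 0)
  frames <- sort(union(ref$frame, est$frame))
  pairs <- purrr::map_dfr(frames, function(f) {
    r <- ref[ref$frame == f, ]
    e <- est[est$frame == f, ]
    if (nrow(r) == 0 || nrow(e) == 0) return(NULL)
    d <- sqrt(outer(r$row, e$row, "-")^2 + outer(r$col, e$col, "-")^2)
    d[d >= epsilon] <- NA_real_
    m <- solve_assignment(d)
    if (nrow(m) == 0) return(NULL)
    tibble(frame = f,
           ref_track = r$track[m$label_t],
           est_track = e$track[m$label_t1],
           dist = m$cost)
  })
  finish_pairing(pairs, ref, est, epsilon)
}

#' Map estimated objects to reference objects by mutual maximum overlap
#'
#' Within each frame, a reference object and an estimated object are paired
#' iff each is the other's unique maximum-overlap partner. Used when objects
#' are extended regions whose centroid definition is ambiguous (the
#' bio-dataset convention); no distance gate is involved, but the paired
#' centroid distance is reported (capped at `epsilon` for the distance-based
#' metrics).
#'
#' @param ref_masks,est_masks Labeled mask sequences of equal length and
#'   dimensions.
#' @param epsilon Distance cap used only when feeding the distance-weighted
#'   metrics; default 5 pixels.
#' @return A `"track_pairing"` (see [map_tracks_by_distance()]).
#' @export
map_tracks_by_overlap <- function(ref_masks, est_masks, epsilon = 5) {
  if (length(ref_masks) != length(est_masks)) {
    stop("reference and estimated sequences must have equal length",
         call. = FALSE)
  }
  ref <- mask_track_set(ref_masks)
  est <- mask_track_set(est_masks)
  pairs <- purrr::map_dfr(seq_along(ref_masks), function(i) {
    ov <- overlap_table(ref_masks[[i]], est_masks[[i]])
    if (nrow(ov) == 0) return(NULL)
    best_for_ref <- ov %>%
      dplyr::group_by(.data$label_t) %>%
      dplyr::filter(.data$pixels == max(.data$pixels)) %>%
      dplyr::filter(dplyr::n() == 1) %>%
      dplyr::ungroup()
    best_for_est <- ov %>%
      dplyr::group_by(.data$label_t1) %>%
      dplyr::filter(.data$pixels == max(.data$pixels)) %>%
      dplyr::filter(dplyr::n() == 1) %>%
      dplyr::ungroup()
    mutual <- dplyr::inner_join(
      best_for_ref, best_for_est,
      by = c("label_t", "label_t1", "pixels")
    )
    if (nrow(mutual) == 0) return(NULL)
    rf <- ref[ref$frame == i - 1L, ]
    ef <- est[est$frame == i - 1L, ]
    ri <- match(mutual$label_t, rf$track)
    ei <- match(mutual$label_t1, ef$track)
    tibble(
      frame = i - 1L,
      ref_track = mutual$label_t,
      est_track = mutual$label_t1,
      dist = pmin(sqrt((rf$row[ri] - ef$row[ei])^2 +
                         (rf$col[ri] - ef$col[ei])^2), epsilon)
    )
  })
  finish_pairing(pairs, ref, est, epsilon)
}

finish_pairing <- function(pairs, ref, est, epsilon) {
  if (nrow(pairs) == 0) {
    pairs <- tibble(frame = integer(), ref_track = integer(),
                    est_track = integer(), dist = double())
  }
  track_pairs <- tibble(ref_track = integer(), est_track = integer(),
                        n = integer())
  if (nrow(pairs) > 0) {
    counts <- dplyr::count(pairs, .data$ref_track, .data$est_track)
    rt <- sort(unique(counts$ref_track))
    et <- sort(unique(counts$est_track))
    m <- matrix(NA_real_, length(rt), length(et))
    m[cbind(match(counts$ref_track, rt),
            match(counts$est_track, et))] <- -counts$n
    sol <- solve_assignment(m)
    if (nrow(sol) > 0) {
      track_pairs <- tibble(ref_track = rt[sol$label_t],
                            est_track = et[sol$label_t1],
                            n = as.integer(-sol$cost))
    }
  }
  structure(list(pairs = pairs, track_pairs = track_pairs,
                 epsilon = epsilon, ref = ref, est = est),
            class = "track_pairing")
}

#' @export
print.track_pairing <- function(x, ...) {
  cat(sprintf(
    "<track_pairing> %d paired positions over %d frames; %d track pairs\n",
    nrow(x$pairs), length(unique(x$pairs$frame)), nrow(x$track_pairs)))
  invisible(x)
}

#' Count true/false positive and false negative tracking decisions
#'
#' With `scope = "decisions"`, the unit is a frame-to-frame link: a
#' reference link (a reference track present at two consecutive frames) is a
#' TP when both its endpoints are paired to the same estimated track, and
#' estimated links not explained this way are FPs. With
#' `scope = "whole_track"`, the unit is the entire track: a reference track
#' is a TP when one estimated track is paired with it at every frame of the
#' reference track's lifetime.
#'
#' @param pairing A `"track_pairing"`.
#' @param scope `"decisions"` or `"whole_track"`.
#' @return A named list `tp`, `fp`, `fn`.
#' @export
count_tp_fp_fn <- function(pairing, scope = c("decisions", "whole_track")) {
  scope <- match.arg(scope)
  ref <- pairing$ref
  est <- pairing$est
  pairs <- pairing$pairs
  if (scope == "decisions") {
    ref_links <- count_links(ref)
    est_links <- count_links(est)
    tp <- 0L
    if (nrow(pairs) > 0) {
      key <- paste(pairs$frame, pairs$ref_track)
      part <- stats::setNames(pairs$est_track, key)
      by_track <- split(ref$frame, ref$track)
      for (tr in names(by_track)) {
        fr <- sort(by_track[[tr]])
        consec <- fr[which(diff(fr) == 1)]
        for (f in consec) {
          p1 <- part[paste(f, tr)]
          p2 <- part[paste(f + 1L, tr)]
          if (!is.na(p1) && !is.na(p2) && p1 == p2) tp <- tp + 1L
        }
      }
    }
    list(tp = tp, fn = ref_links - tp, fp = est_links - tp)
  } else {
    ref_tracks <- unique(ref$track)
    est_tracks <- unique(est$track)
    tp <- 0L
    if (nrow(pairs) > 0) {
      key <- paste(pairs$frame, pairs$ref_track)
      part <- stats::setNames(pairs$est_track, key)
      for (tr in ref_tracks) {
        fr <- ref$frame[ref$track == tr]
        ps <- part[paste(fr, tr)]
        if (!anyNA(ps) && length(unique(ps)) == 1) tp <- tp + 1L
      }
    }
    list(tp = tp, fn = length(ref_tracks) - tp,
         fp = length(est_tracks) - tp)
  }
}

count_links <- function(tracks) {
  if (nrow(tracks) == 0) return(0L)
  sum(vapply(split(tracks$frame, tracks$track), function(fr) {
    sum(diff(sort(fr)) == 1)
  }, integer(1)))
}

#' Jaccard tracking accuracy
#'
#' `TP / (TP + FN + FP)`, in \[0, 1\]: 0 when every track is missed, 1 when
#' all tracks are perfectly recovered. Applied to frame-to-frame decisions it
#' is the Jaccard metric; applied to complete tracks it is Jaccard Theta.
#' The degenerate all-zero case (nothing to track, nothing tracked) is
#' defined as perfect agreement, 1.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A number in \[0, 1\].
#' @examples
#' jaccard(3, 1, 2) # 0.5
#' @export
jaccard <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) {
    message("jaccard: no tracks on either side; defining agreement as 1")
    return(1)
  }
  tp / (tp + fn + fp)
}

#' Alpha and Beta tracking accuracy
#'
#' Both compare paired centroid distances against the worst case where every
#' reference position is missed at the gating tolerance: with `D` the sum
#' over reference positions of the paired distance (or `epsilon` when
#' unpaired) and `D_dummy = epsilon * n_ref_positions`, Alpha is
#' `1 - D / D_dummy` and ignores spurious (FP) estimated positions, while
#' Beta, `(D_dummy - D) / (D_dummy + epsilon * n_fp_positions)`, additionally
#' penalizes them. Both lie in \[0, 1\] and `beta <= alpha`, with equality
#' iff there are no spurious positions.
#'
#' @param pairing A `"track_pairing"`.
#' @return A number in \[0, 1\].
#' @export
alpha_metric <- function(pairing) {
  dd <- alpha_beta_parts(pairing)
  1 - dd$D / dd$D_dummy
}

#' @rdname alpha_metric
#' @export
beta_metric <- function(pairing) {
  dd <- alpha_beta_parts(pairing)
  (dd$D_dummy - dd$D) / (dd$D_dummy + pairing$epsilon * dd$n_fp)
}

alpha_beta_parts <- function(pairing) {
  ref <- pairing$ref
  if (nrow(ref) == 0) stop("empty reference track set", call. = FALSE)
  key_ref <- paste(ref$frame, ref$track)
  key_pair <- paste(pairing$pairs$frame, pairing$pairs$ref_track)
  d <- pairing$pairs$dist[match(key_ref, key_pair)]
  d[is.na(d)] <- pairing$epsilon
  est <- pairing$est
  key_est <- paste(est$frame, est$track)
  key_pair_e <- paste(pairing$pairs$frame, pairing$pairs$est_track)
  n_fp <- sum(!(key_est %in% key_pair_e))
  list(D = sum(d), D_dummy = pairing$epsilon * nrow(ref), n_fp = n_fp)
}

#' Evaluate tracking accuracy against a reference
#'
#' Computes the four standard accuracy metrics — Alpha, Beta, Jaccard on
#' frame-to-frame decisions, and Jaccard Theta on complete tracks — after
#' mapping estimated to reference tracks either by gated centroid distance
#' or by mutual maximum overlap.
#'
#' @param ref,est Either labeled mask sequences (lists of matrices) or track
#'   tibbles (`track`, `frame`, `row`, `col`). Mask input is required for
#'   `mode = "overlap"`.
#' @param mode `"distance"` (centroid gate, simulated-data convention) or
#'   `"overlap"` (mutual maximum overlap, bio-data convention).
#' @param epsilon Gating tolerance in pixels (default 5).
#' @return A one-row tibble: `alpha`, `beta`, `jaccard`, `jaccard_theta`,
#'   and the underlying counts `tp`, `fp`, `fn` (decisions scope) and
#'   `tp_track`, `fp_track`, `fn_track`.
#' @export
evaluate_tracking <- function(ref, est, mode = c("distance", "overlap"),
                              epsilon = 5) {
  mode <- match.arg(mode)
  is_masks <- function(x) is.list(x) && !is.data.frame(x)
  if (mode == "overlap") {
    if (!is_masks(ref) || !is_masks(est)) {
      stop("overlap mapping requires labeled mask sequences", call. = FALSE)
    }
    pairing <- map_tracks_by_overlap(ref, est, epsilon)
  } else {
    if (is_masks(ref)) ref <- mask_track_set(ref)
    if (is_masks(est)) est <- mask_track_set(est)
    pairing <- map_tracks_by_distance(ref, est, epsilon)
  }
  dec <- count_tp_fp_fn(pairing, "decisions")
  whole <- count_tp_fp_fn(pairing, "whole_track")
  tibble(
    alpha = alpha_metric(pairing),
    beta = beta_metric(pairing),
    jaccard = jaccard(dec$tp, dec$fp, dec$fn),
    jaccard_theta = jaccard(whole$tp, whole$fp, whole$fn),
    tp = dec$tp, fp = dec$fp, fn = dec$fn,
    tp_track = whole$tp, fp_track = whole$fp, fn_track = whole$fn
  )
}
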