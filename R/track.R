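#' Track a labeled mask sequence
#'
#' Runs the full tracking pipeline over a time-ordered sequence of labeled
#' masks: for every consecutive frame pair it computes the pairwise overlap
#' table, detects and (unless fusion is enabled) splits collision clusters,
#' detects mitosis events, links the remaining objects by minimum-cost
#' one-to-one assignment, classifies whatever stays unmatched
#' (border exit/entry, death, birth), and fuses the per-pair decisions into
#' global tracks with unique labels, division edges, fusion edges and a
#' per-track confidence index.
#'
#' The engine is streaming: it holds the pixel data of exactly two frames at
#' any moment, so peak memory does not grow with sequence length. Frames can
#' therefore be supplied as file paths (read one at a time), as an in-memory
#' list, or as a generator function.
#'
#' @param frames One of: a character vector of TIFF paths (or a single glob
#'   pattern) in time order; a list of integer label matrices; or a function
#'   `f(i)` returning the matrix of frame `i` (1-based) — then `n_frames`
#'   must be given.
#' @param config A [tracking_config()].
#' @param output_dir If non-`NULL`, globally relabeled masks are written
#'   there as TIFFs while tracking proceeds.
#' @param keep_masks Keep the relabeled masks in the returned object?
#'   Defaults to `TRUE` when `output_dir` is `NULL`, else `FALSE` (pure
#'   streaming).
#' @param n_frames Number of frames, required when `frames` is a function.
#' @param verbose Emit a per-frame progress line (objects, links, events) to
#'   the message stream.
#' @return An object of class `"tracking_result"`: a list with `tracks`
#'   (tibble: `label`, `birth`, `death`, `origin`, `end`, the four
#'   confidence indicators and `confidence`), `divisions` (tibble `mother`,
#'   `daughter1`, `daughter2`, `frame` — the mother's last frame),
#'   `fusions` (tibble `child`, `parents` list-column, `frame` — the child's
#'   first frame), `n_frames`, `config`, and `masks` (list of relabeled
#'   masks, or `NULL` when streaming). Frame numbers are 0-based throughout.
#' @examples
#' sim <- simulate_particles(n_particles = 4, n_frames = 6, seed = 7)
#' res <- track_masks(sim$masks)
#' tidy(res)
#' glance(res)
#' @export
track_masks <- function(frames, config = tracking_config(),
                        output_dir = NULL, keep_masks = NULL,
                        n_frames = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "tracking_config"))
  src <- frame_source(frames, n_frames)
  n <- src$n
  if (n < 2) {
    stop("tracking needs at least 2 frames, got ", n, call. = FALSE)
  }
  if (is.null(keep_masks)) keep_masks <- is.null(output_dir)
  writer <- mask_writer(output_dir, n)

  st <- new.env(parent = emptyenv())
  st$birth <- integer()
  st$death <- integer()
  st$origin <- character()
  st$end <- character()
  st$border <- logical()
  st$contact <- logical()
  st$max_cost <- double()
  new_track <- function(birth, origin, border) {
    st$birth <- c(st$birth, birth)
    st$death <- c(st$death, birth)
    st$origin <- c(st$origin, origin)
    st$end <- c(st$end, "last_frame")
    st$border <- c(st$border, border)
    st$contact <- c(st$contact, FALSE)
    st$max_cost <- c(st$max_cost, 0)
    length(st$birth)
  }
  divisions <- list()
  fusions <- list()
  out_masks <- if (keep_masks) vector("list", n) else NULL

  # frame 0: every object starts a track, in label order
  raw <- src$get(1L)
  feat <- extract_features(raw)
  lookup <- integer(max(raw, 1L) + 1L)
  for (k in seq_len(nrow(feat))) {
    g <- new_track(0L, "first_frame", feat$touches_border[k])
    lookup[feat$label[k] + 1L] <- g
  }
  prev <- matrix(lookup[raw + 1L], nrow(raw), ncol(raw))
  prev_feat <- feat
  prev_feat$label <- lookup[feat$label + 1L]
  prev_feat <- dplyr::arrange(prev_feat, .data$label)
  writer(prev, 1L)
  if (keep_masks) out_masks[[1]] <- new_labeled_mask(prev, 0L)

  half_scale <- (config$w_o + config$w_c + config$w_s) / 2

  for (i in 2:n) {
    t1 <- i - 1L # 0-based index of the current frame
    raw <- src$get(i)
    if (!all(dim(raw) == dim(prev))) {
      stop("frame ", t1, " dimensions ", paste(dim(raw), collapse = "x"),
           " differ from previous frames", call. = FALSE)
    }
    feat <- extract_features(raw)
    ov <- overlap_table(prev, raw)
    events <- detect_collisions(ov, prev_feat, feat, config)

    consumed_prev <- integer()
    consumed_cur <- integer()
    direct <- tibble(source = integer(), part = integer())
    fusion_now <- list()

    if (nrow(events) > 0 && !config$enable_fusion) {
      for (e in seq_len(nrow(events))) {
        srcs <- events$sources[[e]]
        raw <- separate_cluster(prev, raw, events$cluster[e], srcs)
        parts <- attr(raw, "part_labels")
        direct <- dplyr::bind_rows(
          direct, tibble(source = srcs, part = unname(parts))
        )
        st$contact[srcs] <- TRUE
      }
      consumed_prev <- direct$source
      consumed_cur <- direct$part
      feat <- extract_features(raw)
      ov <- overlap_table(prev, raw)
    } else if (nrow(events) > 0) {
      fusion_now <- lapply(seq_len(nrow(events)), function(e) {
        list(cluster = events$cluster[e], parents = events$sources[[e]])
      })
      consumed_prev <- unlist(events$sources)
      consumed_cur <- events$cluster
    }

    keep_t <- !(prev_feat$label %in% consumed_prev)
    keep_t1 <- !(feat$label %in% consumed_cur)
    ov_rem <- ov[!(ov$label_t %in% consumed_prev) &
                   !(ov$label_t1 %in% consumed_cur), ]
    mit <- detect_mitosis(prev_feat[keep_t, ], feat[keep_t1, ],
                          ov_rem, config)
    mothers <- mit$mother
    daughters <- c(mit$daughter1, mit$daughter2)

    keep_t <- keep_t & !(prev_feat$label %in% mothers)
    keep_t1 <- keep_t1 & !(feat$label %in% daughters)
    ov_rem <- ov_rem[!(ov_rem$label_t %in% mothers) &
                       !(ov_rem$label_t1 %in% daughters), ]
    cm <- linking_cost(prev_feat[keep_t, ], feat[keep_t1, ],
                       ov_rem, config)
    mapping <- solve_assignment(cm)

    # dispositions of prev-frame objects
    matched_prev <- mapping$label_t
    for (g in prev_feat$label) {
      if (g %in% matched_prev || g %in% direct$source) next
      if (g %in% mothers) {
        st$end[g] <- "divided"
      } else if (length(fusion_now) &&
                 g %in% unlist(lapply(fusion_now, `[[`, "parents"))) {
        st$end[g] <- "fused"
        st$contact[g] <- TRUE
      } else if (prev_feat$touches_border[prev_feat$label == g]) {
        st$end[g] <- "left_fov"
      } else {
        st$end[g] <- "died"
      }
    }

    # build the current frame's raw-label -> global-label lookup
    lookup <- integer(max(raw, 1L) + 1L)
    border_of <- stats::setNames(feat$touches_border, feat$label)
    link_cost_of <- stats::setNames(rep(NA_real_, nrow(feat)), feat$label)
    if (nrow(mapping) > 0) {
      lookup[mapping$label_t1 + 1L] <- mapping$label_t
      link_cost_of[as.character(mapping$label_t1)] <- mapping$cost
    }
    if (nrow(direct) > 0) {
      lookup[direct$part + 1L] <- direct$source
      dcost <- pair_costs(prev_feat, feat, ov, config,
                          direct$source, direct$part)
      link_cost_of[as.character(direct$part)] <- dcost
    }

    # fresh tracks, created in ascending raw-label order
    fusion_children <- vapply(fusion_now, `[[`, integer(1), "cluster")
    new_raw <- setdiff(feat$label, c(mapping$label_t1, direct$part))
    for (j in sort(new_raw)) {
      origin <-
        if (j %in% daughters) "division"
        else if (j %in% fusion_children) "fusion"
        else if (border_of[[as.character(j)]]) "entered_fov"
        else "born"
      g <- new_track(t1, origin, FALSE)
      lookup[j + 1L] <- g
    }

    # lineage edges now that daughters/children have global labels
    if (nrow(mit) > 0) {
      for (e in seq_len(nrow(mit))) {
        divisions[[length(divisions) + 1]] <- tibble(
          mother = mit$mother[e],
          daughter1 = lookup[mit$daughter1[e] + 1L],
          daughter2 = lookup[mit$daughter2[e] + 1L],
          frame = t1 - 1L
        )
      }
    }
    for (f in fusion_now) {
      child <- lookup[f$cluster + 1L]
      st$contact[child] <- TRUE
      fusions[[length(fusions) + 1]] <- tibble(
        child = child, parents = list(f$parents), frame = t1
      )
    }

    # per-track bookkeeping for every object present in the current frame
    for (k in seq_len(nrow(feat))) {
      j <- feat$label[k]
      g <- lookup[j + 1L]
      st$death[g] <- t1
      if (feat$touches_border[k]) st$border[g] <- TRUE
      lc <- link_cost_of[[as.character(j)]]
      if (!is.na(lc) && lc > st$max_cost[g]) st$max_cost[g] <- lc
    }

    cur <- matrix(lookup[raw + 1L], nrow(raw), ncol(raw))
    writer(cur, i)
    if (keep_masks) out_masks[[i]] <- new_labeled_mask(cur, t1)
    if (verbose) {
      message(sprintf(
        "frame %d: %d objects, %d links, %d mitosis, %d collision, %d fusion",
        t1, nrow(feat), nrow(mapping) + nrow(direct), nrow(mit),
        if (config$enable_fusion) 0L else length(unique(direct$source)),
        length(fusion_now)))
    }
    prev <- cur
    prev_feat <- feat
    prev_feat$label <- lookup[feat$label + 1L]
    prev_feat <- dplyr::arrange(prev_feat, .data$label)
  }

  lifespan <- st$death - st$birth + 1L
  tracks <- tibble(
    label = seq_along(st$birth),
    birth = st$birth,
    death = st$death,
    origin = st$origin,
    end = st$end,
    c_lifespan = as.numeric(lifespan >= config$min_track_lifespan),
    c_interior = as.numeric(!st$border),
    c_isolated = as.numeric(!st$contact),
    c_link_quality = as.numeric(st$max_cost <= half_scale)
  )
  tracks$confidence <- (tracks$c_lifespan + tracks$c_interior +
                          tracks$c_isolated + tracks$c_link_quality) / 4

  structure(list(
    tracks = tracks,
    divisions = if (length(divisions)) dplyr::bind_rows(divisions) else
      tibble(mother = integer(), daughter1 = integer(),
             daughter2 = integer(), frame = integer()),
    fusions = if (length(fusions)) dplyr::bind_rows(fusions) else
      tibble(child = integer(), parents = list(), frame = integer()),
    n_frames = n,
    config = config,
    masks = out_masks
  ), class = "tracking_result")
}

# cost of specific (label_t, label_t1) pairs under the three-term formula,
# without the feasibility gate (used for links decided outside assignment)
pair_costs <- function(feat_t, feat_t1, overlaps, config, lt, lt1) {
  it <- match(lt, feat_t$label)
  it1 <- match(lt1, feat_t1$label)
  key <- paste(overlaps$label_t, overlaps$label_t1)
  ovp <- overlaps$pixels[match(paste(lt, lt1), key)]
  ovp[is.na(ovp)] <- 0
  a1 <- feat_t$area[it]
  a2 <- feat_t1$area[it1]
  d <- sqrt((feat_t$row[it] - feat_t1$row[it1])^2 +
              (feat_t$col[it] - feat_t1$col[it1])^2)
  config$w_o * (1 - ovp / pmin(a1, a2)) +
    config$w_c * pmin(d, config$d_max) / config$d_max +
    config$w_s * abs(a1 - a2) / pmax(a1, a2)
}

frame_source <- function(frames, n_frames) {
  if (is.character(frames)) {
    if (length(frames) == 1 && grepl("[*?\\[]", frames)) {
      frames <- sort(Sys.glob(frames))
    }
    if (length(frames) == 0) stop("no input frames", call. = FALSE)
    list(n = length(frames),
         get = function(i) read_labeled_tiff(frames[[i]]))
  } else if (is.list(frames)) {
    list(n = length(frames), get = function(i) frames[[i]])
  } else if (is.function(frames)) {
    if (is.null(n_frames)) {
      stop("`n_frames` is required when `frames` is a generator function",
           call. = FALSE)
    }
    list(n = as.integer(n_frames), get = frames)
  } else {
    stop("`frames` must be paths, a list of matrices, or a function",
         call. = FALSE)
  }
}

mask_writer <- function(output_dir, n) {
  if (is.null(output_dir)) return(function(mask, i) invisible(NULL))
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  width <- max(3L, nchar(n - 1))
  function(mask, i) {
    write_labeled_tiff(
      mask, file.path(output_dir,
                      sprintf("mask_%0*d.tif", width, i - 1L)))
  }
}

#' Per-track confidence index
#'
#' The confidence index of a track is the mean of four binary indicators:
#' the track lives at least `min_track_lifespan` frames; it never touches
#' the image border; it was never involved in a collision split or fusion;
#' and none of its frame-to-frame links cost more than half the maximum cost
#' scale `(w_o + w_c + w_s) / 2`. A score of 1 marks a track whose full life
#' cycle can be trusted without review.
#'
#' @param result A `"tracking_result"`.
#' @return Numeric vector of confidences, one per track, in label order.
#' @export
confidence_index <- function(result) {
  stopifnot(inherits(result, "tracking_result"))
  result$tracks$confidence
}

#' Export the lineage tables as CSV files
#'
#' Writes `tracks.csv` (label, birth, death, origin, end, confidence),
#' `divisions.csv` (mother, daughter1, daughter2, frame) and `fusions.csv`
#' (child, parents as a `;`-separated list, frame). Frame numbers are
#' 0-based, matching the mask file order.
#'
#' @param result A `"tracking_result"`.
#' @param directory Output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
export_lineage <- function(result, directory) {
  stopifnot(inherits(result, "tracking_result"))
  if (!dir.exists(directory)) {
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  }
  paths <- file.path(directory,
                     c("tracks.csv", "divisions.csv", "fusions.csv"))
  tr <- result$tracks[, c("label", "birth", "death", "origin", "end",
                          "confidence")]
  utils::write.csv(tr, paths[1], row.names = FALSE)
  utils::write.csv(result$divisions, paths[2], row.names = FALSE)
  fu <- result$fusions
  fu$parents <- vapply(fu$parents, paste, character(1), collapse = ";")
  utils::write.csv(fu, paths[3], row.names = FALSE)
  invisible(paths)
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf(
    "<tracking_result> %d frames, %d tracks, %d divisions, %d fusions\n",
    x$n_frames, nrow(x$tracks), nrow(x$divisions), nrow(x$fusions)))
  cat(sprintf("  mean confidence %.2f; masks %s\n",
              mean(x$tracks$confidence),
              if (is.null(x$masks)) "streamed (not kept)" else "kept"))
  invisible(x)
}

#' Tidy the track table of a tracking result
#' @param x A `"tracking_result"`.
#' @param ... Unused.
#' @return The tracks tibble (one row per global track).
#' @export
tidy.tracking_result <- function(x, ...) x$tracks

#' One-row summary of a tracking result
#' @param x A `"tracking_result"`.
#' @param ... Unused.
#' @return A one-row tibble: frames, tracks, divisions, fusions, mean
#'   confidence.
#' @export
glance.tracking_result <- function(x, ...) {
  tibble(
    n_frames = x$n_frames,
    n_tracks = nrow(x$tracks),
    n_divisions = nrow(x$divisions),
    n_fusions = nrow(x$fusions),
    mean_confidence = mean(x$tracks$confidence)
  )
}
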