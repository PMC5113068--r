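#' Tracking configuration
#'
#' Bundles every tunable of the tracking engine into a validated list. The
#' frame-to-frame linking cost is `w_o * (1 - O) + w_c * delta_c + w_s *
#' delta_s`, where `O` is the pairwise overlap normalized by the smaller
#' object's area, `delta_c` the centroid displacement capped at and divided by
#' `d_max`, and `delta_s` the relative area change. All three terms lie in
#' \[0, 1\], so the weights are directly comparable; overlap carries the
#' largest default weight because spatial overlap is the primary evidence for
#' identity between consecutive frames.
#'
#' @param w_o Weight of the overlap term (>= 0). Default 1.
#' @param w_c Weight of the centroid-displacement term (>= 0). Default 0.5.
#' @param w_s Weight of the size-change term (>= 0). Default 0.2.
#' @param d_max Largest plausible centroid displacement per frame, in pixels.
#'   Pairs with zero overlap whose centroids are further apart than `d_max`
#'   are infeasible links. Default 50.
#' @param min_division_overlap Minimum overlap fraction used by the mitosis
#'   detector, both per daughter (fraction of the daughter's own area covered
#'   by the mother) and combined (fraction of the mother's area covered by the
#'   daughter pair). Default 0.2.
#' @param min_mother_circularity Minimum circularity (`4 * pi * A / P^2`,
#'   clipped to 1) of a mother cell at the frame before division; mitosis is
#'   preceded by the mother rounding up. Default 0.3.
#' @param min_daughter_size_similarity Minimum `min(area) / max(area)` ratio
#'   between the two daughters. Default 0.5.
#' @param min_daughter_aspect_similarity Minimum ratio between the daughters'
#'   aspect ratios. Default 0.7.
#' @param enable_fusion When `TRUE`, a cluster fed by several earlier objects
#'   is recorded as a genuine fusion (lineage branches merging, as for
#'   stem-cell colonies) and masks are left untouched; when `FALSE` (default)
#'   it is treated as a segmentation error and split.
#' @param min_collision_overlap Fraction of its own area by which each earlier
#'   object must overlap a candidate cluster for a collision/fusion to be
#'   declared. Default 0.5 (majority coverage).
#' @param min_track_lifespan Minimum length, in frames, for a track to earn
#'   the lifespan point of the confidence index. Default 5.
#' @param seed Integer seed, used only by the simulator convenience wrappers.
#'
#' @return A list with class `"tracking_config"`.
#' @examples
#' cfg <- tracking_config(w_c = 1)
#' cfg$w_c
#' @export
tracking_config <- function(w_o = 1, w_c = 0.5, w_s = 0.2,
                            d_max = 50,
                            min_division_overlap = 0.2,
                            min_mother_circularity = 0.3,
                            min_daughter_size_similarity = 0.5,
                            min_daughter_aspect_similarity = 0.7,
                            enable_fusion = FALSE,
                            min_collision_overlap = 0.5,
                            min_track_lifespan = 5,
                            seed = 1L) {
  cfg <- list(
    w_o = w_o, w_c = w_c, w_s = w_s, d_max = d_max,
    min_division_overlap = min_division_overlap,
    min_mother_circularity = min_mother_circularity,
    min_daughter_size_similarity = min_daughter_size_similarity,
    min_daughter_aspect_similarity = min_daughter_aspect_similarity,
    enable_fusion = isTRUE(enable_fusion),
    min_collision_overlap = min_collision_overlap,
    min_track_lifespan = min_track_lifespan,
    seed = as.integer(seed)
  )
  validate_tracking_config(cfg)
  structure(cfg, class = "tracking_config")
}

validate_tracking_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (w in c("w_o", "w_c", "w_s")) {
    if (!num1(cfg[[w]]) || cfg[[w]] < 0) {
      stop(sprintf("`%s` must be a single non-negative number", w),
           call. = FALSE)
    }
  }
  if (cfg$w_o + cfg$w_c + cfg$w_s <= 0) {
    stop("at least one of w_o, w_c, w_s must be positive", call. = FALSE)
  }
  if (!num1(cfg$d_max) || cfg$d_max <= 0) {
    stop("`d_max` must be a positive number of pixels", call. = FALSE)
  }
  for (f in c("min_division_overlap", "min_mother_circularity",
              "min_daughter_size_similarity",
              "min_daughter_aspect_similarity", "min_collision_overlap")) {
    if (!num1(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("`%s` must lie in [0, 1]", f), call. = FALSE)
    }
  }
  if (!num1(cfg$min_track_lifespan) || cfg$min_track_lifespan < 1) {
    stop("`min_track_lifespan` must be >= 1 frame", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a tracking configuration from a JSON file
#'
#' The file is a flat JSON object whose keys are [tracking_config()] argument
#' names; absent keys keep their defaults, unknown keys are an error.
#'
#' @param path Path to a JSON file.
#' @param ... Overrides applied on top of the file's values (e.g. from
#'   command-line flags).
#' @return A `"tracking_config"` object.
#' @export
read_tracking_config <- function(path, ...) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(tracking_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(tracking_config, vals)
}

#' @export
print.tracking_config <- function(x, ...) {
  cat("<tracking_config>\n")
  cat(sprintf("  cost weights : w_o = %g, w_c = %g, w_s = %g\n",
              x$w_o, x$w_c, x$w_s))
  cat(sprintf("  gating       : d_max = %g px\n", x$d_max))
  cat(sprintf("  mitosis      : overlap >= %g, circularity >= %g,",
              x$min_division_overlap, x$min_mother_circularity),
      sprintf("size sim >= %g, aspect sim >= %g\n",
              x$min_daughter_size_similarity,
              x$min_daughter_aspect_similarity))
  cat(sprintf("  collisions   : overlap >= %g, fusion %s\n",
              x$min_collision_overlap,
              if (x$enable_fusion) "enabled (record, don't split)"
              else "disabled (split clusters)"))
  cat(sprintf("  confidence   : min lifespan %d frames\n",
              as.integer(x$min_track_lifespan)))
  invisible(x)
}
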