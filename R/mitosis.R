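#' Detect mitosis events between two frames
#'
#' A division is declared for mother `m` at time t and daughters `d1`, `d2`
#' at t+1 when all four biological indicators hold:
#'
#' 1. exactly two objects at t+1 each overlap `m` by at least
#'    `min_division_overlap` of their own area and have `m` as their dominant
#'    source at t (if more than two fragments qualify, the two with the
#'    largest overlap are tested as the daughter pair — mothers divide into
#'    two daughters);
#' 2. the mother is round: `circularity(m) >= min_mother_circularity`
#'    (cells round up before dividing);
#' 3. the mother barely migrates during division, so the daughters' combined
#'    overlap covers at least `min_division_overlap` of the mother's area;
#' 4. the daughters are similar: area ratio `>=
#'    min_daughter_size_similarity` and aspect-ratio ratio `>=
#'    min_daughter_aspect_similarity`.
#'
#' Each object at t+1 joins at most one event; mothers are processed in
#' ascending label order and a daughter already claimed is not reused.
#'
#' @param feat_t,feat_t1 Feature tables of the two frames.
#' @param overlaps Overlap table for the frame pair (after any collision
#'   separation).
#' @param config A [tracking_config()].
#' @return A tibble `mother`, `daughter1`, `daughter2` (labels;
#'   `daughter1 < daughter2`), zero rows when no event is found.
#' @export
detect_mitosis <- function(feat_t, feat_t1, overlaps, config) {
  stopifnot(inherits(config, "tracking_config"))
  empty <- tibble(mother = integer(), daughter1 = integer(),
                  daughter2 = integer())
  if (nrow(overlaps) == 0 || nrow(feat_t) == 0 || nrow(feat_t1) == 0) {
    return(empty)
  }
  ft <- feat_t
  ft1 <- feat_t1
  ov <- overlaps %>%
    dplyr::left_join(ft1[, c("label", "area")],
                     by = c(label_t1 = "label")) %>%
    dplyr::group_by(.data$label_t1) %>%
    dplyr::mutate(dominant = .data$pixels == max(.data$pixels) &
                    sum(.data$pixels == max(.data$pixels)) == 1) %>%
    dplyr::ungroup()

  used_daughters <- integer()
  events <- list()
  for (m in sort(ft$label)) {
    mrow <- ft[ft$label == m, ]
    if (mrow$circularity < config$min_mother_circularity) next
    cand <- ov %>%
      dplyr::filter(.data$label_t == m,
                    .data$dominant,
                    .data$pixels >= config$min_division_overlap * .data$area,
                    !(.data$label_t1 %in% used_daughters)) %>%
      dplyr::arrange(dplyr::desc(.data$pixels), .data$label_t1)
    if (nrow(cand) < 2) next
    pair <- cand[1:2, ]
    if (sum(pair$pixels) < config$min_division_overlap * mrow$area) next
    d <- ft1[match(pair$label_t1, ft1$label), ]
    size_sim <- min(d$area) / max(d$area)
    aspect_sim <- min(d$aspect_ratio) / max(d$aspect_ratio)
    if (size_sim < config$min_daughter_size_similarity) next
    if (aspect_sim < config$min_daughter_aspect_similarity) next
    dd <- sort(pair$label_t1)
    events[[length(events) + 1]] <-
      tibble(mother = m, daughter1 = dd[1], daughter2 = dd[2])
    used_daughters <- c(used_daughters, dd)
  }
  if (length(events) == 0) empty else dplyr::bind_rows(events)
}
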