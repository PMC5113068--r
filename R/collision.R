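#' Detect collision (or fusion) events between two frames
#'
#' A label `j` at time t+1 is a collision cluster when at least two labels at
#' time t each overlap `j` by at least `min_collision_overlap` of their own
#' area: several objects that were individually resolved at t occupy a single
#' label at t+1. With `enable_fusion = TRUE` the same events are returned
#' tagged as genuine fusions (branches of the lineage merging, as for
#' stem-cell colonies) and downstream no mask is modified.
#'
#' @param overlaps Overlap table for the frame pair.
#' @param feat_t,feat_t1 Feature tables of the two frames.
#' @param config A [tracking_config()].
#' @return A tibble `cluster` (label at t+1), `sources` (list column of >= 2
#'   labels at t), `type` (`"collision"` or `"fusion"`).
#' @export
detect_collisions <- function(overlaps, feat_t, feat_t1, config) {
  stopifnot(inherits(config, "tracking_config"))
  empty <- tibble(cluster = integer(), sources = list(),
                  type = character())
  if (nrow(overlaps) == 0) return(empty)
  ov <- dplyr::left_join(overlaps,
                         feat_t[, c("label", "area")],
                         by = c(label_t = "label"))
  strong <- ov[ov$pixels >= config$min_collision_overlap * ov$area, ]
  if (nrow(strong) == 0) return(empty)
  ev <- strong %>%
    dplyr::group_by(.data$label_t1) %>%
    dplyr::summarise(sources = list(sort(.data$label_t)),
                     n = dplyr::n(), .groups = "drop") %>%
    dplyr::filter(.data$n >= 2)
  if (nrow(ev) == 0) return(empty)
  tibble(
    cluster = ev$label_t1,
    sources = ev$sources,
    type = if (config$enable_fusion) "fusion" else "collision"
  )
}

#' Split a collision cluster by seeded geodesic partition
#'
#' The cluster's pixels are divided among the colliding sources. Each
#' source's seed is the intersection of the cluster with that source's
#' footprint at time t; every remaining cluster pixel joins the seed with the
#' shortest within-cluster (geodesic, 8-connected) path distance, so the
#' split follows the cluster's own geometry around concavities. Ties go to
#' the lower source label. The cluster's pixel count is conserved exactly.
#'
#' @param mask_t Labeled mask at time t (the frame where the sources are
#'   individually resolved).
#' @param mask_t1 Labeled mask at t+1 containing the cluster.
#' @param cluster Label of the cluster in `mask_t1`.
#' @param sources Integer labels in `mask_t` to split the cluster among.
#' @param new_labels Labels to assign to the parts, parallel to `sources`.
#'   Defaults to fresh labels above `max(mask_t1)`.
#' @return The modified `mask_t1` with the cluster partitioned; the part
#'   seeded by `sources[k]` carries `new_labels[k]`. Attribute
#'   `"part_labels"` maps sources to the labels used.
#' @export
separate_cluster <- function(mask_t, mask_t1, cluster, sources,
                             new_labels = NULL) {
  sources <- sort(as.integer(sources))
  if (length(sources) < 2) {
    stop("a collision cluster needs at least two sources", call. = FALSE)
  }
  if (is.null(new_labels)) {
    new_labels <- max(mask_t1) + seq_along(sources)
  }
  stopifnot(length(new_labels) == length(sources))
  nr <- nrow(mask_t1)
  pix <- which(mask_t1 == cluster)
  if (length(pix) == 0) {
    stop("cluster label ", cluster, " not present in mask_t1",
         call. = FALSE)
  }
  owner <- integer(length(pix)) # index into sources, 0 = unassigned
  pos <- match(seq_len(length(mask_t1)), pix) # full-grid -> cluster index
  # seeds: cluster pixels covered by each source's footprint at t; a pixel
  # covered by several sources goes to the lowest label (sources are sorted)
  for (k in seq_along(sources)) {
    sk <- which(owner == 0L & mask_t[pix] == sources[k])
    owner[sk] <- k
    if (length(sk) == 0) {
      stop("source ", sources[k], " has no footprint inside the cluster",
           call. = FALSE)
    }
  }
  # multi-source BFS, seeds enqueued in source order so that equal-distance
  # pixels resolve to the lower source label
  queue <- integer(length(pix))
  tail <- 0L
  for (k in seq_along(sources)) {
    sk <- which(owner == k)
    queue[tail + seq_along(sk)] <- sk
    tail <- tail + length(sk)
  }
  head <- 1L
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  wrap_r <- ((pix - 1L) %% nr) + 1L
  while (head <= tail) {
    ci <- queue[head]
    head <- head + 1L
    p <- pix[ci]
    pr <- wrap_r[ci]
    for (o in offs) {
      q <- p + o
      # guard against row wrap-around at matrix edges
      qr <- pr + (if (o == -1L || o == -nr - 1L || o == nr - 1L) -1L
                  else if (o == 1L || o == -nr + 1L || o == nr + 1L) 1L
                  else 0L)
      if (qr < 1L || qr > nr || q < 1L || q > length(mask_t1)) next
      cj <- pos[q]
      if (!is.na(cj) && owner[cj] == 0L) {
        owner[cj] <- owner[ci]
        tail <- tail + 1L
        queue[tail] <- cj
      }
    }
  }
  # pixels unreachable from any seed (separate islands of the same label):
  # give them to the nearest seed centroid in Euclidean terms
  if (any(owner == 0L)) {
    rs <- ((pix - 1L) %% nr) + 1L
    cs <- ((pix - 1L) %/% nr) + 1L
    left <- which(owner == 0L)
    cen_r <- vapply(seq_along(sources),
                    function(k) mean(rs[owner == k]), numeric(1))
    cen_c <- vapply(seq_along(sources),
                    function(k) mean(cs[owner == k]), numeric(1))
    for (ci in left) {
      d2 <- (rs[ci] - cen_r)^2 + (cs[ci] - cen_c)^2
      owner[ci] <- which.min(d2)
    }
  }
  out <- mask_t1
  out[pix] <- as.integer(new_labels[owner])
  attr(out, "part_labels") <- stats::setNames(as.integer(new_labels),
                                              sources)
  out
}
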