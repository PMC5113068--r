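#' Pairwise overlap between objects of two consecutive frames
#'
#' Entry `(i, j)` counts the pixel positions labeled `i` in the first frame
#' and `j` in the second. Zero-overlap pairs are omitted, so the table is
#' sparse.
#'
#' @param mask_t,mask_t1 Labeled masks of identical dimensions.
#' @return A tibble `label_t`, `label_t1`, `pixels` sorted by the pair.
#' @examples
#' m <- matrix(0L, 5, 5); m[1:3, 1:3] <- 1L
#' m2 <- matrix(0L, 5, 5); m2[2:4, 2:4] <- 7L
#' overlap_table(m, m2) # 1 -> 7, 4 shared pixels
#' @export
overlap_table <- function(mask_t, mask_t1) {
  if (!all(dim(mask_t) == dim(mask_t1))) {
    stop("masks must have identical dimensions", call. = FALSE)
  }
  both <- which(mask_t > 0L & mask_t1 > 0L)
  if (length(both) == 0) {
    return(tibble(label_t = integer(), label_t1 = integer(),
                  pixels = integer()))
  }
  tibble(label_t = mask_t[both], label_t1 = mask_t1[both]) %>%
    dplyr::count(.data$label_t, .data$label_t1, name = "pixels")
}

#' Frame-to-frame linking cost matrix
#'
#' The cost of linking object `i` at time t to object `j` at t+1 is
#' `w_o * (1 - O_ij) + w_c * delta_c + w_s * delta_s`, with
#' `O_ij = overlap / min(area_i, area_j)` (full engulfment of the smaller
#' object scores 1, which keeps the term meaningful through divisions and
#' collisions), `delta_c = min(centroid distance, d_max) / d_max`, and
#' `delta_s = |area_i - area_j| / max(area_i, area_j)`. Each term lies in
#' \[0, 1\]. A pair with zero overlap whose centroids are further apart than
#' `d_max` is infeasible (`NA` in the matrix): such a link is never assigned.
#'
#' @param feat_t,feat_t1 Feature tables from [extract_features()] for the two
#'   frames.
#' @param overlaps Overlap table from [overlap_table()] for the same pair.
#' @param config A [tracking_config()].
#' @return An object of class `"cost_matrix"`: list with `costs` (numeric
#'   matrix, `NA` = infeasible), `rows` (labels at t), `cols` (labels at
#'   t+1).
#' @export
linking_cost <- function(feat_t, feat_t1, overlaps, config) {
  stopifnot(inherits(config, "tracking_config"))
  bad_t <- setdiff(overlaps$label_t, feat_t$label)
  bad_t1 <- setdiff(overlaps$label_t1, feat_t1$label)
  if (length(bad_t) > 0 || length(bad_t1) > 0) {
    stop("overlap table references labels absent from the feature tables: ",
         paste(c(bad_t, bad_t1), collapse = ", "), call. = FALSE)
  }
  rows <- feat_t$label
  cols <- feat_t1$label
  n <- length(rows)
  m <- length(cols)
  costs <- matrix(NA_real_, n, m, dimnames = list(rows, cols))
  if (n == 0 || m == 0) {
    return(new_cost_matrix(costs, rows, cols))
  }
  ov <- matrix(0, n, m)
  if (nrow(overlaps) > 0) {
    ov[cbind(match(overlaps$label_t, rows),
             match(overlaps$label_t1, cols))] <- overlaps$pixels
  }
  a_t <- feat_t$area
  a_t1 <- feat_t1$area
  min_area <- outer(a_t, a_t1, pmin)
  max_area <- outer(a_t, a_t1, pmax)
  o_term <- 1 - ov / min_area
  d <- sqrt(outer(feat_t$row, feat_t1$row, "-")^2 +
              outer(feat_t$col, feat_t1$col, "-")^2)
  c_term <- pmin(d, config$d_max) / config$d_max
  s_term <- abs(outer(a_t, a_t1, "-")) / max_area
  costs <- config$w_o * o_term + config$w_c * c_term + config$w_s * s_term
  costs[ov == 0 & d > config$d_max] <- NA_real_
  dimnames(costs) <- list(rows, cols)
  new_cost_matrix(costs, rows, cols)
}

new_cost_matrix <- function(costs, rows, cols) {
  structure(list(costs = costs, rows = rows, cols = cols),
            class = "cost_matrix")
}

#' @export
print.cost_matrix <- function(x, ...) {
  cat(sprintf("<cost_matrix> %d x %d (%d feasible pairs)\n",
              length(x$rows), length(x$cols), sum(!is.na(x$costs))))
  if (length(x$costs) > 0 && length(x$costs) <= 100) print(round(x$costs, 3))
  invisible(x)
}

#' Long view of a cost matrix
#'
#' @param x A `"cost_matrix"`.
#' @param ... Unused.
#' @return Tibble `label_t`, `label_t1`, `cost` over feasible pairs.
#' @export
tidy.cost_matrix <- function(x, ...) {
  if (length(x$costs) == 0) {
    return(tibble(label_t = integer(), label_t1 = integer(),
                  cost = double()))
  }
  feas <- which(!is.na(x$costs), arr.ind = TRUE)
  tibble(
    label_t = x$rows[feas[, 1]],
    label_t1 = x$cols[feas[, 2]],
    cost = x$costs[feas]
  ) %>% dplyr::arrange(.data$label_t, .data$label_t1)
}
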