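# Shortest-augmenting-path (Jonker-Volgenant style) solver for the
# rectangular linear assignment problem. Runs on a finite n x m matrix with
# n <= m and returns, for each row, its matched column. O(n^2 m), exact.
lsap_solve <- function(a) {
  n <- nrow(a)
  m <- ncol(a)
  stopifnot(n <= m, all(is.finite(a)))
  V <- m + 1L # virtual "column 0" of the augmenting path bookkeeping
  u <- numeric(n)
  v <- numeric(m + 1L)
  p <- integer(m + 1L) # p[j] = row matched to column j, 0 = free
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[V] <- i
    j0 <- V
    minv <- rep(Inf, m)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      js <- which(!used[seq_len(m)])
      cur <- a[i0, js] - u[i0] - v[js]
      upd <- cur < minv[js]
      if (any(upd)) {
        minv[js[upd]] <- cur[upd]
        way[js[upd]] <- j0
      }
      jbest <- js[which.min(minv[js])]
      delta <- minv[jbest]
      usedj <- which(used)
      u[p[usedj]] <- u[p[usedj]] + delta
      v[usedj] <- v[usedj] - delta
      free <- which(!used[seq_len(m)])
      minv[free] <- minv[free] - delta
      j0 <- jbest
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == V) break
    }
  }
  match_of_row <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) match_of_row[p[j]] <- j
  match_of_row
}

#' Optimal one-to-one track assignment
#'
#' Solves the linear assignment problem over the feasible entries of a cost
#' matrix: each object at time t is matched to at most one object at t+1 and
#' vice versa, no infeasible pair is ever matched, and among all matchings of
#' maximum feasible cardinality the total cost is minimal. Infeasible entries
#' are encoded internally as a finite sentinel larger than any achievable
#' total, so the solver maximizes cardinality first, cost second; sentinel
#' matches are dropped afterwards.
#'
#' @param costs A `"cost_matrix"` from [linking_cost()], or a plain numeric
#'   matrix with `NA` marking infeasible pairs.
#' @return A tibble `label_t`, `label_t1`, `cost`, one row per matched pair
#'   (empty when nothing is feasible). For a plain matrix, labels are row and
#'   column indices.
#' @examples
#' solve_assignment(matrix(c(1, 2, 2, 1), 2, byrow = TRUE))
#' @export
solve_assignment <- function(costs) {
  if (inherits(costs, "cost_matrix")) {
    a <- costs$costs
    rows <- costs$rows
    cols <- costs$cols
  } else {
    a <- as.matrix(costs)
    rows <- seq_len(nrow(a))
    cols <- seq_len(ncol(a))
  }
  empty <- tibble(label_t = rows[0], label_t1 = cols[0], cost = double())
  n <- nrow(a)
  m <- ncol(a)
  if (n == 0 || m == 0 || all(is.na(a))) return(empty)
  finite_max <- max(a, na.rm = TRUE)
  big <- (abs(finite_max) + 1) * (min(n, m) + 1)
  af <- a
  af[is.na(af)] <- big
  if (n <= m) {
    mc <- lsap_solve(af)
    pairs <- cbind(seq_len(n), mc)
  } else {
    mr <- lsap_solve(t(af))
    pairs <- cbind(mr, seq_len(m))
  }
  keep <- !is.na(a[pairs])
  pairs <- pairs[keep, , drop = FALSE]
  tibble(
    label_t = rows[pairs[, 1]],
    label_t1 = cols[pairs[, 2]],
    cost = a[pairs]
  ) %>% dplyr::arrange(.data$label_t)
}

#' Classify objects left unmatched by the assignment
#'
#' After mitosis handling and optimal assignment, every remaining unmatched
#' object needs an explanation. An unmatched object at time t is a mitotic
#' mother if a detected division consumed it, has left the field of view if
#' it touches the image border, and otherwise died. An unmatched object at
#' t+1 is a division daughter, has entered through the border, or is a birth.
#'
#' @param mapping Tibble of matched pairs from [solve_assignment()].
#' @param feat_t,feat_t1 Feature tables of the two frames.
#' @param mitosis_events Tibble from [detect_mitosis()] (may be empty).
#' @return A tibble `label`, `frame` (`"t"` or `"t1"`), `disposition`.
#'   Dispositions at t: `continued`, `mitotic_mother`, `left_fov`, `died`;
#'   at t+1: `continued`, `daughter`, `entered_fov`, `born`.
#' @export
classify_unassigned <- function(mapping, feat_t, feat_t1, mitosis_events) {
  mothers <- if (nrow(mitosis_events)) mitosis_events$mother else integer()
  daughters <- if (nrow(mitosis_events)) {
    c(mitosis_events$daughter1, mitosis_events$daughter2)
  } else integer()
  dis_t <- dplyr::mutate(
    feat_t[, c("label", "touches_border")],
    disposition = dplyr::case_when(
      .data$label %in% mapping$label_t ~ "continued",
      .data$label %in% mothers ~ "mitotic_mother",
      .data$touches_border ~ "left_fov",
      TRUE ~ "died"
    ),
    frame = "t"
  )
  dis_t1 <- dplyr::mutate(
    feat_t1[, c("label", "touches_border")],
    disposition = dplyr::case_when(
      .data$label %in% mapping$label_t1 ~ "continued",
      .data$label %in% daughters ~ "daughter",
      .data$touches_border ~ "entered_fov",
      TRUE ~ "born"
    ),
    frame = "t1"
  )
  dplyr::bind_rows(dis_t, dis_t1)[, c("label", "frame", "disposition")]
}
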