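# Exhaustive assignment oracle: enumerates every matching, keeps the one of
# maximum feasible cardinality and, among those, minimum total cost.
# Only usable for small matrices (<= ~6x6).
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  best <- list(card = -1L, total = Inf)
  rec <- function(i, used, total, card) {
    if (card + (n - i + 1L) < best$card) return() # cannot beat best
    if (i > n) {
      if (card > best$card ||
          (card == best$card && total < best$total)) {
        best <<- list(card = card, total = total)
      }
      return()
    }
    rec(i + 1L, used, total, card)
    for (j in seq_len(m)) {
      if (!used[j] && !is.na(cost[i, j])) {
        used[j] <- TRUE
        rec(i + 1L, used, total + cost[i, j], card + 1L)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(m), 0, 0L)
  best
}

# disk mask helper: filled disk of given radius centered at (r0, c0), 1-based
disk_mask <- function(nr, nc, r0, c0, radius, label = 1L) {
  m <- matrix(0L, nr, nc)
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  inside <- (g$r - r0)^2 + (g$c - c0)^2 <= radius^2
  m[cbind(g$r[inside], g$c[inside])] <- as.integer(label)
  m
}

# write a mask to a temp TIFF and return the path
write_tmp_tiff <- function(mask) {
  p <- tempfile(fileext = ".tif")
  masktracker:::write_labeled_tiff(mask, p)
  p
}

# brute-force second-moment aspect ratio from a pixel set (unit-pixel
# corrected), independent of the package's implementation
brute_aspect <- function(mask, label) {
  idx <- which(mask == label)
  r <- ((idx - 1) %% nrow(mask)) + 1
  c <- ((idx - 1) %/% nrow(mask)) + 1
  n <- length(idx)
  mrr <- sum((r - mean(r))^2) / n + 1 / 12
  mcc <- sum((c - mean(c))^2) / n + 1 / 12
  mrc <- sum((r - mean(r)) * (c - mean(c))) / n
  ev <- eigen(matrix(c(mrr, mrc, mrc, mcc), 2), symmetric = TRUE)$values
  sqrt(ev[1] / max(ev[2], 1e-12))
}
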