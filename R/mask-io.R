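#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# A labeled mask is an integer matrix (rows x cols): 0 = background, each
# positive value one segmented object. Sequences are plain lists of such
# matrices, frame 0 first; helpers below attach/read the frame index.

new_labeled_mask <- function(pixels, frame_index = 0L) {
  storage.mode(pixels) <- "integer"
  attr(pixels, "frame_index") <- as.integer(frame_index)
  pixels
}

#' Frame index of a labeled mask
#' @param mask An integer labeled mask read by [read_mask_sequence()].
#' @return The 0-based frame index, or `NA` if none was attached.
#' @export
frame_index <- function(mask) {
  idx <- attr(mask, "frame_index")
  if (is.null(idx)) NA_integer_ else idx
}

#' Read a time-ordered sequence of labeled masks
#'
#' Masks are single-plane TIFF images holding non-negative integer labels:
#' background 0, one positive label per segmented object. Any segmentation
#' source is acceptable — labels need not be consecutive, nor stable across
#' frames. 8- and 16-bit files are read as stored; 32-bit float files are
#' interpreted under the convention of [write_tracked_masks()] (integer labels
#' scaled by 2^24). Pixel values are preserved exactly.
#'
#' @param paths Character vector of file paths in time order (the order of the
#'   vector defines frames 0, 1, ...). A glob pattern is expanded with
#'   [Sys.glob()] and sorted lexicographically.
#' @return A list of integer matrices, each carrying a `frame_index`
#'   attribute 0..N-1.
#' @examples
#' d <- tempfile(); dir.create(d)
#' m <- matrix(0L, 32, 32); m[5:9, 5:9] <- 3L
#' write_tracked_masks(list(m), d)
#' seq <- read_mask_sequence(file.path(d, "mask_000.tif"))
#' identical(seq[[1]][5, 5], 3L)
#' @export
read_mask_sequence <- function(paths) {
  if (length(paths) == 1 && grepl("[*?\\[]", paths)) {
    paths <- sort(Sys.glob(paths))
  }
  if (length(paths) == 0) {
    stop("no input mask files (empty path list)", call. = FALSE)
  }
  masks <- lapply(seq_along(paths), function(i) {
    m <- read_labeled_tiff(paths[[i]])
    new_labeled_mask(m, i - 1L)
  })
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share identical dimensions; got ",
         paste(unique(apply(dims, 2, paste, collapse = "x")),
               collapse = ", "),
         call. = FALSE)
  }
  masks
}

read_labeled_tiff <- function(path) {
  x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (is.array(x) && length(dim(x)) == 3) {
    stop("'", path, "': multi-channel images are not labeled masks",
         call. = FALSE)
  }
  bits <- attr(x, "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  if (bits >= 32L) {
    # 32-bit samples come back as raw uint32 words; files written by
    # write_tracked_masks() hold label/2^24, stored by libtiff as
    # approximately label * 256, hence the /256 below. Anything whose
    # de-scaled values are not near-integers is not a labeled mask.
    if (min(x) < 0) {
      stop("'", path, "': pixel data are not non-negative integer labels ",
           "(is this a float-valued image?)", call. = FALSE)
    }
    vals <- x / 256
    m <- round(vals)
    if (max(abs(vals - m)) > 0.2) {
      stop("'", path, "': pixel data are not non-negative integer labels ",
           "(is this a float-valued image?)", call. = FALSE)
    }
  } else {
    m <- x
    if (min(m) < 0) {
      stop("'", path, "': negative pixel values are not labels",
           call. = FALSE)
    }
  }
  storage.mode(m) <- "integer"
  attributes(m) <- list(dim = dim(m)) # drop readTIFF info attributes
  m
}

#' Write a sequence of (tracked) labeled masks as TIFF files
#'
#' One single-plane TIFF per frame, named `mask_000.tif`, `mask_001.tif`, ...
#' (zero-padded to at least 3 digits). Labels up to 65535 are stored as 16-bit
#' unsigned samples; larger labels (up to 2^23 - 1) as 32-bit float samples
#' scaled so that the round-trip through [read_mask_sequence()] is bit-exact.
#'
#' @param masks List of integer matrices (labels >= 0).
#' @param directory Output directory, created if missing.
#' @param prefix Filename prefix, default `"mask_"`.
#' @return Invisibly, the character vector of files written.
#' @export
write_tracked_masks <- function(masks, directory, prefix = "mask_") {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", directory, "'", call. = FALSE)
  }
  width <- max(3L, nchar(length(masks) - 1))
  paths <- file.path(directory, sprintf("%s%0*d.tif", prefix, width,
                                        seq_along(masks) - 1L))
  for (i in seq_along(masks)) {
    write_labeled_tiff(masks[[i]], paths[[i]])
  }
  invisible(paths)
}

write_labeled_tiff <- function(mask, path) {
  m <- as.matrix(mask)
  if (any(m < 0)) stop("labels must be non-negative", call. = FALSE)
  top <- max(m)
  if (top >= 2^23) {
    stop("labels >= 2^23 cannot be stored exactly", call. = FALSE)
  }
  if (top <= 65535) {
    suppressWarnings(
      tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
    )
  } else {
    suppressWarnings(
      tiff::writeTIFF(m / 2^24, path, bits.per.sample = 32L)
    )
  }
  invisible(path)
}

#' Per-object geometric features of one labeled mask
#'
#' Computes, for every distinct nonzero label, the measurements the tracker's
#' cost function and event detectors consume.
#'
#' Conventions: coordinates are 0-based `(row, col)`; the centroid is the
#' unweighted mean of the object's pixel coordinates. The perimeter is the
#' count of object pixels having at least one 4-neighbour outside the object
#' (image borders count as outside); circularity is `4 * pi * area /
#' perimeter^2`, clipped to 1 where pixelation pushes it above 1. The aspect
#' ratio is the major/minor axis ratio of the moment-equivalent ellipse, with
#' the 1/12 per-pixel variance term added to the second central moments so a
#' single pixel has aspect ratio exactly 1.
#'
#' @param mask Integer labeled mask (matrix).
#' @return A tibble with one row per label: `label`, `area`, `row`, `col`
#'   (centroid), `perimeter`, `circularity`, `aspect_ratio`,
#'   `touches_border`. Empty masks give a zero-row tibble.
#' @examples
#' m <- matrix(0L, 40, 40); m[10:19, 5:34] <- 2L
#' extract_features(m)
#' @export
extract_features <- function(mask) {
  idx <- which(mask > 0L)
  empty <- tibble(
    label = integer(), area = integer(),
    row = double(), col = double(),
    perimeter = integer(), circularity = double(),
    aspect_ratio = double(), touches_border = logical()
  )
  if (length(idx) == 0) return(empty)
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- mask[idx]
  r <- ((idx - 1L) %% nr) + 1L
  cl <- ((idx - 1L) %/% nr) + 1L

  # boundary pixels: any 4-neighbour missing or differently labeled
  nb_differs <- function(dr, dc) {
    rn <- r + dr
    cn <- cl + dc
    inside <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    out <- !inside
    out[inside] <- mask[cbind(rn[inside], cn[inside])] != lab[inside]
    out
  }
  boundary <- nb_differs(-1L, 0L) | nb_differs(1L, 0L) |
    nb_differs(0L, -1L) | nb_differs(0L, 1L)

  f <- factor(lab)
  labels <- as.integer(levels(f))
  area <- as.integer(tabulate(f))
  mr <- tapply(r, f, mean)
  mc <- tapply(cl, f, mean)
  per <- as.integer(tapply(boundary, f, sum))
  border <- as.logical(
    tapply(r == 1L | r == nr | cl == 1L | cl == nc, f, any)
  )

  # second central moments with the unit-pixel 1/12 correction
  mrr <- tapply(r, f, stats::var)
  mcc <- tapply(cl, f, stats::var)
  mrc <- mapply(function(rr, cc) {
    if (length(rr) < 2) 0 else stats::cov(rr, cc)
  }, split(r, f), split(cl, f))
  n_1 <- pmax(area - 1L, 1L) / pmax(area, 1L) # var() uses n-1; use n
  mrr <- ifelse(is.na(mrr), 0, mrr) * n_1 + 1 / 12
  mcc <- ifelse(is.na(mcc), 0, mcc) * n_1 + 1 / 12
  mrc <- mrc * n_1
  tr <- mrr + mcc
  det <- mrr * mcc - mrc^2
  disc <- pmax(tr^2 / 4 - det, 0)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- pmax(tr / 2 - sqrt(disc), 1e-12)
  aspect <- sqrt(l1 / l2)

  tibble(
    label = labels,
    area = area,
    row = as.numeric(mr) - 1,
    col = as.numeric(mc) - 1,
    perimeter = per,
    circularity = pmin(1, 4 * pi * area / pmax(per, 1)^2),
    aspect_ratio = pmax(1, aspect),
    touches_border = border
  ) %>% dplyr::arrange(.data$label)
}

# connected components of a binary matrix (8-connectivity), returned as an
# integer matrix labeled 1..k in raster order of first pixel
label_components <- function(binary) {
  nr <- nrow(binary)
  nc <- ncol(binary)
  lab <- matrix(0L, nr, nc)
  idx <- which(binary)
  if (length(idx) == 0) return(lab)
  inside <- matrix(FALSE, nr, nc)
  inside[idx] <- TRUE
  nxt <- 0L
  queue <- integer(length(idx))
  offs_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  offs_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    lab[start] <- nxt
    queue[1] <- start
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      p <- queue[head]
      head <- head + 1L
      pr <- ((p - 1L) %% nr) + 1L
      pc <- ((p - 1L) %/% nr) + 1L
      for (k in 1:8) {
        rn <- pr + offs_r[k]
        cn <- pc + offs_c[k]
        if (rn < 1L || rn > nr || cn < 1L || cn > nc) next
        q <- (cn - 1L) * nr + rn
        if (inside[q] && lab[q] == 0L) {
          lab[q] <- nxt
          tail <- tail + 1L
          queue[tail] <- q
        }
      }
    }
  }
  lab
}
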