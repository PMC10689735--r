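#' Label connected foreground components of a binary matrix
#'
#' Two-pass run-based labelling with 4-connectivity: foreground runs are
#' extracted per row with run-length encoding, runs overlapping between
#' adjacent rows are merged with a union-find, and labels are compacted to
#' 1..n. Written run-wise so that megapixel masks label in well under a
#' second in plain R.
#'
#' @param fg logical matrix (TRUE = foreground).
#' @return integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(fg) {
  if (!is.matrix(fg)) stop("fg must be a matrix")
  nr <- nrow(fg); nc <- ncol(fg)
  out <- matrix(0L, nr, nc)

  # collect runs per row: (row, col_start, col_end, provisional label)
  runs_row <- integer(0); runs_s <- integer(0); runs_e <- integer(0)
  for (i in seq_len(nr)) {
    r <- rle(as.logical(fg[i, ]))
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    runs_row <- c(runs_row, rep.int(i, sum(keep)))
    runs_s <- c(runs_s, starts[keep])
    runs_e <- c(runs_e, ends[keep])
  }
  n_runs <- length(runs_row)
  if (n_runs == 0L) return(out)

  parent <- seq_len(n_runs)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }

  # merge runs in adjacent rows whose column spans overlap
  row_first <- match(seq_len(nr), runs_row)
  for (k in seq_len(n_runs)) {
    i <- runs_row[k]
    if (i == 1L) next
    j <- row_first[i - 1L]
    if (is.na(j)) next
    while (j <= n_runs && runs_row[j] == i - 1L) {
      if (runs_s[j] <= runs_e[k] && runs_e[j] >= runs_s[k]) union(k, j)
      j <- j + 1L
    }
  }

  roots <- vapply(seq_len(n_runs), find, integer(1L))
  labels <- match(roots, sort(unique(roots)))
  for (k in seq_len(n_runs)) {
    out[runs_row[k], runs_s[k]:runs_e[k]] <- labels[k]
  }
  out
}

#' Segment nuclei in a single-channel image
#'
#' Binarizes the image (Otsu by default), labels 4-connected components,
#' fills interior holes, discards components below `min_area`, and by
#' default excludes components touching the image border (their area is
#' truncated by the field of view). Areas are returned in square
#' micrometres.
#'
#' @param image an `exm_image` (intensity image, or an integer label/mask
#'   image where any value > 0 is foreground).
#' @param threshold_spec see [resolve_threshold()].
#' @param min_area_um2 minimum component area in um^2.
#' @param exclude_border drop border-touching components (default TRUE).
#' @param fill_holes fill enclosed background holes (default TRUE).
#' @return data.frame with one row per retained nucleus: `label`,
#'   `area_um2`, `centroid_x_um`, `centroid_y_um`, `touches_border`.
#' @export
segment_nuclei <- function(image, threshold_spec = "otsu", min_area_um2 = 1,
                           exclude_border = TRUE, fill_holes = TRUE) {
  ps_um <- pixel_size(image) / 1000
  thr <- resolve_threshold(image, threshold_spec)
  fg <- unclass(image) > thr
  if (!any(fg)) {
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      touches_border = logical(0)))
  }
  if (fill_holes) {
    # a background component not touching the border is a hole
    bg_lab <- label_components(!fg)
    border_bg <- unique(c(bg_lab[1L, ], bg_lab[nrow(bg_lab), ],
                          bg_lab[, 1L], bg_lab[, ncol(bg_lab)]))
    border_bg <- border_bg[border_bg > 0L]
    fg[bg_lab > 0L & !(bg_lab %in% border_bg)] <- TRUE
  }
  lab <- label_components(fg)
  n_lab <- max(lab)
  if (n_lab == 0L) {
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      touches_border = logical(0)))
  }
  px_area <- ps_um^2
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[idx]
  areas_px <- tabulate(l, nbins = n_lab)
  cx <- tapply((idx[, "col"] - 0.5) * ps_um, l, mean)
  cy <- tapply((idx[, "row"] - 0.5) * ps_um, l, mean)
  border_lab <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  touches <- seq_len(n_lab) %in% border_lab[border_lab > 0L]
  res <- data.frame(label = seq_len(n_lab),
                    area_um2 = areas_px * px_area,
                    centroid_x_um = as.numeric(cx),
                    centroid_y_um = as.numeric(cy),
                    touches_border = touches)
  res <- res[res$area_um2 >= min_area_um2, , drop = FALSE]
  if (exclude_border) res <- res[!res$touches_border, , drop = FALSE]
  rownames(res) <- NULL
  res
}
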