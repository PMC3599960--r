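#' Color a metagene field as an expression mosaic
#'
#' Maps a scalar K-vector to the standard portrait color scale: minimum ->
#' blue (0, 0, 255), arithmetic mean of the unmasked tiles -> green
#' (0, 128, 0), maximum -> maroon (128, 0, 0), with linear interpolation on
#' each of the two segments. Masked tiles (e.g. empty metagenes) render
#' white. The scale is anchored at min/mean/max of the field itself, so any
#' affine transform of the field leaves the image unchanged.
#'
#' @param field numeric K-vector of tile values.
#' @param dims grid dimensions `c(kx, ky)` (row-major tile order).
#' @param mask optional logical K-vector; `TRUE` tiles are drawn white.
#' @return object of class `mosaic`: `field`, `dims`, `mask`, and `rgb`,
#'   a `ky x kx x 3` array in \[0, 1\] (row 1 = y = 1).
#' @export
render_mosaic <- function(field, dims, mask = NULL) {
  kx <- as.integer(dims[1L]); ky <- as.integer(dims[2L])
  K <- kx * ky
  stopifnot(length(field) == K)
  if (is.null(mask)) mask <- rep(FALSE, K)
  stopifnot(length(mask) == K)
  mask <- mask | !is.finite(field)
  if (all(mask)) stop("all tiles are masked; nothing to render")
  cols <- mosaic_colors(field, mask)
  rgb <- array(0, dim = c(ky, kx, 3L))
  for (ch in 1:3)
    rgb[, , ch] <- matrix(cols[, ch], nrow = ky, ncol = kx, byrow = TRUE)
  structure(list(field = field, dims = c(kx, ky), mask = mask, rgb = rgb),
            class = "mosaic")
}

# per-tile RGB in [0,1]; two linear segments blue->green, green->maroon
mosaic_colors <- function(field, mask) {
  blue <- c(0, 0, 255) / 255
  green <- c(0, 128, 0) / 255
  maroon <- c(128, 0, 0) / 255
  v <- field[!mask]
  lo <- min(v); mid <- mean(v); hi <- max(v)
  out <- matrix(1, length(field), 3L)  # white default (masked)
  for (i in which(!mask)) {
    x <- field[i]
    out[i, ] <- if (x <= mid) {
      t <- if (mid > lo) (x - lo) / (mid - lo) else 1
      blue + t * (green - blue)
    } else {
      t <- if (hi > mid) (x - mid) / (hi - mid) else 0
      green + t * (maroon - green)
    }
  }
  out
}

#' Write a mosaic to PNG
#'
#' Each tile is drawn as a `scale` x `scale` pixel block.
#'
#' @param mosaic object from [render_mosaic()].
#' @param path output PNG path.
#' @param scale pixel size per tile.
#' @export
write_mosaic_png <- function(mosaic, path, scale = 8L) {
  stopifnot(inherits(mosaic, "mosaic"))
  big <- mosaic$rgb[rep(seq_len(dim(mosaic$rgb)[1L]), each = scale),
                    rep(seq_len(dim(mosaic$rgb)[2L]), each = scale), ,
                    drop = FALSE]
  png::writePNG(big, target = path)
  invisible(path)
}

#' Write a mosaic's tile values as TSV
#'
#' @param mosaic object from [render_mosaic()], or a plain K-vector plus
#'   `dims`.
#' @param path output path.
#' @param dims needed only when `mosaic` is a bare vector.
#' @export
write_mosaic_tsv <- function(mosaic, path, dims = NULL) {
  if (inherits(mosaic, "mosaic")) {
    field <- mosaic$field; dims <- mosaic$dims
  } else field <- mosaic
  df <- data.frame(tile = seq_along(field),
                   x = rep(seq_len(dims[1L]), times = dims[2L]),
                   y = rep(seq_len(dims[2L]), each = dims[1L]),
                   value = field)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Over- and underexpression summary maps
#'
#' Per metagene, the maximum (overexpression summary) and minimum
#' (underexpression summary) of its profile across the samples. These
#' fields host the sample-invariant "global" spots.
#'
#' @param grid trained `som_grid`.
#' @return list with numeric K-vectors `over` and `under`.
#' @export
summary_maps <- function(grid) {
  stopifnot(inherits(grid, "som_grid"))
  list(over = apply(grid$weights, 1L, max),
       under = apply(grid$weights, 1L, min))
}

#' Mean-rank map of a global ranked gene list
#'
#' Per metagene, the arithmetic mean of the ranks of its member genes in a
#' global ranking; empty metagenes are `NA` (to be masked white).
#'
#' @param assignment a `som_assignment`.
#' @param ranks named numeric vector of ranks covering every assigned gene.
#' @return numeric K-vector of mean ranks (`NA` for empty tiles).
#' @export
rank_map <- function(assignment, ranks) {
  stopifnot(inherits(assignment, "som_assignment"))
  genes <- names(assignment$bmu)
  if (!all(genes %in% names(ranks)))
    stop("ranking does not cover all assigned genes")
  vapply(assignment$clusters, function(cl) {
    if (length(cl) == 0L) NA_real_ else mean(ranks[cl])
  }, numeric(1L))
}

#' Population map of a gene set
#'
#' Per metagene, the number of set members assigned to it.
#'
#' @param set_genes character vector of gene ids.
#' @param assignment a `som_assignment`.
#' @return integer K-vector of counts.
#' @export
population_map <- function(set_genes, assignment) {
  stopifnot(inherits(assignment, "som_assignment"))
  present <- intersect(set_genes, names(assignment$bmu))
  if (length(present) == 0L)
    warning("gene set does not intersect the analyzed genes; all-zero map")
  counts <- integer(assignment$k)
  if (length(present) > 0L) {
    tb <- table(assignment$bmu[present])
    counts[as.integer(names(tb))] <- as.integer(tb)
  }
  counts
}
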