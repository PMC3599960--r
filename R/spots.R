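#' Detect over- or underexpression spots in a metagene field
#'
#' Applies the quantile criterion to one expression state (or summary
#' field): overexpression spots are the connected components (8-neighbor
#' adjacency) of tiles strictly above the `q`-quantile of the field;
#' underexpression spots are components of tiles strictly below the
#' `(1 - q)`-quantile. Quantiles use the empirical order statistic
#' (inverse CDF, type 1), so the default `q = 0.98` marks roughly 2% of
#' tiles. Spots are labeled `A`, `B`, ... in order of decreasing peak
#' deviation, which makes labeling deterministic.
#'
#' @param state numeric K-vector (one sample's metagene state or a summary
#'   field).
#' @param dims grid dimensions `c(kx, ky)`.
#' @param polarity `"over"` or `"under"`.
#' @param q quantile threshold in (0, 1), default 0.98.
#' @param source label recorded on each spot (sample id or `"summary"`).
#' @param min_tiles drop spots smaller than this many tiles (default 1 =
#'   keep all).
#' @return list of `spot` objects with fields `label`, `polarity`, `tiles`
#'   (1-based linear indices), `peak_tile`, `peak_value`, `source`.
#' @export
detect_spots <- function(state, dims, polarity = c("over", "under"),
                         q = 0.98, source = "sample", min_tiles = 1L) {
  polarity <- match.arg(polarity)
  kx <- as.integer(dims[1L]); ky <- as.integer(dims[2L])
  stopifnot(length(state) == kx * ky, q > 0, q < 1)
  if (diff(range(state)) == 0) {
    warning("constant expression state: no spots detected")
    return(list())
  }
  if (polarity == "over") {
    thr <- stats::quantile(state, q, type = 1L, names = FALSE)
    sel <- which(state > thr)
  } else {
    thr <- stats::quantile(state, 1 - q, type = 1L, names = FALSE)
    sel <- which(state < thr)
  }
  comps <- connected_components(sel, kx, ky)
  spots <- lapply(comps, function(tiles) {
    pk <- tiles[if (polarity == "over") which.max(state[tiles])
                else which.min(state[tiles])]
    structure(list(label = NA_character_, polarity = polarity,
                   tiles = sort(tiles), peak_tile = pk,
                   peak_value = state[pk], source = source),
              class = "spot")
  })
  spots <- spots[vapply(spots, function(s) length(s$tiles), 1L) >= min_tiles]
  if (length(spots) == 0L) return(list())
  ord <- order(vapply(spots, function(s)
    if (polarity == "over") -s$peak_value else s$peak_value, numeric(1L)))
  spots <- spots[ord]
  labels <- make_spot_labels(length(spots))
  for (i in seq_along(spots)) spots[[i]]$label <- labels[i]
  spots
}

make_spot_labels <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)]
  else paste0(LETTERS[((seq_len(n) - 1L) %/% 26L)],
              LETTERS[((seq_len(n) - 1L) %% 26L) + 1L])
}

# connected components among `tiles` with 8-neighborhood on a kx x ky grid
connected_components <- function(tiles, kx, ky) {
  if (length(tiles) == 0L) return(list())
  inset <- logical(kx * ky)
  inset[tiles] <- TRUE
  seen <- logical(kx * ky)
  comps <- list()
  for (t0 in tiles) {
    if (seen[t0]) next
    queue <- t0
    seen[t0] <- TRUE
    comp <- integer(0)
    while (length(queue) > 0L) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      comp <- c(comp, cur)
      x <- ((cur - 1L) %% kx) + 1L
      y <- ((cur - 1L) %/% kx) + 1L
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0L && dy == 0L) next
        nx <- x + dx; ny <- y + dy
        if (nx < 1L || nx > kx || ny < 1L || ny > ky) next
        nb <- (ny - 1L) * kx + nx
        if (inset[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

#' Gene list of a spot
#'
#' Union of the miniclusters of the spot's member metagenes; its length is
#' the sum of the member cluster sizes.
#'
#' @param spot a `spot`.
#' @param assignment a `som_assignment`.
#' @return character vector of gene ids.
#' @export
spot_gene_list <- function(spot, assignment) {
  stopifnot(inherits(spot, "spot"), inherits(assignment, "som_assignment"))
  unlist(assignment$clusters[spot$tiles], use.names = FALSE)
}

#' Spots on the over/under summary maps
#'
#' The sample-invariant "global" spots: the quantile criterion applied to
#' the overexpression summary (per-tile max over samples) and, with the
#' mirrored threshold, to the underexpression summary (per-tile min).
#'
#' @param summaries list from [summary_maps()].
#' @param dims grid dimensions.
#' @param q quantile threshold.
#' @return list with `over` and `under` spot lists (source `"summary"`).
#' @export
summary_spots <- function(summaries, dims, q = 0.98) {
  list(over = detect_spots(summaries$over, dims, "over", q, source = "summary"),
       under = detect_spots(summaries$under, dims, "under", q, source = "summary"))
}

#' Tabulate detected spots
#'
#' @param spots list of `spot` objects.
#' @param assignment optional `som_assignment` to add gene counts.
#' @param dims grid dimensions (for peak coordinates).
#' @return data.frame: label, polarity, source, n_tiles, n_genes, peak
#'   tile/x/y and peak value.
#' @export
spot_report <- function(spots, assignment = NULL, dims = NULL) {
  if (length(spots) == 0L)
    return(data.frame(label = character(), polarity = character(),
                      source = character(), n_tiles = integer(),
                      n_genes = integer(), peak_tile = integer(),
                      peak_x = integer(), peak_y = integer(),
                      peak_value = numeric()))
  do.call(rbind, lapply(spots, function(s) {
    ng <- if (is.null(assignment)) NA_integer_
          else length(spot_gene_list(s, assignment))
    px <- py <- NA_integer_
    if (!is.null(dims)) {
      px <- ((s$peak_tile - 1L) %% dims[1L]) + 1L
      py <- ((s$peak_tile - 1L) %/% dims[1L]) + 1L
    }
    data.frame(label = s$label, polarity = s$polarity, source = s$source,
               n_tiles = length(s$tiles), n_genes = ng,
               peak_tile = s$peak_tile, peak_x = px, peak_y = py,
               peak_value = s$peak_value)
  }))
}
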