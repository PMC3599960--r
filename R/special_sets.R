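#' Select a special gene set by a global expression criterion
#'
#' Implements the global-criterion sets used for SOM data filtering:
#' \describe{
#'   \item{`high_expression`}{top `fraction` of genes by maximum
#'     differential expression over samples (the global overexpression
#'     list).}
#'   \item{`top_rank_product`}{top `fraction` by ascending rank product of
#'     the per-sample expression-level rankings (consistently top-ranked
#'     genes).}
#'   \item{`absent`}{present call `pc = 0` in every sample.}
#'   \item{`housekeeper_present`}{present call `pc = 1` in every sample.}
#'   \item{`housekeeper_mean`}{top `fraction` by mean log10 expression
#'     over samples.}
#' }
#'
#' @param criterion one of the names above.
#' @param delta genes x samples differential expression (for
#'   `high_expression`).
#' @param e genes x samples log10 expression (for rank product and mean
#'   criteria).
#' @param pc genes x samples 0/1 present-call matrix (pc criteria only).
#' @param fraction top fraction for the ranked criteria (default 0.10).
#' @return named list of length 1: criterion name -> gene id vector (a
#'   `gene_set_collection`-compatible set).
#' @export
select_special_set <- function(criterion = c("high_expression",
                                             "top_rank_product", "absent",
                                             "housekeeper_present",
                                             "housekeeper_mean"),
                               delta = NULL, e = NULL, pc = NULL,
                               fraction = 0.10) {
  criterion <- match.arg(criterion)
  top_n <- function(v) {
    k <- round(fraction * length(v))
    names(sort(v, decreasing = TRUE))[seq_len(k)]
  }
  genes <- switch(criterion,
    high_expression = {
      if (is.null(delta)) stop("criterion needs `delta`")
      top_n(apply(as.matrix(delta), 1L, max))
    },
    top_rank_product = {
      if (is.null(e)) stop("criterion needs `e`")
      rp <- rank_product(rank_matrix(as.matrix(e)))
      top_n(-rp)  # ascending rank product = consistently top ranked
    },
    absent = {
      if (is.null(pc)) stop("present-call matrix required for pc criteria")
      rownames(pc)[rowSums(as.matrix(pc)) == 0L]
    },
    housekeeper_present = {
      if (is.null(pc)) stop("present-call matrix required for pc criteria")
      rownames(pc)[rowSums(as.matrix(pc) == 1L) == ncol(pc)]
    },
    housekeeper_mean = {
      if (is.null(e)) stop("criterion needs `e`")
      top_n(rowMeans(as.matrix(e)))
    })
  stats::setNames(list(genes), criterion)
}

#' Correlation-filtered tissue-specific gene set from a spot
#'
#' Keeps the spot genes whose expression profile has Pearson correlation
#' above `r_min` with their own metagene's profile; genes with a constant
#' profile (or a constant metagene) are excluded with a warning since the
#' correlation is undefined.
#'
#' @param spot a `spot`.
#' @param delta genes x samples differential expression.
#' @param grid trained `som_grid`.
#' @param assignment a `som_assignment`.
#' @param r_min correlation threshold (default 0.8).
#' @param name set name (default from spot label/source).
#' @return named list of length 1: set name -> filtered gene ids.
#' @export
correlation_filter_spot_set <- function(spot, delta, grid, assignment,
                                        r_min = 0.8, name = NULL) {
  genes <- spot_gene_list(spot, assignment)
  if (length(genes) == 0L) stop("spot contains no genes")
  delta <- as.matrix(delta)
  keep <- logical(length(genes))
  dropped_const <- FALSE
  for (i in seq_along(genes)) {
    g <- genes[i]
    prof <- delta[g, ]
    meta <- grid$weights[assignment$bmu[g], ]
    if (stats::sd(prof) == 0 || stats::sd(meta) == 0) {
      dropped_const <- TRUE
      next
    }
    keep[i] <- stats::cor(prof, meta) > r_min
  }
  if (dropped_const)
    warning("genes with constant profiles excluded (correlation undefined)")
  if (is.null(name))
    name <- paste0("spot_", spot$source, "_", spot$label)
  stats::setNames(list(genes[keep]), name)
}
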