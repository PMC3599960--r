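#' Correspondence-at-the-top (CAT) curve
#'
#' `CAT(r) = |top_r(A) intersect top_r(B)| / r` for r = 1..r_max, with the
#' null reference `r/N` (the expected overlap fraction of two
#' independent random rankings of the same N-gene universe).
#'
#' @param list_a,list_b character vectors of gene ids in rank order over
#'   the same gene universe.
#' @param r_max maximum rank (clamped to N with a warning if larger).
#' @return data.frame with `r`, `cat`, `null` (= r/N).
#' @export
cat_curve <- function(list_a, list_b, r_max = length(list_a)) {
  if (!setequal(list_a, list_b))
    stop("ranked lists must share the same gene universe")
  N <- length(list_a)
  if (r_max > N) {
    warning("r_max exceeds list length; clamped")
    r_max <- N
  }
  pos_b <- match(list_a, list_b)
  # gene at rank r in A is in top_r(B) iff its B-rank <= r; cumulative count
  counts <- cumsum(tabulate(pmax(pos_b, seq_len(N)), nbins = N))
  r <- seq_len(r_max)
  data.frame(r = r, cat = counts[r] / r, null = r / N)
}

#' Cumulative log p-value curve (p-CAT)
#'
#' `p-CAT(r)` is the running sum of log10 p-values (shrinkage-t p-values)
#' of the top r genes of a list. Because every log10 p <= 0, the curve is
#' non-increasing in r; the t-ordered list attains the pointwise minimum
#' over all orderings.
#'
#' @param list_ids gene ids in rank order.
#' @param p named p-value vector covering every listed gene.
#' @param r_max maximum rank.
#' @return data.frame with `r` and `p_cat`.
#' @export
p_cat <- function(list_ids, p, r_max = length(list_ids)) {
  if (!all(list_ids %in% names(p)))
    stop("p-values missing for listed genes")
  r_max <- min(r_max, length(list_ids))
  lp <- log10(p[list_ids[seq_len(r_max)]])
  data.frame(r = seq_len(r_max), p_cat = cumsum(lp))
}

#' Excess cumulative log p over the t-ordered optimum
#'
#' `Delta p-CAT(r) = p-CAT_alt(r) - p-CAT_t(r) >= 0`, the penalty an
#' alternative ordering pays relative to ranking by the shrinkage-t
#' p-values themselves.
#'
#' @param alt_list alternative ordering of the gene universe.
#' @param ref_t_list the p-value-ordered reference list (same universe).
#' @param p named p-value vector.
#' @param r_max maximum rank.
#' @return data.frame with `r` and `delta_p_cat`.
#' @export
delta_p_cat <- function(alt_list, ref_t_list, p, r_max = length(alt_list)) {
  if (!setequal(alt_list, ref_t_list))
    stop("lists must share the same gene universe")
  a <- p_cat(alt_list, p, r_max)
  b <- p_cat(ref_t_list, p, r_max)
  data.frame(r = a$r, delta_p_cat = a$p_cat - b$p_cat)
}

#' Rank correspondence within a window
#'
#' Position r of list A is concordant if that gene's rank in list B lies
#' within plus/minus `window` of r (the green/red strip of an RC plot).
#'
#' @param list_a,list_b rank-ordered gene id vectors (same universe).
#' @param window allowed rank displacement (default 20).
#' @param r_max number of top positions to evaluate.
#' @return data.frame with `r`, `gene`, `rank_b`, `concordant`.
#' @export
rank_correspondence <- function(list_a, list_b, window = 20L,
                                r_max = length(list_a)) {
  if (!setequal(list_a, list_b))
    stop("ranked lists must share the same gene universe")
  r_max <- min(r_max, length(list_a))
  r <- seq_len(r_max)
  rank_b <- match(list_a[r], list_b)
  data.frame(r = r, gene = list_a[r], rank_b = rank_b,
             concordant = abs(rank_b - r) <= window,
             stringsAsFactors = FALSE)
}
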