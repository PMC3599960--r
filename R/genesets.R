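#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#' Duplicate members are collapsed; if `universe` is given, members are
#' filtered to it and sets left empty are dropped with a warning.
#'
#' @param path GMT file.
#' @param universe optional character vector of analyzed gene ids.
#' @return named list of character vectors (class `gene_set_collection`);
#'   descriptions kept in attribute `"description"`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop(sprintf("malformed GMT line %d: need name, description, members", i))
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    sets[[parts[1L]]] <- members
    desc[parts[1L]] <- parts[2L]
  }
  if (!is.null(universe)) {
    sets <- lapply(sets, intersect, y = universe)
    empty <- lengths(sets) == 0L
    if (any(empty)) {
      warning(sprintf("%d gene sets empty after filtering to the universe; dropped",
                      sum(empty)))
      sets <- sets[!empty]
      desc <- desc[names(sets)]
    }
  }
  structure(sets, description = desc, class = "gene_set_collection")
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric overrepresentation p-value
#'
#' The cumulative probability of a larger overlap than observed between a
#' list of `n_list` genes and a set of `n_set` genes drawn from a universe
#' of `n` genes: `p = P(X > n_pos)` (strictly-greater tail, the printed
#' convention). The conventional inclusive tail `P(X >= n_pos)` is
#' available with `tail = "inclusive"`.
#'
#' @param n universe size N.
#' @param n_list list length.
#' @param n_set set size.
#' @param n_pos observed overlap.
#' @param tail `"greater"` (strict, default) or `"inclusive"`.
#' @return p-value.
#' @export
hg_overrepresentation <- function(n, n_list, n_set, n_pos,
                                  tail = c("greater", "inclusive")) {
  tail <- match.arg(tail)
  if (any(c(n, n_list, n_set, n_pos) < 0) || n_list > n || n_set > n ||
      n_pos > min(n_list, n_set) || n_pos < max(0L, n_list + n_set - n))
    stop("impossible contingency margins")
  q <- if (tail == "greater") n_pos else n_pos - 1L
  stats::phyper(q, n_set, n - n_set, n_list, lower.tail = FALSE)
}

#' GSZ regularization parameters
#'
#' Holds the minimum list/set sizes entering the small-sample penalty:
#' the shrinkage weight is
#' `lambda = 1 - min(1, (n_list_min / N_list) * (n_set_min / N_set))` and
#' the floor variance `SE0^2` is the large-N variance evaluated at the
#' minimum sizes, so the denominator inflates for short lists and small
#' sets.
#'
#' @param n_list_min,n_set_min minimum sizes (typical 5-10; default 10).
#' @param permutations permutation count for empirical p-values.
#' @param tail `"two"` or `"one"` tailed permutation test.
#' @param seed RNG seed for the permutation null.
#' @return list of class `gsz_params`.
#' @export
gsz_params <- function(n_list_min = 10L, n_set_min = 10L,
                       permutations = 1000L, tail = c("two", "one"),
                       seed = 1L) {
  tail <- match.arg(tail)
  stopifnot(n_list_min >= 1L, n_set_min >= 1L, permutations >= 100L)
  structure(list(n_list_min = n_list_min, n_set_min = n_set_min,
                 permutations = as.integer(permutations), tail = tail,
                 seed = as.integer(seed)),
            class = "gsz_params")
}

# hypergeometric overlap moments: E(N+) and var(N+)
hg_moments <- function(n, n_list, n_set) {
  mu <- n_set * n_list / n
  v <- mu * (1 - n_set / n) * (n - n_list) / (n - 1)
  list(mean = mu, var = v)
}

#' Gene set Z (GSZ) enrichment score
#'
#' The regularized Z-value of the difference score
#' `dS = S+ - S-` (sum of list scores over set members minus non-members):
#' `GSZ = (dS - E[dS]) / sqrt(lambda * SE^2 + (1 - lambda) * SE0^2)` with
#' `E[dS] = <S>_list * (2 * E[N+] - N_list)` and the exact null variance
#' `SE^2 = 4 * ( var(S)_list / (N_list - 1) *
#' (E[N+] * (N_list - E[N+]) - var(N+)) + <S>_list^2 * var(N+) )`,
#' using the hypergeometric overlap moments. `var(S)_list` is the
#' population (divide-by-N_list) variance. The regularization penalizes
#' short lists and small sets via [gsz_params()].
#'
#' @param scores named numeric vector: the expression scores of the list
#'   genes (the list may be the full universe).
#' @param set_genes character vector: the gene set (within the universe).
#' @param n universe size N (>= length of `scores`).
#' @param n_set set size in the universe (default `length(set_genes)`).
#' @param params a [gsz_params()]; `NULL` disables regularization
#'   (lambda = 1).
#' @return GSZ score (scalar).
#' @export
gsz <- function(scores, set_genes, n, n_set = length(set_genes),
                params = gsz_params()) {
  n_list <- length(scores)
  stopifnot(n_list >= 2L, n >= n_list, n_set <= n)
  if (!all(is.finite(scores))) stop("non-finite scores")
  in_set <- names(scores) %in% set_genes
  s_pos <- sum(scores[in_set])
  s_neg <- sum(scores[!in_set])
  ds <- s_pos - s_neg
  s_tot <- s_pos + s_neg
  s_mean <- s_tot / n_list
  s_var <- sum((scores - s_mean)^2) / n_list  # population form
  mom <- hg_moments(n, n_list, n_set)
  e_ds <- s_mean * (2 * mom$mean - n_list)
  se2 <- 4 * (s_var / (n_list - 1) *
                (mom$mean * (n_list - mom$mean) - mom$var) +
              s_mean^2 * mom$var)
  if (is.null(params)) {
    lambda <- 1; se0_2 <- 0
  } else {
    lambda <- 1 - min(1, (params$n_list_min / n_list) *
                           (params$n_set_min / n_set))
    se0_2 <- 4 * (params$n_list_min * params$n_set_min / n) *
      (s_var * (1 - params$n_set_min / n) +
         s_mean^2 * (1 - params$n_set_min / n) * (1 - params$n_list_min / n))
  }
  denom2 <- lambda * se2 + (1 - lambda) * se0_2
  if (denom2 <= 0) stop("zero GSZ denominator: degenerate scores and margins")
  (ds - e_ds) / sqrt(denom2)
}

#' Full-list GSZ (overexpression Z-score)
#'
#' The closed-form special case for the complete gene list:
#' `Z = (<S>_set - <S>_all) / sqrt(var(S)_all / N_set)` - a Z-statistic on
#' the deviation of the set's mean expression score from the global mean.
#'
#' @param scores named numeric vector over all N genes.
#' @param set_genes gene set (subset of the universe).
#' @return Z score.
#' @export
gsz_full_list <- function(scores, set_genes) {
  in_set <- names(scores) %in% set_genes
  if (!any(in_set)) stop("gene set does not intersect the universe")
  n <- length(scores)
  v <- sum((scores - mean(scores))^2) / n
  if (v == 0) stop("zero score variance")
  (mean(scores[in_set]) - mean(scores)) / sqrt(v / sum(in_set))
}

#' Binary GSZ (overrepresentation Z-score)
#'
#' The closed-form special case for unit scores:
#' `Z = (N+ - E[N+]) / sqrt(var(N+))` with hypergeometric moments. The
#' short-list approximation replaces the denominator by
#' `sqrt(N_set * N_list / N)`.
#'
#' @param n,n_list,n_set,n_pos contingency margins as in
#'   [hg_overrepresentation()].
#' @param approx use the short-list approximation (default FALSE).
#' @return Z score.
#' @export
gsz_binary <- function(n, n_list, n_set, n_pos, approx = FALSE) {
  mom <- hg_moments(n, n_list, n_set)
  v <- if (approx) n_set * n_list / n else mom$var
  if (v <= 0) stop("zero overlap variance: degenerate margins")
  (n_pos - mom$mean) / sqrt(v)
}

#' Permutation p-value for a GSZ score
#'
#' Draws `B` random gene sets of the observed set's size from the
#' universe, recomputes the GSZ score for each, and reports the add-one
#' permutation p-value: two-tailed `p = (1 + #(|null| >= |obs|)) / (1 + B)`
#' or the signed one-tailed version.
#'
#' @param observed observed GSZ score.
#' @param scores named score vector of the list.
#' @param universe character vector of all N gene ids.
#' @param set_size size of the gene set in the universe.
#' @param params a [gsz_params()] (supplies B, tail and seed).
#' @return permutation p-value (always >= 1 / (B + 1)).
#' @export
gsz_permutation_p <- function(observed, scores, universe, set_size,
                              params = gsz_params()) {
  B <- params$permutations
  null <- with_seed(params$seed, {
    vapply(seq_len(B), function(b) {
      rs <- sample(universe, set_size)
      gsz(scores, rs, n = length(universe), n_set = set_size, params = params)
    }, numeric(1L))
  })
  if (params$tail == "two") {
    (1 + sum(abs(null) >= abs(observed))) / (1 + B)
  } else {
    (1 + sum(null >= observed)) / (1 + B)
  }
}

#' Metagene overrepresentation map for one gene set
#'
#' Per metagene, the hypergeometric overrepresentation p-value of the set
#' in the tile's minicluster (`N_list = n_k`). The map is
#' sample-independent (the gene-to-tile assignment is fixed). Tiles with
#' no set members are masked (rendered white).
#'
#' @param set_genes gene set.
#' @param assignment a `som_assignment`.
#' @param tail tail convention of [hg_overrepresentation()].
#' @return list with `p` (K-vector) and `mask` (no set member / empty).
#' @export
metagene_overrepresentation_map <- function(set_genes, assignment,
                                            tail = "greater") {
  stopifnot(inherits(assignment, "som_assignment"))
  universe <- names(assignment$bmu)
  set_in <- intersect(set_genes, universe)
  n <- length(universe); n_set <- length(set_in)
  p <- vapply(assignment$clusters, function(cl) {
    if (length(cl) == 0L) return(NA_real_)
    hg_overrepresentation(n, length(cl), n_set,
                          length(intersect(cl, set_in)), tail = tail)
  }, numeric(1L))
  n_pos <- vapply(assignment$clusters,
                  function(cl) length(intersect(cl, set_in)), integer(1L))
  list(p = p, mask = n_pos == 0L | assignment$n_k == 0L)
}

#' Spot-level gene set enrichment
#'
#' For every set in a collection: the hypergeometric overrepresentation
#' p-value of the spot's gene list and the sample-specific GSZ score of
#' the spot list with its permutation p-value. Results are ranked by GSZ
#' permutation p (ties by HG p).
#'
#' @param spot_genes character vector, the spot gene list.
#' @param collection named list of gene sets (filtered to the universe).
#' @param scores named score vector for the sample, covering the universe.
#' @param universe all analyzed gene ids.
#' @param params a [gsz_params()].
#' @param tail HG tail convention.
#' @return data.frame: set, n_set, n_pos, hg_p, gsz, gsz_p, rank.
#' @export
spot_enrichment <- function(spot_genes, collection, scores, universe,
                            params = gsz_params(), tail = "greater") {
  stopifnot(length(spot_genes) > 0L)
  n <- length(universe)
  list_scores <- scores[spot_genes]
  rows <- lapply(names(collection), function(nm) {
    set_in <- intersect(collection[[nm]], universe)
    n_set <- length(set_in)
    n_pos <- length(intersect(spot_genes, set_in))
    hg_p <- hg_overrepresentation(n, length(spot_genes), n_set, n_pos,
                                  tail = tail)
    z <- gsz(list_scores, set_in, n = n, n_set = n_set, params = params)
    zp <- gsz_permutation_p(z, list_scores, universe, n_set, params)
    data.frame(set = nm, n_set = n_set, n_pos = n_pos, hg_p = hg_p,
               gsz = z, gsz_p = zp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gsz_p, out$hg_p, out$set), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Sample-wise overexpression profile of a gene set
#'
#' Per sample, the full-list GSZ (overexpression Z) of the set on that
#' sample's expression scores, with a permutation p-value per sample and
#' the minimum |GSZ| that reaches a Benjamini-Hochberg fdr of
#' `fdr_threshold` across the profile (the dotted significance line of a
#' profile bar plot; `Inf` when nothing passes).
#'
#' @param set_genes gene set.
#' @param scores genes x samples score matrix (typically delta).
#' @param params a [gsz_params()] for the permutation null.
#' @param fdr_threshold BH fdr level for the threshold line (default 0.2).
#' @return list: `profile` (data.frame sample, gsz, p, significant) and
#'   `threshold`.
#' @export
gene_set_profile <- function(set_genes, scores, params = gsz_params(),
                             fdr_threshold = 0.2) {
  scores <- as.matrix(scores)
  universe <- rownames(scores)
  set_in <- intersect(set_genes, universe)
  if (length(set_in) == 0L) stop("gene set empty within the universe")
  zs <- vapply(seq_len(ncol(scores)), function(m)
    gsz_full_list(stats::setNames(scores[, m], universe), set_in),
    numeric(1L))
  B <- params$permutations
  ps <- vapply(seq_len(ncol(scores)), function(m) {
    s <- stats::setNames(scores[, m], universe)
    null <- with_seed(params$seed + m, {
      vapply(seq_len(B), function(b)
        gsz_full_list(s, sample(universe, length(set_in))), numeric(1L))
    })
    if (params$tail == "two") (1 + sum(abs(null) >= abs(zs[m]))) / (1 + B)
    else (1 + sum(null >= zs[m])) / (1 + B)
  }, numeric(1L))
  adj <- stats::p.adjust(ps, "BH")
  sig <- adj <= fdr_threshold
  thr <- if (any(sig)) min(abs(zs[sig])) else Inf
  list(profile = data.frame(sample = colnames(scores) %||%
                              paste0("s", seq_along(zs)),
                            gsz = zs, p = ps, p_bh = adj,
                            significant = sig, stringsAsFactors = FALSE),
       threshold = thr)
}

#' Top-three enrichment aggregation and clustered heatmap
#'
#' Selects the three most significant gene sets of every (sample, spot)
#' enrichment list, merges them (duplicates removed) and builds a
#' sets x samples matrix of -log10 p, row-ordered by hierarchical
#' clustering (average linkage, Euclidean distance). Optionally rendered
#' as a white-yellow-red heatmap PNG.
#'
#' @param results data.frame with columns `sample`, `set`, `p` (one row
#'   per sample x spot x set enrichment result).
#' @param top number of sets kept per context (default 3).
#' @param path optional PNG output path.
#' @return list: `matrix` (-log10 p, clustered row order), `sets`,
#'   `order`; `NULL` matrix with a warning when no results exist.
#' @export
top_three_heatmap <- function(results, top = 3L, path = NULL) {
  if (nrow(results) == 0L) {
    warning("no enrichment results; empty heatmap")
    return(list(matrix = NULL, sets = character(0), order = integer(0)))
  }
  ctx <- if ("spot" %in% names(results))
    interaction(results$sample, results$spot, drop = TRUE)
  else factor(results$sample)
  keep <- unlist(lapply(split(seq_len(nrow(results)), ctx), function(idx) {
    idx[order(results$p[idx])][seq_len(min(top, length(idx)))]
  }))
  sets <- sort(unique(results$set[keep]))
  samples <- sort(unique(results$sample))
  mat <- matrix(0, length(sets), length(samples),
                dimnames = list(sets, samples))
  for (i in seq_len(nrow(results))) {
    s <- results$set[i]
    if (!(s %in% sets)) next
    v <- -log10(max(results$p[i], 1e-300))
    j <- match(results$sample[i], samples)
    mat[s, j] <- max(mat[s, j], v)
  }
  ord <- if (nrow(mat) > 2L)
    stats::hclust(stats::dist(mat), method = "average")$order
  else seq_len(nrow(mat))
  mat <- mat[ord, , drop = FALSE]
  if (!is.null(path) && nrow(mat) >= 2L && ncol(mat) >= 2L) {
    pal <- grDevices::colorRampPalette(c("white", "yellow", "red"))(100)
    pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                       color = pal, filename = path, silent = TRUE)
  }
  list(matrix = mat, sets = rownames(mat), order = ord)
}
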