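#' Fold-change score
#'
#' The logFC score is the gene-centered log10 differential expression
#' itself; this passthrough exists so all three scores share one calling
#' convention.
#'
#' @param delta genes x samples matrix of differential expression.
#' @return the same matrix, semantically a score table.
#' @export
fc_score <- function(delta) as.matrix(delta)

#' Weighted average difference (WAD) score
#'
#' `WAD[g, m] = w[g, m] * delta[g, m]` where the weight rescales the
#' gene's differential expression to the unit interval within the sample:
#' `w = (delta - min) / (max - min)`, min/max over all genes of sample m.
#' High-expressed genes are thus up-weighted ("strong signals are better
#' signals").
#'
#' @param delta genes x samples matrix.
#' @return matrix of WAD scores.
#' @export
wad_score <- function(delta) {
  delta <- as.matrix(delta)
  apply_cols(delta, function(col) {
    rng <- range(col)
    if (rng[1L] == rng[2L])
      stop("constant expression column: WAD weight undefined")
    ((col - rng[1L]) / (rng[2L] - rng[1L])) * col
  })
}

apply_cols <- function(x, f) {
  out <- vapply(seq_len(ncol(x)), function(j) f(x[, j]), numeric(nrow(x)))
  dimnames(out) <- dimnames(x)
  out
}

#' Locally pooled error (LPE) curve for one sample
#'
#' Estimates the mean replicate standard deviation as a function of the
#' log10 expression level: genes are sorted by expression and each gene's
#' pooled SD is the mean of the replicate SDs over a moving window of `W`
#' neighboring genes in that order (window clipped at the edges).
#' Evaluation at arbitrary expression uses step interpolation.
#'
#' @param e numeric vector of log10 expression (one sample).
#' @param sigma numeric vector of replicate SDs, same length.
#' @param W window size in genes (default 200, "a few hundred").
#' @return object of class `lpe_curve`; use [predict_lpe()] to evaluate.
#' @export
lpe_curve <- function(e, sigma, W = 200L) {
  ok <- is.finite(e) & is.finite(sigma)
  e <- e[ok]; sigma <- sigma[ok]
  n <- length(e)
  if (W > n) stop("LPE window larger than the number of genes with SDs")
  if (W < 1L) stop("window must be >= 1")
  ord <- order(e)
  es <- unname(e[ord]); ss <- unname(sigma[ord])
  cs <- cumsum(c(0, ss))
  half <- W %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, lo + W - 1L)
  lo <- pmax(1L, hi - W + 1L)
  pooled <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  structure(list(e = es, sigma_lpe = pooled, W = W), class = "lpe_curve")
}

#' Evaluate an LPE curve
#'
#' Step interpolation: each query point takes the pooled SD of the nearest
#' fitted expression value at or below it (the first value below the
#' fitted range).
#'
#' @param curve an `lpe_curve`.
#' @param e numeric vector of expression values.
#' @return numeric vector of pooled SDs.
#' @export
predict_lpe <- function(curve, e) {
  stopifnot(inherits(curve, "lpe_curve"))
  idx <- findInterval(e, curve$e)
  idx[idx < 1L] <- 1L
  curve$sigma_lpe[idx]
}

#' Shrinkage-t score with locally pooled error
#'
#' Blends the gene-specific replicate SD with the pooled (LPE) SD,
#' `sigma_shr = sqrt(lambda * sigma^2 + (1 - lambda) * sigma_LPE^2)`,
#' and scores differential expression as `t = delta / SE_diff`. The default
#' standard error is the approximate form `sigma_shr / sqrt(R_m)`; the
#' exact form adds the variance contribution of the gene's grand mean,
#' `SE^2 = sigma_shr^2 / R_m + <sigma_shr^2>_m / sum(R)`. Two-sided
#' p-values come from a Student t with `R_m - 1` degrees of freedom;
#' conditions with a single replicate have no per-gene SD, fall back to the
#' pure LPE error and a normal approximation for p.
#'
#' @param delta genes x conditions differential expression.
#' @param e genes x conditions log10 expression (for LPE lookup).
#' @param sigma genes x conditions replicate SDs (`NA` where R = 1).
#' @param R integer replicate count per condition.
#' @param lambda shrinkage weight in \[0, 1\]; 1 = naive per-gene t,
#'   0 = pure pooled error.
#' @param W LPE window size.
#' @param se_mode `"approx"` (default) or `"exact"`.
#' @return list of genes x conditions matrices: `t`, `p`, `se`,
#'   `sigma_shr`, plus the fitted `curves` (one per condition).
#' @export
shrinkage_t <- function(delta, e, sigma, R, lambda = 0.5, W = 200L,
                        se_mode = c("approx", "exact")) {
  se_mode <- match.arg(se_mode)
  stopifnot(lambda >= 0, lambda <= 1)
  delta <- as.matrix(delta); e <- as.matrix(e); sigma <- as.matrix(sigma)
  M <- ncol(delta)
  stopifnot(ncol(e) == M, ncol(sigma) == M, length(R) == M)
  sig_shr <- matrix(NA_real_, nrow(delta), M, dimnames = dimnames(delta))
  curves <- vector("list", M)
  for (m in seq_len(M)) {
    if (all(!is.finite(sigma[, m]))) {
      # single-replicate condition: no per-gene SD exists
      # borrow the pooled curve of the condition with most replicates
      donor <- which.max(R)
      if (all(!is.finite(sigma[, donor])))
        stop("no condition has replicate SDs; cannot build an error model")
      curves[[m]] <- lpe_curve(e[, donor], sigma[, donor], W)
      sig_shr[, m] <- predict_lpe(curves[[m]], e[, m])
    } else {
      curves[[m]] <- lpe_curve(e[, m], sigma[, m], W)
      s_lpe <- predict_lpe(curves[[m]], e[, m])
      sig_shr[, m] <- sqrt(lambda * sigma[, m]^2 + (1 - lambda) * s_lpe^2)
    }
  }
  se <- sweep(sig_shr, 2L, sqrt(R), "/")
  if (se_mode == "exact") {
    gm_var <- rowMeans(sig_shr^2) / sum(R)
    se <- sqrt(se^2 + gm_var)
  }
  tt <- delta / se
  p <- matrix(NA_real_, nrow(delta), M, dimnames = dimnames(delta))
  for (m in seq_len(M)) {
    if (R[m] >= 2L) {
      p[, m] <- 2 * stats::pt(-abs(tt[, m]), df = R[m] - 1L)
    } else {
      p[, m] <- 2 * stats::pnorm(-abs(tt[, m]))
    }
  }
  zero_se <- which(se == 0)
  if (length(zero_se) > 0L) {
    dz <- delta[zero_se]
    tt[zero_se] <- ifelse(dz == 0, 0, sign(dz) * Inf)
    p[zero_se] <- ifelse(dz == 0, 1, 0)
    if (any(dz != 0))
      warning("zero standard error with nonzero differential expression; p set to 0")
  }
  list(t = tt, p = p, se = se, sigma_shr = sig_shr, curves = curves)
}

#' Grenander-type fdr/Fdr estimation from p-values
#'
#' Fits a monotone non-increasing step density `rho(p)` on \[0, 1\]
#' (Grenander-type, via weighted pool-adjacent-violators isotonic
#' regression). Under the assumption that differential expression
#' vanishes at p = 1, the null fraction is `eta0 = rho(1)`; the local false
#' discovery rate is `fdr(p) = eta0 / rho(p)` (capped at 1, exactly 1 at
#' p = 1) and the tail-area rate is `Fdr(p) = eta0 * p / F(p)` with `F` the
#' concave CDF estimate. The fraction of differentially expressed genes is
#' `%DE = 1 - eta0`.
#'
#' The density is fitted on an equal-width histogram of the p-values
#' (isotonic regression of the bin densities, bin-width weighted), the
#' binned form of the Grenander estimator. Binning keeps the estimate
#' well-behaved at the right boundary p = 1, where the unbinned
#' least-concave-majorant slope degenerates to zero beyond the largest
#' observed p-value.
#'
#' @param p numeric vector of p-values in \[0, 1\]; at least 10 required.
#' @param bins number of histogram bins; the default adapts to n with at
#'   most 100.
#' @return object of class `fdr_estimate` with fields `eta0`,
#'   `percent_de`, and step-function data; evaluate with [fdr_local()] and
#'   [fdr_tail()].
#' @export
estimate_fdr <- function(p, bins = NULL) {
  p <- p[is.finite(p)]
  if (length(p) < 10L) stop("need at least 10 p-values")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (is.null(bins)) bins <- max(5L, min(100L, n %/% 10L))
  edges <- seq(0, 1, length.out = bins + 1L)
  counts <- tabulate(pmin(findInterval(p, edges, left.open = TRUE) +
                            (p == 0), bins), nbins = bins)
  dx <- diff(edges)
  slopes <- pava_decreasing(counts / (n * dx), dx)
  Fhat <- cumsum(c(0, slopes * dx))   # concave CDF estimate, ends at 1
  eta0 <- slopes[length(slopes)]
  structure(list(eta0 = eta0, percent_de = 1 - eta0, n = n,
                 knots = edges, slopes = slopes, Fhat = Fhat),
            class = "fdr_estimate")
}

# weighted pool-adjacent-violators for a non-increasing fit
pava_decreasing <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; size <- rep(1L, n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; size[m] <- 1L
    while (m > 1L && val[m - 1L] < val[m]) {
      tot <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (val[m - 1L] * wt[m - 1L] + val[m] * wt[m]) / tot
      wt[m - 1L] <- tot
      size[m - 1L] <- size[m - 1L] + size[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], times = size[seq_len(m)])
}

# density estimate rho(p) at arbitrary p (step function on the knots)
rho_hat <- function(est, p) {
  idx <- findInterval(p, est$knots, left.open = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(est$slopes)] <- length(est$slopes)
  est$slopes[idx]
}

#' Local false discovery rate
#'
#' @param est an `fdr_estimate`.
#' @param p p-values to evaluate at.
#' @return `fdr(p) = min(1, eta0 / rho(p))`; exactly 1 at p = 1.
#' @export
fdr_local <- function(est, p) {
  stopifnot(inherits(est, "fdr_estimate"))
  pmin(1, est$eta0 / rho_hat(est, p))
}

#' Tail-area (cumulative) false discovery rate
#'
#' @param est an `fdr_estimate`.
#' @param p p-values to evaluate at.
#' @return `Fdr(p) = eta0 * p / F(p)`; equals `fdr(0)` at p = 0 and `eta0`
#'   at p = 1.
#' @export
fdr_tail <- function(est, p) {
  stopifnot(inherits(est, "fdr_estimate"))
  Fp <- stats::approx(est$knots, est$Fhat, xout = p, rule = 2L)$y
  out <- ifelse(p > 0, est$eta0 * p / Fp, est$eta0 / est$slopes[1L])
  pmin(1, out)
}

#' Rank genes by score magnitude
#'
#' Descending `|score|`; ties broken by lexicographic gene id so rankings
#' are deterministic.
#'
#' @param scores named numeric vector (one sample's scores).
#' @param scope optional character vector restricting the ranking to a
#'   gene subset (e.g. a spot gene list); default all genes.
#' @return data.frame with `gene`, `score`, `rank` in rank order.
#' @export
rank_genes <- function(scores, scope = NULL) {
  if (!is.null(scope)) {
    missing <- setdiff(scope, names(scores))
    if (length(missing) > 0L) stop("scores missing for scoped genes")
    scores <- scores[scope]
  }
  if (length(scores) == 0L) stop("empty ranking scope")
  ord <- order(-abs(scores), names(scores))
  data.frame(gene = names(scores)[ord], score = unname(scores[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Metagene-level significance by arithmetic averaging
#'
#' Per metagene, the mean of a per-gene statistic (t, log p, fdr, ...) over
#' its member genes; empty metagenes are `NA`.
#'
#' @param assignment a `som_assignment`.
#' @param stat named numeric vector of per-gene statistics.
#' @return numeric K-vector.
#' @export
metagene_significance <- function(assignment, stat) {
  stopifnot(inherits(assignment, "som_assignment"))
  vapply(assignment$clusters, function(cl) {
    if (length(cl) == 0L) NA_real_ else mean(stat[cl])
  }, numeric(1L))
}

#' Spot-level significance
#'
#' Mean of a per-gene statistic over all genes of all metagenes in the
#' spot (equivalently the cluster-size-weighted mean of the metagene
#' averages).
#'
#' @param spot a `spot`.
#' @param assignment a `som_assignment`.
#' @param stat named numeric vector of per-gene statistics.
#' @return scalar mean.
#' @export
spot_significance <- function(spot, assignment, stat) {
  genes <- spot_gene_list(spot, assignment)
  if (length(genes) == 0L) stop("spot contains no genes")
  mean(stat[genes])
}

#' Rank product across samples
#'
#' Geometric mean of a gene's per-sample ranks,
#' `RP_g = (prod_m rank[g, m])^(1/M)`; small values mean consistently
#' top-ranked.
#'
#' @param ranks genes x samples matrix of ranks (each column a permutation
#'   of 1..N).
#' @return named numeric vector of rank products.
#' @export
rank_product <- function(ranks) {
  ranks <- as.matrix(ranks)
  exp(rowMeans(log(ranks)))
}

#' Per-sample rank matrix for a chosen ordering
#'
#' @param x genes x samples matrix; genes are ranked per sample in
#'   decreasing order of `x` (rank 1 = largest), ties by gene id.
#' @return genes x samples integer matrix of ranks.
#' @export
rank_matrix <- function(x) {
  x <- as.matrix(x)
  out <- apply_cols(x, function(col) {
    r <- numeric(length(col))
    r[order(-col, rownames(x))] <- seq_along(col)
    r
  })
  rownames(out) <- rownames(x)
  out
}

#' Full per-gene score table
#'
#' Computes logFC, WAD and shrinkage-t scores with p-values and, per
#' sample, Grenander fdr/Fdr estimates and per-score ranks.
#'
#' @param prep output of [preprocess_expression()] (needs `delta`, `e`,
#'   `sigma`, `R`).
#' @param lambda,W,se_mode passed to [shrinkage_t()].
#' @return object of class `score_table`: matrices `logFC`, `WAD`, `t`,
#'   `p`, `fdr`, `Fdr`, rank matrices per score, and the per-sample
#'   `fdr_estimates` (with `eta0`, `percent_de`).
#' @export
score_table <- function(prep, lambda = 0.5, W = 200L,
                        se_mode = c("approx", "exact")) {
  se_mode <- match.arg(se_mode)
  delta <- prep$delta
  st <- shrinkage_t(delta, prep$e, prep$sigma, prep$R, lambda, W, se_mode)
  ests <- lapply(seq_len(ncol(delta)), function(m) estimate_fdr(st$p[, m]))
  names(ests) <- colnames(delta)
  fdr <- vapply(seq_len(ncol(delta)),
                function(m) fdr_local(ests[[m]], st$p[, m]),
                numeric(nrow(delta)))
  Fdr <- vapply(seq_len(ncol(delta)),
                function(m) fdr_tail(ests[[m]], st$p[, m]),
                numeric(nrow(delta)))
  dimnames(fdr) <- dimnames(Fdr) <- dimnames(delta)
  structure(list(logFC = fc_score(delta), WAD = wad_score(delta),
                 t = st$t, p = st$p, se = st$se, fdr = fdr, Fdr = Fdr,
                 rank_logFC = rank_matrix(abs(delta)),
                 rank_WAD = rank_matrix(abs(wad_score(delta))),
                 rank_t = rank_matrix(abs(st$t)),
                 fdr_estimates = ests, lambda = lambda, W = W),
            class = "score_table")
}

#' Export a score table as long-format TSV
#'
#' @param tab a `score_table`.
#' @param path output path.
#' @export
write_score_table <- function(tab, path) {
  stopifnot(inherits(tab, "score_table"))
  genes <- rownames(tab$logFC)
  samples <- colnames(tab$logFC)
  df <- do.call(rbind, lapply(samples, function(m) {
    data.frame(gene = genes, sample = m,
               logFC = tab$logFC[, m], WAD = tab$WAD[, m], t = tab$t[, m],
               p = tab$p[, m], fdr = tab$fdr[, m], Fdr = tab$Fdr[, m],
               rank_logFC = tab$rank_logFC[, m],
               rank_WAD = tab$rank_WAD[, m], rank_t = tab$rank_t[, m],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
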