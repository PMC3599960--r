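test_that("FC and WAD scores follow their definitions", {
  d <- matrix(c(-1, 1, 3, 0, 1.5, -2), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(fc_score(d), d)

  w <- wad_score(d)
  # column {-1, 1, 3}: weights 0, 0.5, 1
  expect_equal(unname(w[, 1]), c(0, 0.5, 3))
  # max tile keeps its delta, min tile drops to zero
  expect_equal(w[3, 1], d[3, 1])
  expect_equal(w[1, 1], 0)
  expect_error(wad_score(matrix(1, 3, 1)), "constant")

  # all-positive columns: WAD is a monotone transform of FC, same ordering
  set.seed(3)
  pos <- matrix(runif(50, 0.1, 2), 50, 1,
                dimnames = list(sprintf("g%02d", 1:50), "s"))
  o_fc <- rank_genes(setNames(pos[, 1], rownames(pos)))$gene
  o_wad <- rank_genes(setNames(wad_score(pos)[, 1], rownames(pos)))$gene
  expect_equal(o_fc, o_wad)
})

test_that("LPE curves pool replicate SDs over expression-sorted windows", {
  # constant sigma: curve is constant
  cst <- lpe_curve(1:50, rep(0.3, 50), W = 7)
  expect_equal(cst$sigma_lpe, rep(0.3, 50))

  # hand-checked moving average of 3 on 6 sorted points
  e <- c(1, 2, 3, 4, 5, 6)
  cv <- lpe_curve(e, e, W = 3)
  expect_equal(cv$sigma_lpe, c(2, 2, 3, 4, 5, 5))

  # invariant under input permutation
  set.seed(5)
  perm <- sample(6)
  cv2 <- lpe_curve(e[perm], e[perm], W = 3)
  expect_equal(cv2$sigma_lpe, cv$sigma_lpe)

  expect_error(lpe_curve(1:5, 1:5, W = 9), "window")

  # step evaluation
  expect_equal(predict_lpe(cv, c(0, 3.5, 10)), c(2, 3, 5))
})

test_that("shrinkage-t blends gene and pooled errors as scheduled", {
  fx <- small_fixture(seed = 6, n_genes = 300)
  prep <- preprocess_expression(fx$expr, fx$conditions)
  W <- 50
  # lambda = 1: naive per-gene error (quantile normalization can leave a
  # few genes with identical replicate values, hence zero SD and SE)
  st1 <- suppressWarnings(
    shrinkage_t(prep$delta, prep$e, prep$sigma, prep$R, lambda = 1, W = W))
  expect_equal(unname(st1$sigma_shr), unname(prep$sigma), tolerance = 1e-12)
  # lambda = 0: pure pooled error
  st0 <- shrinkage_t(prep$delta, prep$e, prep$sigma, prep$R, lambda = 0, W = W)
  for (m in seq_along(prep$R))
    expect_equal(unname(st0$sigma_shr[, m]),
                 predict_lpe(st0$curves[[m]], prep$e[, m]))

  # approximate SE: delta 1, sigma_shr 0.5, R 4 -> SE 0.25, t 4
  sub <- shrinkage_t(matrix(1), matrix(2.5), matrix(0.5), R = 4L,
                     lambda = 1, W = 1)
  expect_equal(unname(sub$se[1, 1]), 0.25)
  expect_equal(unname(sub$t[1, 1]), 4)
  expect_equal(unname(sub$p[1, 1]), 2 * pt(-4, df = 3))

  # lambda = 1 with exact SE reproduces the classical one-sample t
  # on the replicate means (single-condition oracle via t.test)
  lg <- log10(fx$expr[1:20, fx$conditions == fx$conditions[1]])
  mgrand <- rowMeans(log10(fx$expr[1:20, ]))
  # oracle: t-test of the condition's replicate mean against the gene mean,
  # using the replicate SD of that condition alone (approx form)
  la <- log_and_average(fx$expr[1:20, ], fx$conditions)
  dd <- center_genes(la$e)
  stA <- shrinkage_t(dd, la$e, la$sigma, la$R, lambda = 1, W = 5)
  R1 <- la$R[1]
  oracle_t <- dd[, 1] / (la$sigma[, 1] / sqrt(R1))
  expect_equal(unname(stA$t[, 1]), unname(oracle_t))

  # exact SE mode adds the grand-mean variance term
  stE <- shrinkage_t(dd, la$e, la$sigma, la$R, lambda = 1, W = 5,
                     se_mode = "exact")
  expect_true(all(stE$se >= stA$se))
  manual <- sqrt(stA$sigma_shr[, 1]^2 / R1 +
                 rowMeans(stA$sigma_shr^2) / sum(la$R))
  expect_equal(unname(stE$se[, 1]), unname(manual))
})

test_that("fdr estimation recovers the null fraction with exact boundary values", {
  set.seed(11)
  # pure uniform: eta0 near 1, fdr near 1 everywhere
  est <- estimate_fdr(runif(10000))
  expect_lt(abs(est$eta0 - 1), 0.05)
  expect_lt(abs(est$percent_de), 0.05)
  expect_equal(fdr_local(est, 1), 1)           # exact by construction
  expect_equal(fdr_tail(est, 1), est$eta0)     # Fdr(1) = eta0
  expect_equal(fdr_tail(est, 0), fdr_local(est, 0))

  # 30% Beta(0.1, 1) + 70% uniform at n = 10,000
  p2 <- c(rbeta(3000, 0.1, 1), runif(7000))
  e2 <- estimate_fdr(p2)
  expect_gt(e2$eta0, 0.65)
  expect_lt(e2$eta0, 0.78)
  expect_equal(fdr_local(e2, 1), 1)

  # Fdr <= fdr in the mid/upper p-range for the monotone estimate
  ps <- seq(0.3, 1, by = 0.05)
  expect_true(all(fdr_tail(e2, ps) <= fdr_local(e2, ps) + 1e-12))

  expect_error(estimate_fdr(runif(5)), "at least 10")
  expect_error(estimate_fdr(c(runif(20), 1.5)), "0, 1")
})

test_that("gene ranking is by |score| with lexicographic tie-break", {
  s <- setNames(c(1, -3, 2, -3), c("d", "c", "b", "a"))
  r <- rank_genes(s)
  expect_equal(r$gene, c("a", "c", "b", "d"))
  expect_equal(r$rank, 1:4)
  # scoped ranking
  r2 <- rank_genes(s, scope = c("b", "d"))
  expect_equal(r2$gene, c("b", "d"))
  expect_equal(rank_genes(s["b"])$rank, 1)
  # matches a brute-force stable sort
  set.seed(13)
  s3 <- setNames(round(rnorm(100), 1), sprintf("g%03d", sample(100)))
  brute <- names(s3)[order(-abs(s3), names(s3))]
  expect_equal(rank_genes(s3)$gene, brute)
})

test_that("metagene and spot averaging obey the stated identities", {
  d <- small_delta(n = 40)
  g <- som_train(d, som_linear_init(d, c(3, 3)),
                 som_schedule(presentations = 1000, seed = 2))
  a <- map_genes(d, g)
  stat <- setNames(rnorm(nrow(d)), rownames(d))
  ms <- metagene_significance(a, stat)
  for (k in which(a$n_k > 0))
    expect_equal(ms[k], mean(stat[a$clusters[[k]]]))
  # two-gene cluster with log p -2 and -4 averages to -3
  a2 <- structure(list(bmu = setNames(c(1, 1), c("x", "y")),
                       clusters = list(c("x", "y")), n_k = 2L, k = 1L),
                  class = "som_assignment")
  expect_equal(metagene_significance(a2, c(x = -2, y = -4)), -3)

  sp <- detect_spots(metagene_expression_state(g, 1), c(3, 3), "over", 0.6)
  s <- sp[[1]]
  v <- spot_significance(s, a, stat)
  # equals the n_k-weighted mean of the member tiles' metagene averages
  ks <- s$tiles[a$n_k[s$tiles] > 0]
  expect_equal(v, sum(ms[ks] * a$n_k[ks]) / sum(a$n_k[ks]))
  # spot of all tiles gives the global mean
  all_spot <- structure(list(label = "X", polarity = "over",
                             tiles = 1:9, peak_tile = 1, peak_value = 1,
                             source = "t"), class = "spot")
  expect_equal(spot_significance(all_spot, a, stat), mean(stat))
})

test_that("rank products are geometric means, invariant to sample order", {
  rk <- cbind(a = c(1, 2, 3), b = c(1, 8, 3))
  rownames(rk) <- paste0("g", 1:3)
  rp <- rank_product(rk)
  expect_equal(unname(rp["g1"]), 1)
  expect_equal(unname(rp["g2"]), 4)  # sqrt(2 * 8)
  expect_equal(rank_product(rk[, c(2, 1)]), rp)
  # rank_matrix ranks each column descending with id ties
  x <- cbind(s1 = c(0.1, 0.9, 0.5))
  rownames(x) <- paste0("g", 1:3)
  expect_equal(unname(rank_matrix(x)[, 1]), c(3, 1, 2))
})

test_that("score_table assembles consistent matrices and ranks", {
  fx <- small_fixture(seed = 14, n_genes = 250)
  prep <- preprocess_expression(fx$expr, fx$conditions)
  tab <- score_table(prep, W = 50)
  N <- nrow(prep$delta)
  for (m in seq_len(ncol(prep$delta))) {
    expect_setequal(tab$rank_t[, m], seq_len(N))
    expect_setequal(tab$rank_WAD[, m], seq_len(N))
  }
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$fdr >= 0 & tab$fdr <= 1))
  expect_true(all(tab$Fdr >= 0 & tab$Fdr <= 1))
  tsv <- tempfile(fileext = ".tsv")
  write_score_table(tab, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), N * ncol(prep$delta))
})
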