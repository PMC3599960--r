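test_that("GMT parsing filters to the universe and round-trips", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tdesc\tg2\tg2\tg9"), gmt)
  sets <- read_gmt(gmt)
  expect_length(sets, 2)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(sets$setB, c("g2", "g9"))  # duplicate member collapsed

  f <- read_gmt(gmt, universe = c("g1", "g2", "g3"))
  expect_equal(f$setB, "g2")  # members outside the universe are filtered
  expect_warning(f2 <- read_gmt(gmt, universe = c("g1", "g3")), "dropped")
  expect_equal(f2$setA, c("g1", "g3"))
  expect_null(f2$setB)

  writeLines("broken_line_no_tabs", gmt)
  expect_error(read_gmt(gmt), "line 1")

  # write -> read identity
  out <- tempfile(fileext = ".gmt")
  orig <- list(s1 = c("a", "b"), s2 = c("c"))
  write_gmt(orig, out)
  back <- read_gmt(out)
  expect_equal(unclass(back)[names(orig)], orig, ignore_attr = TRUE)
})

test_that("hypergeometric tail equals exhaustive enumeration (N <= 12)", {
  # worked example: N=4, list 2, set 2, overlap 1 -> 1/6
  expect_equal(hg_overrepresentation(4, 2, 2, 1), 1 / 6)
  # maximal overlap leaves no larger overlap: p = 0
  expect_equal(hg_overrepresentation(10, 3, 5, 3), 0)
  # empty set: p = 0
  expect_equal(hg_overrepresentation(10, 3, 0, 0), 0)
  expect_error(hg_overrepresentation(10, 3, 5, 4), "margins")

  for (n in c(5, 8, 12)) {
    for (n_list in c(2, n %/% 2)) {
      for (n_set in c(1, 3)) {
        lo <- max(0, n_list + n_set - n)
        for (n_pos in lo:min(n_list, n_set)) {
          expect_equal(hg_overrepresentation(n, n_list, n_set, n_pos),
                       hg_enumerate(n, n_list, n_set, n_pos),
                       tolerance = 1e-12)
        }
      }
    }
  }
  # inclusive tail shifts the sum by one term
  expect_equal(hg_overrepresentation(10, 4, 5, 2, tail = "inclusive"),
               hg_overrepresentation(10, 4, 5, 1))
})

test_that("general GSZ reduces exactly to the binary Z for unit scores", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(20:500, 1)
    n_list <- sample(2:(n - 1), 1)
    n_set <- sample(1:(n - 1), 1)
    universe <- sprintf("u%04d", seq_len(n))
    lst <- sample(universe, n_list)
    st <- sample(universe, n_set)
    n_pos <- length(intersect(lst, st))
    mom <- somportraits:::hg_moments(n, n_list, n_set)
    if (mom$var <= 0) next
    z_gen <- gsz(setNames(rep(1, n_list), lst), st, n = n, n_set = n_set,
                 params = NULL)
    z_bin <- gsz_binary(n, n_list, n_set, n_pos)
    expect_equal(z_gen, z_bin, tolerance = 1e-10)
  }
})

test_that("full-list and binary closed forms match their worked examples", {
  s <- setNames(c(1, 2, 3, 4), paste0("g", 1:4))
  expect_equal(gsz_full_list(s, c("g3", "g4")), 1 / sqrt(0.625),
               tolerance = 1e-9)
  expect_equal(gsz_full_list(s, names(s)), 0)  # whole universe
  expect_error(gsz_full_list(setNames(rep(2, 4), names(s)), "g1"), "variance")

  expect_equal(gsz_binary(100, 10, 10, 4), 3 / sqrt(0.81818181818),
               tolerance = 1e-9)
  # expectation-level overlap scores zero
  expect_equal(gsz_binary(100, 10, 10, 1), 0)
  # short-list approximation close to exact for small margins
  for (nl in c(10, 25)) for (ns in c(10, 25)) {
    ex <- gsz_binary(1000, nl, ns, 3)
    ap <- gsz_binary(1000, nl, ns, 3, approx = TRUE)
    expect_lt(abs(ap - ex) / abs(ex), 0.1)
  }
})

test_that("GSZ regularization penalizes short lists and damps incoherent sets", {
  universe <- sprintf("u%03d", 1:200)
  set.seed(32)
  sc <- setNames(rnorm(200), universe)
  # lambda formula endpoints
  prm <- gsz_params(n_list_min = 10, n_set_min = 10)
  long <- gsz(sc, universe[1:20], n = 200, params = prm)
  expect_true(is.finite(long))
  # coherent vs incoherent set of equal size: coherent scores higher
  sc2 <- sc
  sc2[universe[1:10]] <- 2      # coherent positives
  sc2[universe[11:20]] <- c(rep(2, 5), rep(-2, 5))  # compensating signs
  z_coh <- abs(gsz(sc2, universe[1:10], n = 200, params = prm))
  z_inc <- abs(gsz(sc2, universe[11:20], n = 200, params = prm))
  expect_gt(z_coh, z_inc)
})

test_that("permutation p-values are seeded, bounded and null-uniform", {
  universe <- sprintf("u%03d", 1:150)
  set.seed(33)
  sc <- setNames(rnorm(150), universe)
  prm <- gsz_params(permutations = 200, seed = 9)
  st <- universe[1:12]
  z <- gsz(sc, st, n = 150, params = prm)
  p1 <- gsz_permutation_p(z, sc, universe, 12, prm)
  p2 <- gsz_permutation_p(z, sc, universe, 12, prm)
  expect_identical(p1, p2)                 # seeded
  expect_gte(p1, 1 / 201)                 # add-one bound
  # a zero observation is never extreme
  expect_gt(gsz_permutation_p(0, sc, universe, 12, prm), 0.5)

  # null uniformity: p-values of random sets pass a KS check
  set.seed(34)
  prm2 <- gsz_params(permutations = 150, seed = 5)
  ps <- replicate(120, {
    rs <- sample(universe, 10)
    zz <- gsz(sc, rs, n = 150, n_set = 10, params = prm2)
    gsz_permutation_p(zz, sc, universe, 10, prm2)
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("metagene overrepresentation maps match per-tile brute force", {
  d <- small_delta(n = 60)
  g <- som_train(d, som_linear_init(d, c(3, 3)),
                 som_schedule(presentations = 1500, seed = 6))
  a <- map_genes(d, g)
  set.seed(35)
  st <- sample(rownames(d), 15)
  mp <- metagene_overrepresentation_map(st, a)
  for (k in seq_len(a$k)) {
    if (a$n_k[k] == 0) {
      expect_true(is.na(mp$p[k]))
      next
    }
    expect_equal(mp$p[k],
                 hg_overrepresentation(60, a$n_k[k], 15,
                                       length(intersect(a$clusters[[k]], st))))
  }
  expect_equal(unname(mp$mask),
               unname(sapply(a$clusters,
                             function(cl) length(intersect(cl, st)) == 0)))

  # a set confined to one cluster is most significant there
  k_big <- which.max(a$n_k)
  conf <- a$clusters[[k_big]]
  mpc <- metagene_overrepresentation_map(conf, a)
  expect_equal(which.min(mpc$p), k_big)
})

test_that("spot enrichment ranks a planted set first among decoys", {
  fx <- small_fixture(seed = 36, n_genes = 400)
  prep <- preprocess_expression(fx$expr, fx$conditions)
  som <- train_som(prep$delta, dims = c(8, 8),
                   schedule = som_schedule(presentations = 15000, seed = 36))
  sp <- summary_spots(summary_maps(som$grid), som$dims, q = 0.95)
  collection <- matched_gmt(fx, decoys = 4, seed = 2)
  universe <- rownames(prep$delta)
  # the sample where module 1 is active
  m_active <- which(fx$groups == fx$module_group[1])[1]
  sc <- setNames(prep$delta[, m_active], universe)
  jacc <- sapply(sp$over, function(s) {
    gl <- spot_gene_list(s, som$assignment)
    length(intersect(gl, fx$modules[[1]])) / length(union(gl, fx$modules[[1]]))
  })
  s_best <- sp$over[[which.max(jacc)]]
  er <- spot_enrichment(spot_gene_list(s_best, som$assignment), collection,
                        sc, universe,
                        params = gsz_params(permutations = 200, seed = 3))
  expect_equal(er$set[1], "module1")
  expect_lt(er$hg_p[er$set == "module1"], min(er$hg_p[grepl("decoy", er$set)]))
})

test_that("gene set profiles peak in the active sample group", {
  fx <- small_fixture(seed = 37, n_genes = 400)
  prep <- preprocess_expression(fx$expr, fx$conditions)
  prof <- gene_set_profile(fx$modules[[1]], prep$delta,
                           params = gsz_params(permutations = 150, seed = 4))
  active <- which(fx$groups == fx$module_group[1])
  expect_true(all(prof$profile$gsz[active] > max(prof$profile$gsz[-active])))
  # whole-universe set gives a flat zero profile
  prof0 <- gene_set_profile(rownames(prep$delta), prep$delta,
                            params = gsz_params(permutations = 150, seed = 4))
  expect_true(all(abs(prof0$profile$gsz) < 1e-12))
})

test_that("top-three aggregation deduplicates and orders deterministically", {
  res <- data.frame(
    sample = rep(c("s1", "s2"), each = 5),
    spot = "A",
    set = c(paste0("x", 1:5), c("x1", "x2", "y3", "y4", "y5")),
    p = c(0.001, 0.002, 0.003, 0.5, 0.6, 0.004, 0.001, 0.002, 0.7, 0.8))
  hm <- top_three_heatmap(res)
  # union of per-context top-3 with duplicates removed
  expect_setequal(hm$sets, c("x1", "x2", "x3", "y3"))
  expect_equal(dim(hm$matrix), c(4, 2))
  hm2 <- top_three_heatmap(res)
  expect_identical(hm$matrix, hm2$matrix)
  expect_warning(empty <- top_three_heatmap(res[0, ]), "no enrichment")
  expect_null(empty$matrix)
})
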