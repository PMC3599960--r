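test_that("linear initialization spans the two leading eigenvectors", {
  d <- small_delta()
  g <- som_linear_init(d, c(2, 2))
  # independent eigen decomposition of the profile covariance
  eg <- eigen(crossprod(d) / (nrow(d) - 1), symmetric = TRUE)
  vs <- lapply(1:2, function(i) {
    v <- eg$vectors[, i] * sqrt(eg$values[i])
    if (v[which.max(abs(v))] < 0) -v else v
  })
  expect_equal(unname(g$weights[1, ]), unname(-vs[[1]] - vs[[2]]))  # (1,1)
  expect_equal(unname(g$weights[2, ]), unname(vs[[1]] - vs[[2]]))   # (2,1)
  expect_equal(unname(g$weights[3, ]), unname(-vs[[1]] + vs[[2]]))  # (1,2)
  expect_equal(unname(g$weights[4, ]), unname(vs[[1]] + vs[[2]]))   # (2,2)

  # center tile of an odd grid has zero coefficients
  g3 <- som_linear_init(d, c(3, 3))
  expect_equal(unname(g3$weights[5, ]), rep(0, ncol(d)))

  # deterministic: identical input gives identical grids
  expect_identical(som_linear_init(d, c(5, 4))$weights,
                   som_linear_init(d, c(5, 4))$weights)

  # degenerate covariance rejected
  rank1 <- outer(1:10, c(1, 2, 3))
  expect_error(som_linear_init(rank1, c(2, 2)), "rank")
})

test_that("best_matching_unit agrees with an exhaustive scan and breaks ties low", {
  d <- small_delta()
  g <- som_linear_init(d, c(4, 4))
  expect_equal(best_matching_unit(g$weights[7, ], g), 7)
  set.seed(2)
  for (i in 1:20) {
    pr <- rnorm(ncol(d))
    brute <- which.min(colSums((t(g$weights) - pr)^2))
    expect_equal(best_matching_unit(pr, g), unname(brute))
  }
  # exact tie between two metagenes resolves to the lowest linear index
  gt <- som_grid(3, 1, weights = rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_equal(best_matching_unit(c(1, 0), gt), 1)
  expect_equal(best_matching_unit(c(0.5, 0.5), gt), 1)
})

test_that("training updates behave at schedule extremes", {
  d <- small_delta(n = 20)
  g <- som_linear_init(d, c(3, 3))
  # zero learning rate: nothing moves
  s0 <- som_schedule(presentations = 500, rate_max = 1e-12, rate_min = 0,
                     seed = 1)
  expect_equal(som_train(d, g, s0)$weights, g$weights, tolerance = 1e-9)

  # one gene, radius 0, rate 1, one presentation: BMU becomes the profile
  one <- d[1, , drop = FALSE]
  s1 <- som_schedule(presentations = 1, rate_max = 1, rate_min = 1,
                     radius_init = 0, radius_min = 0, seed = 1)
  tr <- som_train(one, g, s1)
  bmu <- best_matching_unit(one[1, ], g)
  expect_equal(unname(tr$weights[bmu, ]), unname(one[1, ]))

  # identical gene rows: all metagenes converge toward the shared profile
  same <- matrix(rep(d[1, ], 30), 30, ncol(d), byrow = TRUE)
  gi <- som_linear_init(rbind(same, d[2, ] * 1e-3), c(3, 3))
  dist_max <- function(w) max(sqrt(rowSums(sweep(w, 2, d[1, ])^2)))
  stages <- sapply(c(200, 2000, 20000), function(p) {
    dist_max(som_train(same, gi, som_schedule(presentations = p,
                                              seed = 9))$weights)
  })
  expect_true(all(diff(stages) < 0))
})

test_that("training is bit-reproducible for a fixed seed", {
  d <- small_delta()
  g <- som_linear_init(d, c(5, 5))
  s <- som_schedule(presentations = 3000, seed = 77)
  w1 <- som_train(d, g, s)$weights
  w2 <- som_train(d, g, s)$weights
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))
  w3 <- som_train(d, g, som_schedule(presentations = 3000, seed = 78))$weights
  expect_false(identical(w1, w3))
})

test_that("map_genes partitions the gene set and allows empty tiles", {
  d <- small_delta()
  g <- som_train(d, som_linear_init(d, c(4, 4)),
                 som_schedule(presentations = 2000, seed = 3))
  a <- map_genes(d, g)
  expect_equal(sum(a$n_k), nrow(d))
  expect_setequal(unlist(a$clusters), rownames(d))
  expect_equal(unname(lengths(a$clusters)), unname(a$n_k))

  # K = 1: everything in one cluster
  g1 <- som_grid(1, 1, weights = matrix(0, 1, ncol(d)))
  a1 <- map_genes(d, g1)
  expect_equal(unname(a1$n_k), nrow(d))

  # genes placed exactly on distinct metagenes land on those tiles
  probe <- g$weights[c(2, 9), ]
  rownames(probe) <- c("p1", "p2")
  ap <- map_genes(probe, g)
  expect_equal(unname(ap$bmu), c(2, 9))
})

test_that("expression states are columns of the metagene matrix", {
  d <- small_delta()
  g <- som_linear_init(d, c(3, 3))
  expect_equal(metagene_expression_state(g, 1), g$weights[, 1])
  expect_equal(metagene_expression_state(g, "s2"), g$weights[, "s2"])
  all_states <- sapply(seq_len(ncol(d)), metagene_expression_state, grid = g)
  expect_equal(unname(all_states), unname(g$weights))
  expect_length(metagene_expression_state(g, 1), g$k)
  expect_error(metagene_expression_state(g, 99), "out of range")
})

test_that("trained maps are topology-preserving and self-organized", {
  fx <- small_fixture(seed = 21, n_genes = 500, n_samples = 8)
  prep <- preprocess_expression(fx$expr, fx$conditions)
  som <- train_som(prep$delta, dims = c(10, 10),
                   schedule = som_schedule(presentations = 20000, seed = 21))
  co <- som$grid$coords
  # genes of one planted module sit closer on the grid than across modules
  bmu1 <- som$assignment$bmu[fx$modules[[1]]]
  bmu2 <- som$assignment$bmu[fx$modules[[2]]]
  grid_dist <- function(a, b)
    sqrt((co[a, 1] - co[b, 1])^2 + (co[a, 2] - co[b, 2])^2)
  within1 <- mean(grid_dist(rep(bmu1, each = length(bmu1)), rep(bmu1, length(bmu1))))
  between <- mean(grid_dist(rep(bmu1, each = length(bmu2)), rep(bmu2, length(bmu1))))
  expect_lt(within1, between)

  # neighboring metagenes correlate more than distant ones
  w <- som$grid$weights
  cors_at <- function(dlo, dhi) {
    acc <- c()
    for (k in seq_len(nrow(w))) {
      dd <- sqrt((co[, 1] - co[k, 1])^2 + (co[, 2] - co[k, 2])^2)
      sel <- which(dd >= dlo & dd <= dhi & seq_len(nrow(w)) > k)
      if (length(sel))
        acc <- c(acc, suppressWarnings(cor(w[k, ], t(w[sel, , drop = FALSE]))))
    }
    mean(acc, na.rm = TRUE)
  }
  expect_gt(cors_at(1, 1), cors_at(5, 100))
})
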