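test_that("rook and queen adjacency have the textbook neighbour counts", {
  w_rook <- build_weights(matrix(TRUE, 4, 4), "rook", "binary")
  w_queen <- build_weights(matrix(TRUE, 4, 4), "queen", "binary")
  deg_r <- lengths(w_rook$neighbors)
  deg_q <- lengths(w_queen$neighbors)
  # corners / edges / interior
  corner <- c(1, 4, 13, 16); interior <- c(6, 7, 10, 11)
  expect_true(all(deg_r[corner] == 2) && all(deg_q[corner] == 3))
  expect_true(all(deg_r[interior] == 4) && all(deg_q[interior] == 8))
  expect_equal(sum(deg_r), 2 * (2 * 4 * 3))        # 24 rook edges
  # adjacency is symmetric
  W <- dense_weights(w_queen)
  expect_equal(W, t(W))
  # row standardization makes each row sum to 1
  wr <- build_weights(matrix(TRUE, 4, 4), "queen", "row")
  expect_true(all(abs(vapply(wr$weights, sum, 0) - 1) < 1e-15))
  expect_error(build_weights(matrix(TRUE, 1, 1)), "at least 2")
})

test_that("nodata cells leave the graph and isolated cells are flagged", {
  m <- matrix(TRUE, 3, 5)
  m[, 2] <- FALSE          # disconnects column 1 from the rest under rook
  m[2, 1] <- FALSE
  w <- build_weights(m, "rook", "row")
  expect_equal(length(w$cells), sum(m))
  # cells (1,1) and (3,1) have no valid rook neighbour left
  expect_equal(w$cells[w$isolated], c(1L, 3L))
  expect_error(build_weights(rbind(c(TRUE, FALSE), c(FALSE, TRUE)), "rook"),
               "all cells are isolated")
})

test_that("global Moran's I equals the brute-force double loop to 1e-12", {
  set.seed(19)
  for (cfg in list(list(5, 5, "queen", "row"), list(4, 6, "rook", "binary"),
                   list(3, 7, "queen", "binary"), list(5, 4, "rook", "row"))) {
    x <- matrix(rnorm(cfg[[1]] * cfg[[2]]), cfg[[1]], cfg[[2]])
    w <- build_weights(matrix(TRUE, cfg[[1]], cfg[[2]]), cfg[[3]], cfg[[4]])
    expect_equal(global_morans_i(x, w),
                 brute_global_moran(as.numeric(x[w$cells]), dense_weights(w)),
                 tolerance = 1e-12)
  }
})

test_that("local Moran's I equals the brute-force oracle and sums to a global multiple", {
  set.seed(20)
  x <- matrix(rnorm(25), 5, 5)
  w <- build_weights(matrix(TRUE, 5, 5), "queen", "row")
  li <- local_morans_i(x, w)
  oracle <- brute_local_moran(as.numeric(x[w$cells]), dense_weights(w))
  expect_equal(as.numeric(li[w$cells]), oracle, tolerance = 1e-12)
  # sum of local I is proportional to global I: sum Ii = global * S0 * (n-1)/n
  n <- 25; s0 <- sum(unlist(w$weights))
  expect_equal(sum(li), global_morans_i(x, w) * s0 * (n - 1) / n,
               tolerance = 1e-10)
})

test_that("a checkerboard under rook row-standardized weights gives I = -1", {
  cb <- outer(1:8, 1:8, function(r, c) as.numeric((r + c) %% 2 == 0))
  w <- build_weights(matrix(TRUE, 8, 8), "rook", "row")
  expect_equal(global_morans_i(cb, w), -1, tolerance = 1e-12)
  # and every cell is a perfect spatial outlier locally
  li <- local_morans_i(cb, w)
  expect_true(all(li < 0))
})

test_that("Moran's I is invariant to affine transformations of the field", {
  set.seed(21)
  x <- matrix(rnorm(36), 6, 6)
  w <- build_weights(matrix(TRUE, 6, 6), "queen", "row")
  expect_equal(global_morans_i(3 * x - 7, w), global_morans_i(x, w),
               tolerance = 1e-12)
  expect_equal(local_morans_i(-2 * x + 1, w), local_morans_i(x, w),
               tolerance = 1e-12)
})

test_that("permutation p-values are deterministic, in range, and find a planted cluster", {
  set.seed(22)
  x <- matrix(rnorm(144, 50, 2), 12, 12)
  x[5:8, 5:8] <- x[5:8, 5:8] + 40      # strong high-high block
  p1 <- permutation_p(x, build_weights(!is.na(x)), n_perm = 199, seed = 9L)
  p2 <- permutation_p(x, build_weights(!is.na(x)), n_perm = 199, seed = 9L)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 <= 1))
  expect_gte(min(p1), 1 / 200)
  res <- lisa(x, n_perm = 199, seed = 9L)
  expect_true(all(res$cluster[6:7, 6:7] == "HH"))
  expect_gt(res$global_i, 0)
  expect_error(permutation_p(x, build_weights(!is.na(x)), n_perm = 50),
               ">= 99")
})

test_that("the classifier assigns all four Moran-scatter quadrants", {
  # archetypes: high block (HH), low cell inside it (LH), high spike in the
  # low background (HL), deep background (LL); significance is forced so the
  # quadrant geometry is tested in isolation from permutation power
  x <- matrix(10, 11, 11)
  x[2:5, 2:5] <- 100
  x[3, 3] <- 10
  x[9, 9] <- 100
  w <- build_weights(!is.na(x), "queen", "row")
  li <- local_morans_i(x, w)
  p_sig <- matrix(0.001, 11, 11)
  lab <- lisa_classify(x, w, li, p_sig, alpha = 0.05)
  expect_equal(lab[3, 3], "LH")
  expect_equal(lab[9, 9], "HL")
  expect_equal(lab[4, 4], "HH")
  expect_equal(lab[10, 3], "LL")
  # nothing significant -> everything NS
  expect_true(all(lisa_classify(x, w, li, matrix(1, 11, 11)) == "NS"))
})

test_that("lisa() flags planted high and low clusters end to end", {
  set.seed(24)
  x <- matrix(rnorm(225, 50, 1), 15, 15)
  x[3:6, 3:6] <- x[3:6, 3:6] + 40
  x[10:13, 10:13] <- x[10:13, 10:13] - 40
  res <- lisa(x, n_perm = 499, seed = 5L, alpha = 0.05)
  expect_true(all(res$cluster[4:5, 4:5] == "HH"))
  expect_true(all(res$cluster[11:12, 11:12] == "LL"))
  expect_true(all(res$cluster %in% c("HH", "LL", "HL", "LH", "NS")))
  # the overwhelming share of plain background stays NS
  bg <- res$cluster[8:9, 1:15]
  expect_gt(mean(bg == "NS"), 0.8)
})

test_that("nodata holes propagate NA through the whole LISA stack", {
  set.seed(23)
  x <- matrix(rnorm(100), 10, 10)
  x[c(3, 44, 91)] <- NA
  res <- lisa(x, n_perm = 99, seed = 4L)
  expect_true(all(is.na(res$local_i[c(3, 44, 91)])))
  expect_true(all(is.na(res$p[c(3, 44, 91)])))
  expect_true(all(is.na(res$cluster[c(3, 44, 91)])))
  expect_false(anyNA(res$local_i[-c(3, 44, 91)]))
})
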