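chain_layout <- make_layout(c("c1", "c2", "c3"),
                            cbind(c(0, 1, 2), 0, 0))

test_that("distance-threshold adjacency produces the expected neighbor graph", {
  A <- build_adjacency(chain_layout, 1.5)
  expect_true(A["c1", "c2"] && A["c2", "c3"])
  expect_false(A["c1", "c3"])
  expect_true(all(diag(unclass(A)) == FALSE))
  expect_identical(unclass(A), t(unclass(A)))
  expect_warning(build_adjacency(chain_layout, 0.5), "without neighbors")
  expect_error(build_adjacency(chain_layout, -1), "> 0")
})

test_that("the paired t map matches the textbook formula and its edge cases", {
  set.seed(41)
  n <- 8
  avgA <- array(rnorm(n * 2 * 5), c(n, 2, 5), dimnames = list(NULL, c("c1", "c2"), NULL))
  avgB <- array(rnorm(n * 2 * 5), c(n, 2, 5), dimnames = list(NULL, c("c1", "c2"), NULL))
  tm <- paired_tmap(avgA, avgB)
  for (ch in 1:2) for (s in 1:5) {
    oracle <- t.test(avgA[, ch, s], avgB[, ch, s], paired = TRUE)$statistic
    expect_lt(abs(tm$t[ch, s] - oracle), 1e-10)
  }
  expect_equal(tm$t_crit, qt(0.975, n - 1))

  expect_true(all(paired_tmap(avgA, avgA)$t == 0))

  constant <- avgA
  constant[, 1, 1] <- avgB[, 1, 1] + 1   # zero-variance positive difference
  expect_equal(paired_tmap(constant, avgB)$t[1, 1], Inf, ignore_attr = TRUE)
  expect_error(paired_tmap(avgA[1:2, , , drop = FALSE],
                           avgB[1:2, , , drop = FALSE]), "3 participants")
})

test_that("clusters form over same-sign spatio-temporal neighborhoods", {
  A <- build_adjacency(chain_layout, 1.5)
  tm <- matrix(0, 3, 50, dimnames = list(c("c1", "c2", "c3"), NULL))
  tm[1:2, 10:12] <- 5
  tm[3, 40] <- 5
  cl <- form_clusters(tm, 2, A)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, function(x) nrow(x$members), integer(1)), c(6L, 1L))
  expect_equal(sort(vapply(cl, function(x) x$mass, numeric(1))), c(5, 30))
  # opposite-sign points never join
  tm[2, 10:12] <- -5
  cl2 <- form_clusters(tm, 2, A)
  expect_length(cl2, 3)
  expect_length(form_clusters(matrix(0, 3, 50,
                                     dimnames = list(c("c1", "c2", "c3"), NULL)),
                              2, A), 0)
})

test_that("clustering equals an independent label-propagation oracle", {
  set.seed(42)
  labels <- paste0("c", 1:6)
  for (i in 1:60) {
    pos <- cbind(runif(6), runif(6), 0)
    lay <- make_layout(labels, pos)
    A <- suppressWarnings(build_adjacency(lay, 0.5))
    tm <- matrix(rnorm(6 * 20, sd = 1.3), 6, 20,
                 dimnames = list(labels, NULL))
    got <- form_clusters(tm, 1.5, A)
    want <- bfs_cluster_oracle(tm, 1.5, A)
    expect_identical(cluster_signature(got, 6), cluster_signature(want, 6))
  }
})

test_that("the permutation null enumerates all sign patterns when feasible", {
  set.seed(43)
  n <- 5
  labels <- c("c1", "c2", "c3")
  avgA <- array(rnorm(n * 3 * 10), c(n, 3, 10), dimnames = list(NULL, labels, NULL))
  avgB <- array(rnorm(n * 3 * 10), c(n, 3, 10), dimnames = list(NULL, labels, NULL))
  A <- build_adjacency(chain_layout, 1.5)
  cfg <- cbpt_config(n_permutations = 1000, seed = 7)
  null <- permutation_null(avgA, avgB, cfg, A)
  expect_true(attr(null, "exhaustive"))
  expect_length(null, 32)

  # independent enumeration: per-pattern t maps via the textbook formula,
  # clustered with the label-propagation oracle
  D <- avgA - avgB
  t_crit <- qt(1 - cfg$cluster_forming_p / 2, n - 1)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  oracle <- apply(signs, 1, function(s) {
    Df <- array(s * matrix(D, nrow = n), dim(D), dimnames = dimnames(D))
    tm <- matrix(NA_real_, 3, 10, dimnames = list(labels, NULL))
    for (ch in 1:3) for (sm in 1:10) {
      x <- Df[, ch, sm]
      tm[ch, sm] <- mean(x) / (sd(x) / sqrt(n))
    }
    cl <- bfs_cluster_oracle(tm, t_crit, A)
    if (length(cl) == 0) 0 else max(abs(vapply(cl, function(x) x$mass,
                                               numeric(1))))
  })
  expect_equal(sort(null), sort(oracle), tolerance = 1e-9)
})

test_that("identical conditions give a degenerate null and a fixed seed reproduces it", {
  set.seed(44)
  labels <- c("c1", "c2", "c3")
  avgA <- array(rnorm(4 * 3 * 8), c(4, 3, 8), dimnames = list(NULL, labels, NULL))
  A <- build_adjacency(chain_layout, 1.5)
  null0 <- permutation_null(avgA, avgA, cbpt_config(n_permutations = 50, seed = 1), A)
  expect_true(all(null0 == 0))

  avgB <- array(rnorm(4 * 3 * 8), c(4, 3, 8), dimnames = list(NULL, labels, NULL))
  cfg <- cbpt_config(n_permutations = 10, seed = 99)
  expect_identical(permutation_null(avgA, avgB, cfg, A),
                   permutation_null(avgA, avgB, cfg, A))
})

test_that("cbpt_test orders clusters by mass with valid, monotone p values", {
  set.seed(45)
  labels <- pkg_layout$label[pkg_layout$type == "scalp"][1:8]
  null <- simulate_null_averages(10, labels, 25, pkg_layout, seed = 5)
  res <- cbpt_test(null$avgA, null$avgB, pkg_layout,
                   cbpt_config(n_permutations = 200, seed = 6), max_dist = 0.06)
  if (nrow(res) > 1) {
    expect_true(all(diff(abs(res$mass)) <= 1e-12))
    expect_true(all(diff(res$p_mc) >= -1e-12))
  }
  expect_true(all(res$p_mc >= 1 / 201))
  expect_true(all(res$p_mc <= 1))
  expect_error(cbpt_test(null$avgA[1:2, , ], null$avgB[1:2, , ], pkg_layout,
                         cbpt_config(n_permutations = 10)), "participants")
})

test_that("an injected spatio-temporal effect is detected where it was placed", {
  set.seed(46)
  labels <- pkg_layout$label[pkg_layout$type == "scalp"][1:16]
  patch_ch <- labels[1:8]
  patch_s <- 20:29  # 100 ms at 100 Hz
  hits <- 0
  for (i in 1:10) {
    null <- simulate_null_averages(20, labels, 50, pkg_layout,
                                   sampling_rate = 100, seed = 100 + i)
    avgA <- null$avgA
    avgA[, match(patch_ch, labels), patch_s] <-
      avgA[, match(patch_ch, labels), patch_s] + 2
    res <- cbpt_test(avgA, null$avgB, pkg_layout,
                     cbpt_config(n_permutations = 200, seed = 200 + i),
                     max_dist = 0.06)
    sig <- res[res$significant, ]
    overlap <- any(vapply(seq_len(nrow(sig)), function(k) {
      m <- sig$members[[k]]
      any(labels[m[, "channel"]] %in% patch_ch & m[, "sample"] %in% patch_s)
    }, logical(1)))
    hits <- hits + overlap
  }
  expect_gte(hits, 9)
})
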