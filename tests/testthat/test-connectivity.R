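test_that("binarization is strict at the threshold", {
  expect_equal(as.vector(binarize(c(0.25, 0.15, 0.2, 0))), c(1, 0, 0, 0))
  m <- binarize(rbind(a = c(0.5, 0), b = c(0, 0)))
  expect_equal(as.vector(m["b", ]), c(0, 0))
})

test_that("the coactivity coefficient satisfies its coordination contracts", {
  a <- burst_vector(2400, seq(1, 2201, by = 200), 40)
  expect_equal(coactivity_pair(a, a), 1) # perfect coordination
  b <- burst_vector(400, 1, 200)
  c2 <- burst_vector(400, 201, 200)
  expect_equal(coactivity_pair(b, c2), 0) # no coordination at all
  # equal active times, half overlap: coordinated 50% of the time
  d <- burst_vector(400, 1, 200)
  e <- burst_vector(400, 101, 200)
  expect_equal(coactivity_pair(d, e), 0.5)
  # never-active pairs are 0, not NaN
  expect_equal(coactivity_pair(rep(0L, 10), rep(1L, 10)), 0)
  expect_error(coactivity_pair(1:4, 1:5), "length")
  # the literal printed normalization is available but cannot reach 1
  expect_equal(coactivity_pair(d, d, norm = "printed"), 1 / 200)
})

test_that("the coactivity matrix matches hand-computed 3-cell overlaps", {
  a <- burst_vector(100, 1, 40)   # T = 40
  b <- burst_vector(100, 21, 40)  # T = 40, overlap with a = 20
  c3 <- burst_vector(100, 61, 30) # T = 30, overlap a = 0, overlap b = 0
  bin <- rbind(a = a, b = b, c = c3)
  res <- coactivity_matrix(bin, n_shuffles = 50, seed = 1)
  expect_equal(res$C["a", "b"], 20 / sqrt(40 * 40))
  expect_equal(res$C["a", "c"], 0)
  expect_equal(res$C["b", "c"], 0)
  expect_equal(diag(res$C), rep(1, 3), ignore_attr = TRUE)
  expect_true(isSymmetric(res$C))
  expect_equal(res$c_islet, mean(c(0.5, 0, 0)))
  expect_equal(res$connectivity_class, "low")
  expect_error(coactivity_matrix(bin[1, , drop = FALSE]), "2 cells")
})

test_that("coactivity agrees with a brute-force oracle on random instances", {
  brute <- function(bin) {
    m <- nrow(bin)
    C <- diag(1, m)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i == j) next
        ti <- sum(bin[i, ]); tj <- sum(bin[j, ])
        tij <- sum(bin[i, ] == 1 & bin[j, ] == 1)
        C[i, j] <- if (ti == 0 || tj == 0) 0 else tij / sqrt(ti * tj)
      }
    }
    C
  }
  set.seed(14)
  for (rep in 1:100) {
    bin <- matrix(as.integer(runif(6 * 120) < 0.3), nrow = 6)
    res <- coactivity_matrix(bin, n_shuffles = 5, seed = rep)
    expect_equal(unname(res$C), brute(bin), tolerance = 1e-12)
  }
})

test_that("coactivity is invariant to a common circular shift of all cells", {
  set.seed(6)
  bin <- rbind(a = markov_activity(600), b = markov_activity(600),
               c = markov_activity(600))
  shift <- function(v, k) c(v[(k + 1):length(v)], v[1:k])
  bin2 <- t(apply(bin, 1, shift, k = 137))
  r1 <- coactivity_matrix(bin, n_shuffles = 10, seed = 3)
  r2 <- coactivity_matrix(bin2, n_shuffles = 10, seed = 3)
  expect_equal(r1$C, r2$C, ignore_attr = TRUE)
})

test_that("the shuffle null flags aligned pairs and spares independent ones", {
  set.seed(10)
  a <- burst_vector(2400, seq(1, 2201, by = 200), 60)
  res <- shuffle_null(a, a, n_shuffles = 500)
  expect_true(res$significant)
  expect_equal(res$observed, 1)
  expect_lt(res$null_mean + 2 * res$null_sd, 1)

  # all-zero vectors: never significant, null stats zero
  z <- shuffle_null(rep(0L, 100), a[1:100], n_shuffles = 50)
  expect_false(z$significant)
  expect_equal(z$null_mean, 0)
  expect_error(shuffle_null(a, a, n_shuffles = 0), "n_shuffles")
})

test_that("rotation surrogates reproduce explicit-rotation statistics", {
  # the sampled-lag implementation must match brute-force rotated copies
  set.seed(4)
  a <- markov_activity(300)
  b <- markov_activity(300)
  o <- isletca:::circular_overlap(as.numeric(a), as.numeric(b))
  brute <- vapply(0:299, function(lag) {
    rb <- if (lag == 0) b else c(b[(lag + 1):300], b[1:lag])
    sum(a * rb)
  }, numeric(1))
  # circular_overlap enumerates the same multiset of co-active counts as
  # explicitly rotating one vector through every offset
  expect_equal(sort(as.integer(o)), sort(as.integer(brute)))
})

test_that("criterion hubs need 80% strong significant partners", {
  m <- 11
  C <- matrix(0.5, m, m)
  sig <- matrix(TRUE, m, m)
  diag(sig) <- FALSE
  # cell 1 has 10 significant partners, 9 with C >= 0.8
  C[1, 2:10] <- C[2:10, 1] <- 0.85
  C[1, 11] <- C[11, 1] <- 0.5
  diag(C) <- 1
  res <- structure(
    list(C = C, significant = sig, cell_ids = paste0("c", 1:m),
         degree = rowSums(sig)),
    class = "coactivity_result"
  )
  hubs <- identify_hubs_criterion(res)
  expect_true(hubs$is_hub_criterion[1]) # 9/10 = 90% >= 80%
  # now only 7/10 strong
  C[1, 8:10] <- C[8:10, 1] <- 0.5
  res$C <- C
  expect_false(identify_hubs_criterion(res)$is_hub_criterion[1])
  # cells with zero significant partners are never hubs
  res$significant[2, ] <- res$significant[, 2] <- FALSE
  res$degree <- rowSums(res$significant)
  expect_false(identify_hubs_criterion(res)$is_hub_criterion[2])
})

test_that("top-10% hubs are the best connected, ties broken deterministically", {
  m <- 50
  sig <- matrix(FALSE, m, m)
  # cell i is connected to cells 1..min(i+1, m) so degree grows with index
  for (i in seq_len(m)) {
    for (j in seq_len(m)) if (i != j && j <= i + 1) sig[i, j] <- sig[j, i] <- TRUE
  }
  C <- matrix(0.9, m, m); diag(C) <- 1
  res <- structure(
    list(C = C, significant = sig, cell_ids = paste0("c", 1:m),
         degree = rowSums(sig)),
    class = "coactivity_result"
  )
  hubs <- identify_hubs_top10(res)
  expect_equal(sum(hubs$is_hub_top10), 5) # ceiling(0.1 * 50)
  expect_true(hubs$is_hub_top10[which.max(res$degree)])
})

test_that("network export produces the full edge list and places nodes", {
  bin <- rbind(a = burst_vector(200, 1, 100),
               b = burst_vector(200, 1, 100),
               c = burst_vector(200, 51, 100))
  res <- coactivity_matrix(bin, n_shuffles = 200, seed = 7)
  cen <- tibble::tibble(cell_id = c("a", "b", "c"), x_px = c(0, 10, 20),
                        y_px = c(0, 0, 5))
  net <- export_network(res, cen)
  expect_equal(nrow(net$edges), 3) # n(n-1)/2
  expect_equal(net$nodes$x_px, c(0, 10, 20))
  sig_only <- export_network(res, cen, significant_only = TRUE)
  expect_true(all(sig_only$edges$significant))
  expect_warning(net2 <- export_network(res, cen[1:2, ]), "origin")
  expect_equal(net2$nodes$x_px[3], 0)
})
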