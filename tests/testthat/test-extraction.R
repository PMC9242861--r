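test_that("Poisson resampling is unbiased, deterministic and errors on negatives", {
  m0 <- matrix(0, 3, 4)
  expect_equal(poisson_resample(m0, seed = 1), m0)
  expect_error(poisson_resample(matrix(-1, 1, 1)), "negative")
  expect_equal(poisson_resample(matrix(3, 5, 5), seed = 9),
               poisson_resample(matrix(3, 5, 5), seed = 9))
  ## CLT bound: mean of 10,000 resamples of an entry of 5 within 5 +/- 3*sqrt(5/1e4)
  draws <- poisson_resample(matrix(5, 100, 100), seed = 2)
  expect_lt(abs(mean(draws) - 5), 3 * sqrt(5 / 1e4))
})

test_that("KL-NMF factorizes exactly factorizable input and keeps outputs non-negative", {
  set.seed(41)
  w <- runif(48, 0, 2)
  h <- runif(30, 1, 5)
  mat <- t(outer(w, h))           # rank-1, samples x channels
  reps <- run_nmf(mat, k = 1, n_replicates = 3, seed = 4, resample = FALSE,
                  max_iter = 4000, tol = 1e-12)
  for (r in reps) {
    expect_lt(r$divergence, 1e-6 * sum(mat))
    expect_true(all(r$W >= 0) && all(r$H >= 0))
    ## multiplicative updates never increase the objective
    expect_true(all(diff(r$trace) <= 1e-8 * max(abs(r$trace[1]), 1)))
  }
  expect_error(run_nmf(mat, k = 0), ">= 1")
  expect_error(run_nmf(mat[1:3, ], k = 10), "exceeds")
})

test_that("well-separated planted signatures are recovered by every replicate", {
  set.seed(42)
  sig1 <- unit_signature("het:2:>40Mb") * 0.7 +
    unit_signature("het:2:10Mb-40Mb") * 0.3
  sig2 <- unit_signature("loh:1:1Mb-10Mb") * 0.6 +
    unit_signature("loh:1:100kb-1Mb") * 0.4
  truth <- cbind(sig1, sig2)
  mix <- sim_mixture_catalogue(truth, 60, seg_range = c(100, 300), seed = 6)
  reps <- run_nmf(mix$counts, k = 2, n_replicates = 6, seed = 8,
                  max_iter = 2000, tol = 1e-8)
  for (r in reps) {
    W <- apply(r$W, 2, function(x) x / sum(x))
    expect_true(all(best_match_cosines(W, truth) >= 0.99))
  }
})

test_that("replicate clustering yields consensus signatures with a stability score", {
  set.seed(43)
  W0 <- cbind(unit_signature("het:2:>40Mb"),
              unit_signature("loh:1:0-100kb"))
  mk_rep <- function(noise) {
    W <- W0 + matrix(runif(96, 0, noise), 48, 2)
    list(W = W, H = matrix(1, 2, 5), divergence = 0, trace = 0)
  }
  ## identical replicates: stability 1, consensus = replicate
  reps <- replicate(4, mk_rep(0), simplify = FALSE)
  cons <- cluster_replicates(reps, k = 2)
  expect_equal(cons$stability, 1.0)
  expect_true(all(best_match_cosines(cons$W, W0) == 1))
  ## small perturbations: consensus within cosine 0.999 of clean truth
  reps2 <- replicate(8, mk_rep(0.01), simplify = FALSE)
  cons2 <- cluster_replicates(reps2, k = 2)
  expect_true(all(best_match_cosines(cons2$W, W0) >= 0.999))
  expect_gt(cons2$stability, 0.9)
  expect_error(cluster_replicates(reps[1], 1), ">= 2")
})

test_that("rank selection applies the stability and error-elbow rule", {
  ## flattening error at k = 3 with collapsing stability beyond
  s <- select_k(1:4, c(1.0, 1.0, 0.95, 0.4), c(1.0, 0.5, 0.1, 0.095))
  expect_equal(s$selected_k, 3)
  expect_false(s$flagged)
  ## single repeated pattern: k = 1
  s1 <- select_k(1:3, c(1.0, 0.5, 0.4), c(0.2, 0.19, 0.18))
  expect_equal(s1$selected_k, 1)
  ## nothing qualifies: fall back to max stability, flagged
  s2 <- select_k(2:4, c(0.5, 0.7, 0.6), c(1, 0.99, 0.98))
  expect_equal(s2$selected_k, 3)
  expect_true(s2$flagged)
})

test_that("consolidation merges shared signatures and is order-invariant", {
  A <- unit_signature("het:2:>40Mb")
  B <- unit_signature("loh:1:0-100kb")
  C <- unit_signature("het:9+:1Mb-10Mb")
  ## two identical sets: clusters = original signatures at cosine 1
  cons <- consolidate(list(cbind(A, B), cbind(A, B)))
  expect_equal(ncol(cons), 2)
  expect_true(all(best_match_cosines(cons, cbind(A, B)) == 1))
  ## {A,B} + {A,C} with B orthogonal to C: three clusters {A,A},{B},{C}
  cons2 <- consolidate(list(cbind(A, B), cbind(A, C)))
  expect_equal(ncol(cons2), 3)
  expect_true(all(best_match_cosines(cons2, cbind(A, B, C)) == 1))
  ## permutation invariance in input order
  cons3 <- consolidate(list(cbind(A, C), cbind(A, B)))
  expect_equal(ncol(cons3), 3)
  expect_true(all(best_match_cosines(cons3, cons2) == 1))
  ## single set: identity
  single <- consolidate(cbind(A, B))
  expect_true(all(best_match_cosines(single, cbind(A, B)) == 1))
})

test_that("linear-combination pruning removes exactly the dependent signature", {
  sigs <- archetype_signatures()
  ## mutually near-orthogonal archetypes: nothing removed
  kept <- prune_linear_combinations(sigs, n_resamples = 20, seed = 51)
  expect_equal(colnames(kept), colnames(sigs))
  ## exact linear combination is removed
  lc <- 0.5 * sigs[, "dip"] + 0.5 * sigs[, "cin"]
  with_lc <- cbind(sigs[, c("dip", "cin")], lc = lc)
  kept2 <- prune_linear_combinations(with_lc, n_resamples = 20, seed = 52)
  expect_setequal(colnames(kept2), c("dip", "cin"))
  ## K = 2 distinct signatures: neither removed
  kept3 <- prune_linear_combinations(sigs[, c("dip", "loh")],
                                     n_resamples = 20, seed = 53)
  expect_equal(ncol(kept3), 2)
  ## a unique channel carrier survives even when otherwise reconstructable
  carrier <- 0.94 * sigs[, "dip"] + 0.06 * unit_signature("homdel:0:0-100kb")
  with_carrier <- cbind(sigs[, c("dip", "cin")], uc = carrier)
  kept4 <- prune_linear_combinations(with_carrier, n_resamples = 20,
                                     seed = 54)
  expect_true("uc" %in% colnames(kept4))
})
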