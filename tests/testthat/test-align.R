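test_that("free-end alignment of simple matrices is exact", {
  expect_equal(nw_affine(matrix(0, 3, 3), -1, -0.1)$score, 0)
  a <- nw_affine(diag(c(1, 1)), -1, -0.1)
  expect_equal(a$score, 2)
  expect_equal(a$pairs, cbind(1:2, 1:2), ignore_attr = TRUE)
  expect_error(nw_affine(matrix(numeric(), 0, 0), -1, -0.1), "empty")
})

test_that("the DP equals the exhaustive oracle on seeded random matrices", {
  set.seed(20)
  for (t in 1:200) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    S <- matrix(rnorm(n * m), n, m)
    go <- -runif(1, 0, 2); ge <- -runif(1, 0, 0.5)
    fe <- t %% 2 == 0
    expect_equal(nw_affine(S, go, ge, free_ends = fe)$score,
                 brute_force_align(S, go, ge, free_ends = fe),
                 tolerance = 1e-9)
  }
})

test_that("recomputing the score from the traced pairs reproduces the DP score", {
  set.seed(30)
  for (t in 1:100) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    S <- matrix(rnorm(n * m), n, m)
    go <- -runif(1, 0, 2); ge <- -runif(1, 0, 0.5)
    fe <- t %% 2 == 0
    a <- nw_affine(S, go, ge, free_ends = fe)
    expect_equal(score_alignment(a$pairs, S, go, ge, free_ends = fe),
                 a$score, tolerance = 1e-9)
    if (nrow(a$pairs) > 1) {
      expect_true(all(diff(a$pairs[, 1]) > 0))
      expect_true(all(diff(a$pairs[, 2]) > 0))
    }
  }
})

test_that("global mode charges terminal gaps", {
  S <- matrix(c(1, 0, 0, 0), 2, 2)
  # free ends: align only (1,1)
  expect_equal(nw_affine(S, -1, -0.5, free_ends = TRUE)$score, 1)
  # global: all residues must be accounted for
  g <- nw_affine(S, -1, -0.5, free_ends = FALSE)
  expect_equal(g$score, brute_force_align(S, -1, -0.5, free_ends = FALSE))
})

test_that("enumerative search spends exactly sum(2^k) DP runs", {
  pr <- fixture_pair()
  a1 <- align_enumerative(pr$query, pr$tmpl, K_max = 1)
  expect_equal(a1$n_dp, 2L)
  a3 <- align_enumerative(pr$query, pr$tmpl, K_max = 3)
  expect_equal(a3$n_dp, 2L + 4L + 8L)
})

test_that("greedy search spends 2K DP runs and never beats the enumerative score", {
  pr <- fixture_pair()
  g2 <- align_greedy(pr$query, pr$tmpl, K = 2)
  expect_equal(g2$n_dp, 4L)
  g4 <- align_greedy(pr$query, pr$tmpl, K = 4)
  expect_equal(g4$n_dp, 8L)
  e4 <- align_enumerative(pr$query, pr$tmpl, K_max = 4)
  expect_lte(g4$score, e4$score + 1e-12)
  # greedy's winning mask is among the enumerated ones at K components
  expect_equal(length(unclass(g4$mask)), 4L)
})

test_that("alignment results carry consistent CMOq and coverage", {
  pr <- fixture_pair()
  a <- align_enumerative(pr$query, pr$tmpl, K_max = 3)
  expect_equal(a$cmoq,
               cmoq(pr$query$contact_map, pr$tmpl$contact_map, a))
  expect_equal(a$coverage, nrow(a$pairs) / nchar(pr$query$sequence))
  # the DP score is recomputable from the winning mask's matrix
  S <- score_matrix(pr$query, pr$tmpl, mask = a$mask, k = a$K_used)
  g <- composite_gaps(scoring_params())
  expect_equal(score_alignment(a$pairs, S, g[["g_o"]], g[["g_e"]]),
               a$score, tolerance = 1e-9)
})

test_that("with no contact term all masks coincide and greedy equals enumerative", {
  pr <- fixture_pair()
  params <- scoring_params(w1 = 0)
  e <- align_enumerative(pr$query, pr$tmpl, K_max = 3, params = params)
  g <- align_greedy(pr$query, pr$tmpl, K = 3, params = params)
  expect_equal(e$score, g$score, tolerance = 1e-12)
  expect_equal(e$pairs, g$pairs)
  # ties resolve to the smallest k and the all-positive mask
  expect_equal(e$K_used, 1L)
  expect_equal(unclass(e$mask), 1L, ignore_attr = TRUE)
  expect_equal(unclass(g$mask), rep(1L, 3), ignore_attr = TRUE)
})

test_that("the best alignment is invariant to eigen-solver sign conventions", {
  pr <- fixture_pair()
  ref <- align_enumerative(pr$query, pr$tmpl, K_max = 3)
  for (s in 1:3) {
    flip <- withr::with_seed(s, sample(c(1, -1), pr$tmpl$eigen$K,
                                       replace = TRUE))
    tm2 <- pr$tmpl
    tm2$eigen$vectors <- tm2$eigen$vectors %*% diag(flip)
    alt <- align_enumerative(pr$query, tm2, K_max = 3)
    expect_equal(alt$score, ref$score, tolerance = 1e-9)
    expect_equal(alt$pairs, ref$pairs)
  }
})
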