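test_that("the eigenvector match score handles its boundary cases", {
  expect_equal(s_cm(numeric(3), numeric(3)), 0)
  expect_equal(s_cm(c(1, 0), c(1, 0)), 1)
  expect_equal(s_cm(c(1, 0), c(2, 0)), 0.5)
  expect_equal(s_cm(numeric(0), numeric(0)), 0)
  expect_error(s_cm(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("the eigenvector match score is bounded, symmetric and flip-invariant", {
  set.seed(1)
  for (t in 1:500) {
    k <- sample(1:7, 1)
    u <- rnorm(k); v <- rnorm(k)
    s <- s_cm(u, v)
    expect_lte(abs(s), 1)
    expect_equal(s, s_cm(v, u))
    expect_equal(s, s_cm(-u, -v))
  }
  u <- rnorm(5)
  expect_equal(s_cm(u, u), 1)
})

test_that("the vectorised eigenvector score matches the scalar definition", {
  set.seed(7)
  U <- matrix(rnorm(12), 4, 3); U[2, ] <- 0
  P <- matrix(rnorm(15), 5, 3); P[4, ] <- 0
  M <- conthread:::s_cm_matrix(U, P)
  for (i in 1:4) for (j in 1:5)
    expect_equal(M[i, j], s_cm(U[i, ], P[j, ]), tolerance = 1e-12)
  # differing component counts are zero-padded
  expect_equal(conthread:::s_cm_matrix(U[, 1:2], P)[1, 1],
               s_cm(c(U[1, 1:2], 0), P[1, ]))
})

test_that("profile score is the clipped symmetrised cross score", {
  onehot <- function(k, v = 1) { x <- numeric(20); x[k] <- v; x }
  # identical one-hot rows with positive self log-odds score positively
  expect_gt(s_prof(onehot(3), onehot(3, 5), onehot(3), onehot(3, 5)), 0)
  # orthogonal one-hot rows with zero log-odds elsewhere score 0
  expect_equal(s_prof(onehot(3), onehot(3, 5), onehot(7), onehot(7, 5)), 0)
  # hand-built case evaluated independently over the 20 letters
  qf <- onehot(1, 0.6); qf[2] <- 0.4
  tl <- seq(-1, 1, length.out = 20)
  tf <- onehot(2, 1)
  ql <- rep(0.5, 20)
  manual <- 0.5 * (sum(qf * tl) + sum(tf * ql))
  expect_equal(s_prof(qf, ql, tf, tl), manual)
  # clipping
  expect_equal(s_prof(onehot(1), onehot(1, 100), onehot(1), onehot(1, 100),
                      clip = 5), 5)
})

test_that("secondary-structure score is signed query confidence", {
  expect_equal(s_ss(c(1, 0, 0), "H"), 1)
  expect_equal(s_ss(c(1, 0, 0), "E"), -1)
  expect_equal(s_ss(c(0.7, 0.2, 0.1), "H"), 0.7)
  expect_equal(s_ss(c(0.7, 0.2, 0.1), "C"), -0.7)
  qss <- sec_struct(c("H", "E"), rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1)))
  tss <- sec_struct(c("H", "C"))
  M <- conthread:::s_ss_matrix(qss, tss)
  expect_equal(M, rbind(c(0.7, -0.7), c(-0.8, -0.8)), ignore_attr = TRUE)
})

test_that("the combined score matrix reduces to its parts", {
  pr <- fixture_pair()
  params0 <- scoring_params(w1 = 0, w2 = 0, w3 = 0, w4 = 0.1)
  S <- score_matrix(pr$query, pr$tmpl, k = 2, params = params0)
  expect_true(all(S == 0.1))
  params1 <- scoring_params(w1 = 1, w2 = 0, w3 = 0, w4 = 0)
  ep <- decompose(pr$query$contact_map, 2)
  U <- profile_vectors(ep, k = 2)
  P <- profile_vectors(pr$tmpl$eigen, k = 2)
  expect_equal(score_matrix(pr$query, pr$tmpl, k = 2, params = params1),
               conthread:::s_cm_matrix(U, P), tolerance = 1e-12)
})

test_that("a tiny combined matrix matches per-cell evaluation", {
  q <- make_toy_query(toy_spec(list(c("H", 8)), seed = 2), id = "tq")
  tm <- make_toy_template(toy_spec(list(c("H", 8)), seed = 5), id = "tt")
  params <- scoring_params()
  S <- score_matrix(q, tm, k = 3, params = params)
  ep <- decompose(q$contact_map, 3)
  U <- profile_vectors(ep, k = 3)
  P <- profile_vectors(tm$eigen, k = 3)
  for (i in c(1, 4, 8)) for (j in c(2, 8)) {
    expect_equal(S[i, j],
                 params$w1 * s_cm(U[i, seq_len(min(3, ncol(U)))],
                                  P[j, seq_len(min(3, ncol(P)))]) +
                 params$w2 * s_prof(q$profile$freq[i, ], q$profile$logodds[i, ],
                                    tm$profile$freq[j, ],
                                    tm$profile$logodds[j, ]) +
                 params$w3 * s_ss(q$ss$conf[i, ], tm$ss$states[j]) +
                 params$w4,
                 tolerance = 1e-12)
  }
})

test_that("composite gap penalties combine the per-term values", {
  g <- composite_gaps(scoring_params())
  expect_equal(unname(g["g_o"]), -1.0)
  expect_equal(unname(g["g_e"]), -0.0977)
  zero <- scoring_params(gap_open = c(cm = 0, prof = 0, ss = 0),
                         gap_extend = c(cm = 0, prof = 0, ss = 0))
  expect_equal(unname(composite_gaps(zero)), c(0, 0))
  doubled <- scoring_params(w1 = 1.0, w2 = 0.8, w3 = 0.2)
  expect_equal(unname(composite_gaps(doubled)),
               2 * unname(composite_gaps(scoring_params())))
})

test_that("score matrices are bit-reproducible for fixed inputs", {
  pr <- fixture_pair()
  a <- score_matrix(pr$query, pr$tmpl, mask = c(1L, -1L, 1L), k = 3)
  b <- score_matrix(pr$query, pr$tmpl, mask = c(1L, -1L, 1L), k = 3)
  expect_identical(a, b)
})
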