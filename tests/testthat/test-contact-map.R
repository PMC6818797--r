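test_that("contact maps normalise ordering and collapse duplicates by max probability", {
  cm <- contact_map(10, i = c(9, 1, 1), j = c(1, 9, 9), p = c(0.9, 0.3, 0.5))
  expect_equal(n_contacts(cm), 1L)
  expect_equal(cm$i, 1L)
  expect_equal(cm$j, 9L)
  expect_equal(cm$p, 0.9)

  expect_error(contact_map(10, 3, 3, 0.5), "self pairs")
  expect_error(contact_map(10, 1, 11, 0.5), "out of range")
  expect_error(contact_map(10, 1, 2, 0), "probabilities")
})

test_that("native contact maps follow the strict distance cutoff", {
  mk <- function(d) residue_chain("x", c("A", "A"),
                                  rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(n_contacts(native_contact_map(mk(5.0))), 1L)
  expect_equal(n_contacts(native_contact_map(mk(9.0))), 0L)
  expect_equal(n_contacts(native_contact_map(mk(8.0))), 0L)  # strict <
})

test_that("an ideal helix produces the full (i, i+4) contact ladder", {
  s <- make_toy_structure(toy_spec(list(c("H", 10)), seed = 3))
  cm <- native_contact_map(s$chain)
  # independent brute-force distance check
  d <- as.matrix(dist(s$chain$xyz))
  for (i in 1:6) {
    expect_lt(d[i, i + 4], 8)
    expect_true(any(cm$i == i & cm$j == i + 4))
  }
})

test_that("contact selection keeps per-class quotas with deterministic ties", {
  L <- 100L
  # saturated candidate set: every pair with separation >= 5, random probs
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] >= 5, ]
  p <- withr::with_seed(11, runif(nrow(idx), 0.01, 1))
  pred <- contact_map(L, idx[, 1], idx[, 2], p)
  ss <- sec_struct(rep("C", L))
  sel <- select_contacts(pred, ss, range_quotas())
  sep <- sel$j - sel$i
  expect_equal(sum(sep >= 24), 179L)
  expect_equal(sum(sep >= 12 & sep <= 23), 41L)
  expect_equal(sum(sep <= 11), 31L)
  expect_equal(n_contacts(sel), 251L)
  # selection is a subset of the input
  expect_true(all(paste(sel$i, sel$j) %in% paste(pred$i, pred$j)))
})

test_that("under-quota classes keep all their candidates", {
  pred <- contact_map(100, i = c(1, 2, 3), j = c(7, 9, 10),
                      p = c(0.5, 0.4, 0.3))
  sel <- select_contacts(pred, sec_struct(rep("C", 100)))
  expect_equal(n_contacts(sel), 3L)
})

test_that("separation-4 pairs need five consecutive helix residues", {
  L <- 20L
  states <- rep("C", L)
  states[10:14] <- "H"
  pred <- contact_map(L, i = 10, j = 14, p = 0.9)
  expect_equal(n_contacts(select_contacts(pred, sec_struct(states))), 1L)
  states[12] <- "C"   # break the helix
  expect_equal(n_contacts(select_contacts(pred, sec_struct(states))), 0L)
  # a separation-4 pair outside any helix is never a candidate
  pred2 <- contact_map(L, i = 1, j = 5, p = 0.9)
  expect_equal(n_contacts(select_contacts(pred2, sec_struct(rep("C", L)))), 0L)
})

test_that("contact overlap counts preserved pairs under an alignment", {
  q <- contact_map(10, i = c(1, 2), j = c(6, 7), p = c(1, 1))
  t <- contact_map(10, i = 1, j = 6, p = 1)
  id_aln <- cbind(1:10, 1:10)
  expect_equal(contact_overlap(q, t, id_aln), 1L)
  expect_equal(contact_overlap(q, t, matrix(integer(), 0, 2)), 0L)
  expect_equal(contact_overlap(q, q, id_aln), n_contacts(q))
  expect_error(contact_overlap(q, t, cbind(1, 20)), "out of range")
})

test_that("overlap is monotone as an alignment is extended", {
  cm <- random_contact_map(15, 0.3, seed = 5)
  full <- cbind(1:15, 1:15)
  prev <- -1L
  for (k in 0:15) {
    o <- contact_overlap(cm, cm, full[seq_len(k), , drop = FALSE])
    expect_gte(o, prev)
    prev <- o
  }
})

test_that("CMOq is the overlap fraction of query contacts", {
  q <- contact_map(10, i = c(1, 2), j = c(6, 7), p = c(1, 1))
  t <- contact_map(10, i = 1, j = 6, p = 1)
  id_aln <- cbind(1:10, 1:10)
  expect_equal(cmoq(q, t, id_aln), 0.5)
  expect_equal(cmoq(q, q, id_aln), 1)
  disjoint <- contact_map(10, i = 3, j = 9, p = 1)
  expect_equal(cmoq(q, disjoint, id_aln), 0)
  expect_error(cmoq(contact_map(10), t, id_aln), "empty")
})

test_that("CMOacc truncates predictions to the native count", {
  native <- contact_map(20, i = 1:4, j = 7:10, p = rep(1, 4))
  expect_equal(cmoacc(native, native), 1)
  # top-4 by probability share 2 of 4 native pairs
  pred <- contact_map(20,
                      i = c(1, 2, 11, 12, 3, 4),
                      j = c(7, 8, 17, 18, 9, 10),
                      p = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  expect_equal(cmoacc(pred, native), 0.5)
  disjoint <- contact_map(20, i = 11, j = 17, p = 0.9)
  expect_equal(cmoacc(disjoint, native), 0)
  expect_error(cmoacc(pred, contact_map(20)), "empty")
})

test_that("CMO statistics stay within [0, 1] on random inputs", {
  for (s in 1:20) {
    a <- random_contact_map(12, 0.3, seed = s)
    b <- random_contact_map(12, 0.3, seed = s + 100)
    if (n_contacts(a) == 0 || n_contacts(b) == 0) next
    v <- cmoq(a, b, cbind(1:12, 1:12))
    expect_gte(v, 0); expect_lte(v, 1)
    w <- cmoacc(a, b)
    expect_gte(w, 0); expect_lte(w, 1)
  }
})
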