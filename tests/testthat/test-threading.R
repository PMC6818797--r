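test_that("Z-scores standardise to mean 0 and population SD 1", {
  expect_equal(zscores(c(0.2, 0.4)), c(-1, 1))
  expect_equal(zscores(rep(0.3, 5)), rep(0, 5))
  expect_error(zscores(0.5), "at least 2")
  x <- withr::with_seed(3, runif(40))
  z <- zscores(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
})

test_that("threading a query against a library containing its own fold ranks it first", {
  q <- fixture_query()
  hits <- thread(q, fixture_library(), m_refine = 6)
  expect_equal(hits[[1]]$template_id, "ab_fold")
  expect_equal(hits[[1]]$cmoq, 1.0)
  expect_equal(hits[[1]]$stage, "refined")
  df <- as.data.frame(hits)
  expect_equal(nrow(df), 6L)
  expect_true(all(diff(df$cmoq) <= 1e-12))
  # stage-1 Z-scores standardise over the whole library
  expect_equal(mean(df$zscore), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(df$zscore^2)), 1, tolerance = 1e-9)
})

test_that("the final top hit does not depend on library iteration order", {
  q <- fixture_query()
  lib <- fixture_library()
  rev_lib <- template_library(rev(lib$entries))
  h1 <- thread(q, lib, m_refine = 6)
  h2 <- thread(q, rev_lib, m_refine = 6)
  expect_equal(h1[[1]]$template_id, h2[[1]]$template_id)
  expect_equal(h1[[1]]$cmoq, h2[[1]]$cmoq)
  expect_equal(as.data.frame(h1)$template, as.data.frame(h2)$template)
})

test_that("refining more templates never worsens the top hit", {
  q <- fixture_query(fn_rate = 0.2, fp_rate = 0.05, noise_seed = 8)
  lib <- fixture_library()
  top_cmoq <- vapply(c(1, 3, 6), function(m)
    thread(q, lib, m_refine = m)[[1]]$cmoq, 0)
  expect_true(all(diff(top_cmoq) >= -1e-12))
})

test_that("a library no larger than m_refine reduces to pure enumerative ranking", {
  q <- fixture_query()
  lib <- fixture_library()
  hits <- thread(q, lib, m_refine = 100)
  expect_true(all(vapply(hits, `[[`, "", "stage") == "refined"))
  direct <- vapply(lib$entries, function(tm)
    align_enumerative(q, tm, K_max = 7)$cmoq, 0)
  ids <- vapply(lib$entries, `[[`, "", "id")
  want <- ids[order(-direct, ids)]
  expect_equal(as.data.frame(hits)$template, want)
})

test_that("threading rejects degenerate inputs", {
  q <- fixture_query()
  expect_error(thread(q, template_library(list())), "empty")
  q$contact_map <- contact_map(nchar(q$sequence))
  expect_error(thread(q, fixture_library()), "contact map is empty")
})

test_that("the contact restraint energy matches its branch anchors", {
  expect_equal(e_con(5, 1), -1)
  expect_equal(e_con(12, 1, D = 16), -0.5)
  expect_equal(e_con(100, 0.7), 0.7)
})

test_that("the contact restraint energy is continuous and monotone", {
  for (u in c(0.1, 1.0)) {
    for (b in c(8, 16, 80)) {
      eps <- 1e-9
      expect_equal(e_con(b - eps, u, D = 16), e_con(b + eps, u, D = 16),
                   tolerance = 1e-6)
    }
    d <- seq(0, 90, by = 0.01)
    v <- e_con(d, u, D = 16)
    expect_true(all(diff(v) >= -1e-12))
    expect_true(all(v >= -u - 1e-12 & v <= u + 1e-12))
  }
})

test_that("the confidence score composes its factors multiplicatively", {
  expect_equal(c_score(M = 100, M_tot = 100, rmsd_avg = 1, z1 = 6.8,
                       overlap = 0, Nq = 10), 0)
  base <- c_score(M = 100, M_tot = 200, rmsd_avg = 2, z1 = 3.4,
                  overlap = 5, Nq = 10)
  expect_equal(c_score(M = 50, M_tot = 200, rmsd_avg = 2, z1 = 3.4,
                       overlap = 5, Nq = 10), base - log(2))
  expect_error(c_score(M = 10, M_tot = 100, rmsd_avg = 1, z1 = 0,
                       overlap = 0, Nq = 10), "non-positive")
})
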