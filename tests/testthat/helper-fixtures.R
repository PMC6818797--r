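# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture_specs <- function() {
  if (is.null(.fixture_cache$specs))
    .fixture_cache$specs <- toy_fold_set()
  .fixture_cache$specs
}

fixture_library <- function() {
  if (is.null(.fixture_cache$lib))
    .fixture_cache$lib <- make_toy_library(fixture_specs())
  .fixture_cache$lib
}

fixture_query <- function(fn_rate = 0, fp_rate = 0, noise_seed = 1L) {
  make_toy_query(fixture_specs()[[1]], id = "q1",
                 fn_rate = fn_rate, fp_rate = fp_rate,
                 noise_seed = noise_seed)
}

# a small query/template pair on distinct folds
fixture_pair <- function() {
  list(query = fixture_query(),
       tmpl = fixture_library()$entries[[2]])
}

# dense random symmetric 0/1 contact map
random_contact_map <- function(L, density = 0.15, seed = 1L) {
  withr::with_seed(seed, {
    n_all <- L * (L - 1) / 2
    idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    pick <- runif(n_all) < density
    contact_map(L, idx[pick, 1], idx[pick, 2], p = rep(1, sum(pick)))
  })
}
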