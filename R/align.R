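#' Alignment result
#'
#' @param pairs 2-column integer matrix of aligned (query, template)
#'   indices, strictly increasing in both columns.
#' @param score Total dynamic-programming score.
#' @param lq,lt Query and template lengths.
#' @param mask Sign mask that produced the alignment (or `NULL`).
#' @param K_used Number of eigen components in play.
#' @param cmoq CMOq of the alignment (or `NA`).
#' @param n_dp Number of DP runs spent producing it.
#' @return A list of class `alignment_result` with a `coverage` field
#'   (aligned pairs / query length).
#' @export
alignment_result <- function(pairs, score, lq, lt, mask = NULL,
                             K_used = NA_integer_, cmoq = NA_real_,
                             n_dp = NA_integer_) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) > 1L &&
      (any(diff(pairs[, 1]) <= 0L) || any(diff(pairs[, 2]) <= 0L)))
    stop("alignment pairs must be strictly increasing in both coordinates")
  structure(list(pairs = pairs, score = score,
                 coverage = nrow(pairs) / lq, lq = as.integer(lq),
                 lt = as.integer(lt), mask = mask,
                 K_used = as.integer(K_used), cmoq = cmoq,
                 n_dp = as.integer(n_dp)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> %d pairs (coverage %.2f), score %.4f, CMOq %s\n",
    nrow(x$pairs), x$coverage,
    x$score, ifelse(is.na(x$cmoq), "NA", sprintf("%.3f", x$cmoq))))
  invisible(x)
}

#' Affine-gap Needleman-Wunsch alignment
#'
#' Maximum-score alignment of a query (rows) to a template (columns) under
#' the affine scheme where an internal gap of length `l` costs
#' `g_o + g_e * l`. With `free_ends` (the threading convention) no penalty
#' is applied to terminal gaps in either sequence, so the aligned block can
#' slide freely. Traceback is deterministic with tie order
#' diagonal > up > left.
#'
#' @param S Numeric score matrix (`Lq x Lt`), finite.
#' @param g_o,g_e Gap open/extend penalties, both `<= 0`.
#' @param free_ends Logical; default `TRUE`.
#' @return An [alignment_result()].
#' @export
nw_affine <- function(S, g_o, g_e, free_ends = TRUE) {
  S <- as.matrix(S)
  if (!length(S)) stop("empty score matrix")
  stopifnot(all(is.finite(S)), g_o <= 0, g_e <= 0)
  res <- nw_affine_cpp(S, g_o, g_e, free_ends)
  alignment_result(res$pairs, res$score, nrow(S), ncol(S), n_dp = 1L)
}

#' Recompute an alignment's score from its pairs
#'
#' Sums the pairwise scores of the aligned pairs and charges
#' `g_o + g_e * l` for every internal gap run in either sequence (and for
#' terminal gaps too when `free_ends = FALSE`). Used to check that DP
#' results are self-consistent.
#'
#' @param pairs 2-column matrix of aligned index pairs.
#' @inheritParams nw_affine
#' @return The total score as a number.
#' @export
score_alignment <- function(pairs, S, g_o, g_e, free_ends = TRUE) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  gap_cost <- function(l) if (l > 0L) g_o + g_e * l else 0
  if (!nrow(pairs)) {
    if (free_ends) return(0)
    return(gap_cost(nrow(S)) + gap_cost(ncol(S)))
  }
  total <- sum(S[pairs])
  dq <- diff(pairs[, 1]) - 1L
  dt <- diff(pairs[, 2]) - 1L
  total <- total + sum(vapply(dq, gap_cost, 0)) + sum(vapply(dt, gap_cost, 0))
  if (!free_ends) {
    total <- total + gap_cost(pairs[1, 1] - 1L) + gap_cost(pairs[1, 2] - 1L) +
      gap_cost(nrow(S) - pairs[nrow(pairs), 1]) +
      gap_cost(ncol(S) - pairs[nrow(pairs), 2])
  }
  total
}

# enumerate the 2^k sign masks in lexicographic order (+1 before -1,
# component 1 most significant), as a k x 2^k matrix of columns
enumerate_masks <- function(k) {
  if (k == 0L) return(matrix(integer(), 0L, 1L))
  m <- as.matrix(expand.grid(rep(list(c(1L, -1L)), k))[, k:1, drop = FALSE])
  t(unname(m))
}

#' Enumerative sign search
#'
#' The eigenvector sign ambiguity means the query's contact-profile vectors
#' are only defined up to a per-component global sign. This driver runs the
#' DP for every sign mask over the top-k components, cumulatively for
#' k = 1..K_max, i.e. `sum_{k=1..K_max} 2^k` DP runs (254 at K_max = 7),
#' and returns the single highest-scoring alignment. Ties are resolved
#' toward smaller k, then the lexicographically smaller mask (+1 < -1).
#'
#' @param query A `query_record`.
#' @param tmpl A `template_entry`.
#' @param K_max Largest number of components considered (default 7).
#' @param params A `scoring_params`.
#' @param free_ends Passed to [nw_affine()].
#' @return An [alignment_result()] carrying the winning `mask`, `K_used`,
#'   the CMOq against the template's native map, and `n_dp`.
#' @export
align_enumerative <- function(query, tmpl, K_max = 7L,
                              params = scoring_params(), free_ends = TRUE) {
  stopifnot(K_max >= 1L)
  q_eigen <- query_eigen(query, max(K_max, params$K))
  base <- base_score_matrix(query, tmpl, params)
  g <- composite_gaps(params)
  best <- NULL
  n_dp <- 0L
  for (k in seq_len(K_max)) {
    masks <- enumerate_masks(k)
    for (c in seq_len(ncol(masks))) {
      mask <- masks[, c]
      S <- score_matrix(query, tmpl, mask = mask, k = k, params = params,
                        base = base, q_eigen = q_eigen)
      aln <- nw_affine(S, g[["g_o"]], g[["g_e"]], free_ends)
      n_dp <- n_dp + 1L
      if (is.null(best) || aln$score > best$score) {
        best <- aln
        best$mask <- sign_mask(mask)
        best$K_used <- k
      }
    }
  }
  finish_alignment(best, query, tmpl, n_dp)
}

#' Greedy sign search
#'
#' Component signs are fixed one at a time, starting from the eigenvector
#' with the largest eigenvalue: both signs of component k are evaluated
#' with earlier components at their chosen signs and later components at
#' +1, and the sign with the higher DP score is kept (+1 on ties). Uses
#' `2 * K` DP runs; its best score never exceeds the enumerative search's.
#'
#' @param query A `query_record`.
#' @param tmpl A `template_entry`.
#' @param K Number of components (default 2, the library-scan setting).
#' @inheritParams align_enumerative
#' @return An [alignment_result()].
#' @export
align_greedy <- function(query, tmpl, K = 2L, params = scoring_params(),
                         free_ends = TRUE) {
  stopifnot(K >= 1L)
  q_eigen <- query_eigen(query, max(K, params$K))
  base <- base_score_matrix(query, tmpl, params)
  g <- composite_gaps(params)
  mask <- rep(1L, K)
  best <- NULL
  n_dp <- 0L
  run <- function(mask) {
    S <- score_matrix(query, tmpl, mask = mask, k = K, params = params,
                      base = base, q_eigen = q_eigen)
    nw_affine(S, g[["g_o"]], g[["g_e"]], free_ends)
  }
  for (k in seq_len(K)) {
    mask[k] <- 1L
    plus <- run(mask)
    mask[k] <- -1L
    minus <- run(mask)
    n_dp <- n_dp + 2L
    if (plus$score >= minus$score) {   # tie keeps +1
      mask[k] <- 1L
      best <- plus
    } else {
      best <- minus
    }
  }
  best$mask <- sign_mask(mask)
  best$K_used <- K
  finish_alignment(best, query, tmpl, n_dp)
}

finish_alignment <- function(aln, query, tmpl, n_dp) {
  aln$n_dp <- as.integer(n_dp)
  aln$cmoq <- if (n_contacts(query$contact_map))
    cmoq(query$contact_map, tmpl$contact_map, aln) else NA_real_
  aln
}
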