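#' Two-stage template search
#'
#' Stage 1 scans the whole library with the cheap greedy sign search at a
#' small `k_greedy` (default 2) and ranks every template by CMOq; Z-scores
#' are standardised over this full population. Stage 2 re-aligns the top
#' `m_refine` templates (default 1000) with the enumerative search at a
#' cumulative `k_enum` (default 7) components and re-ranks them by the
#' refined CMOq. Templates outside the refined set keep their stage-1
#' records below all refined ones.
#'
#' @param query A `query_record` with a non-empty selected contact map.
#' @param library A `template_library` or plain list of `template_entry`.
#' @param params A `scoring_params`.
#' @param k_greedy,k_enum,m_refine Search configuration.
#' @param free_ends Alignment end-gap convention (default free).
#' @return A `threading_hits` object: a list of hits, each with
#'   `template_id`, `cmoq`, `zscore` (stage-1), `alignment` and `stage`;
#'   sorted best first. Has an `as.data.frame` method.
#' @export
thread <- function(query, library, params = scoring_params(),
                   k_greedy = 2L, k_enum = 7L, m_refine = 1000L,
                   free_ends = TRUE) {
  entries <- library_entries(library)
  if (!length(entries)) stop("template library is empty")
  if (n_contacts(query$contact_map) == 0L)
    stop("query contact map is empty; nothing to thread with")
  ids <- vapply(entries, `[[`, "", "id")

  stage1 <- lapply(entries, function(tm)
    align_greedy(query, tm, K = k_greedy, params = params,
                 free_ends = free_ends))
  cmoq1 <- vapply(stage1, `[[`, 0, "cmoq")
  z <- if (length(cmoq1) >= 2L) zscores(cmoq1) else rep(0, length(cmoq1))

  # order templates by iteration-order-independent keys
  ord1 <- order(-cmoq1, ids)
  refine <- utils::head(ord1, min(m_refine, length(entries)))

  hits <- vector("list", length(entries))
  for (idx in refine) {
    aln <- align_enumerative(query, entries[[idx]], K_max = k_enum,
                             params = params, free_ends = free_ends)
    hits[[idx]] <- list(template_id = ids[idx], cmoq = aln$cmoq,
                        zscore = z[idx], alignment = aln, stage = "refined")
  }
  for (idx in setdiff(seq_along(entries), refine)) {
    hits[[idx]] <- list(template_id = ids[idx], cmoq = cmoq1[idx],
                        zscore = z[idx], alignment = stage1[[idx]],
                        stage = "greedy")
  }
  refined <- vapply(hits, function(h) h$stage == "refined", TRUE)
  key_cmoq <- vapply(hits, `[[`, 0, "cmoq")
  ord <- order(!refined, -key_cmoq, ids)   # refined block first
  structure(hits[ord], class = "threading_hits",
            n_templates = length(entries))
}

library_entries <- function(library) {
  if (inherits(library, "template_library")) library$entries
  else if (is.list(library)) library
  else stop("expected a template_library or a list of template entries")
}

#' @export
print.threading_hits <- function(x, n = 10L, ...) {
  cat(sprintf("<threading_hits> %d templates ranked; top %d:\n",
              length(x), min(n, length(x))))
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' @export
as.data.frame.threading_hits <- function(x, ...) {
  data.frame(template = vapply(x, `[[`, "", "template_id"),
             cmoq = vapply(x, `[[`, 0, "cmoq"),
             zscore = vapply(x, `[[`, 0, "zscore"),
             coverage = vapply(x, function(h) h$alignment$coverage, 0),
             score = vapply(x, function(h) h$alignment$score, 0),
             stage = vapply(x, `[[`, "", "stage"),
             row.names = NULL)
}

#' Population Z-scores of CMOq values
#'
#' `z_i = (x_i - mean(x)) / sd_pop(x)` with the population (divide-by-n)
#' standard deviation; a degenerate all-equal input yields all zeros.
#'
#' @param values Numeric vector of at least 2 CMOq values.
#' @return Numeric vector of Z-scores (mean 0, population SD 1 when
#'   non-degenerate).
#' @export
zscores <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to standardise")
  mu <- mean(values)
  sd_pop <- sqrt(mean((values - mu)^2))
  if (sd_pop == 0) return(rep(0, length(values)))
  (values - mu) / sd_pop
}

#' Contact restraint energy
#'
#' Piecewise smooth pseudo-energy rewarding a predicted contact `(i, j)`
#' with probability `u` when the model's C-beta distance `d` is short:
#' `-u` below 8 A, rising through two midpoint-centred sine ramps to `+u`
#' above 80 A, with crossover parameter `D` (default 16 A). Continuous at
#' all three branch boundaries and non-decreasing in `d`.
#'
#' @param d C-beta-C-beta distance(s) in Angstrom (vectorised).
#' @param u Contact probability in \[0, 1\].
#' @param D Crossover distance in Angstrom (8 < D < 80).
#' @return Energy value(s), in units of `u`.
#' @export
e_con <- function(d, u, D = 16) {
  stopifnot(u >= 0, u <= 1, D > 8, D < 80, all(d >= 0))
  mid1 <- (8 + D) / 2
  mid2 <- (D + 80) / 2
  out <- numeric(length(d))
  b1 <- d < 8
  b2 <- d >= 8 & d < D
  b3 <- d >= D & d <= 80
  b4 <- d > 80
  out[b1] <- -u
  out[b2] <- -0.5 * u * (1 - sin((d[b2] - mid1) / (D - 8) * pi))
  out[b3] <-  0.5 * u * (1 + sin((d[b3] - mid2) / (80 - D) * pi))
  out[b4] <- u
  out
}

#' Model confidence score (C-score)
#'
#' `C = ln( (M / M_tot) * (1 / rmsd_avg) * (z1 / Z0 + overlap / Nq) )`,
#' combining decoy-cluster density, cluster tightness, the top template's
#' Z-score relative to the good-template cutoff `Z0`, and the
#' probability-weighted overlap between the query's predicted contacts and
#' the model's contacts.
#'
#' @param M Decoys in the chosen cluster (`0 < M <= M_tot`).
#' @param M_tot Total decoys clustered.
#' @param rmsd_avg Average RMSD of cluster decoys to the centroid, in
#'   Angstrom (> 0).
#' @param z1 Highest template Z-score.
#' @param overlap Sum of predicted-contact probabilities over contacts
#'   shared by query and model.
#' @param Nq Number of query contacts used (> 0).
#' @param Z0 Z-score cutoff separating good from bad templates
#'   (default 6.8).
#' @return The confidence score (a log, unbounded).
#' @export
c_score <- function(M, M_tot, rmsd_avg, z1, overlap, Nq, Z0 = 6.8) {
  stopifnot(M > 0, M <= M_tot, rmsd_avg > 0, Nq > 0, Z0 > 0)
  arg <- (M / M_tot) * (1 / rmsd_avg) * (z1 / Z0 + overlap / Nq)
  if (arg <= 0) stop("C-score undefined: log argument is non-positive")
  log(arg)
}
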