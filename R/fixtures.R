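# Deterministic synthetic structures, noisy contact maps and brute-force
# oracles. Everything here is synthetic test scaffolding: idealised
# secondary-structure geometry packed into a crude fold, good enough to
# produce realistic contact topologies (helical i,i+4 ladders, cross-strand
# and cross-segment contacts) without any external data.

# run expr with a locally seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic toy protein
#'
#' @param topology List of segments, each a pair `(type, length)` with type
#'   `"H"` (helix), `"E"` (strand) or `"C"` (loop), e.g.
#'   `list(c("H", 10), c("C", 3), c("E", 6))`.
#' @param seed Integer seed fixing the loop jitter and the sequence.
#' @param helix_rise,helix_twist,helix_radius Helix geometry: rise per
#'   residue (A), twist per residue (degrees), C-beta radius (A).
#' @param strand_rise Strand rise per residue (A).
#' @param strand_gap,helix_gap Packing distance between adjacent
#'   strand-strand / other segment axes (A).
#' @return A list of class `toy_spec`.
#' @export
toy_spec <- function(topology, seed = 1L, helix_rise = 1.5,
                     helix_twist = 100, helix_radius = 3.0,
                     strand_rise = 3.4, strand_gap = 4.8, helix_gap = 9.0) {
  segs <- lapply(topology, function(s) {
    list(type = as.character(s[[1]]), len = as.integer(s[[2]]))
  })
  types <- vapply(segs, `[[`, "", "type")
  lens <- vapply(segs, `[[`, 0L, "len")
  stopifnot(all(types %in% SS_STATES), all(lens >= 1L), sum(lens) >= 2L)
  structure(list(segments = segs, seed = as.integer(seed),
                 helix_rise = helix_rise, helix_twist = helix_twist,
                 helix_radius = helix_radius, strand_rise = strand_rise,
                 strand_gap = strand_gap, helix_gap = helix_gap),
            class = "toy_spec")
}

#' Build a synthetic structure from a toy specification
#'
#' Helix and strand segments are generated with ideal local geometry and
#' packed side by side with alternating chain direction (an idealised
#' hairpin/bundle arrangement), which produces helical (i, i+4) ladders,
#' cross-strand pairs and inter-segment tertiary contacts. Loop segments
#' are interpolated between their flanking segments with small seeded
#' jitter. Deterministic for a given spec.
#'
#' @param spec A [toy_spec()].
#' @param id Chain identifier for the result.
#' @return A list with elements `chain` (a `residue_chain`, anchors playing
#'   the C-beta role), `ss` (the designed `sec_struct`) and `sequence`.
#' @export
make_toy_structure <- function(spec, id = "toy") {
  segs <- spec$segments
  n_seg <- length(segs)
  types <- vapply(segs, `[[`, "", "type")
  lens <- vapply(segs, `[[`, 0L, "len")
  L <- sum(lens)
  coords <- vector("list", n_seg)

  core <- which(types != "C")
  x <- 0; z_end <- 0; dirz <- 1; prev_type <- NULL
  for (ci in core) {
    ty <- types[ci]; n <- lens[ci]
    if (!is.null(prev_type)) {
      gap <- if (ty == "E" && prev_type == "E") spec$strand_gap
             else spec$helix_gap
      x <- x + gap
      dirz <- -dirz
    }
    zs <- z_end + dirz * (seq_len(n) - 1) *
      (if (ty == "H") spec$helix_rise else spec$strand_rise)
    if (ty == "H") {
      th <- (seq_len(n) - 1) * spec$helix_twist * pi / 180
      xyz <- cbind(x + spec$helix_radius * cos(th),
                   spec$helix_radius * sin(th), zs)
    } else {
      xyz <- cbind(rep(x, n), 0.4 * (-1)^(seq_len(n)), zs)
    }
    coords[[ci]] <- xyz
    z_end <- zs[n]
    prev_type <- ty
  }

  with_local_seed(spec$seed, {
    for (ci in which(types == "C")) {
      n <- lens[ci]
      from <- if (ci > 1L && !is.null(coords[[ci - 1L]]))
        coords[[ci - 1L]][lens[ci - 1L], ] else NULL
      to <- if (ci < n_seg && !is.null(coords[[ci + 1L]]))
        coords[[ci + 1L]][1L, ] else NULL
      xyz <- if (!is.null(from) && !is.null(to)) {
        t <- seq_len(n) / (n + 1)
        outer(1 - t, from) + outer(t, to)
      } else if (!is.null(from)) {        # C-terminal tail
        step <- from - coords[[ci - 1L]][max(1L, lens[ci - 1L] - 1L), ]
        if (all(step == 0)) step <- c(0, 0, 3.4)
        from + outer(seq_len(n), 3.4 * step / sqrt(sum(step^2)))
      } else {                            # N-terminal tail
        step <- coords[[ci + 1L]][min(2L, lens[ci + 1L]), ] - to
        if (all(step == 0)) step <- c(0, 0, 3.4)
        to - outer(rev(seq_len(n)), 3.4 * step / sqrt(sum(step^2)))
      }
      coords[[ci]] <- xyz + matrix(stats::runif(3 * n, -0.4, 0.4), n, 3)
    }
    seq_aa <- sample(AA_ORDER, L, replace = TRUE)
    xyz <- do.call(rbind, coords)
    states <- rep(types, lens)
    list(chain = residue_chain(id, seq_aa, xyz),
         ss = sec_struct(states),
         sequence = paste(seq_aa, collapse = ""))
  })
}

#' Synthetic profile for a known sequence
#'
#' A sharply peaked stand-in for a real PSSM: the true residue gets
#' log-odds `self_lo` and frequency `self_freq`, all others share the
#' remainder. Deterministic.
#'
#' @param sequence Amino-acid sequence (string or letter vector).
#' @param self_lo Log-odds for the true residue (default 5).
#' @param other_lo Log-odds elsewhere (default -1).
#' @param self_freq Frequency mass on the true residue (default 0.85).
#' @return A `profile_matrix`.
#' @export
make_toy_profile <- function(sequence, self_lo = 5, other_lo = -1,
                             self_freq = 0.85) {
  aa <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  L <- length(aa)
  idx <- match(aa, AA_ORDER)
  if (anyNA(idx)) stop("sequence contains non-standard residues")
  lo <- matrix(other_lo, L, 20L)
  fr <- matrix((1 - self_freq) / 19, L, 20L)
  lo[cbind(seq_len(L), idx)] <- self_lo
  fr[cbind(seq_len(L), idx)] <- self_freq
  profile_matrix(lo, fr, aa = aa)
}

#' Perturb a contact map with false negatives and false positives
#'
#' Emulates an imperfect predicted map: each true contact survives with
#' probability `1 - fn_rate` and gets a high confidence (uniform on
#' 0.6..1); each non-contact with separation >= 5 is added with probability
#' `fp_rate` at a low confidence (uniform on 0.05..0.5), so true contacts
#' rank higher on average. `fn_rate = fp_rate = 0` returns the input
#' unchanged. Deterministic per seed; only independent noise is modelled,
#' not the spatially correlated error structure of real predictors.
#'
#' @param cm A `contact_map` (typically native).
#' @param fn_rate,fp_rate Rates in \[0, 1).
#' @param seed Integer seed.
#' @return A perturbed `contact_map`.
#' @export
perturb_contact_map <- function(cm, fn_rate, fp_rate, seed = 1L) {
  stopifnot(fn_rate >= 0, fn_rate < 1, fp_rate >= 0, fp_rate < 1)
  if (fn_rate == 0 && fp_rate == 0) return(cm)
  L <- cm$length
  with_local_seed(seed, {
    keep <- stats::runif(n_contacts(cm)) >= fn_rate
    i <- cm$i[keep]; j <- cm$j[keep]
    p <- stats::runif(length(i), 0.6, 1)
    if (fp_rate > 0 && L >= 6L) {
      counts <- (L - 5L):1L                         # pairs per separation
      all_i <- sequence(counts)                     # all pairs with j-i >= 5
      all_j <- all_i + rep(5L:(L - 1L), counts)
      cand <- !(paste(all_i, all_j) %in% paste(cm$i, cm$j))
      add <- cand & stats::runif(length(all_i)) < fp_rate
      i <- c(i, all_i[add]); j <- c(j, all_j[add])
      p <- c(p, stats::runif(sum(add), 0.05, 0.5))
    }
    contact_map(L, i, j, p)
  })
}

#' Exhaustive alignment oracle
#'
#' Maximises over every monotone one-to-one pairing of query and template
#' residues, charging `g_o + g_e * l` per internal gap run (and per
#' terminal gap when `free_ends = FALSE`). Implemented as a memoised
#' recursion over successor pairs, equivalent to scoring every alignment;
#' independent of the Gotoh machinery and feasible only for tiny matrices.
#'
#' @param S Score matrix with both dimensions at most 8.
#' @inheritParams nw_affine
#' @return The optimal score (a number).
#' @export
brute_force_align <- function(S, g_o, g_e, free_ends = TRUE) {
  S <- as.matrix(S)
  n <- nrow(S); m <- ncol(S)
  if (n > 8L || m > 8L) stop("oracle limited to 8x8 score matrices")
  gap <- function(l, terminal) {
    if (l <= 0L) return(0)
    if (terminal && free_ends) 0 else g_o + g_e * l
  }
  memo <- new.env(hash = TRUE)
  # best total over alignments whose previous pair was (i0, j0);
  # includes the option of stopping (trailing gaps)
  rest <- function(i0, j0) {
    key <- paste(i0, j0)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- gap(n - i0, TRUE) + gap(m - j0, TRUE)   # stop here
    if (i0 < n && j0 < m) {
      for (i in (i0 + 1L):n) for (j in (j0 + 1L):m) {
        internal <- gap(i - i0 - 1L, FALSE) + gap(j - j0 - 1L, FALSE)
        v <- internal + S[i, j] + rest(i, j)
        if (v > best) best <- v
      }
    }
    memo[[key]] <- best
    best
  }
  # leading gaps before the first pair (i, j) are terminal
  best <- gap(n, TRUE) + gap(m, TRUE)               # empty alignment
  for (i in seq_len(n)) for (j in seq_len(m)) {
    v <- gap(i - 1L, TRUE) + gap(j - 1L, TRUE) + S[i, j] + rest(i, j)
    if (v > best) best <- v
  }
  best
}

#' Assemble a toy query record
#'
#' Builds the toy structure, derives its native contact map, optionally
#' perturbs it with [perturb_contact_map()], and applies the standard
#' contact selection so the record looks exactly like one assembled from
#' real prediction files.
#'
#' @param spec A [toy_spec()].
#' @param id Record identifier.
#' @param fn_rate,fp_rate Contact-map noise rates.
#' @param noise_seed Seed for the perturbation (defaults to `spec$seed`).
#' @param quotas Selection quotas, see [select_contacts()].
#' @param cutoff Contact distance cutoff in Angstrom.
#' @return A `query_record` (with the precomputed `eigen` slot unset; it is
#'   computed on demand during alignment).
#' @export
make_toy_query <- function(spec, id = "query", fn_rate = 0, fp_rate = 0,
                           noise_seed = spec$seed, quotas = range_quotas(),
                           cutoff = 8) {
  s <- make_toy_structure(spec, id)
  cm <- native_contact_map(s$chain, cutoff)
  cm <- perturb_contact_map(cm, fn_rate, fp_rate, noise_seed)
  sel <- select_contacts(cm, s$ss, quotas)
  query_record(id, s$sequence, make_toy_profile(s$sequence), s$ss, sel)
}

#' Assemble a toy template entry
#'
#' @inheritParams make_toy_query
#' @param K Eigen components precomputed for the library entry.
#' @return A `template_entry`.
#' @export
make_toy_template <- function(spec, id = "tmpl", K = 7L, cutoff = 8) {
  s <- make_toy_structure(spec, id)
  template_entry(id, s$chain, make_toy_profile(s$sequence), s$ss,
                 K = K, cutoff = cutoff)
}

#' Standard set of toy fold topologies
#'
#' Six distinct small folds (helix bundles, beta meanders/hairpins and
#' mixed alpha/beta) used throughout the test fixtures. The first topology
#' is the default query fold.
#'
#' @param seed Base seed; topology k uses `seed + k`.
#' @return A named list of [toy_spec()] objects.
#' @export
toy_fold_set <- function(seed = 100L) {
  topo <- list(
    ab_fold  = list(c("C", 2), c("H", 12), c("C", 3), c("E", 6), c("C", 2),
                    c("E", 6), c("C", 3), c("H", 10), c("C", 2)),
    bundle3  = list(c("H", 12), c("C", 3), c("H", 12), c("C", 3), c("H", 12)),
    meander4 = list(c("E", 6), c("C", 2), c("E", 6), c("C", 2), c("E", 6),
                    c("C", 2), c("E", 6)),
    hairpin_h = list(c("C", 2), c("E", 7), c("C", 2), c("E", 7), c("C", 3),
                     c("H", 14), c("C", 2)),
    bundle2  = list(c("C", 3), c("H", 16), c("C", 4), c("H", 16), c("C", 3)),
    mixed_eh = list(c("E", 5), c("C", 2), c("H", 10), c("C", 2), c("E", 5),
                    c("C", 2), c("H", 8))
  )
  out <- lapply(seq_along(topo), function(k)
    toy_spec(topo[[k]], seed = seed + k))
  names(out) <- names(topo)
  out
}

#' Toy template library
#'
#' @param specs List of [toy_spec()] objects (default [toy_fold_set()]).
#' @param K Eigen components per entry.
#' @param cutoff Contact cutoff in Angstrom.
#' @return A `template_library` holding one entry per spec.
#' @export
make_toy_library <- function(specs = toy_fold_set(), K = 7L, cutoff = 8) {
  ids <- names(specs)
  if (is.null(ids)) ids <- sprintf("toy%02d", seq_along(specs))
  entries <- Map(function(sp, id) make_toy_template(sp, id, K, cutoff),
                 specs, ids)
  template_library(unname(entries))
}
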