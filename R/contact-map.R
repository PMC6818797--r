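#' Residue-residue contact map
#'
#' A contact map over a chain of `length` residues is a symmetric set of
#' residue pairs, stored once with `i < j`, each carrying a probability in
#' (0, 1]. Native maps (derived from coordinates) carry probability 1 for
#' every contact; predicted maps carry the predictor's confidence.
#'
#' @param length Number of residues in the chain (>= 1).
#' @param i,j Integer vectors of paired residue indices (1-based). Pairs are
#'   normalised so that `i < j`; self pairs are an error.
#' @param p Numeric vector of contact probabilities in (0, 1]. Duplicate
#'   pairs are collapsed keeping the maximum probability.
#' @return An object of class `contact_map`: a list with elements `length`,
#'   `i`, `j`, `p`, sorted by `(i, j)`.
#' @export
contact_map <- function(length, i = integer(), j = integer(), p = numeric()) {
  stopifnot(length >= 1L, base::length(i) == base::length(j),
            base::length(i) == base::length(p))
  i <- as.integer(i); j <- as.integer(j); p <- as.numeric(p)
  if (any(i == j)) stop("contact map contains self pairs")
  if (base::length(i) &&
      (min(i, j) < 1L || max(i, j) > length))
    stop("contact index out of range [1, ", length, "]")
  if (any(p <= 0 | p > 1)) stop("contact probabilities must lie in (0, 1]")
  swap <- i > j
  if (any(swap)) {
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  if (base::length(i)) {
    # collapse duplicates, keeping the highest probability
    key <- paste(i, j)
    ord <- order(key, -p)
    keep <- !duplicated(key[ord])
    sel <- ord[keep]
    i <- i[sel]; j <- j[sel]; p <- p[sel]
    ord2 <- order(i, j)
    i <- i[ord2]; j <- j[ord2]; p <- p[ord2]
  }
  structure(list(length = as.integer(length), i = i, j = j, p = p),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> L = %d, %d contacts\n", x$length, n_contacts(x)))
  invisible(x)
}

#' Number of contacts in a map
#' @param cm A `contact_map`.
#' @return Integer count of stored pairs.
#' @export
n_contacts <- function(cm) length(cm$i)

#' Dense matrix view of a contact map
#'
#' @param x A `contact_map`.
#' @param value `"binary"` (default) marks contacts as 1 as in the
#'   eigen-decomposition model; `"prob"` fills in the stored probabilities.
#' @param ... Unused.
#' @return A symmetric `L x L` matrix with zero diagonal.
#' @export
as.matrix.contact_map <- function(x, value = c("binary", "prob"), ...) {
  value <- match.arg(value)
  m <- matrix(0, x$length, x$length)
  v <- if (value == "binary") rep(1, n_contacts(x)) else x$p
  m[cbind(x$i, x$j)] <- v
  m[cbind(x$j, x$i)] <- v
  m
}

pair_keys <- function(cm) cm$i * (cm$length + 1) + cm$j

#' Native contact map from coordinates
#'
#' Marks residue pairs whose anchor atoms (C-beta, falling back to C-alpha
#' for glycine or missing side chains) lie closer than `cutoff` Angstrom.
#' All native contacts get probability 1.
#'
#' @param chain A `residue_chain`.
#' @param cutoff Distance cutoff in Angstrom; contacts are strict `< cutoff`
#'   (default 8).
#' @return A `contact_map` of the same length as the chain.
#' @export
native_contact_map <- function(chain, cutoff = 8) {
  stopifnot(inherits(chain, "residue_chain"), cutoff > 0)
  n <- chain_length(chain)
  if (n == 0L) stop("empty chain")
  d <- as.matrix(stats::dist(chain$xyz))
  idx <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  contact_map(n, i = idx[, 1], j = idx[, 2], p = rep(1, nrow(idx)))
}

#' Per-range selection quotas
#'
#' Dimensionless multipliers of the query length controlling how many
#' predicted contacts are retained in each sequence-separation class
#' (long `|i-j| >= 24`, medium `12..23`, short `<= 11`). Defaults were
#' fitted to maximise alignment quality and sum to 2.51.
#'
#' @param sigma_long,sigma_med,sigma_short Non-negative multipliers.
#' @return A list of class `range_quotas`.
#' @export
range_quotas <- function(sigma_long = 1.79, sigma_med = 0.41,
                         sigma_short = 0.31) {
  stopifnot(sigma_long >= 0, sigma_med >= 0, sigma_short >= 0)
  structure(list(sigma_long = sigma_long, sigma_med = sigma_med,
                 sigma_short = sigma_short), class = "range_quotas")
}

round_half_up <- function(x) floor(x + 0.5)

separation_class <- function(sep) {
  ifelse(sep >= 24L, "long", ifelse(sep >= 12L, "med", "short"))
}

#' Select predicted contacts for threading
#'
#' Candidate pairs are those with sequence separation `|i - j| >= 5`, plus
#' separation-4 pairs whose five residues all lie in one contiguous helix
#' (these support helix register alignment). Candidates are partitioned into
#' long- (`>= 24`), medium- (`12..23`) and short-range (`<= 11`) classes and
#' the top `round(sigma_class * L)` by probability are kept per class;
#' a class with fewer candidates than its quota keeps them all.
#'
#' Probability ties at the quota boundary are broken deterministically by
#' smaller `i`, then smaller `j`.
#'
#' @param predicted A `contact_map` of predicted contacts with confidences.
#' @param ss A `sec_struct` of the same length (used for the helix rule).
#' @param quotas A `range_quotas` object.
#' @return A `contact_map` holding the selected subset.
#' @export
select_contacts <- function(predicted, ss, quotas = range_quotas()) {
  stopifnot(inherits(predicted, "contact_map"), inherits(ss, "sec_struct"))
  if (predicted$length != ss_length(ss))
    stop("contact map and secondary structure lengths differ (",
         predicted$length, " vs ", ss_length(ss), ")")
  L <- predicted$length
  sep <- predicted$j - predicted$i
  helix4 <- sep == 4L & same_helix_run(ss, predicted$i)
  keep <- sep >= 5L | helix4
  i <- predicted$i[keep]; j <- predicted$j[keep]; p <- predicted$p[keep]
  cls <- separation_class(j - i)
  quota <- c(long  = round_half_up(quotas$sigma_long  * L),
             med   = round_half_up(quotas$sigma_med   * L),
             short = round_half_up(quotas$sigma_short * L))
  sel <- logical(length(i))
  for (cl in names(quota)) {
    in_cl <- which(cls == cl)
    if (!length(in_cl)) next
    ord <- in_cl[order(-p[in_cl], i[in_cl], j[in_cl])]
    sel[utils::head(ord, quota[[cl]])] <- TRUE
  }
  contact_map(L, i[sel], j[sel], p[sel])
}

# TRUE for each start index i when residues i..i+4 are all H and belong to
# one maximal run of consecutive H states
same_helix_run <- function(ss, starts) {
  h <- ss$states == "H"
  vapply(starts, function(i) {
    if (i + 4L > length(h)) return(FALSE)
    all(h[i:(i + 4L)])
  }, logical(1))
}

#' Contact overlap under an alignment
#'
#' Counts query contacts `(i, j)` whose endpoints are both aligned and map
#' onto a template contact `(aln(i), aln(j))`.
#'
#' @param q Query `contact_map`.
#' @param t Template `contact_map`.
#' @param aln An `alignment_result` (or a 2-column matrix of
#'   query/template index pairs).
#' @return Integer overlap count.
#' @export
contact_overlap <- function(q, t, aln) {
  pairs <- alignment_pairs(aln)
  if (!nrow(pairs)) return(0L)
  if (min(pairs[, 1]) < 1L || max(pairs[, 1]) > q$length ||
      min(pairs[, 2]) < 1L || max(pairs[, 2]) > t$length)
    stop("alignment indices out of range")
  map <- rep(NA_integer_, q$length)
  map[pairs[, 1]] <- pairs[, 2]
  ti <- map[q$i]; tj <- map[q$j]
  ok <- !is.na(ti) & !is.na(tj)
  if (!any(ok)) return(0L)
  a <- pmin(ti[ok], tj[ok]); b <- pmax(ti[ok], tj[ok])
  tkeys <- pair_keys(t)
  sum((a * (t$length + 1) + b) %in% tkeys)
}

alignment_pairs <- function(aln) {
  if (inherits(aln, "alignment_result")) aln$pairs
  else if (is.matrix(aln) && ncol(aln) == 2L) {
    storage.mode(aln) <- "integer"; aln
  } else stop("expected an alignment_result or a 2-column index matrix")
}

#' CMOq: fraction of query contacts preserved by an alignment
#'
#' `CMOq = O(CM_Q, CM_T) / N(CM_Q)` where the numerator is
#' [contact_overlap()] and the denominator the number of (selected) query
#' contacts. This is the statistic used to rank templates.
#'
#' @inheritParams contact_overlap
#' @return A fraction in \[0, 1\].
#' @export
cmoq <- function(q, t, aln) {
  nq <- n_contacts(q)
  if (nq == 0L) stop("CMOq undefined: query contact map is empty")
  contact_overlap(q, t, aln) / nq
}

#' CMOacc: accuracy of a predicted contact map
#'
#' The predicted map is truncated to its top `N(native)` pairs by
#' probability (ties broken by smaller `i`, then `j`) and CMOacc is the
#' fraction of those that are native contacts.
#'
#' @param pred Predicted `contact_map` with confidences.
#' @param native Native `contact_map` (non-empty).
#' @return A fraction in \[0, 1\].
#' @export
cmoacc <- function(pred, native) {
  if (pred$length != native$length)
    stop("predicted and native maps cover chains of different lengths")
  nn <- n_contacts(native)
  if (nn == 0L) stop("CMOacc undefined: native contact map is empty")
  ord <- order(-pred$p, pred$i, pred$j)
  top <- utils::head(ord, nn)
  keys <- pred$i[top] * (native$length + 1) + pred$j[top]
  sum(keys %in% pair_keys(native)) / nn
}
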