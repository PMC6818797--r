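#' Scoring parameters
#'
#' Weights and gap penalties of the combined per-residue-pair alignment
#' score `S(i,j) = w1*S_cm + w2*S_prof + w3*S_ss + w4`, where `S_cm`
#' compares contact-profile eigenvectors, `S_prof` is a profile-profile
#' score, `S_ss` a secondary-structure agreement score and `w4` a constant
#' match bonus applied to every aligned pair. Gap penalties are composed
#' per term: `g_{o,e} = w1*g_{o,e}(cm) + w2*g_{o,e}(prof) + w3*g_{o,e}(ss)`.
#'
#' Defaults: `w = (0.5, 0.4, 0.1, 0.1)`; all per-term gap opens `-1.0`;
#' per-term gap extends `-0.1` (cm, prof) and `-0.077` (ss), giving the
#' composite `(g_o, g_e) = (-1.0, -0.0977)`.
#'
#' @param w1,w2,w3,w4 Term weights.
#' @param gap_open,gap_extend Named vectors with entries `cm`, `prof`, `ss`;
#'   all entries must be `<= 0`.
#' @param eigvec_scaling `"sqrt"` or `"linear"`, see [profile_vectors()].
#' @param prof_clip Symmetric clipping bound for the profile score.
#' @param K Default number of eigen components.
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(w1 = 0.5, w2 = 0.4, w3 = 0.1, w4 = 0.1,
                           gap_open = c(cm = -1.0, prof = -1.0, ss = -1.0),
                           gap_extend = c(cm = -0.1, prof = -0.1, ss = -0.077),
                           eigvec_scaling = c("sqrt", "linear"),
                           prof_clip = 5, K = 7L) {
  eigvec_scaling <- match.arg(eigvec_scaling)
  stopifnot(is.finite(c(w1, w2, w3, w4)),
            all(c("cm", "prof", "ss") %in% names(gap_open)),
            all(c("cm", "prof", "ss") %in% names(gap_extend)),
            all(gap_open <= 0), all(gap_extend <= 0), prof_clip > 0)
  structure(list(w1 = w1, w2 = w2, w3 = w3, w4 = w4,
                 gap_open = gap_open[c("cm", "prof", "ss")],
                 gap_extend = gap_extend[c("cm", "prof", "ss")],
                 eigvec_scaling = eigvec_scaling,
                 prof_clip = prof_clip, K = as.integer(K)),
            class = "scoring_params")
}

#' Composite affine gap penalties
#'
#' @param params A `scoring_params`.
#' @return Named numeric vector `c(g_o, g_e)`, both `<= 0`; an internal gap
#'   of length `l` costs `g_o + g_e * l`.
#' @export
composite_gaps <- function(params = scoring_params()) {
  w <- c(params$w1, params$w2, params$w3)
  c(g_o = sum(w * params$gap_open), g_e = sum(w * params$gap_extend))
}

#' Contact eigenvector match score
#'
#' `S_cm(U, P) = U . P / max(|U|, |P|)^2`, or 0 when both vectors vanish.
#' Unlike a cosine it is sensitive to vector length, and unlike a raw dot
#' product it is bounded: `|S_cm| <= 1`, with equality +1 exactly when
#' `U = P != 0`.
#'
#' @param u,p Numeric contact-profile vectors of equal dimension
#'   (possibly length 0).
#' @return A score in \[-1, 1\].
#' @export
s_cm <- function(u, p) {
  if (length(u) != length(p)) stop("contact eigenvectors differ in dimension")
  d <- max(sum(u * u), sum(p * p))
  if (d == 0) return(0)
  sum(u * p) / d
}

# Vectorised S_cm over all residue pairs: U is Lq x k, P is Lt x k.
s_cm_matrix <- function(U, P) {
  if (ncol(U) != ncol(P)) {
    k <- max(ncol(U), ncol(P))
    pad <- function(m) cbind(m, matrix(0, nrow(m), k - ncol(m)))
    U <- pad(U); P <- pad(P)
  }
  num <- tcrossprod(U, P)
  nu <- rowSums(U^2); np <- rowSums(P^2)
  den <- outer(nu, np, pmax)
  out <- matrix(0, nrow(U), nrow(P))
  nz <- den > 0
  out[nz] <- num[nz] / den[nz]
  out
}

#' Profile-profile score
#'
#' Symmetrised log-odds cross score: the query's observed frequencies are
#' scored against the template's log-odds column and vice versa, averaged
#' and clipped to `[-clip, clip]`.
#'
#' @param q_freq,q_logodds Query profile row (length-20 vectors).
#' @param t_freq,t_logodds Template profile row.
#' @param clip Clipping bound (default 5).
#' @return The clipped average cross score.
#' @export
s_prof <- function(q_freq, q_logodds, t_freq, t_logodds, clip = 5) {
  stopifnot(length(q_freq) == 20L, length(t_freq) == 20L,
            length(q_logodds) == 20L, length(t_logodds) == 20L)
  x <- 0.5 * (sum(q_freq * t_logodds) + sum(t_freq * q_logodds))
  max(-clip, min(clip, x))
}

s_prof_matrix <- function(qprof, tprof, clip = 5) {
  x <- 0.5 * (qprof$freq %*% t(tprof$logodds) +
              qprof$logodds %*% t(tprof$freq))
  pmin(pmax(x, -clip), clip)
}

#' Secondary-structure agreement score
#'
#' Let `s*` be the query's most probable state and `c` its confidence.
#' The score is `+c` when the template residue has state `s*`, else `-c`.
#'
#' @param q_conf Length-3 query state probabilities in order H, E, C.
#' @param t_state Template state, one of `"H"`, `"E"`, `"C"`.
#' @return A score in \[-1, 1\].
#' @export
s_ss <- function(q_conf, t_state) {
  stopifnot(length(q_conf) == 3L, t_state %in% SS_STATES)
  k <- which.max(q_conf)
  c_i <- q_conf[[k]]
  if (SS_STATES[k] == t_state) c_i else -c_i
}

s_ss_matrix <- function(qss, tss) {
  k <- max.col(qss$conf, ties.method = "first")
  conf <- qss$conf[cbind(seq_along(k), k)]
  agree <- outer(SS_STATES[k], tss$states, "==")
  conf * (2 * agree - 1)      # +c on match, -c on mismatch, row-recycled
}

#' Combined alignment score matrix
#'
#' Computes `S(i, j) = w1*S_cm + w2*S_prof + w3*S_ss + w4` for every
#' query/template residue pair, using the top `k` eigen components under
#' the given query sign mask (the template keeps the solver orientation;
#' only relative signs matter).
#'
#' @param query A `query_record` (or list with `profile`, `ss` and an
#'   `eigen` field).
#' @param tmpl A `template_entry`.
#' @param mask Sign mask over the query's first `k` components.
#' @param k Number of eigen components to use.
#' @param params A `scoring_params`.
#' @param base Optional precomputed mask-independent part
#'   (`w2*S_prof + w3*S_ss + w4`), as returned by [base_score_matrix()];
#'   computed when `NULL`.
#' @param q_eigen Optional precomputed query `eigen_profile`.
#' @return An `Lq x Lt` numeric matrix.
#' @export
score_matrix <- function(query, tmpl, mask = rep(1L, k), k = params$K,
                         params = scoring_params(), base = NULL,
                         q_eigen = NULL) {
  if (is.null(q_eigen)) q_eigen <- query_eigen(query, params$K)
  if (is.null(base)) base <- base_score_matrix(query, tmpl, params)
  U <- profile_vectors(q_eigen, mask = mask, scaling = params$eigvec_scaling,
                       k = min(k, q_eigen$K))
  P <- profile_vectors(tmpl$eigen, scaling = params$eigvec_scaling,
                       k = min(k, tmpl$eigen$K))
  params$w1 * s_cm_matrix(U, P) + base
}

#' @rdname score_matrix
#' @export
base_score_matrix <- function(query, tmpl, params = scoring_params()) {
  params$w2 * s_prof_matrix(query$profile, tmpl$profile, params$prof_clip) +
    params$w3 * s_ss_matrix(query$ss, tmpl$ss) + params$w4
}

query_eigen <- function(query, K) {
  if (!is.null(query$eigen)) query$eigen else decompose(query$contact_map, K)
}
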