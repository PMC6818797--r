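#' Eigen-decomposition of a contact map
#'
#' The symmetric 0/1 contact matrix M is factorised as
#' `M = sum_k lambda_k V_k V_k'`. Keeping only the largest `K` positive
#' eigenvalues gives a rank-K approximation that turns the two-body contact
#' potential into per-residue profile vectors (see [profile_vectors()]).
#' Negative eigenvalues are discarded: their square roots would introduce
#' complex profile components.
#'
#' Eigenvectors are only defined up to sign. For reproducibility each
#' retained column is oriented so that its largest-magnitude component is
#' positive (ties resolved to the earliest index); the alignment search
#' later explores the remaining 2^K relative-sign ambiguity explicitly.
#'
#' @param cm A `contact_map`.
#' @param K Maximum number of components to retain (>= 1). The result holds
#'   `min(K, #positive eigenvalues)` components; an empty map yields `K = 0`.
#' @return An `eigen_profile`: list with `K`, `values` (descending, > 0) and
#'   `vectors` (`L x K`, orthonormal columns).
#' @export
decompose <- function(cm, K = 7L) {
  stopifnot(inherits(cm, "contact_map"), K >= 1L)
  M <- as.matrix(cm, value = "binary")
  e <- eigen(M, symmetric = TRUE)
  tol <- 1e-9 * max(1, abs(e$values))
  npos <- sum(e$values > tol)
  k <- min(as.integer(K), npos)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    top <- which.max(abs(vec[, c]))          # earliest index on ties
    if (vec[top, c] < 0) vec[, c] <- -vec[, c]
  }
  structure(list(K = k, values = e$values[seq_len(k)], vectors = vec,
                 length = cm$length),
            class = "eigen_profile")
}

#' @export
print.eigen_profile <- function(x, ...) {
  cat(sprintf("<eigen_profile> L = %d, K = %d", x$length, x$K))
  if (x$K) cat(sprintf(", lambda_1 = %.4g", x$values[1]))
  cat("\n")
  invisible(x)
}

#' Sign mask over eigen components
#'
#' @param bits A vector of +1/-1 entries, one per retained component.
#' @return Integer vector of class `sign_mask`.
#' @export
sign_mask <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) && !all(bits %in% c(1L, -1L)))
    stop("sign mask entries must be +1 or -1")
  structure(bits, class = "sign_mask")
}

#' Per-residue contact-profile vectors
#'
#' Component `k` of residue `i`'s profile vector is
#' `mask_k * sqrt(lambda_k) * v_{i,k}` (default `scaling = "sqrt"`), so that
#' the dot product `U_i . U_j` reproduces the rank-K reconstruction of
#' `M[i, j]` exactly. The `"linear"` scaling uses `lambda_k * v_{i,k}`
#' instead, whose dot products weight each component by `lambda_k^2`.
#'
#' @param ep An `eigen_profile`.
#' @param mask A `sign_mask` (or +1/-1 vector) of length `ep$K`; flipping a
#'   bit flips the sign of one component globally, which leaves all pairwise
#'   dot products within the same chain unchanged but changes cross-chain
#'   comparisons.
#' @param scaling `"sqrt"` (default) or `"linear"`.
#' @param k Optional truncation: use only the first `k` components.
#' @return An `L x k` numeric matrix of profile vectors (rows are residues).
#' @export
profile_vectors <- function(ep, mask = rep(1L, ep$K),
                            scaling = c("sqrt", "linear"), k = ep$K) {
  scaling <- match.arg(scaling)
  k <- min(as.integer(k), ep$K)
  mask <- as.integer(unclass(mask))
  if (length(mask) < k)
    stop("sign mask has ", length(mask), " entries but ", k, " are needed")
  mask <- mask[seq_len(k)]
  if (length(mask) && !all(mask %in% c(1L, -1L)))
    stop("sign mask entries must be +1 or -1")
  if (k == 0L) return(matrix(0, ep$length, 0L))
  scale <- if (scaling == "sqrt") sqrt(ep$values[seq_len(k)])
           else ep$values[seq_len(k)]
  ep$vectors[, seq_len(k), drop = FALSE] %*% diag(mask * scale, nrow = k)
}

#' Frobenius error of the rank-K contact-map reconstruction
#'
#' @param cm The source `contact_map`.
#' @param ep An `eigen_profile` of `cm`.
#' @return `|| M - sum_k lambda_k V_k V_k' ||_F`; non-increasing in K.
#' @export
reconstruction_error <- function(cm, ep) {
  M <- as.matrix(cm, value = "binary")
  U <- profile_vectors(ep, scaling = "sqrt")
  norm(M - tcrossprod(U), type = "F")
}
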