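# Core record types shared by the IO, scoring and threading layers.

# PSI-BLAST PSSM column order; all profile matrices use these columns.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

SS_STATES <- c("H", "E", "C")

#' Residue chain with one anchor atom per residue
#'
#' Internal residue indexing is 1-based and contiguous over the residues
#' observed in the source file; the author residue numbers (which may have
#' gaps and insertion codes) are kept in `resno`/`insert` so positions can
#' be traced back to the file.
#'
#' @param id Chain identifier.
#' @param aa Character vector of 1-letter amino-acid codes.
#' @param xyz `n x 3` matrix of anchor coordinates in Angstrom (the C-beta
#'   atom, or C-alpha for glycine / missing C-beta).
#' @param resno Author residue numbers (integer, default `1:n`).
#' @param insert Insertion codes (default empty strings).
#' @return A list of class `residue_chain`.
#' @export
residue_chain <- function(id, aa, xyz, resno = seq_along(aa),
                          insert = rep("", length(aa))) {
  xyz <- as.matrix(xyz)
  stopifnot(length(aa) >= 1L, nrow(xyz) == length(aa), ncol(xyz) == 3L,
            length(resno) == length(aa), length(insert) == length(aa),
            all(is.finite(xyz)))
  structure(list(id = as.character(id), aa = as.character(aa),
                 xyz = unname(xyz), resno = as.integer(resno),
                 insert = as.character(insert)),
            class = "residue_chain")
}

#' @export
print.residue_chain <- function(x, ...) {
  cat(sprintf("<residue_chain> %s: %d residues\n", x$id, chain_length(x)))
  invisible(x)
}

#' @rdname residue_chain
#' @param chain A `residue_chain`.
#' @export
chain_length <- function(chain) length(chain$aa)

#' Position-specific scoring matrix
#'
#' Holds both halves of the PSI-BLAST ASCII PSSM: per-residue log-odds
#' scores and observed residue frequencies. Columns follow the PSI-BLAST
#' amino-acid order (`A R N D C Q E G H I L K M F P S T W Y V`).
#'
#' @param logodds `L x 20` numeric matrix of log-odds scores.
#' @param freq `L x 20` numeric matrix of observed frequencies on \[0, 1\]
#'   (the ASCII dialect prints percentages; divide by 100 on read).
#' @param aa Optional per-residue query letters.
#' @return A list of class `profile_matrix` with a `length` field.
#' @export
profile_matrix <- function(logodds, freq, aa = NULL) {
  logodds <- as.matrix(logodds); freq <- as.matrix(freq)
  stopifnot(ncol(logodds) == 20L, ncol(freq) == 20L,
            nrow(logodds) == nrow(freq))
  if (any(freq < 0 | freq > 1)) stop("profile frequencies must lie in [0, 1]")
  colnames(logodds) <- colnames(freq) <- AA_ORDER
  structure(list(length = nrow(logodds), logodds = unname(logodds),
                 freq = unname(freq), aa = aa),
            class = "profile_matrix")
}

#' 3-state secondary structure with per-state confidences
#'
#' @param states Character vector over `{H, E, C}`.
#' @param conf Optional `L x 3` matrix of state probabilities in column
#'   order H, E, C; rows must sum to 1 (within 1e-6 after the mild
#'   renormalisation applied here). Defaults to the one-hot encoding of
#'   `states`, as when the assignment comes from a structure.
#' @return A list of class `sec_struct`.
#' @export
sec_struct <- function(states, conf = NULL) {
  states <- as.character(states)
  if (!all(states %in% SS_STATES))
    stop("secondary-structure states must be H, E or C")
  L <- length(states)
  if (is.null(conf)) {
    conf <- matrix(0, L, 3L)
    conf[cbind(seq_len(L), match(states, SS_STATES))] <- 1
  } else {
    conf <- as.matrix(conf)
    stopifnot(nrow(conf) == L, ncol(conf) == 3L, all(conf >= 0))
    rs <- rowSums(conf)
    if (any(abs(rs - 1) > 0.05))
      stop("secondary-structure confidences are not probabilities")
    conf <- conf / rs
  }
  colnames(conf) <- SS_STATES
  structure(list(states = states, conf = unname(conf)), class = "sec_struct")
}

#' @rdname sec_struct
#' @param ss A `sec_struct`.
#' @export
ss_length <- function(ss) length(ss$states)

#' Assembled query record
#'
#' @param id Query identifier.
#' @param sequence Amino-acid sequence (single string).
#' @param profile A `profile_matrix`.
#' @param ss A `sec_struct`.
#' @param contact_map The selected predicted `contact_map`
#'   (see [select_contacts()]).
#' @return A list of class `query_record`.
#' @export
query_record <- function(id, sequence, profile, ss, contact_map) {
  L <- nchar(sequence)
  if (profile$length != L || ss_length(ss) != L || contact_map$length != L)
    stop("query components disagree on sequence length")
  structure(list(id = as.character(id), sequence = sequence,
                 profile = profile, ss = ss, contact_map = contact_map),
            class = "query_record")
}

#' Template library entry
#'
#' Bundles a template's sequence, anchor coordinates, profile, secondary
#' structure, native contact map and the eigen-profile precomputed at the
#' library's configured K.
#'
#' @param id Template identifier.
#' @param chain A `residue_chain`.
#' @param profile A `profile_matrix`.
#' @param ss A `sec_struct` (assigned from coordinates if no file given).
#' @param contact_map Native `contact_map`; defaults to
#'   [native_contact_map()] of `chain` at `cutoff`.
#' @param eigen Precomputed `eigen_profile`; defaults to [decompose()] at `K`.
#' @param K,cutoff Library configuration used for the defaults.
#' @return A list of class `template_entry`.
#' @export
template_entry <- function(id, chain, profile, ss,
                           contact_map = NULL, eigen = NULL,
                           K = 7L, cutoff = 8) {
  L <- chain_length(chain)
  if (is.null(contact_map)) contact_map <- native_contact_map(chain, cutoff)
  if (is.null(eigen)) eigen <- decompose(contact_map, K)
  if (profile$length != L || ss_length(ss) != L || contact_map$length != L)
    stop("template components disagree on chain length")
  structure(list(id = as.character(id),
                 sequence = paste(chain$aa, collapse = ""),
                 chain = chain, profile = profile, ss = ss,
                 contact_map = contact_map, eigen = eigen),
            class = "template_entry")
}

#' @export
print.query_record <- function(x, ...) {
  cat(sprintf("<query_record> %s: L = %d, %d selected contacts\n",
              x$id, nchar(x$sequence), n_contacts(x$contact_map)))
  invisible(x)
}

#' @export
print.template_entry <- function(x, ...) {
  cat(sprintf("<template_entry> %s: L = %d, %d native contacts, K = %d\n",
              x$id, nchar(x$sequence), n_contacts(x$contact_map), x$eigen$K))
  invisible(x)
}
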