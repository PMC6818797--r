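#' Read a CASP RR contact-prediction file
#'
#' Accepts the 5-column dialect `i j d_low d_high prob` with optional
#' `PFRMAT`/`TARGET`/`MODEL` header lines, a free-text sequence block and a
#' trailing `END`. Pairs are normalised to `i < j`; duplicates keep the
#' maximum probability. Indices beyond `length` and probabilities outside
#' \[0, 1\] are errors (they usually indicate an off-by-one dialect bug),
#' as are probability-0 records.
#'
#' @param path Path to the RR file.
#' @param length Chain length the indices must respect.
#' @return A `contact_map`.
#' @export
read_rr_contacts <- function(path, length) {
  stopifnot(length >= 1L)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  is_rec <- vapply(toks, function(tk) {
    base::length(tk) %in% c(3L, 5L) && grepl("^[0-9]+$", tk[1]) &&
      grepl("^[0-9]+$", tk[2])
  }, logical(1))
  recs <- toks[is_rec]
  if (!base::length(recs))
    return(contact_map(length))
  i <- as.integer(vapply(recs, `[`, "", 1))
  j <- as.integer(vapply(recs, `[`, "", 2))
  p <- as.numeric(vapply(recs, function(tk) tk[base::length(tk)], ""))
  if (anyNA(p)) stop("malformed RR record in ", path)
  if (any(i < 1L | j < 1L | i > length | j > length))
    stop("RR contact index exceeds the stated length (", length, ") in ",
         path)
  if (any(p < 0 | p > 1))
    stop("RR probability outside [0, 1] in ", path)
  if (any(p == 0))
    stop("RR record with probability 0 in ", path,
         "; a zero-confidence contact carries no information")
  contact_map(length, i, j, p)
}

#' Write a contact map in the CASP RR dialect
#'
#' Emits `PFRMAT RR`, one `i j 0 8 prob` record per contact (sorted by
#' `(i, j)`), and `END`. Probabilities are printed with 6 decimals so a
#' round trip reproduces them to 1e-6.
#'
#' @param cm A `contact_map`.
#' @param path Output path.
#' @param target Optional `TARGET` header value.
#' @return `path`, invisibly.
#' @export
write_rr <- function(cm, path, target = NULL) {
  hdr <- c("PFRMAT RR",
           if (!is.null(target)) paste("TARGET", target))
  recs <- sprintf("%d %d 0 8 %.6f", cm$i, cm$j, cm$p)
  writeLines(c(hdr, recs, "END"), path)
  invisible(path)
}
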