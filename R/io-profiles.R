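#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the `-out_ascii_pssm` dialect: a header naming the 20 amino-acid
#' columns twice (log-odds, then observed percentages), followed by one row
#' per residue with index, letter, 20 integer log-odds and 20 percentages.
#' Trailing information-content columns and the footer are ignored.
#'
#' @param path Path to the PSSM file.
#' @param sequence Optional query sequence; a length mismatch is an error.
#' @return A `profile_matrix` (frequencies rescaled to \[0, 1\]).
#' @export
read_pssm <- function(path, sequence = NULL) {
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(trimws(lines), function(x)
    strsplit(x, "\\s+")[[1]])
  is_row <- vapply(toks, function(tk) {
    length(tk) >= 42L && grepl("^[0-9]+$", tk[1]) &&
      nchar(tk[2]) == 1L && tk[2] %in% LETTERS
  }, logical(1))
  rows <- toks[is_row]
  if (!length(rows)) stop("no PSSM rows found in ", path)
  idx <- as.integer(vapply(rows, `[`, "", 1))
  if (!identical(idx, seq_along(idx)))
    stop("malformed PSSM: residue indices are not 1..L in ", path)
  aa <- vapply(rows, `[`, "", 2)
  num <- t(vapply(rows, function(tk) as.numeric(tk[3:42]), numeric(40)))
  if (anyNA(num)) stop("malformed PSSM row in ", path)
  lo <- num[, 1:20, drop = FALSE]
  fr <- num[, 21:40, drop = FALSE] / 100
  if (!is.null(sequence) && nchar(sequence) != length(aa))
    stop("PSSM has ", length(aa), " rows but the sequence has ",
         nchar(sequence), " residues")
  profile_matrix(lo, fr, aa = aa)
}

#' Write a profile in the PSI-BLAST ASCII PSSM dialect
#'
#' @param profile A `profile_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  aa <- profile$aa
  if (is.null(aa)) aa <- rep("A", profile$length)
  hdr <- paste0("            ",
                paste(sprintf("%3s", AA_ORDER), collapse = " "), "  ",
                paste(sprintf("%3s", AA_ORDER), collapse = " "))
  body <- vapply(seq_len(profile$length), function(i) {
    paste0(sprintf("%5d %s  ", i, aa[i]),
           paste(sprintf("%3d", round(profile$logodds[i, ])), collapse = " "),
           "  ",
           paste(sprintf("%3d", round(profile$freq[i, ] * 100)),
                 collapse = " "),
           sprintf("  %5.2f %8.2f", 0, 0))
  }, "")
  writeLines(c("", "Last position-specific scoring matrix computed", hdr,
               body, ""), path)
  invisible(path)
}

#' Read a PSIPRED .ss2 secondary-structure prediction
#'
#' Rows carry index, residue letter, predicted state (H/E/C) and the three
#' state probabilities in file order coil, helix, strand. Probabilities are
#' renormalised to sum to exactly 1 and reordered to H, E, C.
#'
#' @param path Path to the `.ss2` file.
#' @param sequence Optional sequence for a length check.
#' @return A `sec_struct`.
#' @export
read_ss2 <- function(path, sequence = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "\\s+")
  ok <- vapply(toks, function(tk) length(tk) == 6L && grepl("^[0-9]+$", tk[1]),
               logical(1))
  toks <- toks[ok]
  if (!length(toks)) stop("no .ss2 rows found in ", path)
  states <- vapply(toks, `[`, "", 3)
  if (!all(states %in% SS_STATES))
    stop("malformed .ss2 state column in ", path)
  pc <- t(vapply(toks, function(tk) as.numeric(tk[4:6]), numeric(3)))
  if (anyNA(pc)) stop("malformed .ss2 probability row in ", path)
  conf <- pc[, c(2L, 3L, 1L), drop = FALSE]   # file order C H E -> H E C
  if (!is.null(sequence) && nchar(sequence) != length(states))
    stop(".ss2 has ", length(states), " rows but the sequence has ",
         nchar(sequence), " residues")
  sec_struct(states, conf)
}

#' Write a secondary structure in the PSIPRED .ss2 dialect
#'
#' @param ss A `sec_struct`.
#' @param path Output path.
#' @param aa Optional residue letters (defaults to `"A"`).
#' @return `path`, invisibly.
#' @export
write_ss2 <- function(ss, path, aa = NULL) {
  L <- ss_length(ss)
  if (is.null(aa)) aa <- rep("A", L)
  conf <- ss$conf[, c(3L, 1L, 2L), drop = FALSE]   # H E C -> C H E
  body <- sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                  seq_len(L), aa, ss$states, conf[, 1], conf[, 2], conf[, 3])
  writeLines(c("# PSIPRED VFORMAT (conthread writer)", "", body), path)
  invisible(path)
}

#' Read a single-record FASTA file
#'
#' @param path Path to a FASTA file; the first record is used.
#' @return Named character scalar (name = record id, value = sequence).
#' @export
read_fasta_seq <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readAAStringSet(path)
    if (!length(set)) stop("empty FASTA file: ", path)
    seqs <- as.character(set[1])
    names(seqs) <- sub("\\s.*$", "", names(set)[1])
    return(seqs)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- which(startsWith(lines, ">"))
  if (!length(hdr)) stop("not a FASTA file: ", path)
  to <- if (length(hdr) > 1L) hdr[2] - 1L else length(lines)
  seq <- paste(lines[(hdr[1] + 1L):to], collapse = "")
  stats::setNames(gsub("\\s", "", seq),
                  sub("^>\\s*(\\S+).*$", "\\1", lines[hdr[1]]))
}

#' Write a single-record FASTA file
#'
#' @param id Record identifier.
#' @param sequence Sequence string.
#' @param path Output path.
#' @param width Line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta_seq <- function(id, sequence, path, width = 60L) {
  starts <- seq(1L, nchar(sequence), by = width)
  chunks <- substring(sequence, starts, pmin(starts + width - 1L,
                                             nchar(sequence)))
  writeLines(c(paste0(">", id), chunks), path)
  invisible(path)
}
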