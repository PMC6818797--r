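#' Read a structure file into a residue chain
#'
#' Parses a PDB or mmCIF file (dispatching on the file extension), keeps
#' the requested chain's standard amino-acid `ATOM` records from the first
#' model, and anchors each residue at its C-beta atom, falling back to
#' C-alpha for glycine or when C-beta is missing. Residues lacking both are
#' dropped with a warning. Author numbering (including insertion codes) is
#' preserved in the result while internal indexing is 1-based and
#' contiguous in file order.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param chain Chain identifier; defaults to the first chain in the file.
#' @return A `residue_chain`.
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
         else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains)
    stop("chain '", chain, "' not found in ", path,
         " (available: ", paste(chains, collapse = ", "), ")")
  at <- at[at$chain == chain, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  at <- at[!is.na(aa1) & aa1 != "X", , drop = FALSE]
  aa1 <- aa1[!is.na(aa1) & aa1 != "X"]
  if (!nrow(at)) stop("chain '", chain, "' has no standard residues")

  rkey <- paste(at$resno, at$insert)
  rkey <- factor(rkey, levels = unique(rkey))       # file order
  anchor <- function(keys) {
    idx <- integer(0)
    dropped <- 0L
    for (lev in levels(keys)) {
      rows <- which(keys == lev)
      cb <- rows[at$elety[rows] == "CB"]
      ca <- rows[at$elety[rows] == "CA"]
      pick <- if (length(cb)) cb[1] else if (length(ca)) ca[1] else NA_integer_
      if (is.na(pick)) dropped <- dropped + 1L else idx <- c(idx, pick)
    }
    if (dropped)
      warning(dropped, " residue(s) without CA or CB dropped from chain ",
              chain)
    idx
  }
  pick <- anchor(rkey)
  residue_chain(id = paste0(basename_noext(path), "_", chain),
                aa = aa1[pick],
                xyz = cbind(at$x[pick], at$y[pick], at$z[pick]),
                resno = at$resno[pick], insert = at$insert[pick])
}

basename_noext <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Assign 3-state secondary structure from anchor geometry
#'
#' A coarse backbone-geometry rule operating on the anchor coordinates
#' alone. Helices are runs of at least `min_helix - 4` consecutive compact
#' i..i+4 windows (span < `helix_span` A); the run-length requirement
#' (two full helical turns) stops isolated tight turns between strands
#' from being read as helix. Remaining residues whose i-1..i+1 span is
#' extended (> `strand_span` A) are labelled strand; everything else is
#' coil. This is far cruder than a hydrogen-bond-based assigner but only
#' the {H, E, C} collapse is consumed downstream.
#'
#' @param chain A `residue_chain`.
#' @param helix_span i,i+4 anchor distance below which a window is helical
#'   (default 7.3 A; the ideal helix gives about 6.3).
#' @param strand_span i-1,i+1 anchor distance above which a residue is
#'   extended (default 6 A; an ideal strand gives about 6.8, a tight turn
#'   or interpolated loop well under 5).
#' @param min_helix Minimum helix length in residues (default 8, i.e. at
#'   least two turns of compact windows).
#' @return A `sec_struct` with one-hot confidences.
#' @export
ss_from_coords <- function(chain, helix_span = 7.3, strand_span = 6,
                           min_helix = 8L) {
  n <- chain_length(chain)
  xyz <- chain$xyz
  d <- function(a, b) sqrt(sum((xyz[a, ] - xyz[b, ])^2))
  h <- logical(n)
  if (n >= 5L) {
    short <- vapply(1:(n - 4L), function(s) d(s, s + 4L) < helix_span, TRUE)
    r <- rle(short)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] && r$lengths[k] >= min_helix - 4L) {
        h[starts[k]:(ends[k] + 4L)] <- TRUE
      }
    }
  }
  e <- logical(n)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (!h[i] && d(i - 1L, i + 1L) > strand_span) e[i] <- TRUE
    }
  }
  states <- ifelse(h, "H", ifelse(e, "E", "C"))
  sec_struct(states)
}

#' Write a chain as a minimal PDB file
#'
#' Emits one anchor atom per residue (`CB`, or `CA` for glycine) so that
#' [read_structure()] round-trips the chain. Used by the fixture writer.
#'
#' @param chain A `residue_chain`.
#' @param path Output path.
#' @param chain_id Single-letter chain identifier (default `"A"`).
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path, chain_id = "A") {
  n <- chain_length(chain)
  aa3 <- bio3d::aa123(chain$aa)
  elety <- ifelse(chain$aa == "G", "CA", "CB")
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(n), elety, aa3, chain_id, chain$resno,
    chain$xyz[, 1], chain$xyz[, 2], chain$xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}
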