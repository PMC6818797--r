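LIBRARY_FORMAT_VERSION <- "1.0"

#' Template library container
#'
#' @param entries List of `template_entry` objects.
#' @param K,cutoff Library configuration recorded in the manifest.
#' @return A list of class `template_library`.
#' @export
template_library <- function(entries, K = 7L, cutoff = 8) {
  stopifnot(all(vapply(entries, inherits, TRUE, "template_entry")))
  structure(list(entries = entries, K = as.integer(K), cutoff = cutoff),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library> %d entries, K = %d, cutoff = %g A\n",
              length(x$entries), x$K, x$cutoff))
  invisible(x)
}

#' @export
length.template_library <- function(x) length(x$entries)

#' Build a template library from a directory of structures
#'
#' Scans `structure_dir` for `.pdb`/`.ent`/`.cif` files (sorted by name, so
#' the build is independent of directory listing order). For each entry
#' `<id>` the profile is read from `<id>.pssm` in `profile_dir`; secondary
#' structure comes from `<id>.ss2` when present, otherwise it is assigned
#' from the coordinates with [ss_from_coords()]. The native contact map and
#' the eigen-profile at `K` are precomputed. Entries that fail to parse are
#' skipped and recorded in the manifest. The on-disk layout is one JSON
#' record per template plus `manifest.json`; rebuilding unchanged inputs is
#' byte-identical.
#'
#' @param structure_dir Directory of coordinate files.
#' @param out_dir Output directory for the serialized library.
#' @param profile_dir Directory of `.pssm`/`.ss2` files (defaults to
#'   `structure_dir`).
#' @param K Eigen components to precompute (default 7).
#' @param cutoff Contact distance cutoff in Angstrom (default 8).
#' @param chain Chain to extract from each structure (default: first).
#' @return The `template_library`, invisibly; side effect: files under
#'   `out_dir`.
#' @export
build_template_library <- function(structure_dir, out_dir,
                                   profile_dir = structure_dir,
                                   K = 7L, cutoff = 8, chain = NULL) {
  files <- sort(list.files(structure_dir,
                           pattern = "\\.(pdb|ent|cif|mmcif)$",
                           full.names = TRUE))
  if (!length(files)) stop("no structure files in ", structure_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  skipped <- list()
  for (f in files) {
    id <- basename_noext(f)
    res <- tryCatch({
      ch <- read_structure(f, chain)
      pssm <- file.path(profile_dir, paste0(id, ".pssm"))
      if (!file.exists(pssm)) stop("missing profile file ", pssm)
      prof <- read_pssm(pssm, paste(ch$aa, collapse = ""))
      ss2 <- file.path(profile_dir, paste0(id, ".ss2"))
      ss <- if (file.exists(ss2))
        read_ss2(ss2, paste(ch$aa, collapse = "")) else ss_from_coords(ch)
      template_entry(id, ch, prof, ss, K = K, cutoff = cutoff)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("skipping ", id, ": ", conditionMessage(res))
      skipped[[length(skipped) + 1L]] <- list(id = id,
                                              error = conditionMessage(res))
    } else {
      entries[[length(entries) + 1L]] <- res
    }
  }
  ord <- order(vapply(entries, `[[`, "", "id"))
  entries <- entries[ord]
  lib <- template_library(entries, K, cutoff)
  for (tm in entries)
    write_entry_json(tm, file.path(out_dir, paste0(tm$id, ".json")))
  manifest <- list(
    format_version = LIBRARY_FORMAT_VERSION,
    K = as.integer(K), cutoff = cutoff,
    entries = lapply(entries, function(tm) list(
      id = tm$id, L = chain_length(tm$chain),
      n_contacts = n_contacts(tm$contact_map), K_eff = tm$eigen$K)),
    skipped = skipped)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(lib)
}

write_entry_json <- function(tm, path) {
  rec <- list(
    id = tm$id, sequence = tm$sequence,
    resno = tm$chain$resno, insert = tm$chain$insert,
    xyz = tm$chain$xyz,
    profile = list(logodds = tm$profile$logodds, freq = tm$profile$freq),
    ss = list(states = tm$ss$states, conf = tm$ss$conf),
    contacts = list(length = tm$contact_map$length, i = tm$contact_map$i,
                    j = tm$contact_map$j, p = tm$contact_map$p),
    eigen = list(K = tm$eigen$K, values = tm$eigen$values,
                 vectors = tm$eigen$vectors))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_entry_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  aa <- strsplit(rec$sequence, "")[[1]]
  chain <- residue_chain(rec$id, aa, rec$xyz, rec$resno, rec$insert)
  cm <- contact_map(rec$contacts$length, rec$contacts$i %||% integer(),
                    rec$contacts$j %||% integer(),
                    rec$contacts$p %||% numeric())
  K <- as.integer(rec$eigen$K)
  v <- rec$eigen$vectors
  vec <- if (K == 0L) matrix(0, cm$length, 0L)
         else if (is.matrix(v)) v
         else matrix(as.numeric(unlist(v)), ncol = K, byrow = TRUE)
  ep <- structure(list(K = K, values = as.numeric(unlist(rec$eigen$values)),
                       vectors = vec, length = cm$length),
                  class = "eigen_profile")
  template_entry(rec$id, chain,
                 profile_matrix(rec$profile$logodds, rec$profile$freq),
                 sec_struct(rec$ss$states, rec$ss$conf),
                 contact_map = cm, eigen = ep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a serialized template library
#'
#' @param dir Directory written by [build_template_library()].
#' @return A `template_library`.
#' @export
read_template_library <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  if (!identical(manifest$format_version, LIBRARY_FORMAT_VERSION))
    stop("unsupported library format version: ", manifest$format_version)
  entries <- lapply(manifest$entries, function(e)
    read_entry_json(file.path(dir, paste0(e$id, ".json"))))
  template_library(entries, K = manifest$K, cutoff = manifest$cutoff)
}

#' Assemble a query record from a directory of prediction files
#'
#' Expects `<id>.fasta`, `<id>.pssm`, `<id>.ss2` and `<id>.rr` in `dir`
#' (any single FASTA file works when `id` is `NULL`). The RR map is passed
#' through [select_contacts()] with the given quotas.
#'
#' @param dir Directory containing the query files.
#' @param id Basename of the file set; default: that of the only `.fasta`
#'   file present.
#' @param quotas A `range_quotas`.
#' @return A `query_record`.
#' @export
read_query <- function(dir, id = NULL, quotas = range_quotas()) {
  if (is.null(id)) {
    fa <- list.files(dir, pattern = "\\.(fasta|fa)$")
    if (length(fa) != 1L)
      stop("expected exactly one FASTA file in ", dir, " or an explicit id")
    id <- basename_noext(fa)
  }
  fasta <- list.files(dir, pattern = paste0("^", id, "\\.(fasta|fa)$"),
                      full.names = TRUE)
  if (!length(fasta)) stop("no FASTA file for '", id, "' in ", dir)
  seqs <- read_fasta_seq(fasta[1])
  sequence <- unname(seqs[1])
  prof <- read_pssm(file.path(dir, paste0(id, ".pssm")), sequence)
  ss <- read_ss2(file.path(dir, paste0(id, ".ss2")), sequence)
  rr <- read_rr_contacts(file.path(dir, paste0(id, ".rr")),
                         nchar(sequence))
  query_record(id, sequence, prof, ss, select_contacts(rr, ss, quotas))
}

#' Write a query record's files to a directory
#'
#' Inverse of [read_query()] (the stored contact map is the selected one).
#' Used by the fixture writer.
#'
#' @param query A `query_record`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_query <- function(query, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_seq(query$id, query$sequence,
                  file.path(dir, paste0(query$id, ".fasta")))
  write_pssm(query$profile, file.path(dir, paste0(query$id, ".pssm")))
  write_ss2(query$ss, file.path(dir, paste0(query$id, ".ss2")),
            aa = strsplit(query$sequence, "")[[1]])
  write_rr(query$contact_map, file.path(dir, paste0(query$id, ".rr")),
           target = query$id)
  invisible(dir)
}
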