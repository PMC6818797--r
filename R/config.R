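#' Load scoring and search configuration from YAML
#'
#' Reads a YAML file with optional `scoring:` and `search:` blocks and
#' merges them over the package defaults. Recognised `scoring` keys:
#' `w1..w4`, `gap_open`/`gap_extend` (maps with `cm`, `prof`, `ss`),
#' `eigvec_scaling`, `prof_clip`, `K`. Recognised `search` keys:
#' `k_greedy`, `k_enum`, `m_refine`.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A list with elements `scoring` (a `scoring_params`) and
#'   `search` (a named list).
#' @export
load_config <- function(path = NULL) {
  search <- list(k_greedy = 2L, k_enum = 7L, m_refine = 1000L)
  if (is.null(path)) return(list(scoring = scoring_params(), search = search))
  cfg <- yaml::read_yaml(path)
  sc <- cfg$scoring %||% list()
  args <- list()
  for (k in c("w1", "w2", "w3", "w4", "eigvec_scaling", "prof_clip", "K"))
    if (!is.null(sc[[k]])) args[[k]] <- sc[[k]]
  for (k in c("gap_open", "gap_extend"))
    if (!is.null(sc[[k]])) args[[k]] <- unlist(sc[[k]])
  scoring <- do.call(scoring_params, args)
  for (k in names(search))
    if (!is.null(cfg$search[[k]])) search[[k]] <- as.integer(cfg$search[[k]])
  list(scoring = scoring, search = search)
}
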