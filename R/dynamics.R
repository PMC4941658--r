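# Counting loci that match ordered state-change patterns along a
# developmental stage path. Pattern alphabet:
#   N = NON only, H = HEMI only, F = FULL only, M = methylated (HEMI or
#   FULL), U = UNINF only.
# UNINF matches no symbol except U, so determinate-state patterns (the
# published transition rows) never count loci that drop out of a stage.

TRANSITION_ALPHABET <- c("N", "H", "F", "M", "U")

#' Build a stage-path transition query
#'
#' @param path ordered sample labels (>= 1; a single stage degenerates to a
#'   per-sample state count).
#' @param pattern character vector over `N`, `H`, `F`, `M`, `U`, one symbol
#'   per stage. `M` matches HEMI or FULL; the other symbols match exactly
#'   one state.
#' @param label free-text label carried through to outputs.
#' @return A list of class `transition_query`.
#' @export
transition_query <- function(path, pattern, label = "") {
  if (length(path) < 1) msap_stop("path must list at least one stage")
  if (length(pattern) != length(path))
    msap_stop("pattern length %d does not match path length %d",
              length(pattern), length(path))
  bad <- setdiff(pattern, TRANSITION_ALPHABET)
  if (length(bad) > 0)
    msap_stop("unknown pattern symbol '%s' (alphabet: %s)", bad[1],
              paste(TRANSITION_ALPHABET, collapse = ", "))
  structure(list(path = path, pattern = pattern, label = label),
            class = "transition_query")
}

symbol_matches <- function(symbol, states) {
  switch(symbol,
         N = states == "NON",
         H = states == "HEMI",
         F = states == "FULL",
         U = states == "UNINF",
         M = states == "HEMI" | states == "FULL")
}

#' Count loci matching a transition pattern along a stage path
#'
#' A locus matches when its state in every stage of the path satisfies the
#' corresponding pattern symbol.
#'
#' @param states character state matrix.
#' @param query a [transition_query()].
#' @return List with `label`, `path`, `pattern`, `count` and `loci` (ids of
#'   the matching loci).
#' @export
count_transitions <- function(states, query) {
  states <- validate_state_matrix(states)
  stopifnot(inherits(query, "transition_query"))
  unknown <- setdiff(query$path, colnames(states))
  if (length(unknown) > 0)
    msap_stop("path references unknown sample '%s'", unknown[1])
  match_all <- rep(TRUE, nrow(states))
  for (k in seq_along(query$path)) {
    match_all <- match_all &
      symbol_matches(query$pattern[k], states[, query$path[k]])
  }
  list(label = query$label, path = query$path, pattern = query$pattern,
       count = sum(match_all), loci = rownames(states)[match_all])
}

#' Tabulate transition counts for a list of queries
#'
#' @param states character state matrix.
#' @param queries list of [transition_query()] objects (possibly empty).
#' @return Data frame with one row per query: `label`, `path`, `pattern`
#'   (comma-joined) and `count`.
#' @export
transition_table <- function(states, queries) {
  if (length(queries) == 0)
    return(data.frame(label = character(), path = character(),
                      pattern = character(), count = integer()))
  rows <- lapply(queries, function(q) {
    res <- count_transitions(states, q)
    data.frame(label = res$label,
               path = paste(res$path, collapse = ","),
               pattern = paste(res$pattern, collapse = ","),
               count = res$count)
  })
  do.call(rbind, rows)
}

#' The default developmental transition query set
#'
#' The ten published stage-path patterns: three over the leaf maturation
#' path (young -> mature leaf) and seven over the vascular path listed in
#' phloem, cambium, mature-xylem column order (the vascular rows condition
#' on cambium as the reference stage but are printed in this column order).
#'
#' @param leaf_path,vascular_path ordered sample labels for the two paths.
#' @return Named list of [transition_query()] objects.
#' @export
default_transition_queries <- function(
    leaf_path = c("youngLeaf", "matureLeaf"),
    vascular_path = c("phloem", "cambium", "matureXylem")) {
  leaf <- list(c("M", "N"), c("F", "H"), c("H", "F"))
  vasc <- list(c("N", "M", "N"), c("N", "M", "M"), c("M", "M", "N"),
               c("H", "F", "F"), c("F", "F", "H"), c("F", "H", "H"),
               c("H", "H", "F"))
  qs <- c(lapply(leaf, function(p) transition_query(leaf_path, p,
                                                    paste(p, collapse = ""))),
          lapply(vasc, function(p) transition_query(vascular_path, p,
                                                    paste(p, collapse = ""))))
  stats::setNames(qs, vapply(qs, `[[`, "", "label"))
}
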