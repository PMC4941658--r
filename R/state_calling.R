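# Core MSAP scoring: dual-lane presence -> methylation state.
#
# HpaII and MspI both cut unmethylated 5'-CCGG. HpaII is blocked by
# double-strand methylation of either cytosine; MspI is blocked by
# hemi-methylation of the external cytosine. Hence for the paired
# EcoRI/HpaII (H) and EcoRI/MspI (M) lanes:
#   (1,1) non-methylated; (0,1) internal cytosine fully methylated;
#   (1,0) external cytosine hemi-methylated; (0,0) uninformative.

#' Classify a HpaII/MspI band pair into a methylation state
#'
#' Vectorised over its arguments. The mapping is a bijection on the three
#' informative patterns: `(1,1) -> NON`, `(0,1) -> FULL`, `(1,0) -> HEMI`;
#' the doubly absent pattern `(0,0)` is `UNINF` (site absence and
#' doubly-blocked methylation are indistinguishable on the gel).
#'
#' @param h_present 0/1 presence in the EcoRI/HpaII lane.
#' @param m_present 0/1 presence in the EcoRI/MspI lane.
#' @return Character vector of state tokens (see [msap_states()]).
#' @export
classify_band_pair <- function(h_present, m_present) {
  if (!all(h_present %in% c(0, 1)))
    msap_stop("h_present must be 0 or 1, got '%s'",
              h_present[!(h_present %in% c(0, 1))][1])
  if (!all(m_present %in% c(0, 1)))
    msap_stop("m_present must be 0 or 1, got '%s'",
              m_present[!(m_present %in% c(0, 1))][1])
  # index 1 + h + 2*m over the four patterns
  lut <- c("UNINF", "HEMI", "FULL", "NON")
  lut[1L + as.integer(h_present) + 2L * as.integer(m_present)]
}

#' Call methylation states for a whole band matrix
#'
#' Element-wise [classify_band_pair()] over the two lanes.
#'
#' @param bands a [band_matrix()].
#' @return Character matrix of state tokens, loci x samples, dimnames
#'   preserved from `bands`.
#' @export
call_states <- function(bands) {
  stopifnot(inherits(bands, "band_matrix"))
  states <- matrix(classify_band_pair(bands$h, bands$m),
                   nrow = nrow(bands$h), dimnames = dimnames(bands$h))
  states
}

#' Summarise a polymorphism count as the fraction of all loci
#'
#' The ratio arithmetic used to report marker polymorphism: the polymorphic
#' fraction as a percentage of total loci on the 0-100 scale.
#'
#' @param polymorphic_loci,total_loci counts.
#' @return Data frame with `total_loci`, `polymorphic_loci`,
#'   `monomorphic_loci` and `polymorphic_fraction` (percent, full precision).
#' @export
polymorphism_summary <- function(polymorphic_loci, total_loci) {
  if (polymorphic_loci > total_loci)
    msap_stop("polymorphic count %d exceeds total %d",
              polymorphic_loci, total_loci)
  data.frame(total_loci = total_loci,
             polymorphic_loci = polymorphic_loci,
             monomorphic_loci = total_loci - polymorphic_loci,
             polymorphic_fraction = 100 * polymorphic_loci / total_loci)
}

#' Identify polymorphic loci
#'
#' A locus is polymorphic iff its called state differs between at least two
#' samples. Because state calling is a bijection on band patterns, this is
#' equivalent to defining polymorphism on the raw lanes.
#'
#' @param states character state matrix, loci x samples (>= 2 samples).
#' @return List with `summary` (a [polymorphism_summary()] data frame),
#'   `is_polymorphic` (named logical per locus) and `polymorphic_loci`
#'   (character vector of polymorphic locus ids).
#' @export
find_polymorphic <- function(states) {
  states <- validate_state_matrix(states)
  if (ncol(states) < 2)
    msap_stop("polymorphism needs >= 2 samples, got %d", ncol(states))
  is_poly <- apply(states, 1, function(r) length(unique(r)) > 1)
  list(summary = polymorphism_summary(sum(is_poly), nrow(states)),
       is_polymorphic = is_poly,
       polymorphic_loci = rownames(states)[is_poly])
}

#' Per-sample band and state counts
#'
#' For each sample, the number of loci in each state, the methylated count
#' (`HEMI + FULL`) and the total bands present (`NON + HEMI + FULL`, i.e.
#' loci amplified in at least one lane). Together with `n_uninf` the state
#' counts partition the locus set.
#'
#' @param states character state matrix, loci x samples.
#' @return Data frame with one row per sample: `sample`, `n_non`, `n_hemi`,
#'   `n_full`, `n_uninf`, `n_methylated`, `n_bands`.
#' @export
per_sample_band_counts <- function(states) {
  states <- validate_state_matrix(states)
  cnt <- function(tok) colSums(states == tok)
  n_non <- cnt("NON"); n_hemi <- cnt("HEMI")
  n_full <- cnt("FULL"); n_uninf <- cnt("UNINF")
  data.frame(sample = colnames(states),
             n_non = n_non, n_hemi = n_hemi, n_full = n_full,
             n_uninf = n_uninf,
             n_methylated = n_hemi + n_full,
             n_bands = n_non + n_hemi + n_full,
             row.names = NULL)
}
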