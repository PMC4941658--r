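# Methylation breadth and sharing across samples. A locus/gene is
# "methylated" in a sample when its state is HEMI or FULL; NON and UNINF
# both count as unmethylated in the binary indicator.

class_indicator <- function(states, class) {
  class <- match.arg(class, c("METHYLATED", "HEMI", "FULL"))
  if (class == "METHYLATED") (states == "HEMI") | (states == "FULL")
  else states == class
}

#' Binary methylation indicator matrix
#'
#' `M[i, j] = 1` iff locus/gene i is methylated (HEMI or FULL) in sample j;
#' NON and UNINF map to 0.
#'
#' @param states character state matrix, loci x samples.
#' @return Integer 0/1 matrix of the same shape and dimnames.
#' @export
methylation_indicator <- function(states) {
  states <- validate_state_matrix(states)
  m <- class_indicator(states, "METHYLATED")
  storage.mode(m) <- "integer"
  m
}

#' Tau methylation-breadth specificity score
#'
#' For a binary indicator vector over n samples with breadth
#' `b = sum(M)`, tau is `(b - 1) / (n - 1)`: 1 when methylated in every
#' sample (no specificity), 0 when methylated in exactly one (maximal
#' specificity), NA when never methylated (the score is defined on
#' methylated genes only).
#'
#' @param m binary 0/1 vector of length n >= 2.
#' @return Tau in `[0, 1]`, or NA for breadth 0.
#' @export
tau_score <- function(m) {
  if (length(m) < 2) msap_stop("tau needs >= 2 samples, got %d", length(m))
  if (!all(m %in% c(0, 1))) msap_stop("indicator entries must be 0 or 1")
  b <- sum(m)
  if (b == 0) return(NA_real_)
  (b - 1) / (length(m) - 1)
}

#' Tau scores for every locus/gene of a state matrix
#'
#' @param states character state matrix, loci/genes x samples (>= 2 samples).
#' @return Data frame with `id`, `breadth` (number of samples methylated)
#'   and `tau`.
#' @export
tau_table <- function(states) {
  m <- methylation_indicator(states)
  if (ncol(m) < 2) msap_stop("tau needs >= 2 samples, got %d", ncol(m))
  breadth <- rowSums(m)
  tau <- ifelse(breadth == 0, NA_real_, (breadth - 1) / (ncol(m) - 1))
  data.frame(id = rownames(m), breadth = breadth, tau = tau,
             row.names = NULL)
}

#' Sample-specific methylation counts
#'
#' A locus is specific to sample j for a class iff it carries that class in
#' j and in no other sample. For `class = "METHYLATED"` this counts loci
#' with methylation breadth exactly 1.
#'
#' @param states character state matrix (>= 2 samples).
#' @param class `"METHYLATED"` (HEMI or FULL), `"HEMI"` or `"FULL"`.
#' @return List with `per_sample` (data frame `sample`, `count`), `total`
#'   (sum over samples) and `fraction` (percent of total loci, 0-100).
#' @export
specific_sites <- function(states, class = c("METHYLATED", "HEMI", "FULL")) {
  states <- validate_state_matrix(states)
  class <- match.arg(class)
  if (ncol(states) < 2)
    msap_stop("specific sites need >= 2 samples, got %d", ncol(states))
  ind <- class_indicator(states, class)
  carriers <- rowSums(ind)
  counts <- colSums(ind & carriers == 1)
  list(per_sample = data.frame(sample = colnames(states),
                               count = unname(counts), row.names = NULL),
       total = sum(counts),
       fraction = 100 * sum(counts) / nrow(states))
}

#' Count loci shared by every member of a sample subset
#'
#' A locus is shared when it carries the class in every subset member. For
#' `class = "METHYLATED"` each member may be HEMI or FULL independently (so
#' the shared methylated total can exceed shared-full + shared-hemi).
#'
#' @param states character state matrix.
#' @param subset non-empty character vector of sample labels.
#' @param class `"METHYLATED"`, `"HEMI"` or `"FULL"`.
#' @return Integer count.
#' @export
shared_sites <- function(states, subset,
                         class = c("METHYLATED", "HEMI", "FULL")) {
  states <- validate_state_matrix(states)
  class <- match.arg(class)
  if (length(subset) == 0) msap_stop("subset must be non-empty")
  unknown <- setdiff(subset, colnames(states))
  if (length(unknown) > 0) msap_stop("unknown sample: '%s'", unknown[1])
  ind <- class_indicator(states[, subset, drop = FALSE], class)
  sum(rowSums(ind) == length(subset))
}

#' Exhaustive Venn region counts for a sample subset
#'
#' For subsets of up to five samples, counts loci by the exact set of subset
#' members in which they carry the class (membership outside the subset is
#' ignored), one row per non-empty region.
#'
#' @param states character state matrix.
#' @param subset 1-5 sample labels.
#' @param class `"METHYLATED"`, `"HEMI"` or `"FULL"`.
#' @return Data frame with `members` (comma-joined labels), `n_members` and
#'   `count`.
#' @export
venn_regions <- function(states, subset,
                         class = c("METHYLATED", "HEMI", "FULL")) {
  states <- validate_state_matrix(states)
  class <- match.arg(class)
  if (length(subset) < 1 || length(subset) > 5)
    msap_stop("venn regions support subsets of 1-5 samples, got %d",
              length(subset))
  unknown <- setdiff(subset, colnames(states))
  if (length(unknown) > 0) msap_stop("unknown sample: '%s'", unknown[1])
  ind <- class_indicator(states[, subset, drop = FALSE], class)
  key <- apply(ind, 1, function(r) paste(subset[as.logical(r)],
                                         collapse = ","))
  keys <- unlist(lapply(seq_along(subset), function(k)
    utils::combn(subset, k, paste, collapse = ",")))
  counts <- vapply(keys, function(k) sum(key == k), integer(1))
  data.frame(members = keys,
             n_members = lengths(strsplit(keys, ",")),
             count = unname(counts), row.names = NULL)
}

#' Fraction of methylated loci with a common pattern across all samples
#'
#' A locus shows a common pattern when every sample carries the identical
#' methylated state (all HEMI or all FULL). The denominator is the number
#' of loci methylated in at least one sample.
#'
#' @param states character state matrix (>= 2 samples).
#' @return List with `n_common`, `n_methylated_loci` and `fraction`
#'   (percent, 0-100; 0 when no locus is methylated anywhere).
#' @export
common_pattern_fraction <- function(states) {
  states <- validate_state_matrix(states)
  if (ncol(states) < 2)
    msap_stop("common patterns need >= 2 samples, got %d", ncol(states))
  meth_any <- rowSums(class_indicator(states, "METHYLATED")) > 0
  all_hemi <- rowSums(states == "HEMI") == ncol(states)
  all_full <- rowSums(states == "FULL") == ncol(states)
  n_common <- sum(all_hemi | all_full)
  n_meth <- sum(meth_any)
  list(n_common = n_common, n_methylated_loci = n_meth,
       fraction = if (n_meth == 0) 0 else 100 * n_common / n_meth)
}
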