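# Synthetic MSAP data with known ground truth. Loci carry a biochemical
# CCGG state; band patterns follow deterministically from the two enzymes'
# methylation sensitivities, so calling the simulated bands must recover
# the truth everywhere except the doubly-blocked class, which is
# indistinguishable from site absence (called UNINF).

#' Biochemical CCGG state tokens
#'
#' `UNMETH` (no methylation: both enzymes cut), `INTERNAL_FULL` (internal
#' cytosine methylated on both strands: only MspI cuts), `EXTERNAL_HEMI`
#' (external cytosine methylated on one strand: only HpaII cuts) and
#' `BLOCKED_BOTH` (methylation blocking both enzymes, e.g. double-strand
#' external methylation — or simply site absence; the assay cannot tell).
#'
#' @return Character vector of the four biochemical tokens.
#' @export
biochem_states <- function() {
  c("UNMETH", "INTERNAL_FULL", "EXTERNAL_HEMI", "BLOCKED_BOTH")
}

#' Band pattern produced by a biochemical state
#'
#' Deterministic enzyme-sensitivity map: `UNMETH -> (1,1)`,
#' `INTERNAL_FULL -> (0,1)`, `EXTERNAL_HEMI -> (1,0)`,
#' `BLOCKED_BOTH -> (0,0)`. Vectorised.
#'
#' @param state character vector of biochemical tokens.
#' @return List with integer vectors `h` (EcoRI/HpaII lane) and `m`
#'   (EcoRI/MspI lane).
#' @export
simulate_band_pattern <- function(state) {
  bad <- setdiff(state, biochem_states())
  if (length(bad) > 0) msap_stop("unknown biochemical state '%s'", bad[1])
  h <- as.integer(state %in% c("UNMETH", "EXTERNAL_HEMI"))
  m <- as.integer(state %in% c("UNMETH", "INTERNAL_FULL"))
  list(h = h, m = m)
}

#' Map biochemical truth onto called-state space
#'
#' What a perfect caller can recover: `UNMETH -> NON`,
#' `INTERNAL_FULL -> FULL`, `EXTERNAL_HEMI -> HEMI`,
#' `BLOCKED_BOTH -> UNINF` (information loss: blocked methylation and site
#' absence collapse).
#'
#' @param state character vector (or matrix) of biochemical tokens.
#' @return Character vector (or matrix) of state tokens.
#' @export
biochem_to_state <- function(state) {
  map <- c(UNMETH = "NON", INTERNAL_FULL = "FULL",
           EXTERNAL_HEMI = "HEMI", BLOCKED_BOTH = "UNINF")
  out <- map[state]
  if (is.matrix(state))
    out <- matrix(out, nrow = nrow(state), dimnames = dimnames(state))
  unname_if_vector(out)
}

unname_if_vector <- function(x) if (is.matrix(x)) x else unname(x)

#' Default per-tissue biochemical class probabilities
#'
#' Calibrated to the observed per-tissue relative levels of the reference
#' MSAP survey: hemi-methylation between about 7.9 and 11.9%, full
#' methylation between about 9.4 and 14.2%, non-methylation between about
#' 33 and 39%, with the shoot apex richest in hemi-methylation, the phloem
#' in full methylation and the female catkin poorest in both. The
#' remainder of each row is the doubly-blocked/absent class.
#'
#' @param samples sample labels; defaults to the ten reference tissues.
#'   Unknown labels get the across-tissue average row.
#' @return Numeric matrix, samples x 4, columns `p_unmeth`,
#'   `p_internal_full`, `p_external_hemi`, `p_blocked`; rows sum to 1.
#' @export
default_class_probs <- function(samples = msap_tissues()) {
  base <- rbind(
    shootApex       = c(0.3700, 0.1350, 0.1193),
    youngLeaf       = c(0.3270, 0.1050, 0.1000),
    matureLeaf      = c(0.3600, 0.1080, 0.0900),
    phloem          = c(0.3700, 0.1416, 0.0950),
    cambium         = c(0.3650, 0.1250, 0.1050),
    developingXylem = c(0.3550, 0.1200, 0.1080),
    matureXylem     = c(0.3600, 0.1220, 0.0930),
    root            = c(0.3750, 0.1150, 0.0900),
    maleCatkin      = c(0.3933, 0.1000, 0.0850),
    femaleCatkin    = c(0.3500, 0.0936, 0.0787))
  avg <- colMeans(base)
  rows <- t(vapply(samples, function(s) {
    if (s %in% rownames(base)) base[s, ] else avg
  }, numeric(3)))
  probs <- cbind(rows, 1 - rowSums(rows))
  colnames(probs) <- c("p_unmeth", "p_internal_full", "p_external_hemi",
                       "p_blocked")
  rownames(probs) <- samples
  probs
}

default_transition_matrix <- function(p_stay = 0.8) {
  states <- msap_states()
  tm <- matrix((1 - p_stay) / 3, 4, 4, dimnames = list(states, states))
  diag(tm) <- p_stay
  tm
}

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults emulate the
#' reference study design: ten tissues, loci grouped into primer pairs of
#' 11-204 loci, fragment lengths 55-550 bp, per-tissue class frequencies
#' from [default_class_probs()], a monomorphic locus fraction of 0.18
#' (matching the observed 82% marker polymorphism), and log-normal
#' expression in which hemi-methylation suppresses transcription more
#' strongly than full methylation.
#'
#' @param n_loci number of MSAP loci.
#' @param samples sample labels.
#' @param class_probs samples x 4 probability matrix (rows sum to 1);
#'   see [default_class_probs()].
#' @param monomorphic_fraction fraction of loci drawn once and copied to
#'   every sample.
#' @param primer_pair_bounds integer bounds on loci per primer pair.
#' @param fragment_length_bounds integer bounds on fragment length (bp).
#' @param n_replicates biological replicates per sample emitted by
#'   [generate_band_matrix()]; 1 disables replicate output.
#' @param replicate_error per-cell probability that a replicate's band call
#'   flips (gel noise).
#' @param stage_samples ordered labels for [generate_stage_series()].
#' @param transition_matrix 4x4 row-stochastic matrix over called states
#'   governing per-step stage transitions.
#' @param mu,sigma baseline natural-log mean and sd of expression.
#' @param delta_hemi,delta_full nonnegative log-scale suppression offsets;
#'   the default `delta_hemi > delta_full` encodes the stronger silencing
#'   by hemi-methylation.
#' @param seed integer seed; all generators are bit-reproducible given it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_loci = 2000,
                              samples = msap_tissues(),
                              class_probs = default_class_probs(samples),
                              monomorphic_fraction = 0.18,
                              primer_pair_bounds = c(11L, 204L),
                              fragment_length_bounds = c(55L, 550L),
                              n_replicates = 1L,
                              replicate_error = 0.02,
                              stage_samples = c("phloem", "cambium",
                                                "matureXylem"),
                              transition_matrix = default_transition_matrix(),
                              mu = 5, sigma = 0.5,
                              delta_hemi = 1.0, delta_full = 0.5,
                              seed = 1L) {
  if (n_loci < 1) msap_stop("n_loci must be positive")
  class_probs <- as.matrix(class_probs)
  if (nrow(class_probs) != length(samples))
    msap_stop("class_probs needs one row per sample")
  rownames(class_probs) <- samples
  sums <- rowSums(class_probs)
  if (any(abs(sums - 1) > 1e-9))
    msap_stop("class probabilities for sample '%s' sum to %.12f, not 1",
              samples[which(abs(sums - 1) > 1e-9)[1]],
              sums[which(abs(sums - 1) > 1e-9)[1]])
  if (any(class_probs < 0)) msap_stop("class probabilities must be >= 0")
  if (monomorphic_fraction < 0 || monomorphic_fraction > 1)
    msap_stop("monomorphic_fraction must be in [0, 1]")
  if (delta_hemi < 0 || delta_full < 0)
    msap_stop("suppression offsets must be >= 0")
  if (sigma <= 0) msap_stop("sigma must be > 0")
  if (replicate_error < 0 || replicate_error > 1)
    msap_stop("replicate_error must be in [0, 1]")
  tm <- as.matrix(transition_matrix)
  if (!identical(dim(tm), c(4L, 4L)) || any(abs(rowSums(tm) - 1) > 1e-9))
    msap_stop("transition_matrix must be 4x4 row-stochastic")
  dimnames(tm) <- list(msap_states(), msap_states())
  structure(list(n_loci = as.integer(n_loci), samples = samples,
                 class_probs = class_probs,
                 monomorphic_fraction = monomorphic_fraction,
                 primer_pair_bounds = as.integer(primer_pair_bounds),
                 fragment_length_bounds = as.integer(fragment_length_bounds),
                 n_replicates = as.integer(n_replicates),
                 replicate_error = replicate_error,
                 stage_samples = stage_samples,
                 transition_matrix = tm,
                 mu = mu, sigma = sigma,
                 delta_hemi = delta_hemi, delta_full = delta_full,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

draw_biochem <- function(n, probs) {
  sample(biochem_states(), n, replace = TRUE, prob = probs)
}

# primer-pair sizes uniform within bounds, cumulated to cover n_loci
assign_primer_pairs <- function(n_loci, bounds) {
  sizes <- integer(0)
  while (sum(sizes) < n_loci) {
    sizes <- c(sizes, sample(seq(bounds[1], bounds[2]), 1))
  }
  pp <- rep(paste0("PP", seq_along(sizes)), times = sizes)[seq_len(n_loci)]
  pp
}

#' Generate a band matrix with known biochemical truth
#'
#' Draws each locus x sample biochemical state from the per-sample class
#' probabilities (a configured fraction of loci is drawn once, from the
#' across-sample mean probabilities, and copied to every sample), derives
#' band patterns with [simulate_band_pattern()], and returns the truth for
#' oracle tests. With `n_replicates > 1`, per-replicate band matrices with
#' independent flip noise are also returned for consensus-calling tests.
#'
#' @param config a [simulation_config()].
#' @param seed overrides `config$seed` when given.
#' @return List with `bands` (noise-free [band_matrix()]), `truth_biochem`
#'   (character matrix of biochemical tokens), `truth_states` (the same
#'   truth in called-state space via [biochem_to_state()]) and, when
#'   replicates are configured, `replicates` (list of noisy band matrices).
#' @export
generate_band_matrix <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n <- config$n_loci
  samples <- config$samples
  truth <- matrix(NA_character_, n, length(samples),
                  dimnames = list(paste0("L", seq_len(n)), samples))
  n_mono <- round(config$monomorphic_fraction * n)
  if (n_mono > 0) {
    mono <- draw_biochem(n_mono, colMeans(config$class_probs))
    truth[seq_len(n_mono), ] <- mono  # recycled column-wise: copies per sample
  }
  if (n_mono < n) {
    idx <- (n_mono + 1):n
    for (s in samples)
      truth[idx, s] <- draw_biochem(length(idx), config$class_probs[s, ])
  }
  pat <- simulate_band_pattern(truth)
  h <- matrix(pat$h, n, dimnames = dimnames(truth))
  m <- matrix(pat$m, n, dimnames = dimnames(truth))
  loci <- data.frame(
    locus_id = rownames(truth),
    primer_pair = assign_primer_pairs(n, config$primer_pair_bounds),
    length_bp = sample(seq(config$fragment_length_bounds[1],
                           config$fragment_length_bounds[2]), n,
                       replace = TRUE),
    stringsAsFactors = FALSE)
  out <- list(bands = band_matrix(h, m, loci = loci, samples = samples),
              truth_biochem = truth,
              truth_states = biochem_to_state(truth))
  if (config$n_replicates > 1) {
    out$replicates <- lapply(seq_len(config$n_replicates), function(r) {
      flip_h <- matrix(stats::runif(length(h)) < config$replicate_error,
                       nrow(h))
      flip_m <- matrix(stats::runif(length(m)) < config$replicate_error,
                       nrow(m))
      band_matrix(abs(h - flip_h), abs(m - flip_m), loci = loci,
                  samples = samples)
    })
  }
  out
}

#' Consensus state calling across replicates
#'
#' Majority vote per locus x sample over replicate state matrices; a tie
#' for the most frequent state yields `UNINF` (the status cannot be
#' determined).
#'
#' @param states_list list of >= 1 identically shaped state matrices.
#' @return Character state matrix of the common shape.
#' @export
consensus_states <- function(states_list) {
  if (length(states_list) == 0) msap_stop("no replicate state matrices")
  states_list <- lapply(states_list, validate_state_matrix)
  d <- dim(states_list[[1]])
  if (!all(vapply(states_list, function(s) identical(dim(s), d), logical(1))))
    msap_stop("replicate state matrices differ in shape")
  flat <- vapply(states_list, as.vector,
                 character(prod(d)))
  flat <- matrix(flat, nrow = prod(d))
  cons <- apply(flat, 1, function(v) {
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) "UNINF" else names(tab)[1]
  })
  matrix(cons, d[1], d[2], dimnames = dimnames(states_list[[1]]))
}

#' Generate a stage series with exact transition ground truth
#'
#' Simulates called states along an ordered developmental path: the first
#' stage is drawn from that sample's class probabilities (in called-state
#' space) and each later stage from the configured transition matrix.
#' Specific fully-specified patterns can be forced onto leading loci to
#' build constructed ground truth.
#'
#' @param config a [simulation_config()] (uses `stage_samples`,
#'   `transition_matrix`, `class_probs`, `n_loci`).
#' @param forced_patterns optional named integer vector, e.g.
#'   `c("FULL,HEMI" = 139)`: that many leading loci are set to the
#'   comma-separated state sequence exactly.
#' @param seed overrides `config$seed` when given.
#' @return List with `states` (loci x stages matrix) and `pattern_counts`
#'   (named integer vector: count of every observed fully-specified state
#'   sequence, keys comma-joined; sums to `n_loci`).
#' @export
generate_stage_series <- function(config, forced_patterns = NULL,
                                  seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  stages <- config$stage_samples
  unknown <- setdiff(stages, config$samples)
  if (length(unknown) > 0)
    msap_stop("stage path references unknown sample '%s'", unknown[1])
  n <- config$n_loci
  tokens <- msap_states()
  st <- matrix(NA_character_, n, length(stages),
               dimnames = list(paste0("L", seq_len(n)), stages))
  p0 <- config$class_probs[stages[1], c("p_unmeth", "p_external_hemi",
                                        "p_internal_full", "p_blocked")]
  st[, 1] <- sample(tokens, n, replace = TRUE, prob = p0)
  for (k in seq_along(stages)[-1]) {
    for (tok in tokens) {
      rows <- which(st[, k - 1] == tok)
      if (length(rows) > 0)
        st[rows, k] <- sample(tokens, length(rows), replace = TRUE,
                              prob = config$transition_matrix[tok, ])
    }
  }
  if (!is.null(forced_patterns)) {
    total <- sum(forced_patterns)
    if (total > n)
      msap_stop("forced patterns need %d loci but only %d simulated",
                total, n)
    at <- 1L
    for (key in names(forced_patterns)) {
      seqs <- strsplit(key, ",")[[1]]
      if (length(seqs) != length(stages))
        msap_stop("forced pattern '%s' has %d stages, path has %d",
                  key, length(seqs), length(stages))
      bad <- setdiff(seqs, tokens)
      if (length(bad) > 0) msap_stop("unknown state '%s' in forced pattern",
                                     bad[1])
      k <- forced_patterns[[key]]
      st[at:(at + k - 1), ] <- matrix(seqs, k, length(stages), byrow = TRUE)
      at <- at + k
    }
  }
  keys <- apply(st, 1, paste, collapse = ",")
  counts <- table(keys)
  list(states = st,
       pattern_counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Generate methylation-suppressed expression
#'
#' Log-normal expression per gene x sample:
#' `exp(Normal(mu - delta(state), sigma))` with `delta(NON) = 0`,
#' `delta(FULL) = delta_full`, `delta(HEMI) = delta_hemi`; UNINF genes get
#' the unsuppressed baseline. The default `delta_hemi > delta_full`
#' reproduces the stronger silencing by hemi-methylation.
#'
#' @param truth_states character state matrix (genes x samples).
#' @param config a [simulation_config()] (uses `mu`, `sigma`, `delta_hemi`,
#'   `delta_full`).
#' @param seed overrides `config$seed` when given.
#' @return Numeric expression matrix of the same shape.
#' @export
generate_expression <- function(truth_states, config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  truth_states <- validate_state_matrix(truth_states)
  set.seed(seed)
  delta <- c(NON = 0, FULL = config$delta_full, HEMI = config$delta_hemi,
             UNINF = 0)
  mu_mat <- matrix(config$mu - delta[truth_states], nrow(truth_states),
                   dimnames = dimnames(truth_states))
  expr <- exp(mu_mat + stats::rnorm(length(mu_mat), 0, config$sigma))
  expr
}
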