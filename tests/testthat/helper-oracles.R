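# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive row-by-row loops, not the package's vectorised
# code paths.

random_state_matrix <- function(n_loci, samples, seed,
                                probs = c(NON = 0.35, HEMI = 0.1,
                                          FULL = 0.12, UNINF = 0.43)) {
  set.seed(seed)
  m <- matrix(sample(names(probs), n_loci * length(samples), replace = TRUE,
                     prob = probs),
              n_loci, length(samples),
              dimnames = list(paste0("L", seq_len(n_loci)), samples))
  m
}

oracle_polymorphic <- function(states) {
  out <- logical(nrow(states))
  for (i in seq_len(nrow(states))) {
    r <- states[i, ]
    out[i] <- any(r != r[1])
  }
  sum(out)
}

oracle_carries <- function(state, class) {
  if (class == "METHYLATED") state %in% c("HEMI", "FULL") else state == class
}

oracle_shared <- function(states, subset, class) {
  n <- 0
  for (i in seq_len(nrow(states))) {
    ok <- TRUE
    for (s in subset) if (!oracle_carries(states[i, s], class)) ok <- FALSE
    if (ok) n <- n + 1
  }
  n
}

oracle_specific <- function(states, class) {
  counts <- stats::setNames(integer(ncol(states)), colnames(states))
  for (i in seq_len(nrow(states))) {
    carriers <- colnames(states)[oracle_carries(states[i, ], class)]
    if (length(carriers) == 1) counts[carriers] <- counts[carriers] + 1
  }
  counts
}

oracle_count_transitions <- function(states, path, pattern) {
  sym_ok <- function(sym, st) {
    switch(sym, N = st == "NON", H = st == "HEMI", F = st == "FULL",
           U = st == "UNINF", M = st %in% c("HEMI", "FULL"))
  }
  n <- 0
  for (i in seq_len(nrow(states))) {
    ok <- TRUE
    for (k in seq_along(path))
      if (!sym_ok(pattern[k], states[i, path[k]])) ok <- FALSE
    if (ok) n <- n + 1
  }
  n
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# pooled-variance two-sample t statistic, closed form
oracle_student_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  df <- length(x) + length(y) - 2
  list(t = t, p = 2 * pt(-abs(t), df))
}

write_band_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# minimal well-formed 2-locus, 2-sample band file
example_band_lines <- c(
  "locus_id\tprimer_pair\tlength_bp\tA.H\tA.M\tB.H\tB.M",
  "L1\tE65+H/M33\t120\t1\t1\t0\t1",
  "L2\tE65+H/M33\t300\t1\t0\t0\t0")
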