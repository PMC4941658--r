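test_that("biochemical states produce the enzyme-sensitivity band patterns", {
  expect_equal(simulate_band_pattern("UNMETH"), list(h = 1L, m = 1L))
  expect_equal(simulate_band_pattern("INTERNAL_FULL"), list(h = 0L, m = 1L))
  expect_equal(simulate_band_pattern("EXTERNAL_HEMI"), list(h = 1L, m = 0L))
  expect_equal(simulate_band_pattern("BLOCKED_BOTH"), list(h = 0L, m = 0L))
  expect_error(simulate_band_pattern("METH"), "unknown biochemical state")
})

test_that("simulate then classify is the identity on informative states", {
  informative <- c(UNMETH = "NON", INTERNAL_FULL = "FULL",
                   EXTERNAL_HEMI = "HEMI")
  pat <- simulate_band_pattern(names(informative))
  expect_equal(classify_band_pair(pat$h, pat$m), unname(informative))
  # the blocked class is called UNINF: documented information loss
  pb <- simulate_band_pattern("BLOCKED_BOTH")
  expect_equal(classify_band_pair(pb$h, pb$m), "UNINF")
})

test_that("calling simulated bands recovers the truth except BLOCKED_BOTH", {
  cfg <- simulation_config(n_loci = 400, seed = 5)
  g <- generate_band_matrix(cfg)
  called <- call_states(g$bands)
  expect_identical(called, g$truth_states)
  blocked <- g$truth_biochem == "BLOCKED_BOTH"
  expect_true(all(called[blocked] == "UNINF"))
  informative <- !blocked
  expect_true(all(called[informative] ==
                    biochem_to_state(g$truth_biochem)[informative]))
})

test_that("generators are seed-deterministic", {
  cfg <- simulation_config(n_loci = 100, seed = 77)
  a <- generate_band_matrix(cfg)
  b <- generate_band_matrix(cfg)
  expect_identical(a, b)
  ea <- generate_expression(a$truth_states, cfg)
  eb <- generate_expression(b$truth_states, cfg)
  expect_identical(ea, eb)
  sa <- generate_stage_series(cfg)
  sb <- generate_stage_series(cfg)
  expect_identical(sa, sb)
  # different seed, different draw
  expect_false(identical(a$truth_states,
                         generate_band_matrix(cfg, seed = 78)$truth_states))
})

test_that("degenerate configurations produce degenerate matrices", {
  probs <- matrix(rep(c(1, 0, 0, 0), each = 3), 3, 4)
  cfg <- simulation_config(n_loci = 50, samples = c("A", "B", "C"),
                           class_probs = probs, monomorphic_fraction = 0,
                           seed = 2)
  g <- generate_band_matrix(cfg)
  expect_true(all(g$bands$h == 1L))
  expect_true(all(g$bands$m == 1L))
  expect_equal(find_polymorphic(call_states(g$bands))$summary$polymorphic_loci,
               0L)

  cfg_mono <- simulation_config(n_loci = 50, samples = c("A", "B", "C"),
                                monomorphic_fraction = 1, seed = 3)
  g2 <- generate_band_matrix(cfg_mono)
  expect_equal(find_polymorphic(g2$truth_states)$summary$polymorphic_loci, 0L)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(class_probs = matrix(0.3, 10, 4)),
               "sum to")
  expect_error(simulation_config(delta_hemi = -1), ">= 0")
  expect_error(simulation_config(sigma = 0), "sigma")
  expect_error(simulation_config(monomorphic_fraction = 2), "\\[0, 1\\]")
})

test_that("empirical class frequencies converge to configured probabilities", {
  cfg <- simulation_config(n_loci = 1e5, monomorphic_fraction = 0, seed = 19)
  g <- generate_band_matrix(cfg)
  n <- cfg$n_loci
  for (s in cfg$samples) {
    for (cls in biochem_states()) {
      p <- cfg$class_probs[s, match(cls, biochem_states())]
      freq <- mean(g$truth_biochem[, s] == cls)
      expect_lt(abs(freq - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
    }
  }
})

test_that("stage series carry exact transition ground truth", {
  ident <- diag(4); dimnames(ident) <- list(msap_states(), msap_states())
  cfg <- simulation_config(n_loci = 500, seed = 23,
                           transition_matrix = ident)
  series <- generate_stage_series(cfg)
  # no transitions: every locus constant along the path
  expect_true(all(apply(series$states, 1,
                        function(r) length(unique(r)) == 1)))
  expect_equal(sum(series$pattern_counts), 500L)

  forced <- generate_stage_series(cfg,
                                  forced_patterns = c("FULL,HEMI,HEMI" = 139))
  q <- transition_query(cfg$stage_samples, c("F", "H", "H"))
  expect_equal(count_transitions(forced$states, q)$count, 139L)
  expect_equal(sum(forced$pattern_counts), 500L)
})

test_that("pattern counts agree with query counting over the whole alphabet", {
  cfg <- simulation_config(n_loci = 200, seed = 29)
  series <- generate_stage_series(cfg)
  sym <- c(NON = "N", HEMI = "H", FULL = "F", UNINF = "U")
  for (key in names(series$pattern_counts)) {
    pat <- sym[strsplit(key, ",")[[1]]]
    q <- transition_query(cfg$stage_samples, unname(pat))
    expect_equal(count_transitions(series$states, q)$count,
                 unname(series$pattern_counts[key]))
  }
})

test_that("expression suppression follows the configured offsets", {
  # zero offsets: state groups share the population mean
  cfg0 <- simulation_config(n_loci = 4000, samples = c("A"),
                            class_probs = matrix(c(0.4, 0.3, 0.3, 0), 1, 4),
                            monomorphic_fraction = 0,
                            delta_hemi = 0, delta_full = 0, seed = 31)
  g <- generate_band_matrix(cfg0)
  ex <- generate_expression(g$truth_states, cfg0)
  lg <- log(ex[, 1])
  st <- g$truth_states[, 1]
  for (cls in c("NON", "HEMI", "FULL")) {
    expect_lt(abs(mean(lg[st == cls]) - cfg0$mu),
              0.05)  # SE ~ sigma/sqrt(n) ~ 0.015
  }

  # positive offsets: ordering NON > FULL > HEMI in group means
  cfg1 <- simulation_config(n_loci = 4000, samples = c("A"),
                            class_probs = matrix(c(0.4, 0.3, 0.3, 0), 1, 4),
                            monomorphic_fraction = 0, seed = 37)
  g1 <- generate_band_matrix(cfg1)
  ex1 <- generate_expression(g1$truth_states, cfg1)
  st1 <- g1$truth_states[, 1]
  m <- tapply(log(ex1[, 1]), st1, mean)
  expect_gt(m["NON"], m["FULL"])
  expect_gt(m["FULL"], m["HEMI"])
})

test_that("replicates are emitted and consensus calling majority-votes", {
  cfg <- simulation_config(n_loci = 200, n_replicates = 3,
                           replicate_error = 0.05, seed = 41)
  g <- generate_band_matrix(cfg)
  expect_length(g$replicates, 3)
  reps <- lapply(g$replicates, call_states)
  cons <- consensus_states(reps)
  # consensus should be closer to truth than any single noisy replicate
  acc_cons <- mean(cons == g$truth_states)
  acc_rep <- sapply(reps, function(r) mean(r == g$truth_states))
  expect_gte(acc_cons, max(acc_rep))

  # explicit majority and tie cases
  a <- matrix("NON", 1, 1, dimnames = list("L1", "S"))
  b <- matrix("FULL", 1, 1, dimnames = list("L1", "S"))
  expect_equal(consensus_states(list(a, a, b))[1, 1], "NON")
  expect_equal(consensus_states(list(a, b))[1, 1], "UNINF")
  expect_equal(consensus_states(list(a, b, b))[1, 1], "FULL")
})
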