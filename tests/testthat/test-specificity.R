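test_that("tau takes its analytic values at the breadth extremes", {
  expect_equal(tau_score(rep(1, 10)), 1)
  expect_equal(tau_score(c(1, rep(0, 9))), 0)
  expect_equal(tau_score(c(rep(1, 5), rep(0, 5))), 4 / 9)
  expect_true(is.na(tau_score(rep(0, 10))))
  expect_error(tau_score(1), ">= 2 samples")
  expect_error(tau_score(c(1, 2)), "0 or 1")
})

test_that("tau is monotone in breadth and bounded on methylated genes", {
  n <- 10
  taus <- sapply(1:n, function(b) tau_score(c(rep(1, b), rep(0, n - b))))
  expect_true(all(diff(taus) > 0))
  expect_true(all(taus >= 0 & taus <= 1))
})

test_that("tau_table matches per-row scoring and flags breadth 0 as NA", {
  st <- random_state_matrix(80, msap_tissues(), 13)
  tt <- tau_table(st)
  m <- methylation_indicator(st)
  expect_equal(tt$breadth, unname(rowSums(m)))
  for (i in c(1, 5, 40)) {
    expected <- tau_score(m[i, ])
    expect_equal(tt$tau[i], expected)
  }
  expect_true(all(is.na(tt$tau[tt$breadth == 0])))
  expect_true(all(tt$tau[tt$breadth >= 1] >= 0, na.rm = TRUE))
})

test_that("the methylation indicator maps NON and UNINF to 0", {
  st <- matrix(c("NON", "HEMI", "FULL", "UNINF"), 2, 2,
               dimnames = list(c("L1", "L2"), c("A", "B")))
  m <- methylation_indicator(st)
  expect_equal(unname(m), matrix(c(0L, 1L, 1L, 0L), 2, 2))
})

test_that("sample-specific counts match an exhaustive scan", {
  # constructed fixture with known singletons
  st <- matrix("NON", 5, 3, dimnames = list(paste0("L", 1:5),
                                            c("A", "B", "C")))
  st[1, "A"] <- "HEMI"                    # HEMI- and METH-specific to A
  st[2, "B"] <- "FULL"                    # FULL- and METH-specific to B
  st[3, c("A", "B")] <- "HEMI"            # breadth 2: not specific
  st[4, "C"] <- "HEMI"; st[4, "A"] <- "FULL"  # HEMI-specific to C only
  res <- specific_sites(st, "METHYLATED")
  expect_equal(res$per_sample$count, c(1L, 1L, 0L))
  hemi <- specific_sites(st, "HEMI")
  expect_equal(hemi$per_sample$count, c(1L, 0L, 1L))

  for (seed in 1:20) {
    st <- random_state_matrix(60, c("A", "B", "C", "D"), seed)
    for (cl in c("METHYLATED", "HEMI", "FULL")) {
      res <- specific_sites(st, cl)
      expect_equal(stats::setNames(res$per_sample$count,
                                   res$per_sample$sample),
                   oracle_specific(st, cl))
    }
  }
})

test_that("identical columns yield no specific sites", {
  col <- sample(msap_states(), 50, replace = TRUE)
  st <- matrix(rep(col, 4), 50, 4,
               dimnames = list(paste0("L", 1:50), LETTERS[1:4]))
  expect_equal(specific_sites(st, "METHYLATED")$total, 0L)
})

test_that("methylated-specific totals equal the breadth-1 locus count", {
  for (seed in 1:10) {
    st <- random_state_matrix(120, msap_tissues(), seed)
    total <- specific_sites(st, "METHYLATED")$total
    breadth <- rowSums(methylation_indicator(st))
    expect_equal(total, sum(breadth == 1))
  }
})

test_that("shared sites agree with set intersection and shrink with the subset", {
  st <- random_state_matrix(50, LETTERS[1:5], 21)
  for (cl in c("METHYLATED", "HEMI", "FULL")) {
    for (k in 1:3) {
      subset <- sample(LETTERS[1:5], k + 1)
      expect_equal(shared_sites(st, subset, cl),
                   oracle_shared(st, subset, cl))
    }
    # degenerate one-sample subset equals that sample's class count
    expect_equal(shared_sites(st, "A", cl),
                 sum(oracle_carries(st[, "A"], cl)))
  }
  # anti-monotonicity over growing subsets, many seeds
  for (seed in 1:30) {
    st <- random_state_matrix(80, LETTERS[1:5], seed + 100)
    subset <- character(0)
    prev <- Inf
    for (s in LETTERS[1:5]) {
      subset <- c(subset, s)
      cur <- shared_sites(st, subset, "METHYLATED")
      expect_lte(cur, prev)
      prev <- cur
    }
  }
})

test_that("disjoint methylation between samples shares nothing", {
  st <- matrix("NON", 10, 2, dimnames = list(paste0("L", 1:10), c("A", "B")))
  st[1:5, "A"] <- "HEMI"
  st[6:10, "B"] <- "FULL"
  expect_equal(shared_sites(st, c("A", "B"), "METHYLATED"), 0L)
  expect_error(shared_sites(st, c("A", "Z"), "METHYLATED"),
               "unknown sample")
  expect_error(shared_sites(st, character(0), "METHYLATED"), "non-empty")
})

test_that("shared methylated can exceed shared full plus shared hemi", {
  # one member HEMI, the other FULL still counts as shared methylated
  st <- matrix(c("HEMI", "FULL"), 1, 2,
               dimnames = list("L1", c("A", "B")))
  expect_equal(shared_sites(st, c("A", "B"), "METHYLATED"), 1L)
  expect_equal(shared_sites(st, c("A", "B"), "HEMI"), 0L)
  expect_equal(shared_sites(st, c("A", "B"), "FULL"), 0L)
})

test_that("venn regions partition the loci carrying the class", {
  st <- random_state_matrix(100, LETTERS[1:4], 31)
  for (cl in c("METHYLATED", "HEMI")) {
    v <- venn_regions(st, LETTERS[1:4], cl)
    carriers <- rowSums(sapply(LETTERS[1:4], function(s)
      oracle_carries(st[, s], cl))) > 0
    expect_equal(sum(v$count), sum(carriers))
    # the all-member region is the shared count
    expect_equal(v$count[v$members == paste(LETTERS[1:4], collapse = ",")],
                 shared_sites(st, LETTERS[1:4], cl))
  }
  expect_error(venn_regions(st, character(0), "HEMI"), "1-5 samples")
})

test_that("common pattern fraction uses the methylated-loci denominator", {
  all_hemi <- matrix("HEMI", 10, 3,
                     dimnames = list(paste0("L", 1:10), c("A", "B", "C")))
  expect_equal(common_pattern_fraction(all_hemi)$fraction, 100)

  st <- all_hemi
  st[, "B"] <- "FULL"  # methylated everywhere but never the same class
  expect_equal(common_pattern_fraction(st)$fraction, 0)

  for (seed in 1:15) {
    st <- random_state_matrix(70, c("A", "B", "C"), seed)
    res <- common_pattern_fraction(st)
    common <- 0; meth <- 0
    for (i in seq_len(nrow(st))) {
      r <- st[i, ]
      if (any(r %in% c("HEMI", "FULL"))) meth <- meth + 1
      if (all(r == "HEMI") || all(r == "FULL")) common <- common + 1
    }
    expect_equal(res$n_common, common)
    expect_equal(res$n_methylated_loci, meth)
    expect_equal(res$fraction, if (meth == 0) 0 else 100 * common / meth)
  }
})
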