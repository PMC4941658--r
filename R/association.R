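# Methylation state vs transcript level. Genes are grouped by their called
# state in a tissue (UNINF excluded) for pairwise mean comparisons, and an
# ordinal state encoding supports a pattern-expression Pearson correlation.

#' Default ordinal encoding of methylation states
#'
#' `NON = 0, FULL = 1, HEMI = 2`: increasing in expected transcriptional
#' suppression (hemi-methylation suppresses more strongly than full
#' internal-cytosine methylation in this system). UNINF has no code and is
#' excluded from encoded analyses. The encoding is an analysis choice and
#' is recorded in every result that uses it.
#'
#' @return Named numeric vector over `NON`, `FULL`, `HEMI`.
#' @export
default_state_encoding <- function() c(NON = 0, FULL = 1, HEMI = 2)

# map a locus-level state matrix onto genes; gene_map is locus_id -> gene_id
map_states_to_genes <- function(states, gene_map) {
  if (is.null(gene_map)) return(states)
  known <- names(gene_map) %in% rownames(states)
  if (!all(known))
    msap_stop("gene map references unknown locus '%s'",
              names(gene_map)[!known][1])
  mapped <- states[names(gene_map), , drop = FALSE]
  rownames(mapped) <- unname(gene_map)
  if (anyDuplicated(rownames(mapped)))
    msap_stop("gene map assigns gene '%s' to more than one locus",
              rownames(mapped)[duplicated(rownames(mapped))][1])
  mapped
}

#' Compare transcript levels between methylation state groups in a tissue
#'
#' Genes are partitioned by their called state in the tissue (HEMI, FULL,
#' NON; UNINF excluded) and mean expression is compared between every pair
#' of groups with two-sided t-tests. By default expression is
#' `log2(x + 1)`-transformed first (qRT-PCR and FPKM scales are
#' multiplicative); means are reported on the analysis scale.
#'
#' @param states character state matrix (loci or genes x samples).
#' @param expr numeric expression matrix, genes x samples.
#' @param tissue sample label present in both matrices.
#' @param gene_map optional named character vector locus_id -> gene_id
#'   linking state rows to expression rows; by default row names are
#'   matched directly.
#' @param log2_transform transform expression with `log2(x + 1)` before
#'   testing (default TRUE)?
#' @param alpha significance threshold for the reported flags.
#' @return List of class `association_result`: `tissue`, `group_sizes`,
#'   `group_means` (named by state), `pairwise` (data frame `pair`,
#'   `t_statistic`, `p_value`), `n_genes`, `log2_transform`. Pairs with a
#'   group of fewer than two genes get NA with a warning.
#' @export
group_expression <- function(states, expr, tissue, gene_map = NULL,
                             log2_transform = TRUE, alpha = 0.05) {
  states <- validate_state_matrix(states)
  states <- map_states_to_genes(states, gene_map)
  if (!tissue %in% colnames(states))
    msap_stop("tissue '%s' not in state matrix", tissue)
  if (!tissue %in% colnames(expr))
    msap_stop("tissue '%s' not in expression matrix", tissue)
  genes <- intersect(rownames(states), rownames(expr))
  if (length(genes) == 0) msap_stop("no genes shared by states and expression")
  st <- states[genes, tissue]
  ex <- expr[genes, tissue]
  if (log2_transform) ex <- log2(ex + 1)
  keep <- st != "UNINF"
  st <- st[keep]; ex <- ex[keep]
  groups <- c("HEMI", "FULL", "NON")
  vals <- lapply(groups, function(g) ex[st == g])
  names(vals) <- groups
  means <- vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1))
  pairs <- utils::combn(groups, 2)
  pw <- apply(pairs, 2, function(p) {
    a <- vals[[p[1]]]; b <- vals[[p[2]]]
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("pair %s-%s: a group has < 2 genes; test is NA",
                      p[1], p[2]), call. = FALSE)
      return(c(NA_real_, NA_real_))
    }
    res <- two_sample_t(a, b)
    c(res$t, res$p)
  })
  pairwise <- data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
                         t_statistic = pw[1, ], p_value = pw[2, ],
                         significant = pw[2, ] < alpha)
  structure(list(tissue = tissue,
                 group_sizes = lengths(vals),
                 group_means = means,
                 pairwise = pairwise,
                 n_genes = length(st),
                 log2_transform = log2_transform),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("tissue %s: %d informative genes%s\n", x$tissue, x$n_genes,
              if (x$log2_transform) " (log2 scale)" else ""))
  cat(sprintf("  mean expression  HEMI %.3f  FULL %.3f  NON %.3f\n",
              x$group_means["HEMI"], x$group_means["FULL"],
              x$group_means["NON"]))
  print(x$pairwise)
  invisible(x)
}

#' Correlate encoded methylation pattern with expression across tissues
#'
#' Pools all gene x tissue pairs over the given tissue subset, encodes each
#' gene's state ordinally (UNINF pairs dropped) and computes the Pearson
#' correlation with expression, with the usual t-test p-value.
#'
#' @param states character state matrix.
#' @param expr numeric expression matrix.
#' @param tissues sample subset; the default is the four vascular tissues,
#'   where transcriptome data are typically available.
#' @param gene_map optional locus_id -> gene_id map (see
#'   [group_expression()]).
#' @param encoding named numeric state encoding (see
#'   [default_state_encoding()]).
#' @param log2_transform transform expression with `log2(x + 1)` first
#'   (default FALSE: Pearson r is invariant to affine but not log scaling)?
#' @return List with `r`, `p_value`, `n_pairs`, `encoding`. With fewer than
#'   3 informative pairs or zero variance in either vector, `r` is NA with
#'   a warning.
#' @export
pattern_correlation <- function(states, expr,
                                tissues = c("phloem", "cambium",
                                            "developingXylem", "matureXylem"),
                                gene_map = NULL,
                                encoding = default_state_encoding(),
                                log2_transform = FALSE) {
  states <- validate_state_matrix(states)
  states <- map_states_to_genes(states, gene_map)
  unknown <- setdiff(tissues, intersect(colnames(states), colnames(expr)))
  if (length(unknown) > 0)
    msap_stop("tissue '%s' missing from states or expression", unknown[1])
  genes <- intersect(rownames(states), rownames(expr))
  st <- as.vector(states[genes, tissues])
  ex <- as.vector(expr[genes, tissues])
  if (log2_transform) ex <- log2(ex + 1)
  keep <- st %in% names(encoding)
  code <- unname(encoding[st[keep]])
  ex <- ex[keep]
  out <- list(r = NA_real_, p_value = NA_real_, n_pairs = length(code),
              encoding = encoding)
  if (length(code) < 3) {
    warning("fewer than 3 informative gene x tissue pairs", call. = FALSE)
    return(out)
  }
  if (stats::sd(code) == 0 || stats::sd(ex) == 0) {
    warning("zero variance in encoded state or expression", call. = FALSE)
    return(out)
  }
  ct <- stats::cor.test(code, ex, method = "pearson")
  out$r <- unname(ct$estimate)
  out$p_value <- ct$p.value
  out
}
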