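#' @keywords internal
"_PACKAGE"

# Fixed TSV dialect for all pipeline files: tab separator, UTF-8, "." decimal,
# no quoting. Fixtures must roundtrip bit-exactly.

#' Methylation state tokens
#'
#' The four per-locus, per-sample methylation states called from the paired
#' EcoRI/HpaII and EcoRI/MspI lanes: `NON` (non-methylated CCGG, band in both
#' lanes), `HEMI` (hemi-methylated external cytosine, HpaII lane only),
#' `FULL` (fully methylated internal cytosine, MspI lane only) and `UNINF`
#' (band absent in both lanes; status undeterminable).
#'
#' @return Character vector of the four state tokens.
#' @export
msap_states <- function() c("NON", "HEMI", "FULL", "UNINF")

#' The ten tissues and organs of the reference sampling design
#'
#' Sample labels used as defaults throughout: two xylem tissues (developing
#' and mature xylem) and eight non-xylem tissues/organs.
#'
#' @return Character vector of ten sample labels.
#' @export
msap_tissues <- function() {
  c("shootApex", "youngLeaf", "matureLeaf", "phloem", "cambium",
    "developingXylem", "matureXylem", "root", "maleCatkin", "femaleCatkin")
}

#' Default xylem / non-xylem group assignment
#'
#' @param samples character vector of sample labels.
#' @return Named character vector mapping each sample to `"xylem"`
#'   (developing and mature xylem) or `"nonXylem"`.
#' @export
default_groups <- function(samples = msap_tissues()) {
  g <- ifelse(samples %in% c("developingXylem", "matureXylem"),
              "xylem", "nonXylem")
  stats::setNames(g, samples)
}

msap_stop <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Construct a dual-lane band-presence matrix
#'
#' Bundles the two parallel digests of an MSAP assay: presence/absence of
#' each locus in the EcoRI/HpaII lane (`h_lane`) and the EcoRI/MspI lane
#' (`m_lane`), plus per-locus metadata.
#'
#' @param h_lane,m_lane integer 0/1 matrices, loci in rows, samples in
#'   columns; identical dimensions.
#' @param loci data frame with columns `locus_id` (unique), `primer_pair`,
#'   `length_bp` (positive integer or NA). Defaults to generated ids.
#' @param samples character vector of unique sample labels; defaults to the
#'   column names of `h_lane`.
#' @return An object of class `band_matrix`: a list with elements `loci`,
#'   `samples`, `h` and `m`.
#' @export
band_matrix <- function(h_lane, m_lane, loci = NULL, samples = NULL) {
  h_lane <- as.matrix(h_lane)
  m_lane <- as.matrix(m_lane)
  if (!identical(dim(h_lane), dim(m_lane)))
    msap_stop("h_lane (%d x %d) and m_lane (%d x %d) differ in shape",
              nrow(h_lane), ncol(h_lane), nrow(m_lane), ncol(m_lane))
  if (is.null(samples)) samples <- colnames(h_lane)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(h_lane)))
  if (anyDuplicated(samples))
    msap_stop("duplicate sample label: '%s'", samples[duplicated(samples)][1])
  if (length(samples) != ncol(h_lane))
    msap_stop("%d sample labels for %d columns", length(samples), ncol(h_lane))
  if (is.null(loci)) {
    loci <- data.frame(locus_id = paste0("L", seq_len(nrow(h_lane))),
                       primer_pair = NA_character_,
                       length_bp = NA_integer_,
                       stringsAsFactors = FALSE)
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (!all(c("locus_id", "primer_pair", "length_bp") %in% names(loci)))
    msap_stop("loci metadata needs columns locus_id, primer_pair, length_bp")
  if (nrow(loci) != nrow(h_lane))
    msap_stop("%d loci rows for %d band rows", nrow(loci), nrow(h_lane))
  if (anyDuplicated(loci$locus_id))
    msap_stop("duplicate locus_id: '%s'",
              loci$locus_id[duplicated(loci$locus_id)][1])
  bad_len <- !is.na(loci$length_bp) & loci$length_bp <= 0
  if (any(bad_len))
    msap_stop("non-positive fragment length for locus '%s'",
              loci$locus_id[bad_len][1])
  for (lane in list(h = h_lane, m = m_lane)) {
    if (!all(lane %in% c(0L, 1L)))
      msap_stop("band presence must be 0 or 1")
  }
  storage.mode(h_lane) <- "integer"
  storage.mode(m_lane) <- "integer"
  dimnames(h_lane) <- dimnames(m_lane) <- list(loci$locus_id, samples)
  structure(list(loci = loci, samples = samples, h = h_lane, m = m_lane),
            class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix: %d loci x %d samples (H and M lanes)\n",
              nrow(x$h), length(x$samples)))
  invisible(x)
}

#' @export
dim.band_matrix <- function(x) c(nrow(x$h), ncol(x$h), 2L)

read_tsv_strict <- function(path) {
  if (!file.exists(path)) msap_stop("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, fileEncoding = "UTF-8")
}

# Parse a character column of band calls, erroring with coordinates on
# anything other than literal "0"/"1" (including explicit NA tokens).
parse_binary_column <- function(x, column, locus_ids) {
  bad <- !(x %in% c("0", "1"))
  if (any(bad)) {
    i <- which(bad)[1]
    msap_stop("non-binary band value '%s' at locus '%s', column '%s'",
              x[i], locus_ids[i], column)
  }
  as.integer(x)
}

#' Read a dual-lane band-presence matrix from TSV
#'
#' Expects a header `locus_id`, `primer_pair`, `length_bp`, then two columns
#' per sample named `<sample>.H` (EcoRI/HpaII lane) and `<sample>.M`
#' (EcoRI/MspI lane) holding 0/1 presence calls. Parsing is strict: any cell
#' other than `0`/`1` (including `NA` tokens) is rejected with its
#' coordinates, and a lane column without its partner is a format error.
#'
#' @param path path to a TSV file.
#' @return A [band_matrix()].
#' @export
read_band_matrix <- function(path) {
  df <- read_tsv_strict(path)
  meta_cols <- c("locus_id", "primer_pair", "length_bp")
  if (!identical(names(df)[seq_len(min(3, ncol(df)))], meta_cols))
    msap_stop("malformed header: expected columns %s first, found '%s'",
              paste(meta_cols, collapse = ", "),
              paste(utils::head(names(df), 3), collapse = ", "))
  lane_cols <- names(df)[-(1:3)]
  suffix_ok <- grepl("\\.(H|M)$", lane_cols)
  if (length(lane_cols) == 0)
    msap_stop("no sample lane columns found")
  if (any(!suffix_ok))
    msap_stop("malformed header: column '%s' is not a '<sample>.H'/'<sample>.M' lane",
              lane_cols[!suffix_ok][1])
  samples <- unique(sub("\\.(H|M)$", "", lane_cols))
  for (s in samples) {
    for (lane in c("H", "M")) {
      col <- paste0(s, ".", lane)
      if (!col %in% lane_cols)
        msap_stop("malformed header: missing lane column '%s'", col)
    }
  }
  if (anyDuplicated(df$locus_id))
    msap_stop("duplicate locus_id: '%s'",
              df$locus_id[duplicated(df$locus_id)][1])
  len <- suppressWarnings(as.integer(df$length_bp))
  bad_len <- !(df$length_bp %in% c("", "NA")) & is.na(len)
  if (any(bad_len))
    msap_stop("non-integer length_bp '%s' at locus '%s'",
              df$length_bp[bad_len][1], df$locus_id[bad_len][1])
  h <- sapply(samples, function(s)
    parse_binary_column(df[[paste0(s, ".H")]], paste0(s, ".H"), df$locus_id))
  m <- sapply(samples, function(s)
    parse_binary_column(df[[paste0(s, ".M")]], paste0(s, ".M"), df$locus_id))
  h <- matrix(h, nrow = nrow(df), dimnames = list(df$locus_id, samples))
  m <- matrix(m, nrow = nrow(df), dimnames = list(df$locus_id, samples))
  loci <- data.frame(locus_id = df$locus_id, primer_pair = df$primer_pair,
                     length_bp = len, stringsAsFactors = FALSE)
  band_matrix(h, m, loci = loci, samples = samples)
}

#' Write a dual-lane band-presence matrix to TSV
#'
#' Inverse of [read_band_matrix()]; `read_band_matrix(write_band_matrix(x))`
#' reproduces `x` bit-exactly.
#'
#' @param bands a [band_matrix()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_band_matrix <- function(bands, path) {
  stopifnot(inherits(bands, "band_matrix"))
  out <- data.frame(locus_id = bands$loci$locus_id,
                    primer_pair = bands$loci$primer_pair,
                    length_bp = bands$loci$length_bp,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (s in bands$samples) {
    out[[paste0(s, ".H")]] <- bands$h[, s]
    out[[paste0(s, ".M")]] <- bands$m[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

validate_state_matrix <- function(states) {
  if (!is.matrix(states) || !is.character(states))
    msap_stop("a state matrix must be a character matrix")
  bad <- !(states %in% msap_states())
  if (any(bad)) {
    i <- which(bad)[1]
    rc <- arrayInd(i, dim(states))
    msap_stop("invalid state token '%s' at locus %d, sample %d",
              states[i], rc[1], rc[2])
  }
  if (is.null(rownames(states)) && nrow(states) > 0)
    rownames(states) <- paste0("L", seq_len(nrow(states)))
  if (is.null(colnames(states)) && ncol(states) > 0)
    colnames(states) <- paste0("S", seq_len(ncol(states)))
  states
}

#' Write a called state matrix to TSV
#'
#' One row per locus (`locus_id` first), one column per sample, cells in
#' `NON`/`HEMI`/`FULL`/`UNINF`. Lossless: [read_state_matrix()] on the file
#' returns the identical matrix.
#'
#' @param states character matrix of state tokens, loci x samples.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_state_matrix <- function(states, path) {
  states <- validate_state_matrix(states)
  out <- data.frame(locus_id = rownames(states), states,
                    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a called state matrix from TSV
#'
#' @param path path to a TSV written by [write_state_matrix()].
#' @return Character matrix of state tokens, loci x samples.
#' @export
read_state_matrix <- function(path) {
  df <- read_tsv_strict(path)
  if (names(df)[1] != "locus_id")
    msap_stop("malformed header: first column must be 'locus_id', found '%s'",
              names(df)[1])
  if (anyDuplicated(df$locus_id))
    msap_stop("duplicate locus_id: '%s'",
              df$locus_id[duplicated(df$locus_id)][1])
  states <- as.matrix(df[, -1, drop = FALSE])
  rownames(states) <- df$locus_id
  validate_state_matrix(states)
}

#' Read a gene expression table from TSV
#'
#' Expects a `gene_id` column then one numeric column per sample. Values are
#' relative expression or FPKM-like measures and must be nonnegative.
#'
#' @param path path to a TSV file.
#' @return Numeric matrix, genes x samples, with gene ids as row names.
#' @export
read_expression <- function(path) {
  df <- read_tsv_strict(path)
  if (names(df)[1] != "gene_id")
    msap_stop("malformed header: first column must be 'gene_id', found '%s'",
              names(df)[1])
  if (nrow(df) == 0) msap_stop("empty expression table: %s", path)
  if (ncol(df) < 2) msap_stop("expression table has no sample columns")
  if (anyDuplicated(df$gene_id))
    msap_stop("duplicate gene_id: '%s'", df$gene_id[duplicated(df$gene_id)][1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(df$gene_id, colnames(vals)))
  if (any(is.na(num))) {
    i <- which(is.na(num))[1]
    rc <- arrayInd(i, dim(num))
    msap_stop("non-numeric expression value '%s' at gene '%s', sample '%s'",
              vals[i], df$gene_id[rc[1]], colnames(num)[rc[2]])
  }
  if (any(num < 0)) {
    i <- which(num < 0)[1]
    rc <- arrayInd(i, dim(num))
    msap_stop("negative expression value %s at gene '%s', sample '%s'",
              num[i], df$gene_id[rc[1]], colnames(num)[rc[2]])
  }
  num
}

#' Write a gene expression table to TSV
#'
#' @param expr numeric matrix, genes x samples (gene ids as row names).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  out <- data.frame(gene_id = rownames(expr), expr,
                    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Run configuration for grouped and staged analyses
#'
#' @param group_assignments named character vector mapping sample labels to
#'   group labels (e.g. xylem / non-xylem).
#' @param stage_paths list of ordered character vectors of sample labels,
#'   each a developmental stage path for transition counting.
#' @param alpha significance threshold in (0, 1); default 0.05.
#' @param seed integer seed for any stochastic step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(group_assignments = default_groups(),
                       stage_paths = list(leaf = c("youngLeaf", "matureLeaf"),
                                          vascular = c("phloem", "cambium",
                                                       "matureXylem")),
                       alpha = 0.05, seed = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    msap_stop("alpha must be a single number in (0, 1)")
  structure(list(group_assignments = group_assignments,
                 stage_paths = stage_paths,
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}
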