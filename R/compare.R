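#' Bin methylation levels into fixed-size blocks
#'
#' Tiles the reference into non-overlapping blocks of `block_size` bp
#' (1-based inclusive: position `block_size` falls in block 1, position
#' `block_size + 1` in block 2) and averages the covered per-cytosine
#' levels of the requested context class within each block (unweighted).
#' Blocks with no covered cytosine are missing (`NA`). 10-kbp blocks are
#' the conventional grain for sample-level methylome comparison.
#'
#' @param calls an `integrated_calls` table (or any table with
#'   `chrom, pos, context` and the level column).
#' @param block_size bin width in bp.
#' @param context `"CG"` or `"CH"`.
#' @param column level column to average.
#' @return a `data.table` (`chrom, bin, start, end, level, n_sites`)
#'   covering every occupied bin.
#' @export
bin_methylation <- function(calls, block_size = 10000L, context = "CG",
                            column = "wave") {
  context <- match.arg(context, c("CG", "CH"))
  if (!column %in% names(calls)) stop("no such level column: ", column)
  dt <- as.data.table(calls)
  keep <- collapse_context(dt$context) == context
  dt <- dt[which(keep)]
  dt[, lvl := dt[[column]]]
  dt[, bin := (pos - 1L) %/% as.integer(block_size) + 1L]
  out <- dt[, .(level = mean(lvl), n_sites = .N), by = .(chrom, bin)]
  out[, `:=`(start = (bin - 1L) * as.integer(block_size) + 1L,
             end = bin * as.integer(block_size))]
  setkey(out, chrom, bin)
  out[, .(chrom, bin, start, end, level, n_sites)]
}

#' Assemble a samples-by-blocks methylation matrix
#'
#' Bins each sample's calls with [bin_methylation()] and aligns the bins
#' across samples; bins a sample does not cover are `NA`.
#'
#' @param call_list named list of `integrated_calls` tables, one per
#'   sample.
#' @inheritParams bin_methylation
#' @return a numeric matrix, blocks in rows (named `chrom:bin`), samples
#'   in columns.
#' @export
sample_block_matrix <- function(call_list, block_size = 10000L,
                                context = "CG", column = "wave") {
  if (is.null(names(call_list)) || any(names(call_list) == ""))
    stop("call_list must be a named list (one name per sample)")
  binned <- lapply(call_list, bin_methylation, block_size = block_size,
                   context = context, column = column)
  keys <- unique(rbindlist(lapply(binned, `[`, j = .(chrom, bin))))
  setkey(keys, chrom, bin)
  mat <- vapply(binned, function(b) b[keys, level, on = .(chrom, bin)],
                numeric(nrow(keys)))
  mat <- matrix(mat, nrow = nrow(keys),
                dimnames = list(paste0(keys$chrom, ":", keys$bin),
                                names(call_list)))
  mat
}

#' Spearman-correlation distance between samples
#'
#' `d(a, b) = 1 - rho_spearman(a, b)` computed on the blocks observed in
#' both samples of each pair (pairwise-complete; set
#' `complete_blocks = TRUE` to restrict every pair to blocks observed in
#' all samples). Ties receive average ranks. Distances lie in `[0, 2]`.
#'
#' @param mat blocks-by-samples matrix from [sample_block_matrix()].
#' @param complete_blocks drop blocks missing in any sample first.
#' @return a symmetric distance matrix with zero diagonal.
#' @export
spearman_distance_matrix <- function(mat, complete_blocks = FALSE) {
  if (ncol(mat) < 2L) stop("need at least two samples")
  if (complete_blocks) mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  rho <- suppressWarnings(
    cor(mat, method = "spearman", use = "pairwise.complete.obs"))
  d <- 1 - rho
  diag(d) <- 0
  d
}

#' Hierarchically cluster samples from a distance matrix
#'
#' Agglomerative clustering with configurable linkage (UPGMA / average by
#' default, the conventional choice for methylome dendrograms). Branch
#' lengths come from the merge heights.
#'
#' @param distmat symmetric distance matrix (e.g. from
#'   [spearman_distance_matrix()]).
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @return an `hclust` tree with samples as leaves.
#' @export
hierarchical_cluster <- function(distmat, linkage = "average") {
  linkage <- match.arg(linkage, c("average", "single", "complete"))
  hclust(as.dist(distmat), method = linkage)
}

#' Serialise a sample tree to Newick
#'
#' @param tree an `hclust` object from [hierarchical_cluster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Spearman correlations for chosen sample pairs
#'
#' @param mat blocks-by-samples matrix.
#' @param pairs two-column table (or matrix) of sample names.
#' @return a `data.table` (`sample_a, sample_b, rho, n_blocks`).
#' @export
correlation_report <- function(mat, pairs) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L) stop("pairs needs two columns of sample names")
  rbindlist(lapply(seq_len(nrow(pairs)), function(i) {
    a <- as.character(pairs[i, 1L]); b <- as.character(pairs[i, 2L])
    if (!a %in% colnames(mat) || !b %in% colnames(mat))
      stop("unknown sample in pair: ", a, " / ", b)
    ok <- !is.na(mat[, a]) & !is.na(mat[, b])
    data.table(sample_a = a, sample_b = b,
               rho = suppressWarnings(
                 cor(mat[ok, a], mat[ok, b], method = "spearman")),
               n_blocks = sum(ok))
  }))
}
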