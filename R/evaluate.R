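#' Mapping rate and mapping accuracy
#'
#' Mapping rate is the fraction of reads that mapped at all (correctly or
#' not) over all reads; mapping accuracy is the fraction of mapped reads
#' placed at their true origin.
#'
#' @param outcomes the per-read outcome table from [emulate_mapper()] (or
#'   any table with an `outcome` column of
#'   `"unmapped"`/`"correct"`/`"mismapped"`).
#' @return a proportion in `[0, 1]`.
#' @export
mapping_rate <- function(outcomes) {
  o <- outcomes$outcome
  if (length(o) == 0L) stop("mapping rate undefined for zero reads")
  sum(o != "unmapped") / length(o)
}

#' @rdname mapping_rate
#' @export
mapping_accuracy <- function(outcomes) {
  o <- outcomes$outcome
  n_mapped <- sum(o != "unmapped")
  if (n_mapped == 0L) stop("mapping accuracy undefined: no mapped reads")
  sum(o == "correct") / n_mapped
}

#' Detected block methylation levels
#'
#' The detected level of a block is the unweighted mean of the per-C
#' merged (or single-mapper) levels of the requested context class over
#' cytosines inside the block. Blocks without any covered cytosine of the
#' context get `NA` and are excluded from downstream accuracy averaging
#' (coverage shortfalls are measured by the detected amount instead).
#'
#' @param calls an `integrated_calls` table from [integrate_positions()],
#'   or any table with `chrom, pos, context` and the level column.
#' @param blocks block definitions (`block_id, chrom, start, end`), e.g.
#'   the `truth` table of a [make_reference()] object.
#' @param context `"CG"` or `"CH"` (CH pools CHG and CHH).
#' @param column which level column to summarise (`"ave"`, `"wave"`,
#'   `"pwave"`, or `"level"` for a single-mapper call table).
#' @return a `data.table` (`block_id, detected, n_sites`) with one row per
#'   block, `detected = NA` where no site was covered.
#' @export
block_detected_levels <- function(calls, blocks, context = "CG",
                                  column = "wave") {
  context <- match.arg(context, c("CG", "CH"))
  if (!column %in% names(calls)) {
    if (column == "level" && all(c("n_meth", "depth") %in% names(calls))) {
      calls <- copy(as.data.table(calls))[, level := n_meth / depth]
    } else stop("no such level column: ", column)
  }
  dt <- as.data.table(calls)
  keep <- collapse_context(dt$context) == context
  dt <- dt[which(keep)]
  blocks <- as.data.table(blocks)
  out <- blocks[, .(block_id, chrom, start, end)]
  if (nrow(dt) == 0L) {
    out[, `:=`(detected = NA_real_, n_sites = 0L)]
    return(out[, .(block_id, detected, n_sites)])
  }
  dt[, lvl := dt[[column]]]
  dt <- dt[blocks, on = .(chrom, pos >= start, pos <= end),
           .(block_id, lvl), nomatch = NULL]
  agg <- dt[, .(detected = mean(lvl), n_sites = .N), by = block_id]
  out <- agg[out[, .(block_id)], on = "block_id"]
  out[is.na(n_sites), n_sites := 0L]
  setkey(out, block_id)
  out[, .(block_id, detected, n_sites)]
}

#' Detection accuracy (d-accuracy)
#'
#' Per block, `100 * (1 - |true - detected|)` with levels on `[0, 1]`:
#' 100 means the detected block level equals the truth, 0 is the maximal
#' possible error. Blocks with an undefined detected level are dropped
#' from the mean.
#'
#' @param truth per-block true levels on `[0, 1]`.
#' @param detected per-block detected levels (`NA` allowed).
#' @return list with `per_block` (percent scale, `NA` where undefined),
#'   `mean` over defined blocks, and `n_blocks` used.
#' @export
d_accuracy <- function(truth, detected) {
  if (length(truth) != length(detected))
    stop("truth and detected must be paired per block")
  per_block <- 100 * (1 - abs(truth - detected))
  ok <- !is.na(per_block)
  list(per_block = per_block,
       mean = if (any(ok)) mean(per_block[ok]) else NA_real_,
       n_blocks = sum(ok))
}

#' Detected amount of cytosines (d-amount)
#'
#' The number of cytosine positions passing the depth threshold. For an
#' `integrated_calls` table the emission rule (`n_i >= k`, per-mapper
#' depth `>= min_depth`) was already applied, so every retained row
#' counts; for a single mapper's call set the depth filter is applied
#' here.
#'
#' @param x an `integrated_calls` table, a [mapper_call_set()], or a
#'   numeric vector of depths.
#' @param min_depth depth threshold.
#' @param ... unused.
#' @return a count.
#' @export
d_amount <- function(x, min_depth = 1L, ...) UseMethod("d_amount")

#' @export
d_amount.integrated_calls <- function(x, min_depth = 1L, ...) nrow(x)

#' @export
d_amount.mapper_call_set <- function(x, min_depth = 1L, ...)
  sum(x$calls$depth >= min_depth)

#' @export
d_amount.default <- function(x, min_depth = 1L, ...)
  sum(as.numeric(x) >= min_depth)

#' Paired one-sided Wilcoxon signed-rank test over blocks
#'
#' Tests whether the per-block d-accuracy of method `a` exceeds that of
#' method `b` (alternative `"greater"` by default). Zero differences are
#' dropped before ranking. The exact null distribution is used for up to
#' 25 non-zero untied pairs, the normal approximation with continuity
#' correction otherwise. If every difference is zero the test is
#' undefined and `p = 1` is returned with a warning.
#'
#' @param dacc_a,dacc_b equal-length per-block values over common blocks.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return the p-value.
#' @export
wilcoxon_paired <- function(dacc_a, dacc_b, alternative = "greater") {
  if (length(dacc_a) != length(dacc_b))
    stop("paired vectors must have equal length")
  ok <- !is.na(dacc_a) & !is.na(dacc_b)
  d <- dacc_a[ok] - dacc_b[ok]
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; signed-rank test undefined")
    return(1)
  }
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  wilcox.test(d, alternative = alternative, mu = 0, exact = exact,
              correct = TRUE)$p.value
}

#' Correlate d-accuracy with mapping rate and accuracy
#'
#' Pearson correlation of per-condition d-accuracy against mapping rate
#' and against mapping accuracy across evaluation report rows.
#'
#' @param reports a table with columns `d_accuracy`, `mapping_rate`,
#'   `mapping_accuracy` (one row per mapper x condition).
#' @return list with `r_mapping_rate` and `r_mapping_accuracy`.
#' @export
correlate_metrics <- function(reports) {
  need <- c("d_accuracy", "mapping_rate", "mapping_accuracy")
  if (!all(need %in% names(reports)))
    stop("reports must have columns: ", paste(need, collapse = ", "))
  for (v in need)
    if (sd(reports[[v]]) == 0)
      stop("zero variance in '", v, "': correlation undefined")
  list(r_mapping_rate = cor(reports$d_accuracy, reports$mapping_rate),
       r_mapping_accuracy = cor(reports$d_accuracy, reports$mapping_accuracy))
}

#' Mean read T density by mapping outcome
#'
#' Bisulfite conversion turns unmethylated Cs into Ts, so hypo-methylated
#' reads are T-rich; mappers that confuse converted Ts with genomic Ts
#' misplace exactly those reads. This summarises the mean per-read T
#' fraction within each mapping-outcome class.
#'
#' @param outcomes outcome table from [emulate_mapper()] (needs
#'   `outcome` and `t_fraction` columns).
#' @return a `data.table` (`outcome, mean_t_fraction, n_reads`).
#' @export
t_density_summary <- function(outcomes) {
  dt <- as.data.table(outcomes)
  dt[, .(mean_t_fraction = mean(t_fraction), n_reads = .N), by = outcome]
}

#' Score one mapper or consensus against block truth
#'
#' Convenience wrapper producing one evaluation row: d-accuracy of the
#' detected block levels against the realized truth, and the detected
#' amount, for a chosen context and level column.
#'
#' @param calls `integrated_calls` table or a [mapper_call_set()]'s
#'   `calls` (with `column = "level"`).
#' @param reference a [make_reference()] object.
#' @param realized the `realized` table of [generate_reads()].
#' @param context `"CG"` or `"CH"`.
#' @param column level column to score.
#' @param blocks optional subset of block ids (e.g. repeat blocks only).
#' @return list with `d_accuracy_mean`, `per_block`, `d_amount`,
#'   `n_blocks`.
#' @export
score_calls <- function(calls, reference, realized, context = "CG",
                        column = "wave", blocks = NULL) {
  truth <- reference$truth
  if (!is.null(blocks)) truth <- truth[block_id %in% blocks]
  det <- block_detected_levels(calls, truth, context = context,
                               column = column)
  tru <- realized[match(det$block_id, block_id),
                  if (context == "CG") realized_mcg else realized_mch]
  da <- d_accuracy(tru, det$detected)
  amount <- if (inherits(calls, "integrated_calls")) nrow(calls) else
    d_amount(calls$depth)
  list(d_accuracy_mean = da$mean, per_block = da$per_block,
       d_amount = amount, n_blocks = da$n_blocks)
}
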