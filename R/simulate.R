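.BASES <- c("A", "C", "G", "T")

#' Build a synthetic reference with block-wise methylation truth
#'
#' Generates a random A/C/G/T reference partitioned into consecutive
#' blocks of `block_size` bp. Each block is independently assigned a true
#' CpG and a true CpH methylation level drawn uniformly on `[0, 1]`. A
#' `repeat_fraction` of blocks carry near-identical copies of one shared
#' motif (2% per-base divergence between copies) and are flagged
#' `is_repeat`; they stand in for interspersed repeat elements, where
#' bisulfite mappers behave worst.
#'
#' Cytosine context (`CG`/`CHG`/`CHH`) is classified on the forward
#' strand from the two downstream bases; trailing cytosines without two
#' downstream bases default to `CHH`.
#'
#' @param n_blocks number of 500-bp-style blocks (>= 1).
#' @param block_size block length in bp.
#' @param repeat_fraction fraction of blocks built from the shared motif.
#' @param chrom reference sequence name.
#' @param seed integer seed; the same seed reproduces the reference and
#'   truth exactly.
#' @return an object of class `sim_reference`: list with `seq` (character
#'   vector of bases), `chrom`, `block_size`, `context` (per-position
#'   context, `NA` at non-C positions), `n_cytosines`, and `truth`, a
#'   `data.table` with one row per block
#'   (`block_id, chrom, start, end, true_mcg, true_mch, is_repeat`).
#' @export
make_reference <- function(n_blocks, block_size = 500L, repeat_fraction = 0.25,
                           chrom = "simchr", seed = 1L) {
  if (n_blocks < 1L) stop("n_blocks must be >= 1")
  if (block_size < 2L) stop("block_size must be >= 2")
  if (repeat_fraction < 0 || repeat_fraction > 1)
    stop("repeat_fraction must be in [0, 1]")
  set.seed(seed)
  n_blocks <- as.integer(n_blocks)
  block_size <- as.integer(block_size)

  n_rep <- as.integer(round(repeat_fraction * n_blocks))
  is_repeat <- rep(FALSE, n_blocks)
  if (n_rep > 0L) is_repeat[sample.int(n_blocks, n_rep)] <- TRUE

  seq <- sample(.BASES, n_blocks * block_size, replace = TRUE)
  if (n_rep > 0L) {
    motif <- sample(.BASES, block_size, replace = TRUE)
    for (b in which(is_repeat)) {
      copy <- motif
      mut <- runif(block_size) < 0.02
      if (any(mut))
        copy[mut] <- sample(.BASES, sum(mut), replace = TRUE)
      seq[((b - 1L) * block_size + 1L):(b * block_size)] <- copy
    }
  }

  truth <- data.table(
    block_id = seq_len(n_blocks),
    chrom = chrom,
    start = (seq_len(n_blocks) - 1L) * block_size + 1L,
    end = seq_len(n_blocks) * block_size,
    true_mcg = runif(n_blocks),
    true_mch = runif(n_blocks),
    is_repeat = is_repeat
  )

  ctx <- .classify_context(seq)
  structure(
    list(seq = seq, chrom = chrom, block_size = block_size,
         context = ctx, n_cytosines = sum(!is.na(ctx)), truth = truth),
    class = "sim_reference"
  )
}

.classify_context <- function(seq) {
  n <- length(seq)
  ctx <- rep(NA_character_, n)
  isC <- seq == "C"
  nxt1 <- c(seq[-1L], "N")
  nxt2 <- c(seq[-(1:2)], "N", "N")
  ctx[isC & nxt1 == "G"] <- "CG"
  ctx[isC & nxt1 != "G" & nxt2 == "G"] <- "CHG"
  ctx[isC & nxt1 != "G" & nxt2 != "G"] <- "CHH"
  ctx
}

#' Redraw the methylation truth of a reference
#'
#' Keeps the sequence, block coordinates and repeat flags but draws fresh
#' uniform CpG / CpH truth levels per block. Two references sharing a
#' sequence with independently drawn truth emulate two tissues profiled
#' on the same genome.
#'
#' @param reference a [make_reference()] object.
#' @param seed integer seed for the new truth draw.
#' @return a `sim_reference` with new `true_mcg` / `true_mch`.
#' @export
redraw_truth <- function(reference, seed) {
  stopifnot(inherits(reference, "sim_reference"))
  set.seed(seed)
  nb <- nrow(reference$truth)
  reference$truth$true_mcg <- runif(nb)
  reference$truth$true_mch <- runif(nb)
  reference
}

#' @export
print.sim_reference <- function(x, ...) {
  cat(sprintf(
    "<sim_reference> %s: %d bp, %d blocks of %d bp (%d repeat), %d cytosines\n",
    x$chrom, length(x$seq), nrow(x$truth), x$block_size,
    sum(x$truth$is_repeat), x$n_cytosines))
  invisible(x)
}

#' Simulate bisulfite-converted sequenced reads
#'
#' Draws `reads_per_block` forward-strand reads per block with uniformly
#' random start positions inside the block (reads never straddle block
#' boundaries, mirroring a generator fed each block as a separate
#' sequence). Each reference cytosine inside a read is kept as `C` with
#' probability equal to the block's true level for its context and
#' otherwise bisulfite-converted to `T`; sequencing errors then
#' substitute bases uniformly at `error_rate` per base.
#'
#' The per-position conversion outcomes are recorded: the evaluation
#' truth for a block is the *realized* conversion rate (the generator's
#' report of what was actually written into the reads), not the drawn
#' target, so finite-sampling noise in the generator never counts against
#' a mapper. The realized block level is the unweighted mean over the
#' block's covered cytosine positions of each position's conversion
#' fraction, matching how detected block levels are summarised.
#'
#' @param reference a [make_reference()] object.
#' @param read_length read length in bp (<= `block_size`).
#' @param reads_per_block reads per block; default
#'   `block_size * coverage / read_length` for 10x coverage (50 reads of
#'   100 bp, or 100 reads of 50 bp, per 500-bp block).
#' @param error_rate per-base substitution probability.
#' @param coverage target mean coverage used for the default
#'   `reads_per_block`.
#' @param seed integer seed.
#' @return an object of class `sim_reads`: list with `bases` (reads x
#'   read_length character matrix after conversion and errors), `start`,
#'   `block_id`, `n_errors`, `t_fraction` per read, the generation
#'   parameters, `realized` (per-block realized truth:
#'   `block_id, realized_mcg, realized_mch`) and `realized_sites`
#'   (per-position conversion outcomes).
#' @export
generate_reads <- function(reference, read_length, reads_per_block = NULL,
                           error_rate = 0, coverage = 10, seed = 1L) {
  stopifnot(inherits(reference, "sim_reference"))
  bs <- reference$block_size
  if (read_length > bs) stop("read_length must be <= block_size")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (is.null(reads_per_block))
    reads_per_block <- as.integer(round(bs * coverage / read_length))
  if (reads_per_block < 1L) stop("reads_per_block must be >= 1")
  set.seed(seed)

  L <- as.integer(read_length)
  truth <- reference$truth
  nb <- nrow(truth)
  n <- nb * reads_per_block
  block_id <- rep(truth$block_id, each = reads_per_block)
  start <- rep(truth$start, each = reads_per_block) +
    sample.int(bs - L + 1L, n, replace = TRUE) - 1L

  posmat <- outer(start, 0:(L - 1L), `+`)       # n x L reference positions
  bases <- matrix(reference$seq[posmat], nrow = n)

  # bisulfite conversion of unmethylated cytosines
  cmask <- bases == "C"
  cpos <- posmat[cmask]
  cctx <- reference$context[cpos]
  cblk <- rep(block_id, times = L)[cmask]
  p <- ifelse(cctx == "CG", truth$true_mcg[cblk], truth$true_mch[cblk])
  meth <- runif(length(p)) < p
  conv <- bases
  conv[cmask][!meth] <- "T"

  sites <- data.table(pos = cpos, context = cctx, block_id = cblk,
                      meth = meth)[
    , .(n = .N, n_meth = sum(meth)), by = .(block_id, pos, context)]
  sites[, level := n_meth / n]
  realized <- sites[, .(
    realized_mcg = if (any(context == "CG")) mean(level[context == "CG"])
                   else NA_real_,
    realized_mch = if (any(context != "CG")) mean(level[context != "CG"])
                   else NA_real_
  ), by = block_id]
  setkey(realized, block_id)

  # sequencing errors: uniform substitution to one of the other three bases
  n_errors <- integer(n)
  if (error_rate > 0) {
    emask <- matrix(runif(n * L) < error_rate, nrow = n)
    idx <- which(emask)
    if (length(idx)) {
      shift <- sample.int(3L, length(idx), replace = TRUE)
      cur <- match(conv[idx], .BASES)
      conv[idx] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
    n_errors <- as.integer(rowSums(emask))
  }

  structure(
    list(bases = conv, start = start, block_id = block_id,
         chrom = reference$chrom, strand = "+",
         read_length = L, error_rate = error_rate,
         reads_per_block = reads_per_block,
         n_errors = n_errors,
         t_fraction = rowMeans(conv == "T"),
         realized = realized, realized_sites = sites),
    class = "sim_reads"
  )
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf(
    "<sim_reads> %d reads of %d bp (%.0f%% error), %d blocks\n",
    nrow(x$bases), x$read_length, 100 * x$error_rate,
    length(unique(x$block_id))))
  invisible(x)
}

#' Parameterise an emulated bisulfite mapper
#'
#' The emulator decides each read's fate from a small linear-response
#' model clamped to `[0, 1]`:
#'
#' * probability of mapping at all:
#'   `base_map_rate - error_sensitivity * (errors / read length)
#'    - repeat_unmap_penalty * is_repeat`
#' * probability that a mapped read is misplaced:
#'   `mismap_rate_base + t_density_sensitivity * (T fraction of the read)
#'    + repeat_mismap_penalty * is_repeat`
#'
#' The T-density term reproduces the behaviour of aligners that confuse
#' bisulfite-converted Ts with genomic Ts: hypo-methylated (T-rich) reads
#' are misplaced more often.
#'
#' @param mapper_id label.
#' @param base_map_rate probability a clean read maps.
#' @param error_sensitivity decline of the mapping probability per unit
#'   read-error fraction.
#' @param mismap_rate_base baseline misplacement probability.
#' @param t_density_sensitivity increase of misplacement probability per
#'   unit T fraction.
#' @param repeat_unmap_penalty mapping-probability penalty inside repeat
#'   blocks.
#' @param repeat_mismap_penalty misplacement-probability increase inside
#'   repeat blocks.
#' @return an object of class `mapper_profile`.
#' @export
mapper_profile <- function(mapper_id, base_map_rate, error_sensitivity = 0,
                           mismap_rate_base = 0, t_density_sensitivity = 0,
                           repeat_unmap_penalty = 0,
                           repeat_mismap_penalty = 0) {
  if (base_map_rate < 0 || base_map_rate > 1)
    stop("base_map_rate must be in [0, 1]")
  if (mismap_rate_base < 0 || mismap_rate_base > 1)
    stop("mismap_rate_base must be in [0, 1]")
  if (error_sensitivity < 0 || t_density_sensitivity < 0 ||
      repeat_unmap_penalty < 0 || repeat_mismap_penalty < 0)
    stop("sensitivities and penalties must be >= 0")
  structure(
    list(mapper_id = mapper_id, base_map_rate = base_map_rate,
         error_sensitivity = error_sensitivity,
         mismap_rate_base = mismap_rate_base,
         t_density_sensitivity = t_density_sensitivity,
         repeat_unmap_penalty = repeat_unmap_penalty,
         repeat_mismap_penalty = repeat_mismap_penalty),
    class = "mapper_profile"
  )
}

#' Preset emulated mapper behaviours
#'
#' Three profiles capturing the qualitative behaviour reported for the
#' widely used bisulfite mappers:
#'
#' * `bismark-like` — three-letter mapper: very accurate, insensitive to
#'   read T density, moderate mapping rate that degrades with read error,
#'   and loses reads (rather than misplacing them) in repeats; its
#'   misplacement rate also creeps up at high error.
#' * `bsmap-like` — wild-card mapper: highest mapping rate on clean
#'   reads but the rate collapses as error rises; lowest accuracy, with
#'   misplacement increasing in T-rich reads and inside repeats.
#' * `bsseeker2-like` — local-alignment three-letter mapper: mapping
#'   rate and accuracy barely react to read error, but T-rich reads are
#'   misplaced and repeats lose reads.
#'
#' @return a named list of three [mapper_profile()] objects.
#' @export
preset_profiles <- function() {
  list(
    `bismark-like` = mapper_profile(
      "bismark-like", base_map_rate = 0.78, error_sensitivity = 5.5,
      mismap_rate_base = 0.01, t_density_sensitivity = 0,
      repeat_unmap_penalty = 0.30, repeat_mismap_penalty = 0.02),
    `bsmap-like` = mapper_profile(
      "bsmap-like", base_map_rate = 0.95, error_sensitivity = 8,
      mismap_rate_base = 0.04, t_density_sensitivity = 0.15,
      repeat_unmap_penalty = 0, repeat_mismap_penalty = 0.25),
    `bsseeker2-like` = mapper_profile(
      "bsseeker2-like", base_map_rate = 0.82, error_sensitivity = 0.8,
      mismap_rate_base = 0.03, t_density_sensitivity = 0.22,
      repeat_unmap_penalty = 0.20, repeat_mismap_penalty = 0.02)
  )
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

#' Emulate mapping of simulated reads by one mapper
#'
#' Each read independently ends up unmapped, mapped at its true origin,
#' or mapped at a uniformly chosen wrong start, with probabilities given
#' by the [mapper_profile()] evaluated on the read's realized error
#' count, its T fraction and whether its block is a repeat. Correctly
#' mapped reads pile their C/T observations onto the true reference
#' positions; misplaced reads pile theirs onto the wrong positions,
#' producing the noise calls that the consensus schemes are designed to
#' suppress. Observations are aggregated into a per-cytosine call set
#' (observed `C` counts as methylated, observed `T` as unmethylated,
#' other bases are ignored), and the per-read outcome labels are kept
#' for mapping-rate / mapping-accuracy scoring.
#'
#' @param reads a [generate_reads()] object.
#' @param reference the [make_reference()] object the reads came from.
#' @param profile a [mapper_profile()].
#' @param seed integer seed.
#' @return list with `callset` (a [mapper_call_set()], `lam` set over all
#'   reference cytosines) and `outcomes`, a `data.table` with one row per
#'   read (`read_id, block_id, outcome, n_errors, t_fraction,
#'   is_repeat`), `outcome` being `"unmapped"`, `"correct"` or
#'   `"mismapped"`.
#' @export
emulate_mapper <- function(reads, reference, profile, seed = 1L) {
  stopifnot(inherits(reads, "sim_reads"),
            inherits(reference, "sim_reference"),
            inherits(profile, "mapper_profile"))
  set.seed(seed)
  n <- nrow(reads$bases)
  L <- reads$read_length
  is_rep <- reference$truth$is_repeat[reads$block_id]

  p_map <- .clamp01(profile$base_map_rate -
                      profile$error_sensitivity * (reads$n_errors / L) -
                      profile$repeat_unmap_penalty * is_rep)
  mapped <- runif(n) < p_map
  p_mis <- .clamp01(profile$mismap_rate_base +
                      profile$t_density_sensitivity * reads$t_fraction +
                      profile$repeat_mismap_penalty * is_rep)
  mis <- mapped & (runif(n) < p_mis)
  outcome <- ifelse(!mapped, "unmapped", ifelse(mis, "mismapped", "correct"))

  final_start <- reads$start
  if (any(mis))
    final_start[mis] <- sample.int(length(reference$seq) - L + 1L, sum(mis),
                                   replace = TRUE)

  keep <- which(mapped)
  if (length(keep)) {
    posmat <- outer(final_start[keep], 0:(L - 1L), `+`)
    obs <- reads$bases[keep, , drop = FALSE]
    cmask <- matrix(reference$seq[posmat] == "C", nrow = length(keep))
    pos <- posmat[cmask]
    base <- obs[cmask]
    informative <- base %in% c("C", "T")
    tab <- data.table(pos = pos[informative], meth = base[informative] == "C")[
      , .(n_meth = sum(meth), depth = .N), by = pos]
    calls <- cytosine_calls(
      chrom = reads$chrom, pos = tab$pos, strand = "+",
      context = reference$context[tab$pos],
      n_meth = tab$n_meth, n_unmeth = tab$depth - tab$n_meth)
  } else {
    calls <- .empty_calls()
  }

  cs <- mapper_call_set(profile$mapper_id, calls, meta = "emulated")
  cs <- set_lambda(cs, reference$n_cytosines)
  outcomes <- data.table(
    read_id = seq_len(n), block_id = reads$block_id, outcome = outcome,
    n_errors = reads$n_errors, t_fraction = reads$t_fraction,
    is_repeat = is_rep)
  list(callset = cs, outcomes = outcomes)
}

#' Export the synthetic reference / reads for use with real mappers
#'
#' `export_reference_fasta` writes the reference as FASTA (via Biostrings
#' when available). `export_reads_fastq` writes the simulated reads as
#' FASTQ with constant quality and the true origin encoded in each read
#' name as `read<id>:<chrom>:<start>:<strand>`, so alignments produced by
#' an external mapper can be scored for mapping accuracy.
#'
#' @param reference a [make_reference()] object.
#' @param reads a [generate_reads()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_reference_fasta <- function(reference, path) {
  s <- paste(reference$seq, collapse = "")
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::DNAStringSet(setNames(s, reference$chrom))
    Biostrings::writeXStringSet(x, path)
  } else {
    writeLines(c(paste0(">", reference$chrom), s), path)
  }
  invisible(path)
}

#' @rdname export_reference_fasta
#' @export
export_reads_fastq <- function(reads, path) {
  n <- nrow(reads$bases)
  seqs <- apply(reads$bases, 1L, paste, collapse = "")
  qual <- strrep("I", reads$read_length)
  rec <- character(4L * n)
  rec[seq(1L, by = 4L, length.out = n)] <-
    sprintf("@read%d:%s:%d:%s", seq_len(n), reads$chrom, reads$start,
            reads$strand)
  rec[seq(2L, by = 4L, length.out = n)] <- seqs
  rec[seq(3L, by = 4L, length.out = n)] <- "+"
  rec[seq(4L, by = 4L, length.out = n)] <- qual
  writeLines(rec, path)
  invisible(path)
}
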