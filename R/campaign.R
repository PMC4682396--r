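#' Configure a simulation benchmark campaign
#'
#' A campaign is a full-factorial sweep over read lengths and read error
#' rates with several replicates per cell, mirroring the standard design
#' for stress-testing bisulfite mappers: long (100 bp) and short (50 bp)
#' reads, error rates 0-8% in 2% steps, 10 replicates — 100 read sets.
#' Reads per block are set so every condition has the same target mean
#' coverage (10x by default: 50 reads of 100 bp or 100 reads of 50 bp
#' per 500-bp block).
#'
#' @param n_blocks number of 500-bp truth blocks in the synthetic
#'   reference.
#' @param block_size block size in bp.
#' @param read_lengths read lengths (bp) to sweep.
#' @param error_rates per-base error rates to sweep.
#' @param replicates read-set replicates per (length, error) cell.
#' @param coverage target mean read coverage per condition.
#' @param repeat_fraction fraction of repeat blocks in the reference.
#' @param profiles named list of [mapper_profile()] objects to emulate.
#' @param min_mappers consensus coverage constraint `k`.
#' @param min_depth per-mapper depth threshold `d`.
#' @param seed master integer seed; all per-condition seeds derive from
#'   it.
#' @return a `campaign_config` list.
#' @export
campaign_config <- function(n_blocks = 200L, block_size = 500L,
                            read_lengths = c(100L, 50L),
                            error_rates = c(0, 0.02, 0.04, 0.06, 0.08),
                            replicates = 10L, coverage = 10,
                            repeat_fraction = 0.25,
                            profiles = preset_profiles(),
                            min_mappers = 2L, min_depth = 1L, seed = 1L) {
  stopifnot(n_blocks >= 1L, block_size >= 2L, replicates >= 1L,
            length(read_lengths) >= 1L, length(error_rates) >= 1L,
            all(read_lengths >= 1L), all(read_lengths <= block_size),
            all(error_rates >= 0), all(error_rates <= 1),
            min_mappers >= 1L, min_depth >= 1L)
  structure(
    list(n_blocks = as.integer(n_blocks), block_size = as.integer(block_size),
         read_lengths = as.integer(read_lengths), error_rates = error_rates,
         replicates = as.integer(replicates), coverage = coverage,
         repeat_fraction = repeat_fraction, profiles = profiles,
         min_mappers = as.integer(min_mappers),
         min_depth = as.integer(min_depth), seed = as.integer(seed)),
    class = "campaign_config"
  )
}

#' Enumerate the read-set conditions of a campaign
#'
#' @param config a [campaign_config()].
#' @return a `data.table` with one row per read set
#'   (`read_length, error_rate, replicate, reads_per_block, seed`); the
#'   default design has `2 x 5 x 10 = 100` rows.
#' @export
campaign_design <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  g <- CJ(replicate = seq_len(config$replicates),
          error_rate = config$error_rates,
          read_length = config$read_lengths, sorted = FALSE)
  setcolorder(g, c("read_length", "error_rate", "replicate"))
  setorder(g, read_length, error_rate, replicate)
  g[, reads_per_block :=
        as.integer(round(config$block_size * config$coverage / read_length))]
  g[, seed := (config$seed + 7919L * .I) %% .Machine$integer.max]
  g[]
}

#' Run one read-set condition through emulation, consensus and scoring
#'
#' Generates one read set, emulates every configured mapper, merges the
#' call sets with all three consensus schemes, and scores everything
#' against the realized block truth.
#'
#' @param reference a [make_reference()] object.
#' @param config a [campaign_config()].
#' @param read_length,error_rate,reads_per_block,seed condition
#'   parameters (one [campaign_design()] row).
#' @return list with `report` (one `data.table` row per mapper and per
#'   consensus method: mapping rate/accuracy, CpG and CpH d-accuracy,
#'   d-amount) and `per_block`, a blocks-by-methods matrix of per-block
#'   CpG d-accuracies for paired tests.
#' @export
run_condition <- function(reference, config, read_length, error_rate,
                          reads_per_block = NULL, seed = 1L) {
  reads <- generate_reads(reference, read_length,
                          reads_per_block = reads_per_block,
                          error_rate = error_rate,
                          coverage = config$coverage, seed = seed)
  emu <- lapply(seq_along(config$profiles), function(i)
    emulate_mapper(reads, reference, config$profiles[[i]], seed = seed + i))
  names(emu) <- vapply(config$profiles, `[[`, "", "mapper_id")
  callsets <- lapply(emu, `[[`, "callset")

  integrated <- integrate_positions(callsets, method = "all",
                                    min_mappers = config$min_mappers,
                                    min_depth = config$min_depth)
  nb <- nrow(reference$truth)
  per_block <- matrix(NA_real_, nrow = nb,
                      ncol = length(emu) + 3L,
                      dimnames = list(NULL, c(names(emu),
                                              c("ave", "wave", "pwave"))))
  rows <- list()
  for (m in names(emu)) {
    calls <- emu[[m]]$callset$calls[depth >= config$min_depth]
    sc <- score_calls(calls, reference, reads$realized, context = "CG",
                      column = "level")
    sc_ch <- score_calls(calls, reference, reads$realized, context = "CH",
                         column = "level")
    per_block[, m] <- sc$per_block
    rows[[m]] <- data.table(
      method = m, kind = "mapper",
      mapping_rate = mapping_rate(emu[[m]]$outcomes),
      mapping_accuracy = mapping_accuracy(emu[[m]]$outcomes),
      d_accuracy_cg = sc$d_accuracy_mean, d_accuracy_ch = sc_ch$d_accuracy_mean,
      d_amount = d_amount(emu[[m]]$callset, config$min_depth))
  }
  for (m in c("ave", "wave", "pwave")) {
    sc <- score_calls(integrated, reference, reads$realized, context = "CG",
                      column = m)
    sc_ch <- score_calls(integrated, reference, reads$realized,
                         context = "CH", column = m)
    per_block[, m] <- sc$per_block
    rows[[m]] <- data.table(
      method = m, kind = "consensus",
      mapping_rate = NA_real_, mapping_accuracy = NA_real_,
      d_accuracy_cg = sc$d_accuracy_mean, d_accuracy_ch = sc_ch$d_accuracy_mean,
      d_amount = d_amount(integrated))
  }
  report <- rbindlist(rows)
  report[, `:=`(read_length = read_length, error_rate = error_rate,
                seed = seed)]
  list(report = report, per_block = per_block, integrated = integrated,
       callsets = callsets, reads = reads)
}

#' Run a full campaign
#'
#' Executes every condition of [campaign_design()] on one shared
#' synthetic reference and stacks the per-condition reports.
#'
#' @param config a [campaign_config()].
#' @param keep_per_block also return the per-block d-accuracy matrices.
#' @param quiet suppress progress messages.
#' @return a `data.table` with one row per condition x method
#'   (`read_length, error_rate, replicate, seed, method, kind,
#'   mapping_rate, mapping_accuracy, d_accuracy_cg, d_accuracy_ch,
#'   d_amount`); when `keep_per_block` is `TRUE`, a list with `report`
#'   and `per_block`.
#' @export
run_campaign <- function(config, keep_per_block = FALSE, quiet = TRUE) {
  stopifnot(inherits(config, "campaign_config"))
  reference <- make_reference(config$n_blocks, config$block_size,
                              config$repeat_fraction, seed = config$seed)
  design <- campaign_design(config)
  out <- vector("list", nrow(design))
  pb <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    d <- design[i]
    if (!quiet)
      message(sprintf("condition %d/%d: L=%d e=%.2f rep=%d", i, nrow(design),
                      d$read_length, d$error_rate, d$replicate))
    res <- run_condition(reference, config, d$read_length, d$error_rate,
                         d$reads_per_block, seed = d$seed)
    res$report[, replicate := d$replicate]
    out[[i]] <- res$report
    if (keep_per_block) pb[[i]] <- res$per_block
  }
  report <- rbindlist(out)
  setcolorder(report, c("read_length", "error_rate", "replicate", "seed",
                        "method", "kind"))
  if (keep_per_block) list(report = report, per_block = pb) else report
}

#' Simulate a two-tissue, two-condition sample cohort
#'
#' Builds one reference sequence, assigns two independent block-wise
#' methylation truths ("tissues" A and B), and profiles each tissue under
#' each read condition with the emulated mappers followed by consensus
#' merging — four samples in which tissue identity and read condition are
#' fully crossed. A clustering that recovers tissue, not read condition,
#' demonstrates that the consensus removed the read-condition signature.
#'
#' @param n_blocks,block_size reference geometry.
#' @param conditions list of `c(read_length, error_rate)` pairs (two by
#'   default: clean long reads vs error-laden short reads).
#' @param profiles named list of [mapper_profile()]s.
#' @param min_mappers,min_depth consensus constraints.
#' @param method consensus level column to keep.
#' @param seed integer seed.
#' @return list with `calls` (named list of `integrated_calls`, names
#'   like `A_cond1`), `tissue` (named character vector of tissue labels)
#'   and `reference_a`, `reference_b`.
#' @export
simulate_cohort <- function(n_blocks = 60L, block_size = 500L,
                            conditions = list(c(100L, 0), c(50L, 0.08)),
                            profiles = preset_profiles(),
                            min_mappers = 2L, min_depth = 1L,
                            method = "wave", seed = 1L) {
  ref_a <- make_reference(n_blocks, block_size, seed = seed)
  ref_b <- redraw_truth(ref_a, seed = seed + 104729L)
  refs <- list(A = ref_a, B = ref_b)
  calls <- list()
  tissue <- character()
  for (ti in names(refs)) {
    for (ci in seq_along(conditions)) {
      cnd <- conditions[[ci]]
      s <- seed + 37L * ci + 1000L * match(ti, names(refs))
      reads <- generate_reads(refs[[ti]], cnd[1L], error_rate = cnd[2L],
                              seed = s)
      emu <- lapply(seq_along(profiles), function(i)
        emulate_mapper(reads, refs[[ti]], profiles[[i]], seed = s + i))
      cs <- lapply(emu, `[[`, "callset")
      id <- sprintf("%s_cond%d", ti, ci)
      calls[[id]] <- integrate_positions(cs, method = method,
                                         min_mappers = min_mappers,
                                         min_depth = min_depth)
      tissue[id] <- ti
    }
  }
  list(calls = calls, tissue = tissue, reference_a = ref_a,
       reference_b = ref_b)
}

# ---- file-level commands (the CLI surface) ---------------------------------

.write_manifest <- function(out_dir, config_lines) {
  cfg_path <- file.path(out_dir, "config.txt")
  writeLines(config_lines, cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  writeLines(c(paste0("config_md5=", hash),
               paste0("created=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             file.path(out_dir, "manifest.txt"))
  invisible(hash)
}

.config_lines <- function(config) {
  c(sprintf("n_blocks=%d", config$n_blocks),
    sprintf("block_size=%d", config$block_size),
    sprintf("read_lengths=%s", paste(config$read_lengths, collapse = ",")),
    sprintf("error_rates=%s", paste(config$error_rates, collapse = ",")),
    sprintf("replicates=%d", config$replicates),
    sprintf("coverage=%g", config$coverage),
    sprintf("repeat_fraction=%g", config$repeat_fraction),
    sprintf("profiles=%s", paste(names(config$profiles), collapse = ",")),
    sprintf("min_mappers=%d", config$min_mappers),
    sprintf("min_depth=%d", config$min_depth),
    sprintf("seed=%d", config$seed))
}

#' Simulate one read set and emulated call sets to disk
#'
#' Writes the synthetic reference (FASTA), the block truth (drawn and
#' realized levels, TSV), one unified call TSV and one outcome TSV per
#' emulated mapper, and a manifest recording the configuration hash.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [campaign_config()]; the first read length / error
#'   rate are used unless overridden.
#' @param read_length,error_rate condition overrides.
#' @param quiet suppress INFO messages.
#' @return invisibly, the named vector of written file paths.
#' @export
cmd_simulate <- function(out_dir, config = campaign_config(),
                         read_length = config$read_lengths[1L],
                         error_rate = config$error_rates[1L],
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- make_reference(config$n_blocks, config$block_size,
                              config$repeat_fraction, seed = config$seed)
  reads <- generate_reads(reference, read_length, error_rate = error_rate,
                          coverage = config$coverage, seed = config$seed)
  paths <- c(reference = file.path(out_dir, "reference.fa"),
             truth = file.path(out_dir, "truth.tsv"))
  export_reference_fasta(reference, paths[["reference"]])
  truth <- merge(reference$truth, reads$realized, by = "block_id")
  fwrite(truth, paths[["truth"]], sep = "\t")
  for (i in seq_along(config$profiles)) {
    pr <- config$profiles[[i]]
    emu <- emulate_mapper(reads, reference, pr, seed = config$seed + i)
    cp <- file.path(out_dir, paste0("calls_", pr$mapper_id, ".tsv"))
    op <- file.path(out_dir, paste0("outcomes_", pr$mapper_id, ".tsv"))
    write_unified(emu$callset, cp)
    fwrite(emu$outcomes, op, sep = "\t")
    paths[paste0("calls_", pr$mapper_id)] <- cp
    paths[paste0("outcomes_", pr$mapper_id)] <- op
    if (!quiet)
      message(sprintf("INFO %s: lambda=%.3f, %d calls, mapping rate %.3f",
                      pr$mapper_id, emu$callset$lam, nrow(emu$callset$calls),
                      mapping_rate(emu$outcomes)))
  }
  .write_manifest(out_dir, c(.config_lines(config),
                             sprintf("read_length=%d", read_length),
                             sprintf("error_rate=%g", error_rate)))
  invisible(paths)
}

#' Merge unified call files into a consensus TSV
#'
#' @param call_files paths to unified call TSVs (one per mapper).
#' @param out output TSV path.
#' @param method `"ave"`, `"wave"`, `"pwave"` or `"all"`.
#' @param min_mappers,min_depth consensus constraints.
#' @param n_reference_cytosines reference cytosine count used to (re)set
#'   each mapper's lambda; when `NULL` the lambda stored in each file is
#'   kept.
#' @param quiet suppress INFO messages.
#' @return `out`, invisibly.
#' @export
cmd_integrate <- function(call_files, out, method = "all", min_mappers = 2L,
                          min_depth = 1L, n_reference_cytosines = NULL,
                          quiet = FALSE) {
  if (length(call_files) < 1L) stop("need at least one call file")
  callsets <- lapply(call_files, read_unified)
  if (!is.null(n_reference_cytosines))
    callsets <- lapply(callsets, set_lambda, n_reference_cytosines)
  res <- integrate_positions(callsets, method = method,
                             min_mappers = min_mappers, min_depth = min_depth)
  if (!quiet)
    message(sprintf("INFO integrated %d mappers -> %d positions (k>=%d, d>=%d)",
                    length(callsets), nrow(res), min_mappers, min_depth))
  write_integrated(res, out)
  invisible(out)
}

#' Read back an integrated-calls TSV
#'
#' @param path a TSV written by [write_integrated()].
#' @return an `integrated_calls` table.
#' @export
read_integrated <- function(path) {
  dt <- fread(path, sep = "\t",
              colClasses = list(character = c("chrom", "strand", "context")),
              showProgress = FALSE)
  setattr(dt, "class", c("integrated_calls", class(dt)))
  dt[]
}

#' Score call files against a truth table on disk
#'
#' @param truth_file truth TSV written by [cmd_simulate()].
#' @param integrated_file integrated TSV from [cmd_integrate()].
#' @param call_files,outcome_files per-mapper unified call and outcome
#'   TSVs (matched by order).
#' @param out report TSV path.
#' @param min_depth single-mapper depth threshold.
#' @return the report `data.table`, invisibly; written to `out`.
#' @export
cmd_evaluate <- function(truth_file, integrated_file, call_files,
                         outcome_files, out, min_depth = 1L) {
  truth <- fread(truth_file, sep = "\t", showProgress = FALSE)
  realized <- truth[, .(block_id, realized_mcg, realized_mch)]
  setkey(realized, block_id)
  reference <- list(truth = truth)  # block coordinates only
  rows <- list()
  for (i in seq_along(call_files)) {
    cs <- read_unified(call_files[i])
    oc <- fread(outcome_files[i], sep = "\t", showProgress = FALSE)
    calls <- cs$calls[depth >= min_depth]
    sc <- score_calls(calls, reference, realized, "CG", "level")
    sc_ch <- score_calls(calls, reference, realized, "CH", "level")
    rows[[i]] <- data.table(
      method = cs$mapper_id, kind = "mapper",
      mapping_rate = mapping_rate(oc), mapping_accuracy = mapping_accuracy(oc),
      d_accuracy_cg = sc$d_accuracy_mean, d_accuracy_ch = sc_ch$d_accuracy_mean,
      d_amount = d_amount(cs, min_depth))
  }
  integrated <- read_integrated(integrated_file)
  for (m in intersect(c("ave", "wave", "pwave"), names(integrated))) {
    sc <- score_calls(integrated, reference, realized, "CG", m)
    sc_ch <- score_calls(integrated, reference, realized, "CH", m)
    rows[[length(rows) + 1L]] <- data.table(
      method = m, kind = "consensus",
      mapping_rate = NA_real_, mapping_accuracy = NA_real_,
      d_accuracy_cg = sc$d_accuracy_mean, d_accuracy_ch = sc_ch$d_accuracy_mean,
      d_amount = nrow(integrated))
  }
  report <- rbindlist(rows)
  fwrite(report, out, sep = "\t")
  invisible(report)
}

#' Cluster sample methylomes from integrated TSVs
#'
#' @param sample_files named character vector of integrated TSV paths.
#' @param out_prefix output prefix; writes `<prefix>_dist.tsv` and
#'   `<prefix>.nwk`.
#' @param block_size bin width in bp.
#' @param context `"CG"` or `"CH"`.
#' @param column level column to bin.
#' @param linkage clustering linkage.
#' @return list with `dist` and `tree`, invisibly.
#' @export
cmd_compare <- function(sample_files, out_prefix, block_size = 10000L,
                        context = "CG", column = "wave",
                        linkage = "average") {
  if (is.null(names(sample_files)) || any(names(sample_files) == ""))
    stop("sample_files must be named by sample")
  calls <- lapply(sample_files, read_integrated)
  mat <- sample_block_matrix(calls, block_size = block_size,
                             context = context, column = column)
  d <- spearman_distance_matrix(mat)
  tree <- hierarchical_cluster(d, linkage = linkage)
  dt <- data.table(sample = rownames(d))
  fwrite(cbind(dt, as.data.table(d)), paste0(out_prefix, "_dist.tsv"),
         sep = "\t")
  write_newick(tree, paste0(out_prefix, ".nwk"))
  invisible(list(dist = d, tree = tree))
}
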