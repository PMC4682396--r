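#' @import data.table
#' @importFrom stats cor dpois rbinom runif sd setNames wilcox.test as.dist
#'   cutree hclust var aggregate
#' @importFrom utils write.table
NULL

.CALL_COLS <- c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth", "depth")
.CONTEXTS <- c("CG", "CHG", "CHH")
.UNIFIED_VERSION <- "bsmerge/1"

#' Construct a per-cytosine call table
#'
#' Builds and validates the internal per-cytosine call representation shared
#' by every reader: one row per (chrom, pos, strand) giving the number of
#' reads observing an unconverted C (`n_meth`), a converted T (`n_unmeth`)
#' and their total (`depth`). Coordinates are 1-based and strand-specific;
#' `context` is one of `CG`, `CHG`, `CHH`.
#'
#' @param chrom character, reference sequence name.
#' @param pos integer, 1-based position of the cytosine on its strand.
#' @param strand character, `"+"` or `"-"`.
#' @param context character, `"CG"`, `"CHG"` or `"CHH"`.
#' @param n_meth integer, reads reporting C (methylated).
#' @param n_unmeth integer, reads reporting T (unmethylated).
#' @return a `data.table` with columns
#'   `chrom, pos, strand, context, n_meth, n_unmeth, depth`.
#' @export
cytosine_calls <- function(chrom, pos, strand, context, n_meth, n_unmeth) {
  dt <- data.table(
    chrom = as.character(chrom), pos = as.integer(pos),
    strand = as.character(strand), context = as.character(context),
    n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth)
  )
  dt[, depth := n_meth + n_unmeth]
  validate_calls(dt)
  dt
}

validate_calls <- function(dt) {
  if (!all(.CALL_COLS %in% names(dt)))
    stop("call table missing columns: ",
         paste(setdiff(.CALL_COLS, names(dt)), collapse = ", "))
  if (nrow(dt) == 0L) return(invisible(dt))
  if (anyNA(dt$pos) || any(dt$pos < 1L))
    stop("positions must be 1-based integers >= 1")
  if (!all(dt$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(dt$context %in% .CONTEXTS))
    stop("context must be one of ", paste(.CONTEXTS, collapse = ", "))
  if (any(dt$n_meth < 0L) || any(dt$n_unmeth < 0L))
    stop("negative read counts")
  if (any(dt$depth != dt$n_meth + dt$n_unmeth))
    stop("depth must equal n_meth + n_unmeth")
  invisible(dt)
}

#' Bundle calls from one mapper into a call set
#'
#' A `mapper_call_set` holds all per-cytosine calls of one mapper together
#' with the mapper's genome-wide mean read depth `lam` (the Poisson
#' parameter used by the pwAve weighting) and a source-format tag.
#' Duplicate (chrom, pos, strand) keys are rejected: a position missing
#' from a mapper is represented by the absence of a row, never by a
#' zero-depth record.
#'
#' @param mapper_id label for the mapper (e.g. `"bismark"`).
#' @param calls a call table as built by [cytosine_calls()].
#' @param lam mean read depth of this mapper over the reference (`NA` to
#'   fill in later via [estimate_lambda()]).
#' @param meta source-format tag.
#' @return an object of class `mapper_call_set`.
#' @export
mapper_call_set <- function(mapper_id, calls, lam = NA_real_, meta = "unified") {
  validate_calls(calls)
  if (anyDuplicated(calls, by = c("chrom", "pos", "strand")))
    stop("duplicate (chrom, pos, strand) keys in call set '", mapper_id, "'")
  if (!is.na(lam) && lam < 0) stop("lam must be >= 0")
  structure(
    list(mapper_id = as.character(mapper_id), calls = calls,
         lam = as.numeric(lam), meta = as.character(meta)),
    class = "mapper_call_set"
  )
}

#' @export
print.mapper_call_set <- function(x, ...) {
  cat(sprintf("<mapper_call_set> %s: %d calls, lambda = %s (%s)\n",
              x$mapper_id, nrow(x$calls),
              ifelse(is.na(x$lam), "unset", format(x$lam)), x$meta))
  invisible(x)
}

.read_tsv <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  if (file.size(path) == 0L) return(data.table())
  fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1),
        showProgress = FALSE)
}

.stop_line <- function(path, i, why) {
  stop(sprintf("malformed line %d in %s: %s", i, path, why), call. = FALSE)
}

#' Read a BS-seeker2 CGmap file
#'
#' CGmap columns: chrom, nucleotide (C on the Watson strand, G on Crick),
#' 1-based position, context (CG/CHG/CHH), dinucleotide context, methylation
#' level, methylated count, total count. Strand is inferred from the
#' nucleotide column (C is `+`, G is `-`).
#'
#' @param path file path.
#' @param mapper_id label attached to the resulting call set.
#' @return a [mapper_call_set()] with `lam` unset.
#' @export
read_cgmap <- function(path, mapper_id = "bsseeker2") {
  dt <- .read_tsv(path, "CGmap")
  if (nrow(dt) == 0L)
    return(mapper_call_set(mapper_id, .empty_calls(), lam = 0, meta = "cgmap"))
  if (ncol(dt) < 8L) stop("CGmap file needs 8 columns: ", path)
  setnames(dt, 1:8, c("chrom", "nuc", "pos", "context", "dinuc", "level",
                      "n_meth", "tot"))
  bad <- which(!dt$nuc %in% c("C", "G"))
  if (length(bad)) .stop_line(path, bad[1L], "nucleotide column must be C or G")
  bad <- which(dt$tot < dt$n_meth)
  if (length(bad)) .stop_line(path, bad[1L], "total count < methylated count")
  out <- cytosine_calls(
    chrom = dt$chrom, pos = dt$pos,
    strand = ifelse(dt$nuc == "C", "+", "-"),
    context = dt$context, n_meth = dt$n_meth, n_unmeth = dt$tot - dt$n_meth
  )
  mapper_call_set(mapper_id, out, meta = "cgmap")
}

#' Read a Bismark genome-wide cytosine report
#'
#' Columns: chrom, 1-based position, strand, count methylated, count
#' unmethylated, context, trinucleotide context. Positions with zero
#' coverage are kept as depth-0 rows by Bismark; they are preserved here
#' and excluded later by the integration's depth filter.
#'
#' @inheritParams read_cgmap
#' @return a [mapper_call_set()] with `lam` unset.
#' @export
read_bismark_report <- function(path, mapper_id = "bismark") {
  dt <- .read_tsv(path, "Bismark cytosine report")
  if (nrow(dt) == 0L) {
    return(mapper_call_set(mapper_id, .empty_calls(), lam = 0,
                           meta = "bismark_report"))
  }
  if (ncol(dt) < 6L) stop("Bismark cytosine report needs >= 6 columns: ", path)
  setnames(dt, 1:6, c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context"))
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad)) .stop_line(path, bad[1L], "strand must be + or -")
  out <- cytosine_calls(dt$chrom, dt$pos, dt$strand, dt$context,
                        dt$n_meth, dt$n_unmeth)
  mapper_call_set(mapper_id, out, meta = "bismark_report")
}

#' Read a Bismark coverage (.cov) file
#'
#' Columns: chrom, start, end (start == end, 1-based), methylation
#' percentage, count methylated, count unmethylated. The coverage format
#' carries neither strand nor context; Bismark emits it for CpG calls, so
#' rows are labelled context `CG` on strand `+` by convention.
#'
#' @inheritParams read_cgmap
#' @return a [mapper_call_set()] with `lam` unset.
#' @export
read_bismark_cov <- function(path, mapper_id = "bismark") {
  dt <- .read_tsv(path, "Bismark coverage")
  if (nrow(dt) == 0L) {
    return(mapper_call_set(mapper_id, .empty_calls(), lam = 0,
                           meta = "bismark_cov"))
  }
  if (ncol(dt) < 6L) stop("Bismark coverage file needs 6 columns: ", path)
  setnames(dt, 1:6, c("chrom", "start", "end", "pct", "n_meth", "n_unmeth"))
  out <- cytosine_calls(dt$chrom, dt$start, "+", "CG", dt$n_meth, dt$n_unmeth)
  mapper_call_set(mapper_id, out, meta = "bismark_cov")
}

#' Read a BSMAP methratio table
#'
#' methratio.py TSV with a header line: chr, pos, strand, context, ratio,
#' eff_CT_count, C_count, CT_count, ... Methylated reads come from
#' `C_count` and depth from the integer `CT_count` column; the fractional
#' `eff_CT_count` (adjusted for SNPs) is deliberately ignored so that
#' depths stay integral.
#'
#' BSMAP reports context as the surrounding 4-mer (e.g. `ACGT`); the
#' centre dinucleotide/trinucleotide is collapsed to CG/CHG/CHH here.
#'
#' @inheritParams read_cgmap
#' @return a [mapper_call_set()] with `lam` unset.
#' @export
read_methratio <- function(path, mapper_id = "bsmap") {
  if (!file.exists(path)) stop("methratio file not found: ", path)
  dt <- fread(path, header = TRUE, sep = "\t", showProgress = FALSE,
              colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    return(mapper_call_set(mapper_id, .empty_calls(), lam = 0,
                           meta = "methratio"))
  }
  nm <- tolower(names(dt))
  need <- c("chr", "pos", "strand", "context", "c_count", "ct_count")
  if (!all(need %in% nm))
    stop("methratio file missing columns: ",
         paste(setdiff(need, nm), collapse = ", "))
  setnames(dt, names(dt), nm)
  ctx <- .collapse_bsmap_context(dt$context)
  n_meth <- as.integer(round(dt$c_count))
  depth <- as.integer(round(dt$ct_count))
  bad <- which(depth < n_meth)
  if (length(bad)) .stop_line(path, bad[1L] + 1L, "CT_count < C_count")
  out <- cytosine_calls(dt$chr, dt$pos, dt$strand, ctx, n_meth, depth - n_meth)
  mapper_call_set(mapper_id, out, meta = "methratio")
}

# BSMAP context k-mer centred on the C (5-mer in methratio output)
# -> CG/CHG/CHH from the two downstream bases
.collapse_bsmap_context <- function(x) {
  ifelse(x %in% .CONTEXTS, x, {
    mid <- (nchar(x) + 1L) %/% 2L
    d1 <- substr(x, mid + 1L, mid + 1L)
    d2 <- substr(x, mid + 2L, mid + 2L)
    ifelse(d1 == "G", "CG", ifelse(d2 == "G", "CHG", "CHH"))
  })
}

.empty_calls <- function() {
  cytosine_calls(character(), integer(), character(), character(),
                 integer(), integer())
}

#' Write / read the unified call format
#'
#' Tab-separated, 1-based, one row per cytosine with all
#' [cytosine_calls()] columns; `mapper_id`, `lam` and a format version are
#' stored in `#key=value` header lines so a round trip is lossless.
#'
#' @param callset a [mapper_call_set()].
#' @param path output (input) file path.
#' @return `write_unified` returns `path` invisibly; `read_unified`
#'   returns a [mapper_call_set()].
#' @export
write_unified <- function(callset, path) {
  stopifnot(inherits(callset, "mapper_call_set"))
  hdr <- c(
    paste0("#format=", .UNIFIED_VERSION),
    paste0("#mapper_id=", callset$mapper_id),
    paste0("#lam=", format(callset$lam, digits = 17)),
    paste0("#meta=", callset$meta),
    paste(.CALL_COLS, collapse = "\t")
  )
  writeLines(hdr, path)
  if (nrow(callset$calls) > 0L) {
    fwrite(callset$calls[, .CALL_COLS, with = FALSE], path, sep = "\t",
           append = TRUE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_unified
#' @export
read_unified <- function(path) {
  if (!file.exists(path)) stop("unified file not found: ", path)
  lines <- readLines(path, n = 64L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
  if (!"format" %in% keys || vals[keys == "format"] != .UNIFIED_VERSION)
    stop("not a ", .UNIFIED_VERSION, " file (bad or missing #format header): ",
         path)
  dt <- fread(path, skip = length(hdr), header = TRUE, sep = "\t",
              colClasses = list(character = c("chrom", "strand", "context")),
              showProgress = FALSE)
  calls <- if (nrow(dt) == 0L) .empty_calls() else
    cytosine_calls(dt$chrom, dt$pos, dt$strand, dt$context,
                   dt$n_meth, dt$n_unmeth)
  mapper_call_set(vals[keys == "mapper_id"], calls,
                  lam = as.numeric(vals[keys == "lam"]),
                  meta = vals[keys == "meta"])
}

#' Estimate a mapper's genome-wide mean read depth
#'
#' The Poisson parameter of the pwAve weighting is the mapper's average
#' read depth over the whole reference. The denominator counts every
#' reference cytosine position of the analysed context set, so positions
#' absent from the call set contribute depth 0; set
#' `covered_only = TRUE` to average over covered positions instead.
#'
#' @param callset a [mapper_call_set()].
#' @param n_reference_cytosines number of cytosine positions in the
#'   reference (ignored when `covered_only = TRUE`).
#' @param covered_only average over covered positions only.
#' @return the mean depth (a single number).
#' @export
estimate_lambda <- function(callset, n_reference_cytosines,
                            covered_only = FALSE) {
  stopifnot(inherits(callset, "mapper_call_set"))
  tot <- sum(as.numeric(callset$calls$depth))
  if (covered_only) {
    n <- sum(callset$calls$depth > 0L)
    if (n == 0L) return(0)
    return(tot / n)
  }
  if (length(n_reference_cytosines) != 1L || is.na(n_reference_cytosines) ||
      n_reference_cytosines < 1)
    stop("n_reference_cytosines must be a count >= 1")
  tot / n_reference_cytosines
}

#' Set a call set's lambda from a reference cytosine count
#'
#' @inheritParams estimate_lambda
#' @return the call set with `lam` filled in.
#' @export
set_lambda <- function(callset, n_reference_cytosines, covered_only = FALSE) {
  callset$lam <- estimate_lambda(callset, n_reference_cytosines, covered_only)
  callset
}

#' Collapse cytosine contexts to CG / CH
#'
#' CpH analyses pool the CHG and CHH trinucleotide contexts. Every call
#' belongs to exactly one of the two collapsed classes.
#'
#' @param context character vector of `CG`/`CHG`/`CHH`.
#' @return character vector of `"CG"` / `"CH"`.
#' @export
collapse_context <- function(context) {
  out <- ifelse(context == "CG", "CG",
                ifelse(context %in% c("CHG", "CHH"), "CH", NA_character_))
  if (anyNA(out)) stop("unknown context value(s)")
  out
}
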