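#' Per-cytosine methylation level
#'
#' The methylation level at a cytosine is the fraction of covering reads
#' that report an unconverted C: `M = n_meth / (n_meth + n_unmeth)`.
#' Zero-coverage positions have no defined level; inside the integration a
#' mapper without coverage is simply excluded from the sums (it never
#' contributes a zero term), so this function returns `NA` at depth 0.
#'
#' @param n_meth reads reporting C.
#' @param n_unmeth reads reporting T.
#' @return level in `[0, 1]`, `NA` where depth is 0. Vectorised.
#' @export
methylation_level <- function(n_meth, n_unmeth) {
  if (any(n_meth < 0, na.rm = TRUE) || any(n_unmeth < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  d <- n_meth + n_unmeth
  ifelse(d > 0, n_meth / d, NA_real_)
}

#' Consensus levels at a single position
#'
#' Low-level building blocks of the three consensus schemes, operating on
#' the covering mappers of one cytosine position (all depths > 0):
#'
#' * `integrate_ave()` — plain average of the per-mapper levels.
#' * `depth_weights()` — weights proportional to read depth.
#' * `integrate_wave()` — depth-weighted average.
#' * `poisson_weights()` — weights proportional to the Poisson probability
#'   of observing each mapper's depth given its genome-wide mean depth
#'   `lambda`; an anomalously high (or low) depth for a mapper is
#'   down-weighted because excess reads at a position are more likely to
#'   contain mismapped ones.
#' * `integrate_pwave()` — Poisson-weighted average.
#'
#' Weight vectors sum to 1 over the covering mappers, so all three merged
#' levels are convex combinations of the inputs and stay within
#' `[min(levels), max(levels)]`. `poisson_weights()` works in log space;
#' in the degenerate case where every Poisson mass is zero (e.g.
#' `lambda = 0` with positive depth) it falls back to depth weights with a
#' warning.
#'
#' @param levels per-mapper methylation levels of the covering mappers.
#' @param depths per-mapper read depths (all > 0).
#' @param lambdas per-mapper genome-wide mean depths (all > 0).
#' @return a merged level, or a weight vector summing to 1.
#' @export
integrate_ave <- function(levels) {
  if (length(levels) < 1L) stop("need at least one covering mapper")
  mean(levels)
}

#' @rdname integrate_ave
#' @export
depth_weights <- function(depths) {
  if (length(depths) < 1L) stop("need at least one covering mapper")
  if (any(depths <= 0)) stop("covering mappers must have depth > 0")
  depths / sum(depths)
}

#' @rdname integrate_ave
#' @export
integrate_wave <- function(levels, depths) {
  sum(depth_weights(depths) * levels)
}

#' @rdname integrate_ave
#' @export
poisson_weights <- function(depths, lambdas) {
  if (length(depths) < 1L) stop("need at least one covering mapper")
  if (length(lambdas) != length(depths))
    stop("depths and lambdas must have equal length")
  if (any(depths <= 0)) stop("covering mappers must have depth > 0")
  if (any(lambdas < 0)) stop("lambdas must be >= 0")
  lp <- dpois(round(depths), lambdas, log = TRUE)
  if (all(is.infinite(lp))) {
    warning("all Poisson masses are zero; falling back to depth weights")
    return(depth_weights(depths))
  }
  w <- exp(lp - max(lp))
  w / sum(w)
}

#' @rdname integrate_ave
#' @export
integrate_pwave <- function(levels, depths, lambdas) {
  sum(poisson_weights(depths, lambdas) * levels)
}

#' Merge call sets across mappers position by position
#'
#' For every (chrom, pos, strand) key, a mapper is *covering* iff its
#' depth at that key is at least `min_depth`. A position is emitted iff
#' the number of covering mappers `n_i` is at least `min_mappers`
#' (default 2: the point at which the consensus keeps a higher detected
#' amount than the strictest single mapper while still gaining accuracy).
#' Merged levels are computed over the covering mappers only.
#'
#' `n_i` counts mappers by *coverage*, not by a positive methylation
#' level: a mapper reporting a genuinely unmethylated site (level 0 at
#' good depth) is real evidence and is kept. Set
#' `positive_level_only = TRUE` for the stricter reading that also
#' requires `M_ij > 0`.
#'
#' @param callsets a list of [mapper_call_set()] objects (>= 1) sharing a
#'   reference namespace. Each needs `lam` set when `method` includes
#'   pwAve.
#' @param method `"ave"`, `"wave"`, `"pwave"` or `"all"`.
#' @param min_mappers minimum number of covering mappers `k`.
#' @param min_depth minimum per-mapper depth `d` for a mapper to count as
#'   covering (1 for simulated reads; 5 is the usual choice for real
#'   WGBS).
#' @param positive_level_only also require `M_ij > 0` for coverage.
#' @return a `data.table` of class `integrated_calls`: one row per
#'   emitted position with `chrom, pos, strand, context, n_covering,
#'   depth_total` and a level column per requested method (`ave`,
#'   `wave`, `pwave`).
#' @export
integrate_positions <- function(callsets, method = "all", min_mappers = 2L,
                                min_depth = 1L, positive_level_only = FALSE) {
  if (!is.list(callsets) || length(callsets) < 1L ||
      !all(vapply(callsets, inherits, TRUE, "mapper_call_set")))
    stop("callsets must be a non-empty list of mapper_call_set objects")
  method <- match.arg(method, c("ave", "wave", "pwave", "all"))
  methods <- if (method == "all") c("ave", "wave", "pwave") else method
  if (min_mappers < 1L) stop("min_mappers must be >= 1")
  if (min_depth < 1L) stop("min_depth must be >= 1")

  ids <- vapply(callsets, `[[`, "", "mapper_id")
  if (anyDuplicated(ids)) stop("duplicate mapper_id among call sets")
  lam <- vapply(callsets, `[[`, 0, "lam")
  if ("pwave" %in% methods && anyNA(lam))
    stop("pwAve requires lam on every call set (see estimate_lambda)")

  long <- rbindlist(lapply(callsets, function(cs) {
    dt <- cs$calls[depth >= min_depth,
                   .(chrom, pos, strand, context, n_meth, depth)]
    dt[, mapper := cs$mapper_id]
    dt
  }))
  long[, level := n_meth / depth]
  if (positive_level_only) long <- long[level > 0]
  if (nrow(long) == 0L) return(.empty_integrated(methods))

  long[, lam := lam[match(mapper, ids)]]
  out <- long[, {
    res <- list(context = context[1L], n_covering = .N,
                depth_total = sum(depth))
    if ("ave" %in% methods) res$ave <- mean(level)
    if ("wave" %in% methods) res$wave <- sum(depth * level) / sum(depth)
    if ("pwave" %in% methods) {
      lp <- dpois(depth, lam, log = TRUE)
      if (all(is.infinite(lp))) {
        w <- depth / sum(depth)
      } else {
        w <- exp(lp - max(lp))
        w <- w / sum(w)
      }
      res$pwave <- sum(w * level)
    }
    res
  }, by = .(chrom, pos, strand)]
  out <- out[n_covering >= min_mappers]
  setkey(out, chrom, pos, strand)
  setattr(out, "class", c("integrated_calls", class(out)))
  out[]
}

.empty_integrated <- function(methods) {
  out <- data.table(chrom = character(), pos = integer(), strand = character(),
                    context = character(), n_covering = integer(),
                    depth_total = integer())
  for (m in methods) out[[m]] <- numeric()
  setattr(out, "class", c("integrated_calls", class(out)))
  out
}

#' Write integrated calls as TSV or bedGraph
#'
#' The TSV keeps the internal 1-based coordinates; the bedGraph export
#' converts to 0-based half-open intervals on write (only there) and
#' reports one chosen level column scaled to percent.
#'
#' @param x an `integrated_calls` table.
#' @param path output path.
#' @param column level column for the bedGraph track.
#' @return `path`, invisibly.
#' @export
write_integrated <- function(x, path) {
  fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname write_integrated
#' @export
write_bedgraph <- function(x, path, column = "wave") {
  if (!column %in% names(x)) stop("no such level column: ", column)
  bg <- data.table(chrom = x$chrom, start = x$pos - 1L, end = x$pos,
                   value = round(100 * x[[column]], 6))
  writeLines(sprintf("track type=bedGraph name=%s", column), path)
  fwrite(bg, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}
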