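# Independent reference implementations used to cross-check the package.
# These stay deliberately naive (flat loops, direct formulas).

# Poisson pmf from first principles: exp(-lam) * lam^k / k!
oracle_pois_pmf <- function(k, lam) {
  exp(-lam + k * log(lam) - sum(log(seq_len(k))))
}

oracle_poisson_weights <- function(depths, lambdas) {
  p <- mapply(oracle_pois_pmf, depths, lambdas)
  p / sum(p)
}

# Naive position-by-position integration over a list of mapper_call_set
oracle_integrate <- function(callsets, min_mappers, min_depth) {
  key_of <- function(dt) paste(dt$chrom, dt$pos, dt$strand, sep = "|")
  all_keys <- unique(unlist(lapply(callsets, function(cs) key_of(cs$calls))))
  rows <- list()
  for (k in all_keys) {
    levels <- c(); depths <- c(); lambdas <- c(); ctx <- NA
    for (cs in callsets) {
      i <- match(k, key_of(cs$calls))
      if (!is.na(i) && cs$calls$depth[i] >= min_depth) {
        levels <- c(levels, cs$calls$n_meth[i] / cs$calls$depth[i])
        depths <- c(depths, cs$calls$depth[i])
        lambdas <- c(lambdas, cs$lam)
        ctx <- cs$calls$context[i]
      }
    }
    if (length(levels) >= min_mappers) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      rows[[k]] <- data.frame(
        chrom = parts[1], pos = as.integer(parts[2]), strand = parts[3],
        context = ctx, n_covering = length(levels),
        ave = mean(levels),
        wave = sum(depths / sum(depths) * levels),
        pwave = sum(oracle_poisson_weights(depths, lambdas) * levels))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos, out$strand), ]
}

# Exact one-sided signed-rank p-value by enumerating all sign assignments
oracle_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  if (alternative == "greater") mean(w_all >= w_obs)
  else if (alternative == "less") mean(w_all <= w_obs)
  else stop("unsupported")
}

# Naive UPGMA agglomeration returning the cophenetic distance matrix
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  dd <- d
  diag(dd) <- Inf
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    idx <- which(dd == min(dd), arr.ind = TRUE)[1L, ]
    a <- min(idx); b <- max(idx)
    h <- dd[a, b]
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- h; coph[j, i] <- h
    }
    newd <- rep(Inf, m)
    for (k in seq_len(m)) {
      if (k == a || k == b) next
      newd[k] <- (sizes[a] * dd[a, k] + sizes[b] * dd[b, k]) /
        (sizes[a] + sizes[b])
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    dd[a, ] <- newd; dd[, a] <- newd; dd[a, a] <- Inf
    clusters <- clusters[-b]; sizes <- sizes[-b]
    dd <- dd[-b, -b, drop = FALSE]
  }
  coph
}

# Spearman by explicit rank transform (average ranks) then Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Random small call set generator for fuzz/round-trip tests
random_callset <- function(n, mapper_id = "m", seed = 1, chroms = c("c1", "c2")) {
  set.seed(seed)
  keys <- unique(data.frame(
    chrom = sample(chroms, 3 * n, TRUE),
    pos = sample.int(500, 3 * n, TRUE),
    strand = sample(c("+", "-"), 3 * n, TRUE)))[seq_len(n), ]
  n_meth <- rpois(n, 3)
  n_unmeth <- rpois(n, 4)
  calls <- cytosine_calls(keys$chrom, keys$pos, keys$strand,
                          sample(c("CG", "CHG", "CHH"), n, TRUE),
                          n_meth, n_unmeth)
  mapper_call_set(mapper_id, calls, lam = mean(n_meth + n_unmeth))
}
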