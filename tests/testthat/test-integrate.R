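test_that("methylation level is the unconverted-C fraction", {
  expect_equal(methylation_level(3, 1), 0.75)
  expect_equal(methylation_level(0, 7), 0)
  expect_equal(methylation_level(5, 0), 1)
  expect_true(is.na(methylation_level(0, 0)))
  expect_error(methylation_level(-1, 2), "non-negative")
})

test_that("plain average and depth weights follow the defining formulas", {
  expect_equal(integrate_ave(c(0.5, 0.7)), 0.6)
  expect_equal(integrate_ave(0.2), 0.2)
  expect_equal(integrate_ave(c(0.1, 0.2, 0.9)), 0.4)
  expect_equal(depth_weights(c(10, 30)), c(0.25, 0.75))
  expect_equal(depth_weights(c(7, 7, 7)), rep(1 / 3, 3))
  expect_equal(depth_weights(c(1, 2, 3)), c(1 / 6, 1 / 3, 1 / 2))
  expect_error(depth_weights(numeric()), "covering")
  expect_error(depth_weights(c(1, 0)), "depth > 0")
})

test_that("depth-weighted average interpolates and reduces correctly", {
  expect_equal(integrate_wave(c(0.2, 0.6), c(10, 30)), 0.5)
  lv <- c(0.15, 0.4, 0.8)
  expect_equal(integrate_wave(lv, c(5, 5, 5)), integrate_ave(lv))
  expect_equal(integrate_wave(0.33, 12), 0.33)
})

test_that("Poisson weights match an independent log-factorial pmf oracle", {
  expect_equal(poisson_weights(c(10, 10), c(10, 10)), c(0.5, 0.5))
  w <- poisson_weights(c(10, 30), c(10, 10))
  expect_equal(w[1] / w[2],
               oracle_pois_pmf(10, 10) / oracle_pois_pmf(30, 10),
               tolerance = 1e-12)
  # depth 2 is typical for lambda 2, anomalously low for lambda 20
  w2 <- poisson_weights(c(2, 2), c(2, 20))
  expect_true(w2[1] > w2[2])
  set.seed(5)
  for (i in 1:50) {
    depths <- sample.int(60, 3)
    lambdas <- runif(3, 0.5, 40)
    expect_equal(poisson_weights(depths, lambdas),
                 oracle_poisson_weights(depths, lambdas), tolerance = 1e-12)
  }
})

test_that("Poisson weighting falls back to depth weights on total underflow", {
  expect_warning(w <- poisson_weights(c(4, 6), c(0, 0)), "depth weights")
  expect_equal(w, c(0.4, 0.6))
})

test_that("pwAve reduces to Ave in the symmetric case and to identity alone", {
  lv <- c(0.1, 0.5, 0.9)
  expect_equal(integrate_pwave(lv, c(8, 8, 8), c(8, 8, 8)), integrate_ave(lv))
  expect_equal(integrate_pwave(0.42, 3, 7), 0.42)
  set.seed(6)
  for (i in 1:20) {
    lv <- runif(3); dp <- sample.int(40, 3); lam <- runif(3, 1, 30)
    expect_equal(integrate_pwave(lv, dp, lam),
                 sum(oracle_poisson_weights(dp, lam) * lv), tolerance = 1e-12)
  }
})

test_that("merged levels are convex combinations of the inputs", {
  set.seed(7)
  for (i in 1:200) {
    k <- sample(1:4, 1)
    lv <- runif(k); dp <- sample.int(50, k, replace = TRUE)
    lam <- runif(k, 0.5, 30)
    for (m in list(integrate_ave(lv), integrate_wave(lv, dp),
                   integrate_pwave(lv, dp, lam))) {
      expect_gte(m, min(lv) - 1e-12)
      expect_lte(m, max(lv) + 1e-12)
    }
  }
})

test_that("position-wise integration matches the naive oracle exactly", {
  sets <- lapply(1:3, function(i)
    random_callset(200, mapper_id = paste0("m", i), seed = 20 + i))
  got <- integrate_positions(sets, method = "all", min_mappers = 2,
                             min_depth = 1)
  want <- oracle_integrate(sets, min_mappers = 2, min_depth = 1)
  expect_equal(nrow(got), nrow(want))
  g <- as.data.frame(got[order(chrom, pos, strand)])
  rownames(want) <- NULL
  expect_equal(g$pos, want$pos)
  expect_equal(g$n_covering, want$n_covering)
  expect_equal(g$ave, want$ave, tolerance = 1e-12)
  expect_equal(g$wave, want$wave, tolerance = 1e-12)
  expect_equal(g$pwave, want$pwave, tolerance = 1e-12)
})

test_that("a single call set with k = 1 passes through unchanged", {
  cs <- random_callset(80, seed = 31)
  cs$calls <- cs$calls[depth > 0]
  got <- integrate_positions(list(cs), method = "all", min_mappers = 1)
  expect_equal(nrow(got), nrow(cs$calls))
  m <- merge(as.data.frame(got), as.data.frame(cs$calls),
             by = c("chrom", "pos", "strand"))
  expect_equal(m$ave, m$n_meth / m$depth)
  expect_equal(m$wave, m$ave)
  expect_equal(m$pwave, m$ave)
})

test_that("positions covered by fewer than k mappers are absent", {
  mk <- function(id, pos) mapper_call_set(id, cytosine_calls(
    "c1", pos, "+", "CG", rep(2L, length(pos)), rep(2L, length(pos))), lam = 4)
  sets <- list(mk("a", c(1L, 5L, 9L)), mk("b", c(5L, 9L)), mk("c", 9L))
  got <- integrate_positions(sets, min_mappers = 2)
  expect_setequal(got$pos, c(5L, 9L))       # pos 1 covered by one mapper only
  expect_equal(got[pos == 9L, n_covering], 3L)
})

test_that("raising min_mappers never increases the emitted positions", {
  sets <- lapply(1:3, function(i)
    random_callset(150, mapper_id = paste0("m", i), seed = 40 + i))
  n <- sapply(1:3, function(k)
    nrow(integrate_positions(sets, min_mappers = k)))
  expect_true(all(diff(n) <= 0))
})

test_that("min_depth excludes shallow mappers from coverage", {
  mk <- function(id, depth) mapper_call_set(id, cytosine_calls(
    "c1", 1L, "+", "CG", depth, 0L), lam = 4)
  sets <- list(mk("a", 6L), mk("b", 2L))
  expect_equal(nrow(integrate_positions(sets, min_mappers = 2, min_depth = 5)),
               0L)
  got <- integrate_positions(sets, min_mappers = 1, min_depth = 5)
  expect_equal(got$n_covering, 1L)
})

test_that("the strict positive-level reading drops unmethylated evidence", {
  mk <- function(id, nm) mapper_call_set(id, cytosine_calls(
    "c1", 1L, "+", "CG", nm, 5L), lam = 5)
  sets <- list(mk("a", 0L), mk("b", 3L))
  expect_equal(integrate_positions(sets, min_mappers = 2)$n_covering, 2L)
  strict <- integrate_positions(sets, min_mappers = 2,
                                positive_level_only = TRUE)
  expect_equal(nrow(strict), 0L)
})

test_that("integration requires at least one call set", {
  expect_error(integrate_positions(list()), "non-empty")
})

test_that("bedGraph export converts to 0-based half-open coordinates", {
  cs <- random_callset(10, seed = 50)
  cs$calls <- cs$calls[depth > 0]
  got <- integrate_positions(list(cs), min_mappers = 1)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(got, f, column = "wave")
  lines <- readLines(f)
  expect_match(lines[1], "^track")
  first <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(first[3]) - as.integer(first[2]), 1L)
  expect_equal(as.integer(first[2]), got$pos[1] - 1L)
})
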