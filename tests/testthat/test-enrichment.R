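test_that("enrichment ratio is the observed-over-expected hit fraction", {
  expect_equal(enrichment_ratio(2, 10, 20, 100), 1.0)
  # scale invariance in all four counts
  expect_equal(enrichment_ratio(4, 20, 40, 200), 1.0)
  expect_equal(enrichment_ratio(6, 30, 15, 300),
               enrichment_ratio(2, 10, 5, 100), tolerance = 1e-12)
  expect_error(enrichment_ratio(1, 0, 5, 100), "positive")
  expect_error(enrichment_ratio(1, 10, 101, 100), "<=")
})

test_that("rounding for reported ratios is half away from zero", {
  expect_equal(round_half_away(24.0233, 2), 24.02)
  expect_equal(round_half_away(0.125, 2), 0.13)
  expect_equal(round_half_away(-0.125, 2), -0.13)
})

test_that("hypergeometric upper tail matches exact enumeration", {
  expect_equal(hypergeom_sf(0, 5, 4, 10), 1.0)
  # C(4,3)C(6,2) + C(4,4)C(6,1) over C(10,5) = 66/252
  expect_equal(hypergeom_sf(3, 5, 4, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_sf(5, 5, 4, 10), 0)        # k > min(n, K)
  # spot-check random small configurations against the brute-force oracle
  set.seed(31)
  for (i in 1:50) {
    N <- sample(5:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_sf(k, n, K, N), hyper_brute(k, n, K, N),
                 tolerance = 1e-12)
  }
  # monotone non-increasing in k
  p <- hypergeom_sf(0:10, 205, 88, 43338)
  expect_true(all(diff(p) <= 0))
})

test_that("Benjamini-Hochberg adjustment applies the step-up rule", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  p <- runif(50)^2
  adj <- bh_adjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  # step-up output is monotone in sort order, and re-adjustment is a
  # fixed point on the tied-block outputs of the worked examples (it is
  # NOT idempotent on arbitrary lists)
  expect_true(all(diff(sort(adj)) >= 0))
  for (q in list(c(0.01, 0.02, 0.03), c(0.01, 0.04, 0.03, 0.02))) {
    once <- bh_adjust(q)
    expect_equal(bh_adjust(once), once)
  }
})

test_that("ORA on the published carboplatin pathway counts", {
  rows <- kegg_example_counts()
  N <- recover_reference_size(rows, n = 205)
  expect_length(N, 1L)
  res <- run_ora(query = character(), categories = rows, N = N, n = 205)
  expect_equal(nrow(res), 14L)
  hem <- res[res$name == "Hematopoietic cell lineage", ]
  expect_equal(round_half_away(hem$ratio, 2), 24.02)
  expect_lte(hem$p_raw, 6.02e-11)
  # BH only inflates: every raw p is bounded by its printed adjusted p
  m <- match(res$name, rows$name)
  expect_true(all(res$p_raw <= rows$p_adj[m]))
  expect_true(all(res$selected[res$p_adj < 0.01]))
  expect_equal(res$p_adj, sort(res$p_adj))   # sorted ascending
})

test_that("ORA handles saturation and empty intersections", {
  sets <- list(ALL = sprintf("G%03d", 1:40), HALF = sprintf("G%03d", 1:20))
  res <- run_ora(sprintf("G%03d", 1:40), sets, N = 40)
  expect_equal(res$ratio[res$name == "ALL"], 1.0)
  expect_equal(res$p_raw[res$name == "ALL"], 1.0)
  expect_false(res$selected[res$name == "ALL"])
  none <- run_ora(c("X1", "X2"), sets, N = 100)
  expect_true(all(none$k == 0))
  expect_true(all(none$p_raw == 1))
  expect_false(any(none$selected))
  expect_error(run_ora(character(), sets, N = 40), "empty query")
  expect_error(run_ora("G001", list(), N = 40), "no categories")
})

test_that("reference-size recovery is exact, and detects contradictions", {
  # rows generated from a known universe are self-consistent
  N0 <- 40000L; n <- 205
  K <- c(90, 61, 333, 45); k <- c(11, 16, 40, 9)
  rows <- data.frame(name = paste0("c", 1:4), K = K, k = k,
                     ratio = round_half_away(k * N0 / (n * K), 2))
  expect_true(N0 %in% recover_reference_size(rows, n))
  # fabricated contradictory printed ratios admit no universe
  bad <- rows
  bad$ratio[1] <- bad$ratio[1] + 5
  expect_error(recover_reference_size(bad, n), "violates row")
})

test_that("a planted enriched category ranks first almost surely", {
  # mirrors the hematopoietic configuration: fold 24, K=88, N=43338, n=205
  cats <- c(planted = 88L, c1 = 120L, c2 = 60L, c3 = 200L, c4 = 88L)
  first <- vapply(1:200, function(s) {
    u <- simulate_gene_universe(43338, 205, cats,
                                planted = list(name = "planted", fold = 24),
                                seed = s)
    res <- run_ora(u$query, u$categories, N = 43338)
    res$name[1] == "planted"
  }, logical(1))
  expect_gte(mean(first), 0.95)
})

test_that("a fold-1 plant is a null: expected enrichment ratio 1", {
  cats <- c(planted = 80L, other = 50L)
  ratios <- vapply(1:200, function(s) {
    u <- simulate_gene_universe(5000, 100, cats,
                                planted = list(name = "planted", fold = 1),
                                seed = 1000 + s)
    k <- length(intersect(u$query, u$categories$planted))
    (k / length(u$query)) / (80 / 5000)
  }, numeric(1))
  # binomial Monte-Carlo error on the mean ratio over 200 seeds
  mc_se <- sd(ratios) / sqrt(200)
  expect_lt(abs(mean(ratios) - 1), 3 * mc_se)
})

test_that("GMT and gene-list files round-trip", {
  sets <- list(A = c("G1", "G2", "G3"), B = c("G2", "G9"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f, description = "demo")
  back <- read_gmt(f)
  expect_equal(back[], sets, ignore_attr = TRUE)
  g <- withr::local_tempfile()
  writeLines(c("tp53", " BRCA1 ", "", "tp53"), g)
  expect_equal(read_gene_list(g), c("TP53", "BRCA1"))
  bad <- withr::local_tempfile()
  writeLines("only-one-field", bad)
  expect_error(read_gmt(bad), "malformed GMT line 1")
})
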