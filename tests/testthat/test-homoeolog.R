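# helper: a count matrix over homoeolog pairs with explicit At/Dt means per
# accession (M, T), 4 replicates each, Poisson noise
pair_fixture <- function(atM, dtM, atT, dtT, reps = 4, seed = 1) {
  set.seed(seed)
  n <- length(atM)
  at_id <- sprintf("At%03d", seq_len(n)); dt_id <- sprintf("Dt%03d", seq_len(n))
  samples <- data.frame(
    sample_id = c(paste0("M.10dpa.r", 1:reps), paste0("T.10dpa.r", 1:reps)),
    accession = rep(c("M", "T"), each = reps), stage = 10,
    replicate = rep(1:reps, 2), stringsAsFactors = FALSE)
  mu <- rbind(cbind(matrix(atM, n, reps), matrix(atT, n, reps)),
              cbind(matrix(dtM, n, reps), matrix(dtT, n, reps)))
  counts <- matrix(rpois(length(mu), mu), nrow(mu),
                   dimnames = list(c(at_id, dt_id), samples$sample_id))
  list(counts = counts, samples = samples,
       pairs = data.frame(at_gene = at_id, dt_gene = dt_id,
                          stringsAsFactors = FALSE))
}

test_that("triplet extraction handles the worked examples", {
  nodes <- data.frame(gene = c("o1", "a1", "d1", "o2", "a2", "d2", "d3",
                               "o3", "a3"),
                      genome = c("outgroup", "At", "Dt", "outgroup", "At",
                                 "Dt", "Dt", "outgroup", "At"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(a = c("o1", "o1", "o2", "a2", "o3"),
                      b = c("a1", "d1", "a2", "d2", "a3"),
                      stringsAsFactors = FALSE)
  r <- extract_triplets(edges, nodes)
  # o1-a1-d1 is a clean triplet; o2's component lacks nothing but d3 is
  # isolated... o2-a2-d2 is clean; o3-a3 misses a Dt; d3 is a singleton
  expect_equal(nrow(r$triplets), 2)
  expect_equal(r$triplets$outgroup, c("o1", "o2"))
  expect_equal(r$triplets$At, c("a1", "a2"))
  expect_equal(unname(r$rejected["missing_genome"]), 2L)
  # a duplicated genome in a component rejects it
  edges2 <- rbind(edges, data.frame(a = "o2", b = "d3"))
  r2 <- extract_triplets(edges2, nodes)
  expect_equal(nrow(r2$triplets), 1)
  expect_equal(unname(r2$rejected["duplicated_genome"]), 1L)
  # self-edges are ignored
  edges3 <- rbind(edges, data.frame(a = "o1", b = "o1"))
  expect_equal(extract_triplets(edges3, nodes)$triplets, r$triplets)
})

test_that("triplet extraction matches the BFS oracle on random graphs", {
  for (s in c(101, 202, 303, 404)) {
    g <- random_graph(n_nodes = 40, n_edges = 35, seed = s)
    got <- extract_triplets(g$edges, g$nodes)$triplets
    want <- oracle_triplets(g$edges, g$nodes)
    expect_equal(got, want, label = paste("seed", s))
  }
})

test_that("triplet extraction is invariant to edge order and direction", {
  g <- random_graph(n_nodes = 30, n_edges = 25, seed = 77)
  r1 <- extract_triplets(g$edges, g$nodes)
  shuffled <- g$edges[rev(seq_len(nrow(g$edges))), c("b", "a")]
  r2 <- extract_triplets(shuffled, g$nodes)
  expect_equal(r1$triplets, r2$triplets)
  expect_equal(r1$rejected, r2$rejected)
})

test_that("unlabelled or duplicated nodes are rejected with clear errors", {
  nodes <- data.frame(gene = c("a", "b"), genome = c("At", "Dt"),
                      stringsAsFactors = FALSE)
  expect_error(extract_triplets(data.frame(x = "a", y = "zz"), nodes),
               "without genome label")
  nodes2 <- rbind(nodes, data.frame(gene = "a", genome = "outgroup"))
  expect_error(extract_triplets(data.frame(x = "a", y = "b"), nodes2),
               "duplicate")
})

test_that("homoeolog bias detects a constructed 4-fold At skew", {
  fx <- pair_fixture(atM = c(rep(2000, 20), rep(500, 80)),
                     dtM = rep(500, 100),
                     atT = c(rep(2000, 20), rep(500, 80)),
                     dtT = rep(500, 100), seed = 11)
  b <- homoeolog_bias(fx$counts, fx$samples, fx$pairs, accession = "M")
  expect_gt(mean(b$biased[1:20]), 0.9)
  expect_true(all(b$direction[1:20][b$biased[1:20]] == "At"))
  expect_lt(mean(b$biased[21:100]), 0.1)
  expect_equal(median(b$log2_at_dt[1:20]), 2, tolerance = 0.15)
})

test_that("ratio change sign convention: positive = more At in M", {
  # pairs 1-15: At doubles in M only; pairs 16-30: Dt doubles in M only
  fx <- pair_fixture(atM = c(rep(1000, 15), rep(500, 15), rep(500, 70)),
                     dtM = c(rep(500, 15), rep(1000, 15), rep(500, 70)),
                     atT = rep(500, 100), dtT = rep(500, 100), seed = 13)
  rc <- ratio_change(fx$counts, fx$samples, fx$pairs)
  expect_gt(median(rc$delta_ratio[1:15]), 0.8)
  expect_lt(median(rc$delta_ratio[16:30]), -0.8)
  expect_gt(mean(rc$significant[1:30]), 0.8)
  expect_lt(mean(rc$significant[31:100]), 0.1)
})

test_that("swapping accession labels negates the ratio change", {
  fx <- pair_fixture(atM = c(rep(1500, 10), rep(400, 60)),
                     dtM = rep(400, 70),
                     atT = rep(400, 70), dtT = rep(400, 70), seed = 17)
  rc1 <- ratio_change(fx$counts, fx$samples, fx$pairs)
  samples2 <- fx$samples
  samples2$accession <- c(M = "T", T = "M")[samples2$accession]
  rc2 <- ratio_change(fx$counts, samples2, fx$pairs)
  expect_equal(rc2$delta_ratio, -rc1$delta_ratio)
  expect_equal(rc2$p, rc1$p)
})

test_that("reallocation between homoeologs changes ratio but not total", {
  # constant At+Dt = 1000 in both accessions, At share moves 0.75 -> 0.25
  n_eff <- 25; n_null <- 75
  fx <- pair_fixture(atM = c(rep(750, n_eff), rep(500, n_null)),
                     dtM = c(rep(250, n_eff), rep(500, n_null)),
                     atT = c(rep(250, n_eff), rep(500, n_null)),
                     dtT = c(rep(750, n_eff), rep(500, n_null)), seed = 19)
  rc <- ratio_change(fx$counts, fx$samples, fx$pairs)
  tc <- total_change(fx$counts, fx$samples, fx$pairs)
  expect_gt(mean(rc$significant[1:n_eff]), 0.85)
  expect_lt(mean(tc$significant[1:n_eff]), 0.1)
  expect_equal(median(rc$delta_ratio[1:n_eff]), log2(3) - log2(1 / 3),
               tolerance = 0.2)
  # and the mirror case: total doubles, ratio fixed
  fx2 <- pair_fixture(atM = c(rep(1000, n_eff), rep(500, n_null)),
                      dtM = c(rep(1000, n_eff), rep(500, n_null)),
                      atT = rep(500, 100), dtT = rep(500, 100), seed = 23)
  rc2 <- ratio_change(fx2$counts, fx2$samples, fx2$pairs)
  tc2 <- total_change(fx2$counts, fx2$samples, fx2$pairs)
  expect_gt(mean(tc2$significant[1:n_eff]), 0.85)
  expect_lt(mean(rc2$significant[1:n_eff]), 0.1)
})

test_that("RD-bias association reproduces the sample odds ratio", {
  pairs <- data.frame(at_gene = sprintf("At%02d", 1:40),
                      dt_gene = sprintf("Dt%02d", 1:40),
                      stringsAsFactors = FALSE)
  # 10 RD & biased, 5 RD & unbiased, 5 non-RD & biased, 20 non-RD & unbiased
  rd_genes <- sprintf("At%02d", 1:15)
  bias <- data.frame(at_gene = pairs$at_gene, dt_gene = pairs$dt_gene,
                     biased = c(rep(TRUE, 10), rep(FALSE, 5),
                                rep(TRUE, 5), rep(FALSE, 20)),
                     stringsAsFactors = FALSE)
  a <- rd_bias_association(pairs, rd_genes, bias)
  expect_equal(a$odds_ratio, (10 * 20) / (5 * 5))  # = 8, the sample OR
  expect_equal(unname(a$table[1, 1]), 10L)
  expect_lt(a$p, 0.05)
  # degenerate margin -> NA, not an error
  a2 <- rd_bias_association(pairs, character(0), bias)
  expect_true(is.na(a2$odds_ratio))
})

test_that("RD-type crosstab uses the 1.3 reference and collapse Fisher", {
  pairs <- data.frame(at_gene = sprintf("At%02d", 1:30),
                      dt_gene = sprintf("Dt%02d", 1:30),
                      stringsAsFactors = FALSE)
  rd <- data.frame(gene_id = c(sprintf("At%02d", 1:10), sprintf("Dt%02d", 1:10)),
                   rd_type = rep(c("cis_only", "cis_only"), each = 10),
                   stringsAsFactors = FALSE)
  ct <- crosstab_rd(pairs, rd)
  expect_equal(dim(ct$counts), c(4, 4))
  expect_equal(unname(ct$counts["cis_only", "cis_only"]), 10L)
  expect_equal(unname(ct$counts["none", "none"]), 20L)
  expect_equal(ct$reference, 1.3)
  expect_equal(ct$neg_log10_p, -log10(ct$fisher_p))
  # the diagonal enrichment cell is strongly significant
  expect_gt(ct$neg_log10_p["cis_only", "cis_only"], 1.3)
  expect_equal(sum(ct$counts), 30)
})

test_that("ratio change by RD type groups pairs and respects signs", {
  rc <- data.frame(at_gene = sprintf("At%02d", 1:12),
                   dt_gene = sprintf("Dt%02d", 1:12),
                   delta_ratio = c(0.9, 1, 1, 1.1, -0.9, -1, -1, -1.1,
                                   rep(0.5, 4)),
                   testable = TRUE, stringsAsFactors = FALSE)
  rd <- data.frame(gene_id = c(sprintf("At%02d", 1:4),    # At RD, cis_only
                               sprintf("Dt%02d", 5:8),    # Dt RD, cis_only
                               sprintf("At%02d", 9:9),    # singleton group
                               "At10", "Dt10"),           # both RD -> excluded
                   rd_type = c(rep("cis_only", 8), "trans_only",
                               "cis_only", "cis_only"),
                   stringsAsFactors = FALSE)
  r <- ratio_change_by_rd(rc, rd)
  gAt <- r$groups[r$groups$rd_type == "cis_only" & r$groups$subgenome == "At", ]
  gDt <- r$groups[r$groups$rd_type == "cis_only" & r$groups$subgenome == "Dt", ]
  expect_equal(gAt$n, 4L); expect_equal(gAt$median, 1)
  expect_equal(gDt$n, 4L); expect_equal(gDt$median, -1)
  # pairs with RD in both homoeologs are excluded from the one-sided groups
  expect_equal(sum(r$groups$n), 9)
  g1 <- r$groups[r$groups$rd_type == "trans_only" & r$groups$subgenome == "At", ]
  expect_true(g1$skipped)
  expect_true(is.na(g1$p))
  expect_true(is.finite(r$at_vs_dt$p[r$at_vs_dt$rd_type == "cis_only"]))
})
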