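# helper: build a deterministic dataset where a block of genes carries a
# known (A, B) configuration and the remainder is flat, then fit
make_fit <- function(configs, base = 2000, reps_p = 4, reps_f1 = 3,
                     n_null = 150, allelic_base = 400, seed = 1, ...) {
  set.seed(seed)
  n <- nrow(configs) + n_null
  muM <- c(base * 2^(configs$A), rep(base, n_null))
  muT <- rep(base, n)
  p <- c(2^configs$B / (1 + 2^configs$B), rep(0.5, n_null))
  ids <- sprintf("g%04d", seq_len(n))
  noise <- function(mu, k) matrix(rpois(length(mu) * k, rep(mu, k)), ncol = k)
  samples <- data.frame(
    sample_id = c(paste0("M.10dpa.r", 1:reps_p), paste0("T.10dpa.r", 1:reps_p),
                  paste0("MxT.10dpa.r", 1:reps_f1), paste0("TxM.10dpa.r", 1:reps_f1)),
    accession = rep(c("M", "T", "MxT", "TxM"), c(reps_p, reps_p, reps_f1, reps_f1)),
    stage = 10,
    replicate = c(1:reps_p, 1:reps_p, 1:reps_f1, 1:reps_f1),
    stringsAsFactors = FALSE)
  counts <- cbind(noise(muM, reps_p), noise(muT, reps_p),
                  noise(sqrt(muM * muT), 2 * reps_f1))
  dimnames(counts) <- list(ids, samples$sample_id)
  hyb <- samples$sample_id[samples$accession %in% c("MxT", "TxM")]
  allelic <- matrix(0L, n, 2 * length(hyb))
  cn <- character(2 * length(hyb))
  for (j in seq_along(hyb)) {
    tot <- rpois(n, allelic_base)
    m <- rbinom(n, tot, p)
    allelic[, 2 * j - 1] <- m; allelic[, 2 * j] <- tot - m
    cn[2 * j - 1] <- paste0(hyb[j], ".M_allele"); cn[2 * j] <- paste0(hyb[j], ".T_allele")
  }
  dimnames(allelic) <- list(ids, cn)
  cistrans_fit(counts, samples, allelic, ...)
}

test_that("divergence estimates recover constructed A and B configurations", {
  cfg <- data.frame(A = c(2, 2, 0), B = c(0, 2, 1.5))  # trans, cis, compensatory
  fit <- make_fit(cfg[rep(1:3, each = 25), , drop = FALSE], seed = 3)
  e <- fit$estimates[fit$estimates$hybrid == "MxT", ]
  trans_block <- 1:25; cis_block <- 26:50; comp_block <- 51:75
  expect_equal(median(e$A[trans_block]), 2, tolerance = 0.15)
  expect_equal(median(e$B[trans_block]), 0, tolerance = 0.15)
  expect_equal(median(e$trans[trans_block]), 2, tolerance = 0.2)
  expect_equal(median(e$B[cis_block]), 2, tolerance = 0.15)
  expect_equal(median(e$trans[cis_block]), 0, tolerance = 0.2)
  expect_equal(median(e$A[comp_block]), 0, tolerance = 0.15)
  expect_equal(median(e$B[comp_block]), 1.5, tolerance = 0.15)
  # trans_effect = A - B exactly
  expect_equal(e$trans, e$A - e$B)
  # and the constructed blocks are classified as II, I, V
  expect_gt(mean(e$category[trans_block] == "II"), 0.7)
  expect_gt(mean(e$category[cis_block] == "I"), 0.7)
  expect_gt(mean(e$category[comp_block] == "V"), 0.7)
})

test_that("classification follows the seven-category decision table", {
  sig <- 0.01; ns <- 0.5
  # columns: A, B, q_A, q_B, q_AvsB -> expected category
  cases <- list(
    list(1, 1, sig, sig, ns, "I"),
    list(1, 0, sig, ns, sig, "II"),
    list(2, 1, sig, sig, sig, "III"),    # B > 0, A-B = 1 > 0: same direction
    list(1, 2, sig, sig, sig, "IV"),     # B > 0, A-B = -1 < 0: opposite
    list(0.1, 1, ns, sig, sig, "V"),
    list(0, 0, ns, ns, ns, "VI"),
    list(0, 0, ns, ns, sig, "VII"),      # conflicting: trans effect without divergence
    list(1, 1, sig, sig, NA, "VII"),     # untestable -> ambiguous sink
    list(1, 0.5, sig, ns, ns, "VII")     # A significant but unattributable
  )
  for (cs in cases) {
    got <- classify_regulation(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]])
    expect_equal(as.character(got), cs[[6]],
                 label = paste("case", paste(unlist(cs), collapse = "/")))
  }
  # lfc cutoff moves a weak-but-significant A out of the divergent categories
  expect_equal(as.character(classify_regulation(0.3, 0.3, sig, sig, ns,
                                                lfc_cutoff = 1)), "VI")
})

test_that("categories partition the tested genes and percentages sum to 100", {
  fit <- make_fit(data.frame(A = 2, B = 2)[rep(1, 20), , drop = FALSE], seed = 5)
  for (cond in split(fit$summary, list(fit$summary$hybrid, fit$summary$stage))) {
    expect_equal(sum(cond$n), length(fit$universes[["10"]]))
    expect_equal(sum(cond$pct), 100, tolerance = 0.1)
  }
  e <- fit$estimates
  expect_false(any(is.na(e$category)))
  expect_equal(nrow(e), 2 * length(fit$universes[["10"]]))
})

test_that("swapping parent labels negates A and B and preserves categories", {
  sim <- tiny_sim(seed = 9, n_genes = 500)
  fit1 <- cistrans_fit(sim)
  # relabel M<->T (and m<->t allele columns, and the cross-direction names)
  samples2 <- sim$samples
  samples2$accession <- c(M = "T", T = "M", MxT = "TxM", TxM = "MxT")[samples2$accession]
  map_id <- function(x) {
    y <- x
    y <- sub("^M\\.", "Mtmp.", y); y <- sub("^T\\.", "M.", y); y <- sub("^Mtmp\\.", "T.", y)
    y <- sub("^MxT\\.", "XX.", y); y <- sub("^TxM\\.", "MxT.", y); y <- sub("^XX\\.", "TxM.", y)
    y
  }
  samples2$sample_id <- map_id(samples2$sample_id)
  counts2 <- sim$counts; colnames(counts2) <- map_id(colnames(counts2))
  allelic2 <- sim$allelic
  cn <- colnames(allelic2)
  lib <- map_id(sub("\\.[MT]_allele$", "", cn))
  allele <- ifelse(grepl("M_allele$", cn), "T_allele", "M_allele")
  colnames(allelic2) <- paste0(lib, ".", allele)
  fit2 <- cistrans_fit(counts2, samples2, allelic2)

  e1 <- fit1$estimates[fit1$estimates$hybrid == "MxT" & fit1$estimates$stage == 10, ]
  e2 <- fit2$estimates[fit2$estimates$hybrid == "TxM" & fit2$estimates$stage == 10, ]
  e2 <- e2[match(e1$gene_id, e2$gene_id), ]
  expect_equal(e2$A, -e1$A)
  expect_equal(e2$B, -e1$B)
  expect_equal(as.character(e2$category), as.character(e1$category))
})

test_that("cis proportion reproduces the worked values and stays in [0, 1]", {
  est <- data.frame(gene_id = c("a", "b", "c"),
                    A = c(1, 2, 0), B = c(1, 1, 1.5))
  est$trans <- est$A - est$B
  cp <- cis_proportion(est)
  expect_equal(cp$per_gene$cis_prop, c(1, 0.5, 0.5))
  # property: bounded; 1 iff A = B; 0 iff B = 0
  set.seed(3)
  est2 <- data.frame(gene_id = as.character(1:200),
                     A = rnorm(200), B = rnorm(200))
  est2$trans <- est2$A - est2$B
  v <- cis_proportion(est2)$per_gene$cis_prop
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(cis_proportion(data.frame(gene_id = "z", A = 2, B = 0, trans = 2)
                              )$per_gene$cis_prop, 0)
  # |B| + |A-B| = 0 rows are excluded and counted
  est3 <- data.frame(gene_id = c("a", "b"), A = c(0, 1), B = c(0, 1),
                     trans = c(0, 0))
  cp3 <- cis_proportion(est3)
  expect_equal(cp3$n_excluded, 1)
  expect_equal(nrow(cp3$per_gene), 1)
})

test_that("cis proportion bins are half-open on |A| with a final open bin", {
  est <- data.frame(gene_id = as.character(1:5),
                    A = c(1, 1.99, 2, 3.5, 6), B = c(0.5, 1, 1, 2, 3))
  est$trans <- est$A - est$B
  b <- cis_proportion(est)$bins
  expect_equal(b$n, c(2L, 1L, 1L, 1L))
  expect_equal(b$bin, c("[1,2)", "[2,3)", "[3,4)", ">=4"))
})

test_that("sign chi-squared reproduces the closed form", {
  r <- sign_chisq(60, 40)
  expect_equal(r$statistic, 4.0)
  expect_equal(r$p, pchisq(4, 1, lower.tail = FALSE))
})

test_that("reciprocal consensus implements the agreement rule", {
  est <- data.frame(
    gene_id = rep(c("a", "b", "c", "d"), 2),
    hybrid = rep(c("MxT", "TxM"), each = 4),
    stage = 10,
    category = factor(c("I", "I", "VI", "V", "I", "II", "VI", "V"),
                      levels = c("I", "II", "III", "IV", "V", "VI", "VII")),
    stringsAsFactors = FALSE)
  cons <- consensus_rd(est)$consensus
  expect_equal(cons$rd[cons$gene_id == "a"], TRUE)    # (I, I) -> RD
  expect_equal(cons$rd[cons$gene_id == "b"], FALSE)   # (I, II) -> disagreement
  expect_equal(cons$rd[cons$gene_id == "c"], FALSE)   # (VI, VI) -> conserved
  expect_equal(cons$rd[cons$gene_id == "d"], TRUE)    # (V, V) -> RD
})

test_that("RD typing follows the cis-only / trans-only / cis+trans rule", {
  cons <- data.frame(
    gene_id = c("a", "a", "b", "b", "c", "d", "d"),
    stage = c(10, 20, 10, 20, 10, 10, 20),
    rd = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    category = c("I", NA, "I", "II", "V", "II", "II"),
    stringsAsFactors = FALSE)
  rt <- rd_type(cons)
  expect_equal(rt$rd_type[rt$gene_id == "a"], "cis_only")   # I at one stage only
  expect_equal(rt$rd_type[rt$gene_id == "b"], "cis_trans")  # I then II
  expect_equal(rt$rd_type[rt$gene_id == "c"], "cis_trans")  # V involves both
  expect_equal(rt$rd_type[rt$gene_id == "d"], "trans_only") # II at both stages
})

test_that("direction summaries: constant positive A gives certain deviation", {
  est <- data.frame(gene_id = as.character(1:10), hybrid = "MxT", stage = 10,
                    A = rep(1, 10), B = rnorm(10, 2),
                    category = factor(rep("I", 10),
                                      levels = c("I", "II", "III", "IV", "V", "VI", "VII")))
  est$trans <- est$A - est$B
  ds <- direction_summaries(est)
  rowI <- ds$category_tests[ds$category_tests$category == "I", ]
  expect_equal(rowI$mean_A, 1)
  expect_lt(rowI$p_A, 1e-10)
  # categories of size < 2 are skipped with a flag
  expect_true(all(ds$category_tests$skipped[ds$category_tests$category != "I"]))
  expect_equal(ds$sign_tests$n_pos[ds$sign_tests$measure == "A"], 10)
})

test_that("cross-replicate correlation yields all ordered pairs", {
  sim <- tiny_sim(seed = 13, n_genes = 300)
  fit <- cistrans_fit(sim)
  cr <- correlation_crossrep(fit, "MxT", 10)
  expect_equal(nrow(cr$pairs), 6)  # 3 replicates -> 6 ordered combinations
  expect_true(all(cr$pairs$rep_B != cr$pairs$rep_Bprime))
  expect_true(all(abs(cr$pairs$r) <= 1))
})

test_that("standard correlation flags degenerate variance", {
  est <- data.frame(gene_id = as.character(1:5), hybrid = "MxT", stage = 10,
                    A = rnorm(5), B = rep(1, 5))
  est$trans <- est$A - est$B
  r <- correlation_standard(est)
  expect_true(r$degenerate)
  expect_true(is.na(r$r))
})

test_that("noiseless analytic estimates with independent c and t show no artifact", {
  # A and B built directly from truth (no shared measurement error): the
  # standard correlation has nothing to be biased by
  set.seed(17)
  c_ <- rnorm(2000, 0, 0.75); t_ <- rnorm(2000, 0, 0.75)
  est <- data.frame(gene_id = as.character(1:2000), hybrid = "MxT", stage = 10,
                    A = c_ + t_, B = c_)
  est$trans <- est$A - est$B
  r <- correlation_standard(est)$r
  expect_lt(abs(r), 0.1)
})
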