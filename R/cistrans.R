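# Core estimator: A/B/A-B divergence estimation, seven-category regulatory
# classification, reciprocal-hybrid consensus RD calling, and the
# standard vs. cross-replicate cis-trans correlation.

CATEGORIES <- c("I", "II", "III", "IV", "V", "VI", "VII")

#' Seven-category regulatory classification
#'
#' Pure decision table over the three tests (parental divergence A != 0,
#' allelic divergence B != 0, trans effect A != B) and the signs of the
#' point estimates:
#' \itemize{
#'   \item I cis-only: A != 0, B != 0, A = B
#'   \item II trans-only: A != 0, B = 0, A != B
#'   \item III cis+trans enhancing: A != 0, B != 0, A != B, sign(B) = sign(A-B)
#'   \item IV cis+trans compensating: as III with opposite signs
#'   \item V compensatory: A = 0, B != 0, A != B
#'   \item VI conserved: A = 0, B = 0, A = B
#'   \item VII ambiguous: every remaining (statistically conflicting or
#'     untestable) pattern
#' }
#' Significance means q < alpha and, for A and B, |estimate| >= lfc_cutoff.
#'
#' @param A,B log2 parental and allelic divergence point estimates.
#' @param q_A,q_B,q_AvsB BH-adjusted q-values of the three tests (NA =
#'   untestable).
#' @param alpha significance level (default 0.05).
#' @param lfc_cutoff optional |log2FC| cutoff layered on q < alpha for the
#'   A and B calls (default 0).
#' @return factor with levels I..VII.
#' @export
classify_regulation <- function(A, B, q_A, q_B, q_AvsB,
                                alpha = 0.05, lfc_cutoff = 0) {
  sigA <- !is.na(q_A) & q_A < alpha & abs(A) >= lfc_cutoff
  sigB <- !is.na(q_B) & q_B < alpha & abs(B) >= lfc_cutoff
  sigT <- !is.na(q_AvsB) & q_AvsB < alpha
  untestable <- is.na(q_A) | is.na(q_B) | is.na(q_AvsB)
  trans <- A - B
  same_dir <- sign(B) == sign(trans)
  cat <- rep("VII", length(A))
  cat[sigA & sigB & !sigT] <- "I"
  cat[sigA & !sigB & sigT] <- "II"
  cat[sigA & sigB & sigT & same_dir] <- "III"
  cat[sigA & sigB & sigT & !same_dir] <- "IV"
  cat[!sigA & sigB & sigT] <- "V"
  cat[!sigA & !sigB & !sigT] <- "VI"
  cat[untestable] <- "VII"
  factor(cat, levels = CATEGORIES)
}

# internal: analyse one hybrid x stage condition
.analyse_condition <- function(Mcnt, Tcnt, sfM, sfT, m_mat, t_mat,
                               alpha, lfc_cutoff, pseudocount) {
  resA <- test_pairwise(Mcnt, Tcnt, sfM, sfT, pseudocount = pseudocount)

  sf_all <- size_factors(cbind(m_mat, t_mat))
  sfm <- sf_all[seq_len(ncol(m_mat))]
  sft <- sf_all[ncol(m_mat) + seq_len(ncol(t_mat))]
  informative <- rowSums((m_mat + t_mat) > 0) >= 2
  resB <- test_pairwise(m_mat, t_mat, sfm, sft, pseudocount = pseudocount)
  resB$testable <- resB$testable & informative
  resB$q <- NA_real_
  resB$q[resB$testable] <- bh_adjust(resB$p[resB$testable])

  rA <- replicate_ratios(Mcnt, Tcnt, sfM, sfT, pseudocount)
  rB <- log2(sweep(m_mat, 2, sfm, "/") + pseudocount) -
        log2(sweep(t_mat, 2, sft, "/") + pseudocount)
  rB[(m_mat + t_mat) == 0] <- NA  # uninformative library for this gene
  resAB <- test_A_vs_B(rA, rB)
  resAB$testable <- resAB$testable & informative & resA$testable
  resAB$q <- NA_real_
  resAB$q[resAB$testable] <- bh_adjust(resAB$p[resAB$testable])

  A <- resA$log2fc
  B <- resB$log2fc
  q_A <- ifelse(resA$testable, resA$q, NA)
  q_B <- ifelse(resB$testable, resB$q, NA)
  q_T <- ifelse(resAB$testable, resAB$q, NA)
  data.frame(
    gene_id = resA$gene_id, A = A, B = B, trans = A - B,
    q_A = q_A, q_B = q_B, q_AvsB = q_T,
    category = classify_regulation(A, B, q_A, q_B, q_T, alpha, lfc_cutoff),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit the cis/trans regulatory-divergence model
#'
#' The package's core fitting function. For every hybrid x stage condition it
#' estimates per gene the parental divergence A = log2(M/T) (cis + trans),
#' the allelic divergence B = log2(m/t) within the hybrid (cis only), and the
#' trans effect A - B; attaches q-values of the three tests (NB Wald for A
#' and B, Welch t of replicate-level ratios for A vs B, each BH-corrected
#' across genes); assigns the seven regulatory categories; and derives the
#' reciprocal-hybrid consensus RD gene set with cis/trans typing.
#'
#' @param counts integer matrix of total read counts, genes x samples (or an
#'   \code{\link{simulate_ase}} result, in which case the remaining data
#'   arguments are taken from it).
#' @param samples sample sheet: sample_id, accession (M, T, MxT, TxM), stage,
#'   replicate.
#' @param allelic allele-resolved count matrix with column pairs
#'   \code{<lib>.M_allele} / \code{<lib>.T_allele} for each F1 library.
#' @param alpha significance level for all tests (default 0.05).
#' @param lfc_cutoff |log2FC| cutoff layered on q < alpha (default 0).
#' @param pseudocount added to normalized counts in all log-ratio estimates
#'   (default 0.5).
#' @param min_depth expression filter: a gene enters a stage's universe only
#'   if its mean parental read count exceeds this in at least one accession
#'   (default 5).
#' @return object of class \code{cistrans_fit}: \code{estimates} (long table
#'   gene x hybrid x stage with A, B, trans, q-values, category),
#'   \code{summary} (category counts and percentages per condition),
#'   \code{consensus} (per-stage reciprocal consensus), \code{rd} (RD genes
#'   with rd_type), \code{concordance}, plus inputs and parameters.
#' @export
cistrans_fit <- function(counts, samples = NULL, allelic = NULL,
                         alpha = 0.05, lfc_cutoff = 0,
                         pseudocount = 0.5, min_depth = 5) {
  if (inherits(counts, "ase_sim")) {
    sim <- counts
    counts <- sim$counts; samples <- sim$samples; allelic <- sim$allelic
  }
  counts <- as.matrix(counts)
  allelic <- as.matrix(allelic)
  validate_samples(samples, colnames(counts))
  validate_allelic(allelic, samples)

  stages <- sort(unique(samples$stage))
  hybrids <- c("MxT", "TxM")
  sf_tot <- size_factors(counts)

  estimates <- list(); universes <- list()
  for (st in stages) {
    mcols <- samples$sample_id[samples$accession == "M" & samples$stage == st]
    tcols <- samples$sample_id[samples$accession == "T" & samples$stage == st]
    if (length(mcols) < 2 || length(tcols) < 2)
      stop("need >= 2 parental replicates per accession at stage ", st)
    uni <- rowMeans(counts[, mcols, drop = FALSE]) > min_depth |
           rowMeans(counts[, tcols, drop = FALSE]) > min_depth
    universes[[as.character(st)]] <- rownames(counts)[uni]
    for (h in hybrids) {
      libs <- samples$sample_id[samples$accession == h & samples$stage == st]
      if (length(libs) < 2) stop("need >= 2 F1 libraries for ", h, " at stage ", st)
      m_mat <- allelic[uni, paste0(libs, ".M_allele"), drop = FALSE]
      t_mat <- allelic[uni, paste0(libs, ".T_allele"), drop = FALSE]
      est <- .analyse_condition(counts[uni, mcols, drop = FALSE],
                                counts[uni, tcols, drop = FALSE],
                                sf_tot[mcols], sf_tot[tcols],
                                m_mat, t_mat, alpha, lfc_cutoff, pseudocount)
      est$hybrid <- h; est$stage <- st
      estimates[[paste(h, st)]] <- est
    }
  }
  estimates <- do.call(rbind, estimates)
  rownames(estimates) <- NULL
  estimates <- estimates[, c("gene_id", "hybrid", "stage", "A", "B", "trans",
                             "q_A", "q_B", "q_AvsB", "category")]

  summ <- do.call(rbind, lapply(split(estimates, list(estimates$hybrid, estimates$stage)),
    function(d) {
      tab <- table(d$category)
      data.frame(hybrid = d$hybrid[1], stage = d$stage[1],
                 category = names(tab), n = as.integer(tab),
                 pct = 100 * as.integer(tab) / nrow(d),
                 stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL

  cons <- consensus_rd(estimates)
  rd <- rd_type(cons)

  fit <- structure(list(
    estimates = estimates, summary = summ, consensus = cons$consensus,
    concordance = cons$concordance, rd = rd,
    counts = counts, samples = samples, allelic = allelic,
    size_factors = sf_tot, universes = universes,
    params = list(alpha = alpha, lfc_cutoff = lfc_cutoff,
                  pseudocount = pseudocount, min_depth = min_depth)
  ), class = "cistrans_fit")
  fit
}

#' Reciprocal-hybrid consensus and RD calling
#'
#' A gene displays regulatory divergence (RD) at a stage iff both reciprocal
#' hybrids assign it the same divergent category (I-V). Concordance between
#' hybrids is reported both over all genes and excluding genes ambiguous
#' (VII) in either hybrid.
#'
#' @param estimates the \code{estimates} table of a \code{cistrans_fit} (or
#'   any data.frame with gene_id, hybrid, stage, category).
#' @return list: \code{consensus} (gene_id, stage, cat_MxT, cat_TxM, rd,
#'   category) and \code{concordance} (per stage, overall and
#'   ambiguity-excluded agreement rates).
#' @export
consensus_rd <- function(estimates) {
  if (inherits(estimates, "cistrans_fit")) estimates <- estimates$estimates
  stages <- sort(unique(estimates$stage))
  cons <- list(); conc <- list()
  for (st in stages) {
    a <- estimates[estimates$hybrid == "MxT" & estimates$stage == st, ]
    b <- estimates[estimates$hybrid == "TxM" & estimates$stage == st, ]
    b <- b[match(a$gene_id, b$gene_id), ]
    agree <- as.character(a$category) == as.character(b$category)
    amb <- a$category == "VII" | b$category == "VII"
    rd <- agree & a$category %in% c("I", "II", "III", "IV", "V")
    cons[[as.character(st)]] <- data.frame(
      gene_id = a$gene_id, stage = st,
      cat_MxT = as.character(a$category), cat_TxM = as.character(b$category),
      rd = rd, category = ifelse(rd, as.character(a$category), NA),
      stringsAsFactors = FALSE)
    conc[[as.character(st)]] <- data.frame(
      stage = st, n_genes = nrow(a),
      concordance_all = mean(agree),
      concordance_excl_ambiguous = mean(agree[!amb]),
      n_rd = sum(rd), stringsAsFactors = FALSE)
  }
  list(consensus = do.call(rbind, c(cons, make.row.names = FALSE)),
       concordance = do.call(rbind, c(conc, make.row.names = FALSE)))
}

#' Type RD genes as cis-only, trans-only or cis+trans
#'
#' Union of per-stage RD genes; a gene is cis_only when category I is the
#' only divergent consensus category it shows across stages (with no
#' divergence at the other stage), trans_only likewise for II, and cis_trans
#' in every other case (III-V involve both effects).
#'
#' @param consensus the \code{consensus} element of \code{\link{consensus_rd}}
#'   (or its list result).
#' @return data.frame: gene_id, rd_type, stage_support.
#' @export
rd_type <- function(consensus) {
  if (is.list(consensus) && !is.data.frame(consensus)) consensus <- consensus$consensus
  rd <- consensus[consensus$rd, ]
  if (!nrow(rd)) {
    return(data.frame(gene_id = character(), rd_type = character(),
                      stage_support = character(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(rd, rd$gene_id), function(d) {
    cats <- unique(d$category)
    type <- if (identical(cats, "I")) "cis_only"
            else if (identical(cats, "II")) "trans_only"
            else "cis_trans"
    data.frame(gene_id = d$gene_id[1], rd_type = type,
               stage_support = paste(sort(unique(d$stage)), collapse = "+"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  out[order(out$gene_id), , drop = FALSE]
}

#' Standard (shared-replicate) cis-trans correlation
#'
#' Pearson correlation between B and A - B with the same B estimate in both
#' coordinates. This estimator is intrinsically biased toward negative
#' values because measurement error in B enters the two coordinates with
#' opposite sign; see \code{\link{correlation_crossrep}} for the bias-free
#' alternative.
#'
#' @param estimates a \code{cistrans_fit} or its \code{estimates} table.
#' @return data.frame per hybrid x stage: r, n, degenerate flag.
#' @export
correlation_standard <- function(estimates) {
  if (inherits(estimates, "cistrans_fit")) estimates <- estimates$estimates
  out <- lapply(split(estimates, list(estimates$hybrid, estimates$stage)), function(d) {
    ok <- is.finite(d$B) & is.finite(d$trans)
    degenerate <- sum(ok) < 3 || stats::sd(d$B[ok]) == 0 || stats::sd(d$trans[ok]) == 0
    r <- if (degenerate) NA_real_ else stats::cor(d$B[ok], d$trans[ok])
    data.frame(hybrid = d$hybrid[1], stage = d$stage[1], r = r, n = sum(ok),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Cross-replicate cis-trans correlation
#'
#' Removes the shared-error artifact of the standard estimator by computing
#' B from one F1 replicate and B' (entering A - B') from a different
#' replicate, so the two coordinates carry independent measurement errors.
#' A is recomputed from all parental replicates and is common to both
#' reciprocal hybrids. All ordered replicate pairs (i, j), i != j are
#' analysed: with 3 replicates, exactly 6 combinations.
#'
#' @param fit a \code{cistrans_fit} object.
#' @param hybrid "MxT" or "TxM".
#' @param stage one of the fitted stages.
#' @param pseudocount stabilizer for single-replicate ratios (defaults to the
#'   fit's).
#' @return list: \code{pairs} (rep_B, rep_Bprime, r, n) and \code{mean_r}.
#' @export
correlation_crossrep <- function(fit, hybrid = "MxT", stage = NULL,
                                 pseudocount = NULL) {
  stopifnot(inherits(fit, "cistrans_fit"))
  samples <- fit$samples
  if (is.null(stage)) stage <- sort(unique(samples$stage))[1]
  ps <- pseudocount %||% fit$params$pseudocount
  libs <- samples$sample_id[samples$accession == hybrid & samples$stage == stage]
  if (length(libs) < 2) stop("cross-replicate correlation needs >= 2 F1 replicates")
  uni <- fit$universes[[as.character(stage)]]

  m_mat <- fit$allelic[uni, paste0(libs, ".M_allele"), drop = FALSE]
  t_mat <- fit$allelic[uni, paste0(libs, ".T_allele"), drop = FALSE]
  sf_all <- size_factors(cbind(m_mat, t_mat))
  sfm <- sf_all[seq_along(libs)]; sft <- sf_all[length(libs) + seq_along(libs)]
  Bmat <- log2(sweep(m_mat, 2, sfm, "/") + ps) - log2(sweep(t_mat, 2, sft, "/") + ps)

  est <- fit$estimates
  A <- est$A[est$hybrid == hybrid & est$stage == stage]
  names(A) <- est$gene_id[est$hybrid == hybrid & est$stage == stage]
  A <- A[uni]

  idx <- expand.grid(i = seq_along(libs), j = seq_along(libs))
  idx <- idx[idx$i != idx$j, ]
  rows <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx$i[k]; j <- idx$j[k]
    ok <- is.finite(Bmat[, i]) & is.finite(A - Bmat[, j])
    data.frame(rep_B = i, rep_Bprime = j,
               r = stats::cor(Bmat[ok, i], (A - Bmat[, j])[ok]),
               n = sum(ok), stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  list(pairs = pairs, mean_r = mean(pairs$r))
}

#' Proportion of expression divergence attributable to cis effects
#'
#' Per gene, |B| / (|B| + |A - B|), the share of the total absolute
#' divergence due to cis; always in [0, 1], equal to 1 iff A = B (pure cis)
#' and 0 iff B = 0 (pure trans). Genes are binned by absolute parental
#' divergence |A| into half-open intervals [1,2), [2,3), [3,4), [4, Inf) and
#' per-bin means are reported with 95% normal CIs.
#'
#' @param estimates a \code{cistrans_fit} or its estimates table (needs
#'   columns A, B, trans).
#' @return list: \code{per_gene} (gene_id, cis_prop), \code{bins} (bin, n,
#'   mean, ci_lo, ci_hi), \code{n_excluded} genes with |B| + |A-B| = 0.
#' @export
cis_proportion <- function(estimates) {
  if (inherits(estimates, "cistrans_fit")) estimates <- estimates$estimates
  denom <- abs(estimates$B) + abs(estimates$trans)
  ok <- is.finite(denom) & denom > 0
  prop <- abs(estimates$B[ok]) / denom[ok]
  absA <- abs(estimates$A[ok])
  breaks <- c(1, 2, 3, 4, Inf)
  bin <- cut(absA, breaks, right = FALSE,
             labels = c("[1,2)", "[2,3)", "[3,4)", ">=4"))
  bins <- do.call(rbind, lapply(levels(bin), function(b) {
    v <- prop[!is.na(bin) & bin == b]
    n <- length(v)
    se <- if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
    data.frame(bin = b, n = n, mean = if (n) mean(v) else NA_real_,
               ci_lo = if (n) mean(v) - 1.96 * se else NA_real_,
               ci_hi = if (n) mean(v) + 1.96 * se else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(per_gene = data.frame(gene_id = estimates$gene_id[ok], cis_prop = prop,
                             abs_A = absA, stringsAsFactors = FALSE),
       bins = bins, n_excluded = sum(!ok & is.finite(denom)))
}

#' Chi-squared test of sign counts against a 50:50 split
#'
#' @param n_pos,n_neg counts of positive and negative values (zeros excluded
#'   by the caller).
#' @return list(statistic, p, n_pos, n_neg).
#' @export
sign_chisq <- function(n_pos, n_neg) {
  n <- n_pos + n_neg
  if (n == 0) return(list(statistic = NA_real_, p = NA_real_,
                          n_pos = n_pos, n_neg = n_neg))
  ct <- stats::chisq.test(c(n_pos, n_neg), p = c(0.5, 0.5), correct = FALSE)
  list(statistic = unname(ct$statistic), p = ct$p.value,
       n_pos = n_pos, n_neg = n_neg)
}

#' Magnitude and direction summaries per regulatory category
#'
#' Per category: one-sample t-tests of A and of B against zero (skipped with
#' a flag below 2 genes). Globally: 1-df chi-squared tests of the counts of
#' positive vs. negative A (and B) against 50:50, zeros excluded.
#'
#' @param estimates a \code{cistrans_fit} or its estimates table.
#' @param categories which categories to summarise (default I-V).
#' @return list: \code{category_tests} data.frame and \code{sign_tests}
#'   data.frame (one row for A, one for B).
#' @export
direction_summaries <- function(estimates, categories = c("I", "II", "III", "IV", "V")) {
  if (inherits(estimates, "cistrans_fit")) estimates <- estimates$estimates
  cat_tests <- do.call(rbind, lapply(categories, function(k) {
    d <- estimates[estimates$category == k, ]
    row <- data.frame(category = k, n = nrow(d),
                      mean_A = NA_real_, t_A = NA_real_, p_A = NA_real_,
                      mean_B = NA_real_, t_B = NA_real_, p_B = NA_real_,
                      skipped = nrow(d) < 2, stringsAsFactors = FALSE)
    if (nrow(d) >= 2) {
      one_sample <- function(v) {
        if (stats::sd(v) > 0) {
          tt <- stats::t.test(v)
          c(mean(v), unname(tt$statistic), tt$p.value)
        } else {
          # constant vector: zero within-sample variance, so any nonzero
          # mean deviates from zero with certainty
          c(mean(v), if (mean(v) == 0) 0 else Inf, as.numeric(mean(v) == 0))
        }
      }
      a <- one_sample(d$A); b <- one_sample(d$B)
      row$mean_A <- a[1]; row$t_A <- a[2]; row$p_A <- a[3]
      row$mean_B <- b[1]; row$t_B <- b[2]; row$p_B <- b[3]
    }
    row
  }))
  sel <- estimates$category %in% categories
  sA <- sign_chisq(sum(estimates$A[sel] > 0), sum(estimates$A[sel] < 0))
  sB <- sign_chisq(sum(estimates$B[sel] > 0), sum(estimates$B[sel] < 0))
  sign_tests <- data.frame(
    measure = c("A", "B"),
    n_pos = c(sA$n_pos, sB$n_pos), n_neg = c(sA$n_neg, sB$n_neg),
    chisq = c(sA$statistic, sB$statistic), p = c(sA$p, sB$p),
    stringsAsFactors = FALSE)
  list(category_tests = cat_tests, sign_tests = sign_tests)
}
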