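# Inheritance-mode classification of parental expression divergence from F1
# total expression, and its association with the regulatory categories.

INHERITANCE_MODES <- c("additive", "dominant_M", "dominant_T",
                       "transgressive_up", "transgressive_down", "unassigned")

#' Classify expression inheritance mode in an F1 hybrid
#'
#' For genes with significant parental divergence (q_A < alpha in the
#' supplied fit), three contrasts are tested with the NB Wald machinery:
#' F1 vs parent M (qm), F1 vs parent T (qt), and F1 vs the arithmetic
#' midparent of replicate-paired normalized parental counts (qmid).
#' Decision table: additive iff the midparent is not rejected while both
#' single-parent contrasts are; dominant toward the parent whose contrast is
#' not rejected; transgressive when both parents are rejected, the midparent
#' is rejected, and the F1 mean lies outside the parental range; every other
#' pattern (statistically conflicting) is unassigned.
#'
#' @param fit a \code{\link{cistrans_fit}}.
#' @param hybrid "MxT" or "TxM".
#' @param stage stage to classify (default: first).
#' @param alpha significance level (defaults to the fit's).
#' @return data.frame of class \code{inheritance_calls}: gene_id, hybrid,
#'   stage, mode, qm, qt, qmid, f1_mean, m_mean, t_mean.
#' @export
classify_inheritance <- function(fit, hybrid = "MxT", stage = NULL, alpha = NULL) {
  stopifnot(inherits(fit, "cistrans_fit"))
  samples <- fit$samples
  if (is.null(stage)) stage <- sort(unique(samples$stage))[1]
  alpha <- alpha %||% fit$params$alpha
  ps <- fit$params$pseudocount
  uni <- fit$universes[[as.character(stage)]]

  mcols <- samples$sample_id[samples$accession == "M" & samples$stage == stage]
  tcols <- samples$sample_id[samples$accession == "T" & samples$stage == stage]
  fcols <- samples$sample_id[samples$accession == hybrid & samples$stage == stage]
  sf <- fit$size_factors
  M <- fit$counts[uni, mcols, drop = FALSE]
  T_ <- fit$counts[uni, tcols, drop = FALSE]
  F1 <- fit$counts[uni, fcols, drop = FALSE]

  est <- fit$estimates
  est <- est[est$hybrid == hybrid & est$stage == stage, ]
  est <- est[match(uni, est$gene_id), ]
  divergent <- !is.na(est$q_A) & est$q_A < alpha

  res_m <- test_pairwise(F1, M, sf[fcols], sf[mcols], pseudocount = ps)
  res_t <- test_pairwise(F1, T_, sf[fcols], sf[tcols], pseudocount = ps)

  # arithmetic midparent on normalized counts, replicate-paired; the extra
  # replicate of the larger parental group pairs with the other group's mean
  Mn <- sweep(M, 2, sf[mcols], "/"); Tn <- sweep(T_, 2, sf[tcols], "/")
  nm <- ncol(Mn); nt <- ncol(Tn); npair <- max(nm, nt)
  mid <- matrix(NA_real_, nrow(Mn), npair, dimnames = list(rownames(Mn), NULL))
  mM <- rowMeans(Mn); mT <- rowMeans(Tn)
  for (i in seq_len(npair)) {
    a <- if (i <= nm) Mn[, i] else mM
    b <- if (i <= nt) Tn[, i] else mT
    mid[, i] <- (a + b) / 2
  }
  res_mid <- test_pairwise(F1, mid, sf[fcols], rep(1, npair), pseudocount = ps)

  # BH within each contrast across the divergent gene set
  qm <- qt <- qmid <- rep(NA_real_, length(uni))
  qm[divergent] <- bh_adjust(res_m$p[divergent])
  qt[divergent] <- bh_adjust(res_t$p[divergent])
  qmid[divergent] <- bh_adjust(res_mid$p[divergent])

  f1_mean <- res_m$mean1; m_mean <- res_m$mean2; t_mean <- res_t$mean2
  mode <- rep("unassigned", length(uni))
  sig_m <- qm < alpha; sig_t <- qt < alpha; sig_mid <- qmid < alpha
  both <- divergent & sig_m & sig_t
  mode[both & !sig_mid] <- "additive"
  mode[both & sig_mid & f1_mean > pmax(m_mean, t_mean)] <- "transgressive_up"
  mode[both & sig_mid & f1_mean < pmin(m_mean, t_mean)] <- "transgressive_down"
  mode[divergent & !sig_m & sig_t] <- "dominant_M"
  mode[divergent & sig_m & !sig_t] <- "dominant_T"
  mode[!divergent] <- NA  # only A != 0 genes are classified

  out <- data.frame(gene_id = uni, hybrid = hybrid, stage = stage,
                    mode = mode, qm = qm, qt = qt, qmid = qmid,
                    f1_mean = f1_mean, m_mean = m_mean, t_mean = t_mean,
                    stringsAsFactors = FALSE)
  out <- out[divergent, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("inheritance_calls", "data.frame")
  out
}

#' Association between inheritance mode and regulatory category
#'
#' Cross-tabulates inheritance modes (rows) against regulatory categories
#' I-V (columns) on the shared gene set, reports Pearson residuals
#' (obs - exp) / sqrt(exp) of the chi-square test of independence, a
#' per-cell two-sided Fisher exact p (2x2 collapse of each cell against the
#' rest), and the global chi-square test.
#'
#' @param inheritance an \code{inheritance_calls} table.
#' @param calls a data.frame with gene_id and category (e.g. the fit's
#'   estimates for the matching hybrid x stage).
#' @return list: \code{table}, \code{residuals}, \code{fisher_p} (matrices),
#'   \code{global_chisq}, \code{global_p}; empty rows/columns are dropped
#'   and recorded in \code{dropped}.
#' @export
inheritance_by_category <- function(inheritance, calls) {
  g <- intersect(inheritance$gene_id, calls$gene_id)
  mode <- inheritance$mode[match(g, inheritance$gene_id)]
  cat <- as.character(calls$category[match(g, calls$gene_id)])
  keep <- !is.na(mode) & mode != "unassigned" & cat %in% c("I", "II", "III", "IV", "V")
  tab <- table(factor(mode[keep], levels = setdiff(INHERITANCE_MODES, "unassigned")),
               factor(cat[keep], levels = c("I", "II", "III", "IV", "V")))
  dropped <- list(rows = rownames(tab)[rowSums(tab) == 0],
                  cols = colnames(tab)[colSums(tab) == 0])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(table = tab, residuals = NULL, fisher_p = NULL,
                global_chisq = NA, global_p = NA, dropped = dropped))
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  resid <- (tab - exp) / sqrt(exp)
  fisher_p <- tab * NA
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    a <- tab[i, j]
    b <- sum(tab[i, ]) - a
    c_ <- sum(tab[, j]) - a
    d <- sum(tab) - a - b - c_
    fisher_p[i, j] <- stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value
  }
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, residuals = resid, fisher_p = fisher_p,
       global_chisq = unname(chi$statistic), global_p = chi$p.value,
       dropped = dropped)
}

#' Dominance direction split per regulatory category
#'
#' Among dominant genes of each category, the percentage that are
#' M-dominant, with a binomial 95% CI and the 50% no-preference reference.
#'
#' @param inheritance an \code{inheritance_calls} table.
#' @param calls data.frame with gene_id and category.
#' @return data.frame: category, n_dominant, pct_dominant_M, ci_lo, ci_hi,
#'   reference (50), flagged when the category holds no dominant genes.
#' @export
dominance_split <- function(inheritance, calls) {
  .mode_split(inheritance, calls, modes = c("dominant_M", "dominant_T"),
              up = "dominant_M", label = "pct_dominant_M")
}

#' Transgression direction split per regulatory category
#'
#' Among transgressive genes of each category, the percentage up-regulated.
#'
#' @inheritParams dominance_split
#' @return data.frame as in \code{\link{dominance_split}} with
#'   \code{pct_up}.
#' @export
transgressive_split <- function(inheritance, calls) {
  .mode_split(inheritance, calls, modes = c("transgressive_up", "transgressive_down"),
              up = "transgressive_up", label = "pct_up")
}

.mode_split <- function(inheritance, calls, modes, up, label) {
  g <- intersect(inheritance$gene_id, calls$gene_id)
  mode <- inheritance$mode[match(g, inheritance$gene_id)]
  cat <- as.character(calls$category[match(g, calls$gene_id)])
  out <- do.call(rbind, lapply(c("I", "II", "III", "IV", "V"), function(k) {
    sel <- cat == k & mode %in% modes & !is.na(mode)
    n <- sum(sel)
    if (n == 0) {
      return(data.frame(category = k, n = 0L, pct = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        reference = 50, flagged = TRUE, stringsAsFactors = FALSE))
    }
    x <- sum(mode[sel] == up)
    ci <- stats::binom.test(x, n)$conf.int
    data.frame(category = k, n = n, pct = 100 * x / n,
               ci_lo = 100 * ci[1], ci_hi = 100 * ci[2],
               reference = 50, flagged = FALSE, stringsAsFactors = FALSE)
  }))
  names(out)[names(out) == "pct"] <- label
  out
}
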