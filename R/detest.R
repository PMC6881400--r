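# Count normalization and the statistical tests underlying classification:
# A != 0 and B != 0 (negative-binomial Wald), A != B (Welch t on replicate
# log-ratios), with Benjamini-Hochberg correction.

#' Median-of-ratios size factors
#'
#' Per-sample scale factors: for each sample the median over genes of
#' count / geometric row mean, computed on genes with all-positive counts,
#' then rescaled to geometric mean 1. Falls back to total-count
#' normalization (with a warning) when no gene is positive in every sample.
#'
#' @param counts numeric matrix, genes x samples.
#' @return positive numeric vector, one factor per column, geometric mean 1.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1) stop("need at least one sample")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no gene has positive counts in all samples; using total-count normalization")
    tot <- colSums(counts)
    if (any(tot == 0)) stop("sample with zero total count cannot be normalized")
    sf <- tot / exp(mean(log(tot)))
    return(stats::setNames(sf, colnames(counts)))
  }
  k <- counts[pos, , drop = FALSE]
  gm <- exp(rowMeans(log(k)))
  sf <- apply(k / gm, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values; NA p-values are excluded from the family size
#' and returned as NA.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs allowed).
#' @return q-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# trended method-of-moments dispersion, squeezed toward a phi ~ a0 + a1/mu fit
.moment_dispersion <- function(norm1, norm2, sf1, sf2) {
  n1 <- ncol(norm1); n2 <- ncol(norm2)
  mu1 <- rowMeans(norm1); mu2 <- rowMeans(norm2)
  df <- (n1 - 1) + (n2 - 1)
  if (df < 1) stop("need at least 2 replicates overall beyond group count")
  v1 <- if (n1 > 1) row_vars(norm1) else 0
  v2 <- if (n2 > 1) row_vars(norm2) else 0
  s2 <- ((n1 - 1) * ifelse(is.na(v1), 0, v1) + (n2 - 1) * ifelse(is.na(v2), 0, v2)) / df
  mu_bar <- (n1 * mu1 + n2 * mu2) / (n1 + n2)
  # Var(K/s) = mu/s + phi mu^2; subtract the mean shot-noise term
  cbar <- mean(c(1 / sf1, 1 / sf2))
  phi_raw <- (s2 - mu_bar * cbar) / mu_bar^2
  phi_raw[!is.finite(phi_raw)] <- NA
  ok <- is.finite(phi_raw) & mu_bar > 0
  phi_pos <- pmax(phi_raw, 0)
  # trend phi(mu) = a0 + a1/mu, coefficients clamped nonnegative
  trend <- rep(stats::median(phi_pos[ok], na.rm = TRUE), length(mu_bar))
  if (sum(ok) >= 10) {
    fit <- try(stats::lm(phi_pos[ok] ~ I(1 / mu_bar[ok])), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      a <- pmax(stats::coef(fit), 0)
      trend <- a[1] + a[2] / pmax(mu_bar, 1e-8)
    }
  }
  trend[!is.finite(trend)] <- 0
  d0 <- 10  # prior weight of the trend, in residual-df units
  phi <- (d0 * trend + df * ifelse(is.na(phi_raw), trend, phi_pos)) / (d0 + df)
  pmax(phi, 0)
}

#' Negative-binomial Wald test of equal means between two replicate groups
#'
#' Normalizes each group's columns by the supplied (or internally computed)
#' size factors, estimates a per-gene NB dispersion by method of moments
#' squeezed toward a mean-dispersion trend, and tests equality of group means
#' with a Wald statistic on the log scale. Used for parental divergence
#' (A: M vs T totals), allelic divergence (B: m vs t counts per hybrid),
#' homoeolog bias (At vs Dt), and homoeolog-total contrasts.
#'
#' @param counts1,counts2 matrices (genes x replicates) on a shared gene
#'   universe (same row order).
#' @param sf1,sf2 size factors for the columns of each matrix; when NULL,
#'   median-of-ratios factors are computed on \code{cbind(counts1, counts2)}.
#' @param pseudocount added to normalized group means for the log2
#'   fold-change estimate (default 0.5).
#' @param min_depth genes whose mean raw count is \code{<= min_depth} in
#'   every group are flagged untestable (estimate 0, p = 1). Default 0
#'   (caller applies the expression filter).
#' @return data.frame: gene_id, log2fc (group1 over group2), se, p, q,
#'   testable, mean1, mean2 (normalized means).
#' @export
test_pairwise <- function(counts1, counts2, sf1 = NULL, sf2 = NULL,
                          pseudocount = 0.5, min_depth = 0) {
  counts1 <- as.matrix(counts1); counts2 <- as.matrix(counts2)
  if (nrow(counts1) != nrow(counts2)) stop("groups must share the gene universe")
  n1 <- ncol(counts1); n2 <- ncol(counts2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 replicates per group")
  if (is.null(sf1) || is.null(sf2)) {
    sf <- size_factors(cbind(counts1, counts2))
    sf1 <- sf[seq_len(n1)]; sf2 <- sf[n1 + seq_len(n2)]
  }
  norm1 <- sweep(counts1, 2, sf1, "/")
  norm2 <- sweep(counts2, 2, sf2, "/")
  mu1 <- rowMeans(norm1); mu2 <- rowMeans(norm2)
  phi <- .moment_dispersion(norm1, norm2, sf1, sf2)

  testable <- !(rowMeans(counts1) <= min_depth & rowMeans(counts2) <= min_depth)
  testable <- testable & (mu1 + mu2 > 0)

  lfc <- log2((mu1 + pseudocount) / (mu2 + pseudocount))
  # Var(mean of normalized counts) per group, delta method to the log scale
  v1 <- (mu1 * mean(1 / sf1) + phi * mu1^2) / n1
  v2 <- (mu2 * mean(1 / sf2) + phi * mu2^2) / n2
  vlog <- v1 / (mu1 + pseudocount)^2 + v2 / (mu2 + pseudocount)^2
  se <- sqrt(vlog) / log(2)
  z <- log((mu1 + pseudocount) / (mu2 + pseudocount)) / sqrt(vlog)
  p <- 2 * stats::pnorm(-abs(z))
  p[vlog == 0] <- ifelse(mu1[vlog == 0] == mu2[vlog == 0], 1, 0)
  lfc[!testable] <- 0; p[!testable] <- 1; se[!testable] <- NA

  q <- rep(NA_real_, length(p))
  q[testable] <- bh_adjust(p[testable])
  data.frame(gene_id = rownames(counts1) %||% as.character(seq_along(p)),
             log2fc = lfc, se = se, p = p, q = q,
             testable = testable, mean1 = mu1, mean2 = mu2,
             stringsAsFactors = FALSE, row.names = NULL)
}

# vectorised Welch two-sample t-test over rows of two ratio matrices;
# returns list(estimate, t, df, p); rows with < 2 finite values on either
# side get p = 1 and testable = FALSE
welch_rows <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  nx <- rowSums(is.finite(x)); ny <- rowSums(is.finite(y))
  x[!is.finite(x)] <- NA; y[!is.finite(y)] <- NA
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- apply(x, 1, stats::var, na.rm = TRUE)
  vy <- apply(y, 1, stats::var, na.rm = TRUE)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- is.finite(se2) & se2 == 0
  p[zero] <- ifelse(abs(mx[zero] - my[zero]) < 1e-12, 1, 0)
  tstat[zero] <- ifelse(abs(mx[zero] - my[zero]) < 1e-12, 0, Inf)
  testable <- nx >= 2 & ny >= 2
  p[!testable] <- 1
  list(estimate = mx - my, t = tstat, df = df, p = p, testable = testable)
}

#' Welch t-test of parental vs. allelic log-ratios (trans-effect test)
#'
#' Tests A != B per gene by comparing the set of replicate-level parental
#' log2(M_i / T_i) ratios against the set of replicate-level allelic
#' log2(m_j / t_j) ratios (Welch, unequal variances). Ratios must be built
#' from normalized counts with a pseudocount (see
#' \code{\link{replicate_ratios}}).
#'
#' @param parental_ratios matrix of replicate-level parental log2 ratios
#'   (genes x replicate pairs).
#' @param allelic_ratios matrix of replicate-level allelic log2 ratios
#'   (genes x F1 libraries).
#' @return data.frame: gene_id, estimate (mean parental minus mean allelic
#'   ratio), t, df, p, q, testable.
#' @export
test_A_vs_B <- function(parental_ratios, allelic_ratios) {
  w <- welch_rows(parental_ratios, allelic_ratios)
  q <- rep(NA_real_, length(w$p))
  q[w$testable] <- bh_adjust(w$p[w$testable])
  data.frame(gene_id = rownames(parental_ratios) %||% as.character(seq_along(w$p)),
             estimate = w$estimate, t = w$t, df = w$df, p = w$p, q = q,
             testable = w$testable, stringsAsFactors = FALSE, row.names = NULL)
}

#' Replicate-level log2 ratios between two matched column groups
#'
#' Pairs column i of \code{counts1} with column i of \code{counts2} after
#' normalization; when replicate numbers differ, each extra replicate is
#' paired with the other group's mean. Returns
#' log2((x + ps) / (y + ps)) per gene per pair.
#'
#' @param counts1,counts2 count matrices (genes x replicates).
#' @param sf1,sf2 size factors for their columns.
#' @param pseudocount stabilizer (default 0.5).
#' @return matrix, genes x max(ncol1, ncol2).
#' @export
replicate_ratios <- function(counts1, counts2, sf1, sf2, pseudocount = 0.5) {
  norm1 <- sweep(as.matrix(counts1), 2, sf1, "/")
  norm2 <- sweep(as.matrix(counts2), 2, sf2, "/")
  n1 <- ncol(norm1); n2 <- ncol(norm2)
  n <- max(n1, n2)
  m1 <- rowMeans(norm1); m2 <- rowMeans(norm2)
  out <- matrix(NA_real_, nrow(norm1), n)
  for (i in seq_len(n)) {
    a <- if (i <= n1) norm1[, i] else m1
    b <- if (i <= n2) norm2[, i] else m2
    out[, i] <- log2((a + pseudocount) / (b + pseudocount))
  }
  rownames(out) <- rownames(counts1)
  out
}
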