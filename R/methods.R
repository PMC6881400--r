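# S3 methods for cistrans_fit

#' @export
print.cistrans_fit <- function(x, ...) {
  cat("cis/trans regulatory-divergence fit\n")
  cat(sprintf("  %d genes x %d samples; stages: %s; alpha = %g, lfc >= %g\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$samples$stage)), collapse = ", "),
              x$params$alpha, x$params$lfc_cutoff))
  for (st in names(x$universes))
    cat(sprintf("  stage %s: %d genes pass the depth filter\n",
                st, length(x$universes[[st]])))
  cat(sprintf("  RD genes (reciprocal consensus, union over stages): %d\n",
              nrow(x$rd)))
  invisible(x)
}

#' @export
summary.cistrans_fit <- function(object, ...) {
  out <- list(
    categories = object$summary,
    concordance = object$concordance,
    rd_types = table(object$rd$rd_type),
    correlation_standard = correlation_standard(object),
    params = object$params)
  class(out) <- "summary.cistrans_fit"
  out
}

#' @export
print.summary.cistrans_fit <- function(x, ...) {
  cat("Regulatory category composition (% of depth-filtered genes):\n")
  wide <- stats::xtabs(pct ~ paste(hybrid, stage) + category, data = x$categories)
  print(round(wide, 1))
  cat("\nReciprocal-hybrid concordance:\n")
  print(x$concordance, row.names = FALSE)
  cat("\nRD gene types:\n")
  print(x$rd_types)
  cat("\nStandard (shared-replicate) cis-trans correlation r(B, A-B):\n")
  print(x$correlation_standard, row.names = FALSE)
  invisible(x)
}

#' Extract divergence estimates
#'
#' @param object a \code{cistrans_fit}.
#' @param hybrid,stage optional filters; defaults to all conditions.
#' @param ... unused.
#' @return data.frame with gene_id, hybrid, stage, A, B, trans.
#' @export
coef.cistrans_fit <- function(object, hybrid = NULL, stage = NULL, ...) {
  e <- object$estimates
  if (!is.null(hybrid)) e <- e[e$hybrid %in% hybrid, ]
  if (!is.null(stage)) e <- e[e$stage %in% stage, ]
  e[, c("gene_id", "hybrid", "stage", "A", "B", "trans")]
}

#' Scatter plot of allelic (cis) vs. parental divergence by category
#'
#' B (y) against A (x) for one hybrid x stage condition, colored by the
#' seven regulatory categories, with the A = B diagonal (pure cis) and the
#' axes (pure trans / compensatory) as reference lines.
#'
#' @param x a \code{cistrans_fit}.
#' @param hybrid,stage condition to display (defaults: first of each).
#' @param ... passed to \code{plot}.
#' @export
plot.cistrans_fit <- function(x, hybrid = "MxT", stage = NULL, ...) {
  e <- x$estimates
  if (is.null(stage)) stage <- sort(unique(e$stage))[1]
  e <- e[e$hybrid == hybrid & e$stage == stage, ]
  cols <- c(I = "#D55E00", II = "#0072B2", III = "#009E73", IV = "#CC79A7",
            V = "#E69F00", VI = "grey70", VII = "grey40")
  ord <- order(e$category, decreasing = TRUE)  # divergent categories on top
  graphics::plot(e$A[ord], e$B[ord], col = cols[as.character(e$category[ord])],
                 pch = 16, cex = 0.4,
                 xlab = "parental divergence A = log2(M/T)",
                 ylab = "allelic divergence B = log2(m/t)",
                 main = sprintf("%s, stage %s", hybrid, stage), ...)
  graphics::abline(0, 1, lty = 2); graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   cex = 0.7, bty = "n")
  invisible(x)
}
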