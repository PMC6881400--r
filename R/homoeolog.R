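# Allopolyploid layer: syntenic 1:1:1 triplet extraction, At/Dt homoeolog
# expression bias, domestication change of homoeolog ratio and total, and
# association with regulatory-divergence status.

#' Extract 1:1:1 syntenic triplets from a homology graph
#'
#' Computes connected components of the collinearity-derived homology graph
#' and keeps only components containing exactly one gene per (sub)genome —
#' the high-confidence multi-genome anchors; all other components are
#' rejected and counted by reason (a genome missing, or represented more
#' than once).
#'
#' @param edges data.frame with two columns of gene ids (undirected edges);
#'   self-edges are dropped.
#' @param nodes data.frame with columns \code{gene} and \code{genome}; every
#'   gene appearing in \code{edges} must be labelled.
#' @param genomes the expected genome labels (default
#'   \code{c("outgroup", "At", "Dt")}), in the column order of the output.
#' @return list: \code{triplets} (data.frame, one column per genome),
#'   \code{rejected} (counts by reason), \code{n_components}.
#' @export
extract_triplets <- function(edges, nodes, genomes = c("outgroup", "At", "Dt")) {
  stopifnot(ncol(edges) >= 2, all(c("gene", "genome") %in% names(nodes)))
  if (anyDuplicated(nodes$gene)) stop("duplicate gene labels in node table")
  edges <- edges[as.character(edges[[1]]) != as.character(edges[[2]]), , drop = FALSE]
  used <- unique(c(as.character(edges[[1]]), as.character(edges[[2]]), nodes$gene))
  miss <- setdiff(used, nodes$gene)
  if (length(miss)) stop("genes without genome label: ", paste(head(miss), collapse = ", "))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes$gene)
  comp <- igraph::components(g)
  genome_of <- stats::setNames(nodes$genome, nodes$gene)
  member <- split(names(comp$membership), comp$membership)

  triplets <- list(); rejected <- c(missing_genome = 0L, duplicated_genome = 0L)
  for (cm in member) {
    tab <- table(factor(genome_of[cm], levels = genomes))
    if (all(tab == 1) && length(cm) == length(genomes)) {
      row <- vapply(genomes, function(gn) cm[genome_of[cm] == gn], character(1))
      triplets[[length(triplets) + 1L]] <- row
    } else if (any(tab > 1)) {
      rejected["duplicated_genome"] <- rejected["duplicated_genome"] + 1L
    } else {
      rejected["missing_genome"] <- rejected["missing_genome"] + 1L
    }
  }
  trip <- if (length(triplets)) {
    df <- as.data.frame(do.call(rbind, triplets), stringsAsFactors = FALSE)
    names(df) <- genomes
    df[do.call(order, df), , drop = FALSE]
  } else {
    stats::setNames(as.data.frame(matrix(character(), 0, length(genomes)),
                                  stringsAsFactors = FALSE), genomes)
  }
  rownames(trip) <- NULL
  list(triplets = trip, rejected = rejected, n_components = comp$no)
}

.pair_counts <- function(counts, pairs, cols) {
  at <- as.matrix(counts[pairs$at_gene, cols, drop = FALSE])
  dt <- as.matrix(counts[pairs$dt_gene, cols, drop = FALSE])
  list(at = at, dt = dt)
}

#' Homoeolog expression bias within an accession
#'
#' Tests At vs Dt expression for each homoeolog pair within one accession x
#' stage using the NB pairwise test on replicate counts; a pair is biased
#' when q < alpha, with the direction recorded. Pairs in which either
#' homoeolog fails the depth filter are untestable.
#'
#' @param counts total count matrix (genes x samples).
#' @param samples sample sheet.
#' @param pairs data.frame with at_gene, dt_gene.
#' @param accession "M" or "T".
#' @param stage stage to test.
#' @param sf size factors for the columns of \code{counts} (default
#'   median-of-ratios on the full table).
#' @param alpha significance level (default 0.05).
#' @param min_depth depth filter on the pair's mean counts (default 5).
#' @param pseudocount stabilizer (default 0.5).
#' @return data.frame: at_gene, dt_gene, log2_at_dt, p, q, biased,
#'   direction (At/Dt/none), testable.
#' @export
homoeolog_bias <- function(counts, samples, pairs, accession = "M", stage = NULL,
                           sf = NULL, alpha = 0.05, min_depth = 5,
                           pseudocount = 0.5) {
  if (is.null(stage)) stage <- sort(unique(samples$stage))[1]
  cols <- samples$sample_id[samples$accession == accession & samples$stage == stage]
  if (length(cols) < 2) stop("need >= 2 replicates in accession ", accession)
  sf <- sf %||% size_factors(as.matrix(counts))
  pc <- .pair_counts(counts, pairs, cols)
  testable <- rowMeans(pc$at) > min_depth & rowMeans(pc$dt) > min_depth
  res <- test_pairwise(pc$at, pc$dt, sf[cols], sf[cols], pseudocount = pseudocount)
  res$testable <- res$testable & testable
  res$q <- NA_real_
  res$q[res$testable] <- bh_adjust(res$p[res$testable])
  biased <- !is.na(res$q) & res$q < alpha
  data.frame(at_gene = pairs$at_gene, dt_gene = pairs$dt_gene,
             log2_at_dt = res$log2fc, p = res$p, q = res$q,
             biased = biased,
             direction = ifelse(!biased, "none",
                                ifelse(res$log2fc > 0, "At", "Dt")),
             testable = res$testable, stringsAsFactors = FALSE)
}

# replicate-level log2(At/Dt) ratios for the pairs, one column per replicate
.pair_ratios <- function(counts, pairs, cols, sf, pseudocount) {
  pc <- .pair_counts(counts, pairs, cols)
  at <- sweep(pc$at, 2, sf[cols], "/")
  dt <- sweep(pc$dt, 2, sf[cols], "/")
  log2((at + pseudocount) / (dt + pseudocount))
}

#' Domestication change in homoeolog expression ratio
#'
#' Welch t-test per pair of the replicate-level log2(At/Dt) ratios in
#' accession M against those in accession T, BH-corrected across pairs.
#' Delta-ratio sign convention: positive = increased At contribution in M
#' (domesticated minus wild).
#'
#' @inheritParams homoeolog_bias
#' @return data.frame: at_gene, dt_gene, delta_ratio (mean M ratio minus
#'   mean T ratio), t, p, q, significant, testable.
#' @export
ratio_change <- function(counts, samples, pairs, stage = NULL, sf = NULL,
                         alpha = 0.05, min_depth = 5, pseudocount = 0.5) {
  if (is.null(stage)) stage <- sort(unique(samples$stage))[1]
  mcols <- samples$sample_id[samples$accession == "M" & samples$stage == stage]
  tcols <- samples$sample_id[samples$accession == "T" & samples$stage == stage]
  if (length(mcols) < 2 || length(tcols) < 2) stop("need >= 2 replicates per accession")
  sf <- sf %||% size_factors(as.matrix(counts))
  rm_ <- .pair_ratios(counts, pairs, mcols, sf, pseudocount)
  rt_ <- .pair_ratios(counts, pairs, tcols, sf, pseudocount)
  pcM <- .pair_counts(counts, pairs, mcols); pcT <- .pair_counts(counts, pairs, tcols)
  testable <- (rowMeans(pcM$at) > min_depth | rowMeans(pcM$dt) > min_depth) &
              (rowMeans(pcT$at) > min_depth | rowMeans(pcT$dt) > min_depth)
  w <- welch_rows(rm_, rt_)
  q <- rep(NA_real_, length(w$p))
  ok <- w$testable & testable
  q[ok] <- bh_adjust(w$p[ok])
  data.frame(at_gene = pairs$at_gene, dt_gene = pairs$dt_gene,
             delta_ratio = w$estimate, t = w$t, p = w$p, q = q,
             significant = !is.na(q) & q < alpha, testable = ok,
             stringsAsFactors = FALSE)
}

#' Domestication change in total homoeolog-pair expression
#'
#' NB pairwise test of the per-replicate At + Dt sums between accessions M
#' and T for each pair.
#'
#' @inheritParams homoeolog_bias
#' @return data.frame: at_gene, dt_gene, log2fc (M over T), p, q,
#'   significant, testable.
#' @export
total_change <- function(counts, samples, pairs, stage = NULL, sf = NULL,
                         alpha = 0.05, min_depth = 5, pseudocount = 0.5) {
  if (is.null(stage)) stage <- sort(unique(samples$stage))[1]
  mcols <- samples$sample_id[samples$accession == "M" & samples$stage == stage]
  tcols <- samples$sample_id[samples$accession == "T" & samples$stage == stage]
  sf <- sf %||% size_factors(as.matrix(counts))
  pcM <- .pair_counts(counts, pairs, mcols); pcT <- .pair_counts(counts, pairs, tcols)
  sumM <- pcM$at + pcM$dt; sumT <- pcT$at + pcT$dt
  res <- test_pairwise(sumM, sumT, sf[mcols], sf[tcols], pseudocount = pseudocount)
  testable <- res$testable & (rowMeans(sumM) > min_depth | rowMeans(sumT) > min_depth)
  res$q <- NA_real_
  res$q[testable] <- bh_adjust(res$p[testable])
  data.frame(at_gene = pairs$at_gene, dt_gene = pairs$dt_gene,
             log2fc = res$log2fc, p = res$p, q = res$q,
             significant = !is.na(res$q) & res$q < alpha, testable = testable,
             stringsAsFactors = FALSE)
}

#' Association between pair-level RD status and homoeolog bias
#'
#' A homoeolog pair is RD when at least one of its homoeologs is an RD gene.
#' Fisher's exact test of RD membership against biased membership over the
#' pair universe.
#'
#' @param pairs pair table (at_gene, dt_gene).
#' @param rd_genes character vector of RD gene ids.
#' @param bias a \code{\link{homoeolog_bias}} result aligned with
#'   \code{pairs}.
#' @return list: table (2x2), odds_ratio, p; NA odds ratio and p when a
#'   margin is degenerate.
#' @export
rd_bias_association <- function(pairs, rd_genes, bias) {
  rd_pair <- pairs$at_gene %in% rd_genes | pairs$dt_gene %in% rd_genes
  biased <- bias$biased[match(paste(pairs$at_gene, pairs$dt_gene),
                              paste(bias$at_gene, bias$dt_gene))]
  tab <- table(factor(rd_pair, levels = c(TRUE, FALSE)),
               factor(biased, levels = c(TRUE, FALSE)),
               dnn = c("RD", "biased"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, odds_ratio = NA_real_, p = NA_real_))
  ft <- stats::fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])  # sample odds ratio
  list(table = tab, odds_ratio = or, p = ft$p.value)
}

#' Cross-tabulation of RD types between At and Dt homoeologs
#'
#' 4x4 matrix of pair counts over RD types (none, cis_only, trans_only,
#' cis_trans) of the At (rows) and Dt (columns) homoeolog, with per-cell
#' enrichment by 2x2-collapse Fisher exact test reported on the -log10(p)
#' scale (p = 0.05 maps to 1.3).
#'
#' @param pairs pair table (at_gene, dt_gene).
#' @param rd an \code{\link{rd_type}} table (gene_id, rd_type).
#' @return list: counts, fisher_p, neg_log10_p (4x4 matrices),
#'   reference = 1.3.
#' @export
crosstab_rd <- function(pairs, rd) {
  lv <- c("none", "cis_only", "trans_only", "cis_trans")
  typ <- function(g) {
    t <- rd$rd_type[match(g, rd$gene_id)]
    factor(ifelse(is.na(t), "none", t), levels = lv)
  }
  tab <- table(At = typ(pairs$at_gene), Dt = typ(pairs$dt_gene))
  fp <- tab * NA
  total <- sum(tab)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    a <- tab[i, j]; b <- sum(tab[i, ]) - a
    c_ <- sum(tab[, j]) - a; d <- total - a - b - c_
    fp[i, j] <- stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value
  }
  list(counts = tab, fisher_p = fp, neg_log10_p = -log10(fp), reference = 1.3)
}

#' Homoeolog ratio change grouped by RD type of the divergent homoeolog
#'
#' For pairs with RD in exactly one homoeolog, groups pairs by (RD type of
#' the divergent homoeolog) x (subgenome carrying it) and summarises the
#' domestication ratio change: median and quartiles, one-sample t-test
#' against zero, and a two-sample Welch test between the At-RD and Dt-RD
#' groups of the same type. Groups of fewer than 2 pairs are skipped with a
#' flag.
#'
#' @param rc a \code{\link{ratio_change}} result.
#' @param rd an \code{\link{rd_type}} table.
#' @return list: \code{groups} (rd_type, subgenome, n, median, q1, q3, mean,
#'   t, p, skipped) and \code{at_vs_dt} (per rd_type Welch p).
#' @export
ratio_change_by_rd <- function(rc, rd) {
  at_rd <- rc$at_gene %in% rd$gene_id
  dt_rd <- rc$dt_gene %in% rd$gene_id
  one <- xor(at_rd, dt_rd)
  sub <- ifelse(at_rd, "At", "Dt")
  type <- ifelse(at_rd, rd$rd_type[match(rc$at_gene, rd$gene_id)],
                        rd$rd_type[match(rc$dt_gene, rd$gene_id)])
  d <- data.frame(delta = rc$delta_ratio, subgenome = sub, rd_type = type,
                  stringsAsFactors = FALSE)[one & rc$testable, ]

  grp <- expand.grid(rd_type = c("cis_only", "trans_only", "cis_trans"),
                     subgenome = c("At", "Dt"), stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(seq_len(nrow(grp)), function(k) {
    v <- d$delta[d$rd_type == grp$rd_type[k] & d$subgenome == grp$subgenome[k]]
    n <- length(v)
    base <- data.frame(rd_type = grp$rd_type[k], subgenome = grp$subgenome[k],
                       n = n, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                       mean = NA_real_, t = NA_real_, p = NA_real_,
                       skipped = n < 2, stringsAsFactors = FALSE)
    if (n >= 2) {
      qs <- stats::quantile(v, c(0.25, 0.5, 0.75))
      base$q1 <- qs[1]; base$median <- qs[2]; base$q3 <- qs[3]
      base$mean <- mean(v)
      if (stats::sd(v) > 0) {
        tt <- stats::t.test(v)
        base$t <- unname(tt$statistic); base$p <- tt$p.value
      }
    }
    base
  }))
  at_vs_dt <- do.call(rbind, lapply(unique(grp$rd_type), function(k) {
    va <- d$delta[d$rd_type == k & d$subgenome == "At"]
    vd <- d$delta[d$rd_type == k & d$subgenome == "Dt"]
    p <- if (length(va) >= 2 && length(vd) >= 2 &&
             (stats::sd(va) > 0 || stats::sd(vd) > 0))
      stats::t.test(va, vd)$p.value else NA_real_
    data.frame(rd_type = k, n_at = length(va), n_dt = length(vd), p = p,
               stringsAsFactors = FALSE)
  }))
  list(groups = groups, at_vs_dt = at_vs_dt)
}
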