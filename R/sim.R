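# Seeded simulator of parental and F1 allelic read counts with known
# cis/trans/inheritance/homoeolog structure, emulating a two-accession
# (domesticated "M" x wild "T") reciprocal-F1 fiber RNA-seq design.

#' Simulation parameters
#'
#' Container of all knobs of the count simulator. Defaults emulate the study
#' design of wild vs. domesticated allotetraploid crop transcriptomes:
#' two parental accessions (M = domesticated, T = wild) at two developmental
#' stages (10 and 20 dpa) with 4 parental replicates, reciprocal F1 hybrids
#' (MxT, TxM) with 3 replicates each, and 7.5% of hybrid reads
#' allele-informative.
#'
#' @param n_genes number of genes.
#' @param prop_by_class named proportions over the six true regulatory classes
#'   \code{conserved}, \code{cis_only}, \code{trans_only}, \code{enhancing},
#'   \code{compensating}, \code{compensatory}; must sum to 1. Applied by
#'   deterministic largest-remainder rounding so the truth composition is
#'   exact.
#' @param effect_size magnitude (log2 units) of cis/trans effects; either a
#'   scalar or a named vector with per-class overrides.
#' @param base_mean_log_mu,base_mean_log_sd lognormal parameters of the
#'   per-gene expected count in parent T.
#' @param dispersion negative-binomial dispersion phi (Var = mu + phi mu^2);
#'   0 gives Poisson counts.
#' @param allelic_fraction fraction rho of hybrid reads that are
#'   allele-informative (default 0.075).
#' @param n_rep_parent parental replicates; scalar, or length-2 vector
#'   \code{c(M, T)}.
#' @param n_rep_f1 replicates per reciprocal hybrid.
#' @param stages developmental stages (labels only; truth shared across
#'   stages, noise independent).
#' @param homoeolog_fraction fraction of genes paired as At/Dt homoeologs.
#' @param prop_inheritance named proportions over inheritance modes
#'   \code{additive}, \code{dominant_M}, \code{dominant_T},
#'   \code{transgressive_up}, \code{transgressive_down}.
#' @param transgressive_shift log2 shift beyond the parental range for
#'   transgressive F1 totals.
#' @param midparent \code{"geometric"} (default; additivity on the log2 scale
#'   on which A and B are defined) or \code{"arithmetic"} midparent for
#'   additive F1 totals.
#' @param lib_size_sd lognormal sd of per-library depth factors (exercises
#'   normalization; default 0.2).
#' @param seed integer seed; the simulator is fully reproducible given it.
#' @return object of class \code{sim_params} (a validated list).
#' @export
sim_params <- function(n_genes = 10000,
                       prop_by_class = c(conserved = 0.85, cis_only = 0.05,
                                         trans_only = 0.04, enhancing = 0.005,
                                         compensating = 0.015, compensatory = 0.04),
                       effect_size = 1.5,
                       base_mean_log_mu = log(200),
                       base_mean_log_sd = 1,
                       dispersion = 0.05,
                       allelic_fraction = 0.075,
                       n_rep_parent = 4,
                       n_rep_f1 = 3,
                       stages = c(10, 20),
                       homoeolog_fraction = 0.5,
                       prop_inheritance = c(additive = 0.62, dominant_M = 0.17,
                                            dominant_T = 0.17,
                                            transgressive_up = 0.02,
                                            transgressive_down = 0.02),
                       transgressive_shift = 1.5,
                       midparent = c("geometric", "arithmetic"),
                       lib_size_sd = 0.2,
                       seed = 1L) {
  classes <- c("conserved", "cis_only", "trans_only", "enhancing",
               "compensating", "compensatory")
  if (!all(classes %in% names(prop_by_class)))
    stop("prop_by_class must name all six classes")
  prop_by_class <- prop_by_class[classes]
  if (abs(sum(prop_by_class) - 1) > 1e-9)
    stop("prop_by_class must sum to 1")
  modes <- c("additive", "dominant_M", "dominant_T",
             "transgressive_up", "transgressive_down")
  if (!all(modes %in% names(prop_inheritance)))
    stop("prop_inheritance must name all five modes")
  prop_inheritance <- prop_inheritance[modes]
  if (abs(sum(prop_inheritance) - 1) > 1e-9)
    stop("prop_inheritance must sum to 1")
  if (length(n_rep_parent) == 1) n_rep_parent <- c(M = n_rep_parent, T = n_rep_parent)
  names(n_rep_parent) <- c("M", "T")
  stopifnot(n_genes >= 1, all(n_rep_parent >= 1), n_rep_f1 >= 1,
            allelic_fraction > 0, allelic_fraction <= 1,
            dispersion >= 0, homoeolog_fraction >= 0, homoeolog_fraction <= 1,
            lib_size_sd >= 0)
  structure(list(
    n_genes = as.integer(n_genes), prop_by_class = prop_by_class,
    effect_size = effect_size, base_mean_log_mu = base_mean_log_mu,
    base_mean_log_sd = base_mean_log_sd, dispersion = dispersion,
    allelic_fraction = allelic_fraction,
    n_rep_parent = stats::setNames(as.integer(n_rep_parent), c("M", "T")),
    n_rep_f1 = as.integer(n_rep_f1),
    stages = stages, homoeolog_fraction = homoeolog_fraction,
    prop_inheritance = prop_inheritance,
    transgressive_shift = transgressive_shift,
    midparent = match.arg(midparent),
    lib_size_sd = lib_size_sd, seed = as.integer(seed)
  ), class = "sim_params")
}

effect_for_class <- function(params, class) {
  e <- params$effect_size
  if (length(e) > 1 && !is.null(names(e)) && class %in% names(e)) return(unname(e[class]))
  unname(e[1])
}

#' Simulate per-gene regulatory truth
#'
#' Assigns every gene a true regulatory class (exact largest-remainder
#' composition), cis effect \code{c} and trans effect \code{t_eff} (log2
#' units, signs random subject to the class constraint), a lognormal base
#' mean, an inheritance mode, and optional At/Dt homoeolog pairing.
#'
#' Class constraints: cis_only has \code{c != 0, t_eff = 0}; trans_only the
#' reverse; enhancing has \code{c} and \code{t_eff} equal and of the same
#' sign; compensating has opposite signs with \code{|t_eff| = |c|/2} so the
#' parental divergence does not cancel; compensatory has \code{t_eff = -c};
#' conserved has both zero.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return data.frame of class \code{sim_truth}: gene_id, true_class, c,
#'   t_eff, base_mean, inheritance_mode, subgenome, homoeolog_partner.
#' @export
simulate_truth <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_genes
  counts <- largest_remainder(n, params$prop_by_class)
  cls <- sample(rep(names(counts), counts))

  cc <- numeric(n); tt <- numeric(n)
  for (k in names(counts)) {
    idx <- which(cls == k)
    if (!length(idx)) next
    e <- effect_for_class(params, k)
    s <- sample(c(-1, 1), length(idx), replace = TRUE)
    switch(k,
      conserved    = { },
      cis_only     = { cc[idx] <- e * s },
      trans_only   = { tt[idx] <- e * s },
      enhancing    = { cc[idx] <- e * s; tt[idx] <- e * s },
      compensating = { cc[idx] <- e * s; tt[idx] <- -e * s / 2 },
      compensatory = { cc[idx] <- e * s; tt[idx] <- -e * s }
    )
  }

  base_mean <- exp(stats::rnorm(n, params$base_mean_log_mu, params$base_mean_log_sd))

  mode_counts <- largest_remainder(n, params$prop_inheritance)
  modes <- sample(rep(names(mode_counts), mode_counts))

  ids <- gene_ids(n)
  subgenome <- rep(NA_character_, n)
  partner <- rep(NA_character_, n)
  n_pairs <- floor(n * params$homoeolog_fraction / 2)
  if (n_pairs > 0) {
    paired <- sample.int(n, 2 * n_pairs)
    at <- paired[seq_len(n_pairs)]
    dt <- paired[n_pairs + seq_len(n_pairs)]
    subgenome[at] <- "At"; subgenome[dt] <- "Dt"
    partner[at] <- ids[dt]; partner[dt] <- ids[at]
  }

  structure(data.frame(
    gene_id = ids, true_class = cls, c = cc, t_eff = tt,
    base_mean = base_mean, inheritance_mode = modes,
    subgenome = subgenome, homoeolog_partner = partner,
    stringsAsFactors = FALSE
  ), class = c("sim_truth", "data.frame"))
}

#' Expected expression means implied by the truth table
#'
#' Converts per-gene (c, t_eff, base_mean, inheritance_mode) into expected
#' normalized expression: parent T is the base mean, parent M is
#' \code{base * 2^(c + t_eff)} (parental divergence reflects cis plus trans),
#' the allele-M share within the hybrid allelic pool is
#' \code{p = 2^c / (1 + 2^c)} (only cis survives the common trans
#' environment), and the F1 total follows the inheritance mode.
#'
#' @param truth a \code{\link{simulate_truth}} table.
#' @param params the matching \code{\link{sim_params}}.
#' @return data.frame: gene_id, mu_M, mu_T, p_allele_M, mu_f1.
#' @export
expected_means <- function(truth, params) {
  mu_T <- truth$base_mean
  mu_M <- truth$base_mean * 2^(truth$c + truth$t_eff)
  p <- 2^truth$c / (1 + 2^truth$c)
  mid <- if (params$midparent == "geometric") sqrt(mu_M * mu_T) else (mu_M + mu_T) / 2
  shift <- 2^params$transgressive_shift
  mu_f1 <- switch_mode <- numeric(nrow(truth))
  mu_f1 <- ifelse(truth$inheritance_mode == "additive", mid,
           ifelse(truth$inheritance_mode == "dominant_M", mu_M,
           ifelse(truth$inheritance_mode == "dominant_T", mu_T,
           ifelse(truth$inheritance_mode == "transgressive_up",
                  pmax(mu_M, mu_T) * shift,
                  pmin(mu_M, mu_T) / shift))))
  data.frame(gene_id = truth$gene_id, mu_M = mu_M, mu_T = mu_T,
             p_allele_M = p, mu_f1 = mu_f1, stringsAsFactors = FALSE)
}

#' Simulate read-count tables from a truth table
#'
#' Draws parental and F1-total counts from a negative binomial
#' (Var = mu + phi mu^2; Poisson when phi = 0) around per-library depth
#' factors, then derives allele-informative hybrid counts by binomial
#' thinning of each F1 gene count with probability rho and a binomial split
#' between the M-type and T-type allele with the cis-determined share p.
#' Both reciprocal hybrids share the same truth; only noise is independent.
#'
#' @param truth a \code{\link{simulate_truth}} table.
#' @param params the matching \code{\link{sim_params}}.
#' @return list of class \code{sim_counts}: \code{counts} (integer matrix,
#'   genes x samples), \code{samples} (sample sheet: sample_id, accession in
#'   M/T/MxT/TxM, stage, replicate, class), \code{allelic} (integer matrix
#'   with column pairs \code{<lib>.M_allele} / \code{<lib>.T_allele}),
#'   \code{allelic_samples}, \code{lib_factors}.
#' @export
simulate_counts <- function(truth, params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 1L)  # derived substream: counts independent of truth layout
  mu <- expected_means(truth, params)
  n <- nrow(truth)
  phi <- params$dispersion
  rho <- params$allelic_fraction

  draw <- function(mean_vec) {
    if (phi > 0) stats::rnbinom(n, mu = mean_vec, size = 1 / phi)
    else stats::rpois(n, lambda = mean_vec)
  }

  samples <- do.call(rbind, lapply(params$stages, function(st) {
    rbind(
      data.frame(accession = "M", stage = st, replicate = seq_len(params$n_rep_parent[["M"]]),
                 class = "parental_total", stringsAsFactors = FALSE),
      data.frame(accession = "T", stage = st, replicate = seq_len(params$n_rep_parent[["T"]]),
                 class = "parental_total", stringsAsFactors = FALSE),
      data.frame(accession = "MxT", stage = st, replicate = seq_len(params$n_rep_f1),
                 class = "hybrid_total", stringsAsFactors = FALSE),
      data.frame(accession = "TxM", stage = st, replicate = seq_len(params$n_rep_f1),
                 class = "hybrid_total", stringsAsFactors = FALSE)
    )
  }))
  samples$sample_id <- sprintf("%s.%sdpa.r%d", samples$accession, samples$stage,
                               samples$replicate)
  samples <- samples[, c("sample_id", "accession", "stage", "replicate", "class")]

  lib_factors <- stats::setNames(
    exp(stats::rnorm(nrow(samples), 0, params$lib_size_sd)), samples$sample_id)

  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(truth$gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mean_j <- switch(samples$accession[j], M = mu$mu_M, T = mu$mu_T, mu$mu_f1)
    counts[, j] <- as.integer(draw(mean_j * lib_factors[j]))
  }

  hyb <- samples[samples$class == "hybrid_total", ]
  allelic <- matrix(0L, n, 2 * nrow(hyb), dimnames = list(truth$gene_id, NULL))
  acol <- character(2 * nrow(hyb))
  for (j in seq_len(nrow(hyb))) {
    tot <- counts[, hyb$sample_id[j]]
    informative <- stats::rbinom(n, tot, rho)
    m <- stats::rbinom(n, informative, mu$p_allele_M)
    allelic[, 2 * j - 1] <- m
    allelic[, 2 * j] <- informative - m
    acol[2 * j - 1] <- paste0(hyb$sample_id[j], ".M_allele")
    acol[2 * j] <- paste0(hyb$sample_id[j], ".T_allele")
  }
  colnames(allelic) <- acol

  structure(list(counts = counts, samples = samples, allelic = allelic,
                 allelic_samples = hyb, lib_factors = lib_factors),
            class = "sim_counts")
}

#' Simulate a full allele-specific-expression dataset
#'
#' Convenience wrapper: \code{\link{simulate_truth}} then
#' \code{\link{simulate_counts}}, plus the homoeolog pair table implied by
#' the truth pairing.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return list of class \code{ase_sim} with elements truth, counts, samples,
#'   allelic, allelic_samples, pairs (at_gene, dt_gene), lib_factors, params.
#' @export
simulate_ase <- function(params = sim_params()) {
  truth <- simulate_truth(params)
  sim <- simulate_counts(truth, params)
  at <- truth$gene_id[!is.na(truth$subgenome) & truth$subgenome == "At"]
  pairs <- data.frame(
    at_gene = at,
    dt_gene = truth$homoeolog_partner[match(at, truth$gene_id)],
    stringsAsFactors = FALSE)
  structure(c(list(truth = truth, pairs = pairs, params = params), sim),
            class = "ase_sim")
}

#' @export
print.ase_sim <- function(x, ...) {
  cat("Simulated ASE dataset:", nrow(x$truth), "genes,",
      nrow(x$samples), "libraries,",
      nrow(x$pairs), "homoeolog pairs\n")
  cat("Class composition:\n")
  print(table(x$truth$true_class))
  invisible(x)
}
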