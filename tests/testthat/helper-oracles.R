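# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# BH step-up, straight from the definition: sort p, q_i = p_i * m / i,
# enforce monotonicity by cumulative minimum from the largest rank.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# median-of-ratios size factors by explicit loops
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(x) all(x > 0))
  k <- counts[keep, , drop = FALSE]
  geo <- apply(k, 1, function(x) prod(x)^(1 / length(x)))
  sf <- numeric(ncol(k))
  for (j in seq_len(ncol(k))) sf[j] <- median(k[, j] / geo)
  sf / prod(sf)^(1 / length(sf))
}

# connected components by breadth-first search on an adjacency list, then
# the one-gene-per-genome filter, independent of igraph
oracle_triplets <- function(edges, nodes, genomes = c("outgroup", "At", "Dt")) {
  adj <- lapply(setNames(nm = nodes$gene), function(g) character())
  for (k in seq_len(nrow(edges))) {
    a <- as.character(edges[k, 1]); b <- as.character(edges[k, 2])
    if (a == b) next
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  genome_of <- setNames(nodes$genome, nodes$gene)
  seen <- character(); out <- list()
  for (start in nodes$gene) {
    if (start %in% seen) next
    comp <- character(); queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    labs <- genome_of[comp]
    if (length(comp) == length(genomes) &&
        setequal(labs, genomes) && !anyDuplicated(labs)) {
      out[[length(out) + 1]] <- vapply(genomes, function(g) comp[labs == g],
                                       character(1))
    }
  }
  if (!length(out)) {
    return(setNames(as.data.frame(matrix(character(), 0, length(genomes)),
                                  stringsAsFactors = FALSE), genomes))
  }
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- genomes
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# random labelled homology graph for the triplet oracle
random_graph <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- data.frame(
    gene = sprintf("n%03d", seq_len(n_nodes)),
    genome = sample(c("outgroup", "At", "Dt"), n_nodes, replace = TRUE),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    a = sample(nodes$gene, n_edges, replace = TRUE),
    b = sample(nodes$gene, n_edges, replace = TRUE),
    stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}

# deterministic multi-gene fixture: a count matrix around flat means with a
# block of genes carrying a known M/T fold change, low noise
fixture_parental <- function(n_genes = 120, n_shift = 12, fold = 4,
                             base = 1000, reps = 4, seed = 99, phi = 0.01) {
  set.seed(seed)
  mu <- rep(base, n_genes)
  fc <- rep(1, n_genes); fc[seq_len(n_shift)] <- fold
  M <- sapply(seq_len(reps), function(i) rnbinom(n_genes, mu = mu * fc, size = 1 / phi))
  T_ <- sapply(seq_len(reps), function(i) rnbinom(n_genes, mu = mu, size = 1 / phi))
  rownames(M) <- rownames(T_) <- sprintf("g%04d", seq_len(n_genes))
  list(M = M, T = T_, shifted = seq_len(n_shift))
}

# relabel a dataset so that parent M becomes T and vice versa (accessions,
# sample ids, allele columns, cross directions); used for symmetry checks
swap_parent_labels <- function(counts, samples, allelic) {
  map_id <- function(x) {
    y <- x
    y <- sub("^M\\.", "Mtmp.", y); y <- sub("^T\\.", "M.", y)
    y <- sub("^Mtmp\\.", "T.", y)
    y <- sub("^MxT\\.", "XX.", y); y <- sub("^TxM\\.", "MxT.", y)
    y <- sub("^XX\\.", "TxM.", y)
    y
  }
  samples$accession <- c(M = "T", T = "M", MxT = "TxM",
                         TxM = "MxT")[samples$accession]
  samples$sample_id <- map_id(samples$sample_id)
  colnames(counts) <- map_id(colnames(counts))
  cn <- colnames(allelic)
  lib <- map_id(sub("\\.[MT]_allele$", "", cn))
  allele <- ifelse(grepl("M_allele$", cn), "T_allele", "M_allele")
  colnames(allelic) <- paste0(lib, ".", allele)
  list(counts = counts, samples = samples, allelic = allelic)
}

# deterministic dataset with explicit per-gene parental and F1 total means;
# allelic counts follow p = muM / (muM + muT) (a purely cis architecture)
fixture_inheritance <- function(muM, muT, muF1, reps_p = 4, reps_f1 = 3,
                                allelic_depth = 300, seed = 1) {
  set.seed(seed)
  n <- length(muM)
  ids <- sprintf("g%04d", seq_len(n))
  samples <- data.frame(
    sample_id = c(paste0("M.10dpa.r", 1:reps_p), paste0("T.10dpa.r", 1:reps_p),
                  paste0("MxT.10dpa.r", 1:reps_f1), paste0("TxM.10dpa.r", 1:reps_f1)),
    accession = rep(c("M", "T", "MxT", "TxM"), c(reps_p, reps_p, reps_f1, reps_f1)),
    stage = 10,
    replicate = c(1:reps_p, 1:reps_p, 1:reps_f1, 1:reps_f1),
    stringsAsFactors = FALSE)
  noise <- function(mu, k) matrix(rpois(length(mu) * k, rep(mu, k)), ncol = k)
  counts <- cbind(noise(muM, reps_p), noise(muT, reps_p), noise(muF1, 2 * reps_f1))
  dimnames(counts) <- list(ids, samples$sample_id)
  p <- muM / (muM + muT)
  hyb <- samples$sample_id[samples$accession %in% c("MxT", "TxM")]
  allelic <- matrix(0L, n, 2 * length(hyb))
  cn <- character(2 * length(hyb))
  for (j in seq_along(hyb)) {
    tot <- rpois(n, allelic_depth)
    m <- rbinom(n, tot, p)
    allelic[, 2 * j - 1] <- m; allelic[, 2 * j] <- tot - m
    cn[2 * j - 1] <- paste0(hyb[j], ".M_allele")
    cn[2 * j] <- paste0(hyb[j], ".T_allele")
  }
  dimnames(allelic) <- list(ids, cn)
  list(counts = counts, samples = samples, allelic = allelic)
}

# small complete dataset with deterministic structure for io / fit tests
tiny_sim <- function(seed = 7, n_genes = 400, ...) {
  simulate_ase(sim_params(n_genes = n_genes, seed = seed,
                          base_mean_log_mu = log(400), base_mean_log_sd = 0.5,
                          ...))
}
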