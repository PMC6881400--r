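# End-to-end pipeline driver: read or simulate inputs, fit, classify
# inheritance, run the homoeolog layer, and write a report bundle.

#' Build a pipeline configuration
#'
#' @param counts,allelic,samples,pairs paths to input TSVs; when
#'   \code{simulate = TRUE} they are ignored and a dataset is simulated.
#' @param outdir output directory.
#' @param alpha,lfc_cutoff,pseudocount,min_depth analysis parameters.
#' @param seed integer seed (drives the simulator and nothing else; the
#'   analysis itself is deterministic).
#' @param simulate simulate inputs instead of reading them.
#' @param sim_params a \code{\link{sim_params}} object used when simulating.
#' @param crossrep,inheritance,homoeolog stage toggles.
#' @return a validated config list.
#' @export
pipeline_config <- function(counts = NULL, allelic = NULL, samples = NULL,
                            pairs = NULL, outdir = "cistrans_out",
                            alpha = 0.05, lfc_cutoff = 0, pseudocount = 0.5,
                            min_depth = 5, seed = 1L, simulate = is.null(counts),
                            sim_params = NULL, crossrep = TRUE,
                            inheritance = TRUE, homoeolog = TRUE) {
  stopifnot(alpha > 0, alpha <= 1, lfc_cutoff >= 0, pseudocount >= 0, min_depth >= 0)
  if (!simulate) {
    for (p in c(counts, allelic, samples)) {
      if (is.null(p) || !file.exists(p)) stop_io("input file missing: ", p %||% "(unset)")
    }
  }
  list(counts = counts, allelic = allelic, samples = samples, pairs = pairs,
       outdir = outdir, alpha = alpha, lfc_cutoff = lfc_cutoff,
       pseudocount = pseudocount, min_depth = min_depth, seed = as.integer(seed),
       simulate = simulate, sim_params = sim_params, crossrep = crossrep,
       inheritance = inheritance, homoeolog = homoeolog)
}

#' Read a YAML pipeline config file
#' @param path YAML file; keys mirror \code{\link{pipeline_config}} arguments.
#' @return config list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y), names(formals(pipeline_config)))])
}

log_info <- function(...) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                          sprintf(...)))

#' Run the full cis/trans analysis pipeline
#'
#' Simulation (or input reading) -> divergence estimation and classification
#' -> reciprocal consensus / RD typing -> correlations -> inheritance ->
#' homoeolog layer, writing per-module TSVs, a summary JSON and a run
#' manifest (parameters, seed, input checksums) under \code{config$outdir}.
#' Deterministic given the seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a list with the fit and the report paths.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("alpha=%g lfc=%g pseudocount=%g min_depth=%g seed=%d",
                 config$alpha, config$lfc_cutoff, config$pseudocount,
                 config$min_depth, config$seed)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_io(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }

  inputs <- step("input", {
    if (config$simulate) {
      sp <- config$sim_params %||% sim_params(seed = config$seed)
      sp$seed <- config$seed
      sim <- simulate_ase(sp)
      write_sim(sim, file.path(config$outdir, "sim"))
      list(counts = sim$counts, samples = sim$samples, allelic = sim$allelic,
           pairs = sim$pairs, truth = sim$truth)
    } else {
      samples <- read_samples(config$samples)
      list(counts = read_counts(config$counts),
           samples = samples,
           allelic = read_allelic(config$allelic, samples),
           pairs = if (!is.null(config$pairs)) read_pairs(config$pairs) else NULL,
           truth = NULL)
    }
  })
  log_info("input: %d genes, %d samples", nrow(inputs$counts), ncol(inputs$counts))

  fit <- step("classify", cistrans_fit(
    inputs$counts, inputs$samples, inputs$allelic,
    alpha = config$alpha, lfc_cutoff = config$lfc_cutoff,
    pseudocount = config$pseudocount, min_depth = config$min_depth))
  for (st in names(fit$universes))
    log_info("stage %s: %d genes pass depth filter", st, length(fit$universes[[st]]))

  write_tsv_df(fit$estimates, file.path(config$outdir, "estimates.tsv"), hdr)
  write_tsv_df(fit$rd, file.path(config$outdir, "rd_genes.tsv"), hdr)

  summary_json <- list(
    parameters = config[c("alpha", "lfc_cutoff", "pseudocount", "min_depth", "seed")],
    category_summary = fit$summary,
    concordance = fit$concordance,
    correlation_standard = correlation_standard(fit),
    sign_tests = direction_summaries(fit)$sign_tests)

  if (config$crossrep) {
    summary_json$correlation_crossrep <- lapply(
      stats::setNames(nm = c("MxT", "TxM")), function(h) {
        lapply(stats::setNames(nm = as.character(sort(unique(inputs$samples$stage)))),
               function(st) {
          cr <- correlation_crossrep(fit, hybrid = h, stage = st)
          list(mean_r = cr$mean_r, r = cr$pairs$r)
        })
      })
  }

  if (config$inheritance) {
    inh <- step("inheritance", {
      do.call(rbind, lapply(c("MxT", "TxM"), function(h) {
        do.call(rbind, lapply(sort(unique(inputs$samples$stage)), function(st)
          classify_inheritance(fit, hybrid = h, stage = st)))
      }))
    })
    write_tsv_df(inh, file.path(config$outdir, "inheritance.tsv"), hdr)
    log_info("inheritance: %d divergent genes classified", nrow(inh))
    st1 <- sort(unique(inputs$samples$stage))[1]
    calls1 <- fit$estimates[fit$estimates$hybrid == "MxT" & fit$estimates$stage == st1, ]
    assoc <- inheritance_by_category(inh[inh$hybrid == "MxT" & inh$stage == st1, ], calls1)
    summary_json$inheritance_association <- list(
      table = as.data.frame.matrix(assoc$table),
      global_chisq = assoc$global_chisq, global_p = assoc$global_p)
  }

  if (config$homoeolog && !is.null(inputs$pairs) && nrow(inputs$pairs)) {
    hom <- step("homoeolog", {
      sf <- fit$size_factors
      st1 <- sort(unique(inputs$samples$stage))[1]
      bias_M <- homoeolog_bias(inputs$counts, inputs$samples, inputs$pairs, "M", st1,
                               sf, config$alpha, config$min_depth, config$pseudocount)
      bias_T <- homoeolog_bias(inputs$counts, inputs$samples, inputs$pairs, "T", st1,
                               sf, config$alpha, config$min_depth, config$pseudocount)
      rc <- ratio_change(inputs$counts, inputs$samples, inputs$pairs, st1, sf,
                         config$alpha, config$min_depth, config$pseudocount)
      tc <- total_change(inputs$counts, inputs$samples, inputs$pairs, st1, sf,
                         config$alpha, config$min_depth, config$pseudocount)
      list(bias_M = bias_M, bias_T = bias_T, rc = rc, tc = tc)
    })
    write_tsv_df(hom$rc, file.path(config$outdir, "homoeolog_ratio_change.tsv"),
                 paste(hdr, "| delta_ratio sign: positive = increased At contribution in M (M - T)"))
    write_tsv_df(hom$tc, file.path(config$outdir, "homoeolog_total_change.tsv"), hdr)
    assoc <- rd_bias_association(inputs$pairs, fit$rd$gene_id, hom$bias_M)
    summary_json$homoeolog <- list(
      biased_pairs_M = sum(hom$bias_M$biased), biased_pairs_T = sum(hom$bias_T$biased),
      ratio_changed = sum(hom$rc$significant), total_changed = sum(hom$tc$significant),
      rd_bias_odds_ratio = assoc$odds_ratio, rd_bias_p = assoc$p)
    log_info("homoeolog: %d pairs, %d biased in M", nrow(inputs$pairs),
             sum(hom$bias_M$biased))
  }

  json_path <- file.path(config$outdir, "summary.json")
  jsonlite::write_json(summary_json, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")

  manifest <- list(
    package_version = as.character(utils::packageVersion("cistrans")),
    parameters = config[c("alpha", "lfc_cutoff", "pseudocount", "min_depth",
                          "seed", "simulate")],
    input_checksums = list(
      counts = digest_matrix(inputs$counts),
      allelic = digest_matrix(inputs$allelic)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(fit = fit, outdir = config$outdir, summary = summary_json))
}

# lightweight content checksum (sum-based; changes iff the data change,
# up to hash collisions of the serialized bytes)
digest_matrix <- function(m) {
  raw <- serialize(m, NULL)
  sprintf("%d-%.0f", length(raw), sum(as.integer(raw)) +
            sum(as.integer(raw[seq(1, length(raw), by = 7)]) * 31))
}
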