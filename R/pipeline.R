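## End-to-end orchestration: filter -> phenotype adjustment -> LD / blocks ->
## mixed-model GWAS per trial x environment -> stability -> epistasis ->
## stacking, with per-stage logging, file outputs and a reproducibility
## manifest.

#' Pipeline configuration
#'
#' All thresholds default to the published analysis values. Either provide
#' \code{genotypes}/\code{phenotypes} file paths, or set \code{simulate} to a
#' list of \code{\link{simulation_spec}} overrides to run on synthetic data.
#' Configs round-trip losslessly through YAML
#' (\code{\link{read_pipeline_config}}).
#'
#' @param genotypes genotype file path (or NULL when simulating).
#' @param genotype_format format passed to \code{\link{read_genotypes}}.
#' @param phenotypes phenotype CSV path (columns trial, env, experiment, rep,
#'   block, entry, is_check, GY, DH, PH), or NULL when simulating.
#' @param simulate NULL, or a list of \code{\link{simulation_spec}} argument
#'   overrides.
#' @param outdir output directory.
#' @param seed seed for every stochastic stage.
#' @param max_missing,min_maf,line_max_missing marker/line filter thresholds.
#' @param ci_low,ci_high,recomb_high,strong_frac,max_span_bp block-finder
#'   parameters.
#' @param min_hap_freq minimum haplotype-allele frequency.
#' @param ld_baseline,ld_span,ld_max_pairs LD-decay parameters.
#' @param n_pcs PCs in the MLM ("auto" = BIC choice, or a fixed count).
#' @param min_class minimum lines per tested allele class.
#' @param p_strong,p_weak,min_eyts_env,min_envs,min_eyts_multi stability
#'   thresholds.
#' @param epistasis_alpha,epistasis_candidates epistasis scan threshold and
#'   mode ("assoc" = pairs among marginally associated blocks, "all").
#' @param epistasis_marginal_p marginal P cut for candidate blocks.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(genotypes = NULL, genotype_format = "matrix-csv",
                            phenotypes = NULL, simulate = NULL,
                            outdir = "hapgwas_run", seed = 1L,
                            max_missing = 0.30, min_maf = 0.15,
                            line_max_missing = 0.60,
                            ci_low = 0.6, ci_high = 0.95, recomb_high = 0.90,
                            strong_frac = 0.95, max_span_bp = 10e6,
                            min_hap_freq = 0.05,
                            ld_baseline = 0.1, ld_span = 0.5,
                            ld_max_pairs = 50000L,
                            n_pcs = "auto", min_class = 10L,
                            p_strong = 1e-4, p_weak = 1e-3,
                            min_eyts_env = 3L, min_envs = 2L,
                            min_eyts_multi = 2L,
                            epistasis_alpha = 1e-4,
                            epistasis_candidates = "assoc",
                            epistasis_marginal_p = 0.01) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read / write a pipeline config as YAML
#' @param path YAML file path.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a \code{pipeline_config}.
#' @return \code{path}, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full haplotype-GWAS pipeline
#'
#' Executes filter -> phenotype adjustment -> LD decay -> haplotype blocks ->
#' per-trial-per-environment mixed-model association -> stability
#' classification -> epistasis scan -> favorable-haplotype stacking, writing
#' each stage's table and a JSON manifest (config, per-stage counts, output
#' checksums) under \code{config$outdir}. A failing stage stops with a
#' message naming the stage; completed outputs are retained alongside a
#' \code{FAILED_<stage>} marker file.
#'
#' @param config a \code{\link{pipeline_config}} (or path to its YAML).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), counts = list(),
                   r_version = as.character(getRversion()))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(file.path(config$outdir, paste0("FAILED_", name)))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ## ---- inputs ----
  truth <- NULL
  inp <- stage("input", {
    if (!is.null(config$simulate)) {
      spec <- do.call(simulation_spec,
                      c(config$simulate, list(seed = config$seed)))
      sim <- simulate_genotypes(spec)
      ph <- simulate_phenotypes(sim, spec)
      truth <- ph$truth
      list(g = sim$genotypes, pheno = ph$pheno, truth = ph$truth)
    } else {
      g <- read_genotypes(config$genotypes, config$genotype_format)
      pheno <- utils::read.csv(config$phenotypes, stringsAsFactors = FALSE)
      list(g = g, pheno = pheno, truth = NULL)
    }
  })
  manifest$counts$input <- c(lines = n_lines(inp$g),
                             markers = n_markers(inp$g),
                             pheno_rows = nrow(inp$pheno))
  message("input: ", n_lines(inp$g), " lines x ", n_markers(inp$g), " markers")

  ## ---- marker and line filters ----
  g <- stage("filter", {
    fm <- filter_markers(inp$g, config$max_missing, config$min_maf)
    if (fm$report$n_output == 0) stop("empty marker set after filtering")
    g <- filter_lines(fm$genotypes, config$line_max_missing)
    manifest$counts$filter <- c(markers_in = fm$report$n_input,
                                removed_missing = fm$report$n_removed_missing,
                                removed_maf = fm$report$n_removed_maf,
                                markers_out = fm$report$n_output,
                                lines_out = n_lines(g))
    write_genotypes_csv(g, file.path(config$outdir, "genotypes_filtered.csv"))
    g
  })
  message("filter: ", n_markers(g), " markers, ", n_lines(g), " lines retained")
  pheno <- inp$pheno[inp$pheno$entry %in% rownames(g$calls), , drop = FALSE]

  ## ---- phenotype adjustment ----
  adj <- stage("pheno", {
    adj <- adjust_block_effects(pheno, trait = "GY")
    for (tr in intersect(c("DH", "PH"), names(pheno))) {
      if (any(pheno$is_check)) {
        a2 <- check_adjust_table(pheno, tr)
        names(a2)[names(a2) == "value"] <- tr
        adj <- merge(adj, a2, by = c("entry", "trial", "env"), all.x = TRUE)
      }
    }
    names(adj)[names(adj) == "value"] <- "GY"
    utils::write.csv(adj, file.path(config$outdir, "adjusted_means.csv"),
                     row.names = FALSE)
    adj
  })
  manifest$counts$pheno <- c(adjusted_rows = nrow(adj))
  message("pheno: ", nrow(adj), " adjusted entry x trial x env means")

  ## ---- LD decay ----
  decay <- stage("ld", {
    decay <- ld_decay(g, max_dist_bp = config$max_span_bp,
                      sample_pairs = config$ld_max_pairs, seed = config$seed,
                      baseline = config$ld_baseline, span = config$ld_span)
    write_tsv(decay$curve, file.path(config$outdir, "ld_decay_curve.tsv"))
    decay
  })
  manifest$counts$ld <- c(pairs = decay$n_pairs,
                          decay_mb = decay$decay_distance_bp / 1e6)
  message(sprintf("ld: decay at %.2f Mb (%d pairs)",
                  decay$decay_distance_bp / 1e6, decay$n_pairs))

  ## ---- haplotype blocks ----
  hg <- stage("blocks", {
    params <- ld_params(config$ci_low, config$ci_high, config$recomb_high)
    blocks <- find_blocks(g, params, max_span_bp = config$max_span_bp,
                          strong_frac = config$strong_frac)
    if (!length(blocks)) stop("no haplotype blocks found")
    hg <- build_haplotype_genotypes(g, blocks, config$min_hap_freq)
    bdf <- as.data.frame(hg$blocks)
    bdf$alleles <- vapply(hg$blocks, function(b) paste(b$alleles, collapse = ","), "")
    write_tsv(bdf, file.path(config$outdir, "blocks.tsv"))
    utils::write.csv(as.data.frame(hg$calls),
                     file.path(config$outdir, "haplotype_calls.csv"))
    hg
  })
  cov <- genome_coverage(g)
  manifest$counts$blocks <- c(n_blocks = length(hg$blocks),
                              coverage_mb = cov$total_mb)
  message("blocks: ", length(hg$blocks), " haplotype blocks")

  ## ---- association per trial x environment ----
  assoc <- stage("gwas", {
    rows <- list()
    for (tr in unique(adj$trial)) {
      ids_tr <- unique(adj$entry[adj$trial == tr])
      li <- match(intersect(ids_tr, rownames(g$calls)), rownames(g$calls))
      if (length(li) < 30) next
      g_tr <- subset_genotypes(g, lines = li)
      K <- vanraden_kinship(g_tr)
      pcs <- genotype_pcs(g_tr, 10L)
      hg_tr <- list(calls = hg$calls[li, , drop = FALSE],
                    block_ids = hg$block_ids)
      class(hg_tr) <- "haplotype_genotypes"
      for (ev in unique(adj$env[adj$trial == tr])) {
        d <- adj[adj$trial == tr & adj$env == ev, ]
        y <- stats::setNames(d$GY, d$entry)
        rows[[paste(tr, ev)]] <- assoc_scan(
          hg_tr, y, K = K, n_pcs = config$n_pcs, pcs = pcs,
          min_class = config$min_class, trial = tr, env = ev)
      }
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    write_tsv(res, file.path(config$outdir, "assoc.tsv"))
    res
  })
  manifest$counts$gwas <- c(tests = nrow(assoc),
                            trial_envs = length(unique(paste(assoc$trial,
                                                             assoc$env))))
  message("gwas: ", nrow(assoc), " block tests")

  ## ---- stability ----
  stable <- stage("stability", {
    crit <- stability_criteria(config$p_strong, config$p_weak,
                               config$min_eyts_env, config$min_envs,
                               config$min_eyts_multi)
    env_tabs <- do.call(rbind, lapply(unique(assoc$env), function(ev)
      env_stable(assoc, ev, crit)))
    multi <- multienv_stable(assoc, crit)
    write_tsv(env_tabs, file.path(config$outdir, "stable_env.tsv"))
    write_tsv(multi, file.path(config$outdir, "stable_multienv.tsv"))
    list(env = env_tabs, multi = multi)
  })
  manifest$counts$stability <- c(env_specific = nrow(stable$env),
                                 multi_env = nrow(stable$multi))
  message("stability: ", nrow(stable$env), " env-specific, ",
          nrow(stable$multi), " multi-env stable associations")

  ## ---- epistasis ----
  epi <- stage("epistasis", {
    rows <- list()
    for (key in unique(paste(assoc$trial, assoc$env, sep = "\r"))) {
      tr <- strsplit(key, "\r")[[1]][1]
      ev <- strsplit(key, "\r")[[1]][2]
      a <- assoc[assoc$trial == tr & assoc$env == ev, ]
      cand <- if (config$epistasis_candidates == "all") hg$block_ids
        else unique(a$block_id[!is.na(a$p_value) &
                                 a$p_value < config$epistasis_marginal_p])
      if (length(cand) < 2) next
      d <- adj[adj$trial == tr & adj$env == ev, ]
      li <- match(d$entry, rownames(hg$calls))
      hmat <- hg$calls[li, cand, drop = FALSE]
      rows[[key]] <- pairwise_scan(hmat, d$GY, alpha = config$epistasis_alpha,
                                   min_class = config$min_class,
                                   trial = tr, env = ev)
    }
    epi <- do.call(rbind, rows)
    if (is.null(epi)) epi <- pairwise_scan(matrix(NA_integer_, 0, 2),
                                           numeric(0), alpha = 1)
    rownames(epi) <- NULL
    write_tsv(epi, file.path(config$outdir, "epistasis.tsv"))
    epi
  })
  manifest$counts$epistasis <- c(significant_pairs = nrow(epi))
  message("epistasis: ", nrow(epi), " significant interactions")

  ## ---- stacking ----
  stack <- stage("stacking", {
    if (nrow(stable$multi) == 0) {
      list(trend = NULL)
    } else {
      ## favorable allele per stable block: from its most significant hit
      fav <- vapply(stable$multi$block_id, function(b) {
        hits <- assoc[assoc$block_id == b & !is.na(assoc$p_value), ]
        hits$favorable[which.min(hits$p_value)]
      }, "")
      st <- data.frame(block_id = stable$multi$block_id, favorable = fav)
      fm <- favorable_matrix(hg, st)
      counts <- stacking_counts(fm)
      ## pooled adjusted GY per line: mean over its trial's environments
      ## (every entry is observed in the same environment set, so the pooled
      ## means stay on the raw kg/ha scale and comparable across lines)
      ymean <- tapply(adj$GY, adj$entry, mean, na.rm = TRUE)
      y <- as.numeric(ymean[rownames(hg$calls)])
      trend <- additive_trend(counts, y)
      utils::write.csv(as.data.frame(fm),
                       file.path(config$outdir, "favorable_matrix.csv"))
      write_tsv(trend$class_means,
                file.path(config$outdir, "stacking_classes.tsv"))
      list(trend = trend, counts = counts)
    }
  })
  if (!is.null(stack$trend)) {
    manifest$counts$stacking <- c(slope = stack$trend$slope,
                                  pct_increase = stack$trend$pct_increase)
    message(sprintf("stacking: slope %.1f kg/ha per haplotype, %.1f%% increase",
                    stack$trend$slope, stack$trend$pct_increase))
  }

  ## ---- manifest ----
  outs <- list.files(config$outdir, full.names = TRUE)
  outs <- outs[!grepl("manifest\\.json$", outs)]
  manifest$counts <- lapply(manifest$counts, as.list)
  manifest$checksums <- as.list(tools::md5sum(outs))
  names(manifest$checksums) <- basename(outs)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest$results <- list(genotypes = g, pheno = inp$pheno, adjusted = adj,
                           decay = decay,
                           hap_genotypes = hg, assoc = assoc, stable = stable,
                           epistasis = epi, stacking = stack, truth = inp$truth)
  invisible(manifest)
}
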