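## Forward-in-time simulator of inbred breeding cohorts: founder haplotypes,
## generations of random crossing with Poisson crossovers, selfing to
## near-homozygosity, GBS-like missingness, and multi-environment yield-trial
## phenotypes with additive block QTL, planted epistasis, genotype x
## environment effect scaling and a target entry-mean heritability.

## one global seed expands to fixed per-stage substreams so adding a stage
## never perturbs earlier draws
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 2017L + sum(utf8ToInt(stage)) %% 1000L
}

#' Simulation specification
#'
#' Study-condition defaults: 1,000 advanced inbred lines derived from a
#' narrow elite pool of 16 founders by 8 generations of random crossing (1.5
#' crossovers per
#' chromosome per meiosis) and 6 generations of selfing; 2,000 biallelic
#' markers on 3 chromosomes of 100 Mb; 15\% missing calls; 7 trial cohorts
#' phenotyped in 4 environments (I, MD, SD, HS) in alpha-lattice-like
#' experiments of 28 entries + 2 checks, 3 replicates, incomplete blocks of
#' 6 plots; entry-mean heritability 0.5 per environment.
#'
#' @param n_lines number of inbred lines.
#' @param n_founders founder haplotypes.
#' @param chromosomes data.frame(chrom, length_bp, n_markers).
#' @param rec_rate expected crossovers per chromosome per meiosis.
#' @param generations generations of random crossing.
#' @param selfing selfing generations (residual heterozygosity ~ 0.5^selfing).
#' @param missing_rate missing-call rate injected into observed genotypes.
#' @param het_rate artifact heterozygous-call rate in observed genotypes.
#' @param maf_range ancestral allele-frequency range (uniform draw per
#'   marker).
#' @param n_ancestors ancestral haplotypes the founders descend from; few
#'   ancestors give the strong local haplotype structure (high short-range
#'   r2) typical of elite breeding pools.
#' @param founder_divergence per-site probability that a founder deviates
#'   from its ancestral haplotype (independent redraw).
#' @param environments environment labels.
#' @param env_means environment mean yields, kg/ha.
#' @param gxe_scale per-environment scaling of all genetic effects.
#' @param qtl data.frame(marker, effect): additive QTL, effect in kg/ha added
#'   to carriers (minor-allele homozygotes) of that marker, before G x E
#'   scaling. Marker = index or id.
#' @param epistasis list of \code{list(markers = c(...), effect = ...)}:
#'   effect added when the line carries the minor homozygote at every listed
#'   marker.
#' @param polygenic_sd standard deviation (kg/ha) of the polygenic value,
#'   drawn N(0, polygenic_sd^2 K) with K the VanRaden kinship.
#' @param h2 target entry-mean broad-sense heritability per environment.
#' @param cohorts number of trial cohorts (EYTs); lines are split evenly.
#' @param replicates,entries_per_experiment,checks_per_experiment,block_size
#'   trial layout.
#' @param block_sd,rep_sd incomplete-block and replicate effect SDs, kg/ha.
#' @param dh_coupling per-environment coupling of days-to-heading to the
#'   genetic yield value (positive: later lines yield more); defaults mirror
#'   irrigated-positive / stress-negative phenology patterns.
#' @param ph_coupling plant-height coupling (positive in all environments).
#' @param seed mandatory RNG seed.
#' @return list of class \code{simulation_spec}.
#' @export
simulation_spec <- function(n_lines = 1000L, n_founders = 16L,
                            chromosomes = data.frame(
                              chrom = c("1A", "2B", "3D"),
                              length_bp = 1e8,
                              n_markers = c(667L, 667L, 666L)),
                            rec_rate = 1.5, generations = 8L, selfing = 6L,
                            missing_rate = 0.15, het_rate = 0.002,
                            maf_range = c(0.1, 0.5), n_ancestors = 4L,
                            founder_divergence = 0.2,
                            environments = c("I", "MD", "SD", "HS"),
                            env_means = c(I = 6000, MD = 4500, SD = 2500,
                                          HS = 3500),
                            gxe_scale = c(I = 1, MD = 0.8, SD = 0.6,
                                          HS = 0.7),
                            qtl = NULL, epistasis = NULL,
                            polygenic_sd = 300, h2 = 0.5, cohorts = 7L,
                            replicates = 3L, entries_per_experiment = 28L,
                            checks_per_experiment = 2L, block_size = 6L,
                            block_sd = 150, rep_sd = 50,
                            dh_coupling = c(I = 0.3, MD = 0, SD = -0.3,
                                            HS = -0.3),
                            ph_coupling = 0.4, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(all(c(missing_rate, het_rate, h2) >= 0),
            all(c(missing_rate, het_rate, h2) <= 1), rec_rate >= 0,
            sum(chromosomes$n_markers) > 0, n_founders >= 2)
  spec <- as.list(environment())
  structure(spec, class = "simulation_spec")
}

## crossover mask over the whole marker map: TRUE = take parent 1
cross_mask <- function(map_pos, map_len, rec_rate) {
  unlist(lapply(seq_along(map_pos), function(c) {
    pos <- map_pos[[c]]
    k <- stats::rpois(1, rec_rate)
    seg <- if (k > 0) findInterval(pos, sort(stats::runif(k, 0, map_len[c])))
           else rep(0L, length(pos))
    (seg + sample(0:1, 1)) %% 2 == 0
  }), use.names = FALSE)
}

#' Simulate inbred-line genotypes
#'
#' Founder haplotypes are drawn per marker at a uniform allele-frequency
#' spectrum, recombined through \code{generations} rounds of random crossing
#' (Poisson crossovers), then selfed. Observed calls add heterozygous-call
#' artifacts and missingness; true calls are kept for phenotype simulation.
#' Codes are oriented so 0 = major homozygote. Deterministic given the spec
#' seed.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list of class \code{sim_genotypes}: \code{genotypes} (observed
#'   \code{\link{genotype_matrix}}), \code{true_calls} (pre-artifact matrix),
#'   \code{ancestry} (founder-of-origin codes for both gametes),
#'   \code{founder_maf}.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(stage_seed(spec$seed, "genotypes"))
  chr <- spec$chromosomes
  map_pos <- lapply(seq_len(nrow(chr)), function(c) {
    sort(sample.int(chr$length_bp[c], chr$n_markers[c]))
  })
  m <- sum(chr$n_markers)
  map <- data.frame(
    marker = unlist(lapply(seq_len(nrow(chr)), function(c)
      paste0("S", chr$chrom[c], "_", map_pos[[c]]))),
    chrom = rep(chr$chrom, chr$n_markers),
    pos = unlist(map_pos))

  ## founders descend from a few ancestral haplotypes with per-site
  ## divergence: this seeds the strong short-range LD of an elite pool
  p <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  nF <- spec$n_founders
  nA <- max(2L, min(spec$n_ancestors, nF))
  anc <- matrix(stats::rbinom(nA * m, 1L, rep(p, each = nA)), nA, m)
  pool_a <- anc[rep_len(seq_len(nA), nF), , drop = FALSE]
  mut <- matrix(stats::runif(nF * m) < spec$founder_divergence, nF, m)
  pool_a[mut] <- stats::rbinom(sum(mut), 1L, rep(p, each = nF)[mut])
  pool_o <- matrix(rep(seq_len(nF), m), nF, m)
  f_freq <- colMeans(pool_a)
  founder_maf <- pmin(f_freq, 1 - f_freq)   # realized founder MAF

  ## crossing-pool size: large enough that drift over the crossing
  ## generations rarely pushes common founder alleles below the MAF filter
  P <- max(200L, 4L * nF)
  for (g in seq_len(spec$generations)) {
    new_a <- matrix(0L, P, m)
    new_o <- matrix(0L, P, m)
    np <- nrow(pool_a)
    for (h in seq_len(P)) {
      par <- sample.int(np, 2, replace = np < 2)
      take1 <- cross_mask(map_pos, chr$length_bp, spec$rec_rate)
      new_a[h, ] <- ifelse(take1, pool_a[par[1], ], pool_a[par[2], ])
      new_o[h, ] <- ifelse(take1, pool_o[par[1], ], pool_o[par[2], ])
    }
    pool_a <- new_a
    pool_o <- new_o
  }

  n <- spec$n_lines
  h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
  o1 <- matrix(0L, n, m); o2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    par <- sample.int(nrow(pool_a), 2, replace = FALSE)
    a1 <- pool_a[par[1], ]; a2 <- pool_a[par[2], ]
    b1 <- pool_o[par[1], ]; b2 <- pool_o[par[2], ]
    for (s in seq_len(spec$selfing)) {
      m1 <- cross_mask(map_pos, chr$length_bp, spec$rec_rate)
      m2 <- cross_mask(map_pos, chr$length_bp, spec$rec_rate)
      na1 <- ifelse(m1, a1, a2); nb1 <- ifelse(m1, b1, b2)
      na2 <- ifelse(m2, a1, a2); nb2 <- ifelse(m2, b1, b2)
      a1 <- na1; a2 <- na2; b1 <- nb1; b2 <- nb2
    }
    h1[i, ] <- a1; h2[i, ] <- a2; o1[i, ] <- b1; o2[i, ] <- b2
  }
  true_calls <- h1 + h2

  ## orient so 0 = major homozygote
  flip <- colMeans(true_calls) / 2 > 0.5
  true_calls[, flip] <- 2L - true_calls[, flip]

  obs <- true_calls
  if (spec$het_rate > 0) {
    idx <- which(stats::runif(length(obs)) < spec$het_rate)
    obs[idx] <- 1L
  }
  if (spec$missing_rate > 0) {
    obs[stats::runif(length(obs)) < spec$missing_rate] <- NA_integer_
  }
  line_ids <- sprintf("L%04d", seq_len(n))
  dimnames(true_calls) <- list(line_ids, map$marker)
  g <- genotype_matrix(obs, map = map, line_ids = line_ids)
  structure(list(genotypes = g, true_calls = true_calls,
                 ancestry = list(h1 = o1, h2 = o2),
                 founder_maf = founder_maf),
            class = "sim_genotypes")
}

## resolve QTL marker references (index or id) against a map
qtl_index <- function(marker, map) {
  if (is.numeric(marker)) return(as.integer(marker))
  idx <- match(as.character(marker), map$marker)
  if (anyNA(idx)) stop("unknown QTL marker: ", marker[is.na(idx)][1])
  idx
}

#' Simulate multi-environment trial phenotypes
#'
#' Genetic value per line = additive QTL effects (carriers of the minor
#' homozygote) + planted epistatic terms + a polygenic value drawn from
#' N(0, polygenic_sd^2 K); each environment scales it by \code{gxe_scale} and
#' shifts by \code{env_means}. Residual plot variance is set per environment
#' so the realized entry-mean heritability matches the \code{h2} target; plot
#' values add replicate and incomplete-block effects. Lines are split into
#' cohorts (one trial each); the first \code{checks_per_experiment} lines of
#' each cohort serve as the checks of every experiment of that trial.
#'
#' @param sim a \code{sim_genotypes} object (true calls are used), or a
#'   \code{\link{genotype_matrix}}.
#' @param spec the \code{\link{simulation_spec}}.
#' @return list of class \code{sim_phenotypes}: \code{pheno} (data.frame
#'   trial, env, experiment, rep, block, entry, is_check, GY, DH, PH),
#'   \code{truth} (cohort per line, genetic values per environment, residual
#'   SDs).
#' @export
simulate_phenotypes <- function(sim, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  calls <- if (inherits(sim, "sim_genotypes")) sim$true_calls
           else if (inherits(sim, "genotype_matrix")) sim$calls
           else stop("sim must be sim_genotypes or genotype_matrix")
  set.seed(stage_seed(spec$seed, "phenotypes"))
  n <- nrow(calls)
  line_ids <- rownames(calls)
  map <- if (inherits(sim, "sim_genotypes")) sim$genotypes$map else sim$map

  g0 <- numeric(n)
  if (!is.null(spec$qtl) && nrow(spec$qtl)) {
    for (k in seq_len(nrow(spec$qtl))) {
      idx <- qtl_index(spec$qtl$marker[k], map)
      g0 <- g0 + spec$qtl$effect[k] * (calls[, idx] == 2L)
    }
  }
  if (!is.null(spec$epistasis)) {
    for (term in spec$epistasis) {
      idx <- qtl_index(term$markers, map)
      carrier <- rowSums(calls[, idx, drop = FALSE] == 2L) == length(idx)
      g0 <- g0 + term$effect * carrier
    }
  }
  if (spec$polygenic_sd > 0) {
    gm <- structure(list(calls = calls, map = map), class = "genotype_matrix")
    K <- vanraden_kinship(gm)
    L <- chol(K + diag(1e-6, n))
    g0 <- g0 + spec$polygenic_sd * drop(crossprod(L, stats::rnorm(n)))
  }

  envs <- spec$environments
  G <- outer(g0, spec$gxe_scale[envs])        # lines x environments
  var_G <- apply(G, 2, stats::var)
  if (any(var_G <= 0) && spec$h2 > 0)
    stop("zero genetic variance; target heritability ", spec$h2,
         " unattainable")
  sigma_e <- if (spec$h2 > 0)
    sqrt(spec$replicates * var_G * (1 - spec$h2) / spec$h2)
  else rep(stats::sd(g0) + 1000, length(envs))
  if (spec$h2 == 0) G[] <- 0
  names(sigma_e) <- envs

  cohort <- sprintf("EYT%02d", rep(seq_len(spec$cohorts),
                                   each = ceiling(n / spec$cohorts))[seq_len(n)])
  parts <- list()
  for (tr in unique(cohort)) {
    lines_tr <- which(cohort == tr)
    nc <- spec$checks_per_experiment
    checks <- line_ids[lines_tr[seq_len(min(nc, length(lines_tr)))]]
    entries <- setdiff(line_ids[lines_tr], checks)
    n_exp <- max(1L, ceiling(length(entries) / spec$entries_per_experiment))
    exp_of <- rep(seq_len(n_exp), each = spec$entries_per_experiment,
                  length.out = length(entries))
    for (ev in envs) {
      for (x in seq_len(n_exp)) {
        plot_lines <- c(entries[exp_of == x], checks)
        np <- length(plot_lines)
        for (r in seq_len(spec$replicates)) {
          ord <- sample(np)
          blk <- ceiling(seq_len(np) / spec$block_size)
          n_blk <- max(blk)
          blk_eff <- stats::rnorm(n_blk, 0, spec$block_sd)
          rep_eff <- stats::rnorm(1, 0, spec$rep_sd)
          ids <- plot_lines[ord]
          li <- match(ids, line_ids)
          zg <- (g0[li] - mean(g0)) / max(stats::sd(g0), 1e-8)
          parts[[length(parts) + 1L]] <- data.frame(
            trial = tr, env = ev, experiment = sprintf("%s_E%02d", tr, x),
            rep = r, block = sprintf("b%02d", blk),
            entry = ids, is_check = ids %in% checks,
            GY = unname(spec$env_means[ev]) + G[li, ev] + rep_eff +
              blk_eff[blk] + stats::rnorm(np, 0, sigma_e[ev]),
            DH = 75 + spec$dh_coupling[ev] * zg * 3 + stats::rnorm(np, 0, 1.5),
            PH = 100 + spec$ph_coupling * zg * 6 + stats::rnorm(np, 0, 4))
        }
      }
    }
  }
  pheno <- do.call(rbind, parts)
  rownames(pheno) <- NULL
  structure(list(pheno = pheno,
                 truth = list(cohort = stats::setNames(cohort, line_ids),
                              genetic_values = G, g0 = g0,
                              sigma_e = sigma_e)),
            class = "sim_phenotypes")
}

## minimal independent CI oracle used only to stamp expected values into the
## fixture manifest (dense-grid likelihood, written directly from the
## multinomial definition)
fixture_ci_oracle <- function(counts, step = 1e-4) {
  nt <- sum(counts)
  pA <- (counts[1] + counts[2]) / nt
  pB <- (counts[1] + counts[3]) / nt
  D_obs <- counts[1] / nt - pA * pB
  s <- if (D_obs >= 0) 1 else -1
  dmax <- if (s > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, by = step)
  ll <- numeric(length(grid))
  pr <- cbind(pA * pB + s * grid * dmax,
              pA * (1 - pB) - s * grid * dmax,
              (1 - pA) * pB - s * grid * dmax,
              (1 - pA) * (1 - pB) + s * grid * dmax)
  pr[pr < 0] <- 0
  for (k in 1:4) {
    if (counts[k] == 0) next
    t_ <- counts[k] * log(pr[, k])
    t_[pr[, k] <= 0] <- -Inf
    ll <- ll + t_
  }
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  c(grid[which(cum >= 0.05)[1]], grid[which(cum >= 0.95)[1]])
}

#' Write the small named fixture bundle
#'
#' Emits the toy instances used across the package examples — a perfect-LD
#' marker pair, an independent pair, a 6-SNP block-finder case and a
#' 3-block / 4-line stacking fixture — as matrix-csv files plus a JSON
#' manifest of expected outputs computed by direct enumeration at generation
#' time. Byte-identical for a given seed.
#'
#' @param seed RNG seed.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
fixture_suite <- function(seed, dir = tempfile("fixtures")) {
  set.seed(stage_seed(seed, "fixtures"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed)

  ## 1. perfect-LD pair: two identical columns, 60/60 split
  calls <- cbind(rep(c(0L, 2L), each = 60), rep(c(0L, 2L), each = 60))
  g1 <- genotype_matrix(calls, map = data.frame(marker = c("P1", "P2"),
                                                chrom = "1A",
                                                pos = c(1e6, 1.5e6)))
  write_genotypes_csv(g1, file.path(dir, "perfect_ld_pair.csv"))
  manifest$perfect_ld_pair <- list(Dprime = 1, r2 = 1,
                                   classification = "strong_LD")

  ## 2. independence pair: all four two-locus classes equally frequent
  calls <- cbind(rep(c(0L, 0L, 2L, 2L), each = 30),
                 rep(c(0L, 2L, 0L, 2L), each = 30))
  g2 <- genotype_matrix(calls, map = data.frame(marker = c("I1", "I2"),
                                                chrom = "1A",
                                                pos = c(1e6, 1.5e6)))
  write_genotypes_csv(g2, file.path(dir, "independence_pair.csv"))
  ci <- fixture_ci_oracle(c(30, 30, 30, 30))
  manifest$independence_pair <- list(
    D = 0, ci_high = ci[2],
    classification = if (ci[2] < 0.90) "strong_recombination" else "inconclusive")

  ## 3. block-finder case: SNPs 1-3 in perfect LD, SNPs 4-6 independent noise
  base <- rep(c(0L, 2L), each = 60)
  noise <- replicate(3, sample(c(0L, 2L), 120, replace = TRUE))
  calls <- cbind(base, base, base, noise)
  g3 <- genotype_matrix(calls, map = data.frame(
    marker = paste0("BK", 1:6), chrom = "2B",
    pos = c(1e6, 1.2e6, 1.4e6, 5e6, 9e6, 13e6)))
  write_genotypes_csv(g3, file.path(dir, "block_oracle.csv"))
  manifest$block_oracle <- list(n_blocks = 1, members = c("BK1", "BK2", "BK3"))

  ## 4. stacking fixture: 4 lines x 3 blocks, hand-enumerated indicators
  hap <- matrix(c(1L, 2L, 1L, NA,
                  1L, 1L, 2L, 2L,
                  2L, 1L, 1L, 1L), 4, 3,
                dimnames = list(paste0("L", 1:4), paste0("HB", 1:3)))
  stable <- data.frame(block_id = paste0("HB", 1:3),
                       favorable = c("1", "2", "1"))
  utils::write.csv(as.data.frame(hap), file.path(dir, "stacking_calls.csv"))
  utils::write.csv(stable, file.path(dir, "stacking_stable.csv"),
                   row.names = FALSE)
  expected <- matrix(c(1L, 0L, 1L, NA,
                       0L, 0L, 1L, 1L,
                       0L, 1L, 1L, 1L), 4, 3)
  manifest$stacking <- list(indicator = expected,
                            counts = rowSums(expected > 0, na.rm = TRUE))

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "dir") <- dir
  invisible(manifest)
}
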