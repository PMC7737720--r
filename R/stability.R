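## Stability classification of haplotype-block associations across elite
## yield trials (EYTs) and testing environments.

#' Stability criteria
#'
#' Thresholds of the two stability definitions. Environment-specific: a block
#' is stable for one testing environment when some EYT gives P <
#' \code{p_strong} and at least \code{min_eyts_env} EYTs (the strong one
#' included) give P < \code{p_weak}. Multi-environment: P < \code{p_weak}
#' hits spanning at least \code{min_envs} distinct environments and
#' \code{min_eyts_multi} distinct EYTs. No multiplicity correction beyond
#' these fixed thresholds.
#'
#' @param p_strong strong per-EYT threshold (default 1e-4).
#' @param p_weak supporting threshold (default 1e-3).
#' @param min_eyts_env EYTs required for environment-specific stability.
#' @param min_envs,min_eyts_multi environments / EYTs required for
#'   multi-environment stability.
#' @return list of class \code{stability_criteria}.
#' @export
stability_criteria <- function(p_strong = 1e-4, p_weak = 1e-3,
                               min_eyts_env = 3L, min_envs = 2L,
                               min_eyts_multi = 2L) {
  stopifnot(p_strong <= p_weak)
  structure(list(p_strong = p_strong, p_weak = p_weak,
                 min_eyts_env = min_eyts_env, min_envs = min_envs,
                 min_eyts_multi = min_eyts_multi),
            class = "stability_criteria")
}

#' Environment-specific stable associations
#'
#' @param results association data.frame with columns \code{block_id},
#'   \code{trial}, \code{env}, \code{p_value} (e.g. rbind-ed
#'   \code{\link{assoc_scan}} outputs over trials).
#' @param env the testing environment to classify.
#' @param criteria a \code{\link{stability_criteria}}.
#' @return data.frame(block_id, env, category, n_trials_weak, min_p,
#'   supporting) — one row per stable block; \code{supporting} lists the
#'   qualifying "trial;env (p)" tuples.
#' @export
env_stable <- function(results, env, criteria = stability_criteria()) {
  d <- results[results$env == env & !is.na(results$p_value), , drop = FALSE]
  out <- lapply(split(d, d$block_id), function(b) {
    weak <- b[b$p_value < criteria$p_weak, , drop = FALSE]
    n_weak <- length(unique(weak$trial))
    if (any(b$p_value < criteria$p_strong) && n_weak >= criteria$min_eyts_env) {
      data.frame(block_id = b$block_id[1], env = env,
                 category = paste0("env_specific(", env, ")"),
                 n_trials_weak = n_weak, min_p = min(b$p_value),
                 supporting = paste(sprintf("%s;%s (%.2g)", weak$trial,
                                            weak$env, weak$p_value),
                                    collapse = ", "))
    }
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(block_id = character(), env = character(),
                      category = character(), n_trials_weak = integer(),
                      min_p = numeric(), supporting = character())
  }
  rownames(out) <- NULL
  out
}

#' Multi-environment stable associations
#'
#' A block is multi-environment stable when its P < \code{p_weak} hits cover
#' at least \code{min_envs} distinct environments and \code{min_eyts_multi}
#' distinct EYTs jointly. \code{per_env = TRUE} applies the stricter reading:
#' at least \code{min_envs} environments must each carry hits from
#' \code{min_eyts_multi} or more distinct EYTs.
#'
#' @param results association data.frame (see \code{\link{env_stable}}).
#' @param criteria a \code{\link{stability_criteria}}.
#' @param per_env use the stricter per-environment reading.
#' @return data.frame(block_id, category, n_envs, n_trials, min_p,
#'   supporting), one row per stable block.
#' @export
multienv_stable <- function(results, criteria = stability_criteria(),
                            per_env = FALSE) {
  d <- results[!is.na(results$p_value) &
                 results$p_value < criteria$p_weak, , drop = FALSE]
  out <- lapply(split(d, d$block_id), function(b) {
    envs <- unique(b$env)
    trials <- unique(b$trial)
    stable <- if (per_env) {
      per_env_trials <- tapply(b$trial, b$env, function(t) length(unique(t)))
      sum(per_env_trials >= criteria$min_eyts_multi) >= criteria$min_envs
    } else {
      length(envs) >= criteria$min_envs &&
        length(trials) >= criteria$min_eyts_multi
    }
    if (stable) {
      data.frame(block_id = b$block_id[1], category = "multi_env",
                 n_envs = length(envs), n_trials = length(trials),
                 min_p = min(b$p_value),
                 supporting = paste(sprintf("%s;%s (%.2g)", b$trial, b$env,
                                            b$p_value), collapse = ", "))
    }
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(block_id = character(), category = character(),
                      n_envs = integer(), n_trials = integer(),
                      min_p = numeric(), supporting = character())
  }
  rownames(out) <- NULL
  out
}
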