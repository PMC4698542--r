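#' Monte-Carlo comparison configuration
#'
#' Parameters of the parametric-bootstrap Monte-Carlo group comparison: a
#' large normal population is simulated from the reference group's mean and
#' SD (`pool_size` points), the sampling distribution of comparator-sized
#' means is built by `reps` repeated draws, and the central `1 - alpha`
#' percentile interval of those means is the significance band.
#'
#' @param pool_size points in the simulated population (default 1,000,000).
#' @param reps resampling repetitions (default 10,000).
#' @param alpha two-sided significance level.
#' @param seed optional RNG seed; when set, every comparison run from this
#'   config is reproducible.
#' @return a list of class `mc_config`.
#' @export
mc_config <- function(pool_size = 1e6, reps = 1e4, alpha = 0.05, seed = NULL) {
  pool_size <- as.integer(pool_size)
  reps <- as.integer(reps)
  if (!(pool_size >= reps && reps >= 100L)) {
    stop("need pool_size >= reps >= 100")
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  structure(list(pool_size = pool_size, reps = reps, alpha = alpha,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mc_config")
}

#' Simulate the reference population
#'
#' `pool_size` draws from Normal(mean, sd). With `sd = 0` every point equals
#' the mean.
#'
#' @param mean,sd reference-group mean and SD (`sd >= 0`).
#' @param config an [mc_config()].
#' @return numeric vector of length `config$pool_size`.
#' @export
simulate_pool <- function(mean, sd, config = mc_config()) {
  stopifnot(sd >= 0)
  if (!is.null(config$seed)) set.seed(config$seed)
  stats::rnorm(config$pool_size, mean, sd)
}

#' Sampling distribution of comparator-sized means
#'
#' Draws `n` points from the pool (with replacement), takes their mean, and
#' repeats `config$reps` times: the Monte-Carlo sampling distribution of the
#' mean at the comparator's sample size.
#'
#' @param pool simulated population (see [simulate_pool()]).
#' @param n comparator group size (>= 2).
#' @param config an [mc_config()].
#' @return numeric vector of `config$reps` means.
#' @export
sampling_distribution_of_means <- function(pool, n, config = mc_config()) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  if (!is.null(config$seed)) set.seed(config$seed)
  idx <- sample.int(length(pool), n * config$reps, replace = TRUE)
  .colMeans(pool[idx], n, config$reps)
}

#' Monte-Carlo comparison of two group summaries
#'
#' The reference group supplies the mean and SD that seed the simulated
#' population; the comparator supplies its sample size and observed mean.
#' The confidence bounds are the `alpha/2` and `1 - alpha/2` empirical
#' percentiles of the sampling distribution of comparator-sized means; the
#' comparator is significantly different when its observed mean falls
#' outside that interval (bounds count as inside). The two-sided empirical
#' p-value is `2 * min(frac of simulated means <= observed, frac >=
#' observed)`, floored at `1/reps` and capped at 1.
#'
#' @param ref,comp one-row [summarize_groups()] rows (or lists with `group`,
#'   `measure`, `n`, `mean`, `sd`) for the same measure.
#' @param config an [mc_config()].
#' @return one-row data frame: `measure`, `reference`, `comparator`,
#'   `ref_mean`, `ref_sd`, `n_comp`, `observed`, `ci_low`, `ci_high`,
#'   `p_empirical`, `significant`, `self`.
#' @export
compare_groups <- function(ref, comp, config = mc_config()) {
  if (!identical(as.character(ref$measure), as.character(comp$measure))) {
    stop("measure mismatch: '", ref$measure, "' vs '", comp$measure, "'")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config; cfg$seed <- NULL
  pool <- simulate_pool(ref$mean, ref$sd, cfg)
  means <- sampling_distribution_of_means(pool, comp$n, cfg)
  ci <- stats::quantile(means, c(config$alpha / 2, 1 - config$alpha / 2),
                        names = FALSE)
  observed <- comp$mean
  significant <- observed < ci[1] || observed > ci[2]
  p <- 2 * min(mean(means <= observed), mean(means >= observed))
  p <- min(1, max(p, 1 / config$reps))
  data.frame(measure = as.character(ref$measure),
             reference = as.character(ref$group),
             comparator = as.character(comp$group),
             ref_mean = ref$mean, ref_sd = ref$sd,
             n_comp = as.integer(comp$n), observed = observed,
             ci_low = ci[1], ci_high = ci[2],
             p_empirical = p, significant = significant,
             self = identical(as.character(ref$group),
                              as.character(comp$group)),
             stringsAsFactors = FALSE)
}

#' Full ordered comparison matrix
#'
#' Runs [compare_groups()] for every measure and every ordered
#' (reference, comparator) group pair — including self-comparisons, which
#' are flagged in the `self` column — mirroring a statistical table with one
#' confidence-interval column per reference group and one row per measure x
#' comparator. No multiple-testing correction is applied; the number of
#' non-self comparisons is recorded in attribute `"n_comparisons"`.
#'
#' @param summaries a [summarize_groups()] data frame (proteins, indices, or
#'   both row-bound together).
#' @param config an [mc_config()]; its seed makes the whole matrix
#'   reproducible.
#' @param references,comparators optional subsets of group names.
#' @return a `comparison_matrix` data frame, one [compare_groups()] row per
#'   measure x reference x comparator.
#' @export
comparison_matrix <- function(summaries, config = mc_config(),
                              references = NULL, comparators = NULL) {
  stopifnot(inherits(summaries, "data.frame"),
            all(c("group", "measure", "n", "mean", "sd") %in% names(summaries)))
  groups <- unique(summaries$group)
  if (length(groups) < 2L && is.null(references)) {
    stop("need at least 2 groups for a comparison matrix")
  }
  if (is.null(references)) references <- groups
  if (is.null(comparators)) comparators <- groups
  measures <- unique(summaries$measure)
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config; cfg$seed <- NULL

  rows <- vector("list", length(measures) * length(references) * length(comparators))
  k <- 0L
  for (m in measures) {
    sm <- summaries[summaries$measure == m, , drop = FALSE]
    for (r in references) {
      for (cm in comparators) {
        k <- k + 1L
        rows[[k]] <- compare_groups(sm[sm$group == r, , drop = FALSE],
                                    sm[sm$group == cm, , drop = FALSE], cfg)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- config$alpha
  attr(out, "n_comparisons") <- sum(!out$self)
  class(out) <- c("comparison_matrix", "data.frame")
  out
}

#' Significance stars
#'
#' Figure-legend convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001. Note the empirical p-value is floored at `1/reps`, so
#' finer stars need more repetitions.
#'
#' @param p numeric vector of p-values.
#' @return character vector of stars (empty string when p >= 0.05).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else ""
  }, character(1))
}

#' Wide confidence-interval table
#'
#' Reshapes a [comparison_matrix()] into the familiar statistical-table
#' layout: one row per measure x comparator, one confidence-interval column
#' per reference group (the interval of the reference-seeded sampling
#' distribution at the comparator's n), plus the comparator's observed mean
#' and significance stars against the first reference.
#'
#' @param cm a `comparison_matrix`.
#' @param digits digits for the formatted bounds.
#' @return a data frame with columns `measure`, `comparator`, `observed`,
#'   `stars_vs_<first reference>`, and `ci_vs_<reference>` for every
#'   reference group.
#' @export
format_comparison_table <- function(cm, digits = 4) {
  stopifnot(inherits(cm, "comparison_matrix"))
  refs <- unique(cm$reference)
  comps <- unique(cm$comparator)
  measures <- unique(cm$measure)
  base <- expand.grid(comparator = comps, measure = measures,
                      stringsAsFactors = FALSE)[, c("measure", "comparator")]
  fmt <- function(lo, hi) {
    sprintf(paste0("[%.", digits, "f, %.", digits, "f]"), lo, hi)
  }
  key_cm <- paste(cm$measure, cm$comparator, cm$reference, sep = "\r")
  out <- base
  first_ref_key <- paste(base$measure, base$comparator, refs[1], sep = "\r")
  m0 <- match(first_ref_key, key_cm)
  out$observed <- cm$observed[m0]
  out[[paste0("stars_vs_", refs[1])]] <- significance_stars(cm$p_empirical[m0])
  for (r in refs) {
    m <- match(paste(base$measure, base$comparator, r, sep = "\r"), key_cm)
    out[[paste0("ci_vs_", r)]] <- fmt(cm$ci_low[m], cm$ci_high[m])
  }
  out
}
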