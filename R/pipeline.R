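#' Study configuration
#'
#' Bundles everything [run_study()] needs: the design (groups, panel,
#' loading control, reference group), the input mode (a band table to
#' analyze, or `NULL` to simulate one from the design), the contrast-index
#' definitions, the Monte-Carlo settings, a master seed, and an optional
#' output directory.
#'
#' @param design a [synthetic_design()]; also defines groups/panel when an
#'   external band table is analyzed.
#' @param input `NULL` (simulate from `design`), a path to a band-table
#'   file, or a band-table data frame.
#' @param index_definitions named list of protein pairs, as in
#'   [default_index_definitions()].
#' @param mc an [mc_config()] (its seed, if any, is overridden by `seed`).
#' @param seed master seed: one integer drives simulation and every
#'   Monte-Carlo comparison, making the whole run reproducible.
#' @param control_group group label of pooled control-sample lanes.
#' @param output_dir if non-NULL, [write_results()] is called on the bundle.
#' @return a list of class `study_config`.
#' @export
study_config <- function(design = default_design(),
                         input = NULL,
                         index_definitions = default_index_definitions(),
                         mc = mc_config(),
                         seed = 1L,
                         control_group = "control",
                         output_dir = NULL) {
  stopifnot(inherits(design, "synthetic_design"), inherits(mc, "mc_config"))
  for (nm in names(index_definitions)) {
    miss <- setdiff(index_definitions[[nm]], design$proteins)
    if (length(miss) > 0L) {
      stop("index '", nm, "' uses protein(s) not in the panel: ",
           paste(miss, collapse = ", "))
    }
  }
  structure(list(design = design, input = input,
                 index_definitions = index_definitions, mc = mc,
                 seed = as.integer(seed), control_group = control_group,
                 output_dir = output_dir),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' The file mirrors [study_config()]: top-level keys `design` (groups,
#' proteins, loading_control, reference_group, effect, noise_sd, n_blots,
#' blot_sets, batch_sd, loading_sd), `indices` (name: \[A, B\]), `mc`
#' (pool_size, reps, alpha), `seed`, `input`, `output_dir`. Effect and noise
#' maps are nested `group: {protein: value}`; omitted cells keep their
#' defaults (effect 1.0, SD 0.10).
#'
#' @param path YAML file path.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$design)) stop("config file lacks a `design` block")
  d <- cfg$design
  groups <- unlist(d$groups)
  proteins <- unlist(d$proteins)
  fill <- function(block, default) {
    m <- matrix(default, length(groups), length(proteins),
                dimnames = list(names(groups), proteins))
    for (g in names(block)) {
      for (p in names(block[[g]])) {
        if (!g %in% names(groups)) stop("unknown group in config: ", g)
        if (!p %in% proteins) stop("unknown protein in config: ", p)
        m[g, p] <- block[[g]][[p]]
      }
    }
    m
  }
  design <- synthetic_design(
    groups = groups, proteins = proteins,
    loading_control = d$loading_control,
    reference_group = if (is.null(d$reference_group)) names(groups)[1]
                      else d$reference_group,
    effect = fill(d$effect, 1), noise_sd = fill(d$noise_sd, 0.10),
    n_blots = if (is.null(d$n_blots)) 2L else d$n_blots,
    blot_sets = if (is.null(d$blot_sets)) NULL else unlist(d$blot_sets),
    batch_sd = if (is.null(d$batch_sd)) 0.2 else d$batch_sd,
    loading_sd = if (is.null(d$loading_sd)) 0.05 else d$loading_sd,
    replicates = if (is.null(d$replicates)) 1L else d$replicates,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed)
  idx <- if (is.null(cfg$indices)) default_index_definitions()
         else lapply(cfg$indices, unlist)
  mc <- do.call(mc_config, c(cfg$mc))
  study_config(design = design, input = cfg$input,
               index_definitions = idx, mc = mc,
               seed = if (is.null(cfg$seed)) 1L else cfg$seed,
               output_dir = cfg$output_dir)
}

#' Run the full analysis
#'
#' Orchestrates the chain: obtain a band table (simulate from the design or
#' read/validate the input), run the loading-control QC, normalize, build
#' group summaries, compute contrast indices, and fill the full ordered
#' Monte-Carlo comparison matrix over proteins and indices. A QC failure is
#' reported (warning + flag) but does not abort the downstream stages.
#' Everything is deterministic given the config's seed.
#'
#' @param config a [study_config()].
#' @return a list of class `study_result`: `qc`, `normalized`, `summaries`,
#'   `indices`, `index_summaries`, `comparisons`, `comparison_table`,
#'   `provenance`. Written to `config$output_dir` when set.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  design <- config$design
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L)

  table <- config$input
  if (is.null(table)) {
    table <- generate_table(design, seed = sub_seeds[1])
  } else {
    if (is.character(table)) table <- read_band_table(table)
    known <- c(names(design$groups), config$control_group)
    unknown <- setdiff(unique(table$group), known)
    if (length(unknown) > 0L) {
      stop("unknown group label(s) in band table: ",
           paste(unknown, collapse = ", "))
    }
  }

  mc <- config$mc
  mc$seed <- sub_seeds[2]

  qc <- loading_control_qc(table, control_protein = design$loading_control,
                           reference_group = design$reference_group,
                           config = mc, control_group = config$control_group)
  if (!qc$pass) {
    warning("loading-control QC failed for '", design$loading_control,
            "'; continuing with the analysis")
  }

  normalized <- normalize_blots(table,
                                reference_group = design$reference_group,
                                control_group = config$control_group)
  summaries <- summarize_groups(normalized)
  indices <- compute_indices(normalized, config$index_definitions)
  index_summaries <- summarize_groups(indices)

  comparisons <- comparison_matrix(rbind(summaries, index_summaries), mc)
  comparison_table <- format_comparison_table(comparisons)

  provenance <- list(
    package = "blotmc",
    version = as.character(utils::packageVersion("blotmc")),
    seed = config$seed,
    mc = list(pool_size = mc$pool_size, reps = mc$reps, alpha = mc$alpha),
    reference_group = design$reference_group,
    loading_control = design$loading_control,
    normalization_steps = attr(normalized, "provenance")$steps,
    qc_pass = qc$pass,
    n_comparisons = attr(comparisons, "n_comparisons"))

  bundle <- structure(
    list(qc = qc, band_table = table, normalized = normalized,
         summaries = summaries, indices = indices,
         index_summaries = index_summaries, comparisons = comparisons,
         comparison_table = comparison_table, provenance = provenance),
    class = "study_result")
  if (!is.null(config$output_dir)) write_results(bundle, config$output_dir)
  bundle
}

#' @export
print.study_result <- function(x, ...) {
  ns <- sum(x$comparisons$significant & !x$comparisons$self)
  cat("blotmc study result\n",
      "  groups:      ", paste(unique(x$summaries$group), collapse = ", "), "\n",
      "  measures:    ", length(unique(x$comparisons$measure)),
      " (", length(unique(x$summaries$measure)), " proteins, ",
      length(unique(x$index_summaries$measure)), " indices)\n",
      "  QC:          ", if (x$qc$pass) "pass" else "FAIL", "\n",
      "  significant: ", ns, " of ", x$provenance$n_comparisons,
      " non-self comparisons at alpha = ", x$provenance$mc$alpha, "\n",
      sep = "")
  invisible(x)
}
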