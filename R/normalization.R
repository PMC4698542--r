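#' Two-stage blot normalization with fold-of-reference scaling
#'
#' Implements the two-stage normalization used for multi-blot panels, per
#' protein:
#' \enumerate{
#'   \item set average: each band is divided by the mean raw density of all
#'     bands of the same protein in its blot set (blots run at the same
#'     time);
#'   \item control sample: the result is divided by the (equally normalized)
#'     pooled control-sample band of the same protein on the band's own blot;
#'   \item fold of reference: values are scaled so the reference group's mean
#'     is exactly 1 for every protein.
#' }
#' Both stages are ratios, so the final values are invariant to their order
#' and to any common multiplicative factor on a blot (the blot-batch effect
#' cancels exactly through the control-sample ratio). If an animal appears on
#' several blot replicates, its rows are averaged into one value per animal x
#' protein before fold-of-reference scaling.
#'
#' @param table a `band_table` with columns `blot_id`, `lane_id`,
#'   `animal_id`, `group`, `protein`, `raw_density`.
#' @param blot_sets named vector mapping blot id to blot-set id. Defaults to
#'   the table's `"blot_sets"` attribute, else a single set.
#' @param control_lanes named vector mapping blot id to the lane id of the
#'   pooled control sample. Defaults to the table's `"control_lanes"`
#'   attribute, else the lanes of rows with group `control_group`.
#' @param reference_group group whose mean defines 1.
#' @param control_group group label marking control-sample rows (excluded
#'   from the output).
#' @return a `normalized_table`: data frame with columns `animal_id`,
#'   `group`, `protein`, `value`, reference group and a provenance record of
#'   the steps applied attached as attributes.
#' @export
normalize_blots <- function(table,
                            blot_sets = NULL,
                            control_lanes = NULL,
                            reference_group = "normal",
                            control_group = "control") {
  stopifnot(is.data.frame(table))
  need <- c("blot_id", "lane_id", "animal_id", "group", "protein", "raw_density")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L) stop("band table lacks column(s): ",
                              paste(miss, collapse = ", "))
  if (any(table$raw_density <= 0)) stop("raw densities must be strictly positive")

  if (is.null(blot_sets)) blot_sets <- attr(table, "blot_sets")
  blots <- unique(table$blot_id)
  if (is.null(blot_sets)) blot_sets <- stats::setNames(rep(1L, length(blots)), blots)
  unassigned <- setdiff(blots, names(blot_sets))
  if (length(unassigned) > 0L) {
    stop("blot(s) not assigned to a blot set: ", paste(unassigned, collapse = ", "))
  }

  if (is.null(control_lanes)) control_lanes <- attr(table, "control_lanes")
  if (is.null(control_lanes)) {
    ctrl_rows <- table[table$group == control_group, c("blot_id", "lane_id")]
    ctrl_rows <- unique(ctrl_rows)
    if (anyDuplicated(ctrl_rows$blot_id)) {
      stop("multiple control-sample lanes on blot(s): ",
           paste(unique(ctrl_rows$blot_id[duplicated(ctrl_rows$blot_id)]),
                 collapse = ", "))
    }
    control_lanes <- stats::setNames(ctrl_rows$lane_id, ctrl_rows$blot_id)
  }
  no_ctrl <- setdiff(blots, names(control_lanes))
  if (length(no_ctrl) > 0L) {
    stop("no control-sample lane for blot(s): ", paste(no_ctrl, collapse = ", "))
  }

  set_of <- blot_sets[table$blot_id]
  # stage 1: per (set, protein) mean of all bands of that protein in the set
  set_key <- paste(set_of, table$protein, sep = "\r")
  set_mean <- tapply(table$raw_density, set_key, mean)
  if (any(!is.finite(set_mean)) || any(set_mean <= 0)) {
    stop("non-positive blot-set mean encountered")
  }
  v1 <- table$raw_density / set_mean[set_key]

  # stage 2: divide by the control-sample band of the same (blot, protein)
  is_ctrl <- table$lane_id == control_lanes[table$blot_id]
  bp_key <- paste(table$blot_id, table$protein, sep = "\r")
  ctrl_v1 <- stats::setNames(v1[is_ctrl], bp_key[is_ctrl])
  if (anyDuplicated(names(ctrl_v1))) stop("duplicated control band on a blot")
  missing_bp <- setdiff(unique(bp_key), names(ctrl_v1))
  if (length(missing_bp) > 0L) {
    stop("missing control band for (blot, protein): ",
         paste(gsub("\r", " / ", missing_bp), collapse = "; "))
  }
  v2 <- v1 / ctrl_v1[bp_key]

  keep <- !is_ctrl & table$group != control_group
  ap_key <- paste(table$animal_id, table$protein, sep = "\r")[keep]
  val <- tapply(v2[keep], ap_key, mean)   # average blot replicates per animal
  meta <- table[keep, c("animal_id", "group", "protein")]
  meta <- unique(data.frame(meta, key = ap_key, stringsAsFactors = FALSE))
  out <- data.frame(animal_id = meta$animal_id, group = meta$group,
                    protein = meta$protein, value = as.numeric(val[meta$key]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein, out$group, out$animal_id), , drop = FALSE]
  rownames(out) <- NULL

  # stage 3: fold of the reference group
  if (!reference_group %in% out$group) {
    stop("reference group '", reference_group, "' absent from the table")
  }
  ref <- out[out$group == reference_group, ]
  ref_mean <- tapply(ref$value, ref$protein, mean)
  missing_ref <- setdiff(unique(out$protein), names(ref_mean))
  if (length(missing_ref) > 0L) {
    stop("no reference-group animals for protein(s): ",
         paste(missing_ref, collapse = ", "))
  }
  out$value <- out$value / ref_mean[out$protein]

  attr(out, "reference_group") <- reference_group
  attr(out, "provenance") <- list(
    steps = c("blot_set_average", "control_sample_ratio", "fold_of_reference"),
    blot_sets = blot_sets, control_lanes = control_lanes,
    reference_group = reference_group)
  class(out) <- c("normalized_table", "data.frame")
  out
}

#' Per-group summaries of normalized expression or index values
#'
#' Computes per group x measure: number of animals, sample mean, sample SD
#' (n - 1 denominator) and SEM = SD / sqrt(n). Works on a
#' [normalize_blots()] table (measure column `protein`) or a
#' [compute_indices()] table (measure column `index`).
#'
#' @param x data frame with columns `group`, `value`, and either `protein`
#'   or `index`.
#' @return a `group_summary` data frame with columns `group`, `measure`,
#'   `n`, `mean`, `sd`, `sem`.
#' @export
summarize_groups <- function(x) {
  stopifnot(is.data.frame(x))
  mcol <- intersect(c("protein", "index"), names(x))[1]
  if (is.na(mcol)) stop("expected a `protein` or `index` column")
  if (!all(c("group", "value") %in% names(x))) {
    stop("expected `group` and `value` columns")
  }
  key <- paste(x$group, x[[mcol]], sep = "\r")
  n <- tapply(x$value, key, length)
  if (any(n < 2L)) {
    bad <- unique(gsub("\r", " / ", names(n)[n < 2L]))
    stop("fewer than 2 animals for group / measure: ",
         paste(bad, collapse = "; "))
  }
  mu <- tapply(x$value, key, mean)
  sd <- tapply(x$value, key, stats::sd)
  parts <- do.call(rbind, strsplit(names(mu), "\r", fixed = TRUE))
  out <- data.frame(group = parts[, 1], measure = parts[, 2],
                    n = as.integer(n), mean = as.numeric(mu),
                    sd = as.numeric(sd),
                    sem = as.numeric(sd) / sqrt(as.numeric(n)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$measure, out$group), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Loading-control quality check
#'
#' Verifies that the loading-control protein (e.g. GAPDH) shows no
#' significant group difference from the reference group, using the same
#' Monte-Carlo comparison procedure as the main analysis. The check passes
#' iff no comparison is significant at the configured alpha.
#'
#' @param table a raw `band_table` (normalized internally) or an existing
#'   `normalized_table`.
#' @param control_protein name of the loading-control protein.
#' @param reference_group reference group name.
#' @param config an [mc_config()]; its `alpha` is the QC level and its seed
#'   makes the check reproducible.
#' @param ... passed to [normalize_blots()] when `table` is a raw band table.
#' @return a list of class `qc_report`: `pass` (logical), `comparisons`
#'   (a `comparison_matrix` row per group vs reference; empty when only the
#'   reference group is present), `control_protein`, `alpha`.
#' @export
loading_control_qc <- function(table, control_protein = "GAPDH",
                               reference_group = "normal",
                               config = mc_config(), ...) {
  if (!inherits(table, "normalized_table")) {
    animals <- unique(table$animal_id[table$group != "control"])
    has_ctrl <- unique(table$animal_id[table$protein == control_protein])
    missing <- setdiff(animals, has_ctrl)
    if (length(missing) > 0L) {
      stop("control protein '", control_protein, "' missing for animal(s): ",
           paste(missing, collapse = ", "))
    }
    table <- normalize_blots(table, reference_group = reference_group, ...)
  }
  sub <- table[table$protein == control_protein, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("control protein '", control_protein, "' absent from the table")
  }
  gs <- summarize_groups(sub)
  others <- setdiff(gs$group, reference_group)
  if (length(others) == 0L) {
    cmp <- NULL
    pass <- TRUE
  } else {
    if (!is.null(config$seed)) set.seed(config$seed)
    cfg <- config; cfg$seed <- NULL
    ref <- gs[gs$group == reference_group, ]
    cmp <- do.call(rbind, lapply(others, function(g) {
      compare_groups(ref, gs[gs$group == g, ], cfg)
    }))
    pass <- !any(cmp$significant)
  }
  structure(list(pass = pass, comparisons = cmp,
                 control_protein = control_protein,
                 alpha = config$alpha),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Loading-control QC (", x$control_protein, "), alpha = ", x$alpha,
      ": ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  if (!is.null(x$comparisons)) {
    print(x$comparisons[, c("reference", "comparator", "observed",
                            "ci_low", "ci_high", "significant")], ...)
  }
  invisible(x)
}
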