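#' Construct a synthetic study design
#'
#' A `synthetic_design` holds everything needed to forward-simulate a
#' Western-blot band table: the group structure (animals per group), the
#' protein panel (including a designated loading-control protein), true mean
#' expression per group x protein as fold-of-reference, true between-animal
#' SDs on the same scale, and the nuisance structure of the measurement
#' process (multiplicative blot-batch factors shared by all lanes of a blot,
#' and per-lane loading factors).
#'
#' The reference group has true mean 1 for every protein by construction, and
#' the loading-control protein has true mean 1 in every group (a loading
#' control is, by definition, condition-invariant).
#'
#' @param groups named integer vector: animals per group. Every count must be
#'   at least 2. The first group is taken as the reference unless
#'   `reference_group` says otherwise.
#' @param proteins character vector of protein names, including
#'   `loading_control`.
#' @param loading_control name of the loading-control protein.
#' @param reference_group name of the reference (untreated/normal) group.
#' @param effect groups x proteins matrix of true mean expression as
#'   fold-of-reference (dimensionless, all > 0). Defaults to all 1.
#' @param noise_sd groups x proteins matrix of true between-animal SDs on the
#'   fold-of-reference scale (all >= 0). Defaults to 0.10 everywhere.
#' @param n_blots number of blots the animals are spread across.
#' @param blot_sets integer vector of length `n_blots` assigning each blot to
#'   a blot set (blots "run at the same time"). Defaults to pairs.
#' @param batch_sd SD (log scale) of the multiplicative log-normal blot-batch
#'   factor, median 1.
#' @param loading_sd SD (log scale) of the multiplicative log-normal per-lane
#'   loading factor, median 1.
#' @param protein_scale named numeric vector of per-protein baseline raw
#'   intensities (antibody gain). Defaults to 1 for every protein, so that in
#'   the zero-noise case raw densities equal the design's true means.
#' @param replicates blot replicates per animal x protein (re-runs of the
#'   whole blot layout with fresh batch/loading factors).
#' @param seed integer RNG seed stored with the design.
#' @return an object of class `synthetic_design`.
#' @seealso [default_design()], [generate_table()]
#' @export
synthetic_design <- function(groups,
                             proteins,
                             loading_control,
                             reference_group = names(groups)[1],
                             effect = NULL,
                             noise_sd = NULL,
                             n_blots = 2L,
                             blot_sets = NULL,
                             batch_sd = 0.2,
                             loading_sd = 0.05,
                             protein_scale = NULL,
                             replicates = 1L,
                             seed = 1L) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a named vector of animal counts")
  }
  groups <- vapply(groups, as.integer, integer(1))
  if (any(groups < 2L)) {
    stop("every group must have at least 2 animals; offending: ",
         paste(names(groups)[groups < 2L], collapse = ", "))
  }
  proteins <- as.character(proteins)
  if (anyDuplicated(proteins)) stop("duplicated protein names")
  if (!loading_control %in% proteins) {
    stop("loading control '", loading_control, "' is not in the protein panel")
  }
  if (!reference_group %in% names(groups)) {
    stop("reference group '", reference_group, "' is not in `groups`")
  }

  blank <- function(fill) {
    matrix(fill, nrow = length(groups), ncol = length(proteins),
           dimnames = list(names(groups), proteins))
  }
  if (is.null(effect)) effect <- blank(1)
  if (is.null(noise_sd)) noise_sd <- blank(0.10)
  effect <- effect[names(groups), proteins, drop = FALSE]
  noise_sd <- noise_sd[names(groups), proteins, drop = FALSE]
  if (any(effect <= 0)) stop("all true means must be > 0")
  if (any(noise_sd < 0)) stop("all SDs must be >= 0")
  if (any(effect[reference_group, ] != 1)) {
    stop("the reference group must have effect 1.0 for every protein")
  }
  if (any(effect[, loading_control] != 1)) {
    stop("the loading-control protein must have effect 1.0 in every group")
  }
  if (batch_sd < 0 || loading_sd < 0) stop("batch_sd and loading_sd must be >= 0")

  n_blots <- as.integer(n_blots)
  if (n_blots < 1L) stop("need at least one blot")
  if (is.null(blot_sets)) blot_sets <- (seq_len(n_blots) + 1L) %/% 2L
  if (length(blot_sets) != n_blots) stop("`blot_sets` must have one entry per blot")
  if (is.null(protein_scale)) {
    protein_scale <- stats::setNames(rep(1, length(proteins)), proteins)
  }
  if (!all(proteins %in% names(protein_scale)) || any(protein_scale <= 0)) {
    stop("`protein_scale` must give a positive scale for every protein")
  }

  structure(
    list(groups = groups, proteins = proteins,
         loading_control = loading_control,
         reference_group = reference_group,
         effect = effect, noise_sd = noise_sd,
         n_blots = n_blots, blot_sets = as.integer(blot_sets),
         batch_sd = batch_sd, loading_sd = loading_sd,
         protein_scale = protein_scale[proteins],
         replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "synthetic_design")
}

#' Default four-group synaptic-protein design
#'
#' The default design emulates a four-group study of visual-cortex synaptic
#' proteins: normally reared adults (n = 6), one month of fluoxetine (n = 8),
#' one week of monocular deprivation (MD, n = 6), and fluoxetine combined with
#' MD (n = 8). The panel holds 12 synaptic proteins plus GAPDH as loading
#' control. True group means are fold-of-normal effects taken from the printed
#' percent changes of the study this design emulates (proteins without a
#' reported significant change default to 1.0), and between-animal SDs are
#' reconstructed from the printed SEMs as SD = SEM x sqrt(n). Where no SEM is
#' printed the SD defaults to a conservative 0.10.
#'
#' @param seed RNG seed stored with the design.
#' @param ... further arguments passed to [synthetic_design()] (e.g.
#'   `batch_sd`, `loading_sd`, `n_blots`).
#' @return a `synthetic_design` for 28 animals, 13 proteins, 4 blots in 2 sets.
#' @examples
#' d <- default_design()
#' d$effect["fluoxetine", "VGLUT1"]   # 0.71
#' d$noise_sd["MD", "VGLUT1"]         # 0.084 * sqrt(6)
#' @export
default_design <- function(seed = 1L, ...) {
  groups <- c(normal = 6L, fluoxetine = 8L, MD = 6L, fluoxetine_MD = 8L)
  proteins <- c("synapsin", "synaptophysin", "VGLUT1", "VGAT",
                "PSD95", "gephyrin",
                "GluN1", "GluA2", "GluN2B", "GluN2A",
                "GABAAa1", "GABAAa3", "GAPDH")
  effect <- matrix(1, length(groups), length(proteins),
                   dimnames = list(names(groups), proteins))
  noise <- matrix(0.10, length(groups), length(proteins),
                  dimnames = list(names(groups), proteins))
  set_cell <- function(group, protein, pct_change, sem) {
    effect[group, protein] <<- 1 + pct_change
    noise[group, protein] <<- sem * sqrt(groups[[group]])
  }
  # fluoxetine alone
  set_cell("fluoxetine", "VGLUT1",  -0.29, 0.030)
  set_cell("fluoxetine", "GluN1",   -0.15, 0.048)
  set_cell("fluoxetine", "GluN2B",  -0.28, 0.045)
  set_cell("fluoxetine", "GABAAa1", +0.24, 0.110)
  # MD alone
  set_cell("MD", "synaptophysin", -0.13, 0.041)
  set_cell("MD", "VGLUT1",        +0.25, 0.084)
  set_cell("MD", "PSD95",         -0.37, 0.056)
  set_cell("MD", "gephyrin",      -0.45, 0.040)
  set_cell("MD", "GluN1",         +0.25, 0.088)
  set_cell("MD", "GluA2",         +0.18, 0.059)
  set_cell("MD", "GABAAa3",       +0.18, 0.066)
  # fluoxetine + MD
  set_cell("fluoxetine_MD", "VGLUT1",  -0.13, 0.049)
  set_cell("fluoxetine_MD", "PSD95",   +0.46, 0.150)
  set_cell("fluoxetine_MD", "gephyrin",+0.34, 0.110)
  set_cell("fluoxetine_MD", "GluN1",   -0.18, 0.045)
  set_cell("fluoxetine_MD", "GluA2",   -0.15, 0.042)
  set_cell("fluoxetine_MD", "GluN2B",  -0.21, 0.040)
  set_cell("fluoxetine_MD", "GABAAa1", +0.24, 0.200)

  synthetic_design(groups = groups, proteins = proteins,
                   loading_control = "GAPDH", reference_group = "normal",
                   effect = effect, noise_sd = noise,
                   n_blots = 4L, blot_sets = c(1L, 1L, 2L, 2L),
                   seed = seed, ...)
}

# normal draws with mean `mean` and sd `sd`, resampled until strictly positive
rtrunc_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal resampling did not converge")
  }
  x
}

#' Generate a synthetic band table from a design
#'
#' Forward model of the measurement process: the raw density of animal `a`,
#' protein `p` is
#' `scale(p) * true_mean(group(a), p) * animal_effect(a, p) * batch(blot(a)) * loading(lane(a))`
#' where `animal_effect` is normal with mean 1 and SD `noise_sd / true_mean`,
#' truncated to be strictly positive by resampling, and batch/loading factors
#' are log-normal with median 1. Each blot additionally carries one pooled
#' control-sample lane whose expected level is the panel average for each
#' protein; it shares the blot's batch factor and has its own loading factor.
#'
#' Animals are dealt round-robin across blots so that groups are balanced
#' within each blot. The output is reproducible bit-for-bit for a fixed seed.
#'
#' @param design a [synthetic_design()].
#' @param seed RNG seed; defaults to the seed stored in the design.
#' @return a `band_table`: a data frame with columns `blot_id`, `lane_id`,
#'   `animal_id`, `group`, `protein`, `raw_density` (control-sample rows carry
#'   group `"control"`), with the generating design attached as attribute
#'   `"design"` and blot-set / control-lane maps as attributes.
#' @export
generate_table <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(seed)

  groups <- design$groups
  animals <- unlist(lapply(names(groups), function(g) {
    paste(g, seq_len(groups[[g]]), sep = "_")
  }), use.names = FALSE)
  animal_group <- rep(names(groups), groups)
  n_animals <- length(animals)

  # round-robin deal over blots: balances groups across blots
  blot_of_animal <- ((seq_len(n_animals) - 1L) %% design$n_blots) + 1L

  reps <- design$replicates
  blot_ids <- if (reps == 1L) {
    paste0("B", seq_len(design$n_blots))
  } else {
    as.vector(outer(paste0("B", seq_len(design$n_blots)),
                    paste0(".", seq_len(reps)), paste0))
  }
  # physical blots: n_blots per replicate, same lane layout each time
  n_phys <- design$n_blots * reps
  phys_base <- rep(seq_len(design$n_blots), times = reps)

  batch <- exp(stats::rnorm(n_phys, 0, design$batch_sd))

  # lane layout per base blot: lane 1 = pooled control sample, then animals
  lanes_per_blot <- lapply(seq_len(design$n_blots), function(b) {
    which(blot_of_animal == b)
  })
  n_lanes <- vapply(lanes_per_blot, length, integer(1)) + 1L
  loading <- lapply(seq_len(n_phys), function(k) {
    exp(stats::rnorm(n_lanes[phys_base[k]], 0, design$loading_sd))
  })

  # biological animal effect, shared across blot replicates
  eff <- design$effect[animal_group, , drop = FALSE]
  sdrel <- design$noise_sd[animal_group, , drop = FALSE] / eff
  animal_effect <- matrix(
    rtrunc_pos(length(eff), rep(1, length(eff)), as.vector(sdrel)),
    nrow = n_animals,
    dimnames = list(animals, design$proteins))

  panel_mean <- colMeans(design$effect[animal_group, , drop = FALSE])

  out <- vector("list", n_phys * length(design$proteins))
  k <- 0L
  for (ph in seq_len(n_phys)) {
    b <- phys_base[ph]
    idx <- lanes_per_blot[[b]]
    lane_ids <- sprintf("L%02d", seq_len(n_lanes[b]))
    for (p in design$proteins) {
      scale_p <- design$protein_scale[[p]]
      ctrl <- scale_p * panel_mean[[p]] * batch[ph] * loading[[ph]][1]
      dens <- scale_p * design$effect[cbind(animal_group[idx], p)] *
        animal_effect[idx, p] * batch[ph] * loading[[ph]][-1]
      k <- k + 1L
      out[[k]] <- data.frame(
        blot_id = blot_ids[ph],
        lane_id = lane_ids,
        animal_id = c(paste0("control_", blot_ids[ph]), animals[idx]),
        group = c("control", animal_group[idx]),
        protein = p,
        raw_density = c(ctrl, dens),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  stopifnot(all(tab$raw_density > 0))

  attr(tab, "design") <- design
  attr(tab, "blot_sets") <- stats::setNames(
    rep(design$blot_sets, times = reps), blot_ids)
  attr(tab, "control_lanes") <- stats::setNames(
    rep("L01", n_phys), blot_ids)
  class(tab) <- c("band_table", "data.frame")
  tab
}
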