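#' Contrast index of two non-negative quantities
#'
#' The contrast index `(a - b) / (a + b)` is a bounded balance statistic
#' borrowed from signal processing: 0 means perfect balance, +1 all `a`,
#' -1 all `b`. It is antisymmetric in its arguments, invariant to a common
#' positive scale, and strictly increasing in `a` for fixed `b > 0`.
#'
#' @param a,b non-negative expression values (vectorized; recycled).
#' @return values in `[-1, 1]`.
#' @examples
#' contrast_index(1, 1)        # 0
#' contrast_index(1, 0)        # 1
#' contrast_index(1.25, 0.75)  # 0.25
#' @export
contrast_index <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("contrast index requires non-negative inputs")
  if (any(a + b == 0)) stop("a + b = 0: balance undefined")
  (a - b) / (a + b)
}

#' Default receptor-subunit and E/I balance definitions
#'
#' The five contrast indices of the default panel, each defined by an
#' (A, B) protein pair:
#' \describe{
#'   \item{AMPAR_NMDAR}{(GluA2 - GluN1) / (GluA2 + GluN1)}
#'   \item{NMDAR_2A_2B}{(GluN2A - GluN2B) / (GluN2A + GluN2B)}
#'   \item{GABAAR_a1_a3}{(GABAAa1 - GABAAa3) / (GABAAa1 + GABAAa3)}
#'   \item{presynaptic_EI}{(VGLUT1 - VGAT) / (VGLUT1 + VGAT)}
#'   \item{postsynaptic_EI}{(PSD95 - gephyrin) / (PSD95 + gephyrin)}
#' }
#' @return named list of length-2 character vectors `c(A, B)`.
#' @export
default_index_definitions <- function() {
  list(AMPAR_NMDAR = c("GluA2", "GluN1"),
       NMDAR_2A_2B = c("GluN2A", "GluN2B"),
       GABAAR_a1_a3 = c("GABAAa1", "GABAAa3"),
       presynaptic_EI = c("VGLUT1", "VGAT"),
       postsynaptic_EI = c("PSD95", "gephyrin"))
}

#' Compute contrast indices per animal
#'
#' Indices are computed within animal — pairing protein A and protein B from
#' the same animal — so that groups of index values retain per-animal
#' dispersion and can feed the same summary and comparison machinery as the
#' proteins themselves. If an animal has several values per protein (blot
#' replicates), they are averaged first.
#'
#' @param table a `normalized_table` (see [normalize_blots()]).
#' @param definitions named list of `c(protein_A, protein_B)` pairs; defaults
#'   to [default_index_definitions()].
#' @return an `index_table` data frame with columns `animal_id`, `group`,
#'   `index`, `value`.
#' @export
compute_indices <- function(table, definitions = default_index_definitions()) {
  stopifnot(is.data.frame(table),
            all(c("animal_id", "group", "protein", "value") %in% names(table)))
  if (length(definitions) == 0L) stop("no index definitions given")

  key <- paste(table$animal_id, table$protein, sep = "\r")
  val <- tapply(table$value, key, mean)
  animals <- unique(table[, c("animal_id", "group")])

  out <- vector("list", length(definitions))
  for (i in seq_along(definitions)) {
    def <- definitions[[i]]
    nm <- names(definitions)[i]
    if (length(def) != 2L) stop("index '", nm, "' must name exactly 2 proteins")
    a <- val[paste(animals$animal_id, def[1], sep = "\r")]
    b <- val[paste(animals$animal_id, def[2], sep = "\r")]
    bad <- animals$animal_id[is.na(a) | is.na(b)]
    if (length(bad) > 0L) {
      stop("index '", nm, "': missing ", def[1], " or ", def[2],
           " for animal(s): ", paste(bad, collapse = ", "))
    }
    out[[i]] <- data.frame(animal_id = animals$animal_id,
                           group = animals$group,
                           index = nm,
                           value = contrast_index(as.numeric(a), as.numeric(b)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$index, res$group, res$animal_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("index_table", "data.frame")
  res
}
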