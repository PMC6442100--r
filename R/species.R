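#' Bead species table for the GMO / ethanol / water / metformin system
#'
#' The mesoscale model uses five bead species. One glyceryl-monooleate (GMO)
#' molecule is split into a hydrophilic head bead `A` (glycerol backbone plus
#' ester carboxyl) and a hydrophobic tail bead `B` (the oleoyl hydrocarbon
#' chain), bonded as a dimer. Water, ethanol and metformin hydrochloride
#' (`MET`) are single-bead species; a water bead lumps `water_per_bead`
#' molecules together, the usual degree of coarse-graining for aqueous DPD.
#'
#' @param water_per_bead Number of water molecules represented by one water
#'   bead (default 3).
#' @return A data frame with columns `id`, `molar_mass` (g/mol per molecule),
#'   `hbonding` (can the species hydrogen-bond) and `molecules_per_bead`.
#' @examples
#' species_table()
#' @export
species_table <- function(water_per_bead = 3) {
  stopifnot(water_per_bead >= 1)
  data.frame(
    id = c("A", "B", "WATER", "ETHANOL", "MET"),
    molar_mass = c(119.1, 237.4, 18.02, 46.07, 165.6),
    hbonding = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    molecules_per_bead = c(1, 1, water_per_bead, 1, 1),
    stringsAsFactors = FALSE
  )
}

.species_ids <- c("A", "B", "WATER", "ETHANOL", "MET")

#' Define a formulation by mass parts
#'
#' A formulation is a named composition in mass parts of the four components:
#' GMO (split into A + B beads at simulation time), ethanol, water and
#' metformin hydrochloride.
#'
#' @param name Formulation label, e.g. `"F4"`.
#' @param gmo,ethanol,water,met Mass parts (w/w/w/w) of each component.
#' @return An object of class `formulation`.
#' @examples
#' formulation("F4", gmo = 64, ethanol = 6, water = 30, met = 5)
#' @export
formulation <- function(name, gmo, ethanol, water, met) {
  parts <- c(gmo = gmo, ethanol = ethanol, water = water, met = met)
  if (any(!is.finite(parts)) || any(parts < 0))
    stop("mass parts must be finite and non-negative")
  if (gmo + water <= 0) stop("formulation needs a positive GMO + water content")
  if (sum(parts) <= 0) stop("total mass must be positive")
  structure(list(name = as.character(name), mass_parts = parts),
            class = "formulation")
}

#' @export
print.formulation <- function(x, ...) {
  cat(sprintf("<formulation %s> GMO/ethanol/water/Met = %s (w/w/w/w)\n",
              x$name, paste(x$mass_parts, collapse = "/")))
  invisible(x)
}

#' Read a formulation table from delimited text
#'
#' Expects columns `name`, `gmo`, `ethanol`, `water`, `met` (mass parts).
#'
#' @param path File path.
#' @param sep Field separator (default `","`).
#' @return A list of [formulation()] objects.
#' @export
read_formulation_table <- function(path, sep = ",") {
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("name", "gmo", "ethanol", "water", "met")
  if (!all(need %in% names(df)))
    stop("formulation table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    formulation(df$name[i], df$gmo[i], df$ethanol[i], df$water[i], df$met[i]))
}

#' Write a formulation table to delimited text
#'
#' @param formulations List of [formulation()] objects.
#' @param path File path.
#' @param sep Field separator (default `","`).
#' @export
write_formulation_table <- function(formulations, path, sep = ",") {
  df <- do.call(rbind, lapply(formulations, function(f)
    data.frame(name = f$name, gmo = f$mass_parts[["gmo"]],
               ethanol = f$mass_parts[["ethanol"]],
               water = f$mass_parts[["water"]], met = f$mass_parts[["met"]])))
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
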