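#' Construct a Flory-Huggins interaction matrix
#'
#' @param chi Symmetric numeric matrix with dimnames drawn from the species
#'   ids `A`, `B`, `WATER`, `ETHANOL`, `MET`; diagonal must be exactly zero.
#' @param temperature Temperature in Kelvin the parameters refer to.
#' @param provenance Optional character matrix of the same shape marking each
#'   entry's origin (e.g. `"printed"` vs `"default"`).
#' @return An object of class `chi_matrix`.
#' @export
chi_matrix <- function(chi, temperature = 298, provenance = NULL) {
  if (!is.matrix(chi) || nrow(chi) != ncol(chi))
    stop("chi must be a square matrix")
  ids <- rownames(chi)
  if (is.null(ids) || !identical(ids, colnames(chi)))
    stop("chi must have matching row/column species names")
  if (!all(ids %in% .species_ids))
    stop("unknown species: ", paste(setdiff(ids, .species_ids), collapse = ", "))
  if (any(!is.finite(chi))) stop("chi entries must be finite")
  if (any(abs(chi - t(chi)) > 1e-9)) stop("chi must be symmetric")
  if (any(diag(chi) != 0)) stop("chi diagonal must be exactly zero")
  chi <- (chi + t(chi)) / 2   # symmetrize exactly
  diag(chi) <- 0
  structure(list(chi = chi, temperature = temperature,
                 provenance = provenance),
            class = "chi_matrix")
}

#' @export
print.chi_matrix <- function(x, ...) {
  cat(sprintf("<chi_matrix> %d species at %g K\n", nrow(x$chi), x$temperature))
  print(round(x$chi, 3))
  invisible(x)
}

#' Default Flory-Huggins matrix for the Met/GMO/ethanol/water system
#'
#' Three pairs carry the values estimated for this system by atomistic
#' simulation: chi(B, WATER) = 5.1 (the oleoyl tail is strongly hydrophobic),
#' chi(B, ETHANOL) = 0.5 (weakly miscible) and chi(WATER, A) = -1.1 (the
#' glycerol head is attracted to water). The remaining pairs are shipped,
#' overridable defaults chosen to respect the qualitative picture: ethanol is
#' miscible with water, metformin and the A head; the B tail repels the polar
#' species; A and B are moderately incompatible (they segregate into head and
#' tail regions of the bilayer). The `provenance` matrix marks which entries
#' are estimated values (`"printed"`) and which are shipped defaults
#' (`"default"`).
#'
#' @param overrides Named list of pair overrides, names like `"A:ETHANOL"`
#'   (order irrelevant), values the chi to use.
#' @param temperature Temperature in Kelvin (default 298).
#' @return A [chi_matrix()].
#' @examples
#' chm <- default_chi_matrix()
#' chm$chi["B", "WATER"]    # 5.1
#' @export
default_chi_matrix <- function(overrides = NULL, temperature = 298) {
  ids <- .species_ids
  chi <- matrix(0, 5, 5, dimnames = list(ids, ids))
  prov <- matrix("zero", 5, 5, dimnames = list(ids, ids))
  set <- function(i, j, v, p) {
    chi[i, j] <<- v; chi[j, i] <<- v
    prov[i, j] <<- p; prov[j, i] <<- p
  }
  # estimated for this system (atomistic-simulation values)
  set("B", "WATER", 5.1, "printed")
  set("B", "ETHANOL", 0.5, "printed")
  set("WATER", "A", -1.1, "printed")
  # shipped defaults for pairs without an estimated value
  set("WATER", "ETHANOL", -0.3, "default")
  set("ETHANOL", "MET", -0.5, "default")
  set("WATER", "MET", -0.5, "default")
  set("A", "ETHANOL", -0.2, "default")
  set("A", "MET", -0.3, "default")
  set("A", "B", 2.0, "default")
  set("B", "MET", 4.0, "default")
  if (!is.null(overrides)) {
    for (key in names(overrides)) {
      pair <- strsplit(key, ":", fixed = TRUE)[[1]]
      if (length(pair) != 2 || !all(pair %in% ids))
        stop("override key must be '<species>:<species>', got: ", key)
      set(pair[1], pair[2], overrides[[key]], "override")
    }
  }
  chi_matrix(chi, temperature = temperature, provenance = prov)
}

#' Estimate a Flory-Huggins parameter from Hildebrand solubility parameters
#'
#' Uses the standard regular-solution route
#' \eqn{\chi = v_{ref} (\delta_i - \delta_j)^2 / (RT)}. Being a squared
#' difference this is non-negative by construction, so it cannot reproduce
#' negative chi values arising from hydrogen bonding; a warning is issued
#' when either species can hydrogen-bond.
#'
#' @param input List with `delta` (named vector of solubility parameters,
#'   (J/cm^3)^0.5), `v_ref` (reference molar volume, cm^3/mol) and
#'   `temperature` (K, default 298).
#' @param pair Character vector of the two species ids.
#' @return Dimensionless chi (non-negative).
#' @examples
#' inp <- list(delta = c(WATER = 47.8, B = 26.5), v_ref = 18, temperature = 298)
#' chi_from_solubility(inp, c("WATER", "B"))   # 3.30
#' @export
chi_from_solubility <- function(input, pair) {
  stopifnot(length(pair) == 2)
  delta <- input$delta
  missing <- setdiff(pair, names(delta))
  if (length(missing))
    stop("species not in solubility input: ", paste(missing, collapse = ", "))
  v_ref <- input$v_ref
  temperature <- input$temperature %||% 298
  if (any(delta[pair] < 0)) stop("solubility parameters must be non-negative")
  if (v_ref <= 0) stop("v_ref must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  sp <- species_table()
  hb <- sp$hbonding[match(pair, sp$id)]
  if (any(hb, na.rm = TRUE))
    warning("regular-solution route cannot produce negative chi for ",
            "hydrogen-bonding pairs; treat the result as an upper-bound guess")
  R <- 8.314  # J/(mol K)
  unname(v_ref * (delta[pair[1]] - delta[pair[2]])^2 / (R * temperature))
}

#' Map a Flory-Huggins matrix to DPD repulsion parameters
#'
#' The conservative repulsion between unlike beads follows the linear
#' Groot-Warren mapping \eqn{a_{ij} = a_{ii} + k(\rho)\,\chi_{ij}} with
#' k = 3.27 at bead density rho = 3. For any other density the coefficient
#' must be supplied explicitly.
#'
#' @param chi A [chi_matrix()].
#' @param a_ii Like-bead repulsion (kT/r_c), default 25.
#' @param rho Bead number density (r_c^-3), default 3.
#' @param k Mapping coefficient; defaults to 3.27 when `rho == 3`, otherwise
#'   required.
#' @return Symmetric repulsion matrix (kT/r_c) with `a_ii` on the diagonal.
#' @examples
#' a <- chi_to_repulsion(default_chi_matrix())
#' a["B", "WATER"]   # 25 + 3.27 * 5.1 = 41.68
#' @export
chi_to_repulsion <- function(chi, a_ii = 25, rho = 3, k = NULL) {
  stopifnot(inherits(chi, "chi_matrix"))
  if (a_ii <= 0) stop("a_ii must be positive")
  if (rho <= 0) stop("rho must be positive")
  if (is.null(k)) {
    if (rho != 3)
      stop("no chi -> repulsion coefficient is known for rho != 3; ",
           "supply k explicitly")
    k <- 3.27
  }
  a <- a_ii + k * chi$chi
  diag(a) <- a_ii
  a
}

#' Read a chi matrix from delimited text
#'
#' Expects a header row and first column of species ids and a symmetric
#' numeric body; symmetry is validated to 1e-9.
#'
#' @param path File path.
#' @param sep Field separator (default `","`).
#' @param temperature Temperature in Kelvin to record (default 298).
#' @return A [chi_matrix()].
#' @export
read_chi_matrix <- function(path, sep = ",", temperature = 298) {
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE)
  m <- as.matrix(df)
  chi_matrix(m, temperature = temperature)
}

#' Write a chi matrix to delimited text
#'
#' @param chi A [chi_matrix()].
#' @param path File path.
#' @param sep Field separator (default `","`).
#' @export
write_chi_matrix <- function(chi, path, sep = ",") {
  stopifnot(inherits(chi, "chi_matrix"))
  df <- data.frame(species = rownames(chi$chi), chi$chi, check.names = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
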