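#' Dimensionless free-energy parameters for aggregation models
#'
#' Collects every free energy used by the filament, strip, cube and
#' lattice-gas models, all in units of RT, together with the derived
#' Boltzmann weights.  The coil conformation and the empty (solvent) site are
#' the reference states with weight one, so any interaction left at its
#' default of 0 RT simply drops out of the model.
#'
#' @param R1,R2,R3 Interfacial free energies (RT) for helix-coil, sheet-coil
#'   and helix-sheet interfaces between neighbouring proteins along the
#'   propagation axis.  The associated initiation parameters are
#'   `sigma_i = exp(-2 R_i)`; a single ordered segment with two interfaces
#'   pays the full `sigma_i`, each individual interface the square root.
#' @param P1,P2 Propagation free energies (RT) for the helix and sheet
#'   states; `s1 = exp(P1)`, `s2 = exp(P2)`.
#' @param K Polymerization free energy (RT) per nearest-neighbour protein
#'   pair on the lattice, independent of conformation; `k = exp(K)`.
#' @param B Inter-filament sheet-sheet binding free energy (RT) used by the
#'   canonical strip and cube models; `b = exp(B)`.
#' @param F Inter-filament sheet-link free energy (RT) used by the
#'   grand-canonical models; `f = exp(F)`.
#' @param A Nucleation (protein-solvent surface) free energy (RT) of the
#'   grand-canonical models; `alpha = exp(-2 A)`, with each solvent-protein
#'   boundary paying `exp(-A)`.
#'
#' @return An object of class `energy_params`: a named list holding the free
#'   energies and the derived weights `sigma1`, `sigma2`, `sigma3`, `s1`,
#'   `s2`, `k`, `b`, `f`, `alpha`.
#'
#' @examples
#' p <- energy_params(P2 = 2.7, K = 2.7, B = 1.95, R2 = -1.64)
#' p$s2          # exp(2.7)
#' p$sigma2      # exp(+3.28): favourable sheet-coil interfaces
#' @export
energy_params <- function(R1 = 0, R2 = 0, R3 = 0, P1 = 0, P2 = 0,
                          K = 0, B = 0, F = 0, A = 0) {
  fe <- c(R1 = R1, R2 = R2, R3 = R3, P1 = P1, P2 = P2,
          K = K, B = B, F = F, A = A)
  if (!all(is.finite(fe))) {
    stop("all free energies must be finite numbers", call. = FALSE)
  }
  p <- list(
    R1 = R1, R2 = R2, R3 = R3, P1 = P1, P2 = P2,
    K = K, B = B, F = F, A = A,
    sigma1 = exp(-2 * R1), sigma2 = exp(-2 * R2), sigma3 = exp(-2 * R3),
    s1 = exp(P1), s2 = exp(P2), k = exp(K), b = exp(B), f = exp(F),
    alpha = exp(-2 * A)
  )
  w <- unlist(p[c("sigma1", "sigma2", "sigma3", "s1", "s2",
                  "k", "b", "f", "alpha")])
  if (!all(is.finite(w) & w > 0)) {
    stop("derived Boltzmann weights must be strictly positive and finite ",
         "(a free energy is too large in magnitude)", call. = FALSE)
  }
  structure(p, class = "energy_params")
}

#' Rebuild an `energy_params` object with some free energies replaced
#'
#' @param params An [energy_params()] object.
#' @param ... Named free energies (RT) to override, e.g. `P2 = 3`.
#' @return A new `energy_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "energy_params"))
  repl <- list(...)
  fields <- c("R1", "R2", "R3", "P1", "P2", "K", "B", "F", "A")
  bad <- setdiff(names(repl), fields)
  if (length(bad)) {
    stop("unknown free-energy name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  args <- params[fields]
  args[names(repl)] <- repl
  do.call(energy_params, args)
}

#' @export
print.energy_params <- function(x, ...) {
  cat("<energy_params> (free energies in RT)\n")
  fe <- unlist(x[c("R1", "R2", "R3", "P1", "P2", "K", "B", "F", "A")])
  fe <- fe[fe != 0]
  if (!length(fe)) {
    cat("  all interactions at reference (0 RT)\n")
  } else {
    for (nm in names(fe)) cat(sprintf("  %-3s = %g\n", nm, fe[[nm]]))
  }
  invisible(x)
}

#' @export
as_tibble.energy_params <- function(x, ...) {
  tibble::tibble(
    term = c("R1", "R2", "R3", "P1", "P2", "K", "B", "F", "A"),
    free_energy_RT = unlist(x[c("R1", "R2", "R3", "P1", "P2",
                                "K", "B", "F", "A")], use.names = FALSE),
    weight = unlist(x[c("sigma1", "sigma2", "sigma3", "s1", "s2",
                        "k", "b", "f", "alpha")], use.names = FALSE)
  )
}

#' Published sheet-coil parameter sets
#'
#' Convenience constructors for the fitted q = 2 sheet-coil parameter sets of
#' the amyloid-beta(1-40) ensemble (filament + two-filament strip + stacked
#' "cube" fibril) and the alpha-synuclein strip ensemble (one to four
#' filaments).  The sheet interaction is stored as `P2`/`R2` (the sheet
#' propagation and sheet-coil interface slots); some sources label the same
#' single sheet interaction of a two-state model `P1`.
#'
#' @return An [energy_params()] object.
#' @name preset_params
NULL

#' @rdname preset_params
#' @export
params_abeta40 <- function() {
  energy_params(P2 = 7.41, B = 1.4, R2 = -2.47, K = 0.45)
}

#' @rdname preset_params
#' @export
params_asyn <- function() {
  energy_params(P2 = 2.7, K = 2.7, B = 1.95, R2 = -1.64)
}
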