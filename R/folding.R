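#' Zipper-model partition function
#'
#' Single-stretch ("zipper") model for the helix-coil transition: a chain of
#' `N` residues may contain at most one helical block, of any length `kk`
#' from 1 to `N`, with `N - kk + 1` placements, nucleation weight `sigma`
#' and propagation weight `s` per helical residue:
#' `Z = 1 + sum_k (N - k + 1) sigma s^k`.
#' The geometric closed form is used away from `s = 1`; at `|s - 1| < 1e-4`
#' the exact degenerate sum `1 + sigma N (N + 1) / 2 * s^..` is replaced by
#' the limit form to avoid catastrophic cancellation.
#'
#' @param N Chain length in residues (>= 1).
#' @param sigma Initiation parameter (> 0, typically << 1).
#' @param s Propagation parameter (> 0).
#' @return The partition function (>= 1).
#' @examples
#' zipper_partition(1, 0.001, 1.2)   # 1 + sigma * s
#' @export
zipper_partition <- function(N, sigma, s) {
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  stopifnot(sigma >= 0, s > 0)
  if (abs(s - 1) < 1e-4) {
    ## exact limit of the sum at s = 1 plus first-order correction
    kk <- seq_len(N)
    return(1 + sigma * sum((N - kk + 1) * s^kk))
  }
  1 + sigma * (s^(N + 2) - (N + 1) * s^2 + N * s) / (s - 1)^2
}

#' Zimm-Bragg partition function in the long-chain limit
#'
#' `lambda_1^N` with the dominant transfer-matrix eigenvalue
#' `lambda_1 = (1 + s + sqrt((s - 1)^2 + 4 s sigma)) / 2`.
#'
#' @inheritParams zipper_partition
#' @export
zb_partition_thermolimit <- function(N, sigma, s) {
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  zb_lambda1(sigma, s)^N
}

#' Dominant eigenvalue of the 2x2 helix-coil transfer matrix
#' @inheritParams zipper_partition
#' @export
zb_lambda1 <- function(sigma, s) {
  (1 + s + sqrt((s - 1)^2 + 4 * s * sigma)) / 2
}

#' Closed-form helicity in the thermodynamic limit
#'
#' `theta = 1/2 + (s - 1) / (2 sqrt((s - 1)^2 + 4 sigma s))`: the fraction
#' of helical residues, 1/2 at the transition midpoint `s = 1` for every
#' `sigma`, and reducing to `s / (s + 1)` at `sigma = 1` (independent
#' residues).
#'
#' @inheritParams zipper_partition
#' @export
helicity_closed <- function(sigma, s) {
  stopifnot(sigma > 0, s > 0)
  1 / 2 + (s - 1) / (2 * sqrt((s - 1)^2 + 4 * sigma * s))
}

#' Closed-form mean helical segment length in the thermodynamic limit
#'
#' `L = 1 + 2 s / (1 - s + sqrt((1 - s)^2 + 4 sigma s))`; equals
#' `1 + 1/sqrt(sigma)` at `s = 1` and diverges as `sigma -> 0` for `s > 1`
#' (all-or-none transition).
#'
#' @inheritParams zipper_partition
#' @export
mean_helix_length_closed <- function(sigma, s) {
  stopifnot(sigma > 0, s > 0)
  1 + 2 * s / (1 - s + sqrt((1 - s)^2 + 4 * sigma * s))
}

## The classic one-directional helix-coil transfer matrix (rows = previous
## residue, cols = current): cc 1, ch sigma*s, hc 1, hh s.  A first helical
## residue nucleates, so the initial vector carries sigma*s on h.
.folding_tm <- function(sigma, s) {
  matrix(c(1, 1, sigma * s, s), 2L, 2L)  # columns: to-coil, to-helix
}

.folding_partition <- function(N, sigma, s, boundary = "free") {
  Tm <- .folding_tm(sigma, s)
  iv <- c(1, sigma * s)
  fv <- c(1, 1)
  if (identical(boundary, "coil_only")) {
    iv <- c(1, 0); fv <- c(1, 0)
  }
  v <- fv
  if (N > 1) for (step in seq_len(N - 1)) v <- Tm %*% v
  sum(iv * v)
}

#' Finite-chain helix-coil observables
#'
#' Helicity `theta`, mean number of helical segments `nu` and mean segment
#' length `L` for a finite Zimm-Bragg chain, from logarithmic derivatives of
#' the transfer-matrix partition function with respect to `s` and `sigma`.
#' The identity `L * nu = N_H * theta` holds by construction; as `N` grows
#' the values converge to [helicity_closed()] and
#' [mean_helix_length_closed()].
#'
#' @inheritParams zipper_partition
#' @param boundary `"free"` (ends may be helix or coil) or `"coil_only"`.
#' @param N_H Maximum number of helical residues (defaults to `N`).
#' @return A tibble with columns `theta`, `nu`, `L`.
#' @export
chain_averages <- function(N, sigma, s, boundary = c("free", "coil_only"),
                           N_H = N) {
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  boundary <- match.arg(boundary)
  theta <- log_derivative(function(x) .folding_partition(N, sigma, x, boundary),
                          s) / N_H
  nu <- log_derivative(function(x) .folding_partition(N, x, s, boundary),
                       sigma)
  L <- if (nu > 1e-12) N_H * theta / nu else NA_real_
  tibble::tibble(theta = theta, nu = nu, L = L)
}

#' Helix-coil transition curve
#'
#' Evaluates finite-chain observables over a grid of propagation parameters
#' for plotting or export.
#'
#' @inheritParams chain_averages
#' @param s Vector of propagation parameters.
#' @return A tibble with columns `s`, `theta`, `nu`, `L`.
#' @export
helix_coil_curve <- function(N, sigma, s, boundary = c("free", "coil_only")) {
  boundary <- match.arg(boundary)
  purrr::map_dfr(s, function(si) {
    dplyr::bind_cols(tibble::tibble(s = si),
                     chain_averages(N, sigma, si, boundary))
  })
}
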