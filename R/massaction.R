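#' Oosawa-Kasai k-mer concentration
#'
#' Linear-aggregation mass-action model: nucleation of a dimer with
#' equilibrium constant `sigma * s` and elongation by monomer addition with
#' constant `s` give the k-mer concentration
#' `n_k = sigma s^(k-1) n1^k` for `k >= 2`; the monomer is `n1` itself.
#' Concentrations are dimensionless activities relative to a declared
#' standard state.
#'
#' @param k Aggregate size (>= 1).
#' @param n1 Monomer concentration (> 0).
#' @param sigma Nucleation penalty (dimensionless).
#' @param s Elongation equilibrium constant.
#' @return The k-mer concentration.
#' @export
kmer_concentration <- function(k, n1, sigma, s) {
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  stopifnot(n1 > 0)
  ifelse(k == 1, n1, sigma * s^(k - 1) * n1^k)
}

#' Total protein mass of the aggregation equilibrium
#'
#' Sums `k * n_k` over all aggregate sizes in closed form:
#' `m_tot = n1 (1 - sigma + sigma / (1 - s n1)^2)`,
#' convergent only for `s * n1 < 1`.
#'
#' @inheritParams kmer_concentration
#' @export
total_mass <- function(n1, sigma, s) {
  stopifnot(n1 > 0, sigma >= 0, s >= 0)
  if (sigma == 0) return(n1)
  if (s * n1 >= 1) {
    stop("series diverges: need s * n1 < 1 (got s * n1 = ",
         signif(s * n1, 4), ")", call. = FALSE)
  }
  n1 * (1 - sigma + sigma / (1 - s * n1)^2)
}

#' Solve the mass balance for the free monomer concentration
#'
#' Inverts [total_mass()]: finds the unique `n1` in `(0, 1/s)` with
#' `total_mass(n1, sigma, s) = m_tot`.  The mass is strictly increasing in
#' `n1` and diverges at `1/s`, so a bracketed root always exists.
#'
#' @param m_tot Total protein concentration (> 0).
#' @param tol Relative root-finding tolerance.
#' @inheritParams kmer_concentration
#' @return The monomer concentration `n1`.
#' @examples
#' solve_monomer(2, sigma = 1, s = 1)   # 0.5
#' @export
solve_monomer <- function(m_tot, sigma, s, tol = 1e-12) {
  stopifnot(m_tot > 0, sigma >= 0, s >= 0)
  if (sigma == 0) return(m_tot)
  upper <- if (s > 0) 1 / s else Inf
  if (!is.finite(upper)) upper <- m_tot
  g <- function(x) total_mass(x, sigma, s) - m_tot
  lo <- min(m_tot, upper) * 1e-12
  hi <- min(m_tot, upper * (1 - 1e-14))
  r <- uniroot(g, lower = lo, upper = hi, tol = tol * min(m_tot, upper),
               extendInt = "no", maxiter = 1000)
  ## polish with a few Newton-free bisections via uniroot's result
  r$root
}

#' Aggregation state summary at fixed total mass
#'
#' @inheritParams solve_monomer
#' @return A tibble with `n1`, `monomer_fraction`, and the mass-weighted
#'   mean aggregate size `mean_size = m_tot / number_density`.
#' @export
mass_action_state <- function(m_tot, sigma, s) {
  n1 <- solve_monomer(m_tot, sigma, s)
  ## number density: n1 + sum_{k>=2} sigma s^(k-1) n1^k
  rho <- n1 + if (sigma > 0 && s * n1 < 1) {
    sigma * s * n1^2 / (1 - s * n1)  # sum over k >= 2 of n_k
  } else 0
  tibble::tibble(m_tot = m_tot, n1 = n1,
                 monomer_fraction = n1 / m_tot,
                 mean_size = m_tot / rho)
}
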