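#' Build the transfer matrix of a canonical aggregate model
#'
#' Constructs the column-to-column transfer matrix over composite column
#' states (tuples of per-site conformations).  The entry for the transition
#' from column state `a` to column state `b` is
#' `prod_sites exp(-R(a_i, b_i)) * prop(b) * intra(b)`:
#' one interface factor `exp(-R)` per site whose conformation differs from
#' its left neighbour, the per-site propagation weights of the entered
#' column, and its intra-column sheet-sheet couplings `b`.  The
#' conformation-independent polymerization weight `k` is a global prefactor
#' (one factor per lattice bond) applied by the partition functions, not a
#' matrix entry.
#'
#' For `q = 2`, `Ly = 1` the matrix is 2x2 with characteristic polynomial
#' `lambda^2 - (1 + s) lambda + s (1 - sigma) = 0`, the classic helix-coil
#' form; for a `q = 2` strip at `B = 0` it is the Kronecker product of
#' filament matrices.
#'
#' @param spec A [lattice_spec()].
#' @param params An [energy_params()].
#' @return An object of class `transfer_matrix`: list with `entries` (square
#'   nonnegative matrix), `state_labels`, `states` (integer code matrix),
#'   `spec`, `params`, and the per-state `prop` and `intra` weight vectors.
#' @examples
#' tm <- build_transfer_matrix(lattice_spec("filament"), energy_params())
#' tm$entries          # all-ones 2x2 in the non-interacting limit
#' @export
build_transfer_matrix <- function(spec, params) {
  stopifnot(inherits(spec, "lattice_spec"), inherits(params, "energy_params"))
  states <- .col_states(spec)
  n <- nrow(states)
  u <- .interface_weights(params)
  W <- matrix(1, n, n)
  for (a in seq_len(ncol(states))) {
    W <- W * u[cbind(rep(states[, a] + 1L, times = n),
                     rep(states[, a] + 1L, each = n))]
  }
  ## W[i, j] built column-major: rows = old state, cols = new state
  W <- matrix(W, n, n)
  prop <- .column_prop(states, params)
  intra <- .column_intra(states, spec, params)
  entries <- W * rep(prop * intra, each = n)
  structure(list(entries = entries, state_labels = .state_labels(states),
                 states = states, spec = spec, params = params,
                 prop = prop, intra = intra),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("<transfer_matrix> %d x %d (%s, q=%d)\n",
              nrow(x$entries), ncol(x$entries), x$spec$geometry, x$spec$q))
  m <- x$entries
  dimnames(m) <- list(x$state_labels, x$state_labels)
  print(signif(m, 4), ...)
  invisible(x)
}

## End vectors for a boundary kind: |i> carries each allowed initial
## column's intrinsic weight (propagation x intra-column couplings), <f| is
## the indicator of allowed final columns.  With bond-placed propagation
## (one P factor per x-neighbour pair, the Potts-Hamiltonian reading) the
## final column's propagation weight is divided back out, so a one-column
## aggregate carries only its intra-column couplings.
.end_vectors <- function(tm, boundary, prop = c("site", "bond")) {
  prop <- match.arg(prop)
  mask <- .boundary_mask(tm$states, boundary)
  if (!any(mask)) stop("boundary admits no column states", call. = FALSE)
  list(i = ifelse(mask, tm$prop * tm$intra, 0),
       f = if (prop == "site") as.numeric(mask)
           else ifelse(mask, 1 / tm$prop, 0))
}

#' Open-chain partition function of an aggregate of `Lx` columns
#'
#' Computes `<i| T^(Lx-1) |f>` times the polymerization prefactor
#' `k^(bonds)`, where `bonds = g Lx - Ly Lz` counts every nearest-neighbour
#' protein pair of the open lattice (`g` bonds per column in the bulk).
#' The initial vector carries the first column's intrinsic weights so that
#' every column contributes its propagation and intra-column factors exactly
#' once.
#'
#' @param tm A [build_transfer_matrix()] result.
#' @param Lx Number of columns (>= 1).
#' @param boundary Boundary kind; defaults to the one in the lattice spec.
#' @param prop Propagation-weight placement: `"site"` (every protein
#'   carries its propagation weight, the Ising-form convention) or
#'   `"bond"` (one factor per x-neighbour pair -- the last column carries
#'   none, so a lone protein is weight 1; the Potts-form convention used by
#'   the dilute ensembles).
#' @return The partition function (positive scalar).
#' @export
partition_open <- function(tm, Lx, boundary = NULL, prop = "site") {
  stopifnot(inherits(tm, "transfer_matrix"))
  if (Lx < 1) stop("Lx must be >= 1", call. = FALSE)
  boundary <- boundary %||% tm$spec$boundary
  ev <- .end_vectors(tm, boundary, prop)
  v <- ev$f
  if (Lx > 1) for (step in seq_len(Lx - 1)) v <- tm$entries %*% v
  z0 <- sum(ev$i * v)
  m0 <- tm$spec$Ly * tm$spec$Lz
  z0 * tm$params$k^(.bonds_per_column(tm$spec) * Lx - m0)
}

#' Ring (periodic) partition function
#'
#' `trace(T^Lx)` times `k^(g Lx)`; with periodic boundaries every column has
#' the full complement of `g` bonds.  The per-column free energy
#' `log(Z)/Lx` converges to `log(k^g lambda_1)` as `Lx` grows.
#'
#' @inheritParams partition_open
#' @export
partition_periodic <- function(tm, Lx) {
  stopifnot(inherits(tm, "transfer_matrix"))
  if (Lx < 2) stop("Lx must be >= 2 for a ring", call. = FALSE)
  P <- diag(nrow(tm$entries))
  for (step in seq_len(Lx)) P <- P %*% tm$entries
  sum(diag(P)) * tm$params$k^(.bonds_per_column(tm$spec) * Lx)
}

#' Spectral decomposition of a transfer matrix with boundary coefficients
#'
#' Diagonalizes the transfer matrix and contracts the eigenvector basis with
#' the boundary vectors, so that the open-chain partition function becomes
#' `sum_i c_i lambda_i^(Lx-1)` (times the `k` prefactor).  Eigenvalues are
#' sorted by modulus; the leading one is real and positive for the
#' nonnegative matrices built here.  If the eigenvector basis is
#' ill-conditioned (condition estimate above `1e8`) the decomposition is
#' flagged and callers should fall back to direct matrix powers.
#'
#' @inheritParams partition_open
#' @param prop Propagation-weight placement (see [partition_open()]).
#' @return An object of class `spectral_data`: `values` (complex
#'   eigenvalues), `coefficients` (boundary coefficients `c_i`),
#'   `condition` (condition estimate of the eigenvector basis),
#'   `use_powers` (flag), plus bookkeeping (`k`, `g`, `m0`).
#' @export
spectral_decompose <- function(tm, boundary = NULL, prop = "site") {
  stopifnot(inherits(tm, "transfer_matrix"))
  boundary <- boundary %||% tm$spec$boundary
  ev <- .end_vectors(tm, boundary, prop)
  e <- eigen(tm$entries)
  ord <- order(Mod(e$values), decreasing = TRUE)
  V <- e$vectors[, ord, drop = FALSE]
  vals <- e$values[ord]
  cond <- tryCatch(kappa(V, exact = FALSE), error = function(e) Inf)
  coeff <- tryCatch(
    as.vector(crossprod(ev$i, V)) * as.vector(solve(V, ev$f)),
    error = function(e) rep(NA_complex_, length(vals))
  )
  structure(list(values = vals, coefficients = coeff, condition = cond,
                 use_powers = !is.finite(cond) || cond > 1e8,
                 k = tm$params$k, g = .bonds_per_column(tm$spec),
                 m0 = tm$spec$Ly * tm$spec$Lz),
            class = "spectral_data")
}

#' @export
print.spectral_data <- function(x, ...) {
  cat("<spectral_data>\n  |lambda| :",
      paste(signif(Mod(x$values), 5), collapse = ", "),
      "\n  condition:", signif(x$condition, 3),
      if (x$use_powers) " (ill-conditioned; use matrix powers)" else "", "\n")
  invisible(x)
}

#' Evaluate a partition function from its spectral decomposition
#'
#' @param sd A [spectral_decompose()] result.
#' @param Lx Number of columns.
#' @return `sum_i c_i lambda_i^(Lx-1) * k^(g Lx - m0)`, real part.
#' @export
partition_spectral <- function(sd, Lx) {
  stopifnot(inherits(sd, "spectral_data"))
  Re(sum(sd$coefficients * sd$values^(Lx - 1))) * sd$k^(sd$g * Lx - sd$m0)
}

#' Logarithmic derivative of a positive scalar field
#'
#' Computes `d log f / d log x` at `x0` by centred differences in `log x`
#' with one step of Richardson extrapolation.  This is the workhorse behind
#' every thermodynamic average: the mean number of units carrying a
#' Boltzmann weight `x` in a partition function `Z` is
#' `d log Z / d log x`.
#'
#' @param f A function of a single positive scalar.
#' @param x0 Evaluation point (> 0).
#' @param step Initial step in `log x` (default `1e-4`).
#' @return The logarithmic derivative (scalar).
#' @examples
#' log_derivative(function(s) s^7, 2.3)   # exactly 7
#' @export
log_derivative <- function(f, x0, step = 1e-4) {
  if (!is.finite(x0) || x0 <= 0) stop("x0 must be positive", call. = FALSE)
  lf <- function(h) {
    up <- f(x0 * exp(h)); dn <- f(x0 * exp(-h))
    if (!is.finite(up) || !is.finite(dn) || up <= 0 || dn <= 0) {
      stop("field must be positive and finite near the evaluation point",
           call. = FALSE)
    }
    (log(up) - log(dn)) / (2 * h)
  }
  d1 <- lf(step)
  d2 <- lf(step / 2)
  (4 * d2 - d1) / 3
}

`%||%` <- function(a, b) if (is.null(a)) b else a
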