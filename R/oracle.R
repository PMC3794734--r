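#' Exhaustive-enumeration reference partition functions
#'
#' Ground-truth implementations used to certify the transfer-matrix code:
#' every configuration of the finite lattice is enumerated explicitly and
#' its Boltzmann weight assembled term by term from the effective
#' Hamiltonian -- per-site propagation weights, `exp(-R)` per unlike
#' interface along the propagation axis, lateral sheet-sheet couplings `b`,
#' and `k` per nearest-neighbour bond.  Summation is in fixed lexicographic
#' order with compensated (Kahan) accumulation, so results are
#' bit-reproducible.
#'
#' @param spec A [lattice_spec()].
#' @param Lx Number of columns; the total number of configurations
#'   `q^(Lx * Ly * Lz)` must not exceed `2^24`.
#' @param params An [energy_params()].
#' @param boundary Boundary kind (default from `spec`); `"periodic"` wraps
#'   the x axis.
#' @param prop Propagation-weight placement, `"site"` or `"bond"` (see
#'   [partition_open()]); under `"bond"` the last column of an open chain
#'   carries no propagation weights.
#' @return A list with `Z` (the exact partition function) and
#'   `expectations`: mean counts of helical sites, sheet sites, unlike x
#'   interfaces, lateral sheet-sheet pairs, and mean per-site sheet
#'   fraction.
#' @seealso [partition_open()], [partition_periodic()]
#' @export
enumerate_partition <- function(spec, Lx, params, boundary = NULL,
                                prop = c("site", "bond")) {
  stopifnot(inherits(spec, "lattice_spec"), inherits(params, "energy_params"))
  prop <- match.arg(prop)
  boundary <- boundary %||% spec$boundary
  periodic <- identical(boundary, "periodic")
  Ly <- spec$Ly; Lz <- spec$Lz
  nsite <- Lx * Ly * Lz
  ab <- .alphabet(spec)
  if (length(ab)^nsite > 2^24) {
    stop("state space too large for enumeration (", length(ab), "^", nsite,
         " configurations)", call. = FALSE)
  }
  ## site index (x, y, l) -> (x - 1) * Ly * Lz + (l - 1) * Ly + y
  sidx <- function(x, y, l) (x - 1L) * Ly * Lz + (l - 1L) * Ly + y
  cfg <- as.matrix(expand.grid(rep(list(ab), nsite), KEEP.OUT.ATTRS = FALSE))
  dimnames(cfg) <- NULL

  logw <- numeric(nrow(cfg))
  n_iface <- numeric(nrow(cfg))
  n_bpair <- numeric(nrow(cfg))
  ## per-site propagation free energies; under the bond convention the
  ## last column of an open chain carries none
  pfe <- c(0, params$P1, params$P2)
  pmat <- matrix(pfe[cfg + 1L], nrow(cfg))
  if (prop == "bond" && !periodic) {
    last_sites <- sidx(Lx, rep(seq_len(Ly), Lz), rep(seq_len(Lz), each = Ly))
    pmat[, last_sites] <- 0
  }
  logw <- logw + rowSums(pmat)
  ## x interfaces: R(a,b) per unlike pair
  Rmat <- matrix(0, 3L, 3L)
  Rmat[1L, 2L] <- Rmat[2L, 1L] <- params$R1
  Rmat[1L, 3L] <- Rmat[3L, 1L] <- params$R2
  Rmat[2L, 3L] <- Rmat[3L, 2L] <- params$R3
  xmax <- if (periodic) Lx else Lx - 1L
  if (Lx > 1L || periodic) {
    for (x in seq_len(xmax)) {
      xr <- if (x == Lx) 1L else x + 1L
      for (l in seq_len(Lz)) for (y in seq_len(Ly)) {
        a <- cfg[, sidx(x, y, l)]; b <- cfg[, sidx(xr, y, l)]
        diff <- a != b
        logw <- logw - Rmat[cbind(a + 1L, b + 1L)]
        n_iface <- n_iface + diff
      }
    }
  }
  ## lateral sheet-sheet pairs within columns (strip), plus the cube's
  ## single extra coupling when a whole column is sheet
  if (Ly > 1L) {
    for (x in seq_len(Lx)) for (l in seq_len(Lz)) {
      for (y in seq_len(Ly - 1L)) {
        both <- cfg[, sidx(x, y, l)] == 2L & cfg[, sidx(x, y + 1L, l)] == 2L
        logw <- logw + params$B * both
        n_bpair <- n_bpair + both
      }
    }
  }
  if (Lz == 2L) {
    for (x in seq_len(Lx)) {
      col_sites <- c(sidx(x, seq_len(Ly), 1L), sidx(x, seq_len(Ly), 2L))
      allsheet <- rowSums(cfg[, col_sites, drop = FALSE] == 2L) == length(col_sites)
      logw <- logw + params$B * allsheet
      n_bpair <- n_bpair + allsheet
    }
  }
  ## polymerization: one K per nearest-neighbour bond
  nbond <- if (periodic) .bonds_per_column(spec) * Lx
           else .bonds_per_column(spec) * Lx - Ly * Lz
  logw <- logw + params$K * nbond
  ## boundary restriction on the end columns
  if (!periodic && !identical(boundary, "free")) {
    keepcol <- function(x) {
      sub <- cfg[, c(sidx(x, seq_len(Ly), 1L),
                     if (Lz == 2L) sidx(x, seq_len(Ly), 2L)), drop = FALSE]
      if (identical(boundary, "coil_only")) rowSums(sub != 0L) == 0L
      else rowSums(sub == 1L) == 0L
    }
    keep <- keepcol(1L) & keepcol(Lx)
    logw[!keep] <- -Inf
  }
  w <- exp(logw)
  Z <- .kahan_sum(w)
  nh <- rowSums(matrix(cfg == 1L, nrow(cfg)))
  ns <- rowSums(matrix(cfg == 2L, nrow(cfg)))
  ## sheet sites that carry the s2 propagation weight (for derivative checks)
  smat <- matrix(cfg == 2L, nrow(cfg))
  if (prop == "bond" && !periodic) {
    last_sites <- sidx(Lx, rep(seq_len(Ly), Lz), rep(seq_len(Lz), each = Ly))
    smat[, last_sites] <- FALSE
  }
  nsp <- rowSums(smat)
  list(
    Z = Z,
    expectations = list(
      n_helix = .kahan_sum(w * nh) / Z,
      n_sheet = .kahan_sum(w * ns) / Z,
      n_sheet_prop = .kahan_sum(w * nsp) / Z,
      n_interface = .kahan_sum(w * n_iface) / Z,
      n_sheet_pair = .kahan_sum(w * n_bpair) / Z,
      sheet_fraction = .kahan_sum(w * ns / nsite) / Z
    )
  )
}

## Compensated summation in fixed order; error <= 2 ulp per addition.
.kahan_sum <- function(x) {
  s <- 0; c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}

#' Exhaustive grand-canonical enumeration with solvent sites
#'
#' Exact grand partition function and observables for a small periodic
#' lattice-gas model (variant A or B, see [gc_model()]): every combination
#' of site occupancy and conformation is enumerated, each configuration
#' weighted by `exp(-beta H + beta mu N_p) = w(H) z^Np`.
#'
#' @param model A [gc_model()].
#' @param N Number of columns of the periodic lattice; the composite state
#'   space `(q+1)^(N * Ly)` must not exceed `2^24`.
#' @return A list with `Q` and `expectations`: mean protein count `Np`,
#'   sheet-propagation bond count `theta`, polymerization bond count
#'   `kbonds`, solvent-protein nucleation boundary count `nuc`, and the
#'   derived filament count `gamma = nuc / 2` and filament protein count
#'   `psi = kbonds_x + gamma` (variant A) where appropriate.
#' @export
enumerate_gc_partition <- function(model, N) {
  stopifnot(inherits(model, "gc_model"))
  p <- model$params; Ly <- model$Ly; nc <- model$nc
  if (N < max(2L, nc + 1L)) stop("N too small for the nucleus window",
                                 call. = FALSE)
  nsite <- N * Ly
  if (3L^nsite > 2^24) stop("state space too large", call. = FALSE)
  ## GC site codes: 0 solvent, 1 coil protein, 2 sheet protein
  sidx <- function(x, y) (x - 1L) * Ly + y
  cfg <- as.matrix(expand.grid(rep(list(0:2), nsite), KEEP.OUT.ATTRS = FALSE))
  dimnames(cfg) <- NULL
  occ <- cfg > 0L
  sheet <- cfg == 2L
  np <- rowSums(occ)
  logw <- log(model$z) * np
  n_p1 <- numeric(nrow(cfg)); n_k <- numeric(nrow(cfg))
  n_nuc <- numeric(nrow(cfg))
  wrap <- function(x) ((x - 1L) %% N) + 1L
  ## x-direction protein-protein and boundary terms (Hpp), every filament
  for (x in seq_len(N)) for (y in seq_len(Ly)) {
    a <- sidx(x, y); b <- sidx(wrap(x + 1L), y)
    bothp <- occ[, a] & occ[, b]
    onep <- xor(occ[, a], occ[, b])
    logw <- logw + bothp * (p$K + p$P1 * sheet[, a] -
                              p$R1 * (bothp & (cfg[, a] != cfg[, b])))
    n_k <- n_k + bothp
    n_p1 <- n_p1 + (bothp & sheet[, a])
    logw <- logw - p$R1 * (onep & (sheet[, a] | sheet[, b]))
  }
  if (model$variant == "A") {
    ## nucleation along x, per filament: solvent/protein boundary across a
    ## window of nc occupied middle sites
    for (x in seq_len(N)) for (y in seq_len(Ly)) {
      a <- sidx(x, y); b <- sidx(wrap(x + nc), y)
      mid <- if (nc > 1L) {
        m <- rep(TRUE, nrow(cfg))
        for (d in seq_len(nc - 1L)) m <- m & occ[, sidx(wrap(x + d), y)]
        m
      } else rep(TRUE, nrow(cfg))
      act <- (occ[, a] != occ[, b]) & mid
      logw <- logw - p$A * act
      n_nuc <- n_nuc + act
    }
    ## lateral sheet links F between adjacent filaments
    if (Ly > 1L) {
      for (x in seq_len(N)) for (y in seq_len(Ly - 1L)) {
        a <- sidx(x, y); b <- sidx(x, y + 1L)
        link <- sheet[, a] & sheet[, b]
        logw <- logw + p$F * link
      }
    }
  } else {
    ## variant B: full y-direction interactions and a column-level nucleus
    if (Ly > 1L) {
      for (x in seq_len(N)) for (y in seq_len(Ly - 1L)) {
        a <- sidx(x, y); b <- sidx(x, y + 1L)
        bothp <- occ[, a] & occ[, b]
        onep <- xor(occ[, a], occ[, b])
        logw <- logw + bothp * (p$K + p$F * (sheet[, a] & sheet[, b]) -
                                  p$R1 * (bothp & (cfg[, a] != cfg[, b])))
        n_k <- n_k + bothp
        logw <- logw - p$R1 * (onep & (sheet[, a] | sheet[, b]))
      }
    }
    for (x in seq_len(N)) {
      cola <- occ[, sidx(x, seq_len(Ly)), drop = FALSE]
      colb <- occ[, sidx(wrap(x + 1L), seq_len(Ly)), drop = FALSE]
      flip <- rowSums(cola != colb) == Ly
      unif <- rowSums(cola) %in% c(0L, Ly)
      act <- flip & unif
      logw <- logw - p$A * act
      n_nuc <- n_nuc + act
    }
  }
  w <- exp(logw)
  Q <- .kahan_sum(w)
  list(
    Q = Q,
    expectations = list(
      Np = .kahan_sum(w * np) / Q,
      theta = .kahan_sum(w * n_p1) / Q,
      kbonds = .kahan_sum(w * n_k) / Q,
      nuc = .kahan_sum(w * n_nuc) / Q,
      gamma = .kahan_sum(w * n_nuc) / Q / 2
    )
  )
}
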