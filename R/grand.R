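#' Grand-canonical lattice-gas model of fibril growth
#'
#' Extends the canonical strip models with explicit solvent: every lattice
#' site holds either a solvent cluster or a protein in a coil or sheet
#' conformation, protein number is controlled by the fugacity
#' `z = exp(beta mu_PC)`, and a nucleation free energy `A` is paid at
#' solvent-protein boundaries.  Two variants are supported: in variant A
#' the `nc`-column nucleus lies along the propagation (x) axis and the
#' composite transfer-matrix state remembers `nc` columns, giving dimension
#' `(q+1)^(nc*Ly)`; in variant B the nucleus is a full column (the quasi-1D
#' multi-layer nucleus) and the dimension is `(q+1)^Ly`.  Inter-filament
#' sheet links carry the free energy `F`.
#'
#' @param variant `"A"` (nucleus along x) or `"B"` (nucleus along y).
#' @param Ly Number of filaments (lattice rows).
#' @param nc Nucleus size in columns (variant A; variant B's nucleus is the
#'   column itself and ignores `nc`).
#' @param params An [energy_params()]; uses `P1`, `R1`, `K`, `F`, `A`.
#' @param z Fugacity `exp(beta mu_PC)`.
#' @param q Conformational states per protein; only the two-state
#'   (sheet-coil) model is implemented.
#' @return An object of class `gc_model`.
#' @export
gc_model <- function(variant = c("B", "A"), Ly = 1L, nc = 1L, params,
                     z = 1, q = 2L) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "energy_params"), z > 0)
  if (q != 2L) stop("only the q = 2 sheet-coil lattice gas is implemented",
                    call. = FALSE)
  Ly <- as.integer(Ly); nc <- as.integer(nc)
  if (Ly < 1L || nc < 1L) stop("Ly and nc must be >= 1", call. = FALSE)
  if (variant == "A" && nc * Ly > 8L) {
    stop("variant A composite state capped at nc * Ly <= 8 sites",
         call. = FALSE)
  }
  structure(list(variant = variant, Ly = Ly, nc = nc, q = q,
                 params = params, z = z),
            class = "gc_model")
}

#' @export
print.gc_model <- function(x, ...) {
  dim <- if (x$variant == "A") 3L^(x$nc * x$Ly) else 3L^x$Ly
  cat(sprintf("<gc_model> variant %s, Ly=%d, nc=%d, z=%g (matrix %d x %d)\n",
              x$variant, x$Ly, x$nc, x$z, dim, dim))
  invisible(x)
}

## GC site codes: 0 solvent, 1 coil protein, 2 sheet protein.
## x-direction bond factor between site codes a (left) and b (right):
## occupied pairs pay K, P1 if the left protein is sheet, exp(-R1) if the
## conformations differ; a solvent-protein boundary pays exp(-R1) per
## adjacent sheet protein.
.gc_xfac <- function(a, b, p) {
  if (a > 0L && b > 0L) {
    p$k * (if (a == 2L) p$s1 else 1) * (if (a != b) exp(-p$R1) else 1)
  } else if (a != b && (a == 2L || b == 2L)) {
    exp(-p$R1)
  } else 1
}

## y-direction bond factor inside a column.  Variant A carries the
## sheet-sheet link F only; variant B adds full polymerization and
## interface terms in y.  In both, F binds a pair of sheet proteins (the
## inter-filament steric-zipper contact), mirroring the canonical B.
.gc_yfac <- function(a, b, p, variant) {
  if (variant == "A") {
    if (a == 2L && b == 2L) p$f else 1
  } else {
    if (a > 0L && b > 0L) {
      p$k * (if (a == 2L && b == 2L) p$f else 1) *
        (if (a != b) exp(-p$R1) else 1)
    } else if (a != b && (a == 2L || b == 2L)) {
      exp(-p$R1)
    } else 1
  }
}

.gc_columns <- function(Ly) {
  m <- as.matrix(expand.grid(rep(list(0:2), Ly), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

## Intrinsic weight of a column: fugacity per protein and y couplings.
.gc_column_weight <- function(col, p, z, variant) {
  w <- z^sum(col > 0L)
  if (length(col) > 1L) {
    for (j in seq_len(length(col) - 1L)) {
      w <- w * .gc_yfac(col[j], col[j + 1L], p, variant)
    }
  }
  w
}

#' Transfer matrix of a grand-canonical lattice-gas model
#'
#' @param model A [gc_model()].
#' @return A list of class `gc_transfer_matrix` with `entries`,
#'   `state_labels` and the generating `model`.  For variant A the states
#'   are windows of `nc` consecutive columns (higher-order interactions are
#'   blocked into first-order form); transitions with inconsistent window
#'   overlap have weight zero.
#' @export
build_gc_transfer_matrix <- function(model) {
  stopifnot(inherits(model, "gc_model"))
  p <- model$params; Ly <- model$Ly; z <- model$z
  cols <- .gc_columns(Ly)
  ncol_states <- nrow(cols)
  cw <- apply(cols, 1L, .gc_column_weight, p = p, z = z,
              variant = model$variant)
  key <- c("-", "c", "s")
  collab <- apply(cols, 1L, function(r) paste(key[r + 1L], collapse = ""))
  xfac_cols <- matrix(1, ncol_states, ncol_states)
  for (a in seq_len(ncol_states)) for (b in seq_len(ncol_states)) {
    w <- 1
    for (j in seq_len(Ly)) w <- w * .gc_xfac(cols[a, j], cols[b, j], p)
    xfac_cols[a, b] <- w
  }
  if (model$variant == "B") {
    ea <- exp(-p$A)
    entries <- xfac_cols * rep(cw, each = ncol_states)
    occ <- matrix(cols > 0L, ncol_states)
    full <- rowSums(occ) == Ly
    empty <- rowSums(occ) == 0L
    nucpair <- outer(full, empty) | outer(empty, full)
    entries[nucpair] <- entries[nucpair] * ea
    labels <- collab
  } else {
    nc <- model$nc
    ea <- exp(-p$A)
    nwin <- ncol_states^nc
    widx <- as.matrix(expand.grid(rep(list(seq_len(ncol_states)), nc),
                                  KEEP.OUT.ATTRS = FALSE))
    dimnames(widx) <- NULL
    entries <- matrix(0, nwin, nwin)
    occm <- matrix(cols > 0L, ncol_states)
    for (a in seq_len(nwin)) {
      awin <- widx[a, ]
      for (b in seq_len(nwin)) {
        bwin <- widx[b, ]
        if (nc > 1L && !all(awin[-1L] == bwin[-nc])) next
        newcol <- bwin[nc]
        w <- cw[newcol] * xfac_cols[awin[nc], newcol]
        ## nucleus window: first column of a, middles, new column
        for (j in seq_len(Ly)) {
          o_first <- occm[awin[1L], j]
          o_last <- occm[newcol, j]
          mid_ok <- nc == 1L ||
            all(vapply(2:nc, function(d) occm[awin[d], j], TRUE))
          if (o_first != o_last && mid_ok) w <- w * ea
        }
        entries[a, b] <- w
      }
    }
    labels <- apply(widx, 1L, function(r) paste(collab[r], collapse = "|"))
  }
  structure(list(entries = entries, state_labels = labels, model = model),
            class = "gc_transfer_matrix")
}

#' @export
print.gc_transfer_matrix <- function(x, ...) {
  cat(sprintf("<gc_transfer_matrix> %d x %d (variant %s)\n",
              nrow(x$entries), ncol(x$entries), x$model$variant))
  invisible(x)
}

## Dominant eigenvalue of a nonnegative matrix.
.lambda1 <- function(M) {
  if (nrow(M) <= 400L) {
    max(Re(eigen(M, only.values = TRUE)$values))
  } else {
    v <- rep(1, nrow(M)); lam <- 1
    for (it in seq_len(20000L)) {
      w <- as.vector(M %*% v)
      lam_new <- sqrt(sum(w^2))
      w <- w / lam_new
      if (abs(lam_new - lam) < 1e-14 * lam_new) { lam <- lam_new; break }
      lam <- lam_new; v <- w
    }
    lam
  }
}

#' Grand partition function of a finite periodic lattice
#'
#' `Q = trace(T^N)` for `N` columns with periodic boundaries along x.
#'
#' @param model A [gc_model()].
#' @param N Number of columns (>= nc + 1).
#' @export
gc_partition_periodic <- function(model, N) {
  if (N < model$nc + 1L) stop("N must exceed the nucleus window",
                              call. = FALSE)
  Tm <- build_gc_transfer_matrix(model)$entries
  P <- diag(nrow(Tm))
  for (step in seq_len(N)) P <- P %*% Tm
  sum(diag(P))
}

#' Per-site grand potential
#'
#' `log(lambda_1) / Ly`: the thermodynamic-limit grand potential per lattice
#' site, to which `(Ly N)^(-1) log Q` of finite periodic lattices
#' converges.  Vanishes as `z -> 0` (the all-solvent lattice).
#'
#' @param model A [gc_model()].
#' @export
gc_log_partition_per_site <- function(model) {
  log(.lambda1(build_gc_transfer_matrix(model)$entries)) / model$Ly
}

## log Q as a function of modified parameters; N = NULL means per-site.
.gc_lnQ <- function(model, N = NULL) {
  function(params = model$params, z = model$z) {
    m <- model; m$params <- params; m$z <- z
    if (is.null(N)) {
      log(.lambda1(build_gc_transfer_matrix(m)$entries))
    } else {
      log(gc_partition_periodic(m, N))
    }
  }
}

## Centred log-log derivative with one Richardson step, for functions that
## already return a logarithm.
.log_deriv_ln <- function(lnf, x0, step = 1e-4) {
  d <- function(h) (lnf(x0 * exp(h)) - lnf(x0 * exp(-h))) / (2 * h)
  (4 * d(step / 2) - d(step)) / 3
}

#' Grand-canonical observables
#'
#' Mean protein occupancy `Np`, sheet-bond count `theta`, filament count
#' `gamma` and filament protein count `psi`, from logarithmic derivatives of
#' the grand potential: `Np = z d lnQ / dz`, `theta = d lnQ / d P1`,
#' `gamma = (1/2) d lnQ / d(-A)` (half the mean number of solvent-protein
#' nucleation boundaries), `psi = d lnQ / dK + gamma`.  With `N = NULL`
#' the quantities are per lattice site (thermodynamic limit); with finite
#' `N` they are totals for the periodic `N * Ly` lattice.
#'
#' @param model A [gc_model()].
#' @param N Number of columns of a finite periodic lattice, or `NULL` for
#'   the thermodynamic limit.
#' @return A tibble with `Np`, `theta`, `gamma`, `psi`, `sheet_fraction`
#'   (`theta / Np`) and the normalization used.
#' @export
gc_observables <- function(model, N = NULL) {
  lnQ <- .gc_lnQ(model, N)
  norm <- if (is.null(N)) model$Ly else 1
  p <- model$params
  Np <- .log_deriv_ln(function(z) lnQ(z = z), model$z) / norm
  theta <- .log_deriv_ln(function(s1) lnQ(params = update_params(p, P1 = log(s1))),
                         p$s1) / norm
  gamma <- 0.5 * .log_deriv_ln(function(aa) lnQ(params = update_params(p, A = -log(aa))),
                               exp(-p$A)) / norm
  kd <- .log_deriv_ln(function(k) lnQ(params = update_params(p, K = log(k))),
                      p$k) / norm
  tibble::tibble(Np = Np, theta = theta, gamma = gamma, psi = kd + gamma,
                 sheet_fraction = ifelse(Np > 0, theta / Np, 0),
                 per = if (is.null(N)) "site" else "lattice")
}

#' Chemical potential of aggregated protein from solution concentration
#'
#' Equates the solution and aggregate phase chemical potentials:
#' `mu_PC = mu_ST + mu_SR + RT log(c) - mu_PV`, with the translational plus
#' rotational solution term defaulting to -29 kcal/mol and the vibrational
#' aggregate term to three quarters of it.  Concentration is molar (1 M
#' standard state for the kcal/mol bookkeeping).
#'
#' @param conc_M Solution concentration in mol/L.
#' @param T_K Temperature in kelvin.
#' @param mu_st_sr Translational + rotational solution free energy
#'   (kcal/mol).
#' @param mu_pv Vibrational free energy of the aggregate (kcal/mol);
#'   default `0.75 * mu_st_sr`.
#' @return A tibble with `mu_pc` (kcal/mol), the dimensionless
#'   `beta_mu_pc`, the fugacity `z = exp(beta mu_pc)` and `RT`.
#' @export
mu_pc_from_concentration <- function(conc_M, T_K = 298,
                                     mu_st_sr = -29, mu_pv = NULL) {
  if (any(conc_M <= 0)) stop("concentration must be positive", call. = FALSE)
  stopifnot(T_K > 0)
  mu_pv <- mu_pv %||% (0.75 * mu_st_sr)
  RT <- .R_KCAL * T_K
  mu_pc <- mu_st_sr + RT * log(conc_M) - mu_pv
  tibble::tibble(conc_M = conc_M, mu_pc = mu_pc,
                 beta_mu_pc = mu_pc / RT, z = exp(mu_pc / RT), RT = RT)
}

#' Concentration sweep of a grand-canonical model
#'
#' Maps solution concentrations to the fugacity via the chemical-potential
#' bridge and evaluates the per-site observables; `sheet_fraction`
#' (`theta / Np`) is the fit function for CD data in this ensemble.
#'
#' @param model A [gc_model()] (its `z` is overridden point by point).
#' @param conc_uM Concentrations in micromolar.
#' @inheritParams mu_pc_from_concentration
#' @return A tibble of class `gc_curve`.
#' @export
gc_curve <- function(model, conc_uM, T_K = 298, mu_st_sr = -29,
                     mu_pv = NULL) {
  link <- mu_pc_from_concentration(conc_uM * 1e-6, T_K, mu_st_sr, mu_pv)
  rows <- purrr::map_dfr(seq_along(conc_uM), function(i) {
    m <- model; m$z <- link$z[i]
    ob <- gc_observables(m)
    tibble::tibble(conc_uM = conc_uM[i], mu_pc = link$mu_pc[i],
                   z = link$z[i], Np = ob$Np, theta = ob$theta,
                   sheet_fraction = ob$sheet_fraction)
  })
  class(rows) <- c("gc_curve", class(rows))
  rows
}
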