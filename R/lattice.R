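#' Lattice geometry for a canonical aggregate model
#'
#' Describes the quasi-1D lattice a single aggregate species lives on: a 1D
#' filament, a strip of `Ly` laterally bound filaments (a protofibril), or a
#' "cube" of two `Ly = 2` strips stacked in register (a fibril).  The
#' transfer matrix acts along the x (propagation) axis; one column holds
#' `Ly * Lz` proteins.
#'
#' @param geometry `"filament"`, `"strip"` or `"cube"`.
#' @param Ly Number of filaments per strip (columns have `Ly * Lz` sites).
#' @param Lz Number of stacked strips; 1 except for the cube, where it is 2.
#' @param q Number of conformational states per protein: 2 (coil plus one
#'   ordered state) or 3 (coil, helix, sheet).
#' @param ordered For `q = 2`, which ordered state the model uses:
#'   `"sheet"` (propagation `s2 = exp(P2)`, interface `R2`; lateral binding
#'   `B` applies) or `"helix"` (`s1`, `R1`; no lateral binding).
#' @param nc Nucleus size in columns.  Canonical aggregates smaller than
#'   `nc` columns are excluded from species sums (`min_Lx` in
#'   [fibril_species()] defaults to it).
#' @param boundary Default boundary condition for partition functions:
#'   `"free"`, `"sheet_or_coil"`, `"coil_only"` or `"periodic"`.
#'
#' @return An object of class `lattice_spec`.
#' @seealso [build_transfer_matrix()], [partition_open()]
#' @export
lattice_spec <- function(geometry = c("filament", "strip", "cube"),
                         Ly = NULL, Lz = NULL, q = 2,
                         ordered = c("sheet", "helix"),
                         nc = 1L, boundary = c("free", "sheet_or_coil",
                                               "coil_only", "periodic")) {
  geometry <- match.arg(geometry)
  ordered <- match.arg(ordered)
  boundary <- match.arg(boundary)
  if (!q %in% c(2L, 3L)) stop("q must be 2 or 3", call. = FALSE)
  if (geometry == "filament") {
    if (is.null(Ly)) Ly <- 1L
    if (is.null(Lz)) Lz <- 1L
    if (Ly != 1L || Lz != 1L) {
      stop("a filament has Ly = Lz = 1", call. = FALSE)
    }
  } else if (geometry == "strip") {
    if (is.null(Ly)) stop("strip geometry needs Ly", call. = FALSE)
    if (is.null(Lz)) Lz <- 1L
    if (Lz != 1L || Ly < 1L) stop("a strip has Lz = 1 and Ly >= 1",
                                  call. = FALSE)
  } else {
    if (is.null(Ly)) Ly <- 2L
    if (is.null(Lz)) Lz <- 2L
    if (Ly != 2L || Lz != 2L) {
      stop("the cube model is two Ly = 2 strips stacked in register",
           call. = FALSE)
    }
  }
  if (nc < 1L) stop("nc must be >= 1", call. = FALSE)
  structure(list(geometry = geometry, Ly = as.integer(Ly),
                 Lz = as.integer(Lz), q = as.integer(q), ordered = ordered,
                 nc = as.integer(nc), boundary = boundary),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %s: Ly=%d Lz=%d q=%d (%s) boundary=%s\n",
              x$geometry, x$Ly, x$Lz, x$q,
              if (x$q == 2L) paste0("coil/", x$ordered) else "coil/helix/sheet",
              x$boundary))
  invisible(x)
}

## Conformation alphabet as internal codes: 0 coil, 1 helix, 2 sheet.
.alphabet <- function(spec) {
  if (spec$q == 3L) c(0L, 1L, 2L)
  else c(0L, if (spec$ordered == "helix") 1L else 2L)
}

## All composite column states, one row per state, one column per site.
## Sites are ordered strip-major: site (j, l) -> column (l - 1) * Ly + j.
.col_states <- function(spec) {
  ns <- spec$Ly * spec$Lz
  ab <- .alphabet(spec)
  g <- expand.grid(rep(list(ab), ns), KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g)
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

.state_labels <- function(states) {
  key <- c("c", "h", "s")
  apply(states, 1L, function(r) paste(key[r + 1L], collapse = ""))
}

## Nearest-neighbour bonds per column of the lattice (x + y + z directions);
## an open Lx-column lattice has g * Lx - Ly * Lz bonds, a periodic one g * Lx.
.bonds_per_column <- function(spec) {
  spec$Ly * spec$Lz + (spec$Ly - 1L) * spec$Lz + spec$Ly * (spec$Lz - 1L)
}

## Per-site propagation weight product for each column state.
.column_prop <- function(states, params) {
  pw <- c(1, params$s1, params$s2)
  apply(states, 1L, function(r) prod(pw[r + 1L]))
}

## Intra-column couplings: lateral sheet-sheet binding b between adjacent
## filaments of a strip, and for the cube additionally one b when the whole
## column is sheet.
.column_intra <- function(states, spec, params) {
  n <- nrow(states)
  w <- rep(1, n)
  Ly <- spec$Ly; Lz <- spec$Lz
  if (Ly > 1L) {
    for (l in seq_len(Lz)) {
      off <- (l - 1L) * Ly
      for (j in seq_len(Ly - 1L)) {
        both <- states[, off + j] == 2L & states[, off + j + 1L] == 2L
        w[both] <- w[both] * params$b
      }
    }
  }
  if (Lz == 2L) {
    all_sheet <- rowSums(states == 2L) == Ly * Lz
    w[all_sheet] <- w[all_sheet] * params$b
  }
  w
}

## Interface weight matrix over codes 0..2: exp(-R) per unlike pair, so a
## completed segment with two interfaces carries sigma = exp(-2R).
.interface_weights <- function(params) {
  u <- matrix(1, 3L, 3L)
  u[1L, 2L] <- u[2L, 1L] <- exp(-params$R1)
  u[1L, 3L] <- u[3L, 1L] <- exp(-params$R2)
  u[2L, 3L] <- u[3L, 2L] <- exp(-params$R3)
  u
}

## Boundary mask: which composite column states a chain may start/end in.
.boundary_mask <- function(states, boundary) {
  switch(boundary,
    free = rep(TRUE, nrow(states)),
    sheet_or_coil = apply(states, 1L, function(r) all(r != 1L)),
    coil_only = apply(states, 1L, function(r) all(r == 0L)),
    periodic = stop("periodic boundaries have no end vectors; use ",
                    "partition_periodic()", call. = FALSE),
    stop("unknown boundary kind: ", boundary, call. = FALSE)
  )
}
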