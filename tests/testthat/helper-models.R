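## Shared fixtures: seeded random parameter draws and small model zoos.

random_params <- function(gc = FALSE) {
  energy_params(
    R1 = runif(1, -0.8, 0.8), R2 = runif(1, -0.8, 0.8),
    R3 = runif(1, -0.8, 0.8),
    P1 = runif(1, -1, 1), P2 = runif(1, -1, 1),
    K = runif(1, -0.5, 0.5), B = runif(1, -0.5, 0.8),
    F = if (gc) runif(1, -0.5, 0.8) else 0,
    A = if (gc) runif(1, -0.5, 0.8) else 0
  )
}

## Canonical model zoo used by the oracle-equivalence suite: every geometry
## with a lattice small enough for exhaustive enumeration.
canonical_zoo <- list(
  list(spec = lattice_spec("filament", q = 2), Lx = 6),
  list(spec = lattice_spec("filament", q = 2, boundary = "coil_only"), Lx = 5),
  list(spec = lattice_spec("filament", q = 3), Lx = 5),
  list(spec = lattice_spec("filament", q = 3, boundary = "sheet_or_coil"), Lx = 4),
  list(spec = lattice_spec("strip", Ly = 2, q = 2), Lx = 5),
  list(spec = lattice_spec("strip", Ly = 3, q = 2), Lx = 4),
  list(spec = lattice_spec("strip", Ly = 2, q = 3), Lx = 3),
  list(spec = lattice_spec("cube"), Lx = 3)
)
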