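#' Geometric bond detection
#'
#' Two atoms are bonded when their distance is below `k` times the sum of
#' their covalent radii.  This purely geometric criterion decides when a
#' trajectory has fragmented; `k` therefore controls fragmentation timing
#' and is exposed in the run configuration.
#'
#' @param mol A [molecule()].
#' @param k Dimensionless detection scale (default 1.2).
#' @return A `bond_graph`: list with `adjacency` (logical n x n symmetric
#'   matrix, no self edges), `edges` (two-column matrix of atom index
#'   pairs, i < j) and `k`.
#' @export
detect_bonds <- function(mol, k = 1.2) {
  n <- n_atoms(mol)
  radii <- covalent_radii(mol$symbols)
  adj <- matrix(FALSE, n, n)
  if (n > 1L) {
    d <- as.matrix(stats::dist(mol$coords))
    cutoff <- outer(radii, radii, "+") * k
    adj <- d < cutoff
    diag(adj) <- FALSE
  }
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  colnames(edges) <- c("i", "j")
  structure(list(adjacency = adj, edges = edges, k = k),
            class = "bond_graph")
}

# connected-component labels by BFS over the adjacency matrix
.components <- function(adj) {
  n <- nrow(adj)
  labels <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (labels[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    labels[s] <- comp
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & labels == 0L)
      labels[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Split a molecule into connected fragments
#'
#' Each connected component of the bond graph becomes its own molecule,
#' carrying its atoms' coordinates and velocities.  Fragment charge is set
#' to 0; statistical charge assignment is a separate step.
#'
#' @param mol A [molecule()].
#' @param g A `bond_graph` from [detect_bonds()].
#' @return List of [molecule()]s (length 1 when the molecule is intact),
#'   with an `atom_indices` attribute per fragment mapping back to the
#'   parent's atom order.
#' @export
split_fragments <- function(mol, g) {
  labels <- .components(g$adjacency)
  lapply(seq_len(max(labels)), function(c) {
    idx <- which(labels == c)
    frag <- .subset_molecule(mol, idx)
    attr(frag, "atom_indices") <- idx
    frag
  })
}

#' Internal (vibrational) temperature of a fragment
#'
#' Kinetic energy after removing center-of-mass translation (always) and
#' rigid-body rotation (for 3 or more atoms) is equated to
#' `n_dof/2 * kB * T`.  Degrees of freedom: `3N - 6` for nonlinear
#' polyatomics, `3N - 5` for linear ones, and 1 for atoms and diatomics
#' (the diatomic convention counts the full relative motion against a
#' single vibration; a lone atom has no internal energy and reports 0 K).
#'
#' @param frag A [molecule()] with velocities.
#' @return Temperature in K.
#' @export
fragment_temperature <- function(frag) {
  n <- n_atoms(frag)
  m <- atomic_masses(frag$symbols)
  v <- frag$velocities
  # remove center-of-mass drift
  vcom <- colSums(v * m) / sum(m)
  v <- sweep(v, 2, vcom)
  if (n == 1L) return(0)
  linear <- FALSE
  if (n >= 3L) {
    x <- sweep(frag$coords, 2, colSums(frag$coords * m) / sum(m))
    inertia <- matrix(0, 3, 3)
    for (i in seq_len(n)) {
      r <- x[i, ]
      inertia <- inertia + m[i] * (sum(r^2) * diag(3) - tcrossprod(r))
    }
    ev <- eigen(inertia, symmetric = TRUE)
    linear <- ev$values[3] < 1e-8 * max(ev$values[1], 1e-12)
    # angular velocity from L = I w (pseudo-inverse handles linear case)
    L <- colSums(t(vapply(seq_len(n), function(i)
      m[i] * .cross3(x[i, ], v[i, ]), numeric(3))))
    keep <- ev$values > 1e-10 * max(ev$values[1], 1e-12)
    w <- ev$vectors[, keep, drop = FALSE] %*%
      ((t(ev$vectors[, keep, drop = FALSE]) %*% L) / ev$values[keep])
    v <- v - t(vapply(seq_len(n), function(i) .cross3(as.numeric(w), x[i, ]),
                      numeric(3)))
  }
  ekin <- 0.5 * sum(m * rowSums(v^2)) * .EV_KIN
  ndof <- if (n == 2L) 1 else if (linear) 3 * n - 5 else max(1, 3 * n - 6)
  2 * ekin / (ndof * .KB)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a fragment record
#'
#' One detached fragment with everything the charge-assignment and
#' spectrum stages need.
#'
#' @param mol Fragment [molecule()].
#' @param vertical_ip Vertical ionization potential, eV.
#' @param temperature Internal temperature, K.
#' @param statistical_charge Fraction of the parent charge carried.
#' @param cascade_depth Cascade generation (0 = parent event).
#' @return Object of class `fragment_record`.
#' @export
fragment_record <- function(mol, vertical_ip, temperature,
                            statistical_charge = 0, cascade_depth = 0L) {
  stopifnot(statistical_charge >= 0, statistical_charge <= 1 + 1e-12,
            temperature >= 0)
  structure(list(mol = mol, formula = formula_of(mol),
                 vertical_ip = vertical_ip, temperature = temperature,
                 statistical_charge = statistical_charge,
                 cascade_depth = as.integer(cascade_depth)),
            class = "fragment_record")
}

#' @export
print.fragment_record <- function(x, ...) {
  cat(sprintf("<fragment> %s  IP=%.2f eV  T=%.0f K  q=%.4f  depth=%d\n",
              formula_key(x$formula), x$vertical_ip, x$temperature,
              x$statistical_charge, x$cascade_depth))
  invisible(x)
}
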