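# Shared helpers: independent oracles and small constructed systems.

# provider with an arbitrary closed-form potential (for integrator checks)
analytic_provider <- function(energy_fn, gradient_fn) {
  provider(energy_gradient = function(mol, electronic_temperature = 300) {
    list(energy = energy_fn(mol$coords), gradient = gradient_fn(mol$coords))
  }, name = "analytic")
}

# 1-D harmonic well on atom 1's x coordinate: E = 0.5 k x^2
harmonic_provider <- function(k) {
  analytic_provider(
    function(x) 0.5 * k * x[1, 1]^2,
    function(x) { g <- x * 0; g[1, 1] <- k * x[1, 1]; g })
}

free_provider <- analytic_provider(function(x) 0, function(x) x * 0)

# bound Morse diatomic (two carbons) + its surrogate provider
bound_diatomic <- function(stretch = 0.08) {
  ref <- molecule(c("C", "C"), matrix(c(0, 0, 0, 1.52, 0, 0),
                                      ncol = 3, byrow = TRUE))
  prov <- surrogate_provider(ref, surrogate_params(de = c(default = 4),
                                                   a = c(default = 2)))
  mol <- ref
  mol$coords[2, 1] <- mol$coords[2, 1] + stretch
  list(mol = mol, provider = prov)
}

# random small molecule with well-separated atoms (parser round-trips etc.)
random_molecule <- function(n = 5, symbols = c("C", "H", "N", "O")) {
  repeat {
    coords <- matrix(stats::runif(3 * n, -4, 4), ncol = 3)
    if (n == 1 || min(stats::dist(coords)) > 0.5) break
  }
  molecule(sample(symbols, n, replace = TRUE), coords,
           velocities = matrix(stats::rnorm(3 * n, sd = 0.01), ncol = 3))
}

# exhaustive isotopologue enumeration: the brute-force oracle for
# isotope_pattern on formulas with few atoms
enumerate_isotope_pattern <- function(f) {
  if (is.character(f)) f <- ms_formula(f)
  atoms <- rep(names(f), unclass(f))
  per_atom <- lapply(atoms, function(s) element_info(s)$isotopes)
  grids <- lapply(per_atom, function(iso) seq_len(nrow(iso)))
  combos <- expand.grid(grids)
  acc <- new.env()
  for (r in seq_len(nrow(combos))) {
    mz <- 0L; ab <- 1
    for (a in seq_along(atoms)) {
      iso <- per_atom[[a]][combos[r, a], ]
      mz <- mz + iso$mass_number
      ab <- ab * iso$abundance
    }
    key <- as.character(mz)
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + ab
  }
  mz <- as.integer(ls(acc))
  ord <- order(mz)
  data.frame(mz = mz[ord],
             abundance = vapply(as.character(mz[ord]),
                                function(k) acc[[k]], numeric(1)))
}

# recursive brute-force cascade-tree oracle: given a tree where each node
# splits into children with given weights, total stored charge must equal
# the root weight.  Builds random trees and sums leaf/stored charges the
# slow way, mirroring the multiply-down-the-cascade rule by direct
# recursion.
random_cascade_tree <- function(depth_left, n_children_max = 4) {
  if (depth_left == 0 || stats::runif(1) < 0.3) return(list(leaf = TRUE))
  n <- sample(2:n_children_max, 1)
  w <- stats::runif(n); w <- w / sum(w)
  kids <- vector("list", n)
  sel <- which.max(w)  # cascade continues through the dominant fragment
  for (i in seq_len(n))
    kids[[i]] <- if (i == sel) random_cascade_tree(depth_left - 1) else list(leaf = TRUE)
  list(leaf = FALSE, weights = w, selected = sel, children = kids)
}

oracle_cascade_total <- function(tree, parent_weight) {
  if (tree$leaf) return(parent_weight)
  total <- 0
  for (i in seq_along(tree$children))
    total <- total + oracle_cascade_total(tree$children[[i]],
                                          parent_weight * tree$weights[i])
  total
}

# drive assign_and_select down a prescribed tree, collecting stored charges;
# IPs are crafted so the intended child is the argmax (lowest IP)
walk_cascade_with_package <- function(tree, parent_weight, t_av = 2000) {
  stored <- numeric(0)
  recurse <- function(node, w, depth) {
    if (node$leaf) { stored <<- c(stored, w); return(invisible()) }
    n <- length(node$children)
    # invert the softmax: choose IPs reproducing the node's weights exactly
    ips <- -log(node$weights) * (eims_constants$KB_EV * t_av)
    mols <- lapply(seq_len(n), function(i)
      molecule(c("C", "H"), matrix(c(0, 0, 0, 1, 0, 0), ncol = 3,
                                   byrow = TRUE)))
    recs <- lapply(seq_len(n), function(i)
      fragment_record(mols[[i]], vertical_ip = ips[i], temperature = t_av,
                      cascade_depth = depth))
    out <- assign_and_select(recs, w, t_av = t_av, depth_cap = 50L)
    for (r in out$records) stored <<- c(stored, r$statistical_charge)
    if (!is.null(out$next_record)) {
      sel_pkg <- which.max(node$weights)
      recurse(node$children[[sel_pkg]], out$next_record$statistical_charge,
              depth + 1)
    }
  }
  recurse(tree, parent_weight, 0)
  stored
}
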