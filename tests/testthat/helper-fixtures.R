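# Fixture builders and independent oracles used across the suite.

# Hand-formatted PDB coordinate line (independent of the package writer).
pdb_line <- function(record = "ATOM", serial = 1, name = "CA", altloc = " ",
                     resid = "ALA", chain = "A", resno = 1, icode = " ",
                     x = 0, y = 0, z = 0, occ = 1, b = 0, elem = "C") {
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name),
          altloc, resid, chain, resno, icode, x, y, z, occ, b, elem)
}

# A small protein + ligand PDB text: n_res CA atoms along a 3.8 A walk plus
# ligand HETATM records at given coordinates.
protein_ligand_pdb <- function(ca_xyz, lig_xyz = NULL, lig_resid = "ATP",
                               lig_elem = "C") {
  lines <- character(0)
  for (i in seq_len(nrow(ca_xyz))) {
    lines <- c(lines, pdb_line(serial = i, resno = i, x = ca_xyz[i, 1],
                               y = ca_xyz[i, 2], z = ca_xyz[i, 3]))
  }
  if (!is.null(lig_xyz)) {
    for (j in seq_len(nrow(lig_xyz))) {
      lines <- c(lines, pdb_line(record = "HETATM",
                                 serial = nrow(ca_xyz) + j,
                                 name = paste0(lig_elem, j),
                                 resid = lig_resid, chain = "A",
                                 resno = 900 + 1, x = lig_xyz[j, 1],
                                 y = lig_xyz[j, 2], z = lig_xyz[j, 3],
                                 elem = lig_elem))
    }
  }
  c(lines, "END")
}

# Compact random-walk chain as a coarse model (consecutive nodes 3.8 A
# apart, hence always connected at the 7.5 A cutoff).
random_chain_model <- function(n, seed, cutoff = 7.5) {
  set.seed(seed)
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    u <- rnorm(3)
    xyz[i, ] <- xyz[i - 1, ] + 3.8 * u / sqrt(sum(u^2))
  }
  structure(list(xyz = xyz, role = rep("RESIDUE", n),
                 labels = data.frame(chain = "A", resno = seq_len(n),
                                     insert = "", name = "NODE",
                                     stringsAsFactors = FALSE),
                 cutoff = cutoff),
            class = "coarse_model")
}

# Brute-force Kirchhoff oracle: explicit double loop over node pairs.
brute_kirchhoff <- function(xyz, cutoff) {
  n <- nrow(xyz)
  g <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) {
        g[i, j] <- -1
      }
    }
  }
  diag(g) <- -rowSums(g)
  g
}

# Brute-force rigid-fit oracle: minimize RMSD over rotations by a coarse
# Euler-angle grid followed by Nelder-Mead refinement (translation handled
# by centroid matching).  Independent of the SVD route.
brute_fit_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
    Rz2 <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((A %*% t(rot(ang)) - B)^2)))
  grid <- seq(0, 2 * pi, by = pi / 6)
  best <- NULL; best_val <- Inf
  for (a1 in grid) for (a2 in seq(0, pi, by = pi / 6)) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best_val) { best_val <- v; best <- c(a1, a2, a3) }
  }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# The hand-checkable ligand-attachment example: three collinear residues
# 5 A apart plus one single-atom ligand within the cutoff of residue 1
# only.  The bound network is a 4-node path L-1-2-3.
worked_example_models <- function() {
  ca <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0))
  lig <- rbind(c(-5, 0, 0))
  txt <- protein_ligand_pdb(ca, lig, lig_resid = "LIG")
  model <- parse_pdb(txt, source_id = "worked")
  spec <- ligand_spec("LIG")
  list(model = model, spec = spec,
       bound = build_coarse_model(model, spec, cutoff = 7.5),
       unbound = build_coarse_model(strip_ligands(model, spec), NULL,
                                    cutoff = 7.5))
}

# Minimal delta_profile wrapper for arithmetic tests on given values.
delta_from_values <- function(values) {
  structure(c(list(delta = values, labels = NULL,
                   f_bound = values, f_unbound = rep(0, length(values))),
              gnmflux:::scale_delta(values)),
            class = "delta_profile")
}

# The seeded two-domain fixture analysis used by several regression tests.
two_domain_analysis <- function(decoy_seed = 20210901) {
  s <- make_two_domain_structure(n_residues = 80, ligand_atom_count = 5,
                                 seed = 1337)
  spec <- ligand_spec("LIG")
  bound <- build_coarse_model(s, spec)
  unbound <- build_coarse_model(strip_ligands(s, spec), NULL)
  f_bound <- gnm_fluctuations(bound)
  f_unbound <- gnm_fluctuations(unbound)
  delta <- delta_fluctuations(f_bound, f_unbound)
  decoy <- make_decoy(bound, decoy_seed)
  d_decoy <- delta_fluctuations(gnm_fluctuations(decoy$model), f_unbound)
  list(structure = s, spec = spec, bound = bound, unbound = unbound,
       delta = delta, d_decoy = d_decoy,
       summary = decoy_comparison(delta, d_decoy, seed = decoy_seed),
       radial = radial_profile(delta, bound))
}
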