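# Synthetic structure generators: ideal helices, a two-domain protein with
# a pocket-bound ligand, and analytic graph models with closed-form
# fluctuations.  These supply every structural feature the analysis relies
# on (compact C-alpha chains at ~3.8 A spacing, a ligand cluster in a
# surface pocket, known spectra) without any downloaded data.

atoms_from_ca <- function(xyz, chain = "A", start_resno = 1L) {
  n <- nrow(xyz)
  data.frame(
    record = "ATOM", serial = seq_len(n), name = "CA", altloc = "",
    resid = "ALA", chain = chain,
    resno = start_resno + seq_len(n) - 1L, insert = "",
    x = round(xyz[, 1], 3), y = round(xyz[, 2], 3), z = round(xyz[, 3], 3),
    occ = 1, b = 0, element = "C", stringsAsFactors = FALSE
  )
}

#' Generate an ideal alpha-helical C-alpha trace
#'
#' Standard helix geometry: 1.5 A rise and 100 degrees of turn per residue
#' on a 2.3 A radius, which places consecutive C-alpha atoms ~3.83 A apart.
#' Deterministic (no randomness involved).
#'
#' @param n_residues number of residues (>= 2).
#' @return a `gnm_structure` with one CA ATOM record per residue, chain A.
#' @export
make_helix_chain <- function(n_residues) {
  stopifnot(n_residues >= 2)
  i <- seq_len(n_residues) - 1
  theta <- i * 100 * pi / 180
  xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  structure(list(atoms = atoms_from_ca(xyz), source_id = "synthetic-helix",
                 model_number = 1L),
            class = "gnm_structure")
}

# Self-avoiding confined random walk: `n` points, fixed step, all inside a
# sphere (center, radius), non-consecutive points >= min_sep apart, with an
# optional extra acceptance predicate.  Errors after max_tries rejections.
confined_walk <- function(n, start, step, center, radius, min_sep = 3.0,
                          accept = NULL, prior = NULL, max_tries = 10000) {
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- start
  tries <- 0
  i <- 2
  while (i <= n) {
    u <- stats::rnorm(3)
    cand <- pts[i - 1, ] + step * u / sqrt(sum(u^2))
    ok <- sqrt(sum((cand - center)^2)) <= radius
    if (ok && i > 2) {
      prev <- pts[seq_len(i - 2), , drop = FALSE]
      ok <- min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep
    }
    if (ok && !is.null(prior) && nrow(prior) > 0) {
      ok <- min(sqrt(rowSums(sweep(prior, 2, cand)^2))) >= min_sep
    }
    if (ok && !is.null(accept)) ok <- accept(cand)
    if (ok) {
      pts[i, ] <- cand
      i <- i + 1
    } else {
      tries <- tries + 1
      if (tries > max_tries) {
        stop("random-walk placement failed after ", max_tries,
             " retries; try a different seed", call. = FALSE)
      }
    }
  }
  pts
}

#' Generate a two-domain structure with a pocket-bound ligand
#'
#' Builds two compact domains (self-avoiding 3.8 A random walks confined
#' to ~10 A spheres) joined by an extended 5-residue linker, and places a
#' small ligand cluster (het code LIG) in a surface pocket of domain 1 such
#' that every ligand atom is within 5 A of at least 3 pocket residues and
#' at least 25 A away from every domain-2 residue.  Generation is a pure
#' function of `(n_residues, ligand_atom_count, seed)`; the first feasible
#' placement under the seed is kept.
#'
#' @param n_residues total chain length (>= 30; 5 residues form the linker,
#'   the rest split between the domains).
#' @param ligand_atom_count number of ligand heavy atoms (>= 1; 1 gives an
#'   ion-like single-atom ligand).
#' @param seed integer seed.
#' @return a `gnm_structure` with `n_residues` CA ATOM records (chain A)
#'   followed by the ligand HETATM records (code LIG, chain L).  The pocket
#'   residue numbers are attached as attribute `pocket_residues`.
#' @export
make_two_domain_structure <- function(n_residues = 80, ligand_atom_count = 5,
                                      seed = 1337) {
  stopifnot(n_residues >= 30, ligand_atom_count >= 1)
  with_seed(seed, {
    for (attempt in seq_len(60)) {
      res <- tryCatch(
        two_domain_attempt(n_residues, ligand_atom_count),
        error = function(e) NULL)
      if (!is.null(res)) {
        atoms <- atoms_from_ca(res$ca)
        n <- nrow(res$ca)
        lig <- data.frame(
          record = "HETATM", serial = n + seq_len(nrow(res$lig)),
          name = paste0("C", seq_len(nrow(res$lig))), altloc = "",
          resid = "LIG", chain = "L", resno = 1L, insert = "",
          x = round(res$lig[, 1], 3), y = round(res$lig[, 2], 3),
          z = round(res$lig[, 3], 3),
          occ = 1, b = 0, element = "C", stringsAsFactors = FALSE
        )
        out <- structure(list(atoms = rbind(atoms, lig),
                              source_id = sprintf("synthetic-2dom-%d", seed),
                              model_number = 1L),
                         class = "gnm_structure")
        attr(out, "pocket_residues") <- res$pocket
        return(out)
      }
    }
    stop("two-domain generation failed repeatedly; try a different seed",
         call. = FALSE)
  })
}

two_domain_attempt <- function(n_residues, ligand_atom_count) {
  n_linker <- 5L
  n1 <- (n_residues - n_linker) %/% 2L
  n2 <- n_residues - n_linker - n1
  step <- 3.8
  r_dom <- 10

  # Domain 1 around the origin.
  d1 <- confined_walk(n1, start = c(0, 0, 0), step = step,
                      center = c(0, 0, 0), radius = r_dom)

  # Pocket: a surface residue on the -x face of domain 1 and its two
  # nearest neighbours define a patch; the ligand sits just outside its
  # centroid.  Scan candidate residues and push distances for a placement
  # that touches >= 3 residues without clashing into the chain.
  centroid1 <- colMeans(d1)
  pocket_center <- NULL
  pocket_res <- NULL
  for (cand in order(d1[, 1])[seq_len(min(6, n1))]) {
    near3 <- order(sqrt(rowSums(sweep(d1, 2, d1[cand, ])^2)))[1:3]
    patch <- colMeans(d1[near3, , drop = FALSE])
    outward <- patch - centroid1
    outward <- outward / sqrt(sum(outward^2))
    for (push in c(2.0, 2.5, 3.0, 3.5)) {
      ctr <- patch + push * outward
      dists <- sqrt(rowSums(sweep(d1, 2, ctr)^2))
      if (min(dists) >= 2.5 && sum(dists <= 5.0) >= 3 &&
          ctr[1] < centroid1[1]) {
        pocket_center <- ctr
        pocket_res <- which(dists <= 6.0)
        break
      }
    }
    if (!is.null(pocket_center)) break
  }
  if (is.null(pocket_center)) stop("no feasible surface pocket")

  # Ligand cluster: first atom at the pocket center, the rest within 1.5 A.
  in_pocket <- function(p) {
    sum(sqrt(rowSums(sweep(d1[pocket_res, , drop = FALSE], 2, p)^2))
        <= 5.0) >= 3
  }
  lig <- matrix(NA_real_, ligand_atom_count, 3)
  lig[1, ] <- pocket_center
  if (ligand_atom_count > 1) {
    for (j in 2:ligand_atom_count) {
      placed <- FALSE
      for (k in seq_len(200)) {
        cand <- pocket_center + stats::runif(3, -1.5, 1.5)
        sep_ok <- min(sqrt(rowSums(sweep(lig[seq_len(j - 1), , drop = FALSE],
                                         2, cand)^2))) >= 1.0
        clash <- min(sqrt(rowSums(sweep(d1, 2, cand)^2))) < 2.5
        if (sep_ok && in_pocket(cand) && !clash) {
          lig[j, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("ligand placement failed")
    }
  }
  if (!all(vapply(seq_len(ligand_atom_count),
                  function(j) in_pocket(lig[j, ]), logical(1)))) {
    stop("ligand drifted out of the pocket")
  }

  # Extended linker along +x from the last domain-1 residue, then domain 2
  # confined to a sphere further along +x, kept >= 25.5 A from the ligand.
  p_last <- d1[n1, ]
  linker <- t(vapply(seq_len(n_linker),
                     function(i) p_last + c(i * step, 0, 0), numeric(3)))
  c2 <- linker[n_linker, ] + c(9, 0, 0)
  far_from_lig <- function(p) {
    min(sqrt(rowSums(sweep(lig, 2, p)^2))) >= 25.5
  }
  if (!far_from_lig(linker[n_linker, ])) stop("linker too close to ligand")
  d2 <- confined_walk(n2 + 1L, start = linker[n_linker, ], step = step,
                      center = c2, radius = r_dom,
                      prior = rbind(d1, linker[-n_linker, , drop = FALSE]),
                      accept = far_from_lig)
  d2 <- d2[-1, , drop = FALSE]  # first row duplicates the linker end

  ca <- rbind(d1, linker, d2)
  # Final feasibility checks on the emitted coordinates.
  dom2_rows <- (n1 + n_linker + 1):n_residues
  lig_dom2 <- min(as.matrix(stats::dist(rbind(lig, ca[dom2_rows, ])))[
    seq_len(ligand_atom_count), -seq_len(ligand_atom_count)])
  if (lig_dom2 < 25) stop("ligand-domain2 separation violated")
  list(ca = ca, lig = lig, pocket = pocket_res)
}

#' Analytic graph models with closed-form fluctuations
#'
#' `"path"`: collinear nodes spaced 5 A (cutoff 7.5 A couples only
#' consecutive nodes), giving the path-graph Kirchhoff matrix whose
#' fluctuations follow the effective-resistance closed form.
#' `"complete"`: integer-lattice points inside a ball of radius 3.75 A, so
#' every pairwise distance is within the 7.5 A cutoff (complete graph) with
#' at least 1 A separation; infeasible for n beyond the lattice capacity.
#'
#' @param kind `"path"` or `"complete"`.
#' @param n number of nodes (>= 2).
#' @return a `coarse_model` with all-RESIDUE nodes and cutoff 7.5.
#' @export
make_analytic_model <- function(kind = c("path", "complete"), n) {
  kind <- match.arg(kind)
  stopifnot(n >= 2)
  xyz <- switch(kind,
    path = cbind(5 * (seq_len(n) - 1), 0, 0),
    complete = {
      r <- 3.75
      g <- expand.grid(x = -3:3, y = -3:3, z = -3:3)
      norms <- sqrt(rowSums(g^2))
      g <- g[norms <= r, , drop = FALSE]
      norms <- norms[norms <= r]
      ord <- order(norms, g$x, g$y, g$z)
      if (n > nrow(g)) {
        stop("complete graph infeasible: at most ", nrow(g),
             " nodes fit within the cutoff at 1 A separation", call. = FALSE)
      }
      as.matrix(g[ord[seq_len(n)], ])
    })
  xyz <- unname(as.matrix(xyz))
  structure(list(xyz = xyz, role = rep("RESIDUE", n),
                 labels = data.frame(chain = "A", resno = seq_len(n),
                                     insert = "", name = "NODE",
                                     stringsAsFactors = FALSE),
                 cutoff = 7.5),
            class = "coarse_model")
}

#' Closed-form path-graph fluctuations
#'
#' For the unit-spring path graph the effective resistance between nodes i
#' and j is |i - j|, and the pseudoinverse diagonal follows
#' `f_i = (sum_j R_ij)/N - (sum_{j<k} R_jk)/N^2`.  Used as an independent
#' oracle in validation.
#'
#' @param n number of path nodes.
#' @return numeric vector of the n fluctuation values.
#' @export
path_fluctuations_closed_form <- function(n) {
  i <- seq_len(n)
  rsum <- vapply(i, function(ii) sum(abs(ii - i)), numeric(1))
  total <- sum(rsum) / 2
  rsum / n - total / n^2
}
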