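# Gaussian network model core: Kirchhoff (connectivity) matrix, spectral
# decomposition, and per-node scalar fluctuations.  The spring constant is
# taken as 1, so fluctuations are reported in units of 1/gamma; every ratio
# statistic downstream is invariant to this scale.

#' Build the Kirchhoff connectivity matrix
#'
#' Nodes i != j are coupled (entry -1) when their Euclidean distance is at
#' most the cutoff r_c (inclusive); the diagonal holds the node degree so
#' every row sums to zero.  Residue-residue, residue-ligand and
#' ligand-ligand pairs are all treated identically under the single cutoff.
#'
#' @param model a `coarse_model`, or a numeric N x 3 coordinate matrix
#'   (then `cutoff` must be given).
#' @param cutoff spring cutoff in Angstrom; defaults to the model's stored
#'   cutoff.
#' @return an object of class `gnm_kirchhoff`: list with `gamma` (N x N
#'   symmetric matrix), `n`, and `cutoff`.
#' @export
build_kirchhoff <- function(model, cutoff = NULL) {
  if (inherits(model, "coarse_model")) {
    xyz <- model$xyz
    cutoff <- cutoff %||% model$cutoff
  } else {
    xyz <- as.matrix(model)
    if (is.null(cutoff)) stop("cutoff required for raw coordinates",
                              call. = FALSE)
  }
  n <- nrow(xyz)
  if (n < 2) stop("a GNM needs at least 2 nodes", call. = FALSE)
  if (any(!is.finite(xyz))) stop("non-finite node coordinates", call. = FALSE)
  d <- coord_dist(xyz)
  gamma <- ifelse(d <= cutoff, -1, 0)
  diag(gamma) <- 0
  diag(gamma) <- -rowSums(gamma)
  structure(list(gamma = unname(gamma), n = n, cutoff = cutoff),
            class = "gnm_kirchhoff")
}

# Connected components of the contact graph, by breadth-first search.
contact_components <- function(gamma) {
  n <- nrow(gamma)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(gamma[v, ] == -1 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Eigendecompose a Kirchhoff matrix
#'
#' Full symmetric eigendecomposition with eigenvalues in ascending order.
#' Zero modes (one per connected component of the contact graph) are
#' identified by a rank tolerance `max(N, 1) * eps * lambda_max`, floored
#' at 1e-10.  A disconnected network is an error by default, since in
#' practice it signals a structure-preparation mistake; set
#' `allow_disconnected = TRUE` to proceed with all zero modes excluded
#' (generalized-inverse semantics).
#'
#' @param k a `gnm_kirchhoff`.
#' @param allow_disconnected proceed on a network with more than one
#'   connected component.
#' @return an object of class `gnm_modes`: list with `values` (ascending
#'   eigenvalues), `vectors` (orthonormal columns, matching order),
#'   `zero_mode_count` and `zero_tolerance`.
#' @export
decompose_kirchhoff <- function(k, allow_disconnected = FALSE) {
  stopifnot(inherits(k, "gnm_kirchhoff"))
  eig <- eigen(k$gamma, symmetric = TRUE)
  ord <- order(eig$values)
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  lam_max <- max(values)
  tol <- max(max(k$n, 1) * .Machine$double.eps * lam_max, 1e-10)
  nzero <- sum(values < tol)
  if (nzero > 1 && !allow_disconnected) {
    comp <- contact_components(k$gamma)
    sizes <- sort(tabulate(comp), decreasing = TRUE)
    stop("contact graph is disconnected: ", max(comp),
         " components of sizes ", paste(sizes, collapse = ", "),
         "; pass allow_disconnected = TRUE to analyse anyway",
         call. = FALSE)
  }
  structure(list(values = values, vectors = vectors,
                 zero_mode_count = nzero, zero_tolerance = tol),
            class = "gnm_modes")
}

#' Per-node fluctuations from the mode spectrum
#'
#' The scalar fluctuation of node i is the sum over all nonzero modes of
#' `v_mi^2 / lambda_m`; zero modes (rigid-body motion of each connected
#' component) are excluded.  No mode truncation is applied.
#'
#' @param modes a `gnm_modes`.
#' @param labels optional data frame of node labels to carry along.
#' @param role optional per-node role vector (`"RESIDUE"`/`"LIGAND"`).
#' @return an object of class `fluct_profile`: list with `values` (per-node
#'   fluctuation, >= 0), `labels`, `role`.
#' @export
mode_fluctuations <- function(modes, labels = NULL, role = NULL) {
  stopifnot(inherits(modes, "gnm_modes"))
  keep <- modes$values > modes$zero_tolerance
  if (!any(keep)) {
    stop("degenerate model: no nonzero modes above tolerance", call. = FALSE)
  }
  v2 <- modes$vectors[, keep, drop = FALSE]^2
  f <- as.numeric(v2 %*% (1 / modes$values[keep]))
  structure(list(values = f, labels = labels, role = role),
            class = "fluct_profile")
}

#' Fluctuations from the Moore-Penrose pseudoinverse (independent route)
#'
#' Computes the diagonal of the generalized inverse of the Kirchhoff matrix
#' through `MASS::ginv` (an SVD-based rank-revealing solve), deliberately
#' independent of [mode_fluctuations()] so the two can cross-check each
#' other.
#'
#' @param k a `gnm_kirchhoff`.
#' @inheritParams mode_fluctuations
#' @return a `fluct_profile`.
#' @export
pseudoinverse_fluctuations <- function(k, labels = NULL, role = NULL) {
  stopifnot(inherits(k, "gnm_kirchhoff"))
  g <- MASS::ginv(k$gamma)
  structure(list(values = diag(g), labels = labels, role = role),
            class = "fluct_profile")
}

#' One-call fluctuation profile for a coarse model
#'
#' Convenience wrapper: Kirchhoff build, decomposition and mode sum, with
#' node labels and roles carried through.
#'
#' @param model a `coarse_model`.
#' @param allow_disconnected passed to [decompose_kirchhoff()].
#' @return a `fluct_profile`.
#' @export
gnm_fluctuations <- function(model, allow_disconnected = FALSE) {
  k <- build_kirchhoff(model)
  modes <- decompose_kirchhoff(k, allow_disconnected = allow_disconnected)
  out <- mode_fluctuations(modes, labels = model$labels, role = model$role)
  attr(out, "zero_mode_count") <- modes$zero_mode_count
  out
}

#' @export
print.fluct_profile <- function(x, ...) {
  cat(sprintf("<fluct_profile> %d nodes, sum f = %.6g\n",
              length(x$values), sum(x$values)))
  invisible(x)
}

#' Export node fluctuations as a TSV table
#'
#' @param profile a `fluct_profile` with labels.
#' @param file output path.
#' @return the written data frame, invisibly.
#' @export
write_fluctuation_tsv <- function(profile, file) {
  df <- if (!is.null(profile$labels)) {
    cbind(profile$labels, role = profile$role %||% "RESIDUE",
          f = profile$values)
  } else {
    data.frame(node = seq_along(profile$values), f = profile$values)
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
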