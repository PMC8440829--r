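# Ligand-perturbation analysis: bound-minus-unbound fluctuation differences,
# the increase/decrease ratio statistic, the seeded single-atom decoy
# control, and the radial decay profile of fluctuation change.

profile_residue_part <- function(profile) {
  if (is.null(profile$role)) {
    list(values = profile$values, labels = profile$labels)
  } else {
    keep <- profile$role == "RESIDUE"
    list(values = profile$values[keep],
         labels = profile$labels[keep, , drop = FALSE])
  }
}

check_label_alignment <- function(la, lb, what = "profiles") {
  ka <- residue_key(la$chain, la$resno, la$insert)
  kb <- residue_key(lb$chain, lb$resno, lb$insert)
  if (length(ka) != length(kb) || any(ka != kb)) {
    first <- which(ka[seq_len(min(length(ka), length(kb)))] !=
                   kb[seq_len(min(length(ka), length(kb)))])[1]
    detail <- if (!is.na(first)) {
      paste0("first divergent label at position ", first, ": '",
             ka[first], "' vs '", kb[first], "'")
    } else {
      paste0("lengths differ (", length(ka), " vs ", length(kb), ")")
    }
    stop("residue labels of the two ", what, " do not align: ", detail,
         call. = FALSE)
  }
  invisible(ka)
}

#' Fluctuation difference upon ligand binding
#'
#' Per-residue difference `delta_f = f(bound) - f(unbound)`.  Ligand nodes
#' of the bound profile are dropped; the residue label sets of the two
#' profiles must be identical and identically ordered.  Negative values
#' mark rigidified residues (typically the binding site); positive values
#' mark mobility gains (typically remote).  Signed 0-to-1 scalings for
#' visualization are included: gains scaled by the largest gain, losses by
#' the largest loss (most negative maps to -1).
#'
#' @param bound,unbound `fluct_profile` objects (bound may contain ligand
#'   nodes; unbound must be residue-only).
#' @return an object of class `delta_profile`: list with `delta`, `labels`,
#'   `f_bound`, `f_unbound`, `positive_scaled` (in \[0, 1\]) and
#'   `negative_scaled` (in \[-1, 0\]).
#' @export
delta_fluctuations <- function(bound, unbound) {
  b <- profile_residue_part(bound)
  u <- profile_residue_part(unbound)
  if (!is.null(b$labels) && !is.null(u$labels)) {
    check_label_alignment(b$labels, u$labels)
  } else if (length(b$values) != length(u$values)) {
    stop("bound and unbound profiles have different residue counts (",
         length(b$values), " vs ", length(u$values), ")", call. = FALSE)
  }
  delta <- b$values - u$values
  structure(c(list(delta = delta, labels = b$labels,
                   f_bound = b$values, f_unbound = u$values),
              scale_delta(delta)),
            class = "delta_profile")
}

# Per-structure max-normalized signed scaling (all-zero input stays zero).
scale_delta <- function(delta) {
  pos <- pmax(delta, 0)
  neg <- pmin(delta, 0)
  list(
    positive_scaled = if (any(pos > 0)) pos / max(pos) else pos,
    negative_scaled = if (any(neg < 0)) -neg / min(neg) else neg
  )
}

#' @export
print.delta_profile <- function(x, ...) {
  cat(sprintf("<delta_profile> %d residues: %d increase, %d decrease\n",
              length(x$delta), sum(x$delta > 0), sum(x$delta < 0)))
  invisible(x)
}

#' Increase/decrease ratio statistic
#'
#' Splits residues by the sign of `delta_f` (exact zeros, within
#' `zero_tol`, belong to neither set) and reports the mean gain, the mean
#' magnitude of loss, and their ratio as a percentage
#' `100 * mean_increase / mean_decrease`.  When either set is empty the
#' ratio is `NA` (undefined), with the counts still reported.
#'
#' @param d a `delta_profile`.
#' @param zero_tol magnitude below which a difference counts as zero.
#' @return an object of class `perturbation_summary`: list with
#'   `ratio_percent`, `mean_increase`, `mean_decrease`, `n_increase`,
#'   `n_decrease` (decoy fields unset).
#' @export
ratio_statistic <- function(d, zero_tol = 1e-12) {
  stopifnot(inherits(d, "delta_profile"))
  delta <- d$delta
  if (length(delta) == 0) stop("empty delta profile", call. = FALSE)
  inc <- delta[delta > zero_tol]
  dec <- delta[delta < -zero_tol]
  mean_increase <- if (length(inc)) mean(inc) else NA_real_
  mean_decrease <- if (length(dec)) mean(abs(dec)) else NA_real_
  ratio <- if (length(inc) && length(dec)) {
    100 * mean_increase / mean_decrease
  } else {
    NA_real_
  }
  structure(list(ratio_percent = ratio,
                 mean_increase = mean_increase,
                 mean_decrease = mean_decrease,
                 n_increase = length(inc),
                 n_decrease = length(dec),
                 decoy_mean_on_increase_set = NA_real_,
                 decoy_seed = NA_integer_),
            class = "perturbation_summary")
}

#' @export
print.perturbation_summary <- function(x, ...) {
  cat(sprintf(paste0("<perturbation_summary> ratio %.2f%% ",
                     "(mean +%.4g over %d, mean -%.4g over %d)\n"),
              x$ratio_percent, x$mean_increase, x$n_increase,
              x$mean_decrease, x$n_decrease))
  if (!is.na(x$decoy_mean_on_increase_set)) {
    cat(sprintf("  decoy mean on increase set: %.4g (seed %d)\n",
                x$decoy_mean_on_increase_set, x$decoy_seed))
  }
  invisible(x)
}

#' Build the single-atom decoy-ligand control
#'
#' Replaces the full ligand by one atom drawn uniformly at random from the
#' "bonded" pool: the ligand atoms lying within the cutoff of at least one
#' residue node.  The returned network keeps all residue nodes plus that
#' single ligand node.  The draw is reproducible under the seed.
#'
#' @param bound_model a `coarse_model` containing ligand nodes.
#' @param seed integer seed for the draw (logged with the result).
#' @return an object of class `decoy_model`: list with `model` (the decoy
#'   `coarse_model`), `decoy_index` (index into the bound model's nodes),
#'   `bonded_pool_size` and `seed`.
#' @export
make_decoy <- function(bound_model, seed) {
  stopifnot(inherits(bound_model, "coarse_model"))
  lig_idx <- which(bound_model$role == "LIGAND")
  res_idx <- which(bound_model$role == "RESIDUE")
  if (length(lig_idx) == 0) {
    stop("bound model has no ligand nodes", call. = FALSE)
  }
  d <- coord_dist(bound_model$xyz)
  bonded <- lig_idx[vapply(lig_idx, function(i) {
    any(d[i, res_idx] <= bound_model$cutoff)
  }, logical(1))]
  if (length(bonded) == 0) {
    stop("no ligand atom lies within ", bound_model$cutoff,
         " A of any residue node (no contacts)", call. = FALSE)
  }
  pick <- with_seed(seed, bonded[sample.int(length(bonded), 1)])
  keep <- c(res_idx, pick)
  decoy <- structure(list(xyz = bound_model$xyz[keep, , drop = FALSE],
                          role = bound_model$role[keep],
                          labels = bound_model$labels[keep, , drop = FALSE],
                          cutoff = bound_model$cutoff),
                     class = "coarse_model")
  rownames(decoy$labels) <- NULL
  structure(list(model = decoy, decoy_index = pick,
                 bonded_pool_size = length(bonded), seed = as.integer(seed)),
            class = "decoy_model")
}

#' Compare decoy and known-ligand difference profiles
#'
#' Restricted to the residues where the known ligand increases
#' fluctuations, reports the mean of the decoy's differences on exactly
#' that set.  This set-restricted mean can legitimately be negative: the
#' decoy may reduce mobility where the real ligand enhanced it.
#'
#' @param d_known `delta_profile` from the real ligand.
#' @param d_decoy `delta_profile` from the decoy network (same residues).
#' @param seed the decoy seed, carried into the summary for logging.
#' @param zero_tol as in [ratio_statistic()].
#' @return a `perturbation_summary` of the known ligand with the decoy
#'   fields set.
#' @export
decoy_comparison <- function(d_known, d_decoy, seed = NA_integer_,
                             zero_tol = 1e-12) {
  stopifnot(inherits(d_known, "delta_profile"),
            inherits(d_decoy, "delta_profile"))
  if (!is.null(d_known$labels) && !is.null(d_decoy$labels)) {
    check_label_alignment(d_known$labels, d_decoy$labels, "difference profiles")
  } else if (length(d_known$delta) != length(d_decoy$delta)) {
    stop("difference profiles have different residue counts", call. = FALSE)
  }
  out <- ratio_statistic(d_known, zero_tol = zero_tol)
  inc_set <- d_known$delta > zero_tol
  out$decoy_mean_on_increase_set <-
    if (any(inc_set)) mean(d_decoy$delta[inc_set]) else NA_real_
  out$decoy_seed <- as.integer(seed)
  out
}

#' Radial profile of fluctuation change
#'
#' Bins residues by their minimum distance to any ligand atom and reports
#' the mean difference and count per bin, exposing the decay of the
#' perturbation with distance from the binding pocket.
#'
#' @param d a `delta_profile`.
#' @param bound_model the bound `coarse_model` (provides ligand positions).
#' @param bin_width bin width in Angstrom (default 2.5).
#' @return an object of class `radial_profile`: list with `bin_edges`
#'   (length nbins + 1), `mean_delta`, `counts`, `min_distance` (per
#'   residue).
#' @export
radial_profile <- function(d, bound_model, bin_width = 2.5) {
  stopifnot(inherits(d, "delta_profile"),
            inherits(bound_model, "coarse_model"), bin_width > 0)
  lig_idx <- which(bound_model$role == "LIGAND")
  res_idx <- which(bound_model$role == "RESIDUE")
  if (length(lig_idx) == 0) {
    stop("bound model has no ligand nodes", call. = FALSE)
  }
  if (length(res_idx) != length(d$delta)) {
    stop("delta profile and bound model disagree on residue count",
         call. = FALSE)
  }
  dm <- coord_dist(bound_model$xyz)
  min_dist <- unname(apply(dm[res_idx, lig_idx, drop = FALSE], 1, min))
  nbins <- max(1L, ceiling(max(min_dist) / bin_width))
  edges <- seq(0, nbins * bin_width, by = bin_width)
  bin <- pmin(pmax(ceiling(min_dist / bin_width), 1L), nbins)
  mean_delta <- vapply(seq_len(nbins), function(b) {
    if (any(bin == b)) mean(d$delta[bin == b]) else NA_real_
  }, numeric(1))
  counts <- tabulate(bin, nbins)
  structure(list(bin_edges = edges, mean_delta = mean_delta,
                 counts = counts, min_distance = min_dist),
            class = "radial_profile")
}

#' Export a difference profile as a TSV table
#'
#' Columns: chain, residue number, insertion code, bound and unbound
#' fluctuation, difference, the two signed scalings, and (when a bound
#' model is given) the minimum distance to the ligand.
#'
#' @param d a `delta_profile`.
#' @param file output path.
#' @param bound_model optional bound `coarse_model` for ligand distances.
#' @return the written data frame, invisibly.
#' @export
write_delta_tsv <- function(d, file, bound_model = NULL) {
  df <- data.frame(
    chain = d$labels$chain %||% NA,
    residue_seq = d$labels$resno %||% seq_along(d$delta),
    insertion_code = d$labels$insert %||% "",
    f_bound = d$f_bound, f_unbound = d$f_unbound, delta_f = d$delta,
    positive_scaled = d$positive_scaled,
    negative_scaled = d$negative_scaled,
    stringsAsFactors = FALSE
  )
  if (!is.null(bound_model)) {
    rp <- radial_profile(d, bound_model)
    df$min_ligand_distance <- rp$min_distance
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
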