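# End-to-end pipeline: single-structure analysis and the manifest-driven
# batch screen, with deterministic file outputs and structured stage logs.

#' Configuration for one bound-structure analysis
#'
#' @param input path to a PDB file of the ligand-bound structure.
#' @param ligand_codes character vector of het codes identifying the ligand.
#' @param cutoff spring cutoff in Angstrom (default 7.5).
#' @param decoy_seeds integer vector, one decoy draw per seed (default
#'   20210901).
#' @param chains optional chain filter for the ligand selection.
#' @param bin_width radial bin width in Angstrom (default 2.5).
#' @param model_number coordinate model to read (default 1).
#' @param allow_disconnected proceed on a disconnected contact graph.
#' @param output_dir directory receiving the three artifacts.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(input, ligand_codes, cutoff = 7.5,
                            decoy_seeds = 20210901L, chains = NULL,
                            bin_width = 2.5, model_number = 1L,
                            allow_disconnected = FALSE,
                            output_dir = ".") {
  stopifnot(cutoff > 0, length(ligand_codes) >= 1)
  structure(list(input = input, ligand_codes = ligand_codes, cutoff = cutoff,
                 decoy_seeds = as.integer(decoy_seeds), chains = chains,
                 bin_width = bin_width, model_number = as.integer(model_number),
                 allow_disconnected = allow_disconnected,
                 output_dir = output_dir),
            class = "analysis_config")
}

summary_row <- function(id, codes, n_res, s) {
  data.frame(pdb_id = id, ligand_codes = paste(codes, collapse = ","),
             n_residues = n_res, n_increase = s$n_increase,
             n_decrease = s$n_decrease, mean_increase = s$mean_increase,
             mean_decrease = s$mean_decrease, ratio_percent = s$ratio_percent,
             decoy_seed = s$decoy_seed,
             decoy_mean_on_increase_set = s$decoy_mean_on_increase_set,
             stringsAsFactors = FALSE)
}

#' Run the full analysis for one bound structure
#'
#' Parses the structure, builds the bound and ligand-stripped coarse
#' models, computes both fluctuation profiles and their difference, the
#' ratio statistic, one decoy control per seed, and the radial profile;
#' writes a per-residue TSV, a summary TSV (one row per decoy seed), and a
#' PDB with the difference painted into the B-factor column.
#'
#' @param config an [analysis_config()].
#' @return invisibly, a list with `delta`, `summary` (data frame),
#'   `radial`, and the paths of the written artifacts.
#' @export
run_single <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(config$input) && length(config$input) == 1 &&
      !file.exists(config$input)) {
    stop("input file not found: ", config$input, call. = FALSE)
  }
  model <- parse_pdb(config$input, model_number = config$model_number)
  spec <- ligand_spec(config$ligand_codes, chains = config$chains)

  bound_cm <- build_coarse_model(model, spec, cutoff = config$cutoff)
  stripped <- strip_ligands(model, spec)
  unbound_cm <- build_coarse_model(stripped, NULL, cutoff = config$cutoff)
  log_stage("coarse_model", id = model$source_id,
            n_residues = sum(bound_cm$role == "RESIDUE"),
            n_ligand_atoms = sum(bound_cm$role == "LIGAND"),
            cutoff = config$cutoff)

  f_bound <- gnm_fluctuations(bound_cm,
                              allow_disconnected = config$allow_disconnected)
  f_unbound <- gnm_fluctuations(unbound_cm,
                                allow_disconnected = config$allow_disconnected)
  log_stage("gnm",
            zero_modes_bound = attr(f_bound, "zero_mode_count"),
            zero_modes_unbound = attr(f_unbound, "zero_mode_count"))

  delta <- delta_fluctuations(f_bound, f_unbound)
  radial <- radial_profile(delta, bound_cm, bin_width = config$bin_width)

  rows <- lapply(config$decoy_seeds, function(seed) {
    decoy <- make_decoy(bound_cm, seed)
    f_decoy <- gnm_fluctuations(decoy$model,
                                allow_disconnected = config$allow_disconnected)
    d_decoy <- delta_fluctuations(f_decoy, f_unbound)
    s <- decoy_comparison(delta, d_decoy, seed = seed)
    log_stage("decoy", seed = seed, pool = decoy$bonded_pool_size,
              pick = decoy$decoy_index)
    summary_row(model$source_id, spec$het_codes,
                sum(bound_cm$role == "RESIDUE"), s)
  })
  summary_df <- do.call(rbind, rows)

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(config$output_dir, model$source_id)
  paths <- c(profile = paste0(base, "_delta.tsv"),
             summary = paste0(base, "_summary.tsv"),
             pdb = paste0(base, "_delta.pdb"))
  write_delta_tsv(delta, paths["profile"], bound_model = bound_cm)
  utils::write.table(summary_df, paths["summary"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bmap <- data.frame(chain = delta$labels$chain, resno = delta$labels$resno,
                     insert = delta$labels$insert, value = delta$delta)
  write_bfactor_pdb(stripped, bmap, file = paths["pdb"])
  log_stage("write", dir = config$output_dir)

  invisible(list(delta = delta, summary = summary_df, radial = radial,
                 paths = paths))
}

#' Run a manifest of analyses (batch screen)
#'
#' One summary row per manifest entry, in manifest order; a failing entry
#' is recorded as a failure row without aborting the batch.
#'
#' @param manifest data frame with columns `pdb_path`, `ligand_codes`
#'   (comma-separated het codes), and optional `chain_filter` and `seeds`
#'   (comma-separated decoy seeds).
#' @param output_dir directory for per-structure artifacts and the batch
#'   summary TSV.
#' @param cutoff,bin_width shared analysis parameters.
#' @return a data frame: the summary rows plus `status`
#'   (`"ok"`/`"failed"`) and `error` columns, with attribute `n_failed`.
#' @export
run_manifest <- function(manifest, output_dir = ".", cutoff = 7.5,
                         bin_width = 2.5) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1,
            all(c("pdb_path", "ligand_codes") %in% names(manifest)))
  split_field <- function(x) {
    if (is.null(x) || is.na(x) || !nzchar(x)) NULL
    else trimws(strsplit(x, ",")[[1]])
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    entry <- manifest[i, ]
    codes <- split_field(entry$ligand_codes)
    seeds <- split_field(if ("seeds" %in% names(manifest)) entry$seeds else NULL)
    seeds <- if (is.null(seeds)) 20210901L else as.integer(seeds)
    chains <- split_field(if ("chain_filter" %in% names(manifest))
                            entry$chain_filter else NULL)
    res <- tryCatch({
      cfg <- analysis_config(entry$pdb_path, codes, cutoff = cutoff,
                             decoy_seeds = seeds, chains = chains,
                             bin_width = bin_width, output_dir = output_dir)
      out <- run_single(cfg)
      cbind(out$summary, status = "ok", error = "",
            stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(pdb_id = basename(as.character(entry$pdb_path)),
                 ligand_codes = paste(codes, collapse = ","),
                 n_residues = NA_integer_, n_increase = NA_integer_,
                 n_decrease = NA_integer_, mean_increase = NA_real_,
                 mean_decrease = NA_real_, ratio_percent = NA_real_,
                 decoy_seed = NA_integer_,
                 decoy_mean_on_increase_set = NA_real_,
                 status = "failed", error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(out, file.path(output_dir, "screen_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  attr(out, "n_failed") <- sum(out$status == "failed")
  out
}
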