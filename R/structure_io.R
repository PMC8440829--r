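# Structure input/output and preparation: PDB parsing, ligand selection and
# stripping, coarse-graining to the GNM node set, rigid superposition and
# ligand transplantation, and B-factor painting for visualization.

WATER_CODES <- c("HOH", "WAT", "DOD")

#' Parse a PDB-format structure
#'
#' Reads fixed-column ATOM/HETATM records from a PDB file or character
#' vector of lines, keeping a single coordinate model.  Alternate locations
#' are resolved to one atom per (chain, residue, insertion code, atom name):
#' the highest-occupancy copy wins, ties going to the lexicographically
#' smallest altloc identifier.  Waters and hydrogens are retained at this
#' stage; filtering is the job of downstream selectors.
#'
#' @param input path to a PDB file, or a character vector of PDB lines.
#' @param model_number which coordinate model to keep (default 1, the only
#'   model in crystal structures; further NMR models are ignored).
#' @param source_id identifier stored on the result (defaults to the file
#'   base name, or `"inline"` for text input).
#' @return an object of class `gnm_structure`: a list with `atoms` (a
#'   data frame with one row per retained atom: `record`, `serial`, `name`,
#'   `altloc`, `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `occ`,
#'   `b`, `element`), `source_id` and `model_number`.
#' @export
parse_pdb <- function(input, model_number = 1L, source_id = NULL) {
  stopifnot(is.character(input), length(input) >= 1)
  from_file <- length(input) == 1 && !grepl("\n", input) && file.exists(input)
  if (from_file) {
    path <- input
    lines <- readLines(path, warn = FALSE)
    source_id <- source_id %||% sub("\\.(pdb|ent)$", "",
                                    basename(path), ignore.case = TRUE)
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE))
    source_id <- source_id %||% "inline"
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path))
  }

  is_coord <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_coord)) {
    stop("no ATOM/HETATM coordinate records found in '", source_id, "'",
         call. = FALSE)
  }
  # Fail early, naming the offending line, on malformed coordinate fields.
  for (i in which(is_coord)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed coordinate record (too short) at line ", i, ": ", ln,
           call. = FALSE)
    }
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (anyNA(coords) || any(!is.finite(coords))) {
      stop("malformed coordinate fields at line ", i, ": ", ln, call. = FALSE)
    }
  }

  pdb <- suppressWarnings(suppressMessages(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)))
  at <- pdb$atom
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  model_number <- as.integer(model_number)
  if (model_number < 1 || model_number > n_models) {
    stop("model_number ", model_number, " not present (file has ",
         n_models, " model(s))", call. = FALSE)
  }
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model_number, ] else as.numeric(pdb$xyz)
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)

  atoms <- data.frame(
    record = at$type,
    serial = at$eleno,
    name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resid = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    element = ifelse(is.na(at$elesy), "", at$elesy),
    stringsAsFactors = FALSE
  )

  # Altloc resolution: one copy per (chain, resno, insert, atom name).
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "|")
  if (anyDuplicated(key)) {
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key)[unique(key)],
                          function(idx) {
      if (length(idx) == 1) return(idx)
      sub <- atoms[idx, ]
      best <- idx[sub$occ == max(sub$occ)]
      if (length(best) > 1) {
        best <- best[order(atoms$altloc[best])][1]
      }
      best
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
    rownames(atoms) <- NULL
  }

  structure(list(atoms = atoms, source_id = source_id,
                 model_number = model_number),
            class = "gnm_structure")
}

#' @export
print.gnm_structure <- function(x, ...) {
  n_het <- sum(x$atoms$record == "HETATM")
  cat(sprintf("<gnm_structure> %s: %d atoms (%d ATOM, %d HETATM), model %d\n",
              x$source_id, nrow(x$atoms), nrow(x$atoms) - n_het, n_het,
              x$model_number))
  invisible(x)
}

#' Describe the ligand to analyse
#'
#' @param het_codes character vector of 3-letter hetero residue codes
#'   (e.g. `"ATP"`, `"MG"`).  Water codes (HOH/WAT/DOD) are rejected.
#' @param chains optional chain identifiers restricting the selection.
#' @return an object of class `ligand_spec`.
#' @export
ligand_spec <- function(het_codes, chains = NULL) {
  het_codes <- toupper(trimws(het_codes))
  if (length(het_codes) == 0 || any(!nzchar(het_codes))) {
    stop("het_codes must be a non-empty set of residue codes", call. = FALSE)
  }
  if (any(het_codes %in% WATER_CODES)) {
    stop("water (", paste(intersect(het_codes, WATER_CODES), collapse = ", "),
         ") cannot be selected as a ligand", call. = FALSE)
  }
  structure(list(het_codes = unique(het_codes), chains = chains),
            class = "ligand_spec")
}

empty_selection_error <- function(spec) {
  stop(structure(class = c("gnmflux_empty_selection", "error", "condition"),
                 list(message = paste0("empty ligand selection: no HETATM ",
                                       "atoms match codes {",
                                       paste(spec$het_codes, collapse = ", "),
                                       "}"),
                      call = NULL, codes = spec$het_codes)))
}

ligand_atom_rows <- function(model, spec, heavy_only = TRUE) {
  a <- model$atoms
  sel <- a$record == "HETATM" & a$resid %in% spec$het_codes
  if (!is.null(spec$chains)) sel <- sel & a$chain %in% spec$chains
  if (heavy_only) sel <- sel & !(toupper(a$element) %in% c("H", "D"))
  which(sel)
}

#' Select ligand heavy atoms
#'
#' Returns all non-hydrogen HETATM records whose residue code matches the
#' spec (and chain filter, when given), in file order.
#'
#' @param model a `gnm_structure`.
#' @param spec a [ligand_spec()].
#' @return data frame of the matching atom records.
#' @export
select_ligand_atoms <- function(model, spec) {
  rows <- ligand_atom_rows(model, spec, heavy_only = TRUE)
  if (length(rows) == 0) empty_selection_error(spec)
  model$atoms[rows, , drop = FALSE]
}

#' Remove ligand residues to create the unbound form
#'
#' Deletes every atom of the hetero residues matched by the spec; all other
#' atoms are unchanged and keep their original order.
#'
#' @inheritParams select_ligand_atoms
#' @return a `gnm_structure` without the matching ligand atoms.
#' @export
strip_ligands <- function(model, spec) {
  rows <- ligand_atom_rows(model, spec, heavy_only = FALSE)
  if (length(rows) == 0) empty_selection_error(spec)
  out <- model
  out$atoms <- model$atoms[-rows, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Coarse-grain a structure to the GNM node set
#'
#' Each residue possessing a C-alpha atom contributes one node (file
#' order); when a ligand spec is given, one node per selected ligand heavy
#' atom is appended after the residue nodes.  All nodes interact through
#' the same distance cutoff.
#'
#' @param model a `gnm_structure`.
#' @param spec a [ligand_spec()] or `NULL` for a protein-only model.
#' @param cutoff spring cutoff r_c in Angstrom (default 7.5).
#' @return an object of class `coarse_model`: list with `xyz` (N x 3
#'   matrix), `role` (`"RESIDUE"`/`"LIGAND"` per node), `labels` (data
#'   frame `chain`, `resno`, `insert`, `name`) and `cutoff`.
#' @export
build_coarse_model <- function(model, spec = NULL, cutoff = 7.5) {
  stopifnot(cutoff > 0)
  a <- model$atoms
  prot <- a[a$record == "ATOM", , drop = FALSE]
  res_key <- residue_key(prot$chain, prot$resno, prot$insert)
  res_order <- unique(res_key)
  is_ca <- prot$name == "CA" & toupper(prot$element) != "CA"
  ca <- prot[is_ca, , drop = FALSE]
  ca_key <- residue_key(ca$chain, ca$resno, ca$insert)
  ca <- ca[!duplicated(ca_key), , drop = FALSE]
  ca_key <- ca_key[!duplicated(ca_key)]
  missing <- setdiff(res_order, ca_key)
  if (length(missing) > 0) {
    warning(length(missing), " residue(s) lack a CA atom and were skipped: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "", call. = FALSE)
  }
  # residue nodes in file order
  ca <- ca[order(match(ca_key, res_order)), , drop = FALSE]

  xyz <- as.matrix(ca[, c("x", "y", "z")])
  role <- rep("RESIDUE", nrow(ca))
  labels <- data.frame(chain = ca$chain, resno = ca$resno,
                       insert = ca$insert, name = ca$resid,
                       stringsAsFactors = FALSE)

  if (!is.null(spec)) {
    lig <- select_ligand_atoms(model, spec)
    xyz <- rbind(xyz, as.matrix(lig[, c("x", "y", "z")]))
    role <- c(role, rep("LIGAND", nrow(lig)))
    labels <- rbind(labels,
                    data.frame(chain = lig$chain, resno = lig$resno,
                               insert = lig$insert,
                               name = paste(lig$resid, lig$name, sep = ":"),
                               stringsAsFactors = FALSE))
  }
  if (nrow(xyz) < 2) {
    stop("model too small: a GNM needs at least 2 nodes, got ", nrow(xyz),
         call. = FALSE)
  }
  if (any(!is.finite(xyz))) stop("non-finite node coordinates", call. = FALSE)
  rownames(xyz) <- NULL
  rownames(labels) <- NULL
  structure(list(xyz = xyz, role = role, labels = labels, cutoff = cutoff),
            class = "coarse_model")
}

#' @export
print.coarse_model <- function(x, ...) {
  cat(sprintf("<coarse_model> %d nodes (%d residue, %d ligand), cutoff %.2f A\n",
              nrow(x$xyz), sum(x$role == "RESIDUE"), sum(x$role == "LIGAND"),
              x$cutoff))
  invisible(x)
}

#' Kabsch rigid-body superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' mobile points onto the reference points (paired, equal length).
#'
#' @param mobile,reference numeric matrices (n x 3) of paired coordinates,
#'   n >= 3 and not all collinear.
#' @return list with `rotation` (3 x 3, determinant +1), `translation`
#'   (length-3), and `rmsd` in Angstrom.  The fit of a point `p` (row
#'   vector) is `p %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    stop("mobile and reference must be equal-size n x 3 matrices",
         call. = FALSE)
  }
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 point pairs for superposition",
                  call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (qr(A)$rank < 2 || qr(B)$rank < 2) {
    stop("degenerate (collinear) point configuration", call. = FALSE)
  }
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- as.numeric(cr - R %*% cm)
  fitted <- mobile %*% t(R) + matrix(t_vec, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

anchor_ca_xyz <- function(model, anchors) {
  a <- model$atoms
  ca <- a[a$record == "ATOM" & a$name == "CA", , drop = FALSE]
  want <- residue_key(anchors$chain, anchors$resno,
                      anchors$insert %||% rep("", nrow(anchors)))
  idx <- match(want, residue_key(ca$chain, ca$resno, ca$insert))
  if (anyNA(idx)) {
    stop("anchor residue(s) without CA atom: ",
         paste(want[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  as.matrix(ca[idx, c("x", "y", "z")])
}

#' Transplant a ligand between structures
#'
#' Superposes the donor onto the acceptor over paired anchor residues
#' (C-alpha atoms), applies the resulting rigid transform to the donor's
#' selected ligand atoms, and appends them to the acceptor as HETATM
#' records.  This is how composite bound models are assembled when the
#' ligand and the target protein come from different crystal structures.
#'
#' @param donor,acceptor `gnm_structure` objects.
#' @param spec [ligand_spec()] selecting the donor ligand.
#' @param anchors list with data frames `donor` and `acceptor`, each with
#'   columns `chain`, `resno` (and optional `insert`), paired row by row.
#' @return the acceptor with the transformed ligand atoms appended; the
#'   superposition `rmsd` is attached as an attribute.
#' @export
transplant_ligand <- function(donor, acceptor, spec, anchors) {
  lig <- select_ligand_atoms(donor, spec)
  mob <- anchor_ca_xyz(donor, anchors$donor)
  ref <- anchor_ca_xyz(acceptor, anchors$acceptor)
  fit <- kabsch_superpose(mob, ref)
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  moved <- lig_xyz %*% t(fit$rotation) +
    matrix(fit$translation, nrow(lig_xyz), 3, byrow = TRUE)
  lig$x <- moved[, 1]; lig$y <- moved[, 2]; lig$z <- moved[, 3]
  lig$record <- "HETATM"
  max_serial <- max(acceptor$atoms$serial, 0)
  lig$serial <- max_serial + seq_len(nrow(lig))
  out <- acceptor
  out$atoms <- rbind(acceptor$atoms, lig)
  rownames(out$atoms) <- NULL
  attr(out, "superpose_rmsd") <- fit$rmsd
  out
}

format_pdb_atom_line <- function(rec) {
  name <- rec$name
  # PDB convention: short atom names start in column 14.
  name_fmt <- if (nchar(name) >= 4) substr(name, 1, 4)
              else sprintf(" %-3s", name)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec$record, rec$serial %% 100000L, name_fmt,
          substr(rec$altloc, 1, 1), rec$resid, rec$chain, rec$resno,
          ifelse(rec$insert == "", " ", rec$insert),
          rec$x, rec$y, rec$z, rec$occ, rec$b, rec$element)
}

#' Write a structure in PDB format
#'
#' @param model a `gnm_structure`.
#' @param file optional path; when `NULL` the lines are returned invisibly.
#' @return character vector of PDB lines, invisibly.
#' @export
write_pdb <- function(model, file = NULL) {
  a <- model$atoms
  lines <- vapply(seq_len(nrow(a)),
                  function(i) format_pdb_atom_line(a[i, ]), character(1))
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Paint per-residue values into the B-factor column
#'
#' Every atom of a residue receives that residue's value in the temperature
#' factor column (clamped to the PDB-printable range \[-99.99, 999.99\] and
#' formatted `%6.2f`); atoms of residues absent from the map keep their
#' original B-factor.  Used to carry fluctuation differences into molecular
#' viewers.
#'
#' @param model a `gnm_structure`.
#' @param values either a named numeric vector keyed by
#'   `"chain|resno|insert"` or a data frame with columns `chain`, `resno`,
#'   optional `insert`, and `value`.
#' @param file optional output path.
#' @return character vector of PDB lines, invisibly.
#' @export
write_bfactor_pdb <- function(model, values, file = NULL) {
  if (is.data.frame(values)) {
    keys <- residue_key(values$chain, values$resno,
                        values$insert %||% rep("", nrow(values)))
    values <- stats::setNames(values$value, keys)
  }
  a <- model$atoms
  model_keys <- residue_key(a$chain, a$resno, a$insert)
  unknown <- setdiff(names(values), model_keys)
  if (length(unknown) > 0) {
    stop("residue key(s) not present in the model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hit <- match(model_keys, names(values))
  b <- a$b
  b[!is.na(hit)] <- values[hit[!is.na(hit)]]
  out <- model
  out$atoms$b <- pmin(pmax(b, -99.99), 999.99)
  write_pdb(out, file)
}
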