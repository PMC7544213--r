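# PDB input/output, delegating the format to bio3d and returning the
# atom-level tibble the rest of the package works on.

#' Coerce a bio3d atom table to the package's structure tibble
#' @noRd
structure_tibble <- function(resno, resid, elety, x, y, z, domains = NULL) {
  out <- tibble(
    residue_number = as.integer(resno),
    residue_name   = as.character(resid),
    atom_name      = trimws(as.character(elety)),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)
  )
  if (!all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    abort("structure contains non-finite coordinates")
  }
  attr(out, "domains") <- domains
  class(out) <- c("nmr_structure", class(tibble()))
  out
}

#' Domain definitions of a structure
#'
#' @param structure A structure tibble.
#' @return A tibble with columns `start`, `end`, `label`, or `NULL` when the
#'   structure carries no domain annotation.
#' @export
structure_domains <- function(structure) attr(structure, "domains")

#' Attach domain labels to a structure
#'
#' @param structure A structure tibble.
#' @param domains A tibble/data frame with columns `start`, `end`, `label`;
#'   residue ranges of distinct domains must be disjoint.
#' @return The structure with the `domains` attribute set.
#' @export
set_structure_domains <- function(structure, domains) {
  domains <- as_tibble(domains)
  stopifnot(all(c("start", "end", "label") %in% names(domains)))
  if (nrow(domains) > 1L) {
    rng <- domains[order(domains$start), ]
    if (any(rng$start[-1] <= rng$end[-nrow(rng)])) {
      abort("domain residue ranges must be disjoint")
    }
  }
  attr(structure, "domains") <- domains
  structure
}

#' Domain label per residue
#' @noRd
domain_of_residue <- function(structure, residues) {
  dom <- structure_domains(structure)
  if (is.null(dom)) return(rep(NA_character_, length(residues)))
  out <- rep(NA_character_, length(residues))
  for (i in seq_len(nrow(dom))) {
    out[residues >= dom$start[i] & residues <= dom$end[i]] <- dom$label[i]
  }
  out
}

#' Read a structure from a PDB file
#'
#' Reads ATOM records via bio3d. Residue numbering is taken verbatim from
#' the file; alternate locations other than blank or `'A'` are dropped.
#'
#' @param path Path to the PDB file.
#' @param model_index Which MODEL to take when the file holds several
#'   (default 1, i.e. the first model or the whole file when there are no
#'   MODEL records).
#' @param chain_id Optional chain identifier; an error listing the available
#'   chains is raised when absent from the file.
#' @return A structure tibble (`residue_number`, `residue_name`,
#'   `atom_name`, `x`, `y`, `z`).
#' @export
read_pdb <- function(path, model_index = 1, chain_id = NULL) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) abort(sprintf("failed to read '%s': %s", path, conditionMessage(e)))
  )
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) {
    abort(sprintf("'%s' contains no ATOM records", path))
  }
  keep_alt <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep_alt, , drop = FALSE]
  if (!is.null(chain_id)) {
    chains <- unique(at$chain)
    if (!chain_id %in% chains) {
      abort(sprintf("chain '%s' not in '%s'; available chains: %s",
                    chain_id, path, paste(chains, collapse = ", ")))
    }
    at <- at[at$chain == chain_id, , drop = FALSE]
  }
  n_models <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > n_models) {
    abort(sprintf("model_index %d out of range; '%s' has %d model(s)",
                  model_index, path, n_models))
  }
  # row indices of retained atoms within the original atom table give the
  # xyz triplets of the requested model
  idx <- as.integer(rownames(at))
  if (anyNA(idx)) idx <- which(pdb$atom$type == "ATOM")[seq_len(nrow(at))]
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
  structure_tibble(at$resno, at$resid, at$elety, xyz[, 1], xyz[, 2], xyz[, 3])
}

#' Write a structure to a PDB file, optionally carrying per-residue values
#'
#' Writes fixed-column ATOM records via bio3d. When `bfactor_values` is
#' given (a numeric vector named by residue number) each atom's B-factor
#' column holds the residue's value, clipped to `[0, 999.99]`; residues
#' without a value get 0.00. This is the mechanism used to colour structures
#' by chemical-shift perturbation.
#'
#' @param structure A structure tibble.
#' @param path Output path.
#' @param bfactor_values Optional numeric vector of per-residue values,
#'   names = residue numbers.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, bfactor_values = NULL) {
  b <- rep(0, nrow(structure))
  if (!is.null(bfactor_values)) {
    if (is.null(names(bfactor_values))) {
      abort("bfactor_values must be named by residue_number")
    }
    hit <- match(as.character(structure$residue_number), names(bfactor_values))
    b[!is.na(hit)] <- bfactor_values[hit[!is.na(hit)]]
  }
  b <- pmin(pmax(b, 0), 999.99)
  resid3 <- toupper(structure$residue_name)
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(structure[, c("x", "y", "z")]))),
      resno = structure$residue_number,
      resid = resid3,
      eleno = seq_len(nrow(structure)),
      elety = structure$atom_name,
      chain = "A",
      o = rep(1, nrow(structure)),
      b = b
    )
    TRUE
  }, error = function(e) {
    abort(sprintf("failed to write '%s': %s", path, conditionMessage(e)))
  })
  invisible(path)
}
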