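# Structure file handling: reading PDB/mmCIF models (via bio3d), extracting
# per-chain C-alpha traces, and reading/writing the tabular artifacts
# (secondary-structure annotations, descriptor tables).

#' Construct a C-alpha trace
#'
#' The ordered alpha-carbon coordinates of one chain, treated as an open
#' polygonal curve. Chain breaks (consecutive distance > 4.5 A) are flagged
#' but the curve is still treated as connected for Gauss-integral purposes.
#'
#' @param coords n x 3 numeric matrix, Angstrom.
#' @param residue_ids integer residue identifiers (author numbering,
#'   insertion codes appended); defaults to 1..n.
#' @param chain_id chain identifier.
#' @return A `ca_trace` with fields `chain_id`, `residue_ids`, `coords`,
#'   `n_residues` and `breaks` (indices i where the i -> i+1 step exceeds
#'   4.5 A).
#' @export
ca_trace <- function(coords, residue_ids = NULL, chain_id = "A") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix", call. = FALSE)
  n <- nrow(coords)
  if (n < 3L) stop("degenerate input: a trace needs at least 3 residues", call. = FALSE)
  if (!all(is.finite(coords))) stop("coords must be finite", call. = FALSE)
  if (is.null(residue_ids)) residue_ids <- seq_len(n)
  if (length(residue_ids) != n) {
    stop("residue_ids length must match the number of coordinates", call. = FALSE)
  }
  d <- sqrt(rowSums((coords[-1L, , drop = FALSE] - coords[-n, , drop = FALSE])^2))
  if (any(d == 0)) stop("consecutive trace points must be distinct", call. = FALSE)
  structure(list(chain_id = chain_id, residue_ids = residue_ids,
                 coords = coords, n_residues = n,
                 breaks = which(d > 4.5)),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("C-alpha trace: chain %s, %d residues%s\n", x$chain_id,
              x$n_residues,
              if (length(x$breaks)) sprintf(", %d chain break(s)", length(x$breaks)) else ""))
  invisible(x)
}

#' Read a macromolecular structure file
#'
#' Thin wrapper over bio3d's PDB and mmCIF readers that preserves all models,
#' chains, altloc codes and residue numbering.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return A bio3d `pdb` object (multi-model coordinates in `$xyz`).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  out <- tryCatch(
    withCallingHandlers(
      switch(format,
             pdb = bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                   verbose = FALSE),
             mmcif = bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
      warning = function(w) {
        # bio3d's beta-reader and record-parsing notices are not data problems
        if (grepl("beta version|helix/sheet|PDB has ALT", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }),
    error = function(e) {
      stop(sprintf("failed to parse %s as %s: %s", path, format,
                   conditionMessage(e)), call. = FALSE)
    })
  out
}

#' Extract the C-alpha trace of one chain
#'
#' One point per residue that has a C-alpha atom. Alternate locations are
#' resolved by highest occupancy, ties alphabetically; residues lacking a
#' C-alpha are skipped with a warning; HETATM records and hydrogens are
#' ignored. Chain breaks are flagged on the returned trace.
#'
#' @param model a bio3d `pdb` object from [read_structure()].
#' @param chain_id chain to extract.
#' @param model_index which model (for multi-model files), default 1.
#' @return A [ca_trace].
#' @export
extract_ca_trace <- function(model, chain_id, model_index = 1L) {
  atoms <- model$atom
  in_chain <- atoms$chain == chain_id & atoms$type == "ATOM"
  if (!any(in_chain, na.rm = TRUE)) {
    stop(sprintf("chain '%s' not found in model", chain_id), call. = FALSE)
  }
  chain_rows <- which(in_chain)                    # rows in the full atom table
  ch <- atoms[chain_rows, , drop = FALSE]
  ins <- ifelse(is.na(ch$insert) | ch$insert == "", "", ch$insert)
  res_key <- paste0(ch$resno, ins)
  res_order <- unique(res_key)                     # file order
  is_ca <- ch$elety == "CA"
  ca <- ch[is_ca, , drop = FALSE]
  ca_rows <- chain_rows[is_ca]
  ca_key <- res_key[is_ca]

  missing_ca <- setdiff(res_order, unique(ca_key))
  if (length(missing_ca)) {
    warning(sprintf("chain %s: %d residue(s) lack a C-alpha and were skipped (%s)",
                    chain_id, length(missing_ca),
                    paste(utils::head(missing_ca, 5), collapse = ", ")),
            call. = FALSE)
  }

  # altloc resolution: highest occupancy, ties alphabetical
  rows <- vapply(res_order[res_order %in% ca_key], function(k) {
    idx <- which(ca_key == k)
    if (length(idx) > 1L) {
      occ <- ca$o[idx]
      occ[is.na(occ)] <- 1
      alt <- ifelse(is.na(ca$alt[idx]) | ca$alt[idx] == "", "~", ca$alt[idx])
      idx <- idx[order(-occ, alt)]
    }
    ca_rows[idx[1L]]                               # full-table row index
  }, integer(1))
  if (length(rows) < 3L) {
    stop(sprintf("chain %s has fewer than 3 C-alpha atoms", chain_id), call. = FALSE)
  }

  nm <- nrow(model$xyz)
  if (model_index < 1L || model_index > nm) {
    stop(sprintf("model_index %d out of range (file has %d model(s))",
                 model_index, nm), call. = FALSE)
  }
  # map atom rows to xyz columns of the requested model
  xyz_idx <- as.vector(t(outer(rows, 0:2, function(r, k) 3 * (r - 1) + 1 + k)))
  coords <- matrix(model$xyz[model_index, xyz_idx], ncol = 3, byrow = TRUE)
  tr <- ca_trace(coords,
                 residue_ids = names(rows),
                 chain_id = chain_id)
  if (length(tr$breaks)) {
    warning(sprintf("chain %s: %d chain break(s) flagged (C-alpha step > 4.5 A); the curve is still treated as connected",
                    chain_id, length(tr$breaks)), call. = FALSE)
  }
  tr
}

#' Read / write per-residue secondary-structure annotation tables
#'
#' TSV with header columns `chain_id`, `residue_id`, `ss_class`; classes are
#' `helix`, `sheet` or `coil`. Writing then reading reproduces the table
#' exactly.
#'
#' @param path file path.
#' @return A data.frame with the three columns above.
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  required <- c("chain_id", "residue_id", "ss_class")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(sprintf("annotation table schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("annotation table schema error: no residues", call. = FALSE)
  bad <- setdiff(unique(tab$ss_class), c("helix", "sheet", "coil"))
  if (length(bad)) {
    stop(sprintf("annotation table schema error: unknown class token(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  tab[required]
}

#' @rdname read_annotation_table
#' @param rows data.frame to write.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one or more frames of C-alpha coordinates as a (multi-model) PDB
#'
#' Minimal ATOM/MODEL record writer for C-alpha-only traces, used by the
#' synthetic trajectory generator and accepted by any PDB reader.
#'
#' @param frames a single n x 3 matrix, a [ca_trace], or a list of n x 3
#'   matrices (one per model).
#' @param path output path.
#' @param chain_id chain identifier to write.
#' @export
write_ca_pdb <- function(frames, path, chain_id = "A") {
  if (inherits(frames, "ca_trace")) frames <- list(frames$coords)
  if (is.matrix(frames)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (m in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frames[[m]]
    lines <- sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                     seq_len(nrow(xyz)), chain_id, seq_len(nrow(xyz)),
                     xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
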