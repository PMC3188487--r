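#' Read a PDB file into a C-alpha model
#'
#' Parses ATOM records with [bio3d::read.pdb()], keeps one C-alpha per
#' residue of the selected chain/model, and preserves author numbering and
#' insertion codes.  HETATM records and waters are excluded.  When a
#' residue has alternate locations, the highest-occupancy C-alpha is kept
#' (ties broken by altloc letter order).
#'
#' @param path PDB file.
#' @param chain chain identifier; `NULL` (default) selects the first chain
#'   containing protein C-alpha atoms.
#' @param model_index which MODEL block to use (default 1).
#' @return a [calpha_model()] with `source_label` set to the file name.
#' @export
read_calpha <- function(path, chain = NULL, model_index = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at$row <- seq_len(nrow(at))   # positional link into the xyz columns
  ca <- at[at$type == "ATOM" & at$elety == "CA" &
             !(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (is.null(chain)) {
    if (nrow(ca) == 0L) stop("empty selection: no C-alpha atoms in file")
    chain <- ca$chain[1L]
  }
  ca <- ca[ca$chain %in% chain, , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("empty selection: no C-alpha atoms in chain '", chain, "'")
  mi <- as.integer(model_index)
  xyz <- unclass(pdb$xyz)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (mi < 1L || mi > nrow(xyz)) stop("model_index out of range")
  # altloc resolution: keep highest occupancy within each residue
  ca$insert[is.na(ca$insert)] <- ""
  ca$alt[is.na(ca$alt)] <- ""
  ca$o[is.na(ca$o)] <- 1
  key <- paste(ca$chain, ca$resno, ca$insert, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(ca)), factor(key, unique(key))),
                        function(rows) {
    r <- ca[rows, , drop = FALSE]
    rows[order(-r$o, r$alt)][1L]
  }), use.names = FALSE)
  keep <- sort(keep)
  ca <- ca[keep, , drop = FALSE]
  key <- key[keep]
  if (anyDuplicated(key))
    stop("duplicate residue after altloc resolution: ",
         key[duplicated(key)][1L])
  rowidx <- ca$row
  coords <- cbind(x = xyz[mi, 3 * rowidx - 2],
                  y = xyz[mi, 3 * rowidx - 1],
                  z = xyz[mi, 3 * rowidx])
  calpha_model(coords, resno = ca$resno, chain = ca$chain, resid = ca$resid,
               insert = ca$insert, source_label = basename(path))
}

#' Binding-pocket specification
#'
#' Resolves a comma-separated list of author-numbered residue ranges (for
#' example `"320-328,371-380"`; ranges are inclusive, single residues are
#' written `"10"` or `"10-10"`) against a model.  These residues are the
#' perturbation sites representing the approaching ligand.
#'
#' @param spec character spec, or integer vector of author residue numbers.
#' @param model a [calpha_model()].
#' @param chain optional chain restriction for resolution.
#' @return object of class `binding_pocket`: `spec` (normalized text),
#'   `resno` (author numbers) and `indices` (1-based node indices).
#' @export
#' @examples
#' m <- make_fixture("ideal_helix", 20)
#' parse_pocket_spec("1-4,10", m)
parse_pocket_spec <- function(spec, model, chain = NULL) {
  stopifnot(inherits(model, "calpha_model"))
  if (is.numeric(spec)) {
    resno <- as.integer(spec)
    spec_txt <- paste(resno, collapse = ",")
  } else {
    parts <- trimws(strsplit(as.character(spec), ",")[[1L]])
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L) stop("empty pocket specification")
    resno <- unlist(lapply(parts, function(p) {
      m2 <- regmatches(p, regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", p))[[1L]]
      if (length(m2) == 0L) stop("malformed pocket range: '", p, "'")
      lo <- as.integer(m2[2L])
      hi <- if (nzchar(m2[3L])) as.integer(m2[3L]) else lo
      if (hi < lo) stop("empty pocket range: '", p, "'")
      lo:hi
    }))
    spec_txt <- paste(parts, collapse = ",")
  }
  resno <- unique(resno)
  idx <- resolve_residues(model, resno, chain = chain)
  structure(list(spec = spec_txt, resno = resno, indices = sort(idx)),
            class = "binding_pocket")
}

#' @export
print.binding_pocket <- function(x, ...) {
  cat("Binding pocket: ", x$spec, " (", length(x$indices),
      " resolved residues)\n", sep = "")
  invisible(x)
}

#' Read a reference residue set
#'
#' Plain-text format: one author residue number per line; blank lines and
#' `#` comments ignored.  Used for experimental or coevolution-derived
#' residue lists consumed by the evaluation functions.
#'
#' @param path text file.
#' @return sorted integer vector of residue numbers.
#' @export
read_residue_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no residues in ", path)
  v <- suppressWarnings(as.integer(lines))
  if (anyNA(v)) stop("non-numeric residue entries in ", path)
  sort(unique(v))
}

# fixed-width PDB ATOM record for a C-alpha
format_atom_line <- function(serial, resid, chain, resno, insert, xyz) {
  sprintf("ATOM  %5d  CA  %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f%10s%2s",
          serial %% 100000L, substr(resid, 1L, 3L), substr(chain, 1L, 1L),
          resno, ifelse(nzchar(insert), substr(insert, 1L, 1L), " "),
          xyz[1], xyz[2], xyz[3], 1, 0, "", " C")
}

#' Write a conformer ensemble as a multi-MODEL PDB
#'
#' All models must share the same residue identities; each becomes one
#' MODEL/ENDMDL block of C-alpha ATOM records.  Coordinates survive a
#' round trip through [read_calpha()] to the fixed-width PDB precision
#' (1e-3 Angstrom).
#'
#' @param models a single [calpha_model()] or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(models, path) {
  if (inherits(models, "calpha_model")) models <- list(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, TRUE, "calpha_model")))
  ref <- models[[1L]]
  key <- function(m) paste(m$chain, m$resno, m$insert, sep = "|")
  for (m in models[-1L])
    if (!identical(key(m), key(ref)))
      stop("inconsistent residue sets across ensemble members")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   generated by prscan from %s (%d models)",
                     ref$source_label, length(models)), con)
  for (k in seq_along(models)) {
    m <- models[[k]]
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(vapply(seq_len(n_residues(m)), function(i)
      format_atom_line(i, m$resid[i], m$chain[i], m$resno[i], m$insert[i],
                       m$coords[i, ]), character(1L)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
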