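#' Coarse-grained C-alpha model of a protein chain
#'
#' A `calpha_model` is the node set of the elastic network: one C-alpha per
#' residue, in file order, carrying the author residue numbering so that
#' results can be reported in the numbering used by crystallographers and
#' experimentalists.
#'
#' @param coords numeric N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param resno integer vector of author residue numbers (length N).
#' @param chain character vector of chain identifiers (length 1 or N).
#' @param resid character vector of 3-letter residue codes (length 1 or N).
#' @param insert character vector of insertion codes (`""` for none).
#' @param source_label free-text provenance (PDB id, file name or fixture
#'   name); carried into reports and ensemble output.
#'
#' @return an object of class `calpha_model` with fields `coords`, `resno`,
#'   `chain`, `resid`, `insert` and `source_label`.
#' @export
#' @examples
#' m <- calpha_model(cbind(x = c(0, 3.8), y = 0, z = 0), resno = 1:2)
#' n_residues(m)
calpha_model <- function(coords, resno, chain = "A", resid = "ALA",
                         insert = "", source_label = "model") {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3L)
    stop("'coords' must be an N x 3 matrix")
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 2L)
    stop("a C-alpha model needs at least 2 residues, got ", n)
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in C-alpha model")
  resno <- as.integer(resno)
  if (length(resno) != n)
    stop("'resno' must have one entry per coordinate row")
  chain  <- rep_len(as.character(chain),  n)
  resid  <- rep_len(as.character(resid),  n)
  insert <- rep_len(as.character(insert), n)
  insert[is.na(insert)] <- ""
  key <- paste(chain, resno, insert, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate residue identifier after parsing: ", dup)
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(coords = coords, resno = resno, chain = chain, resid = resid,
         insert = insert, source_label = as.character(source_label)[1L]),
    class = "calpha_model")
}

#' Number of residues (network nodes) in a model
#' @param model a [calpha_model()].
#' @return integer count.
#' @export
n_residues <- function(model) {
  stopifnot(inherits(model, "calpha_model"))
  nrow(model$coords)
}

# "A:10" / "A:10A" labels used in printing and error messages
residue_labels <- function(model) {
  paste0(model$chain, ":", model$resno, model$insert)
}

#' @export
print.calpha_model <- function(x, ...) {
  cat("C-alpha model '", x$source_label, "': ", n_residues(x),
      " residues, chain(s) ", paste(unique(x$chain), collapse = ","),
      ", residues ", min(x$resno), "..", max(x$resno), "\n", sep = "")
  invisible(x)
}

#' Resolve author residue numbers to node indices
#'
#' @param model a [calpha_model()].
#' @param resno integer vector of author residue numbers.
#' @param chain optional chain restriction.
#' @return integer vector of 1-based node indices.
#' @keywords internal
resolve_residues <- function(model, resno, chain = NULL) {
  keep <- if (is.null(chain)) rep(TRUE, n_residues(model))
          else model$chain %in% chain
  idx <- match(as.integer(resno),
               ifelse(keep, model$resno, NA_integer_))
  if (anyNA(idx))
    stop("residue number(s) not present in model: ",
         paste(resno[is.na(idx)], collapse = ", "))
  idx
}
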