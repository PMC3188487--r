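#' Two-way contingency table over a residue universe
#'
#' Cross-classifies a stated residue universe by membership in the
#' predicted and reference sets: `(|P & R|, |P \ R|, |R \ P|, |rest|)`.
#' With `near = 1` a predicted residue within one sequence position of a
#' reference residue counts as a match (off by default; reports should show
#' both).
#'
#' @param predicted,reference integer residue-number sets, subsets of
#'   `universe`.
#' @param universe integer vector: all residues considered (for structure
#'   analyses, all resolved residues of the chain).
#' @param near non-negative integer matching tolerance in sequence
#'   positions (default 0 = exact identity).
#' @return object of class `residue_contingency`: `counts` (2x2 integer
#'   matrix), `universe_size`, `overlap` (the matched predicted residues).
#' @export
contingency_table <- function(predicted, reference, universe, near = 0L) {
  predicted <- unique(as.integer(predicted))
  reference <- unique(as.integer(reference))
  universe <- unique(as.integer(universe))
  out <- setdiff(c(predicted, reference), universe)
  if (length(out))
    stop("residues outside the universe: ", paste(out, collapse = ", "))
  near <- as.integer(near)
  matched_p <- if (near == 0L) intersect(predicted, reference)
    else predicted[vapply(predicted, function(p)
      any(abs(reference - p) <= near), logical(1L))]
  matched_r <- if (near == 0L) intersect(reference, predicted)
    else reference[vapply(reference, function(r)
      any(abs(predicted - r) <= near), logical(1L))]
  a <- length(matched_r)                       # reference residues hit
  b <- length(predicted) - length(matched_p)   # predicted-only
  c_ <- length(reference) - a                  # reference missed
  d <- length(universe) - (a + b + c_)
  counts <- matrix(c(a, c_, b, d), 2L, 2L,
                   dimnames = list(predicted = c("yes", "no"),
                                   reference = c("yes", "no")))
  structure(list(counts = counts, universe_size = length(universe),
                 overlap = sort(matched_p), near = near),
            class = "residue_contingency")
}

#' @export
print.residue_contingency <- function(x, ...) {
  cat("Residue contingency table (universe = ", x$universe_size,
      if (x$near > 0) paste0(", +/-", x$near, " matching") else "",
      "):\n", sep = "")
  print(x$counts)
  cat("matched predicted residues: ",
      if (length(x$overlap)) paste(x$overlap, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Fisher's exact test on a residue contingency table
#'
#' Exact hypergeometric test with fixed margins.  The two-sided p-value
#' (default) follows the probability-mass rule: the sum of probabilities of
#' all tables no more probable than the observed one.  One-sided
#' alternatives are available since enrichment questions are often
#' directional.
#'
#' @param x a [contingency_table()] result or a 2x2 matrix of counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return the p-value (numeric scalar).
#' @export
fisher_exact <- function(x, alternative = c("two.sided", "greater",
                                            "less")) {
  alternative <- match.arg(alternative)
  counts <- if (inherits(x, "residue_contingency")) x$counts else as.matrix(x)
  stopifnot(all(dim(counts) == 2L), all(counts >= 0))
  stats::fisher.test(counts, alternative = alternative)$p.value
}

#' Kabsch RMSD between two structures
#'
#' Least-squares optimal superposition (rotation + translation) followed by
#' the root-mean-square deviation over the selected atoms.  Inputs may be
#' [calpha_model()]s or PDB file paths; atoms are paired by author residue
#' number (and atom name for multi-atom selections) over the residues
#' common to both structures.
#'
#' @param a,b [calpha_model()]s, or PDB paths when `selection` is
#'   `"backbone"` or `"all"`.
#' @param selection `"calpha"` (default), `"backbone"` (N, CA, C, O) or
#'   `"all"` (all heavy atoms).
#' @param chain_a,chain_b optional chain selectors for PDB inputs.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b, selection = c("calpha", "backbone", "all"),
                        chain_a = NULL, chain_b = NULL) {
  selection <- match.arg(selection)
  if (selection == "calpha") {
    ma <- if (inherits(a, "calpha_model")) a else read_calpha(a, chain_a)
    mb <- if (inherits(b, "calpha_model")) b else read_calpha(b, chain_b)
    ka <- paste(ma$resno, ma$insert); kb <- paste(mb$resno, mb$insert)
    common <- intersect(ka, kb)
    xa <- ma$coords[match(common, ka), , drop = FALSE]
    xb <- mb$coords[match(common, kb), , drop = FALSE]
  } else {
    grab <- function(path, chain) {
      pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
      at <- pdb$atom
      keep <- at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT"))
      if (!is.null(chain)) keep <- keep & at$chain %in% chain
      if (selection == "backbone")
        keep <- keep & at$elety %in% c("N", "CA", "C", "O")
      else keep <- keep & !grepl("^H", at$elety)
      at <- at[keep, , drop = FALSE]
      at$insert[is.na(at$insert)] <- ""
      data.frame(key = paste(at$resno, at$insert, at$elety),
                 x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
    }
    ta <- grab(a, chain_a); tb <- grab(b, chain_b)
    ta <- ta[!duplicated(ta$key), ]; tb <- tb[!duplicated(tb$key), ]
    common <- intersect(ta$key, tb$key)
    xa <- as.matrix(ta[match(common, ta$key), c("x", "y", "z")])
    xb <- as.matrix(tb[match(common, tb$key), c("x", "y", "z")])
  }
  if (nrow(xa) < 3L)
    stop("fewer than 3 paired atoms; cannot superpose")
  fitted <- matrix(bio3d::fit.xyz(fixed = as.vector(t(xa)),
                                  mobile = as.vector(t(xb)),
                                  fixed.inds = seq_len(3 * nrow(xa)),
                                  mobile.inds = seq_len(3 * nrow(xa))),
                   ncol = 3L, byrow = TRUE)
  sqrt(mean(rowSums((fitted - xa)^2)))
}
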