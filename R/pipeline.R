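#' Analysis configuration
#'
#' Bundles every tunable of the full analysis.  The defaults are the
#' canonical settings of the method: bonded spring constant 1, non-bonded
#' numerator 8, the 7 canonical force directions, chi threshold 1.0,
#' overlap cutoff 0.98 and sequence window 3.
#'
#' @param structure PDB path or [calpha_model()].
#' @param pocket binding-pocket spec string (author-numbered ranges).
#' @param chain chain selector (`NA`/`NULL` = first protein chain).
#' @param gamma_bonded,nonbonded_numerator,pinv_tolerance network
#'   parameters, see [enm_params()] and [compute_compliance()].
#' @param threshold chi cutoff for hot residues.
#' @param overlap_cutoff pathway edge cutoff.
#' @param window pathway sequence window.
#' @param n_directions 7 for the canonical set, otherwise that many seeded
#'   random unit directions.
#' @param seed seed for random directions / ensembles.
#' @param out_prefix file prefix for [run_full_analysis()] outputs (`NULL`
#'   writes nothing).
#' @return object of class `prs_config` (a named list).
#' @export
prs_config <- function(structure, pocket, chain = NULL, gamma_bonded = 1,
                       nonbonded_numerator = 8, pinv_tolerance = 1e-8,
                       threshold = 1.0, overlap_cutoff = 0.98, window = 3L,
                       n_directions = 7L, seed = 1L, out_prefix = NULL) {
  cfg <- list(structure = structure, pocket = pocket, chain = chain,
              gamma_bonded = gamma_bonded,
              nonbonded_numerator = nonbonded_numerator,
              pinv_tolerance = pinv_tolerance, threshold = threshold,
              overlap_cutoff = overlap_cutoff, window = as.integer(window),
              n_directions = as.integer(n_directions),
              seed = as.integer(seed), out_prefix = out_prefix)
  class(cfg) <- "prs_config"
  cfg
}

#' Read / write a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Round-tripping a config through [write_prs_config()] and
#' [read_prs_config()] reproduces it.
#'
#' @param path text file.
#' @return a [prs_config()].
#' @export
read_prs_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
  num <- c("gamma_bonded", "nonbonded_numerator", "pinv_tolerance",
           "threshold", "overlap_cutoff")
  int <- c("window", "n_directions", "seed")
  args <- stats::setNames(as.list(vals), keys)
  for (k in intersect(names(args), num)) args[[k]] <- as.numeric(args[[k]])
  for (k in intersect(names(args), int)) args[[k]] <- as.integer(args[[k]])
  if (!is.null(args$chain) && args$chain %in% c("", "NA")) args$chain <- NULL
  do.call(prs_config, args)
}

#' @rdname read_prs_config
#' @param cfg a [prs_config()].
#' @export
write_prs_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "prs_config"))
  keep <- !vapply(cfg, is.null, TRUE) &
    !names(cfg) %in% c("out_prefix")
  flat <- vapply(cfg[keep], function(v)
    if (is.character(v) || is.numeric(v)) as.character(v)[1L] else
      stop("non-scalar config entry"), "")
  writeLines(paste(names(flat), flat, sep = " = "), path)
  invisible(path)
}

#' Run the full allosteric analysis
#'
#' Executes the complete procedure: read structure, build the cutoff-free
#' elastic network, invert it, scan perturbations, compute chi, select hot
#' residues, expand by the sequence window, link collinearly responding
#' pairs and extract the maximum-weight pathway.  Optionally writes the chi
#' profile as TSV and the pathway as JSON, both with a provenance header
#' recording the parameters.
#'
#' @param cfg a [prs_config()].
#' @return list with elements `fit` (the [prs()] object), `pathway`
#'   (a `prs_pathway`) and `files` (character vector of outputs written).
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "prs_config"))
  directions <- if (cfg$n_directions == 7L) prs_directions()
                else random_directions(cfg$n_directions, seed = cfg$seed)
  fit <- prs(cfg$structure, pocket = cfg$pocket, chain = cfg$chain,
             threshold = cfg$threshold,
             params = enm_params(gamma_bonded = cfg$gamma_bonded,
                                 nonbonded_numerator = cfg$nonbonded_numerator),
             directions = directions,
             pinv_tolerance = cfg$pinv_tolerance)
  pathway <- tryCatch(
    prs_pathway(fit, cutoff = cfg$overlap_cutoff, window = cfg$window),
    error = function(e) {
      warning("pathway stage: ", conditionMessage(e))
      NULL
    })
  files <- character(0)
  if (!is.null(cfg$out_prefix)) {
    chi_file <- paste0(cfg$out_prefix, "_chi.tsv")
    con <- file(chi_file, "w")
    writeLines(c(
      paste0("# prscan chi profile; source=", fit$model$source_label),
      paste0("# pocket=", fit$pocket$spec, "; threshold=", cfg$threshold,
             "; gamma_b=", cfg$gamma_bonded,
             "; c_nb=", cfg$nonbonded_numerator,
             "; directions=", cfg$n_directions)), con)
    tab <- as.data.frame(fit$chi)
    tab$hot <- tab$chi > cfg$threshold
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    files <- chi_file
    if (!is.null(pathway)) {
      pw_file <- paste0(cfg$out_prefix, "_pathway.json")
      jsonlite::write_json(list(
        source = fit$model$source_label,
        pocket = fit$pocket$spec,
        overlap_cutoff = cfg$overlap_cutoff,
        window = cfg$window,
        residues = pathway$residues,
        residue_names = fit$model$resid[pathway$indices],
        edge_overlaps = pathway$edge_overlaps,
        total_weight = pathway$total_weight),
        pw_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c(files, pw_file)
    }
  }
  list(fit = fit, pathway = pathway, files = files)
}
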