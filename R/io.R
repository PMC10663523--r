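# Readers/writers for the on-disk formats: multi-model PDB conformer
# libraries, PRE measurement CSVs, profile TSVs, JSON summaries, YAML config.

#' Write a conformer list as a multi-model PDB file
#'
#' One MODEL block per conformer.  Each reporter becomes a CA pseudo-atom
#' whose residue number encodes the reporter: helix reporters take their
#' residue number directly (4, 8, 12, ...), G-domain reporters theirs
#' (17-181).  Coordinates are Angstrom in the membrane frame (PDB fixed
#' width, 3 decimals).
#'
#' @param conformers list of [conformer]s with a common reporter set.
#' @param path output file.
#' @export
write_conformer_library <- function(conformers, path) {
  stopifnot(length(conformers) >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  ids <- rownames(conformers[[1]]$xyz)
  resno <- as.integer(sub("^[a-z]+", "", ids))
  if (any(is.na(resno))) resno <- seq_along(ids)
  for (m in seq_along(conformers)) {
    cf <- conformers[[m]]
    stopifnot(identical(rownames(cf$xyz), ids))
    writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_along(ids)) {
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, resno[i], cf$xyz[i, 1], cf$xyz[i, 2], cf$xyz[i, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a conformer library from a multi-model PDB file
#'
#' One [conformer] per MODEL record (read through `bio3d::read.pdb`).
#' Reporters are selected by residue number and atom name; roles derive from
#' the G-domain residue range (inside = `g_domain`, outside = `n_helix`).
#'
#' @param path PDB file with MODEL/ENDMDL records.
#' @param reporter_resno integer residue numbers to select; `NULL` selects
#'   every residue bearing the atom.
#' @param atom_name atom name of the reporter (default `"CA"`).
#' @param g_domain_range residue range of the G domain (default 17-181).
#' @param phosphate_plane_z z of the cis phosphate plane in the file's frame;
#'   subtracted so the returned coordinates have z = 0 at the plane.
#' @return list of [conformer]s.
#' @export
read_conformer_library <- function(path, reporter_resno = NULL,
                                   atom_name = "CA",
                                   g_domain_range = c(17L, 181L),
                                   phosphate_plane_z = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  sel <- pdb$atom$elety == atom_name
  if (!is.null(reporter_resno)) sel <- sel & pdb$atom$resno %in% reporter_resno
  if (!any(sel)) stop("no reporter atoms matched in ", path)
  resno <- pdb$atom$resno[sel]
  if (!is.null(reporter_resno)) {
    missing <- setdiff(reporter_resno, resno)
    if (length(missing))
      stop("selected reporter residue(s) absent: ", paste(missing, collapse = ", "))
  }
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models) || n_models < 1) stop("no MODEL records in ", path)
  cols <- which(sel)
  ids <- ifelse(resno >= g_domain_range[1] & resno <= g_domain_range[2],
                paste0("g", resno), paste0("h", resno))
  roles <- ifelse(resno >= g_domain_range[1] & resno <= g_domain_range[2],
                  "g_domain", "n_helix")
  names(roles) <- ids
  lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)[cols, , drop = FALSE]
    if (any(!is.finite(xyz)))
      stop("non-finite coordinates in model ", m, " of ", path)
    xyz[, 3] <- xyz[, 3] - phosphate_plane_z
    rownames(xyz) <- ids
    conformer(sprintf("model_%d", m), xyz, roles, g_domain_range)
  })
}

#' Read a PRE measurement table from CSV
#'
#' Required columns: `reporter_id`, `i_para`, `i_dia`, `sn_para`, `sn_dia`
#' (optional `residue`, `atom`).  Ratios and errors are computed on load,
#' never read; duplicate reporter ids and non-positive intensities/SN are
#' rejected with the offending row number.
#'
#' @param path CSV file.
#' @return a `pre_measurement` data.frame.
#' @export
read_pre_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  pre_measurement(df)
}

#' Write a PRE measurement or prediction as CSV
#'
#' @param x a `pre_measurement` or `pre_prediction` data.frame.
#' @param path output file.
#' @export
write_pre_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' YAML file with optional blocks `layer`, `pre_params`, `states`, `fit`,
#' `membrane` and top-level `seed`; unknown keys are rejected.  Missing
#' blocks fall back to package defaults, and the fully resolved configuration
#' is returned (and should be serialized with any results for provenance).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return list with elements `layer` ([spin_label_layer]), `params`
#'   ([pre_params]), `states`, `fit` ([fit_config]), `seed`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("layer", "pre_params", "states", "fit", "membrane", "seed",
             "log_level", "paths")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  take <- function(block, builder) {
    args <- raw[[block]]
    if (is.null(args)) builder() else do.call(builder, args)
  }
  states <- if (is.null(raw$states)) default_states() else
    lapply(raw$states, function(s)
      state_definition(s$name, unlist(s$beta_range), unlist(s$gamma_range)))
  validate_states(states)
  fit_args <- raw$fit
  if (!is.null(raw$seed) && is.null(fit_args$seed)) fit_args$seed <- raw$seed
  list(layer = take("layer", spin_label_layer),
       params = take("pre_params", pre_params),
       states = states,
       fit = if (is.null(fit_args)) fit_config() else do.call(fit_config, fit_args),
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}

#' Write a population summary (and its provenance) as JSON
#'
#' @param summary a [repeat_selection] result.
#' @param path output file.
#' @param extra named list merged into the JSON (e.g. resolved config).
#' @export
write_population_json <- function(summary, path, extra = list()) {
  stopifnot(inherits(summary, "population_summary"))
  obj <- c(list(
    populations_pct = as.list(summary$mean_pct),
    sd_pct = as.list(summary$sd_pct),
    com_mean_A = summary$com_mean, com_sd_A = summary$com_sd,
    chi2_median = stats::median(summary$chi2),
    repeats = nrow(summary$per_repeat),
    ensemble_size = summary$cfg$ensemble_size,
    noise_fraction = summary$cfg$noise_fraction,
    seed = summary$cfg$seed), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
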