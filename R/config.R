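# JSON system-configuration files, TSV output with run manifests.
#
# A config describes one promoter system plus optional cascade:
# {"tfs": [...], "concentrations_nM": {tf: val},
#  "kinetics": {"k0_assoc": [...], "k0_dissoc": [...]}           (one of)
#  "energies": {"G0_kcal": [...], "E0_kcal": [[...]],
#               "temperature_K": 298.15, "prefactor_per_s": 1.0} (one of)
#  "raw_M": [[...]],                                             (one of)
#  "rho_per_s": [...],
#  "cascade": {"gamma_per_s":..., "beta_per_s":..., "gamma_p_per_s":...}}
# kinetics$k0_assoc / k0_dissoc are N x 2^N matrices; for each (f, s) the
# relevant entry (association when f is unbound in s) is used.

#' Load a promoter-system configuration
#'
#' Reads and validates a JSON config (see the format sketch in the package
#' source or the vignette). Exactly one of `kinetics`, `energies`, `raw_M`
#' must be present. Defaults (temperature 298.15 K, prefactor 1/s) are
#' applied where omitted.
#'
#' @param path Path to the JSON file.
#' @return A list with `system` ([promoter_system()]), `energetic_model`
#'   (or NULL), `cascade` (or NULL).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  modes <- c("kinetics", "energies", "raw_M")
  present <- modes[modes %in% names(cfg)]
  if (length(present) != 1)
    stop("exactly one of ", paste(modes, collapse = "/"),
         " is required (found: ", paste(present, collapse = ", "), ")")
  if (is.null(cfg$rho_per_s)) stop("missing key: rho_per_s")
  rho <- as.numeric(cfg$rho_per_s)
  em <- NULL
  if (present == "raw_M") {
    M <- as.matrix(cfg$raw_M)
    if (length(rho) != nrow(M))
      stop("rho_per_s must have one entry per raw_M state (", nrow(M), ")")
    if (!is.null(cfg$tfs) && length(cfg$tfs) > 0 &&
        nrow(M) == 2^length(cfg$tfs)) {
      conc <- .cfg_conc(cfg)
      sys <- promoter_system(cfg$tfs, concentrations = conc, rho = rho,
                             raw_M = M)
    } else sys <- raw_system(M, rho)
  } else {
    if (is.null(cfg$tfs)) stop("missing key: tfs")
    tfs <- as.character(cfg$tfs)
    ns <- 2^length(tfs)
    if (length(rho) != ns)
      stop("rho_per_s must have length 2^N = ", ns, ", got ", length(rho))
    conc <- .cfg_conc(cfg, tfs)
    if (present == "kinetics") {
      ka <- as.matrix(cfg$kinetics$k0_assoc)
      kd <- as.matrix(cfg$kinetics$k0_dissoc)
      if (!all(dim(ka) == c(length(tfs), ns)) ||
          !all(dim(kd) == c(length(tfs), ns)))
        stop("k0_assoc and k0_dissoc must be N x 2^N")
      k0 <- matrix(0, length(tfs), ns)
      for (f in seq_along(tfs)) {
        bound <- bitwAnd(seq_len(ns) - 1L, bitwShiftL(1L, f - 1L)) > 0L
        k0[f, ] <- ifelse(bound, kd[f, ], ka[f, ])
      }
      sys <- promoter_system(tfs, k0 = k0, concentrations = conc, rho = rho)
    } else {
      en <- cfg$energies
      if (is.null(en$G0_kcal) || is.null(en$E0_kcal))
        stop("energies requires G0_kcal and E0_kcal")
      em <- energetic_model(tfs, as.numeric(en$G0_kcal),
                            as.matrix(en$E0_kcal),
                            temperature = en$temperature_K %||% 298.15,
                            prefactor = en$prefactor_per_s %||% 1)
      sys <- system_from_energies(em, conc, rho)
    }
  }
  cas <- NULL
  if (!is.null(cfg$cascade)) {
    cc <- cfg$cascade
    need <- c("gamma_per_s", "beta_per_s", "gamma_p_per_s")
    if (!all(need %in% names(cc)))
      stop("cascade requires keys: ", paste(need, collapse = ", "))
    cas <- cascade_params(cc$gamma_per_s, cc$beta_per_s, cc$gamma_p_per_s)
  }
  list(system = sys, energetic_model = em, cascade = cas)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cfg_conc <- function(cfg, tfs = cfg$tfs) {
  if (is.null(cfg$concentrations_nM)) stop("missing key: concentrations_nM")
  conc <- unlist(cfg$concentrations_nM)
  .match_conc(conc, tfs)
}

#' Save a promoter system as a JSON config
#'
#' Writes a config that [load_config()] reads back to a numerically
#' identical system. Kinetic systems are written with `k0` split into
#' association/dissociation blocks; raw systems with `raw_M`; an
#' energetic model, when supplied, is written instead of the kinetics.
#'
#' @param system A [promoter_system()].
#' @param path Output path.
#' @param cascade Optional [cascade_params()].
#' @param energetic_model Optional [energetic_model()]; written as the
#'   `energies` block.
#' @return `path`, invisibly.
#' @export
save_config <- function(system, path, cascade = NULL,
                        energetic_model = NULL) {
  stopifnot(inherits(system, "promoter_system"))
  cfg <- list(rho_per_s = system$rho)
  if (!is.null(energetic_model)) {
    em <- energetic_model
    cfg$tfs <- em$tf_names
    cfg$concentrations_nM <- as.list(system$concentrations)
    cfg$energies <- list(G0_kcal = em$G0, E0_kcal = em$E0,
                         temperature_K = em$temperature,
                         prefactor_per_s = em$prefactor)
  } else if (!is.null(system$raw_M)) {
    cfg$raw_M <- system$raw_M
    if (!is.null(system$tf_names)) {
      cfg$tfs <- system$tf_names
      cfg$concentrations_nM <- as.list(system$concentrations)
    }
  } else {
    n <- length(system$tf_names); ns <- 2^n
    ka <- kd <- system$k0
    for (f in seq_len(n)) {
      bound <- bitwAnd(seq_len(ns) - 1L, bitwShiftL(1L, f - 1L)) > 0L
      ka[f, bound] <- 0
      kd[f, !bound] <- 0
    }
    cfg$tfs <- system$tf_names
    cfg$concentrations_nM <- as.list(system$concentrations)
    cfg$kinetics <- list(k0_assoc = ka, k0_dissoc = kd)
  }
  if (!is.null(cascade))
    cfg$cascade <- list(gamma_per_s = cascade$gamma,
                        beta_per_s = cascade$beta,
                        gamma_p_per_s = cascade$gamma_p)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Write a results table with a run manifest
#'
#' Tab-separated output with deterministic column order and full-precision
#' floats (17 significant digits), plus a JSON sidecar
#' `<path>.manifest.json` recording the content hash, package version,
#' seed and command. Identical records give byte-identical tables.
#'
#' @param records A data.frame.
#' @param path Output path (TSV).
#' @param seed Optional seed to record.
#' @param command Optional command string to record.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, seed = NULL, command = NULL) {
  stopifnot(is.data.frame(records))
  fmt <- records
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  ok <- tryCatch({
    utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e)))
  manifest <- list(
    file = basename(path),
    md5 = unname(tools::md5sum(path)),
    package = "promodyn",
    version = as.character(utils::packageVersion("promodyn")),
    seed = seed,
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}
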