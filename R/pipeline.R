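config_error <- function(field, msg) {
  stop(structure(
    class = c("ribs_config_error", "error", "condition"),
    list(message = paste0("invalid config at '", field, "': ", msg),
         call = NULL)
  ))
}

#' Read a pipeline configuration file
#'
#' Configuration is a JSON or YAML document with these top-level fields:
#' \describe{
#'   \item{references}{`classical` and `swiveled` coordinate file paths.}
#'   \item{domains}{Named domain specs (`head`, `body`, `anchor`), each with
#'     `molecule`, `ranges` (list of `[start, end]` pairs), optional
#'     `markers` (3 residues), optional `core` (explicit core residue list)
#'     and `chain_map` (entry id to chain id; key `default` is the
#'     fallback).}
#'   \item{pairs}{Which (domain, anchor) combinations to report; defaults to
#'     head-vs-body.}
#'   \item{copies}{Optional named list of per-domain chain overrides, one
#'     entry per asymmetric-unit copy of the model structures.}
#'   \item{measurements}{List of measurement specs (see [run_measure()]).}
#'   \item{min_pairs, contact_cutoff}{Numeric thresholds (defaults 50, 4.0).}
#' }
#' The configuration is validated before any computation; validation
#' failures signal a `ribs_config_error` naming the offending field.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return Validated configuration list of class `ribs_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error(path, "file not found")
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE),
    yaml = , yml = yaml::read_yaml(path),
    config_error(path, "unrecognized config extension (want json/yaml)")
  )
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg Configuration list (as parsed from JSON/YAML or built in R).
#' @return The configuration, normalized, with class `ribs_config`.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) config_error("(root)", "must be a mapping")
  if (is.null(cfg$domains) || !is.list(cfg$domains)) {
    config_error("domains", "required mapping of domain definitions")
  }
  name_map <- c(head = "head", body = "body", anchor = "anchor23S")
  domains <- list()
  for (nm in names(cfg$domains)) {
    if (!nm %in% names(name_map)) {
      config_error(paste0("domains.", nm),
                   "unknown domain (expected head/body/anchor)")
    }
    d <- cfg$domains[[nm]]
    if (inherits(d, "ribs_domain")) {
      domains[[nm]] <- d
      next
    }
    for (f in c("molecule", "ranges", "chain_map")) {
      if (is.null(d[[f]])) {
        config_error(paste0("domains.", nm, ".", f), "missing")
      }
    }
    cm <- unlist(d$chain_map)
    domains[[nm]] <- tryCatch(
      domain_definition(name_map[[nm]], d$molecule, d$ranges,
                        markers = d$markers, core = d$core, chain_map = cm),
      error = function(e) config_error(paste0("domains.", nm),
                                       conditionMessage(e))
    )
  }
  pairs <- cfg$pairs
  if (is.null(pairs)) pairs <- list(list(domain = "head", anchor = "body"))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    for (f in c("domain", "anchor")) {
      if (is.null(p[[f]]) || !p[[f]] %in% names(domains)) {
        config_error(paste0("pairs[", i, "].", f),
                     "must name a configured domain")
      }
    }
    if (is.null(domains[[p$domain]]$markers)) {
      config_error(paste0("pairs[", i, "].domain"),
                   "domain used for angles needs marker residues")
    }
  }
  meas <- cfg$measurements
  if (is.null(meas)) meas <- list()
  for (i in seq_along(meas)) {
    m <- meas[[i]]
    path_i <- paste0("measurements[", i, "]")
    if (is.null(m$type) ||
        !m$type %in% c("distance", "contact", "nearest_phosphate", "kink")) {
      config_error(paste0(path_i, ".type"),
                   "must be distance/contact/nearest_phosphate/kink")
    }
    if (is.null(m$id)) config_error(paste0(path_i, ".id"), "missing")
    need <- switch(m$type,
      distance = c("a", "b"),
      contact = c("a", "b"),
      nearest_phosphate = c("base", "mrna_chain"),
      kink = c("chain", "vertex"))
    for (f in need) {
      if (is.null(m[[f]])) config_error(paste0(path_i, ".", f), "missing")
    }
  }
  out <- list(
    references = cfg$references,
    domains = domains,
    pairs = pairs,
    copies = cfg$copies,
    measurements = meas,
    min_pairs = if (is.null(cfg$min_pairs)) 50L else as.integer(cfg$min_pairs),
    contact_cutoff = if (is.null(cfg$contact_cutoff)) 4.0
                     else as.numeric(cfg$contact_cutoff)
  )
  class(out) <- "ribs_config"
  out
}

require_references <- function(cfg) {
  for (f in c("classical", "swiveled")) {
    if (is.null(cfg$references[[f]]) || !is.character(cfg$references[[f]])) {
      config_error(paste0("references.", f), "missing reference path")
    }
    if (!file.exists(cfg$references[[f]])) {
      config_error(paste0("references.", f),
                   paste0("file not found: ", cfg$references[[f]]))
    }
  }
}

#' Write a deterministic TSV report
#'
#' Fixed column order, tab separation, floats formatted to six decimals;
#' reruns on identical inputs are byte-identical.
#'
#' @param df Data frame.
#' @param file Output path (or `""` for stdout).
#' @return `file`, invisibly.
#' @export
write_report <- function(df, file) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]])) {
      fmt[[j]] <- ifelse(is.na(df[[j]]), "NA", sprintf("%.6f", df[[j]]))
    }
  }
  utils::write.table(fmt, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(file)
}

model_copies <- function(cfg) {
  if (is.null(cfg$copies)) list(`1` = list()) else cfg$copies
}

#' Compute orientation reports for model structures
#'
#' End-to-end angle pipeline: reads the classical and swiveled references,
#' calibrates the swivel axis for every configured (domain, anchor) pair,
#' and reports one orientation row per (model, asymmetric-unit copy,
#' domain).
#'
#' @param cfg A `ribs_config` (see [read_pipeline_config()]).
#' @param model_paths Character vector of model coordinate files.
#' @param output_file Optional TSV path (see [write_report()]).
#' @return Data frame with columns entry, copy, domain, phi, theta, psi,
#'   net_swivel, tilt, tilt_direction, core_rmsd, n_atoms.
#' @export
run_angles <- function(cfg, model_paths, output_file = NULL) {
  cfg <- validate_config(unclass(cfg))
  require_references(cfg)
  classical <- read_structure(cfg$references$classical)
  swiveled <- read_structure(cfg$references$swiveled)
  rows <- list()
  for (p in cfg$pairs) {
    domain <- cfg$domains[[p$domain]]
    anchor <- cfg$domains[[p$anchor]]
    cal <- calibrate_swivel(classical, swiveled, domain, anchor,
                            min_pairs = cfg$min_pairs)
    message("calibrated ", domain$name, ": axis magnitude ",
            sprintf("%.3f", cal$magnitude), " degrees")
    for (path in model_paths) {
      model <- read_structure(path)
      for (copy in names(model_copies(cfg))) {
        overrides <- model_copies(cfg)[[copy]]
        ch <- list(domain = overrides[[p$domain]], anchor = overrides[[p$anchor]])
        ori <- compute_orientation(model, cal, classical, domain, anchor,
                                   min_pairs = cfg$min_pairs, copy = copy,
                                   model_chains = ch)
        message(ori$entry_id, " copy ", copy, " ", domain$name,
                ": net swivel ", sprintf("%.3f", ori$net_swivel),
                " deg, tilt ", sprintf("%.3f", ori$tilt),
                " deg (core rmsd ", sprintf("%.3f", ori$core_rmsd),
                " A over ", ori$n_atoms, " atoms)")
        rows[[length(rows) + 1L]] <- as.data.frame(ori)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(output_file)) write_report(out, output_file)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_res <- function(x) list(chain = x$chain, resno = as.integer(x$resno))

#' Run configured atom-level measurements on model structures
#'
#' Executes the configuration's measurement list (distances, contact calls,
#' nearest-phosphate searches, mRNA kink angles) on each model and returns
#' one row per (model, measurement).
#'
#' @inheritParams run_angles
#' @return Data frame with columns entry, id, type, value, status, detail.
#' @export
run_measure <- function(cfg, model_paths, output_file = NULL) {
  cfg <- validate_config(unclass(cfg))
  rows <- list()
  for (path in model_paths) {
    model <- read_structure(path)
    for (m in cfg$measurements) {
      row <- data.frame(entry = model$entry_id, id = m$id, type = m$type,
                        value = NA_real_, status = "ok", detail = "",
                        stringsAsFactors = FALSE)
      if (m$type == "distance") {
        row$value <- atom_distance(
          model,
          atom_spec(m$a$chain, m$a$resno, m$a$atom),
          atom_spec(m$b$chain, m$b$resno, m$b$atom))
      } else if (m$type == "contact") {
        cc <- classify_contact(model, as_res(m$a), as_res(m$b),
                               cutoff = m$cutoff %||% cfg$contact_cutoff)
        row$value <- cc$distance
        row$status <- cc$status
        row$detail <- sprintf("cutoff=%.2f", cc$cutoff)
      } else if (m$type == "nearest_phosphate") {
        np <- nearest_phosphate(model, as_res(m$base), m$mrna_chain)
        row$value <- np$distance
        row$detail <- sprintf("resno=%d", np$resno)
      } else if (m$type == "kink") {
        row$value <- mrna_kink(model, m$chain, as.integer(m$vertex))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entry = character(), id = character(), type = character(),
               value = numeric(), status = character(), detail = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(output_file)) write_report(out, output_file)
  out
}
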