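#' Validate a pipeline run configuration
#'
#' A config sets exactly one input mode: `synthetic` (a list of
#' [ensemble_spec()] arguments, plus optional `plddt` generator arguments) or
#' `files` (a list with `ensemble_files`, `reference_fasta`, optionally
#' `plddt_file`). Common fields: `chain_id`, `detection` ([detect_params()]
#' overrides), `displacement_threshold`, `flank_width`, `n_perm`, `seed`,
#' `out_dir`, `prefix`.
#'
#' @param config named list, or path to a JSON/YAML config file.
#' @return validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      cap_stop("capscan_io_error", "config file not found: %s", config)
    config <- if (tolower(tools::file_ext(config)) %in% c("yml", "yaml"))
      yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config))
    cap_stop("capscan_validation_error", "config must be a list or a file path")
  has_syn <- !is.null(config$synthetic)
  has_files <- !is.null(config$files)
  if (has_syn == has_files)
    cap_stop("capscan_validation_error",
             "exactly one input mode required: set `synthetic` or `files`")
  if (has_syn) {
    syn <- config$synthetic
    frac <- syn$state_fractions
    if (!is.null(frac) && abs(sum(frac) - 1) > 1e-9)
      cap_stop("capscan_validation_error",
               "field `synthetic$state_fractions` must sum to 1 (got %.4f)",
               sum(frac))
  } else {
    f <- config$files
    if (is.null(f$ensemble_files) || length(f$ensemble_files) == 0L)
      cap_stop("capscan_validation_error", "field `files$ensemble_files` is empty")
    if (is.null(f$reference_fasta))
      cap_stop("capscan_validation_error", "field `files$reference_fasta` missing")
  }
  if (is.null(config$seed))
    cap_stop("capscan_validation_error",
             "field `seed` is mandatory (permutation test and generators are stochastic)")
  config$chain_id <- config$chain_id %||% "A"
  config$prefix <- config$prefix %||% "capscan"
  config$displacement_threshold <- config$displacement_threshold %||% 4
  config$flank_width <- config$flank_width %||% 15L
  config$n_perm <- config$n_perm %||% 999L
  config
}

log_step <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[capscan] ", fmt), ...))
}

#' Run the capping screen end to end
#'
#' Generates or reads the ensemble, maps every member onto the reference
#' sequence, assigns secondary structure, builds the order matrix, detects
#' folding events, classifies members into conformational states for the
#' strongest event, runs the pLDDT dip test when a profile is available,
#' measures the folded-versus-alternative segment displacement, and writes
#' the TSV/JSON report. Identical config + seed gives identical payloads.
#'
#' @param config see [validate_config()].
#' @param verbose log every stage and applied default via `message()`.
#' @return A `cap_report` list: `events`, `states`, `dip`, `geometry`,
#'   `files` (paths written, when `out_dir` is set), `config`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  config <- validate_config(config)
  chain_id <- config$chain_id
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cap_stop("capscan_stage_error", "stage '%s' failed: %s",
               name, conditionMessage(e))
    })
  }

  # --- input stage ---------------------------------------------------------
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    plddt_args <- syn$plddt
    syn$plddt <- NULL
    syn$seed <- syn$seed %||% config$seed
    spec <- do.call(ensemble_spec, syn)
    log_step(verbose, "generating synthetic ensemble: n=%d, fractions %s, event %d-%d, seed %d",
             spec$n_members, paste(spec$state_fractions, collapse = "/"),
             spec$event_segment[1], spec$event_segment[2], spec$seed)
    ens <- stage("synthetic", make_ensemble(spec))
    members <- ens$members
    reference <- ens$reference
    profile <- if (!is.null(plddt_args)) {
      plddt_args$chain_length <- spec$chain_length
      plddt_args$dip_segment <- plddt_args$dip_segment %||% spec$event_segment
      plddt_args$seed <- plddt_args$seed %||% (config$seed + 1L)
      stage("plddt", do.call(make_plddt, plddt_args))
    }
  } else {
    f <- config$files
    log_step(verbose, "reading %d ensemble members", length(f$ensemble_files))
    members <- stage("read", lapply(f$ensemble_files, read_structure))
    ref_set <- stage("reference", Biostrings::readAAStringSet(f$reference_fasta))
    reference <- as.character(ref_set[[1]])
    profile <- if (!is.null(f$plddt_file))
      stage("plddt", read_plddt(f$plddt_file, length_out = nchar(reference)))
  }

  # --- mapping and order matrix -------------------------------------------
  log_step(verbose, "mapping %d members onto a %d-residue reference",
           length(members), nchar(reference))
  maps <- stage("map", lapply(members, map_to_reference,
                              chain_id = chain_id, reference = reference))
  om <- stage("order_matrix", build_order_matrix(members, maps, chain_id))

  # --- event detection -----------------------------------------------------
  dp <- do.call(detect_params, config$detection %||% list())
  log_step(verbose, "detecting events (theta_h=%.2f, theta_d=%.2f, min_length=%d, merge_gap=%d)",
           dp$theta_h, dp$theta_d, dp$min_length, dp$merge_gap)
  events <- stage("detect", detect_folding_events(om, dp))
  log_step(verbose, "%d event(s) detected", nrow(events))

  states <- NULL; dip <- NULL; geometry <- NULL
  if (nrow(events) > 0) {
    top <- which.max(events$length)
    segment <- c(events$start[top], events$end[top])

    log_step(verbose, "classifying states for event %d-%d (displacement threshold %.1f A)",
             segment[1], segment[2], config$displacement_threshold)
    states <- stage("classify", classify_states(
      members, maps, segment, chain_id = chain_id,
      displacement_threshold = config$displacement_threshold))

    if (!is.null(profile)) {
      log_step(verbose, "pLDDT dip test (flank_width=%d, n_perm=%d, seed=%d)",
               config$flank_width, config$n_perm, config$seed)
      dip <- stage("dip_test", plddt_dip_test(
        profile, segment, flank_width = config$flank_width,
        n_perm = config$n_perm, seed = config$seed))
      events$mean_dip[top] <- dip$delta
      events$p_value[top] <- dip$p_value
    } else {
      log_step(verbose, "no pLDDT source configured; dip test skipped")
    }

    fold_rep <- which(states$labels == "folded")[1]
    alt_rep <- which(states$labels == "alternative")[1]
    if (!is.na(fold_rep) && !is.na(alt_rep)) {
      disp <- stage("geometry", segment_displacement(
        members[[fold_rep]], members[[alt_rep]], maps[[fold_rep]],
        maps[[alt_rep]], segment, chain_a = chain_id, chain_b = chain_id))
      geometry <- list(segment = segment,
                       folded_member = members[[fold_rep]]$id,
                       alternative_member = members[[alt_rep]]$id,
                       displacement_mean = disp[["mean"]],
                       displacement_max = disp[["max"]])
    }
  }

  files <- NULL
  if (!is.null(config$out_dir)) {
    tracks <- apply(om, 2, paste, collapse = "")
    files <- stage("report", write_report(events, states, geometry,
                                          dir = config$out_dir,
                                          prefix = config$prefix,
                                          ss_tracks = tracks))
    log_step(verbose, "report written to %s", config$out_dir)
  }
  structure(list(events = events, states = states, dip = dip,
                 geometry = geometry, order_matrix = om, files = files,
                 config = config),
            class = "cap_report")
}

#' @export
print.cap_report <- function(x, ...) {
  cat(sprintf("<cap_report> %d event(s)\n", nrow(x$events)))
  if (nrow(x$events)) print(as.data.frame(x$events))
  if (!is.null(x$states)) print(x$states)
  if (!is.null(x$dip)) print(x$dip)
  invisible(x)
}
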