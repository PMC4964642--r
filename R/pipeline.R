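# cli_app: run configuration, end-to-end feature pipeline and the
# programmatic command surface behind the inst/cli/pcnfold script

#' Run configuration
#'
#' Bundles every tunable of the pipeline; the defaults reproduce the study
#' settings (8 A contact cutoff, Miyazawa-Jernigan potentials,
#' Kyte-Doolittle hydropathy, long-range separation floor 12, 10-fold CV
#' with 10000 resamplings).
#'
#' @param threshold contact cutoff in Angstrom.
#' @param potentials a [potential_matrix()] or a TSV path.
#' @param hydropathy a [hydropathy_scale()] or a TSV path.
#' @param min_sep LRCO separation floor.
#' @param tolerance,max_iter entropy-solver controls.
#' @param k,n_resamplings cross-validation controls.
#' @param seed integer seed for every stochastic step.
#' @param chain chain selector (`"first"` or a chain id).
#' @param mode discriminant mode, `"quadratic"` or `"linear"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(threshold = 8.0, potentials = NULL, hydropathy = NULL,
                       min_sep = 12L, tolerance = 1e-8, max_iter = 10000L,
                       k = 10L, n_resamplings = 10000L, seed = 1L,
                       chain = "first", mode = "quadratic") {
  if (is.null(potentials)) potentials <- default_potentials()
  else if (is.character(potentials)) potentials <- read_potential_matrix(potentials)
  if (is.null(hydropathy)) hydropathy <- kyte_doolittle()
  else if (is.character(hydropathy)) {
    df <- utils::read.table(hydropathy, header = TRUE, sep = "\t")
    hydropathy <- hydropathy_scale(stats::setNames(df[[2]], df[[1]]),
                                   basename(hydropathy))
  }
  stopifnot(threshold > 0, min_sep >= 0, tolerance > 0, max_iter >= 1,
            k >= 2, n_resamplings >= 1)
  structure(list(threshold = threshold, potentials = potentials,
                 hydropathy = hydropathy, min_sep = as.integer(min_sep),
                 tolerance = tolerance, max_iter = as.integer(max_iter),
                 k = as.integer(k), n_resamplings = as.integer(n_resamplings),
                 seed = as.integer(seed), chain = chain,
                 mode = match.arg(mode, c("quadratic", "linear"))),
            class = "run_config")
}

config_hash <- function(config) {
  # tiny deterministic fingerprint of the resolved settings (polynomial hash)
  s <- paste(config$threshold, config$potentials$name, config$hydropathy$name,
             config$min_sep, config$tolerance, config$max_iter, config$k,
             config$n_resamplings, config$seed, config$chain, config$mode,
             sep = "|")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' All network observables for one protein
#'
#' Runs the full observable pipeline on a C-alpha trace (or directly on a
#' contact network): PCN construction, backbone-reduced Laplacian features,
#' link density, ensemble entropies and classical comparators.
#'
#' @param x a [ca_trace()] or a [contact_network()].  For a bare network the
#'   sequence-dependent observables use unit link weights and `h_mean` is
#'   `NA`.
#' @param config a [run_config()].
#' @param id identifier for the output row (default: the trace's source id).
#' @return One-row `data.frame` with columns `id`, `chain`, `N_C`, `b`,
#'   `lambda_N`, `lambda_N1`, `lambda_N2`, `R0`, `S_s`, `S_ks`, `S_R`,
#'   `h_mean`, `CO`, `LRCO`.
#' @export
pcn_features <- function(x, config = run_config(), id = NULL) {
  if (inherits(x, "ca_trace")) {
    trace <- x
    pcn <- build_pcn(distance_matrix(trace), config$threshold)
    wnet <- apply_contact_potentials(pcn, trace, config$potentials)
    h <- mean_hydropathy(trace, config$hydropathy)
    chain <- trace$chain_id
    if (is.null(id)) id <- trace$source_id
  } else if (inherits(x, "contact_network")) {
    pcn <- x
    wnet <- structure(list(weights = pcn$adjacency, shift = 0,
                           n_residues = pcn$n_residues),
                      class = "weighted_contact_network")
    h <- NA_real_
    chain <- NA_character_
    if (is.null(id)) id <- "network"
  } else stopf("x must be a ca_trace or contact_network")

  ss <- spectral_summary(pcn)
  ent <- entropy_observables(wnet, config$tolerance, config$max_iter)
  data.frame(
    id = id, chain = chain, N_C = pcn$n_residues,
    b = ss$b,
    lambda_N = ss$lambda_features[["lambda_N"]],
    lambda_N1 = ss$lambda_features[["lambda_N1"]],
    lambda_N2 = ss$lambda_features[["lambda_N2"]],
    R0 = link_density_R0(pcn),
    S_s = ent$S_s, S_ks = ent$S_ks, S_R = ent$S_R,
    h_mean = h,
    CO = contact_order(pcn),
    LRCO = long_range_contact_order(pcn, config$min_sep),
    stringsAsFactors = FALSE)
}

read_feature_input <- function(path, config) {
  if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE))
    read_ca_trace(path, chain = config$chain)
  else
    read_contact_matrix(path)
}

#' Compute the feature table for a batch of inputs
#'
#' Accepts PDB structure files and/or dense 0/1 contact-matrix files.
#' Failures on individual inputs are quarantined and reported; the run only
#' fails when no input succeeds.
#'
#' @param inputs character vector of input paths.
#' @param output optional TSV path; when given, the table is written with a
#'   `#`-comment header carrying the package version and config hash.
#' @param config a [run_config()].
#' @return The feature `data.frame` (one row per successful input), with
#'   attribute `"failures"`: a named character vector of error messages.
#' @export
cmd_features <- function(inputs, output = NULL, config = run_config()) {
  if (length(inputs) < 1L) stopf("need at least one input")
  rows <- list()
  failures <- character(0)
  for (path in inputs) {
    row <- tryCatch(
      pcn_features(read_feature_input(path, config), config,
                   id = sub("\\.[^.]*$", "", basename(path))),
      error = function(e) conditionMessage(e))
    if (is.character(row)) {
      failures[path] <- row
      message(sprintf("SKIP %s: %s", path, row))
    } else rows[[path]] <- row
  }
  if (!length(rows))
    stopf("no input could be processed (%d failure(s))", length(failures))
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(output)) write_feature_table(tab, output, config)
  attr(tab, "failures") <- failures
  tab
}

#' @rdname cmd_features
#' @param tab feature data.frame.
#' @param path TSV file.
#' @export
write_feature_table <- function(tab, path, config = run_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pcnfold %s  config %s",
                     as.character(utils::packageVersion("pcnfold")),
                     config_hash(config)), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cmd_features
#' @export
read_feature_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Classify TS vs MS from feature and label tables
#'
#' Joins a feature table (from [cmd_features()]) with a labels table
#' (columns `id`, `label`, `group`), runs homology-grouped k-fold CV on the
#' requested feature subset, and optionally writes the report as JSON.
#'
#' @param features feature `data.frame` or TSV path.
#' @param labels labels `data.frame` or TSV path with columns `id`, `label`
#'   (`TS`/`MS`), `group`.
#' @param feature_subset character vector of feature column names.
#' @param config a [run_config()].
#' @param json optional path for a JSON report.
#' @return A `fold_cv_report`.
#' @export
cmd_classify <- function(features, labels, feature_subset,
                         config = run_config(), json = NULL) {
  if (is.character(features)) features <- read_feature_table(features)
  if (is.character(labels))
    labels <- utils::read.table(labels, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  need <- setdiff(c("id", "label", "group"), names(labels))
  if (length(need))
    stopf("labels table missing column(s): %s", paste(need, collapse = ", "))
  missing_ids <- setdiff(labels$id, features$id)
  if (length(missing_ids))
    stopf("id(s) missing from feature table: %s",
          paste(missing_ids, collapse = ", "))
  miss <- setdiff(feature_subset, names(features))
  if (length(miss))
    stopf("unknown feature column(s): %s", paste(miss, collapse = ", "))

  feats <- features[match(labels$id, features$id), feature_subset, drop = FALSE]
  ds <- labeled_dataset(labels$id, feats, labels$label, labels$group)
  report <- grouped_kfold_cv(ds, feature_subset, k = config$k,
                             n_resamplings = config$n_resamplings,
                             mode = config$mode, seed = config$seed)
  if (!is.null(json))
    jsonlite::write_json(report_to_list(report), json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' Generate synthetic fixtures from the command surface
#'
#' Writes PDB-format traces (`helix`, `globule`) or dense-matrix networks
#' (`banded`) so generated fixtures flow through the same readers as real
#' data.
#'
#' @param kind `"helix"`, `"globule"` or `"banded"`.
#' @param n size (residues or nodes).
#' @param out output file path.
#' @param seed integer seed.
#' @param occupied occupied separations (banded networks only).
#' @return The output path, invisibly.
#' @export
cmd_simulate <- function(kind = c("helix", "globule", "banded"), n, out,
                         seed = 1L, occupied = c(1L, 3L)) {
  kind <- match.arg(kind)
  switch(kind,
    helix = write_ca_pdb(make_helix_trace(n, sequence_seed = seed), out),
    globule = write_ca_pdb(make_random_globule(n, seed = seed), out),
    banded = write_contact_matrix(make_banded_network(n, occupied), out))
  invisible(out)
}
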