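## Required columns per table schema. Feature columns keep a fixed, documented
## order; percentages are stored on the 0-100 scale.
schema_cols <- function(schema = c("derived", "sample_summary",
                                   "donor_vectors")) {
  schema <- match.arg(schema)
  switch(schema,
    derived = c("donor_id", "run_id", "role", "n_cells",
                derived_feature_cols()),
    sample_summary = c("donor_id", "run_id", "role", "treatment", "n_cells",
                       "tmrm_intensity", "tmrm_intensity_mean",
                       "tmrm_pixel_mean", "tmrm_area_um2", "spot_area_um2",
                       "spot_perimeter_um", "form_factor", "nao_intensity",
                       "mitosox_cyto_intensity"),
    donor_vectors = c("donor_id", "run_id", "role", "control_id",
                      ifc_features_pct(), "mmp_pct", "fccp_response_pct",
                      "ros_per_mass"))
}

#' Read a feature table
#'
#' Reads a CSV feature table and validates it against the named schema,
#' erroring with the file name and the missing or malformed column.
#'
#' @param path CSV file path.
#' @param schema one of \code{"derived"} (per-sample composite features, the
#'   cohort fast-path format), \code{"sample_summary"} (per-treatment medians)
#'   or \code{"donor_vectors"} (normalized percentages).
#' @return validated data frame.
#' @export
read_feature_table <- function(path, schema = "derived") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- schema_cols(schema)
  miss <- setdiff(cols, names(tbl))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s for schema '%s'",
                 path, paste(miss, collapse = ", "), schema), call. = FALSE)
  numcols <- setdiff(cols, c("donor_id", "run_id", "role", "treatment",
                             "control_id"))
  for (cn in numcols) {
    v <- tbl[[cn]]
    if (!is.numeric(v) && !all(is.na(v)))
      stop(sprintf("%s: column '%s' must be numeric", path, cn),
           call. = FALSE)
  }
  tbl
}

#' Write a feature table
#'
#' Writes the table as CSV with the schema's fixed column order first (extra
#' columns follow) and validates completeness before writing.
#'
#' @param tbl data frame.
#' @param path output CSV path.
#' @param schema see \code{\link{read_feature_table}}.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(tbl, path, schema = "derived") {
  cols <- schema_cols(schema)
  miss <- setdiff(cols, names(tbl))
  if (length(miss))
    stop("table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ord <- c(cols, setdiff(names(tbl), cols))
  utils::write.csv(tbl[, ord, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a clinical phenotype table
#'
#' CSV with a \code{donor_id} column and one column per binary phenotype;
#' every phenotype value must be \code{"Yes"}, \code{"No"} or \code{"NA"}
#' (the literal string or an empty cell). Any other value is rejected with its
#' row index and column name.
#'
#' @param path CSV file path.
#' @return data frame with donor_id and character phenotype columns
#'   ("Yes"/"No"/NA).
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  if (!"donor_id" %in% names(tbl))
    stop(path, ": missing column donor_id", call. = FALSE)
  for (cn in setdiff(names(tbl), "donor_id")) {
    v <- trimws(tbl[[cn]])
    bad <- which(!(v %in% c("Yes", "No", "NA", "")))
    if (length(bad))
      stop(sprintf("%s: invalid clinical value '%s' (column '%s', row %d); allowed: Yes, No, NA",
                   path, v[bad[1]], cn, bad[1]), call. = FALSE)
    v[v %in% c("NA", "")] <- NA_character_
    tbl[[cn]] <- v
  }
  tbl
}

ifc_channel_order <- c("brightfield", "nao", "tmrm", "draq5", "mitosox")
ifc_channel_names <- c(brightfield = "BF", nao = "NAO", tmrm = "TMRM",
                       draq5 = "DRAQ5", mitosox = "MITOSOX")

#' Write a cell event as a multi-page TIFF plus JSON sidecar
#'
#' Channels are written as one 32-bit float page each (in the fixed order BF,
#' NAO, TMRM, DRAQ5, MITOSOX), linearly rescaled to [0, 1]; the scale factor,
#' channel names, pixel size, treatment and scalar ground-truth annotations go
#' to the \code{<path>.json} sidecar so the round trip is lossless.
#'
#' @param cell a \code{cell_image}.
#' @param path output file (.tif).
#' @return \code{path}, invisibly.
#' @export
write_cell_image <- function(cell, path) {
  stopifnot(inherits(cell, "cell_image"))
  scale <- max(1e-12, max(vapply(cell$channels, max, numeric(1))))
  pages <- lapply(ifc_channel_order, function(ch) cell$channels[[ch]] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  gt <- cell$ground_truth
  side <- list(
    event_id = cell$event_id,
    treatment = cell$treatment,
    pixel_size = cell$pixel_size,
    scale = scale,
    channels = unname(ifc_channel_names[ifc_channel_order]),
    ground_truth = if (is.null(gt)) NULL else list(
      n_components = gt$n_components,
      areas_px = gt$areas_px,
      areas_um2 = gt$areas_um2,
      perimeters_um = gt$perimeters_um,
      tmrm_level_effective = gt$tmrm_level_effective,
      levels = gt$levels,
      singlet = gt$singlet,
      in_focus = gt$in_focus)
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a cell event written by \code{\link{write_cell_image}}
#'
#' @param path the .tif path (its .json sidecar must sit next to it).
#' @return a \code{cell_image} (mask-level ground truth is not serialized;
#'   scalar annotations are restored).
#' @export
read_cell_image <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side_path))
    stop("image or sidecar missing for ", path, call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(ifc_channel_order))
    stop(path, ": expected ", length(ifc_channel_order), " channel pages",
         call. = FALSE)
  chans <- lapply(pages, function(p) p * side$scale)
  names(chans) <- ifc_channel_order
  structure(list(channels = chans, pixel_size = side$pixel_size,
                 event_id = side$event_id, treatment = side$treatment,
                 ground_truth = side$ground_truth),
            class = "cell_image")
}

#' Read a directory/glob of cell images into paired events
#'
#' @param paths character vector of .tif files, or a directory.
#' @return list of \code{list(untreated =, fccp =)} pairs, matched on
#'   event_id.
#' @export
read_images <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.tiff?$", full.names = TRUE)
  if (length(paths) == 0L) stop("no images found", call. = FALSE)
  cells <- lapply(sort(paths), read_cell_image)
  ids <- vapply(cells, function(c) c$event_id, character(1))
  out <- lapply(unique(ids), function(id) {
    grp <- cells[ids == id]
    trt <- vapply(grp, function(c) c$treatment, character(1))
    list(untreated = if ("untreated" %in% trt) grp[[match("untreated", trt)]],
         fccp = if ("fccp" %in% trt) grp[[match("fccp", trt)]])
  })
  names(out) <- unique(ids)
  out
}

## ---- pipeline configuration -------------------------------------------------

#' Pipeline configuration
#'
#' Builds the full, validated configuration of \code{\link{run_pipeline}}.
#' Unknown keys anywhere in the structure are rejected, and configurations
#' round-trip losslessly through YAML/JSON (\code{\link{write_config}},
#' \code{\link{read_config}}).
#'
#' @param seed master seed for the synthetic stages.
#' @param simulate list: \code{mode} ("features" or "images"), cohort sizes
#'   and noise levels, and (image mode) per-sample event counts and artifact
#'   rates.
#' @param input list: optional \code{feature_table} and \code{clinical_table}
#'   CSV paths that bypass simulation.
#' @param gates,spot_mask gate and spot-mask settings (see
#'   \code{\link{gate_config}}, \code{\link{spot_mask_params}}).
#' @param cohort clustering/embedding settings.
#' @param output_dir where \code{run_pipeline} writes its tables; NULL keeps
#'   everything in memory.
#' @return nested list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1,
                            simulate = list(),
                            input = list(),
                            gates = list(),
                            spot_mask = list(),
                            cohort = list(),
                            output_dir = NULL) {
  defaults <- list(
    seed = 1,
    simulate = list(mode = "features", n_patients = 31, n_controls = 6,
                    run_scale_sd = 0.2, donor_noise_sd = 0.05,
                    patient_hetero_sd = 0.10,
                    n_cells = 20, doublet_rate = 0.05, blur_rate = 0.05,
                    canvas = 256, cell_radius = 80, nucleus_radius = 18,
                    noise_sd = 5),
    input = list(feature_table = NULL, clinical_table = NULL),
    gates = unclass(gate_config()),
    spot_mask = unclass(spot_mask_params()),
    cohort = list(k = "auto", n_neighbors = 8, min_dist = 0.01,
                  umap_seed = 42, missing = "drop", umap = TRUE),
    output_dir = NULL)
  user <- list(seed = seed, simulate = simulate, input = input, gates = gates,
               spot_mask = spot_mask, cohort = cohort,
               output_dir = output_dir)
  merge_section <- function(def, usr, where) {
    if (is.null(usr)) return(def)
    if (!is.list(def)) return(usr)
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown))
      stop(sprintf("unknown config key%s in %s: %s",
                   if (length(unknown) > 1) "s" else "", where,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    for (nm in names(usr)) def[nm] <- list(usr[[nm]])   # keeps NULL entries
    def
  }
  cfg <- defaults
  for (sec in c("simulate", "input", "gates", "spot_mask", "cohort"))
    cfg[[sec]] <- merge_section(defaults[[sec]], user[[sec]], sec)
  cfg$seed <- seed
  cfg$output_dir <- output_dir
  check_number(cfg$seed, "seed", integer = TRUE)
  if (!cfg$simulate$mode %in% c("features", "images"))
    stop("simulate$mode must be 'features' or 'images'", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' Serializes to YAML (default) or JSON by file extension; reading re-runs the
#' full validation, so unknown keys in an edited file are rejected.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param path file ending in .yaml/.yml or .json.
#' @return \code{path} invisibly (write); the validated config (read).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
       else yaml::read_yaml(path)
  pipeline_config(seed = x$seed, simulate = x$simulate,
                  input = x$input %||% list(), gates = x$gates,
                  spot_mask = x$spot_mask, cohort = x$cohort,
                  output_dir = x$output_dir)
}

## Image-mode helper: render, gate, extract and summarize one donor sample.
simulate_donor_sample <- function(base_params, effects, run_scale, n_cells,
                                  doublet_rate, blur_rate, gates, spot_params,
                                  donor_id, run_id, role, seed) {
  p <- base_params
  p$tmrm_level <- p$tmrm_level * effects[["membrane_potential"]] * run_scale
  p$nao_level <- p$nao_level * effects[["mito_mass"]] * run_scale
  p$mitosox_level <- p$mitosox_level * effects[["ros"]] * run_scale
  ## integer dilation radius: small swelling shifts are expressed coarsely in
  ## image mode (the feature-level path carries them exactly)
  p$swelling_scale <- p$swelling_scale * effects[["swelling"]]
  smp <- generate_sample(p, n_cells, doublet_rate, blur_rate, seed = seed)
  gated <- gate_events(smp, gates)
  feats <- extract_features(gated, spot_params)
  summarize_sample(feats, donor_id, run_id, role)
}

#' Run the end-to-end pipeline
#'
#' Executes the workflow: obtain a derived feature table (simulated at the
#' feature level, simulated as images then gated/extracted/aggregated, or read
#' from \code{input$feature_table}), normalize every donor to its in-run
#' control, build healthy reference ranges and abnormality flags, compute the
#' feature-combination detection curve, and run the cohort analysis
#' (Ward clustering, optional UMAP, association tests). Deterministic for a
#' fixed config.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{"ifc_pipeline_result"}: \code{table} (derived
#'   features), \code{vectors}, \code{ranges}, \code{flags},
#'   \code{detection}, \code{cohort}, \code{config}. When
#'   \code{config$output_dir} is set, all tables are also written there
#'   (CSV/JSON/Newick) together with a full-precision config echo.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must come from pipeline_config()", call. = FALSE)
  sim <- config$simulate
  gt <- NULL
  if (!is.null(config$input$feature_table)) {
    tbl <- read_feature_table(config$input$feature_table, "derived")
  } else if (sim$mode == "features") {
    design <- cohort_design(n_patients = sim$n_patients,
                            n_controls = sim$n_controls,
                            run_scale_sd = sim$run_scale_sd,
                            donor_noise_sd = sim$donor_noise_sd,
                            patient_hetero_sd = sim$patient_hetero_sd,
                            seed = config$seed)
    tbl <- generate_cohort_table(design)
    gt <- attr(tbl, "ground_truth")
  } else {
    tbl <- simulate_image_cohort(config)
    gt <- attr(tbl, "ground_truth")
  }
  vectors <- donor_vectors(tbl)
  ranges <- reference_ranges(vectors)
  pat <- vectors[vectors$role == "patient", , drop = FALSE]
  flags <- flag_abnormal(pat, ranges)
  detection <- combination_detection(flags)
  clinical <- NULL
  if (!is.null(config$input$clinical_table)) {
    cl_tab <- read_clinical_table(config$input$clinical_table)
    clinical <- cl_tab[match(pat$donor_id, cl_tab$donor_id), , drop = FALSE]
  }
  cohort <- cohort_analysis(vectors, clinical = clinical,
                            k = config$cohort$k,
                            seed = config$cohort$umap_seed,
                            missing = config$cohort$missing,
                            umap = isTRUE(config$cohort$umap))
  subgroup <- NULL
  if (!all(is.na(pat$subtype))) {
    ref <- vectors[vectors$role == "reference_control",
                   ifc_features_pct(), drop = FALSE]
    subgroup <- subgroup_vs_reference(pat[, ifc_features_pct(), drop = FALSE],
                                      pat$subtype, ref)
  }
  res <- structure(list(table = tbl, vectors = vectors, ranges = ranges,
                        flags = flags, detection = detection,
                        cohort = cohort, subgroup_tests = subgroup,
                        ground_truth = gt, config = config),
                   class = "ifc_pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_outputs(res)
  res
}

## Image-mode cohort: one patient + one in-run control per run, shared
## log-normal run intensity scale, cluster effects applied to the renderer.
simulate_image_cohort <- function(config) {
  sim <- config$simulate
  design <- cohort_design(n_patients = sim$n_patients,
                          n_controls = sim$n_controls,
                          run_scale_sd = sim$run_scale_sd,
                          donor_noise_sd = sim$donor_noise_sd,
                          patient_hetero_sd = sim$patient_hetero_sd,
                          seed = config$seed)
  gates <- do.call(gate_config, config$gates)
  spp <- do.call(spot_mask_params, config$spot_mask)
  base <- cell_phenotype_params(canvas = sim$canvas,
                                cell_radius = sim$cell_radius,
                                nucleus_radius = sim$nucleus_radius,
                                noise_sd = sim$noise_sd)
  no_eff <- stats::setNames(rep(1, 5), names(default_effect_sizes()[["1"]]))
  with_seed(config$seed, {
    seeds <- sample.int(.Machine$integer.max %/% 2L,
                        2L * design$n_patients + 2L * design$n_controls)
    scales <- exp(stats::rnorm(design$n_patients + design$n_controls, 0,
                               design$run_scale_sd))
    rows <- list()
    si <- 0L
    ## control runs against the designated normalizer HC1
    for (k in seq_len(design$n_controls)) {
      run <- sprintf("ctrlrun%02d", k)
      si <- si + 1L
      rows[[length(rows) + 1L]] <- simulate_donor_sample(
        base, no_eff, scales[k], sim$n_cells, sim$doublet_rate,
        sim$blur_rate, gates, spp, sprintf("HC%d", k), run,
        "reference_control", seeds[si])
      si <- si + 1L
      rows[[length(rows) + 1L]] <- simulate_donor_sample(
        base, no_eff, scales[k], sim$n_cells, sim$doublet_rate,
        sim$blur_rate, gates, spp, "HC1", run, "control", seeds[si])
    }
    for (p in seq_len(design$n_patients)) {
      run <- sprintf("run%02d", p)
      cl <- design$cluster_assignment[p]
      eff <- design$effect_sizes[[as.character(cl)]]
      sc <- scales[design$n_controls + p]
      si <- si + 1L
      srow <- simulate_donor_sample(base, eff, sc, sim$n_cells,
                                    sim$doublet_rate, sim$blur_rate, gates,
                                    spp, sprintf("P%02d", p), run, "patient",
                                    seeds[si])
      srow$cluster <- cl
      srow$subtype <- design$subtypes[p]
      rows[[length(rows) + 1L]] <- srow
      si <- si + 1L
      rows[[length(rows) + 1L]] <- simulate_donor_sample(
        base, no_eff, sc, sim$n_cells, sim$doublet_rate, sim$blur_rate,
        gates, spp, sprintf("HC%d", (p - 1L) %% design$n_controls + 1L), run,
        "control", seeds[si])
    }
    summaries <- do.call(rbind, lapply(rows, function(r) {
      for (cn in c("cluster", "subtype"))
        if (is.null(r[[cn]])) r[[cn]] <- NA
      r
    }))
    tbl <- derive_sample_features(summaries)
    tbl$cluster <- summaries$cluster[match(paste(tbl$donor_id, tbl$run_id),
                                           paste(summaries$donor_id,
                                                 summaries$run_id))]
    tbl$subtype <- summaries$subtype[match(paste(tbl$donor_id, tbl$run_id),
                                           paste(summaries$donor_id,
                                                 summaries$run_id))]
    attr(tbl, "ground_truth") <-
      data.frame(donor_id = sprintf("P%02d", seq_len(design$n_patients)),
                 cluster = design$cluster_assignment,
                 stringsAsFactors = FALSE)
    tbl
  })
}

write_pipeline_outputs <- function(res) {
  dir.create(res$config$output_dir, showWarnings = FALSE, recursive = TRUE)
  od <- res$config$output_dir
  write_feature_table(res$table, file.path(od, "derived_features.csv"),
                      "derived")
  write_feature_table(res$vectors, file.path(od, "donor_vectors.csv"),
                      "donor_vectors")
  jsonlite::write_json(
    list(n_reference_donors = attr(res$ranges, "n_reference_donors"),
         ranges = as.data.frame(unclass(res$ranges))),
    file.path(od, "reference_ranges.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(res$flags, file.path(od, "flags.csv"), row.names = FALSE)
  utils::write.csv(res$detection, file.path(od, "combination_detection.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(donor_id = names(res$cohort$labels),
                              cluster = unname(res$cohort$labels)),
                   file.path(od, "cluster_labels.csv"), row.names = FALSE)
  if (!is.null(res$cohort$embedding))
    utils::write.csv(data.frame(donor_id = rownames(res$cohort$embedding),
                                res$cohort$embedding),
                     file.path(od, "embedding.csv"), row.names = FALSE)
  if (!is.null(res$cohort$feature_tests))
    utils::write.csv(res$cohort$feature_tests,
                     file.path(od, "feature_tests.csv"), row.names = FALSE)
  if (!is.null(res$subgroup_tests) && nrow(res$subgroup_tests$tests))
    utils::write.csv(res$subgroup_tests$tests,
                     file.path(od, "subgroup_tests.csv"), row.names = FALSE)
  if (!is.na(res$cohort$clustering$newick))
    writeLines(res$cohort$clustering$newick,
               file.path(od, "dendrogram.nwk"))
  write_config(res$config, file.path(od, "config_echo.json"))
  invisible(od)
}

#' @export
print.ifc_pipeline_result <- function(x, ...) {
  cat(sprintf("<ifc_pipeline_result> %d donor measurements, %d patients\n",
              nrow(x$table), sum(x$vectors$role == "patient")))
  k5 <- x$detection[x$detection$k == max(x$detection$k), ]
  cat(sprintf("any-feature detection: %.1f%% of patients\n", k5$mean_pct))
  print(x$cohort)
  invisible(x)
}
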