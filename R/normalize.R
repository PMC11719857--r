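## Canonical feature naming used throughout the cohort-level code.
ifc_features_pct <- function() c("membrane_potential_pct", "mito_mass_pct",
                                 "swelling_pct", "form_factor_pct", "ros_pct")

derived_feature_cols <- function() c("delta_mmp", "mmp", "nao_intensity",
                                     "tmrm_area_um2", "form_factor",
                                     "mitosox_cyto_intensity", "fccp_ratio")

#' Background-subtracted membrane potential
#'
#' TMRM intensity of the untreated sample minus the residual TMRM intensity
#' under FCCP uncoupling. Negative values are possible (e.g. staining drift)
#' and are returned as-is; downstream code flags them as quality anomalies
#' rather than clipping.
#'
#' @param tmrm_untreated,tmrm_fccp sample-level TMRM intensity summaries
#'   (a.u.), vectorized.
#' @return \code{tmrm_untreated - tmrm_fccp}; NA if either member is missing.
#' @export
delta_mmp <- function(tmrm_untreated, tmrm_fccp) {
  tmrm_untreated - tmrm_fccp
}

#' FCCP response ratio
#'
#' Mean TMRM intensity of the untreated sample divided by the mean TMRM
#' intensity of the FCCP-treated sample. A non-positive FCCP intensity yields
#' a missing value.
#'
#' @param tmrm_untreated,tmrm_fccp mean TMRM intensities (a.u.), vectorized.
#' @return dimensionless ratio, NA where \code{tmrm_fccp <= 0}.
#' @export
fccp_response <- function(tmrm_untreated, tmrm_fccp) {
  out <- tmrm_untreated / tmrm_fccp
  out[!is.na(tmrm_fccp) & tmrm_fccp <= 0] <- NA_real_
  out
}

#' Percent of in-run control
#'
#' @param patient_value,control_value sample-level values sharing a run.
#' @param patient_run,control_run optional run identifiers; if both given they
#'   must match.
#' @return \code{100 * patient_value / control_value}; NA where the control is
#'   non-positive.
#' @export
normalize_to_control <- function(patient_value, control_value,
                                 patient_run = NULL, control_run = NULL) {
  if (!is.null(patient_run) && !is.null(control_run) &&
      !all(patient_run == control_run))
    stop("patient and control values come from different runs", call. = FALSE)
  out <- 100 * patient_value / control_value
  out[!is.na(control_value) & control_value <= 0] <- NA_real_
  out
}

#' ROS production per unit mitochondrial mass
#'
#' Ratio of the normalized MitoSox percentage to the normalized NAO
#' percentage. Both inputs are percent-of-control values, so the ratio is
#' dimensionless (1 = ROS in proportion to mass).
#'
#' @param mitosox_pct,nao_pct normalized percentages, vectorized.
#' @return ratio, NA where \code{nao_pct <= 0}.
#' @export
ros_per_mass <- function(mitosox_pct, nao_pct) {
  out <- mitosox_pct / nao_pct
  out[!is.na(nao_pct) & nao_pct <= 0] <- NA_real_
  out
}

#' Aggregate per-cell features to a per-sample summary
#'
#' Takes the per-cell table of \code{\link{extract_features}} and reduces it
#' to one row per treatment condition with the sample median of every feature
#' (medians are the study's aggregation choice) plus the across-cell mean of
#' integrated TMRM intensity, which the FCCP response ratio uses.
#'
#' @param features a \code{cell_features} data frame.
#' @param donor_id,run_id,role sample identity; `role` is one of
#'   \code{"patient"}, \code{"control"}, \code{"reference_control"}.
#' @return data frame with rows \code{treatment = "untreated"} and, when FCCP
#'   columns are present, \code{treatment = "fccp"}.
#' @export
summarize_sample <- function(features, donor_id, run_id,
                             role = c("patient", "control",
                                      "reference_control")) {
  role <- match.arg(role)
  if (nrow(features) == 0L) stop("empty feature table", call. = FALSE)
  med <- function(v) if (all(is.na(v))) NA_real_ else
    stats::median(v, na.rm = TRUE)
  mn <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  untr <- data.frame(
    donor_id = donor_id, run_id = run_id, role = role,
    treatment = "untreated", n_cells = nrow(features),
    tmrm_intensity = med(features$tmrm_intensity),
    tmrm_intensity_mean = mn(features$tmrm_intensity),
    tmrm_pixel_mean = med(features$tmrm_pixel_mean),
    tmrm_area_um2 = med(features$tmrm_area_um2),
    spot_area_um2 = med(features$spot_area_um2),
    spot_perimeter_um = med(features$spot_perimeter_um),
    form_factor = med(features$form_factor),
    nao_intensity = NA_real_,
    mitosox_cyto_intensity = med(features$mitosox_cyto_intensity),
    stringsAsFactors = FALSE)
  out <- untr
  if (!all(is.na(features$tmrm_intensity_fccp))) {
    fccp <- untr
    fccp$treatment <- "fccp"
    fccp$tmrm_intensity <- med(features$tmrm_intensity_fccp)
    fccp$tmrm_intensity_mean <- mn(features$tmrm_intensity_fccp)
    fccp$tmrm_pixel_mean <- med(features$tmrm_pixel_mean_fccp)
    fccp$tmrm_area_um2 <- NA_real_
    fccp$spot_area_um2 <- NA_real_
    fccp$spot_perimeter_um <- NA_real_
    fccp$form_factor <- NA_real_
    fccp$nao_intensity <- med(features$nao_intensity)
    fccp$mitosox_cyto_intensity <- NA_real_
    out <- rbind(untr, fccp)
  }
  rownames(out) <- NULL
  out
}

#' Derive per-sample composite features
#'
#' Collapses a treatment-level sample summary (rows untreated/FCCP) into the
#' derived feature row used by normalization: background-subtracted membrane
#' potential (delta MMP), absolute MMP, NAO mass (from the FCCP member), total
#' TMRM area, form factor (from sample-median spot area and perimeter when
#' available, otherwise the median per-cell form factor), cytoplasmic MitoSox,
#' and the FCCP response ratio of mean TMRM intensities.
#'
#' @param summary_tbl output of \code{\link{summarize_sample}} (possibly
#'   several samples stacked).
#' @return data frame with one row per donor/run and the columns of
#'   \code{mitoifc:::derived_feature_cols}.
#' @export
derive_sample_features <- function(summary_tbl) {
  need <- c("donor_id", "run_id", "role", "treatment")
  if (!all(need %in% names(summary_tbl)))
    stop("summary table lacks columns: ",
         paste(setdiff(need, names(summary_tbl)), collapse = ", "),
         call. = FALSE)
  key <- interaction(summary_tbl$donor_id, summary_tbl$run_id,
                     summary_tbl$role, drop = TRUE)
  out <- lapply(split(summary_tbl, key), function(s) {
    u <- s[s$treatment == "untreated", , drop = FALSE]
    f <- s[s$treatment == "fccp", , drop = FALSE]
    if (nrow(u) != 1L)
      stop(sprintf("sample %s/%s lacks a unique untreated row",
                   s$donor_id[1], s$run_id[1]), call. = FALSE)
    hasf <- nrow(f) == 1L
    ff <- if (is.finite(u$spot_area_um2) && u$spot_area_um2 > 0 &&
              is.finite(u$spot_perimeter_um))
      u$spot_perimeter_um^2 / (4 * pi * u$spot_area_um2)
    else u$form_factor
    data.frame(
      donor_id = u$donor_id, run_id = u$run_id, role = u$role,
      n_cells = u$n_cells,
      delta_mmp = if (hasf) delta_mmp(u$tmrm_intensity, f$tmrm_intensity)
                  else NA_real_,
      mmp = u$tmrm_intensity,
      nao_intensity = if (hasf) f$nao_intensity else NA_real_,
      tmrm_area_um2 = u$tmrm_area_um2,
      form_factor = ff,
      mitosox_cyto_intensity = u$mitosox_cyto_intensity,
      fccp_ratio = if (hasf)
        fccp_response(u$tmrm_intensity_mean, f$tmrm_intensity_mean)
      else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Normalize a cohort table to in-run controls
#'
#' Converts a derived feature table (from \code{\link{generate_cohort_table}}
#' or \code{\link{derive_sample_features}}) into per-donor normalized
#' percentage vectors. Within every run the single \code{role == "control"}
#' row is the normalizer; every other row in the run is expressed as a
#' percentage of it. The FCCP response ratio is likewise normalized to the
#' control's ratio, and ROS-per-mass is the ratio of the normalized MitoSox
#' and NAO percentages. Negative delta-MMP values are retained and marked in
#' the \code{negative_dmmp} quality column.
#'
#' @param tbl derived feature table; required columns: donor_id, run_id, role
#'   plus the derived feature columns.
#' @return data frame of class \code{"donor_vectors"}: one row per
#'   non-control donor measurement with the five feature percentages,
#'   \code{fccp_response_pct}, \code{ros_per_mass} and metadata columns.
#' @export
donor_vectors <- function(tbl) {
  need <- c("donor_id", "run_id", "role", "delta_mmp", "nao_intensity",
            "tmrm_area_um2", "form_factor", "mitosox_cyto_intensity")
  miss <- setdiff(need, names(tbl))
  if (length(miss))
    stop("table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(split(tbl, tbl$run_id), function(run) {
    ctrl <- run[run$role == "control", , drop = FALSE]
    subj <- run[run$role != "control", , drop = FALSE]
    if (nrow(ctrl) != 1L)
      stop(sprintf("run '%s' must contain exactly one in-run control",
                   run$run_id[1]), call. = FALSE)
    if (nrow(subj) == 0L) return(NULL)
    mp <- normalize_to_control(subj$delta_mmp, ctrl$delta_mmp)
    mass <- normalize_to_control(subj$nao_intensity, ctrl$nao_intensity)
    sw <- normalize_to_control(subj$tmrm_area_um2, ctrl$tmrm_area_um2)
    ffp <- normalize_to_control(subj$form_factor, ctrl$form_factor)
    ros <- normalize_to_control(subj$mitosox_cyto_intensity,
                                ctrl$mitosox_cyto_intensity)
    fr <- if ("fccp_ratio" %in% names(tbl))
      normalize_to_control(subj$fccp_ratio, ctrl$fccp_ratio)
    else rep(NA_real_, nrow(subj))
    mmp_pct <- if ("mmp" %in% names(tbl))
      normalize_to_control(subj$mmp, ctrl$mmp)
    else rep(NA_real_, nrow(subj))
    data.frame(
      donor_id = subj$donor_id, run_id = subj$run_id, role = subj$role,
      cluster = if ("cluster" %in% names(subj)) subj$cluster else NA_integer_,
      subtype = if ("subtype" %in% names(subj)) subj$subtype else NA_character_,
      control_id = ctrl$donor_id,
      membrane_potential_pct = mp, mito_mass_pct = mass, swelling_pct = sw,
      form_factor_pct = ffp, ros_pct = ros,
      mmp_pct = mmp_pct,
      fccp_response_pct = fr,
      ros_per_mass = ros_per_mass(ros, mass),
      negative_dmmp = !is.na(subj$delta_mmp) & subj$delta_mmp < 0,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("donor_vectors", "data.frame")
  out
}

#' Healthy-donor reference ranges
#'
#' Builds the per-feature reference interval from the normalized percentages
#' of the healthy reference donors: the lowest observed percentage is the
#' lower reference value and the highest the upper. Features missing in some
#' control are ranged over the available donors with a warning.
#'
#' @param control_vectors a \code{donor_vectors} table; rows with
#'   \code{role == "reference_control"} are used (all rows if no such role is
#'   present).
#' @return object of class \code{"ifc_ref_ranges"}: data frame (feature,
#'   lower_pct, upper_pct, n_donors) with attribute
#'   \code{n_reference_donors}.
#' @export
reference_ranges <- function(control_vectors) {
  cv <- control_vectors
  if ("role" %in% names(cv) && any(cv$role == "reference_control"))
    cv <- cv[cv$role == "reference_control", , drop = FALSE]
  if (nrow(cv) < 2L)
    stop("reference ranges need at least 2 control donors", call. = FALSE)
  feats <- ifc_features_pct()
  miss <- setdiff(feats, names(cv))
  if (length(miss))
    stop("control vectors lack features: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- lapply(feats, function(f) {
    v <- cv[[f]]
    if (anyNA(v)) {
      warning(sprintf("feature '%s' missing in %d control donor(s); range built on the rest",
                      f, sum(is.na(v))), call. = FALSE)
      v <- v[!is.na(v)]
    }
    if (length(v) < 2L)
      stop(sprintf("feature '%s' observed in fewer than 2 controls", f),
           call. = FALSE)
    data.frame(feature = f, lower_pct = min(v), upper_pct = max(v),
               n_donors = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_reference_donors") <- nrow(cv)
  class(out) <- c("ifc_ref_ranges", "data.frame")
  out
}

#' @export
print.ifc_ref_ranges <- function(x, ...) {
  cat(sprintf("<ifc_ref_ranges> built from %d reference donors\n",
              attr(x, "n_reference_donors")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Flag abnormal feature values
#'
#' A value is abnormal when it strictly exceeds the reference interval on
#' either side (boundary values are normal). Missing feature values give a
#' missing flag, which is excluded from the any-feature summary rather than
#' counted as normal.
#'
#' @param vectors a \code{donor_vectors} data frame (one or more rows).
#' @param ranges an \code{\link{reference_ranges}} object.
#' @return data frame: donor_id, one logical flag per feature, and
#'   \code{any_flag}.
#' @export
flag_abnormal <- function(vectors, ranges) {
  if (!inherits(ranges, "ifc_ref_ranges"))
    stop("'ranges' must come from reference_ranges()", call. = FALSE)
  feats <- ranges$feature
  flags <- sapply(feats, function(f) {
    v <- vectors[[f]]
    lo <- ranges$lower_pct[ranges$feature == f]
    hi <- ranges$upper_pct[ranges$feature == f]
    ifelse(is.na(v), NA, v < lo | v > hi)
  })
  flags <- matrix(flags, nrow = nrow(vectors),
                  dimnames = list(NULL, sub("_pct$", "_flag", feats)))
  any_flag <- apply(flags, 1L, function(r)
    if (all(is.na(r))) NA else any(r, na.rm = TRUE))
  cbind(data.frame(donor_id = vectors$donor_id, stringsAsFactors = FALSE),
        as.data.frame(flags), data.frame(any_flag = any_flag))
}

#' Detection rate over all feature combinations
#'
#' For every subset S of the five features and every subset size k, the
#' detection rate of S is the percentage of patients flagged on at least one
#' feature in S. Results are aggregated per k to the mean, minimum and maximum
#' over all choose(5, k) subsets.
#'
#' @param flag_matrix logical patients x features matrix (or the output of
#'   \code{\link{flag_abnormal}}, from which the five feature-flag columns are
#'   taken). Missing flags are treated as not-flagged, with a warning.
#' @return data frame: k, n_subsets, mean_pct, min_pct, max_pct.
#' @export
combination_detection <- function(flag_matrix) {
  if (is.data.frame(flag_matrix)) {
    cols <- grep("_flag$", names(flag_matrix), value = TRUE)
    cols <- setdiff(cols, "any_flag")
    flag_matrix <- as.matrix(flag_matrix[, cols, drop = FALSE])
  }
  if (is.null(dim(flag_matrix)) || nrow(flag_matrix) == 0L)
    stop("flag matrix must contain at least one patient", call. = FALSE)
  if (anyNA(flag_matrix)) {
    warning("missing flags treated as not-flagged", call. = FALSE)
    flag_matrix[is.na(flag_matrix)] <- FALSE
  }
  mode(flag_matrix) <- "logical"
  n_feat <- ncol(flag_matrix)
  n_pat <- nrow(flag_matrix)
  out <- lapply(seq_len(n_feat), function(k) {
    subsets <- utils::combn(n_feat, k, simplify = FALSE)
    det <- vapply(subsets, function(s)
      100 * sum(apply(flag_matrix[, s, drop = FALSE], 1L, any)) / n_pat,
      numeric(1))
    data.frame(k = k, n_subsets = length(subsets), mean_pct = mean(det),
               min_pct = min(det), max_pct = max(det))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compound-effect grid
#'
#' Percent-of-control matrix of feature responses to molecular compound
#' treatments: each compound-treated sample is normalized against the healthy
#' control analyzed within the same run. Rows cover the six readouts
#' (delta MMP, absolute MMP, mass, swelling, form factor, ROS).
#'
#' @param treated derived feature table of compound-treated samples, with a
#'   \code{compound} column.
#' @param control derived feature table of the matching in-run controls
#'   (matched by \code{run_id}).
#' @return numeric matrix, features x compounds (percent of control).
#'   Compounds whose control run is missing are dropped with a warning.
#' @export
compound_effect_grid <- function(treated, control) {
  if (!"compound" %in% names(treated))
    stop("'treated' needs a compound column", call. = FALSE)
  featmap <- c(delta_mmp = "delta_mmp", mmp = "mmp", mito_mass = "nao_intensity",
               swelling = "tmrm_area_um2", form_factor = "form_factor",
               ros = "mitosox_cyto_intensity")
  cols <- list()
  for (i in seq_len(nrow(treated))) {
    ctrl <- control[control$run_id == treated$run_id[i], , drop = FALSE]
    if (nrow(ctrl) != 1L) {
      warning(sprintf("compound '%s': no unique in-run control; column omitted",
                      treated$compound[i]), call. = FALSE)
      next
    }
    cols[[treated$compound[i]]] <- vapply(featmap, function(cn)
      normalize_to_control(treated[[cn]][i], ctrl[[cn]]), numeric(1))
  }
  if (length(cols) == 0L)
    stop("no compound/control pairs available", call. = FALSE)
  out <- do.call(cbind, cols)
  rownames(out) <- names(featmap)
  out
}
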