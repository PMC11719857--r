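#' Parameters of a synthetic cell phenotype
#'
#' Bundles the generative knobs for one rendered fibroblast. Each of the five
#' measured mitochondrial features has an independent generative counterpart:
#'
#' \itemize{
#'   \item fragmentation: \code{n_mito_components} (number of disjoint
#'     mitochondrial pieces);
#'   \item branching / form factor: \code{branch_elongation} (random-walk
#'     skeleton length per component, px);
#'   \item swelling / TMRM area: \code{swelling_scale} (skeleton dilation
#'     radius, px);
#'   \item membrane potential: \code{tmrm_level}, with the residual fraction
#'     \code{tmrm_fccp_floor} remaining after FCCP uncoupling;
#'   \item mass and ROS: \code{nao_level} and \code{mitosox_level}.
#' }
#'
#' MitoSox is rendered across the whole cytoplasm plus a nuclear confound at
#' \code{mitosox_nuclear_frac} of the cytoplasmic level, so that the
#' nucleus-excluding ROS mask measurably changes the readout.
#'
#' @param n_mito_components positive integer, number of mitochondrial pieces.
#' @param branch_elongation positive real, skeleton steps per component (px).
#' @param swelling_scale positive real, dilation radius of the skeleton (px).
#' @param tmrm_level nonnegative mean mitochondrial TMRM intensity (a.u.).
#' @param tmrm_fccp_floor fraction in [0, 1] of TMRM signal remaining after
#'   uncoupling.
#' @param nao_level,mitosox_level nonnegative intensities (a.u.).
#' @param mitosox_nuclear_frac nuclear MitoSox confound as a fraction of the
#'   cytoplasmic level (default 0.5).
#' @param nucleus_radius,cell_radius nucleus and cell disc radii (px); must
#'   satisfy \code{cell_radius > nucleus_radius > 0}.
#' @param noise_sd additive Gaussian intensity noise (a.u.), applied to every
#'   channel and clamped at zero.
#' @param brightfield_level,draq5_level plateau intensities of the cell body
#'   and nucleus channels.
#' @param canvas square canvas side (px). Must exceed
#'   \code{2 * (cell_radius + 6)}.
#' @param pixel_size physical pixel size (µm/px, default 0.33 at 63x
#'   magnification).
#' @param seed integer or NULL; fixes the cell's geometry and noise.
#' @return object of class \code{"cell_phenotype_params"}.
#' @export
cell_phenotype_params <- function(n_mito_components = 10,
                                  branch_elongation = 4,
                                  swelling_scale = 1,
                                  tmrm_level = 500,
                                  tmrm_fccp_floor = 0.2,
                                  nao_level = 300,
                                  mitosox_level = 200,
                                  mitosox_nuclear_frac = 0.5,
                                  nucleus_radius = 18,
                                  cell_radius = 80,
                                  noise_sd = 0,
                                  brightfield_level = 100,
                                  draq5_level = 400,
                                  canvas = 256,
                                  pixel_size = 0.33,
                                  seed = NULL) {
  check_number(n_mito_components, "n_mito_components", lower = 1, integer = TRUE)
  check_number(branch_elongation, "branch_elongation", lower = 1)
  check_number(swelling_scale, "swelling_scale", lower = 0)
  check_number(tmrm_level, "tmrm_level", lower = 0)
  check_number(tmrm_fccp_floor, "tmrm_fccp_floor", lower = 0, upper = 1)
  check_number(nao_level, "nao_level", lower = 0)
  check_number(mitosox_level, "mitosox_level", lower = 0)
  check_number(mitosox_nuclear_frac, "mitosox_nuclear_frac", lower = 0, upper = 1)
  check_number(nucleus_radius, "nucleus_radius", lower = 1)
  check_number(cell_radius, "cell_radius", lower = 2)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(brightfield_level, "brightfield_level", lower = 0)
  check_number(draq5_level, "draq5_level", lower = 0)
  check_number(canvas, "canvas", lower = 16, integer = TRUE)
  check_number(pixel_size, "pixel_size", lower = 1e-6)
  check_number(seed, "seed", integer = TRUE, allow_null = TRUE)
  if (cell_radius <= nucleus_radius)
    stop("'cell_radius' must exceed 'nucleus_radius'", call. = FALSE)
  if (canvas < 2 * (cell_radius + 6))
    stop("canvas overflow: 'canvas' must be at least 2*(cell_radius + 6)",
         call. = FALSE)
  structure(list(
    n_mito_components = as.integer(n_mito_components),
    branch_elongation = branch_elongation,
    swelling_scale = swelling_scale,
    tmrm_level = tmrm_level,
    tmrm_fccp_floor = tmrm_fccp_floor,
    nao_level = nao_level,
    mitosox_level = mitosox_level,
    mitosox_nuclear_frac = mitosox_nuclear_frac,
    nucleus_radius = nucleus_radius,
    cell_radius = cell_radius,
    noise_sd = noise_sd,
    brightfield_level = brightfield_level,
    draq5_level = draq5_level,
    canvas = as.integer(canvas),
    pixel_size = pixel_size,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "cell_phenotype_params")
}

## Trace one mitochondrial skeleton: a persistent random walk of `steps`
## unit moves confined to `allowed`, starting at linear index `start`.
trace_skeleton <- function(allowed, start, steps) {
  nr <- nrow(allowed)
  i <- ((start - 1L) %% nr) + 1L
  j <- ((start - 1L) %/% nr) + 1L
  ang <- stats::runif(1, 0, 2 * pi)
  px <- start
  ci <- i; cj <- j
  for (s in seq_len(max(0L, as.integer(round(steps)) - 1L))) {
    placed <- FALSE
    for (try in 1:6) {
      ni <- ci + sin(ang); nj <- cj + cos(ang)
      ri <- as.integer(round(ni)); rj <- as.integer(round(nj))
      if (ri >= 1L && ri <= nr && rj >= 1L && rj <= ncol(allowed) &&
          allowed[ri, rj]) {
        ci <- ni; cj <- nj
        px <- c(px, (rj - 1L) * nr + ri)
        placed <- TRUE
        break
      }
      ang <- ang + pi / 2 + stats::rnorm(1, 0, 0.5)
    }
    if (!placed) break
    ang <- ang + stats::rnorm(1, 0, 0.45)
  }
  unique(px)
}

#' Render one synthetic IFC cell event
#'
#' Draws a fibroblast-like event on a square canvas: a brightfield cell disc,
#' a DRAQ5 nucleus, and \code{n_mito_components} tubular mitochondria
#' (dilated random-walk skeletons) confined to the cytoplasm and guaranteed
#' mutually disjoint (placement retries; an error is raised if the cytoplasm
#' cannot host them). Channel content:
#'
#' \itemize{
#'   \item \code{brightfield}: cell disc plateau;
#'   \item \code{nao}: \code{nao_level} on mitochondrial pixels;
#'   \item \code{tmrm}: \code{tmrm_level} on mitochondrial pixels, multiplied
#'     by \code{tmrm_fccp_floor} when \code{treatment = "fccp"};
#'   \item \code{draq5}: nucleus disc only;
#'   \item \code{mitosox}: cytoplasmic plateau plus the nuclear nucleic-acid
#'     confound.
#' }
#'
#' Additive Gaussian noise (sd \code{noise_sd}, clamped at zero) is applied
#' last. The returned ground truth records the true mitochondrial label
#' matrix, per-component areas and perimeters, masks and intensity levels.
#' Rendering the same params twice (same seed) gives identical geometry, so an
#' untreated/FCCP pair shares its cell exactly.
#'
#' @param params a \code{\link{cell_phenotype_params}} object.
#' @param treatment \code{"untreated"} or \code{"fccp"}.
#' @param event_id identifier stored on the event.
#' @return object of class \code{"cell_image"}: list with \code{channels}
#'   (named matrices), \code{pixel_size}, \code{event_id}, \code{treatment}
#'   and \code{ground_truth}.
#' @export
render_cell <- function(params, treatment = c("untreated", "fccp"),
                        event_id = "cell1") {
  if (!inherits(params, "cell_phenotype_params"))
    stop("'params' must be created by cell_phenotype_params()", call. = FALSE)
  treatment <- match.arg(treatment)
  with_seed(params$seed, {
    n <- params$canvas
    ctr <- (n + 1) / 2
    r_sw <- as.integer(round(params$swelling_scale))

    ## nucleus sits slightly off-centre, like a real adherent fibroblast
    nuc_ang <- stats::runif(1, 0, 2 * pi)
    nuc_off <- 0.2 * params$cell_radius
    nci <- ctr + nuc_off * sin(nuc_ang)
    ncj <- ctr + nuc_off * cos(nuc_ang)

    cell <- disc_mask(n, n, ctr, ctr, params$cell_radius)
    nucleus <- disc_mask(n, n, nci, ncj, params$nucleus_radius)

    ## mitochondria must stay clear of nucleus and cell edge even after
    ## dilation by the swelling radius
    ii <- matrix(seq_len(n), n, n)
    jj <- t(ii)
    d_ctr <- sqrt((ii - ctr)^2 + (jj - ctr)^2)
    d_nuc <- sqrt((ii - nci)^2 + (jj - ncj)^2)
    allowed <- d_ctr <= (params$cell_radius - r_sw - 3) &
      d_nuc >= (params$nucleus_radius + r_sw + 2)
    if (!any(allowed))
      stop("canvas overflow: no cytoplasmic room for mitochondria", call. = FALSE)

    mito_lab <- matrix(0L, n, n)
    occupied <- matrix(FALSE, n, n)
    for (comp in seq_len(params$n_mito_components)) {
      placed <- FALSE
      for (try in 1:300) {
        free <- which(allowed & !occupied)
        if (length(free) == 0L) break
        start <- free[sample.int(length(free), 1L)]
        skel <- trace_skeleton(allowed, start, params$branch_elongation)
        comp_mask <- matrix(FALSE, n, n)
        comp_mask[skel] <- TRUE
        comp_mask <- dilate_mask(comp_mask, r_sw)
        ## require an 8-connectivity gap of >= 2 px to earlier components
        if (!any(comp_mask & occupied)) {
          mito_lab[comp_mask] <- comp
          occupied <- occupied | dilate_mask(comp_mask, r_sw + 2L)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf(paste0("could not place mitochondrial component %d ",
                            "without overlap; reduce n_mito_components or ",
                            "enlarge the cell"), comp), call. = FALSE)
    }
    mito <- mito_lab > 0

    areas_px <- as.integer(table(factor(mito_lab[mito_lab > 0],
                                        levels = seq_len(params$n_mito_components))))
    perims_um <- vapply(seq_len(params$n_mito_components), function(k)
      mask_perimeter(mito_lab == k, params$pixel_size), numeric(1))

    tmrm_eff <- params$tmrm_level *
      if (treatment == "fccp") params$tmrm_fccp_floor else 1
    chan <- list(
      brightfield = params$brightfield_level * cell,
      nao         = params$nao_level * mito,
      tmrm        = tmrm_eff * mito,
      draq5       = params$draq5_level * nucleus,
      mitosox     = params$mitosox_level * (cell & !nucleus) +
        params$mitosox_level * params$mitosox_nuclear_frac * nucleus
    )
    chan <- lapply(chan, function(m) m * 1)
    if (params$noise_sd > 0)
      chan <- lapply(chan, function(m)
        pmax(m + matrix(stats::rnorm(length(m), 0, params$noise_sd),
                        nrow(m)), 0))

    structure(list(
      channels = chan,
      pixel_size = params$pixel_size,
      event_id = event_id,
      treatment = treatment,
      ground_truth = list(
        n_components = params$n_mito_components,
        label = mito_lab,
        areas_px = areas_px,
        areas_um2 = areas_px * params$pixel_size^2,
        perimeters_um = perims_um,
        mito_mask = mito,
        nucleus_mask = nucleus,
        nucleus_center = c(nci, ncj),
        cell_mask = cell,
        tmrm_level_effective = tmrm_eff,
        levels = list(tmrm = params$tmrm_level,
                      tmrm_fccp_floor = params$tmrm_fccp_floor,
                      nao = params$nao_level,
                      mitosox = params$mitosox_level,
                      mitosox_nuclear_frac = params$mitosox_nuclear_frac),
        singlet = TRUE,
        in_focus = TRUE
      )
    ), class = "cell_image")
  })
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf("<cell_image %s> %dx%d px, %s, %d mito components%s\n",
              x$event_id, nrow(x$channels[[1]]), ncol(x$channels[[1]]),
              x$treatment,
              x$ground_truth$n_components %||% NA_integer_,
              if (isFALSE(x$ground_truth$singlet)) ", doublet"
              else if (isFALSE(x$ground_truth$in_focus)) ", defocused"
              else ""))
  invisible(x)
}

#' Generate a paired synthetic IFC sample
#'
#' Renders \code{n_cells} untreated/FCCP event pairs from one phenotype,
#' injecting doublets (a second nucleus) at \code{doublet_rate} and defocused
#' events (Gaussian blur of every channel) at \code{blur_rate}. Each injected
#' artifact is recorded in the event's ground truth, so gating performance can
#' be scored exactly.
#'
#' @param params a \code{\link{cell_phenotype_params}} phenotype; its
#'   \code{seed} is ignored in favour of per-event seeds derived from
#'   \code{seed}.
#' @param n_cells number of event pairs (>= 1).
#' @param doublet_rate,blur_rate artifact probabilities in [0, 1).
#' @param blur_sigma Gaussian blur sigma (px) for defocused events.
#' @param seed integer controlling all randomness.
#' @return list of class \code{"ifc_sample"}; each element is
#'   \code{list(untreated =, fccp =)} of \code{\link{render_cell}} events.
#'   Attribute \code{"truth"} is a data frame of the injected event labels.
#' @export
generate_sample <- function(params, n_cells, doublet_rate = 0, blur_rate = 0,
                            blur_sigma = 3, seed = 1) {
  if (!inherits(params, "cell_phenotype_params"))
    stop("'params' must be created by cell_phenotype_params()", call. = FALSE)
  check_number(n_cells, "n_cells", lower = 1, integer = TRUE)
  check_number(doublet_rate, "doublet_rate", lower = 0, upper = 1 - 1e-12)
  check_number(blur_rate, "blur_rate", lower = 0, upper = 1 - 1e-12)
  check_number(blur_sigma, "blur_sigma", lower = 0)
  check_number(seed, "seed", integer = TRUE)
  with_seed(seed, {
    ev_seed <- sample.int(.Machine$integer.max %/% 2L, n_cells)
    doublet <- stats::runif(n_cells) < doublet_rate
    blurred <- stats::runif(n_cells) < blur_rate
    nuc2_ang <- stats::runif(n_cells, 0, 2 * pi)

    events <- vector("list", n_cells)
    for (e in seq_len(n_cells)) {
      p <- params
      p$seed <- ev_seed[e]
      id <- sprintf("ev%03d", e)
      pair <- list(untreated = render_cell(p, "untreated", id),
                   fccp = render_cell(p, "fccp", id))
      if (doublet[e]) {
        n <- p$canvas
        ## second nucleus well clear of the first so the DRAQ5 components
        ## stay separable
        nc1 <- pair$untreated$ground_truth$nucleus_center
        off <- 2.6 * p$nucleus_radius
        nuc2 <- disc_mask(n, n, nc1[1] + off * sin(nuc2_ang[e]),
                          nc1[2] + off * cos(nuc2_ang[e]), p$nucleus_radius)
        for (m in c("untreated", "fccp")) {
          pair[[m]]$channels$draq5 <- pmax(pair[[m]]$channels$draq5,
                                           p$draq5_level * nuc2)
          pair[[m]]$ground_truth$singlet <- FALSE
        }
      }
      if (blurred[e]) {
        for (m in c("untreated", "fccp")) {
          pair[[m]]$channels <- lapply(pair[[m]]$channels, smooth_matrix,
                                       sigma = blur_sigma)
          pair[[m]]$ground_truth$in_focus <- FALSE
        }
      }
      events[[e]] <- pair
    }
    structure(events,
              truth = data.frame(event_id = sprintf("ev%03d", seq_len(n_cells)),
                                 singlet = !doublet, in_focus = !blurred,
                                 stringsAsFactors = FALSE),
              class = c("ifc_sample", "list"))
  })
}

## Default cluster effect sizes (multiplicative, on the percent-of-control
## scale): cluster 1 is the hypometabolic response (membrane potential down,
## mild fragmentation, raised ROS), cluster 2 the hypermetabolic response
## (membrane potential, swelling and mass up, exaggerated FCCP response).
default_effect_sizes <- function() {
  list(`1` = c(membrane_potential = 0.80, mito_mass = 1.00, swelling = 0.95,
               form_factor = 0.90, ros = 1.25),
       `2` = c(membrane_potential = 1.25, mito_mass = 1.30, swelling = 1.35,
               form_factor = 1.00, ros = 1.00))
}

default_subtype_pool <- function() {
  ## plausible mitochondrial-disease subtype mix for a 31-patient cohort;
  ## cluster-2 subtypes lean towards complex IV / proton-pumping defects
  list(`1` = c(rep("Complex I", 5), rep("Mitochondrial translation", 4),
               rep("mtDNA maintenance", 3), rep("Complex V", 2),
               rep("Complex II", 2), rep("Cardiolipin remodeling", 2),
               "Mitochondrial fission", "Complex III"),
       `2` = c(rep("Complex IV", 4), rep("Complex I", 3),
               rep("Multiple complexes", 3), "Complex V",
               "mtDNA maintenance", rep("Mitochondrial translation", 2),
               "Complex III"))
}

#' Design of a synthetic patient cohort
#'
#' Describes the run structure of the study being emulated: each experimental
#' run carries exactly one patient plus one in-run healthy control sharing a
#' log-normal run-level intensity scale (which therefore cancels under
#' percent-of-control normalization), and the healthy reference lines are
#' each measured in a control run against one designated normalizer control.
#'
#' @param n_patients number of patients (default 31).
#' @param n_controls number of healthy reference donors (default 6).
#' @param cluster_assignment integer vector in \{1, 2\} per patient; default
#'   16 patients in cluster 1 and the rest in cluster 2.
#' @param effect_sizes named list \code{list(`1` =, `2` =)} of per-feature
#'   multiplicative shifts (fraction of control; see
#'   \code{mitoifc:::default_effect_sizes}). All entries must be positive and
#'   the membrane-potential shifts must straddle 1 (cluster 1 below, cluster 2
#'   above).
#' @param fccp_effect multiplicative shift of the FCCP response ratio per
#'   cluster (default c(`1` = 1, `2` = 1.6)).
#' @param run_scale_sd log-normal sd of the shared per-run intensity scale.
#' @param donor_noise_sd log-normal sd of healthy-control measurement noise.
#' @param patient_hetero_sd log-normal sd of patient-specific heterogeneity on
#'   top of the cluster effect.
#' @param subtypes optional character vector of disease subtypes per patient;
#'   default draws from a built-in subtype mix.
#' @param seed integer.
#' @return object of class \code{"cohort_design"}.
#' @export
cohort_design <- function(n_patients = 31, n_controls = 6,
                          cluster_assignment = NULL,
                          effect_sizes = default_effect_sizes(),
                          fccp_effect = c(`1` = 1, `2` = 1.6),
                          run_scale_sd = 0.2,
                          donor_noise_sd = 0.05,
                          patient_hetero_sd = 0.10,
                          subtypes = NULL,
                          seed = 1) {
  check_number(n_patients, "n_patients", lower = 1, integer = TRUE)
  check_number(n_controls, "n_controls", lower = 2, integer = TRUE)
  check_number(run_scale_sd, "run_scale_sd", lower = 0)
  check_number(donor_noise_sd, "donor_noise_sd", lower = 0)
  check_number(patient_hetero_sd, "patient_hetero_sd", lower = 0)
  check_number(seed, "seed", integer = TRUE)
  if (is.null(cluster_assignment)) {
    n1 <- min(16L, n_patients)
    cluster_assignment <- c(rep(1L, n1), rep(2L, n_patients - n1))
  }
  cluster_assignment <- as.integer(cluster_assignment)
  if (length(cluster_assignment) != n_patients ||
      !all(cluster_assignment %in% 1:2))
    stop("'cluster_assignment' must give a label in {1,2} per patient",
         call. = FALSE)
  feats <- c("membrane_potential", "mito_mass", "swelling", "form_factor", "ros")
  for (cl in c("1", "2")) {
    e <- effect_sizes[[cl]]
    if (is.null(e) || !all(feats %in% names(e)) || any(e[feats] <= 0))
      stop("'effect_sizes' must hold strictly positive shifts for all five ",
           "features in clusters \"1\" and \"2\"", call. = FALSE)
  }
  if (!(effect_sizes[["1"]]["membrane_potential"] < 1 &&
        effect_sizes[["2"]]["membrane_potential"] > 1))
    stop("membrane-potential shifts must satisfy cluster1 < 1 < cluster2",
         call. = FALSE)
  if (any(fccp_effect <= 0))
    stop("'fccp_effect' entries must be positive", call. = FALSE)
  if (is.null(subtypes)) {
    pool <- default_subtype_pool()
    subtypes <- character(n_patients)
    for (cl in 1:2) {
      idx <- which(cluster_assignment == cl)
      subtypes[idx] <- rep_len(pool[[as.character(cl)]], length(idx))
    }
  }
  if (length(subtypes) != n_patients)
    stop("'subtypes' must have one entry per patient", call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    cluster_assignment = cluster_assignment,
    effect_sizes = lapply(effect_sizes, function(e) e[feats]),
    fccp_effect = fccp_effect,
    run_scale_sd = run_scale_sd,
    donor_noise_sd = donor_noise_sd,
    patient_hetero_sd = patient_hetero_sd,
    subtypes = as.character(subtypes),
    seed = as.integer(seed)
  ), class = "cohort_design")
}

## Raw-scale baselines of the derived per-sample features (arbitrary but
## realistic orders of magnitude; they cancel under normalization).
cohort_baselines <- function() {
  c(delta_mmp = 400, mmp = 500, nao_intensity = 3e4, tmrm_area_um2 = 60,
    form_factor = 2.0, mitosox_cyto_intensity = 1.5e4, fccp_ratio = 4)
}

#' Generate a synthetic cohort feature table
#'
#' Feature-level fast path emulating the cohort structure without rendering
#' images. For every donor measurement, each derived per-sample feature is
#' \code{baseline * run_scale * donor_effect * noise}, where \code{run_scale}
#' is shared between a patient and its in-run control (so it cancels exactly
#' under percent-of-control normalization), \code{donor_effect} is the
#' cluster-specific multiplicative shift (1 for controls) and \code{noise} is
#' log-normal. The planted normalized percentage (what downstream
#' normalization should recover) is stored as ground truth.
#'
#' @param design a \code{\link{cohort_design}}.
#' @return data frame with one row per donor measurement (columns
#'   \code{donor_id, run_id, role, cluster, subtype, n_cells} plus the derived
#'   feature columns), with attribute \code{"ground_truth"}: a data frame of
#'   planted percentages and cluster labels per patient/reference donor.
#' @export
generate_cohort_table <- function(design) {
  if (!inherits(design, "cohort_design"))
    stop("'design' must be created by cohort_design()", call. = FALSE)
  feats <- c("membrane_potential", "mito_mass", "swelling", "form_factor", "ros")
  raw_cols <- c(membrane_potential = "delta_mmp", mito_mass = "nao_intensity",
                swelling = "tmrm_area_um2", form_factor = "form_factor",
                ros = "mitosox_cyto_intensity")
  base <- cohort_baselines()
  with_seed(design$seed, {
    rows <- list()
    gt <- list()
    lnorm_vec <- function(n, sd) exp(stats::rnorm(n, 0, sd))

    add_run <- function(run_id, subj_id, subj_role, ctrl_id, effect,
                        fccp_eff, subj_sd, cluster, subtype) {
      s <- lnorm_vec(1, design$run_scale_sd)
      eps_s <- lnorm_vec(7, subj_sd)
      eps_c <- lnorm_vec(7, design$donor_noise_sd)
      names(eps_s) <- names(eps_c) <-
        c(raw_cols, mmp = "mmp", fccp_ratio = "fccp_ratio")
      eff7 <- c(effect[feats], mmp = 1, fccp_ratio = unname(fccp_eff))
      subj <- base[c(unname(raw_cols), "mmp", "fccp_ratio")]
      ctrl <- subj
      subj <- subj * s * unname(eff7[c(feats, "mmp", "fccp_ratio")]) * unname(eps_s)
      ctrl <- ctrl * s * unname(eps_c)
      mk <- function(id, role, v, cl, st) {
        data.frame(donor_id = id, run_id = run_id, role = role,
                   cluster = cl, subtype = st, n_cells = 500L,
                   delta_mmp = v[["delta_mmp"]], mmp = v[["mmp"]],
                   nao_intensity = v[["nao_intensity"]],
                   tmrm_area_um2 = v[["tmrm_area_um2"]],
                   form_factor = v[["form_factor"]],
                   mitosox_cyto_intensity = v[["mitosox_cyto_intensity"]],
                   fccp_ratio = v[["fccp_ratio"]],
                   stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <<- mk(subj_id, subj_role, subj,
                                       cluster, subtype)
      rows[[length(rows) + 1L]] <<- mk(ctrl_id, "control", ctrl,
                                       NA_integer_, NA_character_)
      planted <- 100 * eff7[c(feats, "fccp_ratio")] *
        eps_s[c(unname(raw_cols), "fccp_ratio")] /
        eps_c[c(unname(raw_cols), "fccp_ratio")]
      gt[[length(gt) + 1L]] <<- data.frame(
        donor_id = subj_id, cluster = cluster, subtype = subtype,
        membrane_potential_pct = planted[["membrane_potential"]],
        mito_mass_pct = planted[["mito_mass"]],
        swelling_pct = planted[["swelling"]],
        form_factor_pct = planted[["form_factor"]],
        ros_pct = planted[["ros"]],
        fccp_response_pct = planted[["fccp_ratio"]],
        stringsAsFactors = FALSE)
    }

    hc_ids <- sprintf("HC%d", seq_len(design$n_controls))
    no_eff <- stats::setNames(rep(1, 5), feats)

    ## control runs: each healthy line measured against the designated
    ## normalizer (HC1), including HC1 itself as an independent tube
    for (k in seq_len(design$n_controls))
      add_run(sprintf("ctrlrun%02d", k), hc_ids[k], "reference_control",
              "HC1", no_eff, 1, design$donor_noise_sd, NA_integer_,
              NA_character_)

    ## patient runs: one patient + one in-run healthy control per run
    for (p in seq_len(design$n_patients)) {
      cl <- design$cluster_assignment[p]
      add_run(sprintf("run%02d", p), sprintf("P%02d", p), "patient",
              hc_ids[(p - 1L) %% design$n_controls + 1L],
              design$effect_sizes[[as.character(cl)]],
              design$fccp_effect[[as.character(cl)]],
              design$patient_hetero_sd, cl, design$subtypes[p])
    }

    tbl <- do.call(rbind, rows)
    rownames(tbl) <- NULL
    attr(tbl, "ground_truth") <- do.call(rbind, gt)
    tbl
  })
}
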