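test_that("membrane-potential background subtraction and FCCP response", {
  expect_equal(delta_mmp(500, 120), 380)
  expect_equal(delta_mmp(250, 250), 0)
  expect_equal(delta_mmp(100, 150), -50)   # retained, not clipped
  expect_equal(fccp_response(500, 120), 4.1667, tolerance = 1e-4)
  expect_equal(fccp_response(7, 7), 1)
  expect_true(is.na(fccp_response(500, 0)))
  ## percent-of-control on the ratio scale
  expect_equal(normalize_to_control(4, 2), 200)
})

test_that("noise-free renderer pair yields the planted delta MMP within 1%", {
  p <- cell_phenotype_params(noise_sd = 0, tmrm_level = 500,
                             tmrm_fccp_floor = 0.2, seed = 41)
  feats <- extract_features(list(list(untreated = render_cell(p),
                                      fccp = render_cell(p, "fccp"))))
  d <- delta_mmp(feats$tmrm_pixel_mean, feats$tmrm_pixel_mean_fccp)
  expect_lt(abs(d - 400) / 400, 0.01)
})

test_that("normalization to the in-run control", {
  expect_equal(normalize_to_control(80, 100), 80)
  expect_equal(normalize_to_control(37, 37), 100)
  expect_equal(normalize_to_control(80 * 3.7, 100 * 3.7), 80)
  expect_true(is.na(normalize_to_control(80, 0)))
  expect_error(normalize_to_control(80, 100, "run1", "run2"),
               "different runs")
})

test_that("ROS per mass is the ratio of normalized percentages", {
  expect_equal(ros_per_mass(150, 75), 2)
  expect_equal(ros_per_mass(100, 100), 1)
  expect_equal(ros_per_mass(150 * 2, 75 * 2), 2)
  expect_true(is.na(ros_per_mass(150, 0)))
})

test_that("reference ranges are the min/max over control percentages", {
  mk <- function(mp) data.frame(donor_id = paste0("HC", seq_along(mp)),
                                role = "reference_control",
                                membrane_potential_pct = mp,
                                mito_mass_pct = 100, swelling_pct = 100,
                                form_factor_pct = 100, ros_pct = 100)
  r <- reference_ranges(mk(c(92, 101, 97, 110, 88, 105)))
  expect_equal(r$lower_pct[r$feature == "membrane_potential_pct"], 88)
  expect_equal(r$upper_pct[r$feature == "membrane_potential_pct"], 110)
  expect_equal(attr(r, "n_reference_donors"), 6)
  r2 <- reference_ranges(mk(rep(100, 4)))
  expect_equal(r2$lower_pct, rep(100, 5))
  expect_equal(r2$upper_pct, rep(100, 5))
  expect_error(reference_ranges(mk(100)), "at least 2")
  cv <- mk(c(95, 100, 105))
  cv$ros_pct[2] <- NA
  expect_warning(r3 <- reference_ranges(cv), "missing in 1")
  expect_equal(r3$n_donors[r3$feature == "ros_pct"], 2)
})

test_that("abnormality flags use strict inequality and tolerate missing values", {
  mk <- function(mp) data.frame(donor_id = "P", role = "patient",
                                membrane_potential_pct = mp,
                                mito_mass_pct = 100, swelling_pct = 100,
                                form_factor_pct = 100, ros_pct = 100)
  ctl <- do.call(rbind, lapply(c(92, 101, 97, 110, 88, 105), mk))
  ctl$role <- "reference_control"
  ctl$donor_id <- paste0("HC", 1:6)
  r <- reference_ranges(ctl)
  expect_true(flag_abnormal(mk(120), r)$membrane_potential_flag)
  expect_false(flag_abnormal(mk(110), r)$membrane_potential_flag)  # boundary
  expect_false(flag_abnormal(mk(88), r)$membrane_potential_flag)   # boundary
  expect_true(flag_abnormal(mk(87.9), r)$membrane_potential_flag)
  expect_false(flag_abnormal(mk(100), r)$any_flag)
  miss <- mk(NA)
  fl <- flag_abnormal(miss, r)
  expect_true(is.na(fl$membrane_potential_flag))
  expect_false(fl$any_flag)  # remaining features are in range
  ## no reference control is flagged against the range it helped build
  own <- flag_abnormal(ctl, r)
  expect_false(any(own$any_flag))
  ## enlarging a range never adds flags
  r_wide <- r
  r_wide$lower_pct <- r$lower_pct - 10
  r_wide$upper_pct <- r$upper_pct + 10
  expect_false(flag_abnormal(mk(115), r_wide)$membrane_potential_flag)
  expect_true(flag_abnormal(mk(115), r)$membrane_potential_flag)
})

test_that("combination detection matches brute-force subset enumeration", {
  toy <- rbind(c(1, 0, 0, 0, 0),
               c(0, 1, 0, 0, 0),
               c(0, 0, 0, 0, 0),
               c(1, 1, 0, 0, 0)) == 1
  cd <- combination_detection(toy)
  k1 <- cd[cd$k == 1, ]
  expect_equal(k1$mean_pct, 20)
  expect_equal(k1$min_pct, 0)
  expect_equal(k1$max_pct, 50)
  ## full agreement with the definition for every k and subset
  for (k in 1:5) {
    dets <- apply(utils::combn(5, k), 2, function(s)
      detection_of_subset(toy, s))
    expect_equal(cd$mean_pct[cd$k == k], mean(dets))
    expect_equal(cd$min_pct[cd$k == k], min(dets))
    expect_equal(cd$max_pct[cd$k == k], max(dets))
  }
  ## union monotonicity and the k = 5 identity with any_flag
  expect_true(all(diff(cd$min_pct) >= 0))
  expect_true(all(diff(cd$mean_pct) >= 0))
  expect_equal(cd$mean_pct[cd$k == 5], 100 * mean(apply(toy, 1, any)))
  ## everyone flagged everywhere: flat 100 with zero range
  allf <- combination_detection(matrix(TRUE, 3, 5))
  expect_equal(allf$mean_pct, rep(100, 5))
  expect_equal(allf$max_pct - allf$min_pct, rep(0, 5))
  expect_error(combination_detection(toy[0, ]), "at least one patient")
  withNA <- toy
  withNA[1, 1] <- NA
  expect_warning(combination_detection(withNA), "not-flagged")
})

test_that("donor vectors normalize against the unique in-run control", {
  tbl <- toy_derived_table()
  v <- donor_vectors(tbl)
  expect_equal(v$membrane_potential_pct, c(80, 130))
  expect_equal(v$mito_mass_pct, c(100, 130))
  expect_equal(v$swelling_pct, c(100, 140))
  expect_equal(v$form_factor_pct, c(90, 100))
  expect_equal(v$ros_pct, c(125, 100))
  expect_equal(v$fccp_response_pct, c(100, 160))
  expect_equal(v$ros_per_mass, c(1.25, 100 / 130))
  bad <- tbl
  bad$role[2] <- "patient"
  expect_error(donor_vectors(bad), "exactly one in-run control")
})

test_that("sample summaries aggregate by median and derive composites", {
  feats <- data.frame(
    event_id = c("e1", "e2", "e3"),
    tmrm_intensity = c(100, 200, 400),
    tmrm_pixel_mean = c(10, 20, 40),
    tmrm_area_um2 = c(5, 6, 10),
    n_spots = c(3, 4, 5),
    spot_area_um2 = c(1, 2, 3),
    spot_perimeter_um = c(4, 5, 6),
    form_factor = c(1, 1.2, 1.4),
    mitosox_cyto_intensity = c(10, 20, 90),
    tmrm_intensity_fccp = c(50, 60, 70),
    tmrm_pixel_mean_fccp = c(5, 6, 7),
    nao_intensity = c(7, 8, 9))
  s <- summarize_sample(feats, "D1", "r1", "patient")
  expect_equal(nrow(s), 2)
  u <- s[s$treatment == "untreated", ]
  expect_equal(u$tmrm_intensity, 200)          # median
  expect_equal(u$tmrm_intensity_mean, mean(c(100, 200, 400)))
  expect_equal(u$mitosox_cyto_intensity, 20)
  d <- derive_sample_features(s)
  expect_equal(d$delta_mmp, 200 - 60)
  expect_equal(d$fccp_ratio, mean(c(100, 200, 400)) / 60)
  expect_equal(d$nao_intensity, 8)
  expect_equal(d$form_factor, 5^2 / (4 * pi * 2))  # from median spot stats
  ## without an FCCP member, composites are missing but the rest is kept
  solo <- feats
  solo$tmrm_intensity_fccp <- NA_real_
  solo$tmrm_pixel_mean_fccp <- NA_real_
  solo$nao_intensity <- NA_real_
  d2 <- derive_sample_features(summarize_sample(solo, "D1", "r1", "patient"))
  expect_true(is.na(d2$delta_mmp))
  expect_true(is.na(d2$nao_intensity))
  expect_equal(d2$tmrm_area_um2, 6)
})

test_that("compound-effect grid normalizes each compound to its in-run control", {
  ctrl <- toy_derived_table()[c(2, 4), ]
  trt <- toy_derived_table()[c(1, 3), ]
  trt$compound <- c("uncoupler", "mass_inducer")
  g <- compound_effect_grid(trt, ctrl)
  expect_equal(dim(g), c(6, 2))
  expect_equal(g["delta_mmp", "uncoupler"], 80)
  expect_equal(g["mito_mass", "mass_inducer"], 130)
  ## a compound with no effect sits at 100% everywhere
  none <- ctrl[1, ]
  none$compound <- "vehicle"
  g2 <- compound_effect_grid(none, ctrl)
  expect_equal(unname(g2[, "vehicle"]), rep(100, 6))
  orphan <- trt
  orphan$run_id <- c("r1", "rX")
  expect_warning(g3 <- compound_effect_grid(orphan, ctrl), "column omitted")
  expect_equal(colnames(g3), "uncoupler")
  ## synthetic uncoupler: halving tmrm_level halves the delta-MMP readout
  p <- small_params(noise_sd = 0, seed = 51)
  p_unc <- small_params(noise_sd = 0, tmrm_level = 250, seed = 51)
  mk_derived <- function(pp, id, role, run) {
    f <- extract_features(list(list(untreated = render_cell(pp),
                                    fccp = render_cell(pp, "fccp"))))
    derive_sample_features(summarize_sample(f, id, run, role))
  }
  trt_img <- mk_derived(p_unc, "treated", "patient", "rA")
  trt_img$compound <- "uncoupler"
  ctrl_img <- mk_derived(p, "ctrl", "control", "rA")
  g4 <- compound_effect_grid(trt_img, ctrl_img)
  expect_lt(abs(g4["delta_mmp", "uncoupler"] - 50), 2)
})
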