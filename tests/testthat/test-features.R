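test_that("gating removes anucleate, defocused and doublet events in order", {
  clean <- generate_sample(small_params(), 4, 0, 0, seed = 1)
  g <- gate_events(clean)
  expect_equal(length(g$events), 4)
  expect_equal(sum(g$report$n_removed), 0)

  ## an event with no DRAQ5 signal falls at the nucleated gate
  anuc <- clean[[1]]
  anuc$untreated$channels$draq5[] <- 0
  g2 <- gate_events(c(list(anuc), clean[2:4]))
  expect_equal(g2$report$n_removed[g2$report$gate == "nucleated"], 1)
  expect_equal(length(g2$events), 3)

  ## injected doublets are caught by the singlet gate, blurred events by the
  ## focus gate, matching the generator's ground-truth labels
  s <- generate_sample(small_params(), 16, doublet_rate = 0.35,
                       blur_rate = 0.25, seed = 6)
  truth <- attr(s, "truth")
  g3 <- gate_events(s)
  expect_equal(g3$report$n_removed[g3$report$gate == "in_focus"],
               sum(!truth$in_focus))
  expect_equal(g3$report$n_removed[g3$report$gate == "singlet"],
               sum(!truth$singlet & truth$in_focus))
  kept <- vapply(g3$events, function(e) e$untreated$event_id, character(1))
  expect_setequal(kept, truth$event_id[truth$singlet & truth$in_focus])

  expect_error(gate_events(list()), "no events")
  strict <- gate_config(draq5_min_total = 1e18)
  expect_warning(gate_events(clean, strict), "all events removed")
})

test_that("spot mask finds constructed components and echoes the study defaults", {
  expect_equal(spot_mask(matrix(0, 40, 40))$n_components, 0)
  ## three disjoint bright discs on a dark background
  img <- matrix(0, 60, 60)
  for (c0 in list(c(15, 15), c(15, 45), c(45, 30)))
    img[outer(1:60, 1:60, function(i, j)
      (i - c0[1])^2 + (j - c0[2])^2 <= 16)] <- 500
  sm <- spot_mask(img, spot_mask_params(max_area = 0), pixel_size = 0.33)
  expect_equal(sm$n_components, 3)
  expect_equal(sm$areas_um2, rep(49 * 0.33^2, 3))
  ## defaults: Bright threshold 10, minimal area 0, maximal area 2
  def <- spot_mask_params()
  expect_equal(def$brightness_threshold_pct, 10)
  expect_equal(def$min_area, 0)
  expect_equal(def$max_area, 2)
  ## the 2 um^2 upper bound removes large components
  sm2 <- spot_mask(img, def, pixel_size = 0.33)
  expect_equal(sm2$n_components, 0)
  expect_error(spot_mask(matrix(c(1, NA), 2, 2)), "finite")
  expect_error(spot_mask_params(min_area = 3, max_area = 2), "min_area")
})

test_that("raising the brightness threshold never shrinks the mask", {
  set.seed(42)
  img <- matrix(seq(0, 100, length.out = 1600) +
                  stats::runif(1600, 0, 5), 40, 40)
  areas <- vapply(c(5, 10, 20, 40, 80), function(th)
    sum(spot_mask(img, spot_mask_params(th, max_area = 0),
                  background_floor = 0)$mask), numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("form factor follows its closed forms and flags empty input", {
  expect_equal(form_factor(2, 10), 100 / (8 * pi), tolerance = 1e-12)
  expect_equal(form_factor(2, 10), 3.9789, tolerance = 1e-4)
  expect_true(is.na(form_factor(numeric(0), numeric(0))))
  expect_true(is.na(form_factor(0, 4)))
  expect_error(form_factor(c(1, 2), 3), "equal length")
  ## medians are used: an outlier spot does not dominate
  expect_equal(form_factor(c(2, 2, 50), c(10, 10, 11)), 100 / (8 * pi))
})

test_that("TMRM area converts pixel counts to physical units", {
  expect_equal(tmrm_area(matrix(0, 10, 10)), 0)
  m <- matrix(0, 40, 40)
  m[11:30, 11:20] <- 1
  expect_equal(tmrm_area(m, pixel_size = 0.33), 200 * 0.1089,
               tolerance = 1e-12)
  ## swelling dilation increases the rendered area monotonically
  a1 <- sum(render_cell(small_params(swelling_scale = 1, seed = 3))$
              ground_truth$areas_um2)
  a2 <- sum(render_cell(small_params(swelling_scale = 2, seed = 3))$
              ground_truth$areas_um2)
  expect_gt(a2, a1)
})

test_that("nucleus exclusion removes the MitoSox nucleic-acid confound", {
  p <- small_params(noise_sd = 0, mitosox_level = 200, seed = 13)
  u <- render_cell(p)
  gt <- u$ground_truth
  got <- cytoplasmic_mitosox(u)
  want <- 200 * sum(gt$cell_mask & !gt$nucleus_mask)
  expect_lt(abs(got - want) / want, 0.05)
  ## not excluding the nucleus adds exactly the nuclear confound integral
  cm <- gt$cell_mask
  with_nucleus <- sum(u$channels$mitosox[cm])
  expect_equal(with_nucleus - sum(u$channels$mitosox[cm & gt$nucleus_mask]),
               sum(u$channels$mitosox[cm & !gt$nucleus_mask]))
  ## signal confined to the nucleus yields ~0 cytoplasmic intensity
  u2 <- u
  u2$channels$mitosox <- u$channels$mitosox * gt$nucleus_mask
  expect_equal(cytoplasmic_mitosox(u2), 0)
  ## nuclear mask swallowing the cell is flagged, not zero-filled
  u3 <- u
  u3$channels$draq5 <- 400 * gt$cell_mask
  expect_warning(val <- cytoplasmic_mitosox(u3), "whole cell")
  expect_true(is.na(val))
})

test_that("noise-free extraction recovers the renderer ground truth within 5%", {
  p <- cell_phenotype_params(noise_sd = 0, seed = 17)
  u <- render_cell(p, "untreated")
  f <- render_cell(p, "fccp")
  gt <- u$ground_truth
  feats <- extract_features(list(list(untreated = u, fccp = f)))
  rel <- function(got, want) abs(got - want) / abs(want)
  expect_equal(feats$n_spots, gt$n_components)
  expect_lt(rel(feats$tmrm_area_um2, sum(gt$areas_um2)), 0.05)
  expect_lt(rel(feats$tmrm_pixel_mean, p$tmrm_level), 0.05)
  expect_lt(rel(feats$spot_area_um2, median(gt$areas_um2)), 0.05)
  expect_lt(rel(feats$spot_perimeter_um, median(gt$perimeters_um)), 0.05)
  expect_lt(rel(feats$nao_intensity, p$nao_level * sum(gt$mito_mask)), 0.05)
  expect_lt(rel(feats$mitosox_cyto_intensity,
                p$mitosox_level * sum(gt$cell_mask & !gt$nucleus_mask)), 0.05)
  ## heavily fragmented phenotype: component count recovered within 1
  p12 <- cell_phenotype_params(n_mito_components = 12, noise_sd = 0, seed = 23)
  pair12 <- list(untreated = render_cell(p12), fccp = render_cell(p12, "fccp"))
  f12 <- extract_features(list(pair12))
  expect_lte(abs(f12$n_spots - 12), 1)
})

test_that("extraction demands consistent pairing and propagates missing FCCP", {
  p <- small_params(seed = 31)
  u <- render_cell(p, "untreated", "evA")
  f <- render_cell(p, "fccp", "evA")
  u2 <- render_cell(small_params(seed = 32), "untreated", "evB")
  expect_error(extract_features(list(list(untreated = u, fccp = f),
                                     list(untreated = u2))),
               "unpaired.*evB")
  solo <- extract_features(list(list(untreated = u2)))
  expect_true(is.na(solo$nao_intensity))
  expect_true(is.na(solo$tmrm_intensity_fccp))
  expect_false(is.na(solo$tmrm_intensity))
  ## gated-out events never reach the feature table
  s <- generate_sample(small_params(), 8, doublet_rate = 0.5, blur_rate = 0,
                       seed = 12)
  g <- gate_events(s)
  tab <- extract_features(g)
  expect_setequal(tab$event_id,
                  vapply(g$events, function(e) e$untreated$event_id,
                         character(1)))
})
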