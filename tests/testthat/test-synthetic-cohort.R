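test_that("phantom construction honors its ground-truth invariants", {
  ph <- make_phantom(seed = 3)
  expect_true(all(ph$icvf_map >= 0 & ph$icvf_map <= 1))
  expect_true(all(ph$odi_map >= 0 & ph$odi_map <= 1))
  expect_true(all(ph$iso_map >= 0 & ph$iso_map <= 1))
  csf <- ph$label_map == phantom_labels[["csf"]]
  expect_true(all(ph$iso_map[csf] == 1))
  # crossing voxels carry exactly two orientations; others at most one
  cross <- ph$label_map == phantom_labels[["wm_crossing"]]
  mu2x <- ph$mu2[, , , 1]
  expect_true(all(!is.na(mu2x[cross])))
  expect_true(all(is.na(mu2x[!cross])))
  # counting oracle: WM voxel count from an independent scan of label_map
  wm_labels <- phantom_labels[c("wm_tract_1", "wm_tract_2", "wm_crossing")]
  manual <- sum(vapply(seq_along(ph$label_map),
                       function(i) ph$label_map[i] %in% wm_labels, TRUE))
  expect_equal(sum(ph$label_map %in% wm_labels), manual)
  expect_gt(manual, 0)
})

test_that("zero-effect patient condition reproduces the control phantom", {
  a <- make_phantom(condition = "control", seed = 5)
  b <- make_phantom(condition = "patient",
                    condition_params = list(odi_delta = 0,
                                            perivascular_gain = 1.6),
                    seed = 5)
  expect_identical(a$label_map, b$label_map)
  expect_identical(a$odi_map, b$odi_map)
  expect_identical(a$icvf_map, b$icvf_map)
  expect_equal(a$perivascular_gain, b$perivascular_gain)
})

test_that("phantom rejects invalid grids and parameters", {
  expect_error(make_phantom(c(8, 8, 8)), "too small")
  expect_error(make_phantom(condition_params = list(odi_delta = 2)), "odi_delta")
  expect_error(make_phantom(condition_params = list(perivascular_gain = -1)),
               "perivascular_gain")
  expect_error(make_phantom(condition_params = list(odi_regions = "nope")),
               "unknown")
})

test_that("noiseless forward signals obey the closed-form special cases", {
  sch <- default_scheme()
  # b = 0: signal equals s0 for any composition
  s <- noddi_signal(sch, c(0, 1, 0), icvf = 0.7, odi = 0.2, iso = 0.1,
                    s0 = 500)
  expect_equal(s[sch$bvals == 0], rep(500, 10))
  # pure free water: s0 * exp(-b * d_iso)
  s <- noddi_signal(sch, c(0, 0, 1), icvf = 0, odi = 1, iso = 1, s0 = 100)
  expect_equal(s[sch$bvals == 1000][1], 100 * exp(-1000 * 3.0e-3),
               tolerance = 1e-12)
  expect_error(noddi_signal(sch, c(0, 0, 1), 0.5, 0.2, 0.1, s0 = -1),
               "positive")
})

test_that("synthesized DWI has the protocol volume count and stays in (0, s0]", {
  ph <- make_phantom(c(20L, 24L, 20L), seed = 1)
  sch <- default_scheme()
  dwi <- synthesize_dwi(ph, sch, s0 = 1000, noise_sigma = 0)
  expect_equal(dim(dwi$signal)[4], 106)
  m <- phantom_mask(ph)
  for (j in c(1, 20, 60, 100)) {
    sl <- dwi$signal[, , , j]
    expect_true(all(sl[m] > 0 & sl[m] <= 1000))
  }
  expect_true(all(dwi$signal[, , , 1][!m] == 0))
})

test_that("Rician noise is biased upward and seed-deterministic", {
  ph <- make_phantom(c(20L, 24L, 20L), seed = 1)
  sch <- acquisition_scheme(rep(0, 4), matrix(0, 4, 3))  # b0-only volumes
  d1 <- synthesize_dwi(ph, sch, s0 = 100, noise_sigma = 30, seed = 9)
  d2 <- synthesize_dwi(ph, sch, s0 = 100, noise_sigma = 30, seed = 9)
  expect_identical(d1$signal, d2$signal)
  d3 <- synthesize_dwi(ph, sch, s0 = 100, noise_sigma = 30, seed = 10)
  expect_false(identical(d1$signal, d3$signal))
  m <- phantom_mask(ph)
  expect_gt(sum(m), 1000)
  expect_gt(mean(d1$signal[, , , 1][m]), 100)  # Rician bias at b = 0
  expect_error(synthesize_dwi(ph, sch, noise_sigma = -1), "noise_sigma")
})

test_that("synthetic cohort table plants the documented structure", {
  tab <- make_clinical_table(seed = 2)
  expect_equal(sum(tab$group == "control"), 52)
  expect_equal(sum(tab$group == "patient"), 44)
  expect_true(all(is.na(tab$truth_cluster[tab$group == "control"])))
  expect_true(all(tab$truth_cluster[tab$group == "patient"] %in% c("A", "B")))
  reg <- attr(tab, "registry")
  expect_setequal(setdiff(names(tab), c("id", "group", "truth_cluster")),
                  reg$variable)
  # invariants: binary columns two-level, timed measures non-negative
  for (v in reg$variable[reg$type == "binary"]) {
    expect_true(all(tab[[v]] %in% 0:1))
  }
  for (v in c("ninehpt_s", "tenmwt_s", "ftsts_s")) {
    expect_true(all(tab[[v]] > 0))
  }
  # derived gait metrics satisfy their defining formulas exactly
  expect_equal(tab$arm_swing_asym_pct,
               asymmetry_percent(tab$arm_swing_right, tab$arm_swing_left))
  expect_equal(tab$tug_dtcost_pct,
               dual_task_cost_percent(tab$tug_s_dt, tab$tug_s_st))
  # determinism
  expect_identical(as.data.frame(make_clinical_table(seed = 2)),
                   as.data.frame(tab))
})

test_that("a zero effect profile makes the planted subgroups exchangeable", {
  reg <- default_variable_registry()
  vars <- reg$variable[!is.na(reg$b_shift)]
  prof <- stats::setNames(rep(0, length(vars)), vars)
  tab <- make_clinical_table(effect_profile = prof, seed = 4)
  planted <- attr(tab, "planted")
  for (v in names(planted)) {
    expect_equal(planted[[v]][["A"]], planted[[v]][["B"]])
  }
  expect_error(make_clinical_table(effect_profile = c(bogus = 1)), "unknown")
  expect_error(make_clinical_table(n_patients = -1), "non-negative")
  expect_error(make_clinical_table(subgroup_fractions = c(0.7, 0.7)),
               "summing to 1")
})
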