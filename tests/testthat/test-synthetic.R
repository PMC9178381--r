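# Synthetic-limb generator and animation: determinism, ground-truth
# recovery, reference-pose behaviour, animation round-trips and the dynamic
# pedal coordinate system.

test_that("blueprints validate feasibility and generation is byte-deterministic", {
  expect_error(limb_blueprint(condyle_radius = 50), "infeasible")
  expect_error(limb_blueprint(fused = FALSE, condyle_spacing = 2),
               "infeasible")
  expect_error(limb_blueprint(resolution = 4), "resolution")

  bp <- limb_blueprint(noise_sd = 0.1, seed = 42, resolution = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_limb_fixture(generate_limb(bp), d1)
  write_limb_fixture(generate_limb(bp), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed moves the noisy vertices
  d3 <- withr::local_tempdir()
  write_limb_fixture(generate_limb(limb_blueprint(noise_sd = 0.1, seed = 43,
                                                  resolution = 10)), d3)
  expect_false(identical(readLines(file.path(d1, "femur_right.obj")),
                         readLines(file.path(d3, "femur_right.obj"))))
})

test_that("zero-noise patches recover blueprint primitives to 1e-6 relative", {
  limb <- test_limb(sides = c("right", "left"), fused = FALSE)
  fits <- fit_limb_primitives(limb)
  for (seg in names(fits)) {
    for (pn in names(fits[[seg]])) {
      tr <- limb$segments[[seg]]$truth[[pn]]
      ft <- fits[[seg]][[pn]]
      scale <- max(abs(tr$centroid), tr$radius %||% 1)
      expect_lt(max(abs(ft$centroid - tr$centroid)) / max(scale, 1), 1e-6,
                label = paste(seg, pn, "centroid"))
      if (tr$type == "sphere" || tr$type == "cylinder")
        expect_lt(abs(ft$radius - tr$radius) / tr$radius, 1e-6,
                  label = paste(seg, pn, "radius"))
      if (tr$type == "cylinder")
        expect_lt(angle_between_deg(ft$axis, tr$axis), 1e-4,
                  label = paste(seg, pn, "axis"))
      if (tr$type == "plane")
        expect_lt(angle_between_deg(ft$normal, tr$normal), 1e-4,
                  label = paste(seg, pn, "normal"))
    }
  }
  # fitted ACSs coincide with the ground-truth ACSs
  acs_fit <- fitted_acs_set(fits, c("right", "left"))
  for (nm in names(acs_fit)) {
    expect_equal(acs_fit[[nm]]$origin, limb$acs_truth[[nm]]$origin,
                 tolerance = 1e-6)
    expect_equal(acs_fit[[nm]]$axes, limb$acs_truth[[nm]]$axes,
                 tolerance = 1e-6)
  }
})

test_that("noisy patches recover primitives within the stated tolerances", {
  bp <- limb_blueprint(noise_sd = 0.07, seed = 77,  # 1% of the head radius
                       resolution = 32)
  limb <- generate_limb(bp)
  fits <- fit_limb_primitives(limb)
  head_tr <- limb$segments$femur_right$truth$femoral_head
  head_ft <- fits$femur_right$femoral_head
  expect_lt(sqrt(sum((head_ft$centroid - head_tr$centroid)^2)),
            0.02 * head_tr$radius)
  cond_tr <- limb$segments$femur_right$truth$femoral_condyles
  cond_ft <- fits$femur_right$femoral_condyles
  expect_lt(angle_between_deg(cond_ft$axis, cond_tr$axis), 1)
})

test_that("the all-zero script reproduces the reference pose and ramps round-trip", {
  limb <- test_limb()
  g <- ground_acs()
  n <- 6
  zero <- data.frame(FE = numeric(n), ABAD = 0, LAR = 0, tx = 0, ty = 0,
                     tz = 0)
  script <- gait_script(
    pelvis = data.frame(yaw = numeric(n), pitch = 0, roll = 0, tx = 0,
                        ty = 0, tz = 0),
    hip = zero, knee = zero, ankle = zero)
  an <- animate_limb(limb, script, g)
  ref <- assemble_reference_pose(limb$acs_truth, g, "right")
  for (seg in c("pelvis", "femur", "crus", "pes")) {
    key <- paste0(seg, "_right")
    ref_tf <- if (seg == "pelvis") ref$pelvis else ref[[key]]
    for (i in seq_len(n)) {
      expect_lt(max(abs(an$sequences[[key]]$transforms[[i]]$R - ref_tf$R)),
                1e-9)
      expect_lt(max(abs(an$sequences[[key]]$transforms[[i]]$t - ref_tf$t)),
                1e-9)
    }
  }
  # a scripted hip FE ramp is recovered exactly by decomposition
  ramp <- zero; ramp$FE <- seq(0, 120, length.out = n)
  script2 <- gait_script(pelvis = data.frame(yaw = numeric(n), pitch = 0,
                                             roll = 0, tx = 0, ty = 0,
                                             tz = 0),
                         hip = ramp, knee = zero, ankle = zero)
  an2 <- animate_limb(limb, script2, g)
  tab <- limb_pose_table(limb$acs_truth, an2$sequences, g, "right")
  hip <- tab[tab$joint == "hip", ]
  expect_equal(hip$FE_deg, ramp$FE, tolerance = 1e-9)
  expect_lt(max_abs_dof(tab[tab$joint == "knee", ]), 1e-9)
})

test_that("scripts exceeding the singularity bound need the stress flag", {
  n <- 3
  zero <- data.frame(FE = numeric(n), ABAD = 0, LAR = 0, tx = 0, ty = 0,
                     tz = 0)
  wild <- zero; wild$ABAD <- c(0, 88, 0)
  pel <- data.frame(yaw = numeric(n), pitch = 0, roll = 0, tx = 0, ty = 0,
                    tz = 0)
  expect_error(gait_script(pel, wild, zero, zero), "85")
  expect_s3_class(gait_script(pel, wild, zero, zero, stress = TRUE),
                  "gait_script")
})

test_that("the full gait script round-trips through animation and decomposition", {
  limb <- test_limb(sides = c("right", "left"))
  g <- ground_acs()
  sc <- default_gait_script(10)
  an <- animate_limb(limb, sc, g)
  for (side in c("right", "left")) {
    tab <- limb_pose_table(limb$acs_truth, an$sequences, g, side)
    for (jn in c("hip", "knee", "ankle")) {
      sub <- tab[tab$joint == jn, ]
      expect_lt(max(abs(sub$FE_deg - sc[[jn]]$FE)), 1e-9)
      expect_lt(max(abs(sub$ABAD_deg - sc[[jn]]$ABAD)), 1e-9)
      expect_lt(max(abs(sub$LAR_deg - sc[[jn]]$LAR)), 1e-9)
      expect_lt(max(abs(sub$t_x_mm - sc[[jn]]$tx)), 1e-9)
    }
    pel <- tab[tab$joint == "pelvis", ]
    expect_lt(max(abs(pel$FE_deg - sc$pelvis$yaw)), 1e-9)
    expect_lt(max(abs(pel$ABAD_deg - sc$pelvis$pitch)), 1e-9)
  }
})

test_that("the skewed-condyle reference pose folds the crus out of parallel", {
  limb_straight <- generate_limb(limb_blueprint(condylar_skew_deg = 0,
                                                resolution = 12))
  limb_skew <- generate_limb(limb_blueprint(condylar_skew_deg = 15,
                                            resolution = 12))
  g <- ground_acs()
  crus_angle <- function(limb) {
    ref <- assemble_reference_pose(limb$acs_truth, g, "right")
    fem_long <- as.vector(ref$femur_right$R %*% c(0, 0, -1))  # distal
    cru_long <- as.vector(ref$crus_right$R %*% c(0, 0, -1))
    # fully folded would make these anti-parallel; skew opens the angle
    180 - jointpose:::vec_angle(fem_long, cru_long) * 180 / pi
  }
  expect_lt(crus_angle(limb_straight), 1e-6)
  expect_equal(crus_angle(limb_skew), 15, tolerance = 1e-6)
})

test_that("scripted metatarsal spread rotates the dynamic pedal axis but not the static one", {
  limb <- test_limb(fused = FALSE)
  g <- ground_acs()
  sc <- default_gait_script(8, pedal_spread_mm = 3, pedal_skew_mm = 2.5)
  an <- animate_limb(limb, sc, g)
  lm <- an$pedal_landmarks$right
  seg <- limb$segments$pes_right
  # express the per-frame dynamic transverse axis in the pes segment frame:
  # with skew scripted it must rotate within the foot; the static MT-III
  # axis is rigidly attached and cannot
  T_pes <- an$sequences$pes_right$transforms
  local_axes <- t(vapply(seq_len(nrow(lm)), function(i) {
    tw <- c(lm$lateral_x[i], lm$lateral_y[i], lm$lateral_z[i]) -
      c(lm$medial_x[i], lm$medial_y[i], lm$medial_z[i])
    as.vector(t(T_pes[[i]]$R) %*% (tw / sqrt(sum(tw^2))))
  }, numeric(3)))
  swing <- max(vapply(seq_len(nrow(local_axes)), function(i)
    angle_between_deg(local_axes[i, ], local_axes[1, ]), numeric(1)))
  expect_gt(swing, 1)
  # frozen metatarsals: the landmark transverse axis is constant in the pes
  # frame (equals the static MT-III axis), and dynamic and static ankle
  # poses agree to 1e-6 deg
  sc0 <- default_gait_script(6)
  an0 <- animate_limb(limb, sc0, g)
  lm0 <- an0$pedal_landmarks$right
  T_pes0 <- an0$sequences$pes_right$transforms
  local_axes0 <- t(vapply(seq_len(nrow(lm0)), function(i) {
    tw <- c(lm0$lateral_x[i], lm0$lateral_y[i], lm0$lateral_z[i]) -
      c(lm0$medial_x[i], lm0$medial_y[i], lm0$medial_z[i])
    as.vector(t(T_pes0[[i]]$R) %*% (tw / sqrt(sum(tw^2))))
  }, numeric(3)))
  for (i in seq_len(nrow(local_axes0)))
    expect_lt(angle_between_deg(local_axes0[i, ],
                                seg$truth$pes_distal$axis), 1e-9)
  tS <- limb_pose_table(limb$acs_truth, an0$sequences, g, "right")
  tD <- limb_pose_table(limb$acs_truth, an0$sequences, g, "right",
                        pes_mode = "dynamic",
                        pedal_landmarks = an0$pedal_landmarks$right)
  aS <- tS[tS$joint == "ankle", ]; aD <- tD[tD$joint == "ankle", ]
  expect_lt(max(abs(as.matrix(aS[, 4:6]) - as.matrix(aD[, 4:6]))), 1e-6)
  # with spread/skew the dynamic decomposition deviates from the static one
  tD2 <- limb_pose_table(limb$acs_truth, an$sequences, g, "right",
                         pes_mode = "dynamic",
                         pedal_landmarks = an$pedal_landmarks$right)
  tS2 <- limb_pose_table(limb$acs_truth, an$sequences, g, "right")
  aD2 <- tD2[tD2$joint == "ankle", ]; aS2 <- tS2[tS2$joint == "ankle", ]
  expect_gt(max(abs(as.matrix(aD2[, 4:6]) - as.matrix(aS2[, 4:6]))), 0.5)
})
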