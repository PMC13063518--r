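test_that("generators are pure functions of their seed", {
  g1 <- gen_bite_recording(seed = 42, noise_sd = 0.1)
  g2 <- gen_bite_recording(seed = 42, noise_sd = 0.1)
  expect_identical(g1$recording$force$values, g2$recording$force$values)
  expect_identical(g1$recording$emg$LT$values, g2$recording$emg$LT$values)
  g3 <- gen_bite_recording(seed = 43, noise_sd = 0.1)
  expect_false(identical(g1$recording$emg$LT$values,
                         g3$recording$emg$LT$values))
})

test_that("generated meshes hit the target edge length within 15 %", {
  s <- gen_surface("sphere", list(radius = 10, extent = 3),
                   edge_length = 0.3)
  expect_lt(abs(s$mean_edge - 0.3), 0.045)
  p <- gen_surface("plane", list(extent = 3), edge_length = 0.3)
  expect_lt(abs(p$mean_edge - 0.3), 0.045)
  expect_equal(attr(p, "k_max_true"), rep(0, nrow(p$vertices)))
})

test_that("noiseless generated recordings recover their prescribed ratios within 2 %", {
  for (sd in c(1, 2)) {
    g <- gen_bite_recording(plateau_N = 60, ic_temporalis = 1.75,
                            ic_masseter = 0.9, noise_sd = 0, seed = sd)
    pt <- process_recording(g$recording, g$truth$bite_window,
                            g$truth$baseline_window)
    expect_equal(pt$ic_temporalis, 1.75, tolerance = 0.02)
    expect_equal(pt$ic_masseter, 0.9, tolerance = 0.02)
    expect_equal(pt$final_bite_force, 60, tolerance = 60 * 0.02)
  }
})

test_that("unit ratios give statistically symmetric channels", {
  g <- gen_bite_recording(ic_temporalis = 1, ic_masseter = 1, seed = 5,
                          noise_sd = 0)
  ks <- suppressWarnings(stats::ks.test(g$recording$emg$LT$values,
                                        g$recording$emg$RT$values))
  expect_gt(ks$p.value, 0.01)
})

test_that("the condyle/fossa pair has the prescribed apex clearance growing to the rim", {
  pr <- gen_condyle_fossa_pair(condyle_r = 10, socket_r = 12,
                               clearance = 0.5, edge_length = 0.4)
  apex <- which.min(rowSums(pr$condyle$vertices[, 1:2]^2))
  expect_equal(pr$gap_true[apex], 0.5, tolerance = 1e-3) # apex vertex sits within one edge of the pole
  r2 <- rowSums(pr$condyle$vertices[, 1:2]^2)
  rim <- r2 > 0.9 * max(r2)
  expect_true(all(pr$gap_true[rim] > pr$gap_true[apex]))
  expect_error(gen_condyle_fossa_pair(clearance = -0.1), "nonnegative")
  expect_error(gen_condyle_fossa_pair(condyle_r = 10, socket_r = 9), "socket_r")
})

test_that("larger incongruence raises the mean congruency value monotonically", {
  vals <- vapply(c(0, 0.1, 0.25), function(inc) {
    pr <- gen_condyle_fossa_pair(condyle_r = 10, socket_r = 10,
                                 clearance = 0.2, incongruence = inc,
                                 edge_length = 0.4)
    cm <- congruency_map(pr$condyle, pr$fossa)
    interior <- rowSums(pr$condyle$vertices[, 1:2]^2) < 2.5^2
    mean(cm$values[interior & is.finite(cm$values)])
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the toy mandible satisfies its construction contracts", {
  m <- gen_toy_mandible()
  expect_s3_class(m, "tmj_model")
  expect_equal(mandible_length(m), 117.8, tolerance = 1e-9)
  expect_equal(mandible_length(gen_toy_mandible(length = 130)), 130,
               tolerance = 1e-9)
  act <- Filter(function(mu) mu$active, m$muscles)
  expect_length(act, 12)
  expect_length(m$ligaments, 14)
  slacks <- sort(unique(vapply(m$ligaments, function(l) l$slack_length,
                               numeric(1))))
  expect_equal(slacks, c(0, 1.9, 4, 7.5))
  expect_error(gen_toy_mandible(length = 80), "90, 150")
  # bilateral symmetry of the construction
  for (mu in m$muscles[seq(1, 6)]) {
    partner <- m$muscles[[paste("right", mu$name, sep = "_")]]
    expect_equal(mu$origin * c(-1, 1, 1), partner$origin)
    expect_equal(mu$insertion * c(-1, 1, 1), partner$insertion)
  }
})

test_that("muscle strengths are overridable and closing moment arms are positive", {
  m <- gen_toy_mandible(muscle_strengths = c(masseter_superficial = 300))
  f <- vapply(m$muscles, function(mu) mu$f_max, numeric(1))
  expect_equal(unname(f[["left_masseter_superficial"]]), 300)
  # every active muscle produces a positive (closing) bite response
  er <- excitation_response(build_sim(m))
  expect_true(all(er$H > 0))
})

test_that("the force curve ramps smoothly to its plateau", {
  fc <- gen_force_curve(50)
  expect_length(fc$values, 250)
  expect_equal(fc$values[1], 0)
  expect_equal(fc$values[250], 50)
  expect_true(all(diff(fc$values) >= -1e-12))
  expect_equal(fc$sample_rate, 1000)
})
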