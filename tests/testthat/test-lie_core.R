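test_that("bound-minus-free differences are plain arithmetic", {
  bound <- tiny_bound()[1, ]
  bound$v_el_bound <- -120; bound$v_vdw_bound <- -80
  free <- data.frame(ligand_id = "L1", v_el_free = -100, v_vdw_free = -60)
  d <- delta_energies(bound, free)
  expect_equal(d$d_el, -20)
  expect_equal(d$d_vdw, -20)

  bound$v_el_bound <- -100; bound$v_vdw_bound <- -60
  d <- delta_energies(bound, free)
  expect_equal(c(d$d_el, d$d_vdw), c(0, 0))

  bound$v_el_bound <- -250.5; bound$v_vdw_bound <- -90.25
  free$v_el_free <- -200.0; free$v_vdw_free <- -100.0
  d <- delta_energies(bound, free)
  expect_equal(c(d$d_el, d$d_vdw), c(-50.5, 9.75))

  expect_error(delta_energies(bound,
                              data.frame(ligand_id = "L9",
                                         v_el_free = 0, v_vdw_free = 0)),
               "ligand mismatch")
})

test_that("per-simulation free energy follows the two model variants", {
  expect_equal(pose_free_energy(lie_params(alpha = 0, beta = 0), -7, 3), 0)
  expect_equal(pose_free_energy(lie_params(alpha = 0.5, beta = 0.25),
                                -10, -20), -12.5)
  expect_equal(pose_free_energy(lie_params(alpha = 0.4, gamma = -3),
                                d_el = 99, d_vdw = -20), -11)
})

test_that("Boltzmann weights normalize, respect ratios and resist overflow", {
  kT <- lie_kT()
  expect_equal(boltzmann_weights(c(-20, -20), kT), c(0.5, 0.5))
  expect_equal(boltzmann_weights(-31.7, kT), 1)
  # a kT*ln(2) gap forces an exact 2:1 ratio
  w <- boltzmann_weights(c(-25, -25 + kT * log(2)), kT)
  expect_equal(w, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # shift stability: magnitudes that would overflow a naive exponential
  # (tolerance reflects float cancellation in the 1e6-magnitude gap)
  w_huge <- boltzmann_weights(c(-1e6, -1e6 + kT * log(2)), kT)
  expect_equal(w_huge, c(2 / 3, 1 / 3), tolerance = 1e-8)
  expect_error(boltzmann_weights(numeric(0)), "empty")
})

test_that("weights are normalized and shift-invariant for arbitrary inputs", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    dg <- rnorm(n, -25, 8)
    kT <- runif(1, 0.5, 5)
    w <- boltzmann_weights(dg, kT)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
    shift <- runif(1, -50, 50)
    expect_equal(boltzmann_weights(dg + shift, kT), w, tolerance = 1e-12)
  }
})

test_that("replicate combination averages or passes through", {
  pair <- data.frame(ligand_id = "L1", protein_conf = "P70", pose = "M1",
                     replicate = c("S1", "S2"),
                     v_el_bound = c(-100, -100), v_vdw_bound = c(-50, -50),
                     stringsAsFactors = FALSE)
  avg <- combine_replicates(pair, "replicate_averaged")
  expect_equal(nrow(avg), 1L)
  expect_equal(c(avg$v_el_bound, avg$v_vdw_bound), c(-100, -50))

  pair$v_el_bound <- c(-100, -110); pair$v_vdw_bound <- c(-50, -40)
  avg <- combine_replicates(pair, "replicate_averaged")
  expect_equal(c(avg$v_el_bound, avg$v_vdw_bound), c(-105, -45))

  expect_identical(combine_replicates(pair, "separate"), pair)
})

test_that("a configuration missing one replicate contributes its single run", {
  bound <- rbind(tiny_bound(),
                 within(tiny_bound(), replicate <- "S2")[1:3, ])
  expect_message(avg <- combine_replicates(bound, "replicate_averaged"),
                 "single replicate")
  expect_equal(nrow(avg), 4L)  # one row per (ligand, conf, pose)
  # the singleton configuration keeps its original values
  single <- avg[avg$ligand_id == "L2" & avg$pose == "M2", ]
  expect_equal(single$v_el_bound, -130)
})

test_that("combined free energy is the weighted mean of per-pose values", {
  p <- lie_params(alpha = 0.4, beta = 0.2)
  one <- data.frame(ligand_id = "L1", protein_conf = "P70", pose = "M1",
                    replicate = "S1", sim_id = "P70-M1-S1",
                    d_el = -20, d_vdw = -50, stringsAsFactors = FALSE)
  res <- combined_free_energy(p, one)
  expect_equal(res$dg_calc, pose_free_energy(p, -20, -50))
  expect_equal(unname(res$weights), 1)

  # equal per-pose values: prediction equals that common value
  two <- rbind(one, one)
  two$sim_id <- c("a", "b"); two$pose <- c("M1", "M2")
  expect_equal(combined_free_energy(p, two)$dg_calc,
               pose_free_energy(p, -20, -50))

  # direct evaluation of the weighting formula: dG_i = (-30, -30 + kT ln 2)
  kT <- p$kT
  d <- data.frame(ligand_id = "L1", protein_conf = "P70",
                  pose = c("M1", "M2"), replicate = "S1",
                  sim_id = c("P70-M1-S1", "P70-M2-S1"),
                  d_el = c(0, 0),
                  d_vdw = c(-30, -30 + kT * log(2)) / 0.4,
                  stringsAsFactors = FALSE)
  res <- combined_free_energy(p, d)
  expect_equal(res$dg_calc,
               (2 / 3) * (-30) + (1 / 3) * (-30 + kT * log(2)),
               tolerance = 1e-12)
})

test_that("combined prediction equals the weight-average identity and is bounded", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    d <- data.frame(ligand_id = "L1", protein_conf = "P70",
                    pose = paste0("M", seq_len(n)), replicate = "S1",
                    sim_id = paste0("sim", seq_len(n)),
                    d_el = runif(n, -60, 0), d_vdw = runif(n, -120, -20),
                    stringsAsFactors = FALSE)
    p <- lie_params(alpha = runif(1, 0.1, 0.7), beta = runif(1, -0.2, 0.6))
    res <- combined_free_energy(p, d)
    expect_equal(res$dg_calc, sum(res$weights * res$dg_i),
                 tolerance = 1e-10)
    expect_gte(res$dg_calc, min(res$dg_i) - 1e-10)
    expect_lte(res$dg_calc, max(res$dg_i) + 1e-10)
  }
})

test_that("weight concentrates on the lowest-energy simulation as kT -> 0", {
  d <- data.frame(ligand_id = "L1", protein_conf = "P70",
                  pose = c("M1", "M2", "M3"), replicate = "S1",
                  sim_id = c("a", "b", "c"),
                  d_el = c(-10, -30, -20), d_vdw = c(-50, -70, -60),
                  stringsAsFactors = FALSE)
  p <- lie_params(alpha = 0.4, beta = 0.2, kT = 1e-8)
  res <- combined_free_energy(p, d)
  expect_equal(unname(res$weights[which.min(res$dg_i)]), 1,
               tolerance = 1e-10)
  expect_equal(res$dg_calc, min(res$dg_i), tolerance = 1e-6)
  # exact ties share the limit weight equally
  d2 <- d[c(2, 2), ]; d2$sim_id <- c("b1", "b2")
  res2 <- combined_free_energy(p, d2)
  expect_equal(unname(res2$weights), c(0.5, 0.5))
})
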