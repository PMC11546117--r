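test_that("transport simulator honours degenerate and symmetric cases", {
  # no permeability, no clearance: receiver stays exactly zero
  cfg0 <- simulation_config(papp_true = 0, noise_cv = 0, seed = 1)
  s0 <- simulate_transport(cfg0)
  expect_equal(s0$values, rep(0, 4))

  # equal concentrations both sides with passive transport only: no net flux
  M <- milkbarrier:::.transport_matrix(1e-6, 0, 0.5, 1.2, "A2B")
  st <- milkbarrier:::.twocomp_step(c(100, 100), M, 3600)
  expect_equal(as.numeric(st), c(100, 100), tolerance = 1e-9)
})

test_that("closed-form propagation matches small-step Euler integration", {
  for (dir in c("A2B", "B2A")) {
    cfg <- simulation_config(papp_true = 10, noise_cv = 0, seed = 1)
    exact <- attr(simulate_transport(cfg, dir), "truth")$true_concentrations
    euler <- simulate_transport_euler(cfg, dir, dt = 0.1)
    expect_lt(max(abs(exact / euler - 1)), 0.001)
  }
  # with an active efflux clearance too
  cfg2 <- simulation_config(papp_true = 5, active_clearance = 2e-6,
                            noise_cv = 0, seed = 1)
  exact <- attr(simulate_transport(cfg2, "B2A"), "truth")$true_concentrations
  euler <- simulate_transport_euler(cfg2, "B2A", dt = 0.1)
  expect_lt(max(abs(exact / euler - 1)), 0.001)
})

test_that("simulator conserves mass and is deterministic per seed", {
  for (p in c(0.3, 5, 18)) {
    cfg <- simulation_config(papp_true = p, noise_cv = 0.05, seed = 42)
    tr <- attr(simulate_transport(cfg, "A2B"), "truth")
    expect_lt(abs(tr$mass_residual) / tr$dose, 1e-9)
  }
  cfg <- simulation_config(papp_true = 3, noise_cv = 0.1, seed = 7)
  a <- simulate_transport(cfg, "A2B")
  b <- simulate_transport(cfg, "A2B")
  expect_identical(a$values, b$values)
  expect_identical(a$donor_value, b$donor_value)
})

test_that("noise-free pipeline recovery sits inside the donor-depletion envelope", {
  # the estimator divides the slope by the initial donor concentration, so
  # donor depletion biases it slightly low; the effect grows with Papp and
  # stays under ~5% at the top of the measured range (8% donor depletion)
  for (p in c(0.3, 1, 5)) {
    cfg <- simulation_config(papp_true = p, noise_cv = 0, seed = 1)
    for (dir in c("A2B", "B2A")) {
      f <- fit_papp(simulate_transport(cfg, dir))
      expect_equal(f$papp, p, tolerance = 0.02)
    }
  }
  cfg18 <- simulation_config(papp_true = 18, noise_cv = 0, seed = 1)
  for (dir in c("A2B", "B2A")) {
    f <- fit_papp(simulate_transport(cfg18, dir))
    expect_lt(f$papp, 18)            # bias is downward
    expect_equal(f$papp, 18, tolerance = 0.05)
  }
})

test_that("noisy pipeline recovery stays within 15% for the median of 6 inserts", {
  for (p in c(0.3, 1, 5, 18)) {
    for (dir in c("A2B", "B2A")) {
      papps <- vapply(1:6, function(i) {
        cfg <- simulation_config(papp_true = p, noise_cv = 0.05,
                                 seed = 1000 + 17 * i)
        fit_papp(simulate_transport(cfg, dir))$papp
      }, numeric(1))
      expect_equal(median(papps), p, tolerance = 0.15)
    }
  }
})

test_that("active efflux clearance produces a polarity ratio that grows with it", {
  est_ratio <- function(cl, seed0 = 50) {
    fits <- list()
    for (i in 1:4) {
      cfg <- simulation_config(papp_true = 2, active_clearance = cl,
                               noise_cv = 0.05, seed = seed0 + i)
      fits <- c(fits, list(fit_papp(simulate_transport(cfg, "A2B",
                                                       insert_id = paste0("a", i)))),
                list(fit_papp(simulate_transport(cfg, "B2A",
                                                 insert_id = paste0("b", i)))))
    }
    summarize_direction(fits)$polarity_ratio
  }
  r0 <- est_ratio(0)
  r1 <- est_ratio(2e-7)
  r2 <- est_ratio(1e-6)
  expect_gt(r0, 0.8)
  expect_lt(r0, 1.25)
  expect_gt(r1, 1)
  expect_gt(r2, r1)
})

test_that("simulated receiver stays under sink conditions at the highest Papp", {
  cfg <- simulation_config(papp_true = 18, noise_cv = 0, seed = 1)
  tr <- attr(simulate_transport(cfg, "A2B"), "truth")
  expect_lt(tr$sink_fraction, 0.05)
})

test_that("TEER course rises logistically and is reproducible", {
  s <- simulate_teer_course(plateau = 721, day50 = 32, noise_sd = 0,
                            days = c(32, 100))
  expect_equal(s$teer[1], 721 / 2, tolerance = 1e-6)
  expect_equal(s$teer[2], 721, tolerance = 1e-6)
  a <- simulate_teer_course(noise_sd = 25, seed = 3)
  b <- simulate_teer_course(noise_sd = 25, seed = 3)
  expect_identical(a$teer, b$teer)
})

test_that("simulated Ct tables have the configured structure", {
  tab <- simulate_ct_table(seed = 4)
  expect_equal(length(unique(tab$gene)), 84 + 5)  # targets + reference panel
  expect_equal(length(unique(tab$replicate)), 3)
  und <- tapply(tab$ct, tab$gene, function(x) all(is.na(x)))
  expect_setequal(names(und)[und], c("SLC22A9", "SLCO1B1", "SLCO1B3"))
  # no undetectable genes requested
  tab2 <- simulate_ct_table(undetectable_genes = character(0), seed = 4)
  expect_false(anyNA(tab2$ct))
  expect_identical(simulate_ct_table(seed = 9), simulate_ct_table(seed = 9))
})
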