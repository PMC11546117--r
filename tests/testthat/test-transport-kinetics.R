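test_that("cumulative reconstruction matches the worked mass-balance example", {
  s <- receiver_series(c(10, 20, 24, 40), donor_value = 5e4,
                       direction = "A2B")
  q <- reconstruct_cumulative(s)$q
  expect_equal(q, c(12, 30, 46.8, 80.4), tolerance = 1e-12)

  # single point: Q = C * V
  s1 <- receiver_series(10, times = 2, donor_value = 5e4, direction = "A2B")
  expect_equal(reconstruct_cumulative(s1)$q, 12)

  # zero concentrations give zero transport
  s0 <- receiver_series(rep(0, 4), donor_value = 5e4, direction = "A2B")
  expect_equal(reconstruct_cumulative(s0)$q, rep(0, 4))
})

test_that("reconstruction conserves mass against the bookkeeping oracle", {
  set.seed(99)
  geom <- default_geom()
  for (i in 1:50) {
    n <- sample(2:6, 1)
    times <- sort(runif(n, 0.1, 4))
    vals <- runif(n, 0, 400)
    frac <- runif(1, 0.1, 0.9)
    dir <- sample(c("A2B", "B2A"), 1)
    v <- if (dir == "A2B") geom$basolateral_volume else geom$apical_volume
    sched <- sampling_schedule(times, frac * v)
    s <- receiver_series(vals, times = times, direction = dir,
                         donor_value = 5e4, schedule = sched, geometry = geom)
    expect_equal(reconstruct_cumulative(s)$q,
                 oracle_cumulative(vals, v, rep(frac * v, n)),
                 tolerance = 1e-12)
  }
})

test_that("LOQ censoring flags points below the limit and detects empty series", {
  s <- receiver_series(c(3, 8, 12), times = c(0.5, 1, 2), donor_value = 5e4,
                       direction = "A2B", loq = 5)
  cs <- censor_loq(s)
  expect_equal(cs$censored, c(TRUE, FALSE, FALSE))

  all_low <- censor_loq(receiver_series(c(1, 2, 3), times = c(0.5, 1, 2),
                                        donor_value = 5e4, direction = "A2B",
                                        loq = 5))
  expect_true(all(all_low$censored))
  expect_identical(attr(all_low, "status"), "below_loq")

  all_high <- censor_loq(receiver_series(c(6, 7, 8), times = c(0.5, 1, 2),
                                         donor_value = 5e4, direction = "A2B",
                                         loq = 5))
  expect_false(any(all_high$censored))
})

test_that("linearity trimming drops leading points only, stopping at the threshold", {
  t <- c(0.5, 1, 1.2, 2)
  # perfectly linear through the origin: nothing dropped
  lin <- fit_linear_window(make_ct(t, 3 * t))
  expect_equal(lin$status, "ok")
  expect_equal(lin$slope_per_h, 3, tolerance = 1e-12)
  expect_equal(lin$r_squared, 1)
  expect_length(lin$points_dropped, 0)

  # lag phase where dropping the origin lifts R^2 over the threshold
  lag1 <- make_ct(t, c(0.2, 8, 14.4, 40))
  f1 <- fit_linear_window(lag1)
  expect_equal(f1$status, "ok")
  expect_equal(f1$points_dropped, 0)  # only the origin went
  expect_gte(f1$r_squared, 0.970)

  # deeper lag: origin and the first sample go; agrees with the brute-force
  # prefix oracle
  lag2 <- make_ct(t, c(0.5, 1.2, 8, 30))
  f2 <- fit_linear_window(lag2)
  expect_equal(f2$status, "ok")
  expect_equal(f2$points_dropped, c(0, 0.5))
  orc <- oracle_trim(c(0, t), c(0, 0.5, 1.2, 8, 30))
  expect_equal(length(f2$points_dropped), orc$n_dropped)
  expect_equal(f2$r_squared, orc$r2, tolerance = 1e-12)

  # only prefixes are ever removed
  expect_true(all(f2$points_dropped < min(f2$points_used)))
})

test_that("trimming refuses fits with fewer than three remaining points", {
  # origin + 3 measured points, still nonlinear after one drop: the next
  # drop would leave 2 points, so no fit is returned
  ct <- make_ct(c(1, 1.2, 2), c(10, 8, 30))
  f <- fit_linear_window(ct)
  expect_equal(f$status, "insufficient_points")
  expect_true(is.na(f$slope))

  # two measured points without the origin cannot be fitted at all
  f2 <- fit_linear_window(make_ct(c(1, 2), c(5, 11)), include_origin = FALSE)
  expect_equal(f2$status, "insufficient_points")
})

test_that("Papp arithmetic and unit-cancellation invariance hold", {
  geom <- default_geom()
  # molar route: 1.5e-13 mol/s on 0.3 cm2 against a 50 uM donor is 10e-6 cm/s
  # (in pmol/nM units: slope 0.15 pmol/s, donor 5e4 nM = 5e4 pmol/mL)
  fit <- structure(list(slope = 0.15, slope_per_h = 0.15 * 3600,
                        intercept = 0, r_squared = 1, points_used = 1:3,
                        points_dropped = numeric(0), status = "ok"),
                   class = "linear_fit")
  expect_equal(compute_papp(fit, geom, 5e4), 10, tolerance = 1e-12)

  # signal route: 0.006 signal.mL/s over 0.3 cm2 and 1000 signal/mL
  fit$slope <- 0.006
  expect_equal(compute_papp(fit, geom, 1000, unit_value = "signal"), 20,
               tolerance = 1e-12)

  # rescaling values and donor together cancels out
  s <- receiver_series(c(10, 20, 24, 40), donor_value = 5e4,
                       direction = "A2B")
  s2 <- receiver_series(c(10, 20, 24, 40) * 37, donor_value = 5e4 * 37,
                        direction = "A2B", loq = 5 * 37)
  expect_equal(fit_papp(s)$papp, fit_papp(s2)$papp, tolerance = 1e-12)

  # unit tags must cancel
  expect_error(compute_papp(fit, geom, 1000, unit_value = "signal",
                            unit_donor = "nM"), "unit mismatch")
  expect_error(compute_papp(fit, geom, 0, unit_value = "signal"), "> 0")

  fit$slope <- 0
  expect_warning(p0 <- compute_papp(fit, geom, 1000, unit_value = "signal"),
                 "zero slope")
  expect_identical(p0, 0)
})

test_that("fully censored series yield a finite LOQ bound, linear in the LOQ", {
  s <- receiver_series(rep(1, 4), donor_value = 5e4, direction = "A2B",
                       loq = 5)
  b <- loq_bound(s)
  expect_gt(b, 0)
  expect_true(is.finite(b))

  s2 <- receiver_series(rep(1, 4), donor_value = 5e4, direction = "A2B",
                        loq = 10)
  expect_equal(loq_bound(s2), 2 * b, tolerance = 1e-12)

  # agrees with substituting the LOQ through the reconstruction by hand
  sub <- receiver_series(rep(5, 4), donor_value = 5e4, direction = "A2B")
  q <- reconstruct_cumulative(sub)$q
  manual <- 1e6 * (q[4] / (2 * 3600)) / (0.3 * 5e4)
  expect_equal(b, manual, tolerance = 1e-12)

  # refuses a series with quantifiable points
  s3 <- receiver_series(c(1, 9, 9, 9), donor_value = 5e4, direction = "A2B")
  expect_error(loq_bound(s3), "fully censored")
})

test_that("fit_papp tags censoring-limited outcomes like the reporting codes", {
  # all below LOQ: no estimate, only an upper bound
  f <- fit_papp(receiver_series(rep(1, 4), donor_value = 5e4,
                                direction = "A2B"))
  expect_equal(f$status, "below_loq")
  expect_true(is.na(f$papp))
  expect_true(is.finite(f$bound))

  # two quantifiable points: estimate flagged, not silently accepted
  f2 <- fit_papp(receiver_series(c(2, 3, 30, 36.67), donor_value = 5e4,
                                 direction = "A2B"))
  expect_equal(f2$status, "two_point_estimate")
  expect_false(is.na(f2$papp))
})

test_that("directional medians and polarity ratios follow the efflux convention", {
  mk <- function(papp, dir) {
    # scale a linear template so the fitted Papp equals the requested value;
    # keep the LOQ negligible so scaling never censors points
    base <- fit_papp(receiver_series(c(10, 20, 24, 40), donor_value = 5e4,
                                     direction = dir, loq = 1e-9))$papp
    fit_papp(receiver_series(papp * c(10, 20, 24, 40) / base,
                             donor_value = 5e4, direction = dir, loq = 1e-9))
  }
  # single replicate: median is that value
  one <- summarize_direction(list(mk(7.65, "A2B")))
  expect_equal(one$median_a2b, 7.65, tolerance = 0.01)
  expect_true(is.na(one$polarity_ratio))

  fits <- c(lapply(c(0.3, 0.38, 0.5), mk, dir = "A2B"),
            lapply(c(0.5, 0.63, 0.8), mk, dir = "B2A"))
  s <- summarize_direction(fits)
  expect_equal(s$polarity_ratio, s$median_b2a / s$median_a2b)
  expect_equal(s$polarity_ratio, 0.63 / 0.38, tolerance = 0.02)

  # one direction fully censored: ratio undetermined, bound qualifier kept
  cens <- fit_papp(receiver_series(rep(1, 4), donor_value = 5e4,
                                   direction = "B2A"))
  s2 <- summarize_direction(list(mk(0.38, "A2B"), cens))
  expect_true(is.na(s2$polarity_ratio))
  expect_identical(s2$qual_b2a, "<=")

  # medians are permutation-invariant and robust to one wild replicate
  vals <- c(0.3, 0.35, 0.4, 0.45, 0.5, 0.55)
  f_a <- lapply(vals, mk, dir = "A2B")
  f_b <- lapply(rev(vals), mk, dir = "A2B")
  expect_equal(summarize_direction(f_a)$median_a2b,
               summarize_direction(f_b)$median_a2b)
  wild <- lapply(c(vals[-6], 1e6), mk, dir = "A2B")
  expect_lte(summarize_direction(wild)$median_a2b, max(vals))
})

test_that("dynamic range uses only quantifiable medians", {
  ref <- read_papp_medians()
  expect_equal(dynamic_range(ref), 18.18 / 0.03, tolerance = 1e-12)
  expect_equal(dynamic_range(c(2, 2, 2)), 1)
  expect_error(dynamic_range(5), "at least 2")
  # bounds and undetermined entries are excluded from the extremes
  quantifiable <- ref$median[!is.na(ref$qual) & ref$qual == ""]
  expect_false(anyNA(quantifiable))
  expect_gt(min(quantifiable), 0)
})

test_that("transport CSV round-trips into receiver series", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(insert_id = "i1", substrate = "atenolol",
                   direction = "A2B", time_h = c(0.5, 1, 1.2, 2),
                   value = c(10, 20, 24, 40), unit = "nM",
                   donor_value = 5e4, loq = 5)
  write.csv(df, path, row.names = FALSE)
  series <- read_transport_csv(path)
  expect_length(series, 1)
  expect_equal(reconstruct_cumulative(series[[1]])$q, c(12, 30, 46.8, 80.4))
})

test_that("summary tables carry the a/b/c footnote codes", {
  below <- fit_papp(receiver_series(rep(1, 4), donor_value = 5e4,
                                    direction = "B2A"))
  ok <- fit_papp(receiver_series(c(10, 20, 24, 40), donor_value = 5e4,
                                 direction = "A2B"))
  tab <- papp_table(list(summarize_direction(list(ok, below))))
  expect_equal(tab$code[tab$direction == "A2B"], "")
  expect_equal(tab$code[tab$direction == "B2A"], "c")

  path <- withr::local_tempfile(fileext = ".csv")
  write_papp_table(tab, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 2)
})
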