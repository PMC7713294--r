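test_that("integrated binding reaches the closed-form equilibrium", {
  net1 <- build_network(1)
  # k_cat = 0: pure binding equilibria for both species
  p <- kinetic_parameters(c(0.4, 0.2), c(2, 4), 0)
  assay <- assay_spec(sampling_times = c(0, 5, 60))
  tc <- simulate_timecourse(net1, p, assay, full_state = TRUE)
  st <- attr(tc, "state")
  ES_star <- binding_equilibrium(E_total = assay$enzyme_total, S_total = 10,
                                 K_d = 2 / 0.4)
  expect_equal(unname(st[3, "ES_phytoene"]), ES_star, tolerance = 1e-6)
  # downstream species never appears without catalysis
  expect_true(all(st[, "phytofluene"] == 0))
})

test_that("no enzyme means nothing changes", {
  net <- build_network(4)
  assay <- assay_spec(enzyme_total = 0,
                      sampling_times = c(0, 10, 60, 120))
  tc <- simulate_timecourse(net, fast_params(), assay)
  expect_true(all(tc$phytoene == 10))
  expect_true(all(tc[, setdiff(timecourse_species(tc), "phytoene")] == 0))
})

test_that("time zero equals the initial condition exactly", {
  net <- build_network(4)
  tc <- simulate_timecourse(net, fast_params(), preset_assay("dense_schedule"))
  expect_identical(tc$phytoene[1], 10)
  expect_identical(unname(unlist(tc[1, -(1:2)])), rep(0, 4))
})

test_that("conservation and monotonicity hold across random parameter draws", {
  withr::local_seed(7)
  net <- build_network(4)
  assay <- preset_assay("dense_schedule")
  for (i in 1:25) {
    p <- draw_parameters(net)
    tc <- simulate_timecourse(net, p, assay, full_state = TRUE)
    drift <- conservation_residuals(attr(tc, "state"), net)
    expect_lt(drift[["carotene"]], 1e-6)
    expect_lt(drift[["enzyme"]], 1e-6)
    # total phytoene non-increasing, terminal product non-decreasing
    expect_true(all(diff(tc$phytoene) <= 1e-9))
    expect_true(all(diff(tc$lycopene) >= -1e-9))
    # no intermediate appears before its precursor has been nonzero
    sp <- net$chain
    first_nonzero <- vapply(sp, function(s) {
      idx <- which(tc[[s]] > 1e-12)
      if (length(idx)) idx[1] else Inf
    }, numeric(1))
    expect_true(all(diff(first_nonzero) >= 0))
  }
})

test_that("subsampling a fine grid matches direct coarse simulation", {
  net <- build_network(4)
  p <- fast_params()
  coarse <- assay_spec(sampling_times = c(0, 10, 30, 60, 120))
  fine <- assay_spec(sampling_times = sort(unique(c(
    seq(0, 120, by = 2.5), c(10, 30, 60)))))
  tc_c <- simulate_timecourse(net, p, coarse)
  tc_f <- simulate_timecourse(net, p, fine)
  sub <- tc_f[match(tc_c$time_min, tc_f$time_min), ]
  for (s in timecourse_species(tc_c)) {
    expect_equal(sub[[s]], tc_c[[s]], tolerance = 1e-6)
  }
})

test_that("ODE consumption rate converges to the quasi-steady-state rate", {
  net <- build_network(4)
  p <- fast_params()
  S0 <- 10
  errs <- vapply(c(0.01, 0.001), function(Et) {
    assay <- assay_spec(initial_phytoene = S0, enzyme_total = Et,
                        sampling_times = c(0, 0.05, 0.1))
    tc <- simulate_timecourse(net, p, assay)
    slope <- -(tc$phytoene[3] - tc$phytoene[2]) / (0.05 * 60)
    qss <- initial_rate_qss(p, S0, Et, 1)
    abs(slope - qss) / qss
  }, numeric(1))
  expect_lt(errs[2], 0.02)
  expect_lt(errs[2], errs[1])  # error shrinks with E_total/S0
})

test_that("initial_rate_qss closed-form limits", {
  p <- fast_params()
  km1 <- (p$k_r[1] + p$k_cat[1]) / p$k_f[1]
  # saturation and half-saturation
  expect_equal(initial_rate_qss(p, 1e9, 0.5, 1), p$k_cat[1] * 0.5,
               tolerance = 1e-6)
  expect_equal(initial_rate_qss(p, km1, 0.5, 1), p$k_cat[1] * 0.5 / 2)
  expect_error(initial_rate_qss(p, 10, 0.5, 5), class = "carokin_unknown_step")
})

test_that("peak_times follows the earliest-maximum tie rule", {
  tc <- structure(
    data.frame(time_min = c(0, 10, 20),
               phytoene = c(5, 5, 5),          # constant -> first time
               phytofluene = c(0, 2, 1),
               lycopene = c(0, 1, 3)),          # increasing -> last time
    class = c("crti_timecourse", "data.frame"))
  pk <- peak_times(tc)
  expect_identical(pk[["phytoene"]], 0)
  expect_identical(pk[["phytofluene"]], 10)
  expect_identical(pk[["lycopene"]], 20)
})

test_that("time-course CSV round-trips losslessly at 6 significant digits", {
  net <- build_network(4)
  tc <- simulate_timecourse(net, fast_params(), preset_assay("dense_schedule"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse(tc, path)
  back <- read_timecourse(path)
  expect_identical(names(back), names(tc))
  for (s in names(tc)) {
    expect_equal(signif(back[[s]], 6), signif(tc[[s]], 6))
  }
})

test_that("malformed CSV headers are rejected with the offending column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("minutes,phytoene", "0,10"), path)
  expect_error(read_timecourse(path), "minutes",
               class = "carokin_format_error")
  writeLines(c("time_min,phytoene,unobtainium", "0,10,1"), path)
  expect_error(read_timecourse(path), "unobtainium",
               class = "carokin_format_error")
})

test_that("detection limit censors only at reporting", {
  net <- build_network(4)
  p <- fast_params()
  tc <- simulate_timecourse(net, p, preset_assay("dense_schedule"))
  censored <- apply_detection_limit(tc, limit = 0.05)
  expect_true(any(tc$lycopene > 0 & tc$lycopene < 0.05))
  expect_true(all(censored$lycopene[censored$lycopene > 0] >= 0.05))
  # the uncensored object is untouched
  expect_true(any(tc$lycopene > 0 & tc$lycopene < 0.05))
})

test_that("integrator agrees with an independent stiff solver (scipy Radau)", {
  net <- build_network(4)
  p <- fast_params()
  assay <- preset_assay("dense_schedule")
  tc <- simulate_timecourse(net, p, assay)

  script <- withr::local_tempfile(fileext = ".py")
  out_csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(sprintf("
import numpy as np
from scipy.integrate import solve_ivp
kf = np.array([%s]); kr = np.array([%s]); kc = np.array([%s, 0.0])
def rhs(t, y):
    n = 4
    S, E, ES = y[:5], y[5], y[6:11]
    dy = np.zeros(11)
    bind = kf * E * S; unbind = kr * ES; cat = kc * ES
    dy[:5] = -bind + unbind
    dy[1:5] += cat[:4]
    dy[6:11] = bind - unbind - cat
    dy[5] = np.sum(-bind + unbind + cat)
    return dy
y0 = np.zeros(11); y0[0] = 10.0; y0[5] = %g
t = np.array([0, 2.5, 5, 7.5, 10, 20, 30, 40, 60, 120]) * 60.0
sol = solve_ivp(rhs, (0, t[-1]), y0, method='Radau', t_eval=t,
                rtol=1e-10, atol=1e-12)
tot = sol.y[:5, :] + sol.y[6:11, :]
np.savetxt(r'%s', tot.T, delimiter=',')
", paste(p$k_f, collapse = ","), paste(p$k_r, collapse = ","),
    paste(p$k_cat, collapse = ","), assay$enzyme_total, out_csv), script)
  status <- system2("python", script)
  expect_identical(status, 0L)
  ref <- as.matrix(read.csv(out_csv, header = FALSE))
  mine <- as.matrix(tc[, net$chain])
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})
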