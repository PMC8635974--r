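test_that("protocol invariants are enforced", {
  ev <- data.frame(agonist_id = c("A", "B"), concentration = 1e-6,
                   t_start = c(10, 30), t_end = c(20, 40))
  expect_s3_class(application_protocol(ev, 60), "application_protocol")
  ev2 <- ev; ev2$t_end[1] <- 35  # overlaps event 2
  expect_error(application_protocol(ev2, 60), "overlapping")
  ev3 <- ev; ev3$concentration[1] <- 0
  expect_error(application_protocol(ev3, 60), "concentrations")
  expect_error(application_protocol(ev, 30), "total_duration")
})

test_that("noiseless clean recording yields the configured ratio step", {
  truth <- clean_truth(c(ACh = 1.0))
  prot <- single_pulse_protocol()
  rec <- generate_fret_recording(prot, truth)
  tr <- compute_ratio(correct_channels(rec, correction_coefficients()))
  amp <- extract_amplitude(tr, prot$events[1, ])
  ## plateau of the latent signal inside the post window (on-kinetics)
  f_post <- 1 - mean(exp(-truth$on_rate * (seq(25.0, 29.5, by = 0.5))))
  expect_equal(amp$raw_amplitude,
               expected_ratio(f_post, truth) - expected_ratio(0, truth),
               tolerance = 1e-9)
})

test_that("zero efficacy gives flat channels and amplitude 0", {
  truth <- clean_truth(c(ACh = 0))
  prot <- single_pulse_protocol()
  rec <- generate_fret_recording(prot, truth)
  expect_equal(diff(range(rec$donor_em)), 0)
  expect_equal(diff(range(rec$acceptor_em)), 0)
  tr <- compute_ratio(correct_channels(rec, correction_coefficients()))
  expect_equal(extract_amplitude(tr, prot$events[1, ])$raw_amplitude, 0)
})

test_that("generator is deterministic under a fixed seed", {
  truth <- fret_ground_truth(std_efficacies(), seed = 11)
  prot <- standard_protocol(names(std_efficacies()))
  r1 <- generate_fret_recording(prot, truth)
  r2 <- generate_fret_recording(prot, truth)
  expect_identical(r1$donor_em, r2$donor_em)
  expect_identical(r1$acceptor_em, r2$acceptor_em)
  p1 <- generate_bret_plate(n_wells = 3, noise_sd = 0.01, seed = 5)
  p2 <- generate_bret_plate(n_wells = 3, noise_sd = 0.01, seed = 5)
  expect_identical(p1, p2)
})

test_that("unknown agonist in protocol is a protocol error", {
  truth <- clean_truth(c(ACh = 1))
  prot <- single_pulse_protocol(agonist = "Xyz")
  expect_error(generate_fret_recording(prot, truth), "Xyz")
})

test_that("bret generator refuses non-positive cycle counts", {
  expect_error(generate_bret_plate(n_cycles = 0), "non-positive")
})

test_that("operational response closed forms hold", {
  ## at zero concentration the response is exactly zero
  expect_equal(operational_response(0, tau = 5, Ki = 1e-6, n = 1.3), 0)
  ## n = 1, tau = 1: saturating response tends to Emax * tau/(tau+1) = 1/2
  expect_equal(operational_response(1e6, tau = 1, Ki = 1e-6, n = 1,
                                    Emax = 1), 0.5, tolerance = 1e-6)
  ## n = 1, tau = 2, Emax = 1, [A] = Ki: Y = tau/(tau+2)
  expect_equal(operational_response(1e-6, tau = 2, Ki = 1e-6, n = 1), 0.5)
  ## generated table evaluates the model on the grid exactly
  tr <- std_op_truth()
  cr <- generate_concentration_response(tr)
  expect_equal(cr$response,
               unname(operational_response(cr$conc_M, tr$tau[cr$agonist],
                                           tr$Ki[cr$agonist], tr$n,
                                           tr$Emax)))
})

test_that("competition binding closed forms and round trip", {
  tab <- generate_competition_binding(IC50 = 3e-8, hill = 1, noise_sd = 0,
                                      grid = c(0, 3e-8, 1e-3))
  expect_equal(tab$percent_specific[tab$conc_M == 0], 100)
  expect_equal(tab$percent_specific[tab$conc_M == 3e-8], 50)
  tab2 <- generate_competition_binding(IC50 = 4e-9, hill = 1.2,
                                       noise_sd = 0)
  fit <- fit_competition(tab2$conc_M, tab2$percent_specific)
  expect_lt(abs(fit$ic50 / 4e-9 - 1), 1e-6)
  expect_lt(abs(fit$hill_slope / 1.2 - 1), 1e-6)
})

test_that("cross-talk shifts the uncorrected ratio; true coefficients fix it", {
  eff <- c(ACh = 1.0)
  truth <- fret_ground_truth(eff, noise_sd = 0, donor_bleach_rate = 0,
                             acceptor_bleach_rate = 0, seed = 2)
  prot <- single_pulse_protocol()
  rec <- generate_fret_recording(prot, truth)
  ev <- prot$events[1, ]
  amp_raw <- extract_amplitude(
    compute_ratio(correct_channels(rec, correction_coefficients())), ev)
  amp_cor <- extract_amplitude(
    compute_ratio(correct_channels(rec, true_coefficients(truth))), ev)
  f_post <- 1 - mean(exp(-truth$on_rate * seq(25.0, 29.5, by = 0.5)))
  expected <- expected_ratio(f_post, truth) - expected_ratio(0, truth)
  expect_gt(abs(amp_raw$raw_amplitude - expected), 1e-3)
  expect_equal(amp_cor$raw_amplitude, expected, tolerance = 1e-9)
})
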