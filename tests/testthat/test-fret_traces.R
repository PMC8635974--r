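test_that("zero coefficients leave channels untouched", {
  truth <- clean_truth(c(ACh = 0.5))
  rec <- generate_fret_recording(single_pulse_protocol(), truth)
  out <- correct_channels(rec, correction_coefficients())
  expect_equal(out$donor_em, rec$donor_em)
  expect_equal(out$acceptor_em, rec$acceptor_em)
})

test_that("true coefficients recover the latent channels exactly", {
  truth <- fret_ground_truth(c(ACh = 0.8), noise_sd = 0, seed = 4)
  prot <- single_pulse_protocol()
  rec <- generate_fret_recording(prot, truth)
  cor <- correct_channels(rec, true_coefficients(truth))
  f <- ligandbias:::latent_fret_signal(rec$time, prot, truth)
  D <- truth$donor_scale * exp(-truth$donor_bleach_rate * rec$time) *
    (1 - truth$kappa * f)
  A <- truth$acceptor_scale * exp(-truth$acceptor_bleach_rate * rec$time) *
    (truth$fret_base + truth$kappa * f)
  expect_equal(cor$donor_em, D, tolerance = 1e-12)
  expect_equal(cor$acceptor_em, A, tolerance = 1e-12)
})

test_that("background-only recording corrects to ~0 and huge background errors", {
  prot <- single_pulse_protocol()
  truth <- clean_truth(c(ACh = 0))
  rec <- generate_fret_recording(prot, truth)
  rec$donor_em <- rec$donor_em * 0 + 80   # flat background-only channels
  rec$acceptor_em <- rec$acceptor_em * 0 + 40
  out <- correct_channels(rec, correction_coefficients(80, 40))
  expect_true(all(abs(out$donor_em) < 1e-12))
  expect_true(all(abs(out$acceptor_em) < 1e-12))
  expect_error(correct_channels(rec, correction_coefficients(200, 0)),
               "correction-coefficient")
})

test_that("ratio arithmetic and masking behave", {
  truth <- clean_truth(c(ACh = 0))
  rec <- generate_fret_recording(single_pulse_protocol(), truth)
  rec$corrected <- TRUE
  rec$acceptor_em <- rec$donor_em
  expect_equal(unique(compute_ratio(rec)$ratio), 1)
  rec$acceptor_em <- 2 * rec$donor_em
  expect_equal(unique(compute_ratio(rec)$ratio), 2)
  ## a few non-positive donor samples are masked with a warning
  rec$donor_em[1:3] <- 0
  expect_warning(tr <- compute_ratio(rec), "masked")
  expect_true(all(is.na(tr$ratio[1:3])))
  ## >10% masked is an error
  rec$donor_em[seq_len(ceiling(0.2 * length(rec$donor_em)))] <- 0
  expect_error(compute_ratio(rec), "non-positive donor")
  ## uncorrected recordings are refused
  rec$corrected <- FALSE
  expect_error(compute_ratio(rec), "corrected")
})

test_that("baseline correction is a no-op on drift-free traces", {
  truth <- clean_truth(std_efficacies())
  prot <- standard_protocol(names(std_efficacies()))
  tr <- compute_ratio(correct_channels(
    generate_fret_recording(prot, truth), correction_coefficients()))
  out <- baseline_correct(tr)
  expect_equal(out$ratio, tr$ratio, tolerance = 1e-9)
})

test_that("pure exponential bleach is divided out to a constant", {
  ## no responses at all: the whole trace is buffer-only drift
  eff <- stats::setNames(rep(0, 7), names(std_efficacies()))
  truth <- fret_ground_truth(eff, noise_sd = 0, donor_bleach_rate = 5e-4,
                             acceptor_bleach_rate = 1e-4,
                             bleedthrough_frac = 0,
                             false_excitation_frac = 0,
                             background = c(donor = 0, acceptor = 0))
  prot <- standard_protocol(names(eff))
  tr <- compute_ratio(correct_channels(
    generate_fret_recording(prot, truth), correction_coefficients()))
  expect_gt(diff(range(tr$ratio)), 0.1)  # drift really present
  out <- baseline_correct(tr)
  expect_lt(diff(range(out$ratio)), 1e-6)
})

test_that("amplitudes survive bleach + responses (end-to-end vs truth)", {
  truth <- fret_ground_truth(std_efficacies(), noise_sd = 0, seed = 8)
  prot <- standard_protocol(names(std_efficacies()))
  rec <- generate_fret_recording(prot, truth)
  tr <- baseline_correct(compute_ratio(
    correct_channels(rec, true_coefficients(truth))))
  nr <- normalize_to_reference(extract_amplitudes(tr))
  eff <- std_efficacies()[nr$agonist_id]
  expect_true(all(abs(nr$normalized_amplitude - eff) < 0.05))
})

test_that("amplitude extraction follows the 5-s window rule", {
  prot <- single_pulse_protocol()
  truth <- clean_truth(c(ACh = 0))
  tr <- compute_ratio(correct_channels(
    generate_fret_recording(prot, truth), correction_coefficients()))
  ## constant trace: amplitude 0
  expect_equal(extract_amplitude(tr, prot$events[1, ])$raw_amplitude, 0)
  ## noiseless step 1.0 -> 1.2 spanning the event: amplitude 0.2
  tr$ratio <- ifelse(tr$time >= prot$events$t_start &
                       tr$time < prot$events$t_end, 1.2, 1.0)
  rec1 <- extract_amplitude(tr, prot$events[1, ])
  expect_equal(rec1$raw_amplitude, 0.2)
  ## windows are half-open [t-5, t): at 2 Hz exactly 10 samples each
  n_pre <- sum(tr$time >= rec1$window_pre_start &
                 tr$time < rec1$window_pre_end)
  expect_identical(n_pre, 10L)
  ## event outside the recording errors and names the event
  bad <- data.frame(agonist_id = "ACh", concentration = 3e-5,
                    t_start = 5000, t_end = 5030)
  expect_error(extract_amplitude(tr, bad), "ACh")
})

test_that("noisy amplitude stays within 3 * noise_sd/sqrt(10) of truth", {
  ## window-mean oracle: the amplitude is a difference of two 10-sample
  ## means, so its SD is sigma_ratio * sqrt(2/10)
  prot <- single_pulse_protocol()
  truth <- fret_ground_truth(c(ACh = 1), noise_sd = 5,
                             donor_bleach_rate = 0,
                             acceptor_bleach_rate = 0,
                             bleedthrough_frac = 0,
                             false_excitation_frac = 0,
                             background = c(donor = 0, acceptor = 0),
                             seed = 21)
  rec <- generate_fret_recording(prot, truth)
  tr <- compute_ratio(correct_channels(rec, correction_coefficients()))
  amp <- extract_amplitude(tr, prot$events[1, ])
  f_post <- 1 - mean(exp(-truth$on_rate * seq(25.0, 29.5, by = 0.5)))
  expected <- expected_ratio(f_post, truth) - expected_ratio(0, truth)
  ## ratio-noise SD from the two channel SDs at baseline intensities
  sd_ratio <- 5 / 1000 * sqrt(1 + expected_ratio(0, truth)^2)
  expect_lt(abs(amp$raw_amplitude - expected), 3 * sd_ratio * sqrt(2 / 10))
})

test_that("amplitude extraction is translation-invariant", {
  truth <- fret_ground_truth(std_efficacies(), seed = 31)
  prot <- standard_protocol(names(std_efficacies()))
  tr <- compute_ratio(correct_channels(
    generate_fret_recording(prot, truth), true_coefficients(truth)))
  shifted <- tr
  shifted$ratio <- tr$ratio + 3.7
  a1 <- extract_amplitudes(tr)
  a2 <- extract_amplitudes(shifted)
  expect_equal(a1$raw_amplitude, a2$raw_amplitude, tolerance = 1e-12)
})

test_that("normalization arithmetic, policies and exclusions", {
  rec <- data.frame(
    cell_id = c("c1", "c1", "c2", "c2", "c2"),
    agonist_id = c("ACh", "X", "ACh", "X", "ACh"),
    concentration = 3e-5,
    raw_amplitude = c(0.10, 0.05, 0.10, 0.06, 0.20))
  out <- normalize_to_reference(rec)
  expect_equal(out$normalized_amplitude[out$cell_id == "c1"], c(1, 0.5))
  ## "first" policy: c2 reference is 0.10, not the larger re-application
  expect_equal(out$normalized_amplitude[out$cell_id == "c2" &
                                          out$agonist_id == "X"], 0.6)
  out_max <- normalize_to_reference(rec, reference_policy = "max")
  expect_equal(out_max$normalized_amplitude[out_max$cell_id == "c2" &
                                              out_max$agonist_id == "X"],
               0.3)
  ## non-positive reference excludes the cell with a reason
  rec$raw_amplitude[1] <- -0.1
  expect_message(out2 <- normalize_to_reference(rec), "excluded")
  expect_false("c1" %in% out2$cell_id)
  expect_match(attr(out2, "excluded")[["c1"]], "non-positive")
  ## normalizing an already-normalized table is the identity
  renorm <- normalize_to_reference(
    transform(out, raw_amplitude = normalized_amplitude))
  expect_equal(renorm$normalized_amplitude, out$normalized_amplitude)
})

test_that("efficacy aggregation computes mean, sd, n per agonist", {
  rec <- data.frame(cell_id = c("c1", "c2", "c1", "c2"),
                    agonist_id = c("A", "A", "B", "B"),
                    normalized_amplitude = c(0.4, 0.6, 0.5, 0.5))
  tab <- aggregate_efficacies(rec, "pw")
  expect_equal(tab$mean[tab$agonist == "A"], 0.5)
  expect_equal(tab$sd[tab$agonist == "A"], sqrt(0.02), tolerance = 1e-12)
  expect_equal(tab$sd[tab$agonist == "B"], 0)
  expect_true(all(tab$n == 2L))
})

test_that("coefficient estimation from calibration recordings is sane", {
  truth <- fret_ground_truth(c(ACh = 0), noise_sd = 0, seed = 6)
  prot <- single_pulse_protocol()
  donor_only <- generate_fret_recording(prot, truth)
  ## donor-only cell: acceptor channel is background + bleed-through only
  donor_only$acceptor_em <- truth$background[["acceptor"]] +
    truth$bleedthrough_frac * (donor_only$donor_em -
                                 truth$background[["donor"]])
  acceptor_only <- generate_fret_recording(prot, truth)
  acceptor_only$donor_em <- acceptor_only$donor_em * 0 +
    truth$background[["donor"]]
  acceptor_only$acceptor_em <- truth$background[["acceptor"]] +
    truth$false_excitation_frac * (acceptor_only$acceptor_direct -
                                     truth$background[["acceptor"]])
  est <- estimate_correction_coefficients(
    donor_only, acceptor_only,
    background_donor = truth$background[["donor"]],
    background_acceptor = truth$background[["acceptor"]])
  expect_equal(est$bleedthrough_frac, truth$bleedthrough_frac,
               tolerance = 1e-9)
  expect_equal(est$false_excitation_frac, truth$false_excitation_frac,
               tolerance = 1e-9)
})
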