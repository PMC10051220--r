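# ptychographic forward model, loss symmetries, and ambiguity handling

make_toy_object <- function(n, seed = 1) {
  amp <- 0.5 + 0.4 * make_phantom("blobs", n, seed = seed)
  phs <- (make_phantom("blobs", n, seed = seed + 50) - 0.5)
  complex_field(amp * cos(phs), amp * sin(phs))
}

test_that("a flat object gives position-independent diffraction", {
  probe <- disk_probe(16, radius = 5, power = 10)
  flat <- complex_field(matrix(1, 48, 48), matrix(0, 48, 48))
  spec <- propagation_spec(1, 1e-6, energy_ev = 1260, regime = "far-field")
  I1 <- ad_val(ptycho_forward_intensity(flat, probe, c(0, 0), spec))
  I2 <- ad_val(ptycho_forward_intensity(flat, probe, c(20, 11), spec))
  expect_lt(max(abs(I1 - I2)), 1e-10)
  # and equals the propagated probe intensity itself
  Ip <- ad_val(ad_cplx_mod2(farfield_propagate(probe)))
  expect_lt(max(abs(I1 - Ip)), 1e-10)
})

test_that("two half-power modes reproduce the single-mode intensity", {
  obj <- make_toy_object(40, seed = 2)
  probe <- disk_probe(16, radius = 5, power = 10)
  spec <- propagation_spec(1, 1e-6, energy_ev = 1260, regime = "far-field")
  half <- complex_field(ad_val(probe$re) / sqrt(2), ad_val(probe$im) / sqrt(2))
  I1 <- ad_val(ptycho_forward_intensity(obj, probe, c(5, 7), spec))
  I2 <- ad_val(ptycho_forward_intensity(obj, list(half, half), c(5, 7), spec))
  expect_lt(max(abs(I1 - I2)), 1e-10)
})

test_that("forward intensity matches a from-scratch evaluator on a 16x16 toy", {
  obj <- make_toy_object(16, seed = 3)
  probe <- disk_probe(8, radius = 3, power = 5)
  spec <- propagation_spec(1, 1e-6, energy_ev = 1260, regime = "far-field")
  pos <- c(4, 6)
  I <- ad_val(ptycho_forward_intensity(obj, probe, pos, spec))
  oc <- as.complex.complex_field(obj)
  pc <- as.complex.complex_field(probe)
  view <- oc[5:12, 7:14]
  ex <- pc * view
  n <- 8
  shift_ix <- function(m) m[c(5:8, 1:4), c(5:8, 1:4)]
  d <- shift_ix(stats::fft(shift_ix(ex))) / n
  expect_lt(max(abs(I - Mod(d)^2)), 1e-8)
})

test_that("loss vanishes at simulation truth and activates the magnitude penalty", {
  obj <- make_toy_object(32, seed = 4)
  probe <- disk_probe(16, radius = 5, power = 50)
  spec <- propagation_spec(1, 1e-6, energy_ev = 1260, regime = "far-field")
  sim <- simulate_ptycho(obj, probe, list(rows = 2, cols = 2, step = 10),
                         jitter_px = 0, spec = spec, seed = 5)
  scale <- sum(sapply(sim$dataset$intensities, function(m) sum(m^2)))
  at_truth <- ptycho_loss(obj, probe, sim$dataset,
                          weights = loss_weights(lambda1 = 1))
  expect_lt(at_truth / scale, 1e-8)
  # scaling the object above unit modulus strictly adds the penalty
  big <- complex_field(ad_val(obj$re) * 1.6, ad_val(obj$im) * 1.6)
  with_pen <- ptycho_loss(big, probe, sim$dataset,
                          weights = loss_weights(lambda1 = 1))
  no_pen <- ptycho_loss(big, probe, sim$dataset, weights = loss_weights())
  expect_gt(with_pen, no_pen)
})

test_that("the loss is invariant to a global phase moved between object and probes", {
  obj <- make_toy_object(32, seed = 6)
  probe <- disk_probe(16, radius = 5, power = 50)
  spec <- propagation_spec(1, 1e-6, energy_ev = 1260, regime = "far-field")
  sim <- simulate_ptycho(obj, probe, list(rows = 2, cols = 2, step = 10),
                         jitter_px = 0, spec = spec, seed = 7)
  phi <- 0.73
  oc <- as.complex.complex_field(obj) * exp(1i * phi)
  pc <- as.complex.complex_field(probe) * exp(-1i * phi)
  v1 <- ptycho_loss(obj, probe, sim$dataset, weights = loss_weights())
  v2 <- ptycho_loss(field_from_complex(oc), field_from_complex(pc),
                    sim$dataset, weights = loss_weights())
  expect_lt(abs(v1 - v2) / max(v1, 1e-10), 1e-10)
})

test_that("noiseless truth is a local minimum under random perturbations", {
  obj <- make_toy_object(24, seed = 8)
  probe <- disk_probe(12, radius = 4, power = 20)
  spec <- propagation_spec(1, 1e-6, energy_ev = 1260, regime = "far-field")
  sim <- simulate_ptycho(obj, probe, list(rows = 2, cols = 2, step = 8),
                         jitter_px = 0, spec = spec, seed = 9)
  base <- ptycho_loss(obj, probe, sim$dataset, weights = loss_weights())
  set.seed(90)
  worse <- replicate(200, {
    pert <- complex_field(ad_val(obj$re) + matrix(rnorm(576, sd = 0.01), 24),
                          ad_val(obj$im) + matrix(rnorm(576, sd = 0.01), 24))
    ptycho_loss(pert, probe, sim$dataset, weights = loss_weights()) >= base
  })
  expect_true(all(worse))
})

test_that("dataset bookkeeping: grid size, jitter statistics, validation", {
  obj <- make_toy_object(64, seed = 10)
  probe <- disk_probe(24, radius = 8, power = 10)
  spec <- propagation_spec(1, 1e-6, energy_ev = 1260, regime = "far-field")
  sim <- simulate_ptycho(obj, probe, list(rows = 5, cols = 5, step = 10),
                         jitter_px = 1, spec = spec, seed = 11)
  expect_length(sim$dataset$intensities, 25)
  rmsj <- sqrt(mean((sim$dataset$positions - sim$truth$positions)^2))
  expect_gt(rmsj, 0.4); expect_lt(rmsj, 0.7)   # uniform +/-1 px draws
  expect_error(ptycho_dataset(sim$dataset$intensities, matrix(0, 3, 2), spec),
               "position count")
  expect_error(reconstruct_ptycho(
    ptycho_dataset(sim$dataset$intensities[1:3],
                   sim$dataset$positions[1:3, ], spec)),
    "diversity")
})
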