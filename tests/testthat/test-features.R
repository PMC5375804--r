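make_video_with_protocol <- function(frames, protocol) {
  thermal_video(frames, fps = protocol$fps,
                metadata = list(protocol = unclass(protocol)))
}

test_that("mean trace averages exactly the masked pixels", {
  p <- toy_protocol()
  h <- 4; w <- 4; f <- protocol_frame_indices(p)$total
  set.seed(2)
  frames <- array(rnorm(h * w * f, 30, 5), dim = c(h, w, f))
  v <- make_video_with_protocol(frames, p)

  one <- matrix(FALSE, h, w); one[2, 3] <- TRUE
  tr <- mean_trace(v, one)
  expect_equal(tr$values, as.numeric(v$frames[2, 3, ]))

  # uniform frames: any mask gives the same trace
  uni <- array(rep(seq_len(f), each = h * w), dim = c(h, w, f))
  vu <- make_video_with_protocol(uni, p)
  m1 <- matrix(c(TRUE, FALSE), h, w)
  expect_equal(mean_trace(vu, m1)$values, as.numeric(seq_len(f)))

  # checkerboard of a, b with full mask -> (a+b)/2
  cb <- array(0, dim = c(h, w, f))
  board <- outer(seq_len(h), seq_len(w), function(i, j) (i + j) %% 2)
  for (k in seq_len(f)) cb[, , k] <- ifelse(board == 1, 10, 20)
  vc <- make_video_with_protocol(cb, p)
  expect_equal(mean_trace(vc, matrix(TRUE, h, w))$values, rep(15, f))

  expect_error(mean_trace(v, matrix(FALSE, h, w)), "empty mask")
})

test_that("buffer trimming keeps [lamp_on, cutoff): 450 frames by default", {
  p <- default_protocol()
  tr <- simulate_trace(material_params(gain = 40), p)
  trimmed <- trim_buffers(tr)
  expect_length(trimmed$values, 450)
  idx <- protocol_frame_indices(p)
  expect_equal(trimmed$values, tr$values[(idx$lamp_on + 1):idx$cutoff])

  zb <- acquisition_protocol(0, 5, 10, 0, 30)
  tr0 <- simulate_trace(material_params(gain = 40), zb)
  expect_equal(trim_buffers(tr0)$values, tr0$values)

  p10 <- acquisition_protocol(1, 5, 10, 1, 10)
  expect_length(trim_buffers(simulate_trace(material_params(), p10))$values, 150)
})

test_that("waveform features match the lumped-model closed forms", {
  p <- default_protocol()
  flat <- temperature_trace(rep(25, 510), p)
  expect_equal(unlist(waveform_features(flat)), c(peak_minus_rest = 0,
                                                  final_minus_rest = 0))

  tr <- simulate_trace(material_params(ambient_temp = 25, gain = 50,
                                       tau_heat = 2, tau_cool = 4), p)
  wf <- waveform_features(tr)
  peak_expected <- 50 * (1 - exp(-2.5))
  expect_equal(wf$peak_minus_rest, peak_expected, tolerance = 1e-9)
  expect_equal(wf$final_minus_rest, peak_expected * exp(-10 / 4),
               tolerance = 1e-9)
  expect_gte(wf$peak_minus_rest, wf$final_minus_rest)

  # closed-form agreement within 1e-9 degrees across parameter draws
  set.seed(4)
  for (i in 1:10) {
    g <- runif(1, 5, 60); th <- runif(1, 0.5, 4); tc <- runif(1, 1, 9)
    wf_i <- waveform_features(simulate_trace(
      material_params(ambient_temp = 25, gain = g, tau_heat = th,
                      tau_cool = tc), p))
    pk <- g * (1 - exp(-5 / th))
    expect_lt(abs(wf_i$peak_minus_rest - pk), 1e-9)
    expect_lt(abs(wf_i$final_minus_rest - pk * exp(-10 / tc)), 1e-9)
  }

  # trace returning exactly to rest by the cutoff
  fast <- waveform_features(simulate_trace(
    material_params(ambient_temp = 25, gain = 50, tau_heat = 2,
                    tau_cool = 0.2), p))
  expect_equal(fast$final_minus_rest, 0, tolerance = 1e-9)
})

test_that("split trace returns the heating and cooling portions exactly", {
  tr <- trim_buffers(simulate_trace(material_params(gain = 30),
                                    default_protocol()))
  parts <- split_trace(tr)
  expect_length(parts$rising$values, 150)
  expect_length(parts$falling$values, 300)
  expect_equal(c(parts$rising$values, parts$falling$values), tr$values)

  toy <- trim_buffers(simulate_trace(material_params(gain = 30),
                                     toy_protocol()))
  toyparts <- split_trace(toy)
  expect_length(toyparts$rising$values, 5)
  expect_length(toyparts$falling$values, 10)
})

test_that("retained spectral component counts follow the below-Nyquist rule", {
  tr <- trim_buffers(simulate_trace(material_params(gain = 30),
                                    default_protocol()))
  whole <- spectral_features(tr, "whole")
  expect_length(whole$amplitudes, 225)
  expect_length(whole$phases, 224)
  expect_equal(whole$frequencies, (0:224) * 30 / 450)

  parts <- split_trace(tr)
  rising <- spectral_features(parts$rising, "rising")
  falling <- spectral_features(parts$falling, "falling")
  expect_equal(c(length(rising$amplitudes), length(rising$phases)), c(75, 74))
  expect_equal(c(length(falling$amplitudes), length(falling$phases)),
               c(150, 149))

  # N/2 amplitudes and N/2 - 1 phases for all even N in use
  for (n in c(150, 300, 450)) {
    p <- acquisition_protocol(0, n / 3 / 30, 2 * n / 3 / 30, 0, 30)
    tt <- temperature_trace(rnorm(n, 25), p, trimmed = TRUE)
    sp <- spectral_features(tt, "whole")
    expect_length(sp$amplitudes, n / 2)
    expect_length(sp$phases, n / 2 - 1)
  }
})

test_that("spectra of canonical signals match DFT theory", {
  p <- default_protocol()
  # constant trace: all energy at 0 Hz
  const <- temperature_trace(rep(3.5, 450), p, trimmed = TRUE)
  sp <- spectral_features(const, "whole")
  expect_equal(sp$amplitudes[1], 450 * 3.5)
  expect_lt(max(sp$amplitudes[-1]), 1e-9 * 450 * 3.5)

  # pure cosine at retained index k: amplitude N/2 at k, ~0 elsewhere
  n <- 450
  for (k in c(3, 17)) {
    x <- cos(2 * pi * k * (0:(n - 1)) / n)
    spk <- spectral_features(temperature_trace(x, p, trimmed = TRUE), "whole")
    expect_equal(spk$amplitudes[k + 1], n / 2, tolerance = 1e-9)
    expect_lt(max(spk$amplitudes[-(k + 1)]), 1e-6 * n)
  }
})

test_that("Parseval and conjugate symmetry hold for random traces", {
  set.seed(13)
  p <- default_protocol()
  for (i in 1:5) {
    x <- rnorm(450, 25, 10)
    spectrum <- fft(x)
    expect_equal(sum(x^2), sum(Mod(spectrum)^2) / 450)
    expect_equal(Mod(spectrum[2:450]), rev(Mod(spectrum[2:450])))
    # the retained half therefore carries all the information
    sp <- spectral_features(temperature_trace(x, p, trimmed = TRUE), "whole")
    expect_equal(sp$amplitudes, Mod(spectrum[1:225]))
  }
})

test_that("amplitude subsets are the k lowest-frequency components", {
  tr <- trim_buffers(simulate_trace(material_params(gain = 30),
                                    default_protocol()))
  sp <- spectral_features(tr, "whole")
  expect_equal(amplitude_subset(sp, 1), sp$amplitudes[1])
  expect_equal(amplitude_subset(sp, 10), sp$amplitudes[1:10])
  expect_equal(amplitude_subset(sp, 225), sp$amplitudes)
  expect_error(amplitude_subset(sp, 0), "1\\.\\.225")
  expect_error(amplitude_subset(sp, 226), "1\\.\\.225")
})

test_that("odd-length traces are rejected for spectral analysis", {
  p <- acquisition_protocol(0, 3, 2, 0, 1)  # 5 trimmed frames
  tt <- temperature_trace(rnorm(5, 25), p, trimmed = TRUE)
  expect_error(spectral_features(tt, "whole"), "odd")
})

test_that("pixelwise spectra agree with the single-pixel trace spectrum", {
  spec <- plain_spec(geometry = "blob", size_range = c(10, 10),
                     jitter = 0.2, edge = 2)
  cfg <- noiseless_config(list(spec))
  out <- render_video(spec, cfg, 5)
  maps <- pixelwise_spectra(out$video, out$mask, component_index = 2)

  px <- which(out$mask)[3]
  rc <- arrayInd(px, dim(out$mask))
  idx <- protocol_frame_indices(cfg$protocol)
  pixel_vals <- as.numeric(out$video$frames[rc[1], rc[2],
                                            (idx$lamp_on + 1):idx$cutoff])
  sp <- spectral_features(temperature_trace(pixel_vals, cfg$protocol,
                                            trimmed = TRUE), "whole")
  expect_equal(maps$ampligram[rc], sp$amplitudes[3])
  expect_equal(maps$phasegram[rc], sp$phases[2])
  expect_true(all(is.na(maps$ampligram[!out$mask])))

  # constant background pixel has ~zero amplitude away from 0 Hz
  bg <- pixelwise_spectra(out$video, !out$mask, component_index = 1)
  expect_lt(max(abs(bg$ampligram), na.rm = TRUE), 1e-3)

  expect_error(pixelwise_spectra(out$video, out$mask, component_index = 400),
               "component_index")
})

test_that("edge-cooled rims separate from the interior in the phasegram", {
  spec <- plain_spec(geometry = "blob", size_range = c(16, 16),
                     jitter = 0, edge = 3)
  cfg <- noiseless_config(list(spec), h = 36, w = 36)
  out <- render_video(spec, cfg, 9)
  maps <- pixelwise_spectra(out$video, out$mask, component_index = 1)
  boundary <- pulsetherm:::mask_boundary(out$mask)
  interior <- out$mask & !boundary
  expect_gt(abs(mean(maps$phasegram[boundary]) - mean(maps$phasegram[interior])),
            1e-3)
  # rim phases are homogeneous and distinct: distributions do not overlap
  expect_true(max(maps$phasegram[boundary]) < min(maps$phasegram[interior]) ||
                min(maps$phasegram[boundary]) > max(maps$phasegram[interior]))
})

test_that("extract_features emits the documented column layout", {
  spec <- plain_spec()
  cfg <- noiseless_config(list(spec), fps = 30)
  out <- render_video(spec, cfg, 3)
  feats <- extract_features(out$video, out$mask)
  expect_equal(nrow(feats), 1)
  expect_true(all(c("wf_peak_minus_rest", "wf_final_minus_rest",
                    "amp_whole_1", "amp_whole_225", "phase_whole_2",
                    "phase_whole_225", "amp_rising_75", "amp_falling_150",
                    "phase_rising_75", "phase_falling_150") %in% names(feats)))
  expect_equal(ncol(feats), 2 + (225 + 224) + (75 + 74) + (150 + 149))

  expect_equal(feature_set_columns("waveform"),
               c("wf_peak_minus_rest", "wf_final_minus_rest"))
  expect_equal(feature_set_columns("whole_amp_1_10"),
               sprintf("amp_whole_%d", 1:10))
  expect_error(feature_set_columns("bogus"), "unknown feature set")
})
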