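test_that("channel_matrix validates and prints", {
  X <- matrix(rnorm(20), 2, 10)
  cm <- channel_matrix(X, c("Cz", "FDS"), c("EEG", "EMG"), 1000)
  expect_s3_class(cm, "channel_matrix")
  expect_identical(dim(cm), c(2L, 10L))
  expect_output(print(cm), "channel_matrix")
  expect_error(channel_matrix(X, "Cz", c("EEG", "EMG"), 1000))
  expect_error(channel_matrix(X, c("Cz", "FDS"), c("EEG", "BAD"), 1000))
})

test_that("load_signals round-trips CSV and TSV with a manifest", {
  set.seed(11)
  X <- matrix(rnorm(3 * 50), 3, 50)
  ids <- c("Cz", "C3", "FDS")
  mods <- c("EEG", "EEG", "EMG")
  df <- as.data.frame(t(X)); names(df) <- ids

  csv <- tempfile(fileext = ".csv")
  write.csv(df, csv, row.names = FALSE)
  man <- setNames(mods, ids)
  cm <- load_signals(csv, man, fs = 500)
  expect_equal(cm$data, X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(cm$channel_ids, ids)
  expect_identical(cm$modalities, mods)
  expect_identical(cm$fs, 500)

  tsv <- tempfile(fileext = ".tsv")
  write.table(df, tsv, sep = "\t", row.names = FALSE)
  cm2 <- load_signals(tsv, man, fs = 500)
  expect_equal(cm2$data, cm$data, tolerance = 1e-12)

  # manifest order wins over file column order
  cm3 <- load_signals(csv, man[c(3, 1, 2)], fs = 500)
  expect_identical(cm3$channel_ids, ids[c(3, 1, 2)])
  expect_equal(cm3$data[1, ], X[3, ], tolerance = 1e-12)

  yml <- tempfile(fileext = ".yaml")
  writeLines(paste0(ids, ": ", mods), yml)
  cm4 <- load_signals(csv, yml, fs = 500)
  expect_identical(cm4$modalities, mods)

  expect_error(load_signals(csv, c(man, Pz = "EEG")), "Pz")
  expect_error(load_signals(tempfile(), man), "not found")
})

test_that("bandpass attenuates out-of-band tones and keeps in-band ones", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)[-1]
  in_band <- sin(2 * pi * 20 * t)   # inside EEG band 0.05-100
  out_band <- sin(2 * pi * 300 * t) # far above
  cm <- channel_matrix(rbind(in_band + out_band), "Cz", "EEG", fs)
  filt <- preprocess(cm, notch = NULL)
  mid <- 500:3500
  resid <- filt$data[1, mid] - in_band[mid]
  expect_lt(sd(resid), 0.05 * sd(out_band[mid]))
  expect_gt(sd(filt$data[1, mid]), 0.9 * sd(in_band[mid]))
})

test_that("notch removes the mains tone and is zero-phase", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)[-1]
  sig <- sin(2 * pi * 10 * t)
  mains <- 0.5 * sin(2 * pi * 50 * t)
  cm <- channel_matrix(rbind(sig + mains), "Cz", "EEG", fs)
  filt <- preprocess(cm, eeg_band = NULL, emg_band = NULL, notch = 50)
  mid <- 500:3500
  expect_lt(sd(filt$data[1, mid] - sig[mid]), 0.02 * sd(mains[mid]))
  # zero-phase: peak cross-correlation with the clean tone at lag 0
  cc <- ccf(filt$data[1, mid], sig[mid], lag.max = 10, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("EMG is rectified after filtering", {
  set.seed(2)
  X <- matrix(rnorm(2 * 3000), 2, 3000)
  cm <- channel_matrix(X, c("Cz", "FDS"), c("EEG", "EMG"), 1000)
  filt <- preprocess(cm)
  expect_true(all(filt$data[2, ] >= 0))
  expect_true(any(filt$data[1, ] < 0))
  raw <- preprocess(cm, rectify_emg = FALSE)
  expect_equal(abs(raw$data[2, ]), filt$data[2, ], tolerance = 1e-12)
})

test_that("preprocess rejects bad inputs", {
  cm <- channel_matrix(matrix(rnorm(100), 1), "Cz", "EEG", 1000)
  expect_error(preprocess(cm, eeg_band = c(100, 0.05)), "band edges")
  expect_error(preprocess(cm, eeg_band = c(10, 600)), "band edges")
  expect_error(preprocess(cm, notch = 700), "below fs/2")
  bad <- cm; bad$data[1, 5] <- NA
  expect_error(preprocess(bad), "non-finite")
})

test_that("epoch_trials cuts 1-based windows and checks bounds", {
  X <- matrix(seq_len(20), 1, 20)
  cm <- channel_matrix(X, "Cz", "EEG", 1000)
  ep <- epoch_trials(cm, onsets = c(1, 6), length = 5)
  expect_length(ep, 2)
  expect_equal(ep[[1]]$data[1, ], 1:5, ignore_attr = TRUE)
  expect_equal(ep[[2]]$data[1, ], 6:10, ignore_attr = TRUE)
  expect_error(epoch_trials(cm, 17, 5), "exceeds")
  expect_error(epoch_trials(cm, 0, 5), "exceeds")
  expect_error(epoch_trials(cm, 1, 0), "positive")
})
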