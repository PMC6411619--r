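make_recording <- function(data, fs = 512, labels = NULL, events = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (is.null(events))
    events <- data.frame(sample = integer(0), condition = character(0))
  structure(list(data = data, sampling_rate = fs, channel_labels = labels,
                 events = events, subject_id = "S1", group = "TD"),
            class = "fpvs_recording")
}

test_that("segmentation yields 47 s epochs of 24064 samples at 512 Hz", {
  fs <- 512
  n <- 60 * fs
  rec <- make_recording(matrix(rnorm(2 * n), 2, n), fs = fs,
                        events = data.frame(sample = 2 * fs + 1,
                                            condition = "upright"))
  segs <- segment_sequences(rec, epoch_pre = 2, epoch_post = 45)
  expect_length(segs$segments, 1)
  expect_equal(ncol(segs$segments[[1]]), 47 * 512)
  expect_equal(segs$t0_offset, -2)
})

test_that("segmentation handles missing events and out-of-bounds epochs", {
  rec <- make_recording(matrix(0, 1, 1000), fs = 100)
  expect_warning(segs <- segment_sequences(rec, 1, 5), "no sequence-onset")
  expect_length(segs$segments, 0)
  rec2 <- make_recording(matrix(0, 1, 1000), fs = 100,
                         events = data.frame(sample = c(50, 200, 950),
                                             condition = c("a", "b", "a")))
  expect_warning(segs2 <- segment_sequences(rec2, 1, 5), "exceeds")
  expect_length(segs2$segments, 1)   # only the event at 200 fits
  expect_equal(segs2$conditions, "b")
  # order preserved for multiple fitting markers
  rec3 <- make_recording(matrix(0, 1, 5000), fs = 100,
                         events = data.frame(sample = c(200, 900, 1600, 2300),
                                             condition = c("a", "b", "c", "d")))
  segs3 <- segment_sequences(rec3, 1, 5)
  expect_equal(segs3$conditions, c("a", "b", "c", "d"))
})

test_that("band-pass keeps 6 Hz, removes DC and attenuates 150 Hz", {
  fs <- 512
  t <- (0:(47 * fs - 1)) / fs
  segs <- structure(list(
    segments = list(rbind(sin(2 * pi * 6 * t), 5 + 0 * t,
                          sin(2 * pi * 150 * t))),
    conditions = "a", sampling_rate = fs,
    channel_labels = c("s6", "dc", "s150"), t0_offset = 0),
    class = "fpvs_segments")
  out <- bandpass_segments(segs, 0.1, 100, 4)
  mid <- (10 * fs):(40 * fs)   # avoid filter edge transients
  amp6 <- projection_amplitude(out$segments[[1]][1, mid], 6, fs)
  expect_equal(amp6, 1, tolerance = 0.01)
  expect_lt(abs(mean(out$segments[[1]][2, mid])), 0.1)
  amp150 <- projection_amplitude(out$segments[[1]][3, mid], 150, fs)
  expect_lt(amp150, 0.05)
  expect_error(bandpass_segments(segs, 0.1, 300), "Nyquist")
})

test_that("decimation halves the sample count and preserves 6 Hz", {
  fs <- 512
  t <- (0:(47 * fs - 1)) / fs
  segs <- structure(list(
    segments = list(matrix(sin(2 * pi * 6 * t), 1)),
    conditions = "a", sampling_rate = fs, channel_labels = "s6",
    t0_offset = -2), class = "fpvs_segments")
  out <- downsample_segments(segs, 256)
  expect_equal(ncol(out$segments[[1]]), 12032)
  expect_equal(out$sampling_rate, 256)
  mid <- (2 * 256):(40 * 256)
  expect_equal(projection_amplitude(out$segments[[1]][1, mid], 6, 256), 1,
               tolerance = 0.01)
  expect_error(downsample_segments(segs, 300), "integer multiple")
})

test_that("blink rate estimation matches injected ground truth", {
  fs <- 256
  expect_equal(blink_rate(rep(0, 10 * fs), fs), 0)
  # 17 stereotyped blinks over 40 s
  x <- rep(0, 40 * fs)
  onsets <- round(seq(1, 39, length.out = 17) * fs)
  kern <- 100 * sin(pi * (0:(0.35 * fs - 1)) / (0.35 * fs - 1))
  for (s in onsets) x[s + seq_along(kern)] <- x[s + seq_along(kern)] + kern
  x <- x + rnorm(length(x), 0, 3)
  expect_equal(blink_rate(x, fs), 17 / 40, tolerance = 0.03)
})

test_that("blink screen flags rates above cohort mean + 2 SD", {
  rates <- c(S1 = 0.40, S2 = 0.42, S3 = 0.43, S4 = 0.44, S5 = 0.41,
             S6 = 0.66)
  scr <- blink_screen(rates)
  expect_true(scr$flagged[scr$subject == "S6"])
  expect_false(any(scr$flagged[scr$subject != "S6"]))
})

test_that("channel interpolation averages the 3 nearest neighbours", {
  labels <- biosemi64_montage()$label
  n <- 100
  m <- matrix(0, length(labels), n)
  nb <- nearest_electrodes("Oz", candidates = setdiff(labels, "Oz"), k = 3)
  # constant 1, 2, 3 on the neighbours -> interpolated value 2
  for (i in seq_along(nb)) m[match(nb[i], labels), ] <- i
  m[match("Oz", labels), ] <- 99
  segs <- structure(list(segments = list(m), conditions = "a",
                         sampling_rate = 64, channel_labels = labels,
                         t0_offset = 0), class = "fpvs_segments")
  out <- interpolate_channels(segs, "Oz")
  expect_equal(unname(out$segments[[1]][match("Oz", labels), 1]), 2)
  expect_equal(out$channel_labels, labels)   # labels and count unchanged
  # identical neighbours reproduce their series exactly
  m2 <- matrix(rnorm(length(labels) * n), length(labels), n)
  series <- rnorm(n)
  for (b in nb) m2[match(b, labels), ] <- series
  segs2 <- structure(list(segments = list(m2), conditions = "a",
                          sampling_rate = 64, channel_labels = labels,
                          t0_offset = 0), class = "fpvs_segments")
  out2 <- interpolate_channels(segs2, "Oz")
  expect_equal(out2$segments[[1]][match("Oz", labels), ], series)
})

test_that("interpolation enforces the 5% cap and known labels", {
  labels <- biosemi64_montage()$label
  segs <- structure(list(segments = list(matrix(0, 64, 10)), conditions = "a",
                         sampling_rate = 64, channel_labels = labels,
                         t0_offset = 0), class = "fpvs_segments")
  expect_equal(floor(0.05 * 64), 3)
  out <- interpolate_channels(segs, c("Oz", "Fz", "Cz"))   # 3 is allowed
  expect_error(interpolate_channels(segs, c("Oz", "Fz", "Cz", "Pz")), "cap")
  expect_error(interpolate_channels(segs, "NOPE"), "unknown")
})

test_that("common average reference zeroes the instantaneous channel mean", {
  m <- matrix(rnorm(5 * 200), 5, 200) + 10   # common-mode offset
  segs <- structure(list(segments = list(m), conditions = "a",
                         sampling_rate = 64,
                         channel_labels = paste0("ch", 1:5), t0_offset = 0),
                    class = "fpvs_segments")
  out <- rereference_average(segs)
  expect_lt(max(abs(colMeans(out$segments[[1]]))), 1e-12)
  # zero-mean input is unchanged
  m2 <- rbind(rep(1, 10), rep(-1, 10))
  segs2 <- structure(list(segments = list(m2), conditions = "a",
                          sampling_rate = 64, channel_labels = c("a", "b"),
                          t0_offset = 0), class = "fpvs_segments")
  expect_equal(rereference_average(segs2)$segments[[1]], m2)
})

test_that("filtering and re-referencing are linear operations", {
  fs <- 256
  set.seed(21)
  a <- matrix(rnorm(3 * 4 * fs), 3)
  b <- matrix(rnorm(3 * 4 * fs), 3)
  mk <- function(m) structure(list(segments = list(m), conditions = "x",
                                   sampling_rate = fs,
                                   channel_labels = c("c1", "c2", "c3"),
                                   t0_offset = 0), class = "fpvs_segments")
  f <- function(m) {
    s <- rereference_average(bandpass_segments(mk(m), 0.1, 100, 4))
    s$segments[[1]]
  }
  expect_lt(max(abs(f(a + b) - (f(a) + f(b)))), 1e-6)
})

test_that("EOG regression removes a shared artifact component", {
  fs <- 128
  set.seed(31)
  eog <- noise_1f(4 * fs, fs, 2, 50)[1, ]
  clean <- matrix(rnorm(2 * 4 * fs), 2)
  m <- clean + rbind(0.8 * eog, 0.3 * eog)
  segs <- structure(list(segments = list(m), conditions = "a",
                         sampling_rate = fs, channel_labels = c("c1", "c2"),
                         t0_offset = 0), class = "fpvs_segments")
  out <- regress_eog(segs, eog)
  expect_lt(abs(stats::cor(out$segments[[1]][1, ], eog)), 0.05)
})
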