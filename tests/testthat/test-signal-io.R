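test_that("CSV and arrow round trips preserve the record", {
  rec <- cached_record(duration = 0.2, seed = 2)
  rec$raw <- rec$raw[1:1000]; rec$label <- rec$label[1:1000]

  csv <- withr::local_tempfile(fileext = ".csv")
  write_record(rec, csv, "csv")
  back <- read_record(csv, "csv", sample_rate = 5000)
  expect_identical(back$label, rec$label)
  expect_lt(max(abs(back$raw - rec$raw)), 1e-9)
  expect_identical(back$sample_rate, 5000)
  expect_identical(readLines(csv, n = 1), "time_index,current_pA,label")

  skip_if_not_installed("arrow")
  pq <- withr::local_tempfile(fileext = ".parquet")
  write_record(rec, pq, "arrow")
  back2 <- read_record(pq, "arrow")
  expect_identical(back2$label, rec$label)
  expect_identical(back2$raw, rec$raw)       # binary container: exact
  expect_identical(back2$sample_rate, 5000)
})

test_that("malformed CSV input is rejected with informative errors", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_index,current_pA,label", "0,1.5,0", "1,2.5"), bad)
  expect_error(read_record(bad, "csv", sample_rate = 5000), "unequal|length")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad2)
  expect_error(read_record(bad2, "csv", sample_rate = 5000), "current_pA")
  expect_error(read_record(bad, "csv"), "sample_rate")
})

test_that("robust scaling matches hand values and inverts exactly", {
  rec <- paired_record(raw = c(0, 1, 2, 3, 4), label = c(0, 1, 0, 1, 0),
                       sample_rate = 5000)
  sc <- robust_scale(rec)
  expect_equal(unname(sc$scaled[1, ]), c(-1, -0.5, 0, 0.5, 1))  # med 2, IQR 2
  expect_setequal(unique(sc$scaled[2, ]), c(-1, 1))             # levels {0,1}
  expect_identical(sc$scaler$label_levels, c(0L, 1L))

  sim <- cached_record(duration = 0.5, seed = 3)
  s2 <- robust_scale(sim)
  expect_equal(median(s2$scaled[1, ]), 0, tolerance = 1e-12)
  expect_equal(unname(diff(quantile(s2$scaled[1, ], c(.25, .75)))), 1,
               tolerance = 1e-12)
  inv <- inverse_scale(s2$scaled, s2$scaler)
  expect_lt(max(abs(inv$raw - sim$raw)), 1e-9)
  expect_identical(inv$label, sim$label)

  flat <- paired_record(rep(1, 10), rep(0:1, 5), 5000)
  expect_error(robust_scale(flat), "interquartile")
  mono <- paired_record(rnorm(10), rep(1L, 10), 5000)
  expect_warning(sc3 <- robust_scale(mono), "single label level")
  expect_true(sc3$scaler$single_level)
  expect_true(all(sc3$scaled[2, ] == -1))
})

test_that("window counts follow floor((L - W)/stride) + 1 and short input errors", {
  mk <- function(L) paired_record(rnorm(L), rep(0:1, length.out = L), 5000)
  expect_identical(dim(make_windows(mk(2560), W = 1280, stride = 1280)$data)[1], 2L)
  expect_identical(dim(make_windows(mk(4096), W = 1280, stride = 640)$data)[1], 5L)
  expect_identical(dim(make_windows(mk(100), W = 16, stride = 7)$data)[1], 13L)
  expect_error(make_windows(mk(1279), W = 1280), "1279")
  # windows are contiguous slices of the scaled signal
  r <- mk(64)
  sc <- robust_scale(r)
  b <- make_windows(r, W = 16, stride = 16)
  expect_equal(b$data[2, , ], sc$scaled[, 17:32], ignore_attr = TRUE)
})

test_that("windowing with a shared scaler commutes with concatenation", {
  r1 <- cached_record(duration = 0.5, seed = 4)
  n <- 4 * 64
  r1$raw <- r1$raw[1:(2 * n)]; r1$label <- r1$label[1:(2 * n)]
  half1 <- paired_record(r1$raw[1:n], r1$label[1:n], 5000)
  half2 <- paired_record(r1$raw[(n + 1):(2 * n)], r1$label[(n + 1):(2 * n)], 5000)
  sc <- robust_scale(r1)$scaler
  whole <- make_windows(r1, W = 64, stride = 64, scaler = sc)
  parts <- lapply(list(half1, half2), make_windows, W = 64, stride = 64,
                  scaler = sc)
  expect_equal(whole$data[1:4, , ], parts[[1]]$data)
  expect_equal(whole$data[5:8, , ], parts[[2]]$data)
})

test_that("augmentation perturbs only the raw row at the stated amplitude", {
  rec <- cached_record(duration = 0.5, seed = 5)
  b <- make_windows(rec, W = 64, stride = 64)
  expect_identical(augment_windows(b, 0), b)

  a <- augment_windows(b, noise_fraction = 0.001, seed = 9)
  expect_identical(a$data[, 2, ], b$data[, 2, ])      # labels untouched
  delta <- a$data[, 1, ] - b$data[, 1, ]
  ptp <- max(b$data[, 1, ]) - min(b$data[, 1, ])
  expect_gt(length(delta), 2000)
  expect_lt(abs(sd(delta) - 0.001 * ptp) / (0.001 * ptp), 0.1)
  # seeded: reproducible
  expect_identical(augment_windows(b, 0.001, seed = 9)$data, a$data)
  expect_false(identical(augment_windows(b, 0.001, seed = 10)$data, a$data))
})

test_that("edge cropping removes the stated number of samples per side", {
  w <- matrix(seq_len(2 * 1280), nrow = 2)
  expect_identical(ncol(crop_edges(w, 0.05)), 1152L)
  expect_identical(crop_edges(w, 0), w)
  w2 <- matrix(seq_len(200), nrow = 2)
  expect_identical(ncol(crop_edges(w2, 0.25)), 50L)
  expect_error(crop_edges(w, 0.5), "0.5")
  # batch form crops every window identically
  rec <- cached_record(duration = 0.5, seed = 5)
  b <- make_windows(rec, W = 64, stride = 64)
  cb <- crop_edges(b, 0.05)
  expect_identical(dim(cb$data)[3], 58L)
  expect_equal(cb$data[1, , ], b$data[1, , 4:61])
})

test_that("label integrity survives scale, window, augment, decode", {
  rec <- cached_record(duration = 0.5, seed = 6)
  b <- make_windows(rec, W = 64, stride = 64)
  b <- augment_windows(b, 0.001, seed = 1)
  recs <- decode_labels(b, crop_fraction = 0)
  got <- unlist(lapply(recs, `[[`, "label"))
  n <- length(got)
  expect_identical(got, rec$label[seq_len(n)])
})
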