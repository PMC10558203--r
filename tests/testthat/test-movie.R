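# Synthetic movie rendering against its own ground truth.

test_that("single ROI, zero noise: every frame's ROI mean equals the trace", {
  protocol <- short_protocol()
  tr <- simulate_cell(opsin = fast_opsin(), protocol = protocol)
  mov <- render_movie(list(tr), list(list(cx = 10, cy = 10, r = 4)),
                      ny = 24, nx = 24, protocol = protocol, frame_rate = 4)
  expect_s3_class(mov$stack, "frame_stack")
  vals <- approx(tr$t, tr$F, xout = mov$stack$t, rule = 2)$y
  for (k in seq_along(mov$stack$t)) {
    expect_equal(mean(mov$stack$data[k, , ][mov$mask == 1]), vals[k])
  }
})

test_that("two-ROI extraction recovers each trace within the noise bound", {
  protocol <- short_protocol()
  tr1 <- simulate_cell(opsin = fast_opsin(), protocol = protocol)
  tr2 <- simulate_cell(opsin = fast_opsin(f_H = 0), protocol = protocol)
  noise <- 5
  mov <- render_movie(list(tr1, tr2),
                      list(list(cx = 8, cy = 8, r = 4),
                           list(cx = 20, cy = 20, r = 4)),
                      ny = 28, nx = 28, protocol = protocol, frame_rate = 4,
                      noise_sd = noise, seed = 42)
  for (i in 1:2) {
    tr <- list(tr1, tr2)[[i]]
    vals <- approx(tr$t, tr$F, xout = mov$stack$t, rule = 2)$y
    n_pix <- sum(mov$mask == i)
    got <- vapply(seq_along(mov$stack$t), function(k) {
      mean(mov$stack$data[k, , ][mov$mask == i])
    }, numeric(1))
    # law of large numbers: ROI mean within a few standard errors
    expect_lt(max(abs(got - vals)), 5 * noise / sqrt(n_pix))
  }
})

test_that("empty layouts give background-only movies; overlaps are rejected", {
  protocol <- short_protocol()
  mov <- render_movie(list(), list(), ny = 16, nx = 16, protocol = protocol)
  expect_true(all(mov$stack$data == 0))
  expect_true(all(mov$mask == 0))

  tr <- simulate_cell(opsin = fast_opsin(), protocol = protocol)
  expect_error(
    render_movie(list(tr, tr),
                 list(list(cx = 10, cy = 10, r = 5),
                      list(cx = 12, cy = 10, r = 5)),
                 ny = 24, nx = 24, protocol = protocol),
    "overlapping")
})
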