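smoothed_from <- function(pos, values, coverage = 50) {
  tr <- count_track(pos = pos, coverage = coverage, n_meth = 0)
  tr$percent <- values
  tr$smoothed <- values     # already-smooth synthetic input
  tr
}

test_that("background estimation follows mean + k*SD with sample-size guard", {
  tr <- count_track(pos = 1:50, coverage = 100, n_meth = 1)
  expect_equal(estimate_background(tr)$background, 1)   # constant 1%, SD 0
  expect_equal(estimate_background(tr, k = 0)$background, 1)
  tr2 <- count_track(pos = 1:100, coverage = 100, n_meth = 0)
  tr2$percent <- rep(c(1, 3), 50)
  bg <- estimate_background(tr2, k = 2)
  expect_equal(bg$background, 2 + 2 * sd(tr2$percent))
  expect_equal(bg$n, 100)
  expect_error(estimate_background(tr[1:10, ]), ">= 20")
})

test_that("boundary calls handle flat, unbounded and bounded tracks", {
  pos <- seq(1600, 9000, by = 4)
  flat <- smoothed_from(pos, rep(1, length(pos)))
  b <- call_boundary(flat, c(1000, 1600), "+", background = 1.5)
  expect_equal(b$status, "at_anchor")
  expect_equal(b$spread_extent, 0)

  high <- smoothed_from(pos, rep(10, length(pos)))
  b2 <- call_boundary(high, c(1000, 1600), "+", background = 1.5)
  expect_equal(b2$status, "unbounded")
  expect_equal(b2$boundary_position, max(pos))

  # clean step at 5000 with a sub-run-length dip before it
  v <- ifelse(pos < 5000, 8, 1)
  v[pos >= 3000 & pos < 3200] <- 0.5   # 200 bp dip < run length 300
  stepped <- smoothed_from(pos, v)
  b3 <- call_boundary(stepped, c(1000, 1600), "+", background = 1.5)
  expect_equal(b3$status, "bounded")
  expect_equal(b3$boundary_position, 5000)
  expect_equal(b3$spread_extent, 3400)
  # the 200 bp dip alone is accepted once the run length drops below it
  b4 <- call_boundary(stepped, c(1000, 1600), "+", background = 1.5,
                      run_length = 150)
  expect_equal(b4$boundary_position, 3000)
  expect_error(call_boundary(stepped, c(20000, 20100), "+", 1.5),
               "anchor outside")
})

test_that("boundary scanning works leftwards and is monotone in background", {
  pos <- seq(200, 7000, by = 4)
  v <- ifelse(pos > 3000, 8, 1) + 0.2 * sin(pos / 50)
  tr <- smoothed_from(pos, v)
  bl <- call_boundary(tr, c(6500, 7000), "-", background = 1.5)
  expect_equal(bl$status, "bounded")
  expect_lt(abs(bl$boundary_position - 3000), 60)
  exts <- vapply(c(1.5, 2, 5, 9.5),
                 function(bg) call_boundary(tr, c(6500, 7000), "-",
                                            bg)$spread_extent, numeric(1))
  expect_true(all(diff(exts) <= 0))   # raising background never extends
})

test_that("identical tracks classify as unchanged; symmetric swap flips the shift", {
  pos <- seq(1600, 9000, by = 4)
  v <- 1 + 10 * exp(-(pos - 1600) / 2000)
  tr <- smoothed_from(pos, v)
  r <- classify_response(tr, tr, c(1000, 1600), "+", background = 1.5)
  expect_equal(r$category, "unchanged")
  expect_equal(r$boundary_shift, 0)
  expect_equal(r$level_ratio, 1)
  # doubled level, same boundary profile shape
  tr2 <- smoothed_from(pos, 1 + 20 * exp(-(pos - 1600) / 2000))
  r2 <- classify_response(tr, tr2, c(1000, 1600), "+", background = 1.5)
  expect_gt(r2$level_ratio, 1.25)
  r2s <- classify_response(tr2, tr, c(1000, 1600), "+", background = 1.5)
  expect_equal(r2s$boundary_shift, -r2$boundary_shift)
  expect_lt(r2s$level_ratio, 1 / 1.25)
  flat <- smoothed_from(pos, rep(1, length(pos)))
  expect_warning(r3 <- classify_response(flat, flat, c(1000, 1600), "+", 1.5),
                 "background")
  expect_equal(r3$category, "unchanged")
})

test_that("differential positions: exact test, BH correction, coverage floor", {
  a <- count_track(pos = 1:30, coverage = 100, n_meth = rep(c(10, 50), 15))
  d0 <- differential_positions(a, a)
  expect_equal(sum(d0$significant), 0)
  expect_true(all(d0$p > 0.99))
  b <- a
  b$n_meth[1] <- 90
  b$percent <- 100 * b$n_meth / b$coverage
  d1 <- differential_positions(a, b)
  expect_lt(d1$p[1], 1e-10)
  expect_true(d1$significant[1])
  expect_equal(d1$effect[1], 80)
  # oracle: fisher.test on the same 2x2 table
  expect_equal(d1$p[1],
               fisher.test(matrix(c(10, 90, 90, 10), 2))$p.value)
  # coverage floor drops positions on either side
  a2 <- a; a2$coverage[2] <- 5L
  d2 <- differential_positions(a2, b)
  expect_false(2 %in% d2$pos)
  expect_error(differential_positions(a[0, ], b), "no shared")
})

test_that("periodicity: cosine recovered, white noise rejected", {
  set.seed(5)
  pos <- sort(sample(0:7999, 2500))
  v <- 10 + 5 * cos(2 * pi * pos / 165)
  tr <- smoothed_from(pos, v + rnorm(length(pos), 0, 0.5))
  tr$smoothed <- rep(10, length(pos))
  p <- estimate_periodicity(tr, max_lag = 400)
  expect_true(p$significant)
  expect_lt(abs(p$repeat_length - 165), 5)

  noise <- smoothed_from(pos, 10 + rnorm(length(pos), 0, 3))
  noise$smoothed <- rep(10, length(pos))
  pn <- estimate_periodicity(noise, max_lag = 400)
  expect_false(pn$significant)
  expect_true(is.na(pn$repeat_length))
  expect_error(estimate_periodicity(tr[tr$pos < 1500, ], max_lag = 400),
               "5 \\* max_lag")
})

test_that("linker enrichment recovers accessibility contrast and guards degenerate input", {
  ann <- tel_annotation(8000)
  m <- tel_model(ann, peak = 0, lambda = 800, background = 0.5,
                 linker_accessibility = 1, core_accessibility = 0.2)
  calls <- binarize_calls(
    simulate_reads(ann, m, emission_model(fpr = 1e-6),
                   read_sampler(target_coverage = 60, mean_read_length = 4000,
                                seed = 8)))
  le <- linker_enrichment(calls, contig_dyads(ann, "tel"))
  expect_gt(le$ratio, 3.5)
  expect_lt(le$ratio, 7)
  expect_true(le$ci[1] < le$ratio & le$ratio < le$ci[2])
  # uniform accessibility: CI contains 1
  mu <- tel_model(ann, peak = 0, lambda = 800, background = 0.5,
                  linker_accessibility = 1, core_accessibility = 1)
  cu <- binarize_calls(
    simulate_reads(ann, mu, emission_model(),
                   read_sampler(target_coverage = 40, mean_read_length = 4000,
                                seed = 9)))
  lu <- linker_enrichment(cu, contig_dyads(ann, "tel"), conf = 0.99)
  expect_true(lu$ci[1] <= 1 && 1 <= lu$ci[2])
  # zero methylation -> undefined ratio
  z <- cu; z$methylated <- FALSE
  expect_error(linker_enrichment(z, contig_dyads(ann, "tel")), "zero methylated")
})

test_that("onset mapping finds first sustained exceedance and censors the rest", {
  mk <- function(time, percents) list(
    time = time,
    track = count_track(pos = seq_along(percents), coverage = 50,
                        n_meth = 0) |> transform(percent = percents))
  tracks <- list(mk(0,  c(0, 0, 5, 0)),
                 mk(15, c(5, 0, 5, 0)),
                 mk(45, c(5, 0, 5, 5)),
                 mk(90, c(5, 5, 5, 0)))
  ot <- onset_times(tracks, background = 2, min_consecutive = 2)
  expect_equal(ot$onset_time, c(15, NA, 0, NA))
  expect_equal(ot$censored, c(FALSE, TRUE, FALSE, TRUE))
  expect_error(onset_times(tracks[c(2, 1, 3)], 2), "sorted")
  expect_error(onset_times(tracks[1:2], 2), ">= 3")
})

test_that("spread model fit recovers a noiseless decay length and censors flat input", {
  pos <- seq(1600, 12000, by = 3)
  v <- 1.2 + 18 * exp(-(pos - 1600) / 800)
  tr <- smoothed_from(pos, v)
  fit <- fit_spread_model(tr, c(1000, 1600), "+", background = 1.2)
  expect_false(fit$censored)
  expect_lt(abs(fit$lambda - 800), 1)
  expect_lt(abs(fit$amplitude - 18), 0.05)
  flat <- smoothed_from(pos, rep(1.2, length(pos)))
  f2 <- fit_spread_model(flat, c(1000, 1600), "+", background = 1.2)
  expect_true(f2$censored)
  expect_true(is.na(f2$lambda))
  expect_error(fit_spread_model(tr[1:5, ], c(1000, 1600), "+", 1.2),
               "degenerate")
})
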