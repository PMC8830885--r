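test_that("aggregate fraction counts emitted and methylated calls per site", {
  df <- data.frame(
    read_id = sprintf("r%d", 1:15), contig = "c", strand = "+",
    pos = c(rep(100, 5), rep(200, 10)),
    prob = c(0.9, 0.95, 0.3, 0.2, 0.1, rep(0.05, 10)),
    stringsAsFactors = FALSE)
  b <- binarize_calls(df, 0.8)
  tr <- aggregate_fraction(b)
  expect_equal(tr$coverage, c(5L, 10L))
  expect_equal(tr$percent, c(40, 0))    # 2 of 5; 0 of 10
  expect_equal(tr$n_meth, c(2L, 0L))
})

test_that("aggregation matches a brute-force per-position recount", {
  ann <- tel_annotation(6000)
  m <- tel_model(ann, lambda = 800)
  calls <- binarize_calls(
    simulate_reads(ann, m, emission_model(),
                   read_sampler(target_coverage = 10, mean_read_length = 2000,
                                seed = 1)))
  tr <- aggregate_fraction(calls)                   # stranded
  key <- paste(calls$pos, calls$strand)
  cov_o <- table(key)
  meth_o <- tapply(calls$methylated, key, sum)
  tk <- paste(tr$pos, tr$strand)
  expect_equal(tr$coverage, as.integer(cov_o[tk]), ignore_attr = TRUE)
  expect_equal(tr$n_meth, as.integer(meth_o[tk]), ignore_attr = TRUE)
  expect_equal(tr$percent, 100 * tr$n_meth / tr$coverage)
  # merging strands pools counts at identical reference positions
  trm <- aggregate_fraction(calls, merge_strands = TRUE)
  expect_equal(sum(trm$coverage), sum(tr$coverage))
  expect_true(all(table(trm$pos) == 1))
})

test_that("coverage filter is inclusive at the floor, a subset, and monotone", {
  tr <- count_track(pos = 1:5, coverage = c(3, 9, 10, 11, 50),
                    n_meth = c(1, 2, 3, 4, 5))
  f10 <- filter_coverage(tr, 10)
  expect_equal(f10$coverage, c(10L, 11L, 50L))   # 9 removed, 10 retained
  expect_equal(f10$percent, tr$percent[3:5])     # values untouched
  f11 <- filter_coverage(tr, 11)
  expect_true(all(f11$pos %in% f10$pos))         # monotone
  expect_equal(nrow(filter_coverage(tr[0, ], 10)), 0)
  expect_error(filter_coverage(tr, 0), "min_coverage")
})

test_that("smoother reproduces constants and linear ramps", {
  set.seed(31)
  pos <- sort(sample(0:5000, 300))
  tr <- count_track(pos = pos, coverage = rep(20, 300), n_meth = rep(0, 300))
  tr$percent <- rep(37, 300)
  s <- smooth_track(tr, span = 0.4)
  expect_lt(max(abs(s$smoothed - 37)), 1e-9)
  tr$percent <- 10 + 0.01 * pos
  s <- smooth_track(tr, span = 0.4, weight_by_coverage = FALSE)
  expect_lt(max(abs(s$smoothed - tr$percent)), 1e-8)
  expect_error(smooth_track(tr, enp_target = 300), "enp_target")
  expect_error(smooth_track(tr[1:2, ], span = 0.5), ">= 3")
})

test_that("coverage weights are scale invariant and enp target is honoured", {
  set.seed(21)
  pos <- sort(sample(0:20000, 800))
  tr <- count_track(pos = pos, coverage = sample(10:80, 800, replace = TRUE),
                    n_meth = 0)
  tr$percent <- 20 + 15 * sin(pos / 700) + rnorm(800, 0, 2)
  s1 <- smooth_track(tr, enp_target = 50)
  tr2 <- tr; tr2$coverage <- tr2$coverage * 2L
  s2 <- smooth_track(tr2, enp_target = 50)
  expect_equal(s1$smoothed, s2$smoothed, tolerance = 1e-8)
  # smoothed values stay within the local range of the raw signal
  # (checked away from the track ends where local-linear fits extrapolate)
  inner <- which(pos > 2000 & pos < 18000)
  win <- 1500
  viol <- vapply(inner, function(i) {
    j <- which(abs(pos - pos[i]) <= win)
    s1$smoothed[i] < min(tr$percent[j]) - 1e-9 ||
      s1$smoothed[i] > max(tr$percent[j]) + 1e-9
  }, logical(1))
  expect_equal(mean(viol), 0)
})

test_that("median normalization excludes masked regions and is idempotent", {
  cov <- data.frame(contig = "chrI",
                    start = seq(0, 990, by = 10), end = seq(10, 1000, by = 10),
                    value = rep(c(2, 4, 6, 100), 25))
  # excluding the high-copy block changes the median
  excl <- data.frame(contig = "chrI", start = 0, end = 0)  # empty exclusion
  n0 <- normalize_chip(cov)
  w <- n0$end - n0$start
  med <- sirspread:::weighted_median(n0$value, w)
  expect_equal(med, 1)
  n1 <- normalize_chip(cov, data.frame(contig = "chrI", start = 750, end = 1000))
  n2 <- normalize_chip(n1, data.frame(contig = "chrI", start = 750, end = 1000))
  expect_equal(n1$value, n2$value)                     # idempotent
  cov3 <- cov; cov3$value <- cov3$value * 7            # scale equivariant
  n3 <- normalize_chip(cov3, data.frame(contig = "chrI", start = 750, end = 1000))
  expect_equal(n3$value, n1$value)
  # hand example: included median 4 -> everything divided by 4
  cov4 <- data.frame(contig = "c", start = 0:4, end = 1:5,
                     value = c(2, 4, 4, 8, 100))
  n4 <- normalize_chip(cov4, data.frame(contig = "c", start = 4, end = 5))
  expect_equal(n4$value, c(2, 4, 4, 8, 100) / 4)
  expect_error(normalize_chip(data.frame(contig = "c", start = 0, end = 10,
                                         value = 0)), "zero")
})

test_that("genotype overlay aligns tracks on the position union without interpolation", {
  a <- count_track(pos = c(10, 20, 30), coverage = 10, n_meth = c(1, 2, 3))
  b <- count_track(pos = c(20, 30, 40), coverage = 10, n_meth = c(5, 6, 7))
  ov <- genotype_overlay(list(wt = a, mut = b))
  expect_equal(ov$pos, c(10, 20, 30, 40))
  expect_equal(ov$wt, c(10, 20, 30, NA))
  expect_equal(ov$mut, c(NA, 50, 60, 70))
  ov2 <- genotype_overlay(list(x = a, y = a))
  expect_identical(ov2$x, ov2$y)
  c2 <- a; c2$contig <- "other"
  expect_error(genotype_overlay(list(a, c2)), "one contig")
})
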