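test_that("annotation construction validates intervals, kinds and dyads", {
  ct <- data.frame(name = "c", length = 1000)
  f <- function(kind, start = 100, end = 200)
    data.frame(contig = "c", start = start, end = end, strand = ".",
               kind = kind, name = kind)
  expect_s3_class(genome_annotation(ct, f("silencer")), "genome_annotation")
  expect_error(genome_annotation(ct, f("enhancer")), "unknown feature kind")
  expect_error(genome_annotation(ct, f("silencer", end = 1200)), "within contig")
  expect_error(genome_annotation(ct, f("silencer", start = 300, end = 300)),
               "half-open")
  expect_error(genome_annotation(ct, f("silencer"),
                                 dyads = data.frame(contig = "c",
                                                    pos = c(100, 150))),
               ">= 100 bp")
  expect_error(genome_annotation(ct, f("silencer"), adenine_density = 0),
               "adenine_density")
})

test_that("derived seeds are deterministic and label-sensitive", {
  expect_identical(derive_seed(1L, "a"), derive_seed(1L, "a"))
  expect_false(derive_seed(1L, "a") == derive_seed(1L, "b"))
  expect_false(derive_seed(1L, "a") == derive_seed(2L, "a"))
  s <- vapply(1:500, function(i) derive_seed(i, "x"), integer(1))
  expect_true(all(s >= 1 & s < 2^31))
})

single_site_annotation <- function(L = 6000, s = 1000, e = 1100,
                                   boundary = NULL) {
  feats <- data.frame(contig = "c", start = s, end = e, strand = ".",
                      kind = "silencer", name = "S")
  if (!is.null(boundary))
    feats <- rbind(feats, data.frame(contig = "c", start = boundary,
                                     end = boundary + 100, strand = ".",
                                     kind = "boundary", name = "B"))
  genome_annotation(data.frame(name = "c", length = L), feats)
}

site_model <- function(peak = 1, lambda = 800, attenuation = 1,
                       background = 0.05, ...) {
  occupancy_model(data.frame(contig = "c", start = 1000, end = 1100,
                             kind = "silencer", peak = peak),
                  lambda = lambda, boundary_attenuation = attenuation,
                  background = background, ...)
}

test_that("occupancy decays from the site edge with the stated closed form", {
  ann <- single_site_annotation()
  m <- site_model(peak = 1, lambda = 800, background = 0.05)
  occ <- occupancy_field(m, ann, "c")
  # inside the recruitment interval: clamp(bg + peak) = 1
  expect_equal(occ[1001:1100], rep(1, 100))
  # d = 800 bp from the right edge (position 1099): bg + e^-1
  expect_equal(occ[1099 + 800 + 1], 0.05 + exp(-1), tolerance = 1e-12)
  # d = 800 from the left edge
  expect_equal(occ[1000 - 800 + 1], 0.05 + exp(-1), tolerance = 1e-12)
  expect_error(occupancy_field(m, ann, "nope"), "unknown contig")
  expect_error(occupancy_field(m, ann, "c", time = -1), "time")
})

test_that("lambda -> 0 leaves only background outside recruitment intervals", {
  ann <- single_site_annotation()
  m <- site_model(peak = 0.9, lambda = 1e-6, background = 0.05)
  occ <- occupancy_field(m, ann, "c")
  expect_equal(occ[1001:1100], rep(0.95, 100))
  expect_equal(occ[-(1001:1100)], rep(0.05, 5900))
})

test_that("boundary attenuation 0 annihilates occupancy past the boundary", {
  ann <- single_site_annotation(boundary = 2000)
  m0 <- site_model(peak = 1, lambda = 5000, attenuation = 0, background = 0.02)
  occ <- occupancy_field(m0, ann, "c")
  # boundary midpoint at 2049.5: all positions beyond are background exactly
  expect_equal(occ[2051:6000], rep(0.02, length(2051:6000)))
  expect_gt(occ[2049], 0.02)
  # attenuation 1 makes the boundary feature inert
  m1 <- site_model(peak = 1, lambda = 5000, attenuation = 1, background = 0.02)
  ann_nb <- single_site_annotation()
  expect_equal(occupancy_field(m1, ann, "c"), occupancy_field(m1, ann_nb, "c"))
})

test_that("occupancy and accessibility stay in [0,1] and occupancy is monotone in lambda", {
  ann <- single_site_annotation(boundary = 3000)
  set.seed(42)
  for (i in 1:20) {
    m <- site_model(peak = runif(1), lambda = runif(1, 10, 5000),
                    attenuation = runif(1), background = runif(1, 0, 0.5),
                    core_accessibility = runif(1, 0.05, 0.5))
    occ <- occupancy_field(m, ann, "c")
    acc <- accessibility_field(ann, m, "c")
    expect_true(all(occ >= 0 & occ <= 1))
    expect_true(all(acc > 0 & acc <= 1))
    m2 <- m; m2$lambda <- m$lambda * (1 + runif(1, 0.1, 2))
    expect_true(all(occupancy_field(m2, ann, "c") >= occ - 1e-12))
  }
})

test_that("time scaling saturates recruitment before spread", {
  ann <- single_site_annotation()
  m <- site_model(peak = 0.8, lambda = 800, background = 0,
                  halftime_recruitment = 10, halftime_spread = 120)
  occ30 <- occupancy_field(m, ann, "c", time = 30)
  # inside the site: t/(t+hr) scaling
  expect_equal(occ30[1050], 0.8 * 30 / 40, tolerance = 1e-12)
  # outside: t/(t+hs) scaling on the decayed term
  expect_equal(occ30[1099 + 400 + 1], 0.8 * exp(-0.5) * 30 / 150,
               tolerance = 1e-12)
  # t = 0 collapses to background; t = Inf recovers the untimed field
  expect_equal(occupancy_field(m, ann, "c", time = 0), rep(0, 6000))
  expect_equal(occupancy_field(m, ann, "c", time = Inf),
               occupancy_field(m, ann, "c"))
})

test_that("accessibility marks 147 bp cores around dyads on a 165 bp repeat", {
  L <- 165 * 40
  dy <- seq(82, L - 83, by = 165)
  ann <- genome_annotation(data.frame(name = "c", length = L),
                           data.frame(contig = "c", start = 0, end = 100,
                                      strand = ".", kind = "control_region",
                                      name = "ctrl"),
                           dyads = data.frame(contig = "c", pos = dy))
  m <- site_model(core_accessibility = 0.2, linker_accessibility = 1)
  # model sites live on contig "c" too; accessibility only needs dyads
  acc <- accessibility_field(ann, m, "c")
  expect_true(all(acc %in% c(0.2, 1)))
  # periodic with period 165 away from the contig edges
  core <- acc == 0.2
  expect_equal(core[166:(L - 165)], core[(166 + 165):L])
  # core fraction = 147/165 up to edge effects
  expect_equal(mean(core), 147 / 165, tolerance = 0.02)
  # no dyads -> uniform linker accessibility
  ann0 <- genome_annotation(data.frame(name = "c", length = L),
                            data.frame(contig = "c", start = 0, end = 100,
                                       strand = ".", kind = "control_region",
                                       name = "ctrl"))
  expect_equal(accessibility_field(ann0, m, "c"), rep(1, L))
})
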