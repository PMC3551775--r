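test_that("phantom generation is bit-reproducible for a fixed seed", {
  a <- generate_phantom(phantom_spec(seed = 123))
  b <- generate_phantom(phantom_spec(seed = 123))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$labels, b$mask$labels)
  c2 <- generate_phantom(phantom_spec(seed = 124))
  expect_false(identical(a$volume$data, c2$volume$data))
})

test_that("phantom RNG does not disturb the caller's random stream", {
  set.seed(99)
  before <- rnorm(3)
  set.seed(99)
  invisible(generate_phantom(phantom_spec(seed = 5)))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("an NP escaping the disc raises a containment error", {
  expect_error(phantom_spec(np_offset = c(8, 0, 0)), "containment")
})

test_that("labels partition the disc and include both reference blocks", {
  ph <- generate_phantom(phantom_spec())
  lm <- default_label_map()
  expect_true(all(ph$mask$labels[ph$mask$labels != 0L] %in% lm))
  np_n <- sum(ph$mask$labels == lm[["NP"]])
  af_n <- sum(ph$mask$labels == lm[["AF"]])
  ivd <- extract_region(ph$volume, ph$mask, "IVD")
  expect_equal(ivd$n, np_n + af_n)
  expect_equal(sum(ph$mask$labels == lm[["CSF"]]), 8^3)
  expect_equal(sum(ph$mask$labels == lm[["BONE"]]), 8^3)
})

test_that("a symmetric noise-free phantom has coincident centres", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0))
  for (rg in c("IVD", "NP", "AF")) {
    s <- extract_region(ph$volume, ph$mask, rg)
    cp <- center_distance(s)
    half_diag <- sqrt(sum(ph$volume$spacing^2)) / 2
    expect_lt(cp$d, half_diag / s$n)
  }
})

test_that("weighted centre of an offset two-tissue phantom matches the closed form", {
  # uniform tissues (gradient off): W is the intensity-weighted centroid of
  # the two analytic ellipsoids, computed from the voxelized masks' volumes
  spec <- phantom_spec(np_offset = c(3, 0, 0), np_gradient = 0, noise_sd = 0)
  ph <- generate_phantom(spec)
  ivd <- extract_region(ph$volume, ph$mask, "IVD")
  np <- extract_region(ph$volume, ph$mask, "NP")
  W <- weighted_center(ivd)
  c_ivd <- spec$ivd_center
  c_np <- spec$ivd_center + spec$np_offset
  v_ivd <- 4 / 3 * pi * prod(spec$ivd_semi_axes)
  v_np <- 4 / 3 * pi * prod(spec$np_semi_axes)
  i_af <- spec$intensity_af
  i_np <- spec$intensity_np
  W_true <- (i_af * v_ivd * c_ivd + (i_np - i_af) * v_np * c_np) /
    (i_af * v_ivd + (i_np - i_af) * v_np)
  expect_lt(sqrt(sum((W - W_true)^2)), sqrt(sum(ph$volume$spacing^2)))
  # and the weighted centre shifts toward the displacement
  expect_gt(W[1] - geometric_center(ivd)[1], 0)
})

test_that("voxelized volume ratio converges to the analytic ellipsoid ratio", {
  spec1 <- phantom_spec(noise_sd = 0)
  spec2 <- phantom_spec(grid_shape = c(96L, 72L, 40L),
                        spacing = c(0.5, 0.5, 0.5),
                        csf_block = c(76L, 91L, 8L, 23L, 12L, 27L),
                        bone_block = c(76L, 91L, 48L, 63L, 12L, 27L),
                        noise_sd = 0)
  truth <- analytic_volume_ratio(spec1)
  err <- vapply(list(spec1, spec2), function(sp) {
    ph <- generate_phantom(sp)
    vr <- volume_ratio(extract_region(ph$volume, ph$mask, "NP"),
                       extract_region(ph$volume, ph$mask, "IVD"))
    abs(vr$ratio - truth)
  }, numeric(1))
  expect_lt(err[2], err[1] / 2)
})

test_that("cohort bookkeeping emits 79 subjects in five groups", {
  cs <- cohort_spec()
  params <- cohort_params(cs)
  expect_equal(nrow(params), 79L)
  expect_equal(as.integer(table(params$group)[c("control", "scoliosis",
                                                "spondylolisthesis")]),
               c(15L, 32L, 32L))
  expect_equal(sum(params$severity == "none"), 15L)
  # reproducible from the master seed
  expect_identical(params, cohort_params(cs))
  co <- generate_cohort(cohort_spec(group_sizes = c(
    scoliosis_low = 3L, scoliosis_high = 3L, spondylolisthesis_low = 3L,
    spondylolisthesis_high = 3L, control = 3L)))
  expect_length(co$subjects, 15L)
  expect_s3_class(co$subjects[[1]]$volume, "volume_grid")
})

test_that("gain is unrecoverable from CSF-normalized indices", {
  base <- phantom_spec(seed = 17)
  idx <- function(gain) {
    ph <- generate_phantom(phantom_spec(gain = gain, seed = 17))
    csf <- extract_region(ph$volume, ph$mask, "CSF")
    ivd <- normalize_region(extract_region(ph$volume, ph$mask, "IVD"),
                            csf, "csf")
    unlist(compute_index_set(ivd))
  }
  expect_equal(idx(1), idx(4.7), tolerance = 1e-9)
})
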