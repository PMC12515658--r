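test_that("volumes round-trip through NIfTI: values and spacing preserved", {
  tmp <- withr::local_tempdir()
  arr <- array(runif(16 * 16 * 4), dim = c(16, 16, 4))
  sp <- c(0.9, 0.9, 7.0)
  f <- file.path(tmp, "vol.nii.gz")
  write_volume(arr, f, sp)
  back <- read_volume(f)
  expect_equal(back$data, arr, tolerance = 0)       # doubles: bit-exact
  expect_true(all(abs(back$spacing - sp) <= 1e-6))  # header pixdim

  lab <- array(sample(0:3, 16 * 16 * 4, replace = TRUE), dim = c(16, 16, 4))
  storage.mode(lab) <- "integer"
  f2 <- file.path(tmp, "lab.nii.gz")
  write_volume(lab, f2, sp)
  expect_identical(as.integer(read_volume(f2)$data), as.integer(lab))
})

test_that("read_volume enforces its contract", {
  tmp <- withr::local_tempdir()
  expect_error(read_volume(file.path(tmp, "nope.nii.gz")), "not found")

  f <- file.path(tmp, "big.nii.gz")
  write_volume(array(0, dim = c(32, 32, 8)), f, c(1, 1, 1))
  small <- voxel_grid(array(label_codes()[["WHITE"]], dim = c(16, 16, 4)),
                      c(1, 1, 1))
  expect_error(read_volume(f, expected_grid = small), "dimension mismatch")
})

test_that("voxel_grid rejects unknown label codes and degenerate domains", {
  lab <- array(3L, dim = c(8, 8, 2))
  lab[1, 1, 1] <- 7L
  expect_error(voxel_grid(lab, c(1, 1, 1)), "invalid tissue label")
  expect_error(
    voxel_grid(array(0L, dim = c(8, 8, 2)), c(1, 1, 1)),
    "no WHITE or GRAY"
  )
  expect_error(voxel_grid(array(3L, dim = c(8, 8, 2)), c(1, 0, 1)),
               "positive")
})

test_that("a written study file set reloads to an equivalent study", {
  tmp <- withr::local_tempdir()
  fx <- phantom_fixture(noise_sd = 0.02, seed = 3)
  study <- make_baseline_study(fx$grid, fx$spec, default_scenarios()[[1]])
  manifest <- write_study(study, tmp, "baseline")
  back <- load_study_manifest(manifest)
  expect_identical(back$grid$labels, study$grid$labels)
  expect_identical(which(back$enhancing), which(study$enhancing))
  expect_identical(which(back$edema), which(study$edema))
  expect_identical(which(back$necrotic), which(study$necrotic))
  expect_equal(back$t1c, study$t1c, tolerance = 0)
  expect_identical(back$day, study$day)
})

test_that("load_study validates inputs: overlaps, missing files, dims", {
  tmp <- withr::local_tempdir()
  fx <- phantom_fixture()
  study <- make_baseline_study(fx$grid, fx$spec, default_scenarios()[[1]])
  write_study(study, tmp, "s")
  paths <- c(t1c = "s_t1c.nii.gz", t2 = "s_t2.nii.gz",
             labels = "s_labels.nii.gz", enhancing = "s_enhancing.nii.gz",
             edema = "s_edema.nii.gz")
  paths <- setNames(file.path(tmp, paths), names(paths))

  expect_s3_class(load_study(paths, day = 0L), "imaging_study")
  expect_error(load_study(paths[-5]), "missing required study file.*edema")

  # corrupt: make the edema mask overlap one enhancing voxel
  edema <- 1L * study$edema
  edema[which(study$enhancing)[1]] <- 1L
  write_volume(edema, paths[["edema"]], fx$grid$spacing)
  expect_error(load_study(paths), "overlap in 1 voxel")
})

test_that("masks outside brain tissue and negative intensities are rejected", {
  fx <- phantom_fixture()
  d <- fx$grid$dims
  enh <- array(FALSE, d)
  enh[which(fx$grid$labels == label_codes()[["BACKGROUND"]])[1]] <- TRUE
  expect_error(
    imaging_study(fx$grid, array(0, d), array(0, d),
                  enhancing = enh, edema = array(FALSE, d)),
    "outside brain tissue"
  )
  t1c <- array(0, d); t1c[1] <- -1
  expect_error(
    imaging_study(fx$grid, t1c, array(0, d),
                  enhancing = array(FALSE, d), edema = array(FALSE, d)),
    ">= 0"
  )
})

test_that("resection-cavity voxels are relabeled CSF at load time", {
  fx <- phantom_fixture()
  d <- fx$grid$dims
  codes <- label_codes()
  cavity <- array(FALSE, d)
  w <- which(fx$grid$labels == codes[["WHITE"]])[1:5]
  cavity[w] <- TRUE
  st <- imaging_study(fx$grid, array(0.1, d), array(0.1, d),
                      enhancing = array(FALSE, d) | FALSE,
                      edema = array(FALSE, d), cavity = cavity,
                      day = 0L)
  # degenerate masks are fine here; the point is the relabeling
  expect_true(all(st$grid$labels[w] == codes[["CSF"]]))
})

test_that("write_result_masks round-trips and enforces grid match", {
  tmp <- withr::local_tempdir()
  fx <- phantom_fixture()
  d <- fx$grid$dims
  res <- structure(list(index = 3L,
                        sim_enhancing = array(FALSE, d),
                        sim_edema = fx$grid$labels == 3L),
                   class = "scenario_result")
  paths <- write_result_masks(res, fx$grid, tmp)
  expect_true(all(file.exists(paths)))
  enh <- read_volume(paths[["enhancing"]])
  expect_true(all(enh$data == 0))                  # empty mask: all zero
  expect_true(all(abs(enh$spacing - fx$grid$spacing) <= 1e-6))
  ed <- read_volume(paths[["edema"]])$data == 1
  expect_identical(which(ed), which(res$sim_edema))

  other <- voxel_grid(array(3L, dim = c(8, 8, 2)), c(1, 1, 1))
  expect_error(write_result_masks(res, other, tmp), "dimension mismatch")
})

test_that("study_pair requires co-registered grids and a positive interval", {
  fx <- phantom_fixture()
  st <- make_baseline_study(fx$grid, fx$spec, default_scenarios()[[1]])
  st2 <- st; st2$day <- 30L
  expect_s3_class(study_pair(st, st2), "study_pair")
  expect_identical(study_pair(st, st2)$interval_days, 30L)
  expect_error(study_pair(st2, st), "after baseline")
})
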