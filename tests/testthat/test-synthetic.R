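test_that("datasets round-trip losslessly through delimited text", {
  fx <- generate_fixture(fixture_spec("shmuel", noise_sd = 0.05, seed = 2),
                         ref_params)
  path <- tempfile(fileext = ".csv")
  write_dataset(fx$data, path)
  back <- read_dataset(path)
  expect_equal(back, fx$data, tolerance = 1e-12)
  # unknown columns survive
  d2 <- fx$data
  d2$note <- "x"
  write_dataset(d2, path)
  expect_true("note" %in% names(read_dataset(path)))
  # empty dataset is fine
  write_dataset(fx$data[0, ], path)
  expect_equal(nrow(read_dataset(path)), 0)
})

test_that("malformed datasets are rejected with line numbers", {
  fx <- generate_fixture(fixture_spec("shmuel", noise_sd = 0.05, seed = 2),
                         ref_params)
  path <- tempfile(fileext = ".csv")
  bad <- fx$data
  bad$sem[3] <- 0
  write_dataset(bad, path)
  expect_error(read_dataset(path), "nonpositive sem at line\\(s\\): 4")
  bad <- fx$data
  bad$time[5:6] <- rev(bad$time[5:6])
  write_dataset(bad, path)
  expect_error(read_dataset(path), "nonmonotone time")
  write.csv(data.frame(a = 1), path, row.names = FALSE)
  expect_error(read_dataset(path), "missing required column")
})

test_that("fixtures are reproducible and leave the RNG state alone", {
  spec <- fixture_spec("drew", noise_sd = 0.05, seed = 7)
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  fx1 <- generate_fixture(spec, ref_params)
  after <- rnorm(1)
  expect_identical(before, after)       # generator restored the RNG stream
  fx2 <- generate_fixture(spec, ref_params)
  expect_identical(fx1$data, fx2$data)
  # byte-identical files
  p1 <- tempfile(); p2 <- tempfile()
  write_dataset(fx1$data, p1)
  write_dataset(fx2$data, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # a different seed gives different noise
  fx3 <- generate_fixture(fixture_spec("drew", noise_sd = 0.05, seed = 8),
                          ref_params)
  expect_false(identical(fx1$data$mean, fx3$data$mean))
})

test_that("noise-free fixtures have zero cost at the true vector", {
  fx <- generate_fixture(fixture_spec("drew", noise_sd = 0), ref_params)
  sim <- data.frame(experiment = fx$data$experiment,
                    observable = fx$data$observable,
                    time = fx$data$time, value = fx$clean)
  expect_equal(as.numeric(lsq_cost(sim, fx$data)), 0)
  expect_equal(fx$data$mean, fx$clean)
})

test_that("every template exercises its study's observable kinds", {
  kinds <- list(
    drew = c("diameter_a", "diameter_v"),
    uhlirova = "diameter_a",
    desjardins = c("dHbO", "dHbR", "dHbT", "BOLD"),
    shmuel = c("BOLD", "LFP"),
    huber = c("BOLD", "CBV", "CBF", "CBV_a", "CBV_v")
  )
  for (tmpl in names(kinds)) {
    cfgs <- study_template(tmpl)
    seen <- unique(unlist(lapply(cfgs, function(cfg)
      names(cfg$observables))))
    expect_setequal(seen, kinds[[tmpl]])
  }
  # the Drew template carries the study's printed point count
  n_drew <- sum(vapply(study_template("drew"), function(cfg)
    length(unlist(cfg$observables)), numeric(1)))
  expect_equal(n_drew, 288)
})

test_that("recovery harness reports errors and verdicts per seed", {
  rec <- recovery_harness("drew", free = "ky_PGE2", seeds = 1,
                          half_width = 0.2, noise_sd = 0,
                          use_configs = 2, n_starts = 4, maxit = 60)
  expect_equal(nrow(rec), 1)
  expect_lt(rec$rel_error, 0.05)
  expect_true(rec$pass_fit)
  expect_true(rec$pass_true)
  # zero seeds give an empty report
  rec0 <- recovery_harness("drew", free = "ky_PGE2", seeds = integer(0))
  expect_equal(nrow(rec0), 0)
})

test_that("fixture manifests record the generating specification", {
  spec <- fixture_spec("shmuel", theta_true = c(ky4 = 1.2),
                       noise_sd = 0.05, seed = 9)
  fx <- generate_fixture(spec, ref_params)
  dir <- tempfile()
  paths <- write_fixture(fx, spec, dir)
  expect_true(all(file.exists(paths)))
  man <- yaml::read_yaml(paths[["manifest"]])
  expect_equal(man$template, "shmuel")
  expect_equal(man$seed, 9)
  expect_equal(man$theta_true$ky4, 1.2)
  expect_equal(man$data_hash,
               unname(tools::md5sum(paths[["data"]])))
  expect_equal(man$n_records, nrow(read_dataset(paths[["data"]])))
})
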