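# Orchestration: configuration validation, end-to-end smoke runs, artifacts,
# determinism.

test_that("configuration is schema-validated before any computation", {
  expect_error(experiment_config("h2", active = c(2, 2),
                                 ansatz = list(kind = "nope")), "ansatz kind")
  expect_error(experiment_config("h2", active = c(2, 2), variant = "sgd"),
               "variant")
  expect_error(experiment_config("h2", active = 2))
  cfg <- experiment_config("h2", active = c(2, 2))
  expect_s3_class(cfg, "experiment_config")
})

test_that("h2 experiment runs end to end, quickly and converged", {
  t0 <- Sys.time()
  cfg <- experiment_config("h2", active = c(2, 2), variant = "vqe")
  out <- run_experiment(cfg)
  expect_true(out$vqe$converged)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  expect_equal(sum(out$gamma * out$system$scf$overlap), 2, tolerance = 1e-8)
  expect_equal(sum(out$mulliken$charges), 0, tolerance = 1e-8)
})

test_that("identical configurations give bitwise-identical trajectory files", {
  cfg1 <- experiment_config("h4_chain", active = c(2, 2), variant = "vqe_ld",
                            output_dir = tempfile("runA"))
  cfg2 <- experiment_config("h4_chain", active = c(2, 2), variant = "vqe_ld",
                            output_dir = tempfile("runB"))
  o1 <- run_experiment(cfg1)
  o2 <- run_experiment(cfg2)
  f1 <- readLines(file.path(cfg1$output_dir, "trajectory.csv"))
  f2 <- readLines(file.path(cfg2$output_dir, "trajectory.csv"))
  expect_identical(f1, f2)
  for (fn in c("trajectory.csv", "properties.json", "config.json",
               "final_spatial_rdm.txt", "gamma_ao.txt")) {
    expect_true(file.exists(file.path(cfg1$output_dir, fn)))
  }
})

test_that("non-converged runs still emit artifacts, flagged", {
  cfg <- experiment_config("h4_chain", active = c(2, 2), variant = "vqe",
                           e_tol = 1e-15, max_iterations = 4L,
                           output_dir = tempfile("runNC"))
  out <- run_experiment(cfg)
  expect_false(out$vqe$converged)
  rep <- jsonlite::fromJSON(file.path(cfg$output_dir, "properties.json"))
  expect_false(rep$converged)
  expect_equal(rep$steps, 4)
})

test_that("an f sweep records one run per value with its step count", {
  steps <- vapply(c(0.05, 0.5), function(f) {
    cfg <- experiment_config("h4_chain", active = c(2, 2), variant = "vqe_ld",
                             f = f)
    run_experiment(cfg)$vqe$steps
  }, numeric(1))
  expect_length(unique(steps), 2L)   # the factor demonstrably changes the path
})

test_that("fixtures expose the documented systems", {
  h2 <- make_fixture("h2")
  expect_equal(n_electrons(h2$geometry), 2)
  h4 <- make_fixture("h4_chain", with_scf = TRUE)
  expect_equal(nrow(h4$scf$overlap), 4)
  expect_equal(n_electrons(h4$geometry), 4)
  expect_error(make_fixture("benzene"), "unknown fixture")
})

test_that("headline f defaults follow the reproduction manifest", {
  expect_equal(ch5_f_default(1.3, "kupccgsd"), 0.05)
  expect_equal(ch5_f_default(1.8, "kupccgsd"), 0.1)
  expect_equal(ch5_f_default(1.3, "gatefabric"), 0.7)
  expect_equal(ch5_f_default(1.4, "gatefabric"), 0.9)
})
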