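test_that("every preset configuration round-trips through YAML bit-exactly", {
  for (nm in scenario_names()) {
    cfg <- scenario_config(nm)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_scenario_config(cfg, path)
    back <- read_scenario_config(path)
    expect_identical(unclass(back), unclass(cfg), label = nm)
  }
})

test_that("config overrides follow modifyList semantics", {
  cfg <- scenario_config("wound_ring_tension",
                         list(stop = list(threshold = 0.2)))
  expect_equal(cfg$stop$threshold, 0.2)
  expect_equal(cfg$stop$max_steps, 400L)   # untouched fields survive
  expect_error(scenario_config("not_a_scenario"))
})

test_that("run_preset is deterministic and writes complete outputs", {
  ov <- list(geometry = list(target_edge_length = 0.1),
             stop = list(max_steps = 15L))
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  r1 <- run_preset(scenario_config("crenel_ear", ov), out = out1)
  r2 <- run_preset(scenario_config("crenel_ear", ov), out = out2)
  f1 <- file.path(out1, "observables.csv")
  f2 <- file.path(out2, "observables.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))   # bit-exact reruns
  expect_true(file.exists(file.path(out1, "boundary_final.csv")))
  expect_true(file.exists(file.path(out1, "run.json")))
  vtks <- list.files(out1, pattern = "^snapshot_.*\\.vtk$")
  expect_gte(length(vtks), 2L)   # initial and final states
  meta <- jsonlite::read_json(file.path(out1, "run.json"))
  expect_identical(meta$config$scenario, "crenel_ear")
})

test_that("VTK and PLY snapshots are well-formed text", {
  m <- small_annulus()
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_legacy(m, vtk)
  head <- readLines(vtk, n = 5)
  expect_match(head[1], "vtk DataFile")
  expect_match(head[5], sprintf("POINTS %d double", nrow(m$vertices)))
  ply <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, ply)
  expect_identical(readLines(ply, n = 1), "ply")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_boundary_csv(m, csv)
  df <- utils::read.csv(csv)
  expect_setequal(unique(df$label), c("outer", "hole"))
  expect_true(all(c("x", "y", "s", "kappa") %in% names(df)))
})

test_that("the command-line entry point dispatches and validates", {
  script <- system.file("scripts", "morphosim", package = "morphosim")
  expect_true(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  # configuration errors exit with status 2
  bad <- suppressWarnings(system2(rscript, c(script, "run"),
                                  stdout = TRUE, stderr = TRUE))
  expect_identical(attr(bad, "status"), 2L)
  # fit-closure on a synthetic trace prints the selected law
  tf <- withr::local_tempfile(fileext = ".csv")
  t <- seq(0, 6, length.out = 50)
  utils::write.csv(data.frame(time = t, value = 2 * exp(-t / 3)), tf,
                   row.names = FALSE)
  out <- system2(rscript, c(script, "fit-closure", tf), stdout = TRUE)
  expect_true(any(grepl("selected law: exponential", out)))
})
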