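small_config <- function(n = 60, seed = 1) {
  sweep_config(d_p = c(2e-6, 10e-6), AR = c(1, 10), n_per_group = n,
               seed = seed)
}

test_that("the default configuration encodes the 36-group / 108,000-particle design", {
  cfg <- sweep_config()
  expect_equal(length(cfg$d_p) * length(cfg$AR), 36)
  expect_equal(length(cfg$d_p) * length(cfg$AR) * cfg$n_per_group, 108000)
  expect_equal(sort(cfg$d_p * 1e6), c(1:7, 10, 20))
  expect_equal(sort(cfg$AR), c(1, 3, 10, 30))
  expect_equal(cfg$waveform$bolus, c(0.45, 0.6))
})

test_that("zero particles per group yields empty results without error", {
  cfg <- sweep_config(n_per_group = 0)
  sw <- run_sweep(cfg)
  expect_equal(nrow(sw$results), 36)
  expect_equal(sum(sw$results$n_injected), 0)
  expect_null(sw$records)
})

test_that("per-group accounting sums to the injected count and DE stays in [0, 1]", {
  sw <- run_sweep(small_config())
  r <- sw$results
  expect_equal(r$n_deposited_upper + r$n_deposited_tree + r$n_exited +
                 r$n_airborne, r$n_injected)
  expect_true(all(r$de_upper >= 0 & r$de_upper <= 1))
  expect_true(all(is.nan(r$de_tree) | (r$de_tree >= 0 & r$de_tree <= 1)))
  expect_silent(ledger_check(sw$ledger))
  # the ledger mirrors the per-group results exactly
  expect_equal(sw$ledger$counts$injected, r$n_injected)
  expect_equal(sw$ledger$counts$deposited,
               r$n_deposited_upper + r$n_deposited_tree)
  # particles that entered the tree either deposited there, exited, or are
  # still airborne; records are consistent with the counts
  rec <- sw$records
  expect_equal(sum(rec$status == "deposited"),
               sum(r$n_deposited_upper + r$n_deposited_tree))
})

test_that("the sweep is bit-reproducible from its seed", {
  sw1 <- run_sweep(small_config(n = 40, seed = 7))
  sw2 <- run_sweep(small_config(n = 40, seed = 7))
  expect_identical(sw1$results, sw2$results)
  expect_identical(sw1$records, sw2$records)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_de_table(sw1, f1); write_de_table(sw2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  rf1 <- tempfile(fileext = ".csv"); rf2 <- tempfile(fileext = ".csv")
  write_deposition_records(sw1, rf1); write_deposition_records(sw2, rf2)
  expect_identical(unname(tools::md5sum(rf1)), unname(tools::md5sum(rf2)))
  # a different seed changes the seed-point subsample
  sw3 <- run_sweep(small_config(n = 40, seed = 8))
  expect_false(identical(sw1$records, sw3$records))
})

test_that("exports produce the documented tables and VTK files", {
  sw <- run_sweep(small_config(n = 40))
  # DE table: one row per group and domain
  f <- tempfile(fileext = ".csv")
  tab <- write_de_table(sw, f)
  expect_equal(nrow(tab), 2 * nrow(sw$results))
  expect_equal(names(tab),
               c("d_p_um", "AR", "region", "DE", "n_entered", "n_deposited"))
  got <- read.csv(f)
  expect_equal(nrow(got), 2 * nrow(sw$results))
  # zero-particle groups still tabulate (one row per group and domain);
  # an empty group grid gives a header-only table
  f0 <- tempfile(fileext = ".csv")
  write_de_table(run_sweep(sweep_config(n_per_group = 0,
                                        d_p = c(2e-6, 1e-5),
                                        AR = c(1, 10))), f0)
  expect_equal(nrow(read.csv(f0)), 8) # 2 x 2 groups, 2 domains each
  fe <- tempfile(fileext = ".csv")
  write_de_table(run_sweep(sweep_config(d_p = numeric(0))), fe)
  expect_equal(nrow(read.csv(fe)), 0)
  # VTK deposition map parses back with one vertex per deposited particle
  fv <- tempfile(fileext = ".vtk")
  write_deposition_vtk(sw, fv, "upper")
  lines <- readLines(fv)
  n_dep <- sum(sw$records$status == "deposited" &
                 sw$records$domain == "upper")
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_match(lines[5], sprintf("^POINTS %d float$", n_dep))
  expect_true(any(grepl("SCALARS neighbor_count", lines)))
  # centerline export and waveform csv
  fc <- tempfile(fileext = ".vtk")
  write_centerline_vtk(sw$config$upper, fc)
  expect_match(readLines(fc)[5], "^POINTS 20 float$")
  fw <- tempfile(fileext = ".csv")
  write_waveform_csv(sw$config$waveform, fw)
  wf <- read.csv(fw)
  expect_equal(names(wf), c("t_s", "Q_Lmin"))
  expect_equal(max(wf$Q_Lmin), 90)
  # manifest records seed and configuration
  fm <- tempfile(fileext = ".json")
  write_manifest(sw, fm)
  man <- jsonlite::read_json(fm)
  expect_equal(man$seed, 1)
  expect_equal(man$n_per_group, 40)
})

test_that("a YAML configuration round-trips into an equivalent sweep setup", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "sweep:",
    "  d_p_um: [2, 5]",
    "  ar: [1, 30]",
    "  n_per_group: 10",
    "  seed: 42",
    "waveform:",
    "  tidal_volume_L: 2.95",
    "  peak_flow_Lmin: 90",
    "  duration_s: 3",
    "  rise_time_s: 0.4",
    "lobar_fractions: {LU: 15, LL: 31, RU: 14, RM: 7, RL: 33}",
    "tree:",
    "  root_diameter_m: 2.45e-3",
    "  terminal_diameter_m: 0.5e-3",
    "  n_levels: 4",
    "upper:",
    "  inlet_diameter_m: 0.02",
    "  constriction_ratio: 0.5"
  ), yml)
  cfg <- read_sweep_config(yml)
  expect_s3_class(cfg, "sweep_config")
  expect_equal(cfg$d_p, c(2e-6, 5e-6))
  expect_equal(cfg$AR, c(1, 30))
  expect_equal(cfg$seed, 42L)
  expect_equal(cfg$waveform$t_h, 4 / 3, tolerance = 1e-12)
  expect_equal(sum(!is.na(cfg$tree$segments$outlet)), 16)
  # the configured sweep runs
  sw <- run_sweep(cfg)
  expect_equal(nrow(sw$results), 4)
})
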