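test_that("branch tables round-trip losslessly through CSV", {
  tbl <- as_branch_table(make_branch_tbl())
  path <- withr::local_tempfile(fileext = ".csv")
  write_branch_table(tbl, path)
  back <- read_branch_table(path)
  expect_equal(nrow(back), 3)
  for (col in setdiff(branch_cols, "species_id")) {
    expect_identical(back[[col]], tbl[[col]], label = col)
  }
  expect_identical(back$species_id, tbl$species_id)

  # empty table -> header-only file
  empty <- tbl[0, ]
  write_branch_table(empty, path)
  expect_length(readLines(path), 1)
})

test_that("a simulated table writes one line per record plus header", {
  d <- simulate_branches(sim_config(n_species = 50, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_branch_table(d, path)
  expect_length(readLines(path), 51)
  # noisy diameters legitimately trip no-widening warnings on re-read
  back <- suppressWarnings(read_branch_table(path))
  # downstream fits identical after the round trip
  expect_equal(number_allometry(back)$slope, number_allometry(d)$slope)
  expect_equal(widening_regression(back)$slope,
               widening_regression(d)$slope)
})

test_that("column mapping, unit conversion and total-length fallback work", {
  raw <- make_branch_tbl()
  names(raw) <- c("Species", "NB", "NT", "DB", "DT", "DistB", "DistT")
  raw$DistB <- raw$DistB / 100  # meters
  raw$DistT <- raw$DistT / 100
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw, path)
  got <- read_branch_table(path, column_map = c(
    species_id = "Species", n_base = "NB", n_tip = "NT",
    d_base_um = "DB", d_tip_um = "DT",
    dist_base_cm = "DistB", dist_tip_cm = "DistT"
  ), length_unit = "m")
  expect_equal(got$dist_base_cm, make_branch_tbl()$dist_base_cm)

  expect_error(
    read_branch_table(path, column_map = c(species_id = "Nope")),
    "absent column"
  )

  # total-length-only file: dist_base := total length, tip offset warned
  tot <- data.frame(species_id = "A", n_base = 10, n_tip = 10,
                    d_base_um = 40, d_tip_um = 20, total_length = 300)
  readr::write_csv(tot, path)
  expect_warning(got <- read_branch_table(path, tip_offset_cm = 10),
                 "total branch length")
  expect_equal(got$dist_base_cm, 300)
  expect_equal(got$dist_tip_cm, 10)
})

test_that("daughter-twig columns are summed into n_tip and flagged", {
  raw <- data.frame(species_id = "Wigandia_urens", n_base = 900,
                    d_base_um = 60, d_tip_um = 25,
                    dist_base_cm = 200, dist_tip_cm = 15,
                    twig1 = 400, twig2 = 350, twig3 = 160)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw, path)
  got <- read_branch_table(path, column_map = c(
    n_tip_daughters = "twig1", n_tip_daughters = "twig2",
    n_tip_daughters = "twig3"
  ))
  expect_equal(got$n_tip, 910)
  expect_true(got$branched)
})

test_that("validation flags invariant violations without mutating data", {
  tbl <- make_branch_tbl()
  expect_equal(nrow(validate_branches(tbl)), 0)

  bad <- tbl
  bad$n_base[1] <- 0                       # error
  bad$d_tip_um[2] <- bad$d_base_um[2] + 5  # warning: no widening
  bad$dist_tip_cm[3] <- bad$dist_base_cm[3] + 1  # error: order
  rep <- validate_branches(bad)
  expect_equal(sum(rep$severity == "error"), 2)
  expect_equal(sum(rep$severity == "warning"), 1)
  expect_setequal(rep$row[rep$severity == "error"], c(1L, 3L))

  # flagged rows are still loaded from file
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path)
  expect_warning(got <- read_branch_table(path), "error")
  expect_equal(nrow(got), 3)
  expect_gt(nrow(attr(got, "validation")), 0)

  # report serializes to JSON
  jpath <- withr::local_tempfile(fileext = ".json")
  write_validation_report(rep, jpath)
  expect_equal(length(jsonlite::read_json(jpath)), nrow(rep))
})

test_that("segment length is strictly positive for valid records", {
  d <- simulate_branches(sim_config(n_species = 200, seed = 9))
  expect_true(all(segment_length(d) > 0))
  expect_equal(segment_length(make_branch_tbl()),
               make_branch_tbl()$dist_base_cm -
                 make_branch_tbl()$dist_tip_cm)
})

test_that("missing mandatory columns are named in the error", {
  tbl <- make_branch_tbl()
  expect_error(as_branch_table(tbl[, -2]), "n_base")
})
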