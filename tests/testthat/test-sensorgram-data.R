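test_that("timecourse and sensorgram constructors enforce their invariants", {
  expect_error(timecourse(1, 1), "at least 2")
  expect_error(timecourse(c(0, 1, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(timecourse(c(0, 1), c(1, NA)), "finite")
  d <- timecourse(0:10, 11:1)
  expect_error(sensorgram(list(wash = d), "s"), "unknown phase")
  expect_error(sensorgram(list(dissociation = d), "s", replicate = 0),
               "replicate")
  s <- sensorgram(list(dissociation = d, baseline = d), "s")
  expect_identical(names(s$phases), c("baseline", "dissociation"))
})

test_that("tidy CSV round trip is lossless and grouping is per replicate", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  t1 <- seq(0, 60, by = 0.2)
  sgs <- list(
    sensorgram(list(association = timecourse(t1, 1 - exp(-0.05 * t1)),
                    dissociation = timecourse(t1, exp(-0.012345678 * t1))),
               sample_id = "A", replicate = 1L, analyte_conc = 3.33e-8),
    sensorgram(list(dissociation = timecourse(t1, exp(-0.002 * t1))),
               sample_id = "A", replicate = 2L))
  write_sensorgrams(sgs, tmp)
  back <- read_sensorgrams(tmp)
  expect_length(back, 2L)
  i <- which(vapply(back, `[[`, integer(1L), "replicate") == 1L)
  expect_equal(back[[i]]$phases$dissociation$responses,
               sgs[[1]]$phases$dissociation$responses, tolerance = 1e-12)
  expect_equal(back[[i]]$analyte_conc, 3.33e-8)
  # write -> read -> write byte-stable
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_sensorgrams(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("tidy reader rejects bad files with the offending location", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,replicate,phase,time_s,response",
               "s,1,dissociation,0,1",
               "s,1,dissociation,2,0.9",
               "s,1,dissociation,1,0.8"), tmp)
  expect_error(read_sensorgrams(tmp), "row 4")
  writeLines(c("sample_id,replicate,phase,time_s,response",
               "s,1,elution,0,1"), tmp)
  expect_error(read_sensorgrams(tmp), "unknown phase label 'elution'")
  writeLines(c("sample_id,phase,time_s,response", "s,dissociation,0,1"), tmp)
  expect_error(read_sensorgrams(tmp), "replicate")
})

test_that("wide dialect imports one sensorgram per sensor column", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,S1,S2", "0,1.0,2.0", "1,0.9,1.8", "2,0.8,1.6"), tmp)
  sgs <- read_sensorgrams(tmp, dialect = "wide")
  expect_length(sgs, 2L)
  expect_identical(sgs[[1]]$sample_id, "S1")
  expect_equal(sgs[[2]]$phases$dissociation$responses, c(2, 1.8, 1.6))
  expect_equal(sgs[[1]]$phases$dissociation$times,
               sgs[[2]]$phases$dissociation$times)
})

test_that("reference subtraction is pointwise, interpolating, antisymmetric", {
  x <- timecourse(0:4, c(1, 2, 3, 4, 5))
  expect_equal(reference_subtract(x, x)$responses, rep(0, 5))
  ref <- timecourse(c(-1, 5), c(0.5, 0.5))
  expect_equal(reference_subtract(timecourse(0:2, c(1, 2, 3)), ref)$responses,
               c(0.5, 1.5, 2.5))
  # reference on a 2x coarser grid: linear interpolation by hand
  coarse <- timecourse(c(0, 2), c(0, 1))          # value 0.5 at t = 1
  expect_equal(reference_subtract(timecourse(0:2, c(1, 2, 3)),
                                  coarse)$responses,
               c(1 - 0, 2 - 0.5, 3 - 1))
  # antisymmetry on shared grids
  a <- timecourse(0:9, sin(0:9))
  b <- timecourse(0:9, cos(0:9))
  expect_equal(reference_subtract(a, b)$responses +
                 reference_subtract(b, a)$responses, rep(0, 10))
  # coverage precondition
  short <- timecourse(c(1, 2), c(0, 0))
  expect_error(reference_subtract(a, short), "does not cover")
})

test_that("inter-step alignment removes the boundary jump and records it", {
  t1 <- 0:20
  assoc <- timecourse(t1, 1 - exp(-0.2 * t1))
  a_end <- assoc$responses[21]
  dis <- timecourse(t1, a_end + 0.05 * exp(-0.01 * t1) + 0.05)
  s <- sensorgram(list(association = assoc, dissociation = dis), "s")
  s2 <- align_intersteps(s)
  expect_equal(s2$phases$dissociation$responses[1], a_end)
  expect_match(s2$notes[length(s2$notes)], "inter-step offset")
  # zero jump: unchanged
  dis0 <- timecourse(t1, a_end * exp(-0.01 * t1))
  s0 <- sensorgram(list(association = assoc, dissociation = dis0), "s")
  expect_equal(align_intersteps(s0)$phases$dissociation$responses,
               dis0$responses)
  expect_error(align_intersteps(sensorgram(list(dissociation = dis), "s")),
               "association")
})

test_that("dissociation windowing rebases, is idempotent, guards size", {
  t1 <- seq(0, 600, by = 1)
  s <- sensorgram(list(dissociation = timecourse(t1, exp(-0.001 * t1))), "s")
  w <- dissociation_window(s, 5, 600)
  expect_equal(w$times[1], 0)
  expect_equal(max(w$times), 595)
  expect_equal(w$responses[1], exp(-0.001 * 5))
  # full window = identity up to rebasing
  full <- dissociation_window(s, 0, NULL)
  expect_equal(full$responses, exp(-0.001 * t1))
  # idempotent for the same (full) window
  again <- dissociation_window(full, 0, NULL)
  expect_equal(again$responses, full$responses)
  expect_error(dissociation_window(s, 5, 6), "widen the window")
  expect_error(dissociation_window(s, 300, 200), "t_start < t_end")
})
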