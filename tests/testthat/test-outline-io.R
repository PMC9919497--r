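test_that("CSV reader parses a valid outline and enforces polygon invariants", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "cell_id,embryo_id,plane,structure,domain,x,y",
    "sq1,e1,sagittal,psm,unassigned,0,0",
    "sq1,e1,sagittal,psm,unassigned,10,0",
    "sq1,e1,sagittal,psm,unassigned,10,10",
    "sq1,e1,sagittal,psm,unassigned,0,10"), f)
  out <- read_outlines(f, "csv")
  expect_equal(nrow(out), 1L)
  expect_equal(out$cell_id, "sq1")
  expect_equal(psmet:::polygon_area(out$vertices[[1]]), 100)
  expect_equal(nrow(attr(out, "rejected")), 0L)
})

test_that("malformed records are rejected individually with a logged reason", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "cell_id,embryo_id,plane,structure,domain,x,y",
    "good,e1,sagittal,psm,unassigned,0,0",
    "good,e1,sagittal,psm,unassigned,10,0",
    "good,e1,sagittal,psm,unassigned,5,8",
    "bad2v,e1,sagittal,psm,unassigned,0,0",
    "bad2v,e1,sagittal,psm,unassigned,10,0",
    "bowtie,e1,sagittal,psm,unassigned,0,0",
    "bowtie,e1,sagittal,psm,unassigned,10,10",
    "bowtie,e1,sagittal,psm,unassigned,10,0",
    "bowtie,e1,sagittal,psm,unassigned,0,10"), f)
  expect_message(out <- read_outlines(f, "csv"), "bad2v")
  rej <- attr(out, "rejected")
  expect_setequal(rej$cell_id, c("bad2v", "bowtie"))
  expect_match(rej$reason[rej$cell_id == "bad2v"], "vertices")
  expect_match(rej$reason[rej$cell_id == "bowtie"], "self-intersecting")
  expect_equal(out$cell_id, "good")
})

test_that("outline round trip is vertex-identical in both dialects", {
  field <- generate_outline_field(quiet_truth(), "sagittal", seed = 11,
                                  cells_per_domain = 17)  # 51 outlines
  csv <- withr::local_tempfile(fileext = ".csv")
  write_outlines(field, csv, "csv")
  back <- read_outlines(csv, "csv")
  expect_equal(nrow(back), nrow(field))
  expect_identical(back$cell_id, field$cell_id)
  for (i in seq_len(nrow(field))) {
    expect_identical(unname(back$vertices[[i]]), unname(field$vertices[[i]]))
  }
  # ImageJ ROI stores 16-bit integers: round first, then expect identity
  field_int <- field
  field_int$vertices <- lapply(field$vertices, round)
  field_int <- field_int[vapply(field_int$vertices, psmet:::is_simple_polygon,
                                TRUE), ]
  zipf <- withr::local_tempfile(fileext = ".zip")
  write_outlines(field_int, zipf, "roi_zip")
  back2 <- read_outlines(zipf, "roi_zip", plane = "sagittal")
  back2 <- back2[match(field_int$cell_id, back2$cell_id), ]
  for (i in seq_len(nrow(field_int))) {
    expect_identical(unname(back2$vertices[[i]]),
                     unname(field_int$vertices[[i]]))
  }
})

test_that("readers never return outlines violating type invariants", {
  field <- generate_outline_field(synthetic_truth(), "transverse", seed = 3,
                                  cells_per_domain = 10)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_outlines(field, csv, "csv")
  back <- read_outlines(csv, "csv")
  for (v in back$vertices) {
    expect_gte(nrow(v), 3)
    expect_true(psmet:::is_simple_polygon(v))
    expect_gt(psmet:::polygon_area(v), 0)
  }
})

test_that("time-lapse reader sorts by time and rejects decreasing somite counts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "t_minutes,segmented_length_um,dii_front_to_border_um,psm_length_um,somite_count",
    "40,2100,1800,2000,0",
    "0,2000,1900,2000,0",
    "80,2200,1700,1990,1"), f)
  tab <- read_timelapse(f)
  expect_equal(tab$t_minutes, c(0, 40, 80))
  expect_equal(tab$somite_count, c(0, 0, 1))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "t_minutes,segmented_length_um,dii_front_to_border_um,psm_length_um,somite_count",
    "0,2000,1900,2000,5",
    "40,2100,1800,2000,4"), bad)
  expect_error(read_timelapse(bad), "row 2")
})

test_that("synthetic time-lapse tracks round-trip losslessly", {
  track <- generate_timelapse(synthetic_truth(), seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_timelapse(track, f)
  back <- read_timelapse(f)
  expect_equal(as.data.frame(back), as.data.frame(track))
})
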