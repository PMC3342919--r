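write_records_csv <- function(df) {
  tmp <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write.csv(df, tmp, row.names = FALSE)
  tmp
}

valid_record <- function(facility = "F1", chem = "Lead", lon = 5, lat = 5,
                         kg = 10) {
  data.frame(facility_id = facility, cas_number = "7439-92-1",
             chemical_name = chem, lon = lon, lat = lat, release_kg_yr = kg)
}

test_that("read_discharge_table round-trips and reports malformed rows", {
  ten <- do.call(rbind, lapply(1:10, function(i)
    valid_record(sprintf("F%02d", i), lon = i, lat = i + 1, kg = i * 2)))
  got <- read_discharge_table(write_records_csv(ten))
  expect_equal(nrow(got), 10)
  expect_equal(got$release_kg_yr, ten$release_kg_yr)
  expect_equal(got$lon, ten$lon)
  expect_equal(got$facility_id, ten$facility_id)

  hdr_only <- ten[0, ]
  expect_equal(nrow(read_discharge_table(write_records_csv(hdr_only))), 0)

  bad <- ten
  bad$release_kg_yr <- as.character(bad$release_kg_yr)
  bad$release_kg_yr[4] <- "not-a-number"
  expect_warning(got2 <- read_discharge_table(write_records_csv(bad)),
                 "malformed")
  expect_equal(nrow(got2), 9)
  expect_equal(attr(got2, "malformed")$row, 4)

  noc <- ten[, -6]
  expect_error(read_discharge_table(write_records_csv(noc)), "release_kg_yr")
})

test_that("staged filters match hand-applied rules on a 10-record fixture", {
  region <- c(0, 10, 0, 10)
  fx <- rbind(
    valid_record("A", kg = 0),                       # zero release
    valid_record("B", kg = 0),                       # zero release
    valid_record("C", lon = 50, lat = 50),           # outside region
    valid_record("D", lon = 0, lat = 0),             # anomalous coordinates
    valid_record("E", kg = 7), valid_record("E", kg = 7),  # identical facility
    valid_record("G", kg = 1), valid_record("G", kg = 2),  # survives
    valid_record("H", kg = 3),                       # survives
    valid_record("I", kg = 4))                       # survives
  filt <- filter_records(fx, region = region)
  expect_equal(nrow(filt$clean), 4)
  expect_setequal(filt$clean$facility_id, c("G", "H", "I"))
  rej <- filt$rejections
  expect_equal(rej$reason[match(c(1, 2), rej$row)],
               c("zero_release", "zero_release"))
  expect_equal(rej$reason[match(3, rej$row)], "outside_region")
  expect_equal(rej$reason[match(4, rej$row)], "anomalous_coordinates")
  expect_equal(rej$reason[match(c(5, 6), rej$row)],
               rep("identical_values_facility", 2))
  # partition: clean + rejected = input, each rejected row logged once
  expect_equal(nrow(filt$clean) + nrow(rej), nrow(fx))
  expect_false(anyDuplicated(rej$row) > 0)
  # idempotence
  again <- filter_records(filt$clean, region = region)
  expect_equal(nrow(again$rejections), 0)
  expect_equal(again$clean$release_kg_yr, filt$clean$release_kg_yr)
  # empty input is legal
  none <- filter_records(fx[0, ], region = region)
  expect_equal(nrow(none$clean), 0)
  expect_equal(nrow(none$rejections), 0)
})

test_that("single-record facilities are never 'identical values'", {
  fx <- valid_record("solo", kg = 5)
  filt <- filter_records(fx, region = c(0, 10, 0, 10))
  expect_equal(nrow(filt$clean), 1)
})

test_that("chemical-subset restriction is stage 1", {
  fx <- valid_record("X", chem = "Dihydrogen monoxide", kg = 0)
  filt <- filter_records(fx, region = c(0, 10, 0, 10))
  expect_equal(filt$rejections$reason, "not_in_chemical_subset")
  expect_equal(filt$rejections$stage, 1L)
})

test_that("watershed assignment sums per shed and chemical, conserving mass", {
  net <- watershed_network(data.frame(
    shed_id = 1:2, area_acres = c(100, 100), downstream_id = c(NA, 1L),
    seed_x = c(2, 8), seed_y = c(5, 5)))
  one <- valid_record("F1", lon = 1, lat = 5, kg = 5)
  got <- assign_watersheds(one, net)
  expect_equal(got$shed_id, 1L)
  expect_equal(got$release_kg_yr, 5)
  two <- rbind(valid_record("F1", lon = 1, lat = 5, kg = 2),
               valid_record("F2", lon = 2.5, lat = 5, kg = 3))
  expect_equal(assign_watersheds(two, net)$release_kg_yr, 5)

  set.seed(21)
  wt <- load_weight_table()
  rec <- data.frame(facility_id = sprintf("F%03d", 1:200),
                    cas_number = "x",
                    chemical_name = sample(wt$chemical_name, 200, TRUE),
                    lon = runif(200, 0, 10), lat = runif(200, 0, 10),
                    release_kg_yr = runif(200, 0.1, 50))
  got <- assign_watersheds(rec, net)
  expect_equal(sum(got$release_kg_yr), sum(rec$release_kg_yr))
  # independent group-by oracle
  shed <- ifelse((rec$lon - 2)^2 + (rec$lat - 5)^2 <=
                   (rec$lon - 8)^2 + (rec$lat - 5)^2, 1L, 2L)
  oracle <- tapply(rec$release_kg_yr, list(shed, rec$chemical_name), sum)
  for (r in seq_len(nrow(got)))
    expect_equal(got$release_kg_yr[r],
                 unname(oracle[as.character(got$shed_id[r]),
                               got$chemical_name[r]]))
})
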