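test_that("pileup tables parse, group and round-trip", {
  df <- rbind(
    make_pileup_row(pos = 100, alt_duplex = 2, alt_single = 8),
    make_pileup_row(pos = 200, alt_duplex = 0, alt_single = 3),
    make_pileup_row(pos = 300, alt_duplex = 1, alt_single = 0)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pileup_table(df, path)
  back <- read_pileup_table(path)
  expect_equal(nrow(back), 3)
  expect_equal(unique(back$sample_id), "S1")
  expect_identical(back$depth, df$depth)
  expect_identical(back$alt_duplex, df$alt_duplex)
  expect_identical(back$alt_single, df$alt_single)
})

test_that("header-only pileup file yields an empty table without error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("sample_id", "patient_id", "sample_type",
                     "collection_day", "chrom", "pos", "ref", "alt",
                     "depth", "alt_duplex", "alt_single"), collapse = "\t"),
             path)
  expect_equal(nrow(read_pileup_table(path)), 0)
})

test_that("pileup invariant violations are rejected with row context", {
  bad_sum <- make_pileup_row(depth = 10, alt_duplex = 6, alt_single = 5)
  expect_error(validate_pileup(bad_sum), "alt counts exceed depth")
  expect_error(validate_pileup(make_pileup_row(alt_duplex = -1)),
               "negative count")
  expect_error(validate_pileup(make_pileup_row(ref = "A", alt = "A")),
               "ref equals alt")
  expect_error(validate_pileup(make_pileup_row(sample_type = "serum")),
               "unknown sample_type")
  dup <- rbind(make_pileup_row(), make_pileup_row())
  expect_error(validate_pileup(dup), "duplicate site")
  # errors from files carry the row number
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pileup_table(make_pileup_row(), path)
  txt <- readLines(path)
  txt[2] <- sub("1000\t2\t8", "5\t2\t8", txt[2])
  writeLines(txt, path)
  expect_error(read_pileup_table(path), "row\\(s\\): 1")
})

test_that("missing pileup columns raise a format error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- make_pileup_row()
  utils::write.table(df[, -which(names(df) == "alt_single")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_pileup_table(path), "missing column.*alt_single")
})

test_that("patient manifests parse with absent markers and validations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,afp,dcp,rfs_days,relapse_event,age",
    "P1,25.5,30,400,1,63",
    "P2,3.2,,183,0,51"
  ), path)
  m <- read_patient_manifest(path)
  expect_equal(nrow(m), 2)
  expect_true(is.na(m$dcp[2]))
  expect_equal(m$afp[1], 25.5)
  expect_identical(m$relapse_event, c(TRUE, FALSE))
  expect_equal(m$age, c(63L, 51L))

  writeLines(c("patient_id,afp,dcp,rfs_days,relapse_event",
               "P1,5,10,0,0"), path)
  expect_error(read_patient_manifest(path), "rfs_days")
  writeLines(c("patient_id,afp,dcp,rfs_days,relapse_event",
               "P1,5,10,100,0", "P1,6,11,200,1"), path)
  expect_error(read_patient_manifest(path), "duplicate patient_id")
})

test_that("screened mutation tables round-trip bit-exactly", {
  scr <- data.frame(
    patient_id = c("P1", "P2"), chrom = "chr2", pos = c(5L, 5L),
    ref = "C", alt = "G",
    vaf_pre = c(1 / 3, 0.02), pre_depth = c(900L, 1500L),
    vaf_post = c(2 / 3000, NA), post_depth = c(3000L, NA),
    mvfc = c((2 / 3000) / (1 / 3), NA),
    mvfc_class = c("tumor", "unevaluable"), stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screened_mutations(scr, path)
  back <- read_screened_mutations(path)
  expect_identical(back$pos, scr$pos)
  expect_identical(back$vaf_pre, scr$vaf_pre)   # bit-exact round trip
  expect_identical(back$mvfc, scr$mvfc)
  expect_identical(back$mvfc_class, scr$mvfc_class)
  # same site in different patients is legal and both rows survive
  expect_equal(nrow(back), 2)
  # empty collection -> header-only file
  write_screened_mutations(scr[0, ], path)
  expect_equal(nrow(read_screened_mutations(path)), 0)
})

test_that("VCF import maps FORMAT fields into pileup columns", {
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=DX,Number=1,Type=Integer,Description=\"Duplex alt\">",
    "##FORMAT=<ID=SX,Number=1,Type=Integer,Description=\"Single alt\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t1000\t.\tA\tT\t.\tPASS\t.\tDP:DX:SX\t1200:3:7\t1100:0:1",
    "chr2\t2000\t.\tG\tC\t.\tPASS\t.\tDP:DX:SX\t900:0:0\t800:2:2",
    "chr3\t3000\t.\tT\tTA\t.\tPASS\t.\tDP:DX:SX\t500:1:1\t400:1:1"
  ), path)
  info <- data.frame(sample_id = c("S1", "S2"), patient_id = "P1",
                     sample_type = c("pre_plasma", "post_plasma"),
                     collection_day = c(-1L, 30L))
  pu <- read_pileup_vcf(path, info)
  expect_equal(nrow(pu), 4)   # indel row dropped, 2 SNVs x 2 samples
  s1 <- pu[pu$sample_id == "S1" & pu$pos == 1000, ]
  expect_equal(s1$depth, 1200L)
  expect_equal(s1$alt_duplex, 3L)
  expect_equal(s1$alt_single, 7L)
  expect_equal(unique(pu$sample_type[pu$sample_id == "S2"]), "post_plasma")
})

test_that("config files round-trip through calling and simulation settings", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "calling:",
    "  mvfc_threshold: 0.25",
    "  min_depth: 200",
    "simulation:",
    "  seed: 9",
    "  n_patients: 4",
    "  tumor_vaf_range: [0.01, 0.04]",
    "evaluate:",
    "  times: [183, 365]"
  ), path)
  cfg <- read_config(path)
  expect_s3_class(cfg$calling, "calling_config")
  expect_equal(cfg$calling$mvfc_threshold, 0.25)
  expect_equal(cfg$calling$min_depth, 200L)
  expect_equal(cfg$calling$alpha, 0.01)  # default preserved
  expect_equal(cfg$simulation$n_patients, 4L)
  expect_equal(cfg$simulation$tumor_vaf_range, c(0.01, 0.04))
  expect_equal(cfg$evaluate$times, c(183, 365))
})

test_that("invalid configuration values are rejected", {
  expect_error(calling_config(alpha = 0), "alpha")
  expect_error(calling_config(mvfc_threshold = 1), "mvfc_threshold")
  expect_error(calling_config(min_depth = 0), "min_depth")
  expect_error(simulation_config(residual_ratio = 1), "residual_ratio")
  expect_error(simulation_config(frac_mrd_positive = 1.2),
               "frac_mrd_positive")
  expect_error(simulation_config(tumor_vaf_range = c(0.05, 0.01)),
               "tumor_vaf_range")
})
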