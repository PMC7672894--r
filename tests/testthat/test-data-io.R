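test_that("delimited tables are read, validated and round-tripped", {
  tf <- tempfile(fileext = ".tsv")
  df <- data.frame(chr = "chr1", from = 1:3, ref = "A", alt = "T",
                   DP = c(100L, 100L, 100L), NV = c(50L, 10L, 99L))
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- read_freq_table(tf)
  expect_equal(d$n, 3)
  expect_equal(d$data$frequency, c(0.5, 0.1, 0.99))
  expect_equal(d$frequency_kind, "VAF")

  # missing required column is a configuration error naming the column
  df2 <- df
  df2$NV <- NULL
  write.table(df2, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_freq_table(tf), "'NV'")

  # out-of-range frequency is a validation error citing the record
  df3 <- data.frame(chr = "chr1", from = 1:2, ref = "A", alt = "T",
                    VAF = c(0.4, 1.2), id = c("ok", "bad"))
  write.table(df3, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_freq_table(tf), "bad")

  # comma-separated files are sniffed
  tfc <- tempfile(fileext = ".csv")
  write.csv(df, tfc, row.names = FALSE, quote = FALSE)
  expect_equal(read_freq_table(tfc)$data$frequency, c(0.5, 0.1, 0.99))

  # write -> read preserves n and frequencies on simulator output
  sim <- simulate_dataset(simulation_config(mu_sim = 10, driver_time = NA,
                                            sampling_time = 12, seed = 7))
  out <- tempfile(fileext = ".tsv")
  write_freq_table(sim$dataset, out)
  back <- read_freq_table(out)
  expect_equal(back$n, sim$dataset$n)
  expect_equal(back$data$frequency, sim$dataset$data$frequency,
               tolerance = 1e-9)
})

test_that("inconsistent read counts are rejected", {
  expect_error(
    freq_dataset(data.frame(depth = 10L, alt_reads = 12L)),
    "exceeds depth")
  expect_error(
    freq_dataset(data.frame(depth = 10L, alt_reads = 5L, vaf = 0.9)),
    "alt_reads/depth")
})

test_that("CCF values are halved and bounded", {
  expect_equal(adjust_ccf(1.0), 0.5)   # clonal -> expected diploid VAF
  expect_equal(adjust_ccf(0.0), 0.0)
  expect_equal(adjust_ccf(1.8), 0.9)   # multi-copy states are legal
  expect_error(adjust_ccf(2.2), "not representable")
  expect_error(adjust_ccf(-0.1), "negative")

  d <- freq_dataset(data.frame(ccf = c(1, 0.6)), frequency_kind = "CCF")
  expect_equal(d$data$frequency, c(0.5, 0.3))
  expect_equal(d$frequency_kind, "CCF_halved")
})

test_that("frequency filtering is strict, idempotent and validated", {
  d <- freq_dataset(data.frame(vaf = c(0.02, 0.05, 0.30)))
  f <- filter_dataset(d, 0.05)
  expect_equal(f$n, 1)  # "above 5%" excludes the boundary value
  expect_equal(f$data$frequency, 0.30)
  expect_equal(f$min_frequency, 0.05)

  clean <- freq_dataset(data.frame(vaf = c(0.1, 0.4, 0.9)))
  expect_equal(filter_dataset(clean, 0)$data, clean$data)

  ff <- filter_dataset(filter_dataset(d, 0.04), 0.04)
  expect_equal(ff$data, filter_dataset(d, 0.04)$data)

  expect_error(filter_dataset(d, 0.95), "lower the cutoff")
})

test_that("VCF input is parsed from per-sample FORMAT fields", {
  vcf <- tempfile(fileext = ".vcf")
  write_vcf_fixture(vcf, data.frame(
    chrom = "chr1", pos = c(100L, 200L), ref = "A", alt = "G",
    depth = c(100L, 80L), alt_reads = c(40L, 20L)))
  d <- read_freq_vcf(vcf)
  expect_equal(d$n, 2)
  expect_equal(d$data$frequency, c(0.4, 0.25))

  expect_error(read_freq_vcf(vcf, sample = "nope"), "TUMOUR")

  # zero-depth records are dropped with a warning
  write_vcf_fixture(vcf, data.frame(
    chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "G",
    depth = c(50L, 0L), alt_reads = c(10L, 0L)))
  expect_warning(d0 <- read_freq_vcf(vcf), "zero depth")
  expect_equal(d0$n, 1)

  # synthetic 100-variant fixture round-trips exactly
  set.seed(99)
  n <- 100
  depth <- rpois(n, 100) + 1L
  alt <- rbinom(n, depth, runif(n, 0.05, 0.95))
  write_vcf_fixture(vcf, data.frame(
    chrom = "chr2", pos = seq_len(n), ref = "C", alt = "T",
    depth = depth, alt_reads = alt))
  d100 <- read_freq_vcf(vcf)
  expect_equal(d100$n, n)
  expect_equal(d100$data$frequency, alt / depth)

  # multiallelic rows: skipped by default, split on request
  lines <- readLines(write_vcf_fixture(vcf, data.frame(
    chrom = "chr3", pos = 1L, ref = "A", alt = "G",
    depth = 90L, alt_reads = 30L)))
  lines <- c(lines,
             "chr3\t5\t.\tA\tG,T\t.\tPASS\t.\tGT:AD:DP\t0/1:50,30,20:100")
  writeLines(lines, vcf)
  expect_message(dm <- read_freq_vcf(vcf), "multiallelic")
  expect_equal(dm$n, 1)  # only the biallelic row survives
  ds <- read_freq_vcf(vcf, multiallelic = "split")
  expect_equal(sort(ds$data$frequency), sort(c(30 / 90, 0.3, 0.2)))
})
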