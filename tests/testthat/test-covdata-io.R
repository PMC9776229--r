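test_that("gene symbols are parsed as the prefix before the first separator", {
  expect_equal(parse_gene("BRCA1_exon24"), "BRCA1")
  expect_equal(parse_gene("TP53"), "TP53")
  expect_equal(parse_gene("EGFR_ex19_del"), "EGFR")
  expect_equal(parse_gene("KMT2A-ex1", separator = "-"), "KMT2A")
})

write_covdata_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a covdata file with the standard field list reads correctly", {
  path <- write_covdata_fixture(c(
    "chrom\tstart\tend\tregion\t5X\t10X\t50X\t100X\t250X\t500X",
    "chr17\t41196311\t41196411\tBRCA1_ex24\t100\t100\t98\t95\t60\t10"))
  cd <- read_covdata(path, samples = "S01")
  expect_equal(nrow(cd$regions), 1)
  expect_equal(cd$regions$end - cd$regions$start, 100)
  expect_equal(cd$regions$gene, "BRCA1")
  expect_equal(cd$depths, c(5L, 10L, 50L, 100L, 250L, 500L))
  expect_equal(as.vector(cd$counts[1, , 1]), c(100, 100, 98, 95, 60, 10))
})

test_that("depth columns are reordered ascending regardless of file order", {
  path <- write_covdata_fixture(c(
    "chrom\tstart\tend\tregion\t500X\t5X\t100X",
    "chr1\t0\t100\tG_ex1\t10\t90\t50"))
  cd <- read_covdata(path)
  expect_equal(cd$depths, c(5L, 100L, 500L))
  expect_equal(as.vector(cd$counts[1, , 1]), c(90, 50, 10))
})

test_that("a header-only covdata file yields an empty table without error", {
  path <- write_covdata_fixture(
    "chrom\tstart\tend\tregion\t5X\t10X\t50X\t100X\t250X\t500X")
  cd <- read_covdata(path)
  expect_equal(nrow(cd$regions), 0)
  expect_equal(length(cd$samples), 1)
})

test_that("covdata validation errors name the offending column, region and sample", {
  miss <- write_covdata_fixture(c("chrom\tstart\tregion\t5X",
                                  "chr1\t0\tG_ex1\t10"))
  expect_error(read_covdata(miss), "end")

  over <- write_covdata_fixture(c("chrom\tstart\tend\tregion\t5X",
                                  "chr1\t0\t100\tG_ex1\t150"))
  expect_error(read_covdata(over, samples = "SA"), "G_ex1.*SA")

  nonmono <- write_covdata_fixture(c("chrom\tstart\tend\tregion\t5X\t10X",
                                     "chr1\t0\t100\tG_ex1\t50\t60"))
  expect_error(read_covdata(nonmono), "increase with depth")
  expect_warning(read_covdata(nonmono, lenient = TRUE),
                 "increase with depth")

  dup <- write_covdata_fixture(c("chrom\tstart\tend\tregion\t5X",
                                 "chr1\t0\t100\tG_ex1\t50",
                                 "chr1\t0\t100\tG_ex1\t40"))
  expect_error(read_covdata(dup), "duplicated region key")
})

test_that("covdata round-trips through both dialects", {
  for (seed in 1:3) {
    cd <- random_covdata(seed)

    wide <- withr::local_tempfile(fileext = ".tsv")
    write_covdata(cd, wide, dialect = "wide")
    back <- read_covdata(wide)
    expect_equal(back$depths, cd$depths)
    expect_equal(back$samples, cd$samples)
    expect_equal(back$regions, cd$regions)
    expect_equal(back$counts, cd$counts)

    dir <- withr::local_tempdir()
    paths <- write_covdata(cd, dir, dialect = "per_sample")
    back2 <- read_covdata(paths, samples = cd$samples)
    expect_equal(back2$counts, cd$counts)
    expect_equal(back2$regions, cd$regions)
  }
})

test_that("per-base tracks materialize over targets with absent bases as zero", {
  targets <- data.frame(chrom = "chr1", start = 0L, end = 100L,
                        region_id = "G_ex1", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")

  writeLines(c("chr1\t0\t50\t100", "chr1\t50\t100\t100"), path)
  pr <- read_perbase(path, targets, "S01")
  expect_length(pr, 1)
  expect_equal(pr[[1]]$depth, rep(100L, 100))

  writeLines("chr1\t0\t40\t77", path)
  pr <- read_perbase(path, targets, "S01")
  expect_equal(pr[[1]]$depth, c(rep(77L, 40), rep(0L, 60)))

  writeLines(c("chr1\t0\t50\t100", "chr1\t40\t100\t90"), path)
  expect_error(read_perbase(path, targets, "S01"), "overlapping")
})

test_that("run-length encoding round-trips arbitrary depth arrays", {
  set.seed(11)
  targets <- data.frame(chrom = "chr1",
                        start = c(0L, 500L), end = c(200L, 650L),
                        region_id = c("A_ex1", "B_ex1"),
                        stringsAsFactors = FALSE)
  for (rep in 1:5) {
    depths <- lapply(targets$end - targets$start, function(n) {
      as.integer(sample(c(0, 5, 80, 500), n, replace = TRUE))
    })
    profiles <- lapply(seq_len(nrow(targets)), function(i) {
      perbase_profile(targets$chrom[i], targets$start[i], targets$end[i],
                      targets$region_id[i], "S01", depths[[i]])
    })
    path <- withr::local_tempfile(fileext = ".bed")
    write_perbase(profiles, path)
    back <- read_perbase(path, targets, "S01")
    for (i in seq_along(back)) {
      expect_equal(back[[i]]$depth, depths[[i]])
    }
    # coordinate conservation
    expect_equal(sum(lengths(lapply(back, `[[`, "depth"))),
                 sum(targets$end - targets$start))
  }
})

test_that("BED output follows the format and its sortedness contract", {
  path <- withr::local_tempfile(fileext = ".bed")
  rec <- data.frame(chrom = "chr1", start = 10L, end = 20L,
                    name = "BRCA1_ex2", stringsAsFactors = FALSE)
  write_bed(rec, path)
  expect_equal(readLines(path), "chr1\t10\t20\tBRCA1_ex2")

  write_bed(rec[0, ], path)
  expect_equal(length(readLines(path)), 0)

  unsorted <- data.frame(chrom = "chr1", start = c(50L, 10L),
                         end = c(60L, 20L), name = c("b", "a"),
                         stringsAsFactors = FALSE)
  expect_error(write_bed(unsorted, path), "not sorted")
  write_bed(unsorted, path, auto_sort = TRUE)
  expect_equal(readLines(path), c("chr1\t10\t20\ta", "chr1\t50\t60\tb"))

  bad <- data.frame(chrom = "chr1", start = 1L, end = 2L, name = "x",
                    score = 1200, stringsAsFactors = FALSE)
  expect_error(write_bed(bad, path), "score")
})

test_that("BED records round-trip through write and read", {
  set.seed(3)
  start <- sort(sample(0:10000, 20))
  rec <- data.frame(chrom = "chr2", start = start, end = start + 50L,
                    name = sprintf("G%02d_ex1", 1:20),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(rec, path)
  back <- read_bed(path)
  expect_equal(back$start, rec$start)
  expect_equal(back$end, rec$end)
  expect_equal(back$region_id, rec$name)
})

test_that("track files carry a declaration line over an identical BED body", {
  rec <- data.frame(chrom = "chr1", start = c(5L, 30L), end = c(15L, 40L),
                    name = c("d1", "d2"), score = c(900, 500),
                    stringsAsFactors = FALSE)
  bed <- withr::local_tempfile(fileext = ".bed")
  trk <- withr::local_tempfile(fileext = ".bed")
  write_bed(rec, bed)
  write_track(rec, trk, track_name = "drops")
  lines <- readLines(trk)
  expect_match(lines[1], '^track name="drops"')
  expect_identical(lines[-1], readLines(bed))

  write_track(rec[0, ], trk, track_name = "empty")
  expect_equal(length(readLines(trk)), 1)
})
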