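test_that("SAM reading preserves TLEN sign convention and pair count", {
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chrS\tLN:100000",
           "p1\t99\tchrS\t1000\t60\t150M\t=\t1150\t300\t*\t*",
           "p1\t147\tchrS\t1150\t60\t150M\t=\t1000\t-300\t*\t*")
  f <- write_temp_lines(sam, ".sam")
  recs <- read_sam_pairs(f)
  expect_equal(nrow(recs), 2L)
  expect_setequal(recs$tlen, c(300L, -300L))
  expect_equal(recs$mapq, c(60L, 60L))
  expect_equal(recs$read_id, c("p1", "p1"))
})

test_that("a generated SAM with n pairs yields 2n records", {
  sim <- simulate_read_pairs(n_background_pairs = 80, decoy_fraction = 0,
                             seed = 11)
  f <- write_temp_lines(sim$sam_lines, ".sam")
  recs <- read_sam_pairs(f)
  expect_equal(nrow(recs), 160L)
  # round trip: file view agrees with the generator's in-memory records
  key <- function(d) d[order(d$read_id, d$tlen),
                       c("read_id", "chrom", "pos", "mapq", "tlen",
                         "is_reverse", "mate_is_reverse")]
  expect_equal(key(recs), key(sim$records), ignore_attr = TRUE)
})

test_that("region queries honour the header: empty region vs unknown contig", {
  sim <- simulate_read_pairs(reference = c(chrS = 200000L, chrN = 50000L),
                             n_background_pairs = 40, decoy_fraction = 0,
                             seed = 2)
  f <- write_temp_lines(sim$sam_lines, ".sam")
  all_recs <- read_sam_pairs(f)
  on_n <- read_sam_pairs(f, region = genomic_interval("chrN", 1, 50000))
  expect_true(nrow(on_n) < nrow(all_recs))
  expect_true(all(on_n$chrom == "chrN"))
  expect_error(read_sam_pairs(f, region = genomic_interval("chrZ", 1, 10)),
               "chrZ")
})

test_that("malformed SAM lines are reported with their line number", {
  sam <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chrS\tLN:1000",
           "ok\t99\tchrS\t10\t60\t10M\t=\t50\t50\t*\t*",
           "broken\t99\tchrS\t10")
  f <- write_temp_lines(sam, ".sam")
  expect_error(read_sam_pairs(f), "line 4")
})

test_that("BED output is 0-based half-open and round-trips losslessly", {
  calls <- data.frame(chrom = "chr1", start = 1392270L, end = 1460317L,
                      sv_type = "dup", support = 6L, source = "discordant",
                      rank = 1L, stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".bed")
  write_cnv_bed(calls, f)
  lines <- readLines(f)
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_equal(fields[2], "1392269")
  expect_equal(fields[3], "1460317")
  expect_equal(fields[4], "dup:6:discordant")
  expect_equal(read_cnv_bed(f), calls)
})

test_that("an empty call set writes a header-only BED that reads back empty", {
  f <- tempfile(fileext = ".bed")
  write_cnv_bed(data.frame(), f)
  expect_true(startsWith(readLines(f)[1], "#"))
  expect_equal(nrow(read_cnv_bed(f)), 0L)
})

test_that("BED round trip preserves arbitrary call sets", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(1:20, 1)
    start <- sample.int(1e6, n)
    calls <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                        start = start,
                        end = start + sample.int(1e5, n),
                        sv_type = sample(c("dup", "del", "unknown"), n, TRUE),
                        support = sample.int(50, n),
                        source = sample(c("discordant", "depth", "consensus"),
                                        n, TRUE),
                        rank = seq_len(n), stringsAsFactors = FALSE)
    f <- tempfile(fileext = ".bed")
    write_cnv_bed(calls, f)
    expect_equal(read_cnv_bed(f), calls)
  }
})

test_that("trio VCF reading maps genotypes, splits ALTs and flags male X hets", {
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1>", "##contig=<ID=chrX>",
           "##INFO=<ID=GNOMAD_AF,Number=A,Type=Float,Description=\"af\">",
           "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"cls\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"gene\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"csq\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tPROBAND\tMOTHER\tFATHER",
           "chr1\t100\t.\tA\tT\t50\tPASS\tGNOMAD_AF=0;CLNSIG=pathogenic;GENE=MYH7;CSQ=missense\tGT\t0/1\t0/0\t0/0",
           "chr1\t200\t.\tG\tA,C\t50\tPASS\tGNOMAD_AF=0.01,0.002;CLNSIG=benign;GENE=TTN;CSQ=other\tGT\t1/2\t0/1\t0/2",
           "chr1\t300\t.\tC\tT\t50\tPASS\tGNOMAD_AF=0;CLNSIG=vus;GENE=ACTC1;CSQ=missense\tGT\t./.\t0/0\t0/1",
           "chrX\t70000000\t.\tC\tT\t50\tPASS\tGNOMAD_AF=0;CLNSIG=pathogenic;GENE=NONO;CSQ=lof\tGT\t0/1\t0/1\t0")
  f <- write_temp_lines(vcf, ".vcf")
  ped <- c(proband = "PROBAND", mother = "MOTHER", father = "FATHER")
  v <- read_trio_vcf(f, ped, proband_sex = "M")
  expect_equal(nrow(v), 5L)  # biallelic site contributes two rows
  expect_equal(v$gt_proband[v$pos == 100], "het")
  expect_equal(v$gt_mother[v$pos == 100], "hom_ref")
  # multi-allelic: proband 1/2 is het for each ALT separately
  two <- v[v$pos == 200, ]
  expect_equal(two$alt, c("A", "C"))
  expect_equal(two$gt_proband, c("het", "het"))
  expect_equal(two$gt_mother, c("het", "hom_ref"))
  expect_equal(two$af_pop, c(0.01, 0.002))
  expect_equal(v$gt_proband[v$pos == 300], "missing")
  # male non-PAR X diploid het: kept and flagged, not converted
  x <- v[v$chrom == "chrX", ]
  expect_equal(x$gt_proband, "het")
  expect_true(x$x_het_male)
  expect_equal(x$gt_father, "hom_ref")  # haploid reference call
  expect_error(read_trio_vcf(f, c(proband = "NOPE", mother = "MOTHER",
                                  father = "FATHER")), "NOPE")
})

test_that("generator VCF round-trips through the reader with annotations intact", {
  tt <- rbind(trio_truth("ar_homozygous", "HADHB"),
              trio_truth("de_novo", "MYH7"))
  sim <- simulate_trio_vcf(tt, n_noise = 50, proband_sex = "F", seed = 21)
  f <- write_temp_lines(sim$vcf_lines, ".vcf")
  v <- read_trio_vcf(f, c(proband = "PROBAND", mother = "MOTHER",
                          father = "FATHER"), proband_sex = "F")
  expect_equal(nrow(v), nrow(sim$variants))
  keys_in <- paste(sim$variants$chrom, sim$variants$pos, sim$variants$ref,
                   sim$variants$alt, sep = ":")
  keys_out <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  expect_setequal(keys_out, keys_in)
  m <- match(keys_in, keys_out)
  expect_equal(v$gt_proband[m], sim$variants$gt_proband)
  expect_equal(v$gt_mother[m], sim$variants$gt_mother)
  expect_equal(v$clinical_class[m], sim$variants$clinical_class)
  expect_equal(v$gene[m], sim$variants$gene)
  expect_equal(v$af_pop[m], sim$variants$af_pop, tolerance = 1e-3)
})
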