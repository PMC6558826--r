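test_that("VCF genotypes are coded as alternate-allele dosage", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb\tc",
    "c1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "c1\t200\tsnp2\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|0\t./."), vcf)
  p <- read_genotypes(vcf, "vcf")
  expect_equal(unname(p$geno[, "snp1"]), c(0L, 1L, 2L))
  expect_equal(unname(p$geno[, "snp2"]), c(2L, 0L, NA_integer_))
  expect_equal(p$map$pos, c(100L, 200L))
})

test_that("non-biallelic VCF sites are skipped with a message", {
  vcf <- tempfile(fileext = ".vcf")
  body <- sprintf("c1\t%d\ts%d\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1", (1:5) * 100, 1:5)
  body[3] <- "c1\t300\ts3\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1"
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
               body), vcf)
  expect_message(p <- read_genotypes(vcf, "vcf"), "skipped 1")
  expect_equal(ncol(p$geno), 4L)
})

test_that("matrix format maps NA entries to missing calls", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("sample,m1,m2", "s1,0,NA", "s2,2,1"), path)
  write.table(data.frame(marker = c("m1", "m2"), chrom = "c1",
                         pos = c(10, 20), ref = "A", alt = "T"),
              paste0(path, ".map"), sep = ",", row.names = FALSE, quote = FALSE)
  p <- read_genotypes(path, "matrix")
  expect_true(is.na(p$geno["s1", "m2"]))
  expect_equal(p$geno["s2", "m1"], 2L)
})

test_that("round-trips reproduce calls, IDs and positions in every format", {
  set.seed(71)
  geno <- matrix(sample(c(0:2, NA), 10 * 50, TRUE), 10, 50,
                 dimnames = list(sprintf("smp%02d", 1:10),
                                 sprintf("mk%03d", 1:50)))
  map <- data.frame(marker = colnames(geno),
                    chrom = rep(c("c1", "c2"), each = 25),
                    pos = rep(seq(1000, by = 997, length.out = 25), 2),
                    ref = sample(c("A", "C"), 50, TRUE),
                    alt = sample(c("G", "T"), 50, TRUE))
  p <- genotype_panel(geno, map)
  for (fmt in c("vcf", "hapmap", "matrix")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_genotypes(p, f, fmt)
    back <- read_genotypes(f, fmt)
    expect_identical(back$geno, p$geno, label = fmt)
    expect_equal(back$map$pos, p$map$pos, label = fmt)
  }
})

test_that("hapmap and vcf renderings of one panel carry identical dosages", {
  set.seed(72)
  geno <- matrix(sample(c(0:2, NA), 8 * 20, TRUE), 8, 20)
  p <- toy_panel(geno)
  f1 <- tempfile(); f2 <- tempfile()
  write_genotypes(p, f1, "vcf")
  write_genotypes(p, f2, "hapmap")
  expect_identical(read_genotypes(f1, "vcf")$geno,
                   read_genotypes(f2, "hapmap")$geno)
})

test_that("hapmap reader sniffs the IUPAC single-letter dialect", {
  path <- tempfile()
  hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                 "s1", "s2", "s3"), collapse = "\t")
  writeLines(c(hdr,
               "m1\tA/G\tc1\t100\t+\tNA\tNA\tNA\tNA\tNA\tNA\tA\tR\tG",
               "m2\tC/T\tc1\t200\t+\tNA\tNA\tNA\tNA\tNA\tNA\tT\tY\tC"), path)
  p <- read_genotypes(path, "hapmap")
  expect_equal(unname(p$geno[, "m1"]), c(0L, 1L, 2L))
  expect_equal(unname(p$geno[, "m2"]), c(2L, 1L, 0L))
})

test_that("GFF3 gene features load with 1-based inclusive coordinates", {
  gff <- write_toy_gff3(tempfile(fileext = ".gff3"), data.frame(
    chrom = "Araip.B06", type = "gene",
    start = c(3631192, 100, 9000), end = c(3632515, 500, 9500),
    id = c("Araip.D6HPL", "g2", "g3")))
  genes <- read_annotation(gff)
  expect_equal(nrow(genes), 3L)
  d6 <- genes[genes$gene == "Araip.D6HPL", ]
  expect_equal(d6$start, 3631192L)
  expect_equal(d6$end, 3632515L)
})

test_that("feature types other than gene are ignored, empty set warns", {
  gff <- write_toy_gff3(tempfile(fileext = ".gff3"), data.frame(
    chrom = "c1", type = c("mRNA", "exon"), start = c(1, 10),
    end = c(100, 50), id = c("t1", "e1")))
  expect_warning(genes <- read_annotation(gff), "no gene")
  expect_equal(nrow(genes), 0L)
})

test_that("SNP-gene overlap follows the shared 1-based inclusive convention", {
  genes <- data.frame(gene = "g", chrom = "c1", start = 100L, end = 200L,
                      strand = "+", annotation = "x")
  overlaps <- function(p) genes$start <= p & p <= genes$end
  expect_false(overlaps(99)); expect_true(overlaps(100))
  expect_true(overlaps(200)); expect_false(overlaps(201))
})

test_that("panel invariants are enforced", {
  expect_error(genotype_panel(matrix(0L, 2, 2),
                              data.frame(marker = c("a", "a"), chrom = "c",
                                         pos = c(1, 2))), "duplicate marker")
  expect_error(genotype_panel(matrix(3L, 2, 2),
                              data.frame(marker = c("a", "b"), chrom = "c",
                                         pos = c(1, 2))), "codes")
  expect_error(genotype_panel(matrix(0L, 2, 2),
                              data.frame(marker = c("a", "b"), chrom = "c",
                                         pos = c(2, 2))), "duplicate \\(chromosome")
})
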