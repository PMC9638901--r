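# toy single-contig reference shared by the hand-built alignments
toy_ref <- c(chr1 = "ACGTACGTAC")

test_that("alignment filter keeps proper unique pairs with MAPQ >= 2", {
  expect_true(filterAlignment(99L, 60L))
  expect_true(all(filterAlignment(c(83L, 163L, 147L), c(2L, 10L, 255L))))
  expect_false(filterAlignment(99L, 1L))   # below the MAPQ floor
  expect_false(filterAlignment(4L, 60L))   # unmapped, not in the flag set
  expect_false(filterAlignment(99L, NA_integer_))
})

test_that("mismatch counting is strand-aware and position-exact", {
  # read identical to the reference: sites counted, no mutations
  cm <- countMismatches("ACGTACGTAC", "10M", 1, "chr1", toy_ref)
  expect_equal(unname(cm[1:4]), c(2L, 2L, 0L, 0L))

  # single T-to-C at the read's 4th position (plus strand)
  cm <- countMismatches("ACGCACGTAC", "10M", 1, "chr1", toy_ref)
  expect_equal(cm[["y_TC"]], 1L)
  expect_equal(cm[["y_GA"]], 0L)
  expect_equal(cm[["n_U"]], 2L)
  expect_equal(cm[["n_G"]], 2L)

  # minus-strand gene: reference A with read G is the T-to-C event
  cm <- countMismatches("GCGTACGTAC", "10M", 1, "chr1", toy_ref,
                        strand = "-")
  expect_equal(cm[["y_TC"]], 1L)   # A->G at position 1
  expect_equal(cm[["n_U"]], 3L)    # reference A positions
  expect_equal(cm[["n_G"]], 3L)    # reference C positions

  expect_error(countMismatches("ACGT", "4M", 1, "chrX", toy_ref), "chrX")
})

test_that("strand symmetry: reverse-complementing everything changes nothing", {
  revcomp <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  for (i in 1:10) {
    L <- 30L
    ref <- paste(sample(bases, L, TRUE), collapse = "")
    read <- strsplit(ref, "")[[1]]
    mut <- sample(L, 4)
    read[mut] <- sample(bases, 4, TRUE)
    read <- paste(read, collapse = "")
    fwd <- countMismatches(read, "30M", 1, "c", c(c = ref), strand = "+")
    rev <- countMismatches(revcomp(read), "30M", 1, "c",
                           c(c = revcomp(ref)), strand = "-")
    expect_equal(unname(fwd[1:4]), unname(rev[1:4]))
  }
})

test_that("SNP masking removes positions from numerator and denominator", {
  # T-to-C mismatch at reference position 4, then masked away
  mask <- snpMask("chr1", 4)
  cm <- countMismatches("ACGCACGTAC", "10M", 1, "chr1", toy_ref, mask = mask)
  expect_equal(cm[["y_TC"]], 0L)
  expect_equal(cm[["n_U"]], 1L)  # position 8 remains

  # masking every position yields an all-zero tally
  all_mask <- snpMask("chr1", 1:10)
  cm <- countMismatches("ACGCACGTAC", "10M", 1, "chr1", toy_ref,
                        mask = all_mask)
  expect_equal(unname(cm[1:4]), c(0L, 0L, 0L, 0L))
})

test_that("low base quality and clipped or inserted bases are excluded", {
  # position 4 (the mismatch) below the quality floor
  qual <- paste(rep("I", 10), collapse = "")
  lowq <- paste0(substr(qual, 1, 3), "#", substr(qual, 5, 10))
  cm <- countMismatches("ACGCACGTAC", "10M", 1, "chr1", toy_ref, qual = lowq)
  expect_equal(cm[["y_TC"]], 0L)
  expect_equal(cm[["n_U"]], 1L)

  # soft clip consumes query only; alignment starts at ref position 3
  cm <- countMismatches("XXGTACGTAC", "2S8M", 3, "chr1", toy_ref)
  expect_equal(unname(cm[1:4]), c(2L, 2L, 0L, 0L))

  # insertion in the read does not shift reference coordinates
  cm <- countMismatches("ACGTTTACGTAC", "4M2I6M", 1, "chr1", toy_ref)
  expect_equal(unname(cm[1:4]), c(2L, 2L, 0L, 0L))
})

test_that("gene assignment distinguishes exonic, intronic and ambiguous reads", {
  models <- list(
    genes = GenomicRanges::GRanges(c("c", "c"),
      IRanges::IRanges(c(1, 500), c(300, 700)), strand = c("+", "+")),
    exons = GenomicRanges::GRangesList(
      gA = GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 200), c(100, 300))),
      gB = GenomicRanges::GRanges("c", IRanges::IRanges(500, 700))))
  names(models$genes) <- c("gA", "gB")

  blk <- function(s, e) GenomicRanges::GRanges("c", IRanges::IRanges(s, e))
  expect_equal(assignGene(blk(10, 60), models),
               list(gene_id = "gA", feature_class = "exonic"))
  # straddles the exon/intron boundary of gA
  expect_equal(assignGene(blk(90, 130), models),
               list(gene_id = "gA", feature_class = "intronic"))
  # spliced read across both exons stays exonic
  spliced <- c(blk(80, 100), blk(200, 220))
  expect_equal(assignGene(spliced, models)$feature_class, "exonic")
  expect_equal(assignGene(blk(290, 510), models)$feature_class, "ambiguous")
  expect_equal(assignGene(blk(400, 450), models)$feature_class, "none")
})

test_that("tallying a synthetic SAM recovers the simulated counts exactly", {
  des <- tilacDesign("s1", "forward")
  sim <- suppressWarnings(  # one-sample design is deliberate here
    simulateReads(c(0.5, 2, 1), des, reads_per_transcript = 40,
                  read_length = 60, seed = 13))
  dir <- tempfile(); dir.create(dir)
  sam <- file.path(dir, "reads.sam"); fa <- file.path(dir, "ref.fa")
  gtf <- file.path(dir, "genes.gtf")
  emitSyntheticSam(sim$tallies, sam, fa, gtf)
  got <- tallyReads(sam, fa, gtf, sample_id = "s1")
  got <- got[match(sim$tallies$read_id, got$read_id), ]
  rownames(got) <- NULL
  expect_equal(got[, c("read_id", "gene_id", "n_U", "n_G", "y_TC", "y_GA")],
               sim$tallies[, c("read_id", "gene_id", "n_U", "n_G",
                               "y_TC", "y_GA")])
  expect_true(all(got$feature_class == "exonic"))
})

test_that("tallying honours the SNP mask end to end", {
  des <- tilacDesign("s1", "forward")
  tl <- toy_tally(y_TC = c(1, 1), y_GA = 0, n_U = 5L, n_G = 5L)
  dir <- tempfile(); dir.create(dir)
  sam <- file.path(dir, "m.sam"); fa <- file.path(dir, "m.fa")
  gtf <- file.path(dir, "m.gtf")
  emitSyntheticSam(tl, sam, fa, gtf)
  # mask the first reference position of the gene's contig: every read's
  # first T (the injected T-to-C site of read 1) vanishes from the tallies
  vcf <- file.path(dir, "m.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "g1\t1\t.\tT\tC\t.\tPASS\t."), vcf)
  got <- tallyReads(sam, fa, gtf, sample_id = "s1", vcf_file = vcf)
  got <- got[match(tl$read_id, got$read_id), ]
  expect_equal(got$y_TC, c(0L, 1L))
  expect_equal(got$n_U, c(4L, 5L))
})

test_that("flag and MAPQ filtering drop records inside tallyReads", {
  tl <- toy_tally(y_TC = c(0, 1), n_U = 4L, n_G = 4L)
  dir <- tempfile(); dir.create(dir)
  sam <- file.path(dir, "f.sam"); fa <- file.path(dir, "f.fa")
  gtf <- file.path(dir, "f.gtf")
  emitSyntheticSam(tl, sam, fa, gtf)
  lines <- readLines(sam)
  i <- grep("^r1\t", lines)
  f <- strsplit(lines[i], "\t")[[1]]
  f[2] <- "4"  # unmapped flag: outside the accepted set
  lines[i] <- paste(f, collapse = "\t")
  writeLines(lines, sam)
  got <- tallyReads(sam, fa, gtf, sample_id = "s1")
  expect_equal(got$read_id, "r2")
})
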