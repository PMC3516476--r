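test_that("circular subsequence wraps and reverse-complements correctly", {
  r <- replicon("toy", "AAAAAAAAGC", circular = TRUE)
  expect_equal(replicon_subseq(r, 9, 4), "GCAA")
  expect_equal(replicon_subseq(r, 9, 4, "-"), "TTGC")
  lin <- replicon("lin", "AAAAAAAAGC", circular = FALSE)
  expect_error(replicon_subseq(lin, 9, 4), "linear")
  expect_equal(replicon_subseq(lin, 9, 2), "GC")
})

test_that("subsequence agrees with the doubled-string oracle exhaustively", {
  set.seed(11)
  s <- random_dna(20)
  r <- replicon("r", s, circular = TRUE)
  for (start in 1:20)
    for (len in 0:20)
      for (strand in c("+", "-"))
        expect_identical(replicon_subseq(r, start, len, strand),
                         subseq_oracle(s, start, len, strand, TRUE))
})

test_that("replicon construction validates alphabet and coordinates", {
  expect_error(replicon("bad", "ACGTX"), "invalid character")
  f <- feature("CDS", 5, 100, strand = "+")
  expect_error(replicon("small", "ACGTACGT", features = f), "outside")
  expect_error(feature("CDS", 10, 5), "end < start")
  w <- feature("CDS", 7, 2, strand = "+", wraps = TRUE)
  expect_silent(replicon("wrapped", "ACGTACGT", circular = TRUE,
                         features = w))
})

test_that("FASTA reading is an identity read", {
  tmp <- tempfile(fileext = ".fasta")
  set.seed(5)
  s <- random_dna(60)
  writeLines(c(">rec1 a plain record", s), tmp)
  r <- read_replicon(tmp)
  expect_equal(r$id, "rec1")
  expect_equal(r$length, 60)
  expect_identical(r$sequence, s)
  expect_equal(nrow(r$features), 0)
})

test_that("GenBank LOCUS topology and complement locations are mapped", {
  tmp <- tempfile(fileext = ".gb")
  seq40 <- strrep("ACGTGGCCAT", 4)
  writeLines(c(
    "LOCUS       test40 40 bp DNA circular UNA",
    "FEATURES             Location/Qualifiers",
    "     source          1..40",
    "     CDS             complement(10..30)",
    "                     /product=\"demo protein\"",
    "ORIGIN",
    paste0("        1 ", tolower(seq40)),
    "//"), tmp)
  r <- read_replicon(tmp)
  expect_true(r$circular)
  expect_identical(r$sequence, seq40)
  expect_equal(nrow(r$features), 1)
  expect_equal(r$features$kind, "CDS")
  expect_equal(r$features$start, 10)
  expect_equal(r$features$end, 30)
  expect_equal(r$features$strand, "-")
  expect_equal(unname(r$features$qualifiers[[1]]["product"]), "demo protein")
})

test_that("write/read round-trips preserve sequence and features", {
  pl <- make_plasmid(small_spec(), seed = 21)
  r <- pl$replicon
  key <- function(f) {
    f <- f[order(f$start, f$kind), c("kind", "start", "end", "strand", "wraps")]
    rownames(f) <- NULL
    f
  }
  # FASTA (sequence only)
  fa <- tempfile(fileext = ".fasta")
  write_replicon(r, fa)
  expect_identical(read_replicon(fa, circular = TRUE)$sequence, r$sequence)
  # GenBank
  gb <- tempfile(fileext = ".gb")
  write_replicon(r, gb)
  back <- read_replicon(gb)
  expect_identical(back$sequence, r$sequence)
  expect_true(back$circular)
  expect_identical(key(back$features), key(r$features))
  # GFF3 + companion FASTA
  gff <- tempfile(fileext = ".gff3")
  cofa <- tempfile(fileext = ".fasta")
  write_replicon(r, gff, fasta = cofa)
  back2 <- read_replicon(gff, format = "gff3", fasta = cofa, circular = TRUE)
  expect_identical(back2$sequence, r$sequence)
  expect_identical(key(back2$features), key(r$features))
})

test_that("tRNA library entries are strand-corrected with exact termini", {
  set.seed(31)
  s <- random_dna(300)
  r <- replicon("chr", s, circular = FALSE,
                features = rbind(
                  feature("tRNA", 101, 176, strand = "+", id = "t_plus"),
                  feature("tRNA", 201, 212, strand = "-", id = "t_minus")))
  lib <- build_trna_library(r, flank_bp = 20, terminus_bp = 8)
  expect_equal(nrow(lib), 2)
  plus <- lib[lib$trna_id == "t_plus", ]
  expect_identical(plus$sequence, replicon_subseq(r, 101, 76, "+"))
  expect_identical(plus$three_prime_terminus,
                   substr(plus$sequence, 76 - 8 + 1, 76))
  expect_identical(plus$upstream_flank, substr(s, 81, 100))
  minus <- lib[lib$trna_id == "t_minus", ]
  # minus-strand gene: reverse complement read ending at the start coord
  expect_identical(minus$sequence, rc(substr(s, 201, 212)))
  expect_identical(minus$three_prime_terminus,
                   substr(rc(substr(s, 201, 212)), 5, 12))
  # terminus is always a suffix of the strand-corrected gene
  expect_true(all(mapply(function(seq, term) endsWith(seq, term),
                         lib$sequence, lib$three_prime_terminus)))
  # no tRNA features -> empty library
  expect_equal(nrow(build_trna_library(replicon("none", "ACGT"))), 0)
})

test_that("BED intervals are converted from 0-based half-open", {
  tmp <- tempfile(fileext = ".bed")
  writeLines("target\t0\t1000\tgi1", tmp)
  gi <- read_genomic_islands(tmp)
  expect_equal(gi$molecule, "target")
  expect_equal(gi$start, 1)
  expect_equal(gi$end, 1000)
})
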