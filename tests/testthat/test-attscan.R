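make_lib <- function(trna_seq, id = "trna1") {
  data.frame(source_id = "host", trna_id = id, isotype = NA_character_,
             sequence = trna_seq,
             three_prime_terminus = substr(trna_seq,
                                           max(1, nchar(trna_seq) - 24),
                                           nchar(trna_seq)),
             upstream_flank = "", downstream_flank = "",
             n_in_terminus = FALSE, stringsAsFactors = FALSE)
}

other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

test_that("a planted terminus match is found once, on either strand", {
  set.seed(51)
  term <- "GGTTCGACTCCG"            # 12 bp tRNA 3' terminus
  trna <- paste0(random_dna(60), term)
  repeat {                          # background guaranteed free of the core
    bg <- random_dna(2000)
    if (!grepl(term, bg, fixed = TRUE) && !grepl(rc(term), bg, fixed = TRUE))
      break
  }
  plus <- paste0(substr(bg, 1, 500), term, substr(bg, 513, 2000))
  # guard against chance extension past the planted core
  substr(plus, 500, 500) <- other_base(substr(trna, 60, 60))
  tgt <- replicon("t", plus, circular = FALSE)
  got <- find_att_candidates(make_lib(trna), tgt, min_match_bp = 10)
  expect_equal(nrow(got), 1)
  expect_equal(got$match_length, 12)
  expect_equal(got$target_start, 501)
  expect_equal(got$target_end, 512)
  expect_equal(got$target_strand, "+")
  expect_identical(got$core_sequence, term)
  expect_equal(got$trna_end_offset, 0)
  # reverse-complement plant: same core reported on the minus strand
  minus <- paste0(substr(bg, 1, 500), rc(term), substr(bg, 513, 2000))
  # extension guard on the minus strand sits just right of the plant:
  # a base never complements itself, so this always blocks extension
  substr(minus, 513, 513) <- substr(trna, 60, 60)
  got2 <- find_att_candidates(make_lib(trna),
                              replicon("t2", minus, circular = FALSE),
                              min_match_bp = 10)
  expect_equal(nrow(got2), 1)
  expect_equal(got2$target_strand, "-")
  expect_identical(got2$core_sequence, term)
  expect_equal(got2$target_start, 501)
  # a 9 bp shared suffix stays below a 10 bp threshold
  trna9 <- paste0(random_dna(40), substr(term, 4, 12))
  short <- paste0(substr(bg, 1, 500), substr(term, 4, 12),
                  substr(bg, 510, 2000))
  substr(short, 500, 500) <- other_base(substr(trna9, 40, 40))
  got3 <- find_att_candidates(make_lib(trna9),
                              replicon("t3", short, circular = FALSE),
                              min_match_bp = 10)
  expect_equal(nrow(got3), 0)
})

test_that("att matcher equals the brute-force suffix x substring oracle", {
  set.seed(52)
  for (i in 1:25) {
    L <- sample(300:800, 1)
    circ <- i %% 2 == 0
    tgt_seq <- random_dna(L)
    trna <- random_dna(sample(30:80, 1))
    # half the cases get the terminus planted to force hits
    if (i %% 3 == 0) {
      k <- sample(8:14, 1)
      at <- sample(1:(L - k), 1)
      substr(tgt_seq, at, at + k - 1) <-
        substr(trna, nchar(trna) - k + 1, nchar(trna))
    }
    tgt <- replicon("t", tgt_seq, circular = circ)
    got <- find_att_candidates(make_lib(trna), tgt, min_match_bp = 6)
    want <- att_oracle(trna, tgt_seq, circ, 6)
    cols <- c("match_length", "target_start", "target_end", "target_strand",
              "core_sequence")
    g <- as.data.frame(got)[do.call(order, got[cols]), cols]
    w <- as.data.frame(want)[do.call(order, want[cols]), cols]
    rownames(g) <- rownames(w) <- NULL
    expect_identical(g, w)
  }
})

test_that("no reported candidate can be extended and remain a match", {
  set.seed(53)
  for (i in 1:10) {
    tgt_seq <- random_dna(600)
    trna <- random_dna(50)
    tgt <- replicon("t", tgt_seq, circular = TRUE)
    got <- find_att_candidates(make_lib(trna), tgt, min_match_bp = 5)
    for (k in seq_len(nrow(got))) {
      cand <- got[k, ]
      if (cand$match_length == nchar(trna)) next
      # one more base leftward on the tRNA must mismatch the target
      prev_t <- substr(trna, nchar(trna) - cand$match_length,
                       nchar(trna) - cand$match_length)
      prev_pos <- ((cand$target_start - 2) %% 600) + 1
      prev_s <- if (cand$target_strand == "+")
        substr(tgt_seq, prev_pos, prev_pos)
      else rc(substr(tgt_seq, ((cand$target_end) %% 600) + 1,
                     ((cand$target_end) %% 600) + 1))
      expect_false(identical(prev_t, prev_s))
    }
  }
})

test_that("expectation score follows the closed form and is monotone", {
  set.seed(54)
  # exactly uniform composition
  tgt <- replicon("u", paste0(strrep("A", 250), strrep("C", 250),
                              strrep("G", 250), strrep("T", 250)))
  core10 <- random_dna(10)
  expect_equal(att_expect_score(core10, tgt, both_strands = TRUE),
               2 * 1000 * 0.25^10)
  expect_equal(att_expect_score(core10, tgt, both_strands = FALSE),
               1000 * 0.25^10)
  # adding a base multiplies by that base's composition probability
  core11 <- paste0(core10, "G")
  expect_equal(att_expect_score(core11, tgt), 0.25 *
                 att_expect_score(core10, tgt))
  # strictly decreasing in match length for any composition
  tgt2 <- replicon("b", random_dna(2000, c(A = .1, C = .4, G = .4, T = .1)))
  s <- random_dna(30)
  scores <- vapply(6:30, function(m)
    att_expect_score(substr(s, 1, m), tgt2), numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("intergenic and genomic-island flags follow feature overlap", {
  set.seed(55)
  feats <- rbind(feature("CDS", 400, 600, strand = "+", id = "cdsA"),
                 feature("CDS", 900, 1100, strand = "-", id = "cdsB"))
  tgt <- replicon("target", random_dna(2000), features = feats)
  cand <- data.frame(trna_id = "t", target_id = "target",
                     match_length = 12, trna_end_offset = 0,
                     target_start = c(501, 701, 950),
                     target_end = c(512, 712, 961),
                     target_strand = "+", wraps = FALSE,
                     core_sequence = "X", expect_score = 1,
                     intergenic = NA, in_genomic_island = NA,
                     stringsAsFactors = FALSE)
  cand$core_sequence <- replicate(3, random_dna(12))
  bed <- tempfile(fileext = ".bed")
  writeLines("target\t0\t1000", bed)
  out <- filter_att_candidates(cand, tgt, read_genomic_islands(bed))
  expect_equal(out$intergenic, c(FALSE, TRUE, FALSE))
  expect_equal(out$in_genomic_island, c(TRUE, TRUE, TRUE))
  out2 <- filter_att_candidates(cand, tgt, intergenic_only = TRUE)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$target_start, 701)
  # intervals on the wrong molecule warn and leave the flag FALSE
  bed2 <- tempfile(fileext = ".bed")
  writeLines("elsewhere\t0\t1000", bed2)
  expect_warning(out3 <- filter_att_candidates(cand, tgt,
                                               read_genomic_islands(bed2)),
                 "no molecule")
  expect_false(any(out3$in_genomic_island))
})

test_that("Campbell integration conserves length and duplicates the core", {
  set.seed(56)
  core <- random_dna(12)
  host_seq <- paste0(random_dna(100), core, random_dna(88))
  plas_seq <- paste0(random_dna(40), core, random_dna(48))
  host <- replicon("host", host_seq, circular = FALSE)
  plasmid <- replicon("plasmid", plas_seq, circular = TRUE)
  attB <- list(target_start = 101, target_end = 112, target_strand = "+",
               core_sequence = core)
  attP <- list(target_start = 41, target_end = 52, target_strand = "+",
               core_sequence = core)
  res <- integrate_replicons(plasmid, host, attP, attB, flank_bp = 10)
  expect_equal(res$cointegrate$length, 300)
  expect_equal(length(gregexpr(core, res$cointegrate$sequence,
                               fixed = TRUE)[[1]]), 2)
  # flank 0 junctions equal the bare core
  res0 <- integrate_replicons(plasmid, host, attP, attB, flank_bp = 0)
  expect_identical(res0$attL_junction, core)
  expect_identical(res0$attR_junction, core)
  # excision returns the host exactly and the plasmid up to rotation
  ex <- excise_cointegrate(res$cointegrate, core)
  expect_identical(ex$host$sequence, host_seq)
  expect_equal(ex$plasmid$length, plasmid$length)
  expect_true(grepl(plas_seq, strrep(ex$plasmid$sequence, 2), fixed = TRUE))
  # differing cores are a precondition error
  attB_bad <- attB; attB_bad$core_sequence <- rc(core)
  expect_error(integrate_replicons(plasmid, host, attP, attB_bad), "core")
})
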