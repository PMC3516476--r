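test_that("planted inverted repeats are reported with exact geometry", {
  set.seed(61)
  arm <- "GCATGC"
  repeat {
    # heavily skewed composition: few complementary pairs, so chance
    # inverted repeats are rare and the planted pair stands alone
    bg <- random_dna(200, c(A = .75, C = .2, G = .03, T = .02))
    toy <- paste0(substr(bg, 1, 80), arm, substr(bg, 81, 100), rc(arm),
                  substr(bg, 101, 200))
    got <- find_inverted_repeats(replicon("toy", toy), min_arm = 6,
                                 max_spacer = 25, max_mismatch = 0)
    if (nrow(got) == 1) break
  }
  expect_equal(got$left_start, 81)
  expect_equal(got$left_end, 86)
  expect_equal(got$right_start, 107)
  expect_equal(got$right_end, 112)
  expect_equal(got$arm_length, 6)
  expect_equal(got$spacer_bp, 20)
  expect_equal(got$mismatches, 0)
  # perfect hairpin: 8 bp arms around a 4 nt loop
  hp <- paste0("CACCACCA", "GGATCCGA", "AAAA", rc("GGATCCGA"), "CACCACCA")
  got2 <- find_inverted_repeats(replicon("hp", hp), min_arm = 8,
                                max_spacer = 6, max_mismatch = 0)
  expect_equal(nrow(got2), 1)
  expect_equal(got2$arm_length, 8)
  expect_equal(got2$spacer_bp, 4)
  validate_repeats(replicon("hp", hp), got2)
})

test_that("inverted-repeat finder equals the quadratic oracle", {
  set.seed(62)
  for (i in 1:12) {
    n <- sample(200:400, 1)
    s <- random_dna(n)
    mm <- sample(0:1, 1)
    r <- replicon("s", s, circular = FALSE)
    got <- find_inverted_repeats(r, min_arm = 4, max_spacer = 8,
                                 max_mismatch = mm, max_arm = 20)
    want <- ir_oracle(s, 4, 8, mm, max_arm = 20)
    cols <- c("left_start", "left_end", "right_start", "right_end",
              "arm_length", "spacer_bp", "mismatches")
    g <- as.data.frame(got)[do.call(order, got[cols]), cols]
    w <- want[do.call(order, want[cols]), cols]
    rownames(g) <- rownames(w) <- NULL
    expect_identical(g, w)
    validate_repeats(r, got, max_mismatch = mm)
  }
})

test_that("circular inverted repeats crossing the origin are found once", {
  set.seed(63)
  arm <- "CCGGTAGC"
  repeat {
    bg <- random_dna(150, c(A = .75, C = .2, G = .03, T = .02))
    if (nrow(find_inverted_repeats(replicon("b", bg), min_arm = 8,
                                   max_spacer = 10, max_mismatch = 0)) == 0)
      break
  }
  # left arm ends at the last base; right arm starts at position 5
  s <- paste0(rc(arm), substr(bg, 1, 130), arm)
  s <- paste0(substr(s, 5, nchar(s)), substr(s, 1, 4))  # rotate: wrap pair
  got <- find_inverted_repeats(replicon("c", s, circular = TRUE),
                               min_arm = 8, max_spacer = 10,
                               max_mismatch = 0)
  expect_equal(nrow(got), 1)
  # arm sequences re-extract correctly across the origin
  r <- replicon("c", s, circular = TRUE)
  left <- replicon_subseq(r, got$left_start, got$arm_length)
  right <- replicon_subseq(r, got$right_start, got$arm_length)
  expect_identical(left, rc(right))
})

test_that("tandem iteron arrays are called with consensus and guards", {
  got <- find_iterons(replicon("t", "ATGCAATGCAATGCA"), unit_min = 5,
                      unit_max = 7, min_copies = 3,
                      max_mismatch_per_copy = 1)
  expect_equal(nrow(got), 1)
  expect_equal(got$unit_length, 5)
  expect_equal(got$copies, 3)
  expect_equal(got$consensus, "ATGCA")
  expect_equal(got$start, 1)
  # one substitution in copy 2 is tolerated within the per-copy budget
  mut <- "ATGCAATCCAATGCA"
  got2 <- find_iterons(replicon("m", mut), 5, 7, 3, 1)
  expect_equal(got2$copies, 3)
  expect_equal(got2$consensus, "ATGCA")
  expect_equal(got2$total_mismatches, 1)
  # the entropy guard suppresses homopolymer 'arrays'
  expect_equal(nrow(find_iterons(replicon("a", strrep("A", 30)), 5, 7, 3, 1)),
               0)
})

test_that("motif scanning with mismatches equals a brute-force scan", {
  set.seed(64)
  box <- "TTATCCACA"
  s <- random_dna(5000)
  substr(s, 1001, 1009) <- box
  mutbox <- box; substr(mutbox, 4, 4) <- "G"
  substr(s, 3001, 3009) <- mutbox
  r <- replicon("m", s, circular = FALSE)
  got <- find_motif(r, box, max_mismatch = 1)
  expect_true(any(got$start == 1001 & got$mismatches == 0))
  expect_true(any(got$start == 3001 & got$mismatches == 1))
  want <- motif_oracle(s, box, 1)
  rownames(got) <- NULL
  expect_identical(got[, c("start", "end", "strand", "mismatches")],
                   want)
  # circular scan picks up origin-crossing footprints too
  s2 <- paste0(substr(box, 4, 9), random_dna(200), substr(box, 1, 3))
  got2 <- find_motif(replicon("c", s2, circular = TRUE), box,
                     max_mismatch = 0)
  expect_true(any(got2$start == 207 & got2$end == 6))
})

test_that("AT-rich windows are merged maximal runs", {
  set.seed(65)
  gc_bg <- random_dna(400, c(A = .05, C = .45, G = .45, T = .05))
  run <- random_dna(50, c(A = .5, C = 0, G = 0, T = .5))
  s <- paste0(substr(gc_bg, 1, 200), run, substr(gc_bg, 201, 400))
  got <- find_at_rich(replicon("at", s), window_bp = 30,
                      min_at_fraction = 0.8)
  expect_equal(nrow(got), 1)
  expect_lte(got$start, 201)
  expect_gte(got$end, 250)
  expect_lte(201 - got$start, 30)
  expect_lte(got$end - 250, 30)
  # uniform 50% AT never reaches a 0.8 threshold
  unif <- replicon("u", strrep("ACGT", 100))
  expect_equal(nrow(find_at_rich(unif, 30, 0.8)), 0)
  # a zero threshold returns the whole molecule
  whole <- find_at_rich(unif, 30, 0)
  expect_equal(nrow(whole), 1)
  expect_equal(whole$start, 1)
  expect_equal(whole$end, 400)
})

test_that("terminal-repeat copies delineate nested transposable units", {
  set.seed(66)
  tr <- random_dna(38, c(A = .2, C = .3, G = .3, T = .2))
  bg <- random_dna(4000)
  plant <- function(s, what, at) {
    substr(s, at, at + nchar(what) - 1) <- what
    s
  }
  s <- plant(plant(plant(bg, tr, 500), tr, 1500), rc(tr), 3200)
  r <- replicon("tn", s, circular = FALSE)
  got <- delineate_transposon(r, repeat_seed = tr)
  expect_equal(nrow(got$copies), 3)
  expect_equal(got$copies$strand, c("+", "+", "-"))
  expect_equal(nrow(got$units), 2)
  outer <- got$units[got$units$nesting == "outer", ]
  inner <- got$units[got$units$nesting == "nested", ]
  expect_equal(outer$unit_start, 500)
  expect_equal(outer$unit_end, 3237)
  expect_equal(inner$unit_start, 1500)
  expect_equal(inner$unit_end, 3237)
  # two copies only: exactly one unit
  s2 <- plant(plant(bg, tr, 500), rc(tr), 3200)
  got2 <- delineate_transposon(replicon("tn2", s2), repeat_seed = tr)
  expect_equal(nrow(got2$units), 1)
  # a single copy is listed but bounds no unit
  s1 <- plant(bg, tr, 500)
  got1 <- delineate_transposon(replicon("tn1", s1), repeat_seed = tr)
  expect_equal(nrow(got1$copies), 1)
  expect_equal(nrow(got1$units), 0)
})
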