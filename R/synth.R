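# Truth-labelled synthetic replicon generator.
#
# The generated plasmid embodies the architecture the detectors assume: a
# ~37 kb circular molecule with two replichore arms of opposite GC skew
# meeting at the planted ori and ter; an oriV block (tandem iterons, a
# DnaA box, an AT-rich window); an oriT inverted-repeat hairpin in GC-rich
# context; an attP core placed intergenically; three copies of a 38 bp
# terminal repeat in +,+,- orientation delineating nested transposable
# units; and background CDS features giving ~90% coding density.  The
# background is i.i.d. with a position-dependent G<->C bias realizing the
# skew arms.  All generation is seeded; re-extracting any truth interval
# from the generated sequence reproduces its payload exactly.

#' Specification of a synthetic plasmid
#'
#' @param length_bp Molecule length (default 37,000).
#' @param gc_percent Background GC percentage (default 62).
#' @param skew_amplitude Per-arm (G-C)/(G+C) bias (default 0.3).
#' @param ori_position,ter_position Replichore boundaries; positions in
#'   `(ori, ter]` (going clockwise, wrapping) carry +amplitude.  Position
#'   defaults are `NULL`, meaning fixed fractions of `length_bp` laid out
#'   like the 37 kb study architecture (oriV block just past the ori,
#'   integrase/att region at ~0.81 L, oriT at ~0.94 L, terminal repeats in
#'   the first half).
#' @param iteron_unit_bp,iteron_copies,iteron_start Tandem iteron array.
#' @param dnaa_box,dnaa_start DnaA-box motif and its position.
#' @param at_rich_bp,at_rich_fraction,at_rich_start AT-rich window.
#' @param orit_arm_bp,orit_loop_bp,orit_start oriT hairpin geometry.
#' @param att_core_bp,att_core_start attP core.
#' @param terminal_repeat_bp Terminal-repeat length (default 38).
#' @param tr_positions,tr_strands Three terminal-repeat copies; the default
#'   +,+,- orientation yields nested outer and inner transposable units.
#' @param coding_density_target Approximate CDS coverage in percent.
#' @return A list of class `plasmid_spec`.
#' @export
plasmid_spec <- function(length_bp = 37000L, gc_percent = 62,
                         skew_amplitude = 0.3,
                         ori_position = NULL, ter_position = NULL,
                         iteron_unit_bp = 21L, iteron_copies = 4L,
                         iteron_start = NULL,
                         dnaa_box = "TTATCCACA", dnaa_start = NULL,
                         at_rich_bp = 80L, at_rich_fraction = 0.9,
                         at_rich_start = NULL,
                         orit_arm_bp = 12L, orit_loop_bp = 6L,
                         orit_start = NULL,
                         att_core_bp = 14L, att_core_start = NULL,
                         terminal_repeat_bp = 38L,
                         tr_positions = NULL,
                         tr_strands = c("+", "+", "-"),
                         coding_density_target = 90) {
  L <- as.integer(length_bp)
  at <- function(f) as.integer(round(f * L))
  if (is.null(ori_position)) ori_position <- at(19000 / 37000)
  if (is.null(ter_position)) ter_position <- at(500 / 37000)
  if (is.null(iteron_start)) iteron_start <- ori_position + 100L
  if (is.null(dnaa_start)) dnaa_start <- ori_position + 230L
  if (is.null(at_rich_start)) at_rich_start <- ori_position + 280L
  if (is.null(orit_start)) orit_start <- at(34900 / 37000)
  if (is.null(att_core_start)) att_core_start <- at(30000 / 37000)
  if (is.null(tr_positions))
    tr_positions <- c(at(2000 / 37000), at(8000 / 37000), at(16000 / 37000))
  spec <- as.list(environment())
  spec$at <- NULL
  spec$L <- NULL
  class(spec) <- "plasmid_spec"
  spec
}

## sample an i.i.d. base vector with given GC and skew sign
sample_bases <- function(n, gc, amp) {
  at <- 1 - gc
  p <- c(A = at / 2, C = gc / 2 * (1 - amp), G = gc / 2 * (1 + amp),
         T = at / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p[DNA_BASES])
}

## random sequence with arbitrary base probabilities (named numeric)
sample_seq <- function(n, p) {
  c2s(sample(names(p), n, replace = TRUE, prob = p))
}

## reserved intervals must not collide
check_packing <- function(iv) {
  iv <- iv[order(iv$start), , drop = FALSE]
  if (nrow(iv) > 1L) {
    clash <- which(iv$start[-1L] <= iv$end[-nrow(iv)])
    if (length(clash))
      stop("infeasible packing; colliding elements: ",
           paste(sprintf("%s/%s", iv$what[clash], iv$what[clash + 1L]),
                 collapse = ", "))
  }
  invisible(iv)
}

## count occurrences of `word` on both strands of circular sequence `s`
count_word_circular <- function(word, s) {
  dd <- paste0(s, substr(s, 1L, nchar(word) - 1L))
  length(fixed_matches(word, dd)) +
    length(fixed_matches(revcomp(word), dd))
}

#' Generate a synthetic plasmid with ground truth
#'
#' @param spec A [plasmid_spec()].
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec and seed.
#' @return A list with `replicon` (an annotated [replicon()]) and `truth`
#'   (a `synthetic_truth` data frame: `kind`, `start`, `end`, `strand`,
#'   `payload`).
#' @export
make_plasmid <- function(spec = plasmid_spec(), seed = 1L) {
  stopifnot(inherits(spec, "plasmid_spec"))
  for (attempt in 0:19) {
    out <- with_seed((seed + attempt * 7919L) %% 2147483647L,
                     make_plasmid_once(spec))
    if (!is.null(out)) return(out)
  }
  stop("could not generate a plasmid with unique planted elements")
}

make_plasmid_once <- function(spec) {
  L <- spec$length_bp
  gc <- spec$gc_percent / 100
  amp <- spec$skew_amplitude

  # --- payloads -------------------------------------------------------
  entropy_ok <- function(s) seq_entropy(s) >= 1.5
  repeat { iteron <- sample_seq(spec$iteron_unit_bp,
                                c(A = .19, C = .31, G = .31, T = .19))
           if (entropy_ok(iteron)) break }
  iteron_arr <- strrep(iteron, spec$iteron_copies)
  # exact composition so the window *is* what the truth table declares:
  # with round(f*n) A/T bases, every 50 bp subwindow of an 80 bp window at
  # f = 0.9 stays >= 0.8 AT whatever the permutation
  n_at <- round(spec$at_rich_fraction * spec$at_rich_bp)
  at_rich <- c2s(sample(c(sample(c("A", "T"), n_at, replace = TRUE),
                          sample(c("C", "G"), spec$at_rich_bp - n_at,
                                 replace = TRUE))))
  arm <- sample_seq(spec$orit_arm_bp, c(A = .1, C = .4, G = .4, T = .1))
  loop <- sample_seq(spec$orit_loop_bp, c(A = .25, C = .25, G = .25, T = .25))
  hairpin <- paste0(arm, loop, revcomp(arm))
  att_core <- sample_seq(spec$att_core_bp,
                         c(A = .25, C = .25, G = .25, T = .25))
  repeat { tr <- sample_seq(spec$terminal_repeat_bp,
                            c(A = .19, C = .31, G = .31, T = .19))
           if (entropy_ok(tr)) break }

  plant <- data.frame(
    what = c("iterons", "dnaa_box", "at_rich", "orit_hairpin", "att_core",
             "terminal_repeat_1", "terminal_repeat_2", "terminal_repeat_3"),
    start = c(spec$iteron_start, spec$dnaa_start, spec$at_rich_start,
              spec$orit_start, spec$att_core_start, spec$tr_positions),
    payload = c(iteron_arr, spec$dnaa_box, at_rich, hairpin, att_core,
                tr, tr, revcomp(tr)),
    strand = c("+", "+", "+", "+", "+", spec$tr_strands),
    stringsAsFactors = FALSE)
  plant$end <- plant$start + nchar(plant$payload) - 1L
  if (any(plant$end > L) || any(plant$start < 1L))
    stop("planted element outside [1, length]")
  check_packing(plant)

  # --- background with two skew arms ---------------------------------
  pos <- seq_len(L)
  plus_arm <- if (spec$ori_position < spec$ter_position)
    pos > spec$ori_position & pos <= spec$ter_position
  else pos > spec$ori_position | pos <= spec$ter_position
  bases <- character(L)
  bases[plus_arm] <- sample_bases(sum(plus_arm), gc, amp)
  bases[!plus_arm] <- sample_bases(sum(!plus_arm), gc, -amp)

  # --- plant payloads, with mismatch guards at element borders --------
  for (i in seq_len(nrow(plant))) {
    bases[plant$start[i]:plant$end[i]] <- s2c(plant$payload[i])
  }
  # stop outward extension of the hairpin arms (guards flank the element)
  hp <- plant[plant$what == "orit_hairpin", ]
  g1 <- wrap_pos(hp$start - 1L, L); g2 <- wrap_pos(hp$end + 1L, L)
  bases[g1] <- "G"
  bases[g2] <- "G"   # G vs comp(G)=C mismatches, ending the repeat cleanly
  # break the iteron periodicity at the array borders so the tandem array
  # starts and ends exactly at its truth coordinates
  itr <- plant[plant$what == "iterons", ]
  unit_ch <- s2c(iteron)
  bases[itr$start - 1L] <-
    setdiff(DNA_BASES, unit_ch[spec$iteron_unit_bp])[1L]
  bases[itr$end + 1L] <- setdiff(DNA_BASES, unit_ch[1L])[1L]

  s <- c2s(bases)

  # --- uniqueness checks (regenerate on the rare collision) -----------
  if (count_word_circular(att_core, s) != 1L) return(NULL)
  if (count_word_circular(tr, s) != 3L) return(NULL)
  if (length(fixed_matches(
        iteron_arr, paste0(s, substr(s, 1L, nchar(iteron_arr) - 1L)))) != 1L)
    return(NULL)
  if (count_word_circular(hairpin, s) != 1L) return(NULL)

  # --- cargo CDS features filling the gaps ----------------------------
  margin <- 12L
  reserved <- cbind(pmax(1L, plant$start - margin),
                    pmin(L, plant$end + margin))
  feats <- empty_features()
  p <- 1L
  orf_id <- 0L
  while (p < L - 400L) {
    gap <- sample(30:110, 1L)
    len <- 3L * sample(100:500, 1L)
    a <- p + gap
    b <- a + len - 1L
    if (b > L) break
    hit <- which(reserved[, 1L] <= b & a <= reserved[, 2L])
    if (length(hit)) {
      # shorten the ORF to fit the space before the blocking element
      zone_start <- min(reserved[hit, 1L])
      fit <- 3L * ((zone_start - a) %/% 3L)
      if (fit >= 300L) {
        orf_id <- orf_id + 1L
        feats <- rbind(feats, feature(
          "CDS", a, a + fit - 1L, strand = sample(c("+", "-"), 1L),
          id = sprintf("orf%02d", orf_id),
          qualifiers = c(product = "hypothetical protein")))
      }
      p <- max(reserved[hit, 2L])
      next
    }
    orf_id <- orf_id + 1L
    feats <- rbind(feats, feature(
      "CDS", a, b, strand = sample(c("+", "-"), 1L),
      id = sprintf("orf%02d", orf_id),
      qualifiers = c(product = "hypothetical protein")))
    p <- b + 1L
  }

  # annotated (non-CDS) features for the planted elements
  feats <- rbind(
    feats,
    feature("oriV", spec$iteron_start,
            plant$end[plant$what == "at_rich"], strand = "+", id = "oriV",
            qualifiers = c(note = "iterons, DnaA box, AT-rich region")),
    feature("oriT", hp$start, hp$end, strand = "+", id = "oriT",
            qualifiers = c(note = "transfer origin hairpin")),
    feature("misc", plant$start[plant$what == "att_core"],
            plant$end[plant$what == "att_core"], strand = "+", id = "attP",
            qualifiers = c(note = "attP core")))
  for (k in 1:3)
    feats <- rbind(feats, feature(
      "repeat_region", spec$tr_positions[k],
      spec$tr_positions[k] + spec$terminal_repeat_bp - 1L,
      strand = spec$tr_strands[k], id = sprintf("TR%d", k),
      qualifiers = c(note = "terminal repeat")))

  rep_out <- replicon("synthetic_plasmid", s, circular = TRUE,
                      features = feats)

  tr_end3 <- spec$tr_positions[3L] + spec$terminal_repeat_bp - 1L
  truth <- rbind(
    data.frame(kind = "ori", start = spec$ori_position,
               end = spec$ori_position, strand = "+",
               payload = NA_character_, stringsAsFactors = FALSE),
    data.frame(kind = "ter", start = spec$ter_position,
               end = spec$ter_position, strand = "+",
               payload = NA_character_, stringsAsFactors = FALSE),
    data.frame(kind = plant$what, start = plant$start, end = plant$end,
               strand = plant$strand, payload = plant$payload,
               stringsAsFactors = FALSE),
    data.frame(kind = c("transposon_outer", "transposon_inner"),
               start = spec$tr_positions[c(1L, 2L)],
               end = c(tr_end3, tr_end3), strand = "+",
               payload = NA_character_, stringsAsFactors = FALSE))
  # the hairpin guards changed two background bases only; payloads intact
  class(truth) <- c("synthetic_truth", class(truth))
  list(replicon = rep_out, truth = truth,
       iteron_unit = iteron, terminal_repeat = tr, att_core = att_core,
       hairpin_arm = arm)
}

#' Generate a synthetic host chromosome carrying an attB site
#'
#' The host carries one plus-strand tRNA gene whose 3' terminus ends in
#' the supplied att core (the attB site), surrounded by background CDS
#' features.  The base immediately 5' of the core inside the tRNA is
#' forced to differ from `upstream_base` so that the attB/attP match
#' cannot extend beyond the planted core.
#'
#' @param att_core The att core shared with the plasmid (from
#'   [make_plasmid()] truth).
#' @param host_length Host length in bp.
#' @param seed Integer seed.
#' @param trna_bp tRNA gene length.
#' @param gc_percent Background GC percentage.
#' @param upstream_base Plasmid base immediately 5' of the attP core, used
#'   for the extension guard (may be `NULL` to skip the guard).
#' @param scramble_core If `TRUE` the tRNA terminus carries a shuffled
#'   core instead (negative control: no attB present).
#' @return A list with `replicon` and `truth` as in [make_plasmid()].
#' @export
make_host <- function(att_core, host_length = 20000L, seed = 1L,
                      trna_bp = 76L, gc_percent = 62,
                      upstream_base = NULL, scramble_core = FALSE) {
  k <- nchar(att_core)
  if (k > trna_bp) stop("att core longer than the tRNA gene")
  with_seed(seed, {
    gc <- gc_percent / 100
    bases <- sample_bases(host_length, gc, 0)
    trna_start <- host_length %/% 2L + 1L
    trna_end <- trna_start + trna_bp - 1L
    core <- att_core
    if (scramble_core) {
      repeat {
        core <- c2s(sample(s2c(att_core)))
        if (core != att_core) break
      }
    }
    trna_seq <- paste0(sample_seq(trna_bp - k,
                                  c(A = .22, C = .28, G = .28, T = .22)),
                       core)
    if (!is.null(upstream_base) && !scramble_core) {
      guard_at <- trna_bp - k
      if (substr(trna_seq, guard_at, guard_at) == upstream_base) {
        alt <- setdiff(DNA_BASES, upstream_base)[1L]
        substr(trna_seq, guard_at, guard_at) <- alt
      }
    }
    bases[trna_start:trna_end] <- s2c(trna_seq)
    feats <- feature("tRNA", trna_start, trna_end, strand = "+",
                     id = "trna1", qualifiers = c(product = "tRNA-Ser"))
    # sparse background CDS annotation away from the tRNA locus
    p <- 1L; oid <- 0L
    while (p < host_length - 1200L) {
      gap <- sample(80:240, 1L)
      len <- 3L * sample(120:400, 1L)
      a <- p + gap; b <- a + len - 1L
      if (b > host_length) break
      if (a <= trna_end + 50L && trna_start - 50L <= b) {
        p <- trna_end + 50L
        next
      }
      oid <- oid + 1L
      feats <- rbind(feats, feature(
        "CDS", a, b, strand = sample(c("+", "-"), 1L),
        id = sprintf("horf%02d", oid),
        qualifiers = c(product = "hypothetical protein")))
      p <- b + 1L
    }
    truth <- data.frame(
      kind = c("trna", "attB_core"),
      start = c(trna_start, trna_end - k + 1L),
      end = c(trna_end, trna_end),
      strand = "+",
      payload = c(trna_seq, core),
      stringsAsFactors = FALSE)
    class(truth) <- c("synthetic_truth", class(truth))
    list(replicon = replicon("synthetic_host", c2s(bases), circular = FALSE,
                             features = feats),
         truth = truth)
  })
}
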