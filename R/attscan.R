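# attP/attB attachment-site prediction.
#
# Candidate att sites are maximal exact matches between the 3' terminus of
# a tRNA gene and a target replicon.  At the word lengths involved
# (10-25 bp) with identity semantics, maximal exact matching is the
# criterion itself, so no aligner is needed.  Each candidate gets an
# expectation score: the expected number of equal-or-longer exact matches
# under a mononucleotide null model of the target, S * L * prod(p(b)) over
# the core bases, with S = 2 when both strands are searched.  Candidates
# are ranked by this score (ascending), not thresholded.

#' Expected count of equal-or-longer exact matches under the null
#'
#' @param core Matched core sequence.
#' @param target Target [replicon()] (supplies length and composition).
#' @param both_strands Were both strands searched?
#' @return Positive numeric expectation score.
#' @export
att_expect_score <- function(core, target, both_strands = TRUE) {
  stopifnot(inherits(target, "replicon"))
  ch <- s2c(target$sequence)
  counts <- table(factor(ch, levels = DNA_BASES))
  tot <- sum(counts)
  if (tot == 0L) stop("target has no A/C/G/T content")
  p <- as.numeric(counts) / tot
  names(p) <- DNA_BASES
  s <- if (both_strands) 2 else 1
  s * target$length * prod(p[s2c(core)])
}

## find all occurrences (start positions) of a fixed pattern in a string
fixed_matches <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

## maximal anchored matches of one tRNA entry against one strand text.
## `text` is the plus-strand (or reverse-strand) sequence of the target;
## for circular molecules the text is tripled and every circular seed
## occurrence is represented in the middle copy, so leftward extension and
## the seed itself always have room.  Returns text-coordinate starts (to be
## normalized by the caller), match lengths and core strings.
anchored_hits <- function(trna_seq, text, L, circular, min_match, offset) {
  tl <- nchar(trna_seq)
  anchor <- tl - offset
  if (anchor < min_match) return(NULL)
  seed <- substr(trna_seq, anchor - min_match + 1L, anchor)
  if (grepl("N", seed, fixed = TRUE)) return(NULL)
  if (circular) {
    search_text <- paste0(text, text, text)
    pos <- fixed_matches(seed, paste0(text, substr(text, 1L, min_match - 1L)))
    pos <- unique(wrap_pos(pos, L)) + L
  } else {
    search_text <- text
    pos <- fixed_matches(seed, search_text)
  }
  if (!length(pos)) return(NULL)
  # N on the target never participates in an exact match
  pos <- pos[!grepl("N", substr(search_text, pos, pos + min_match - 1L),
                    fixed = TRUE)]
  if (!length(pos)) return(NULL)
  tch <- s2c(trna_seq)
  sch <- s2c(search_text)
  out <- vector("list", length(pos))
  for (k in seq_along(pos)) {
    p <- pos[k]
    # extend leftward while both sides agree (N never matches)
    ext <- 0L
    max_ext <- min(anchor - min_match, if (circular) L - min_match else p - 1L)
    while (ext < max_ext) {
      tb <- tch[anchor - min_match - ext]
      sb <- sch[p - 1L - ext]
      if (is.na(sb) || tb != sb || tb == "N") break
      ext <- ext + 1L
    }
    mlen <- min_match + ext
    # right-maximality: at offset 0 the match ends at the tRNA 3' end; at
    # offset > 0 require a mismatch just past the anchor
    if (offset > 0L) {
      tb <- tch[anchor + 1L]
      sb <- sch[p + min_match]
      if (!is.na(sb) && !is.na(tb) && tb == sb && tb != "N") next
    }
    out[[k]] <- data.frame(text_start = p - ext, match_length = mlen,
                           core = substr(search_text, p - ext,
                                         p + min_match - 1L),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) NULL else do.call(rbind, out)
}

#' Find candidate att sites anchored at tRNA 3' termini
#'
#' Reports every maximal exact match of length >= `min_match_bp` between a
#' suffix of a library tRNA (anchored at the 3' terminus unless a positive
#' `max_terminus_offset` relaxes the anchor) and either strand of the
#' target, honouring circular wrap.  A candidate cannot be extended by one
#' base on either end and remain an exact match.
#'
#' @param trna_library A [build_trna_library()] table.
#' @param target Target [replicon()].
#' @param min_match_bp Minimum match length (>= 4; the study criterion is
#'   10).
#' @param require_terminus_anchor If `TRUE` (default) only matches that
#'   include the tRNA 3' terminal base are reported.
#' @param max_terminus_offset With `require_terminus_anchor = FALSE`,
#'   maximal matches ending within this many bases of the terminus are also
#'   reported.
#' @param both_strands Search the reverse strand of the target too.
#' @return A data frame of class `att_candidates`, sorted by ascending
#'   `expect_score` then target coordinate: `trna_id`, `target_id`,
#'   `match_length`, `trna_end_offset`, `target_start`, `target_end`,
#'   `target_strand`, `wraps`, `core_sequence`, `expect_score`,
#'   `intergenic`, `in_genomic_island` (the last two `NA` until
#'   [filter_att_candidates()] is applied).
#' @export
find_att_candidates <- function(trna_library, target, min_match_bp = 10L,
                                require_terminus_anchor = TRUE,
                                max_terminus_offset = 0L,
                                both_strands = TRUE) {
  stopifnot(inherits(target, "replicon"))
  min_match_bp <- as.integer(min_match_bp)
  max_terminus_offset <- as.integer(max_terminus_offset)
  if (min_match_bp < 4L) stop("min_match_bp must be >= 4")
  offsets <- if (require_terminus_anchor) 0L
  else 0L:max_terminus_offset
  L <- target$length
  fwd <- target$sequence
  rev <- revcomp(fwd)
  rows <- list()
  for (i in seq_len(nrow(trna_library))) {
    entry <- trna_library[i, ]
    for (off in offsets) {
      for (strand in if (both_strands) c("+", "-") else "+") {
        text <- if (strand == "+") fwd else rev
        hits <- anchored_hits(entry$sequence, text, L, target$circular,
                              min_match_bp, off)
        if (is.null(hits)) next
        for (k in seq_len(nrow(hits))) {
          ts <- hits$text_start[k]
          mlen <- hits$match_length[k]
          core <- hits$core[k]
          s1 <- wrap_pos(ts, L)
          e1 <- wrap_pos(ts + mlen - 1L, L)
          if (strand == "-") {  # map reverse-text coords to plus strand
            s_plus <- wrap_pos(L - e1 + 1L, L)
            e_plus <- wrap_pos(L - s1 + 1L, L)
            s1 <- s_plus; e1 <- e_plus
          }
          rows[[length(rows) + 1L]] <- data.frame(
            trna_id = entry$trna_id, target_id = target$id,
            match_length = mlen, trna_end_offset = off,
            target_start = s1, target_end = e1, target_strand = strand,
            wraps = e1 < s1, core_sequence = core,
            expect_score = att_expect_score(core, target, both_strands),
            intergenic = NA, in_genomic_island = NA,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trna_id = character(), target_id = character(),
               match_length = integer(), trna_end_offset = integer(),
               target_start = integer(), target_end = integer(),
               target_strand = character(), wraps = logical(),
               core_sequence = character(), expect_score = numeric(),
               intergenic = logical(), in_genomic_island = logical(),
               stringsAsFactors = FALSE)
  if (nrow(out)) {
    out <- unique(out)
    out <- out[order(out$expect_score, out$target_start), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("att_candidates", class(out))
  out
}

#' Flag candidates as intergenic and/or inside genomic islands
#'
#' A candidate is intergenic iff its span overlaps no annotated CDS or tRNA
#' feature of the target; it is inside a genomic island iff it overlaps any
#' supplied interval (see [read_genomic_islands()]).
#'
#' @param candidates An `att_candidates` table.
#' @param target The target [replicon()] carrying the annotation.
#' @param gi_intervals Optional data frame `molecule`/`start`/`end`
#'   (1-based inclusive).
#' @param intergenic_only Drop candidates that overlap a gene.
#' @return The filtered/flagged `att_candidates` table.
#' @export
filter_att_candidates <- function(candidates, target, gi_intervals = NULL,
                                  intergenic_only = FALSE) {
  stopifnot(inherits(target, "replicon"))
  if (!nrow(candidates)) return(candidates)
  genes <- target$features[target$features$kind %in% c("CDS", "tRNA"), ,
                           drop = FALSE]
  gi <- NULL
  if (!is.null(gi_intervals) && nrow(gi_intervals)) {
    gi <- gi_intervals[gi_intervals$molecule == target$id, , drop = FALSE]
    if (!nrow(gi)) {
      warning("genomic-island intervals name no molecule '", target$id,
              "'; in_genomic_island left FALSE")
      gi <- NULL
    }
  }
  for (i in seq_len(nrow(candidates))) {
    s <- candidates$target_start[i]; e <- candidates$target_end[i]
    w <- candidates$wraps[i]
    hit_gene <- FALSE
    for (j in seq_len(nrow(genes)))
      if (intervals_overlap(s, e, w, genes$start[j], genes$end[j],
                            genes$wraps[j], target$length)) {
        hit_gene <- TRUE; break
      }
    candidates$intergenic[i] <- !hit_gene
    in_gi <- FALSE
    if (!is.null(gi))
      for (j in seq_len(nrow(gi)))
        if (intervals_overlap(s, e, w, gi$start[j], gi$end[j], FALSE,
                              target$length)) {
          in_gi <- TRUE; break
        }
    candidates$in_genomic_island[i] <- in_gi
  }
  if (intergenic_only)
    candidates <- candidates[candidates$intergenic, , drop = FALSE]
  rownames(candidates) <- NULL
  candidates
}

#' In-silico Campbell integration at an attP/attB pair
#'
#' Performs the single crossover within the shared core: the cointegrate is
#' the host up to the end of the attB core, then the plasmid rotated to
#' begin just after its attP core, then a second copy of the core, then the
#' host remainder.  Total length is conserved and the core is duplicated,
#' forming the attL and attR junctions.
#'
#' @param plasmid Circular donor [replicon()] carrying the attP core.
#' @param host Host [replicon()] carrying the attB core.
#' @param attP,attB One-row `att_candidates` entries (or equivalent lists
#'   with `target_start`, `target_end`, `target_strand`, `core_sequence`)
#'   located on the plasmid and host respectively, with identical cores.
#' @param flank_bp Flank width reported around each junction core.
#' @return A list of class `integration_result`: `cointegrate` (a
#'   [replicon()]), `attL_junction`, `attR_junction`,
#'   `host_insertion_point`, `core`.
#' @export
integrate_replicons <- function(plasmid, host, attP, attB, flank_bp = 20L) {
  stopifnot(inherits(plasmid, "replicon"), inherits(host, "replicon"))
  if (!plasmid$circular) stop("the integrating plasmid must be circular")
  core <- attP$core_sequence
  if (!identical(core, attB$core_sequence))
    stop("attP and attB cores differ; integration requires an identical core")
  k <- nchar(core)
  Lp <- plasmid$length; Lh <- host$length

  # orient the plasmid so the attP core reads on the plus strand
  pseq <- plasmid$sequence
  p_end <- attP$target_end
  if (attP$target_strand == "-") {
    pseq <- revcomp(pseq)
    p_end <- wrap_pos(Lp - attP$target_start + 1L, Lp)
  }
  # same for the host
  hseq <- host$sequence
  b_start <- attB$target_start; b_end <- attB$target_end
  if (attB$target_strand == "-") {
    hseq <- revcomp(hseq)
    b_start <- Lh - attB$target_end + 1L
    b_end <- Lh - attB$target_start + 1L
  }
  if (substr(hseq, b_start, b_end) != core)
    stop("attB coordinates do not contain the stated core on the host")

  # plasmid remainder, rotated to start just past the attP core
  prot <- paste0(substr(pseq, wrap_pos(p_end + 1L, Lp), Lp),
                 substr(pseq, 1L, wrap_pos(p_end + 1L, Lp) - 1L))
  p_rest <- substr(prot, 1L, Lp - k)
  coint <- paste0(substr(hseq, 1L, b_end), p_rest, core,
                  substr(hseq, b_end + 1L, Lh))
  att_l_start <- b_start
  att_r_start <- b_end + (Lp - k) + 1L
  junction <- function(s) {
    lo <- max(1L, s - flank_bp)
    hi <- min(nchar(coint), s + k - 1L + flank_bp)
    substr(coint, lo, hi)
  }
  out <- list(
    cointegrate = replicon(paste0(host$id, "::", plasmid$id), coint,
                           circular = host$circular),
    attL_junction = junction(att_l_start),
    attR_junction = junction(att_r_start),
    host_insertion_point = b_end,
    core = core,
    attL_core_start = att_l_start,
    attR_core_start = att_r_start)
  class(out) <- "integration_result"
  out
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("<integration> cointegrate %d bp, core %s duplicated at %d and %d\n",
              x$cointegrate$length, x$core, x$attL_core_start,
              x$attR_core_start))
  invisible(x)
}

#' Excise an integrated plasmid at its duplicated core
#'
#' The inverse of [integrate_replicons()]: resolves the cointegrate at the
#' first two occurrences of the core, returning the host (with one core
#' copy retained) and the circular plasmid (up to rotation).
#'
#' @param cointegrate The cointegrate [replicon()].
#' @param core The duplicated core sequence.
#' @return A list with replicons `host` and `plasmid`.
#' @export
excise_cointegrate <- function(cointegrate, core) {
  stopifnot(inherits(cointegrate, "replicon"))
  k <- nchar(core)
  pos <- fixed_matches(core, cointegrate$sequence)
  if (length(pos) < 2L)
    stop("core occurs fewer than twice in the cointegrate")
  q1 <- pos[1L]; q2 <- pos[2L]
  seqc <- cointegrate$sequence
  host <- paste0(substr(seqc, 1L, q1 + k - 1L),
                 substr(seqc, q2 + k, nchar(seqc)))
  plasmid <- substr(seqc, q1 + k, q2 + k - 1L)
  list(host = replicon(paste0(cointegrate$id, "_host"), host,
                       circular = cointegrate$circular),
       plasmid = replicon(paste0(cointegrate$id, "_plasmid"), plasmid,
                          circular = TRUE))
}
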