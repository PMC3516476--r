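# Repeat detectors: inverted-repeat pairs (oriT hairpins, operator sites,
# Tn3-family terminal repeats), tandem direct-repeat arrays (iterons),
# degenerate motif scanning (DnaA boxes), AT-rich windows, and
# composite-transposon delineation from terminal-repeat copies.

#' Find inverted-repeat pairs
#'
#' Reports, for every spacer interval of length `0..max_spacer`, the
#' maximal pair of flanking arms such that the right arm is the reverse
#' complement of the left arm up to `max_mismatch` substitutions.  Arms are
#' extended outward greedily within the mismatch budget and trimmed so that
#' both the innermost and outermost base pairs match (a canonical form that
#' makes "maximal" well defined); overlapping and nested pairs are all
#' reported.  Circularly aware.
#'
#' @param x A [replicon()].
#' @param min_arm Minimum arm length (>= 4).
#' @param max_spacer Maximum spacer (loop) length between the arms.
#' @param max_mismatch Maximum substitutions between the left arm and the
#'   reverse complement of the right arm.  N never matches.
#' @param max_arm Optional cap on arm length.
#' @return Data frame of class `repeat_pairs`: `left_start`, `left_end`,
#'   `right_start`, `right_end` (1-based, normalized onto the molecule),
#'   `arm_length`, `spacer_bp`, `mismatches`, `orientation` (always
#'   `"inverted"` here), sorted by `left_start`.
#' @export
find_inverted_repeats <- function(x, min_arm = 10L, max_spacer = 50L,
                                  max_mismatch = 0L, max_arm = Inf) {
  stopifnot(inherits(x, "replicon"))
  min_arm <- as.integer(min_arm)
  max_spacer <- as.integer(max_spacer)
  max_mismatch <- as.integer(max_mismatch)
  if (min_arm < 4L) stop("min_arm must be >= 4")
  L <- x$length
  # circular molecules are scanned in the middle copy of a tripled text so
  # pairs crossing the origin are seen exactly once (one representative per
  # circular spacer position)
  if (x$circular) {
    ch <- s2c(strrep(x$sequence, 3L))
    cen_range <- (L + 1L):(2L * L)
  } else {
    ch <- s2c(x$sequence)
    cen_range <- seq_len(length(ch))
  }
  cp <- comp_chars(ch)
  n <- length(ch)
  # pair (p, q) matches iff ch[p] == cp[q] and neither is N
  pair_ok <- function(p, q) {
    a <- ch[p]; b <- cp[q]
    !is.na(a) && !is.na(b) && a == b && a != "N"
  }
  rows <- list()
  a_cap <- min(max_arm, if (x$circular) (L - 1L) %/% 2L else n %/% 2L)
  for (s in 0:max_spacer) {
    for (cen in cen_range) {
      # spacer occupies [cen, cen+s-1]; innermost pair is (cen-1, cen+s)
      p0 <- cen - 1L; q0 <- cen + s
      if (p0 < 1L || q0 > n) next
      if (!pair_ok(p0, q0)) next
      # greedy outward extension within the mismatch budget
      mm <- 0L
      t <- 1L
      best_a <- 1L; best_mm <- 0L
      while (t < a_cap) {
        p <- p0 - t; q <- q0 + t
        if (p < 1L || q > n) break
        if ((q - p + 1L) > L) break  # circular arms would overlap
        ok <- pair_ok(p, q)
        if (!ok) {
          mm <- mm + 1L
          if (mm > max_mismatch) break
        } else {
          best_a <- t + 1L; best_mm <- mm
        }
        t <- t + 1L
      }
      if (best_a < min_arm) next
      ls <- p0 - best_a + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        left_start = ls, left_end = p0,
        right_start = q0, right_end = q0 + best_a - 1L,
        arm_length = best_a, spacer_bp = s, mismatches = best_mm,
        orientation = "inverted", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(left_start = integer(), left_end = integer(),
               right_start = integer(), right_end = integer(),
               arm_length = integer(), spacer_bp = integer(),
               mismatches = integer(), orientation = character(),
               stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (x$circular) {
      out$left_start <- wrap_pos(out$left_start, L)
      out$left_end <- wrap_pos(out$left_end, L)
      out$right_start <- wrap_pos(out$right_start, L)
      out$right_end <- wrap_pos(out$right_end, L)
    }
    out <- unique(out)
    out <- out[order(out$left_start, out$spacer_bp), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("repeat_pairs", class(out))
  out
}

## mismatch count between block at i and block at j (length u) of char vec
block_mismatch <- function(ch, i, j, u) {
  a <- ch[i:(i + u - 1L)]; b <- ch[j:(j + u - 1L)]
  sum(a != b | a == "N" | b == "N")
}

#' Find tandem direct-repeat arrays (iterons)
#'
#' Scans unit lengths `unit_min..unit_max` for runs of >= `min_copies`
#' adjacent copies, each within `max_mismatch_per_copy` substitutions of
#' the per-column majority consensus.  A low-complexity guard suppresses
#' units whose Shannon entropy falls below `min_entropy` bits/symbol
#' (homopolymer and dinucleotide artifacts).  Overlapping reports are
#' merged to the longest array.
#'
#' @param x A [replicon()].
#' @param unit_min,unit_max Unit-length search range (`unit_min` >= 5).
#' @param min_copies Minimum number of tandem copies (>= 3).
#' @param max_mismatch_per_copy Substitution budget per copy vs consensus.
#' @param min_entropy Entropy guard in bits/symbol.
#' @return Data frame of class `iteron_arrays`: `start`, `end`,
#'   `unit_length`, `copies`, `consensus`, `max_copy_mismatch`,
#'   `total_mismatches`, `per_copy_mismatches` (list-column).
#' @export
find_iterons <- function(x, unit_min = 15L, unit_max = 25L, min_copies = 3L,
                         max_mismatch_per_copy = 1L, min_entropy = 1.0) {
  stopifnot(inherits(x, "replicon"))
  unit_min <- as.integer(unit_min); unit_max <- as.integer(unit_max)
  min_copies <- as.integer(min_copies)
  max_mismatch_per_copy <- as.integer(max_mismatch_per_copy)
  if (unit_min < 5L) stop("unit_min must be >= 5")
  if (min_copies < 3L) stop("min_copies must be >= 3")
  L <- x$length
  pad <- if (x$circular) min(L, unit_max * 8L) else 0L
  ch <- s2c(paste0(x$sequence, substr(x$sequence, 1L, pad)))
  n <- length(ch)
  rows <- list()
  for (u in unit_min:unit_max) {
    if (2L * u > n) break
    e <- (ch[seq_len(n - u)] != ch[(u + 1L):n]) |
      ch[seq_len(n - u)] == "N" | ch[(u + 1L):n] == "N"
    D <- cumsum(e)
    j_max <- n - 2L * u + 1L
    # mismatches between block at j and block at j+u, vectorized over j
    dbl <- D[seq_len(j_max) + u - 1L] - c(0L, D)[seq_len(j_max)]
    ok <- dbl <= max_mismatch_per_copy
    # array starts: ok position not preceded (u earlier) by an ok position
    prev <- c(rep(FALSE, u), ok[seq_len(max(0L, j_max - u))])
    starts <- which(ok & !prev[seq_len(j_max)])
    for (s in starts) {
      if (x$circular && s > L) next
      copies <- 2L
      while (s + copies * u - 1L + u <= n && ok[s + (copies - 1L) * u]) {
        copies <- copies + 1L
        if (x$circular && copies * u >= L) break
      }
      if (copies < min_copies) next
      mat <- matrix(ch[s:(s + copies * u - 1L)], nrow = copies, ncol = u,
                    byrow = TRUE)
      cons <- apply(mat, 2L, function(col) {
        tb <- sort(table(col), decreasing = TRUE)
        names(tb)[1L]
      })
      per_copy <- apply(mat, 1L, function(row)
        sum(row != cons | row == "N"))
      if (max(per_copy) > max_mismatch_per_copy) next
      consensus <- c2s(cons)
      if (seq_entropy(consensus) < min_entropy) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = s, end = s + copies * u - 1L, unit_length = u,
        copies = copies, consensus = consensus,
        max_copy_mismatch = max(per_copy),
        total_mismatches = sum(per_copy),
        per_copy_mismatches = I(list(unname(per_copy))),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), unit_length = integer(),
               copies = integer(), consensus = character(),
               max_copy_mismatch = integer(), total_mismatches = integer(),
               per_copy_mismatches = I(list()), stringsAsFactors = FALSE)
  if (nrow(out)) {
    # merge overlapping reports: keep the longest span; ties resolve to the
    # cleanest array (fewest total mismatches), then smallest unit/start
    out <- out[order(-(out$end - out$start), out$total_mismatches,
                     out$unit_length, out$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(out))) {
        if (i == j || !keep[j]) next
        if (out$start[j] <= out$end[i] && out$start[i] <= out$end[j])
          keep[j] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
    if (x$circular) {
      out$end <- wrap_pos(out$end, L)
    }
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("iteron_arrays", class(out))
  out
}

#' Scan for a motif with mismatches on both strands
#'
#' @param x A [replicon()].
#' @param motif Motif string (>= 6 bp), e.g. the DnaA-box consensus
#'   `TTATCCACA`.
#' @param max_mismatch Maximum substitutions.
#' @return Data frame: `start`, `end` (plus-strand footprint), `strand`,
#'   `mismatches`, sorted by position.
#' @export
find_motif <- function(x, motif = "TTATCCACA", max_mismatch = 1L) {
  stopifnot(inherits(x, "replicon"))
  motif <- toupper(motif)
  max_mismatch <- as.integer(max_mismatch)
  m <- nchar(motif)
  if (m < 6L) stop("motif length must be >= 6")
  L <- x$length
  text <- if (x$circular) paste0(x$sequence, substr(x$sequence, 1L, m - 1L))
  else x$sequence
  subject <- Biostrings::DNAString(text)
  rows <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") motif else revcomp(motif)
    hits <- Biostrings::matchPattern(pat, subject,
                                     max.mismatch = max_mismatch,
                                     with.indels = FALSE, fixed = TRUE)
    if (!length(hits)) next
    st <- BiocGenerics::start(hits)
    mm <- vapply(seq_along(hits), function(i)
      Biostrings::neditAt(pat, subject, at = st[i], with.indels = FALSE,
                          fixed = TRUE), integer(1L))
    keep <- st <= L
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = st[keep], end = wrap_pos(st[keep] + m - 1L, L),
      strand = strand, mismatches = mm[keep], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), strand = character(),
               mismatches = integer(), stringsAsFactors = FALSE)
  if (nrow(out)) {
    out <- unique(out)
    out <- out[order(out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Find AT-rich intervals
#'
#' Slides a window of `window_bp` one base at a time and reports the merged
#' union of all windows whose A+T fraction reaches `min_at_fraction`.
#'
#' @param x A [replicon()].
#' @param window_bp Window length (>= 20).
#' @param min_at_fraction AT-fraction threshold in `[0, 1]`.
#' @return Data frame of intervals `start`, `end` (1-based inclusive;
#'   may wrap on circular molecules, flagged by `wraps`).
#' @export
find_at_rich <- function(x, window_bp = 50L, min_at_fraction = 0.8) {
  stopifnot(inherits(x, "replicon"))
  window_bp <- as.integer(window_bp)
  if (window_bp < 20L) stop("window_bp must be >= 20")
  L <- x$length
  if (window_bp > L) stop("window_bp exceeds molecule length")
  text <- if (x$circular) paste0(x$sequence, substr(x$sequence, 1L, window_bp - 1L))
  else x$sequence
  ch <- s2c(text)
  at <- cumsum(ch %in% c("A", "T"))
  n_start <- if (x$circular) L else L - window_bp + 1L
  starts <- seq_len(n_start)
  frac <- (at[starts + window_bp - 1L] - c(0L, at)[starts]) / window_bp
  hit <- frac >= min_at_fraction
  if (!any(hit)) {
    return(data.frame(start = integer(), end = integer(), wraps = logical()))
  }
  # union of hit windows, then merge adjacent/overlapping intervals
  idx <- which(hit)
  iv_start <- idx[c(TRUE, diff(idx) > window_bp)]
  iv_end <- idx[c(diff(idx) > window_bp, TRUE)] + window_bp - 1L
  out <- data.frame(start = iv_start, end = iv_end)
  if (x$circular) {
    out$end <- pmin(out$end, iv_start + L - 1L)
    # merge a leading interval with one wrapping around to it
    wraps_in <- out$end > L
    out$end <- ifelse(wraps_in, out$end - L, out$end)
    out$wraps <- wraps_in
    if (nrow(out) > 1L && out$wraps[nrow(out)] &&
        out$start[1L] <= out$end[nrow(out)] + 1L) {
      out$end[nrow(out)] <- max(out$end[1L], out$end[nrow(out)])
      out <- out[-1L, , drop = FALSE]
    }
  } else {
    out$wraps <- FALSE
  }
  rownames(out) <- NULL
  out
}

#' Delineate composite transposons from terminal-repeat copies
#'
#' Locates all copies of a terminal repeat (a supplied seed, or the arm of
#' the longest inverted repeat found de novo) on both strands, then calls
#' transposable units.  Transposon ends are inverted repeats facing each
#' other, so every plus-strand copy paired with a downstream minus-strand
#' copy bounds a unit; with three copies in +,+,- orientation this yields
#' the nested outer and inner units of a composite element.  When no
#' opposed pair exists but >= 2 copies are present, the span between the
#' outermost copies is reported.
#'
#' @param x A [replicon()].
#' @param repeat_seed Terminal-repeat sequence (>= 20 bp), or `NULL` to
#'   seed from the longest de-novo inverted-repeat arm.
#' @param min_copy_identity Minimum identity between copies (default 0.9,
#'   i.e. a 38-bp Tn3-family repeat tolerates 3 substitutions).
#' @return A list of class `transposon_calls` with elements `copies` (the
#'   motif-hit table) and `units` (data frame `unit_start`, `unit_end`,
#'   `left_copy`, `right_copy`, `nesting` in `{"outer","nested"}`).
#' @export
delineate_transposon <- function(x, repeat_seed = NULL,
                                 min_copy_identity = 0.9) {
  stopifnot(inherits(x, "replicon"))
  if (is.null(repeat_seed)) {
    irs <- find_inverted_repeats(x, min_arm = 20L, max_spacer = 50L,
                                 max_mismatch = 1L)
    if (!nrow(irs)) {
      out <- list(copies = find_motif(x, paste(rep("A", 20L), collapse = ""),
                                      0L)[0L, ],
                  units = data.frame(unit_start = integer(),
                                     unit_end = integer(),
                                     left_copy = integer(),
                                     right_copy = integer(),
                                     nesting = character()))
      class(out) <- "transposon_calls"
      return(out)
    }
    best <- irs[which.max(irs$arm_length), ]
    repeat_seed <- replicon_subseq(x, best$left_start, best$arm_length, "+")
  }
  repeat_seed <- toupper(repeat_seed)
  if (nchar(repeat_seed) < 20L) stop("repeat_seed must be >= 20 bp")
  max_mm <- floor((1 - min_copy_identity) * nchar(repeat_seed))
  copies <- find_motif(x, repeat_seed, max_mismatch = max_mm)
  units <- data.frame(unit_start = integer(), unit_end = integer(),
                      left_copy = integer(), right_copy = integer(),
                      nesting = character(), stringsAsFactors = FALSE)
  if (nrow(copies) >= 2L) {
    copies <- copies[order(copies$start), , drop = FALSE]
    k <- nrow(copies)
    # inverted-orientation pairs: + copy before - copy
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (copies$strand[i] == "+" && copies$strand[j] == "-") {
        units <- rbind(units, data.frame(
          unit_start = copies$start[i], unit_end = copies$end[j],
          left_copy = i, right_copy = j, nesting = "nested",
          stringsAsFactors = FALSE))
      }
    }
    outer <- data.frame(unit_start = copies$start[1L],
                        unit_end = copies$end[k], left_copy = 1L,
                        right_copy = k, nesting = "outer",
                        stringsAsFactors = FALSE)
    dup <- units$left_copy == 1L & units$right_copy == k
    units <- rbind(outer, units[!dup, , drop = FALSE])
    units <- units[order(units$unit_start, -units$unit_end), , drop = FALSE]
    rownames(units) <- NULL
  }
  out <- list(copies = copies, units = units, seed = repeat_seed)
  class(out) <- "transposon_calls"
  out
}

#' @export
print.transposon_calls <- function(x, ...) {
  cat(sprintf("<transposon calls> %d terminal-repeat copies, %d unit(s)\n",
              nrow(x$copies), nrow(x$units)))
  if (nrow(x$units)) print(x$units)
  invisible(x)
}

#' Re-check every reported repeat against its own definition
#'
#' Self-validation pass: verifies character by character that each reported
#' inverted-repeat pair satisfies the arm/mismatch contract on the given
#' replicon.
#'
#' @param x A [replicon()].
#' @param pairs A `repeat_pairs` table.
#' @param max_mismatch The mismatch budget the pairs were called with.
#' @return `TRUE` (invisibly) or an error describing the offending row.
#' @export
validate_repeats <- function(x, pairs, max_mismatch = 0L) {
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    left <- replicon_subseq(x, p$left_start, p$arm_length, "+")
    right <- replicon_subseq(x, p$right_start, p$arm_length, "+")
    mm <- sum(s2c(left) != s2c(revcomp(right)))
    if (mm != p$mismatches || mm > max_mismatch)
      stop(sprintf("repeat pair %d fails self-validation (%d mismatches)",
                   i, mm))
  }
  invisible(TRUE)
}
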