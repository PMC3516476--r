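# Independent brute-force oracles used to check the detectors, plus small
# fixture builders.  The oracles deliberately use different algorithms from
# the implementation (full enumeration / doubled-string expansion).

random_dna <- function(n, p = c(A = .25, C = .25, G = .25, T = .25)) {
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

rc <- function(x) {
  paste(rev(unname(c(A = "T", C = "G", G = "C", T = "A",
                     N = "N")[strsplit(x, "")[[1]]])), collapse = "")
}

## circular/linear subsequence by doubling the string
subseq_oracle <- function(seq, start, len, strand = "+", circular = TRUE) {
  text <- if (circular) strrep(seq, 2L) else seq
  out <- substr(text, start, start + len - 1L)
  if (strand == "-") out <- rc(out)
  out
}

## all maximal tRNA-suffix x target matches, by full enumeration over
## suffix length and target position (vectorized over positions)
att_oracle <- function(trna_seq, target_seq, circular, min_match,
                       both_strands = TRUE) {
  L <- nchar(target_seq)
  tl <- nchar(trna_seq)
  rows <- list()
  for (strand in if (both_strands) c("+", "-") else "+") {
    text <- if (strand == "+") target_seq else rc(target_seq)
    big <- if (circular) strrep(text, 3L) else text
    offset <- if (circular) L else 0L
    i_all <- if (circular) (L + 1L):(2L * L) else seq_len(L)
    for (m in min_match:tl) {
      pat <- substr(trna_seq, tl - m + 1L, tl)
      if (grepl("N", pat, fixed = TRUE)) next
      if (circular && m > L) next
      iv <- i_all[i_all + m - 1L <= nchar(big)]
      if (!length(iv)) next
      subs <- substring(big, iv, iv + m - 1L)
      ok <- subs == pat & !grepl("N", subs, fixed = TRUE)
      # maximality on the left: no longer suffix also matches here
      if (m < tl && !(circular && m >= L)) {
        tprev <- substr(trna_seq, tl - m, tl - m)
        prev <- substring(big, iv - 1L, iv - 1L)
        extendable <- iv > 1L & prev == tprev & tprev != "N" & prev != "N"
        ok <- ok & !extendable
      }
      hits <- iv[ok]
      if (!length(hits)) next
      s1 <- ((hits - offset - 1L) %% L) + 1L
      e1 <- ((hits - offset + m - 2L) %% L) + 1L
      if (strand == "-") {
        tmp <- s1
        s1 <- ((L - e1) %% L) + 1L
        e1 <- ((L - tmp) %% L) + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        match_length = m, target_start = s1, target_end = e1,
        target_strand = strand, core_sequence = subs[ok],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(match_length = integer(), target_start = integer(),
               target_end = integer(), target_strand = character(),
               core_sequence = character(), stringsAsFactors = FALSE)
  out[order(out$match_length, out$target_start, out$target_strand), ,
      drop = FALSE]
}

## quadratic inverted-repeat oracle over all (left_start, arm, spacer)
## placements on a LINEAR sequence; vectorized over left_start
ir_oracle <- function(seq, min_arm, max_spacer, max_mismatch,
                      max_arm = 30L) {
  x <- strsplit(seq, "")[[1]]
  y <- unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
  n <- length(x)
  valid <- list()
  for (a in min_arm:max_arm) {
    for (s in 0:max_spacer) {
      span <- 2L * a + s
      K <- n - span + 1L
      if (K < 1L) next
      mm <- integer(K)
      for (t in 0:(a - 1L)) {
        xi <- x[(1L + t):(t + K)]
        yi <- y[(span - t):(span - t - 1L + K)]
        mm <- mm + as.integer(xi != yi | xi == "N" | yi == "N")
      }
      inner <- x[a:(a - 1L + K)] == y[(a + s + 1L):(a + s + K)] &
        x[a:(a - 1L + K)] != "N" & y[(a + s + 1L):(a + s + K)] != "N"
      outer <- x[1L:K] == y[span:(span - 1L + K)] &
        x[1L:K] != "N" & y[span:(span - 1L + K)] != "N"
      l1 <- which(mm <= max_mismatch & inner & outer)
      if (length(l1))
        valid[[length(valid) + 1L]] <- data.frame(
          left_start = l1, arm_length = a, spacer_bp = s,
          mismatches = mm[l1])
    }
  }
  if (!length(valid))
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      arm_length = integer(), spacer_bp = integer(),
                      mismatches = integer()))
  v <- do.call(rbind, valid)
  # one maximal (longest-arm) pair per spacer interval
  v$center <- v$left_start + v$arm_length
  v <- v[order(v$center, v$spacer_bp, -v$arm_length), , drop = FALSE]
  v <- v[!duplicated(v[, c("center", "spacer_bp")]), , drop = FALSE]
  out <- data.frame(left_start = v$left_start,
                    left_end = v$left_start + v$arm_length - 1L,
                    right_start = v$left_start + v$arm_length + v$spacer_bp,
                    right_end = v$left_start + 2L * v$arm_length +
                      v$spacer_bp - 1L,
                    arm_length = v$arm_length, spacer_bp = v$spacer_bp,
                    mismatches = v$mismatches)
  out <- out[order(out$left_start, out$spacer_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## brute-force motif scan on both strands (position-by-position comparison)
motif_oracle <- function(seq, motif, max_mismatch, circular = FALSE) {
  L <- nchar(seq)
  m <- nchar(motif)
  text <- if (circular) paste0(seq, substr(seq, 1L, m - 1L)) else seq
  ch <- strsplit(text, "")[[1]]
  rows <- list()
  for (strand in c("+", "-")) {
    pat <- strsplit(if (strand == "+") motif else rc(motif), "")[[1]]
    for (i in seq_len(if (circular) L else L - m + 1L)) {
      w <- ch[i:(i + m - 1L)]
      mm <- sum(w != pat | w == "N")
      if (mm <= max_mismatch)
        rows[[length(rows) + 1L]] <- data.frame(
          start = i, end = ((i + m - 2L) %% L) + 1L, strand = strand,
          mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(start = integer(), end = integer(), strand = character(),
               mismatches = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## brute-force six-frame ORF caller on the doubled string: for every
## candidate start codon, walk forward to the first in-frame stop and
## backwards to confirm it is the first start of its stop-to-stop segment
orf_oracle <- function(seq, circular, min_aa,
                       starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seq)
  min_nt <- 3L * (min_aa + 1L)
  rows <- list()
  for (strand in c("+", "-")) {
    text <- if (strand == "+") seq else rc(seq)
    big <- if (circular) strrep(text, 2L) else text
    n <- nchar(big)
    codon <- function(p) substr(big, p, p + 2L)
    for (p in seq_len(min(L, n - 2L))) {
      if (!codon(p) %in% starts) next
      # first start of its segment: walk back until a stop/boundary
      q <- p - 3L
      first <- TRUE
      while (q >= 1L) {
        cq <- codon(q)
        if (cq %in% stops) break
        if (cq %in% starts) { first <- FALSE; break }
        q <- q - 3L
      }
      if (!first) next
      # walk forward to the first stop
      e <- NA_integer_
      q <- p + 3L
      while (q + 2L <= n) {
        if (codon(q) %in% stops) { e <- q + 2L; break }
        q <- q + 3L
      }
      if (is.na(e)) next
      nt <- e - p + 1L
      if (nt < min_nt || (circular && nt > L)) next
      wraps <- circular && e > L
      if (strand == "+") {
        rows[[length(rows) + 1L]] <- data.frame(
          start = p, end = if (wraps) e - L else e, strand = "+",
          length_aa = nt %/% 3L - 1L, wraps_origin = wraps,
          stringsAsFactors = FALSE)
      } else {
        e_mod <- ((e - 1L) %% L) + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          start = L - e_mod + 1L, end = L - p + 1L, strand = "-",
          length_aa = nt %/% 3L - 1L, wraps_origin = wraps,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(start = integer(), end = integer(), strand = character(),
               length_aa = integer(), wraps_origin = logical(),
               stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## a small plasmid spec (8 kb) for fast unit tests; same architecture as
## the default, scaled down
small_spec <- function() plasmid_spec(length_bp = 8000L)
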