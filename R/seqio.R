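# Sequence and annotation I/O plus the single circular-coordinate
# convention used by every detector: coordinates are 1-based inclusive,
# features that span the circular origin carry `wraps = TRUE` (end < start
# is then permitted), and external formats keep their native conventions
# (GenBank/GFF3 1-based inclusive, BED 0-based half-open).

FEATURE_KINDS <- c("CDS", "tRNA", "repeat_region", "oriV", "oriT", "misc")

#' Construct an empty feature table
#'
#' @return A zero-row data frame with the feature columns used throughout
#'   the package: `kind`, `start`, `end`, `strand`, `wraps`, `id` and a
#'   `qualifiers` list-column of named character vectors.
#' @export
empty_features <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             strand = character(), wraps = logical(), id = character(),
             qualifiers = I(list()), stringsAsFactors = FALSE)
}

#' Build a feature row
#'
#' @param kind Feature kind, one of `CDS`, `tRNA`, `repeat_region`, `oriV`,
#'   `oriT`, `misc`.
#' @param start,end 1-based inclusive coordinates; `end < start` only with
#'   `wraps = TRUE`.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param id Feature identifier (generated if `NULL`).
#' @param wraps Does the feature span the circular origin?
#' @param qualifiers Named character vector of qualifier key/value pairs.
#' @return A one-row feature data frame.
#' @export
feature <- function(kind, start, end, strand = "*", id = NULL,
                    wraps = FALSE, qualifiers = character()) {
  kind <- match.arg(kind, FEATURE_KINDS)
  if (!wraps && end < start) stop("end < start on a non-wrapping feature")
  if (is.null(id)) id <- sprintf("%s_%d_%d", kind, start, end)
  data.frame(kind = kind, start = as.integer(start), end = as.integer(end),
             strand = strand, wraps = wraps, id = id,
             qualifiers = I(list(qualifiers)), stringsAsFactors = FALSE)
}

#' Construct an annotated replicon
#'
#' The central container: a nucleotide sequence with a circularity flag and
#' a typed feature table.
#'
#' @param id Molecule identifier.
#' @param sequence Nucleotide string over \{A,C,G,T,N\} (case-insensitive,
#'   stored upper-case).
#' @param circular Is the molecule circular?
#' @param features Feature data frame (see [feature()]).
#' @return An object of class `replicon` with fields `id`, `sequence`,
#'   `circular`, `length` and `features`.
#' @export
#' @examples
#' r <- replicon("toy", "ACGTACGTAC", circular = TRUE)
#' r$length
replicon <- function(id, sequence, circular = FALSE,
                     features = empty_features()) {
  sequence <- toupper(sequence)
  check_dna(sequence, sprintf("replicon '%s'", id))
  len <- nchar(sequence)
  if (nrow(features)) {
    bad <- features$start < 1L | features$start > len |
      features$end < 1L | features$end > len
    if (any(bad))
      stop("feature coordinates outside [1, length]: ",
           paste(features$id[bad], collapse = ", "))
  }
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular),
                 length = len, features = features),
            class = "replicon")
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %d bp, %s, %d feature(s)\n", x$id, x$length,
              if (x$circular) "circular" else "linear", nrow(x$features)))
  if (nrow(x$features)) {
    tab <- table(x$features$kind)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract a (possibly wrapping, possibly reverse-strand) subsequence
#'
#' This is the coordinate contract every detector relies on: on a circular
#' molecule a request running past the end wraps around the origin; strand
#' `"-"` returns the reverse complement of the extracted plus-strand text.
#'
#' @param x A [replicon()].
#' @param start 1-based start position on the plus strand.
#' @param length Number of bases to extract (at most the molecule length).
#' @param strand `"+"` or `"-"`.
#' @return A nucleotide string of `length` characters.
#' @export
#' @examples
#' r <- replicon("toy", "AAAAAAAAGC", circular = TRUE)
#' replicon_subseq(r, 9, 4)            # "GCAA"
#' replicon_subseq(r, 9, 4, "-")       # "TTGC"
replicon_subseq <- function(x, start, length, strand = "+") {
  stopifnot(inherits(x, "replicon"))
  if (length < 0L) stop("negative length")
  if (length == 0L) return("")
  if (start < 1L || start > x$length)
    stop(sprintf("start %d outside [1, %d]", start, x$length))
  if (length > x$length)
    stop("requested length exceeds molecule length")
  end <- start + length - 1L
  if (end <= x$length) {
    out <- substr(x$sequence, start, end)
  } else {
    if (!x$circular)
      stop(sprintf("request [%d, %d] runs past the end of linear molecule '%s'",
                   start, end, x$id))
    out <- paste0(substr(x$sequence, start, x$length),
                  substr(x$sequence, 1L, end - x$length))
  }
  if (strand == "-") out <- revcomp(out)
  out
}

## ---------------------------------------------------------------------------
## FASTA

read_fasta_one <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no records in FASTA file: ", path)
  list(id = sub("\\s.*$", "", names(ss)[1L]),
       sequence = toupper(as.character(ss[[1L]])))
}

## ---------------------------------------------------------------------------
## GenBank flat file (minimal reader/writer: LOCUS topology, feature table
## with location + qualifiers, ORIGIN block).  No installed R package parses
## GenBank flat files offline, so this subset is implemented here.

gb_kind <- function(key) {
  switch(key,
         CDS = "CDS", tRNA = "tRNA", repeat_region = "repeat_region",
         rep_origin = "oriV", oriT = "oriT", "misc")
}

parse_gb_location <- function(loc, len) {
  wraps <- FALSE
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
    rng <- do.call(rbind, lapply(parts, function(p) {
      m <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
      if (length(m) == 1L) m <- c(m, m)
      m
    }))
    # a join whose second segment restarts at 1 is an origin-spanning feature
    if (nrow(rng) == 2L && rng[1L, 2L] == len && rng[2L, 1L] == 1L) {
      return(list(start = rng[1L, 1L], end = rng[2L, 2L],
                  strand = strand, wraps = TRUE))
    }
    return(list(start = min(rng), end = max(rng), strand = strand,
                wraps = FALSE))
  }
  m <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1L]])
  if (length(m) == 1L) m <- c(m, m)
  if (anyNA(m)) stop("unparseable GenBank location: ", loc)
  list(start = m[1L], end = m[2L], strand = strand, wraps = FALSE)
}

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  toks <- strsplit(trimws(locus[1L]), "\\s+")[[1L]]
  id <- toks[2L]
  declared_len <- suppressWarnings(as.integer(toks[3L]))
  circular <- any(grepl("\\bcircular\\b", locus[1L], ignore.case = TRUE))

  ori_at <- grep("^ORIGIN", lines)
  if (!length(ori_at)) stop("GenBank record without ORIGIN block: ", path)
  seq_lines <- lines[(ori_at[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste0(seq_lines, collapse = "")))
  if (!is.na(declared_len) && nchar(sequence) != declared_len)
    warning(sprintf("LOCUS length %d differs from ORIGIN length %d in %s",
                    declared_len, nchar(sequence), path))
  len <- nchar(sequence)

  feats <- empty_features()
  f_at <- grep("^FEATURES", lines)
  if (length(f_at)) {
    block <- lines[(f_at[1L] + 1L):(ori_at[1L] - 1L)]
    # feature lines start at column 6, continuation/qualifier lines at column 22
    starts <- grep("^     \\S", block)
    for (k in seq_along(starts)) {
      from <- starts[k]
      to <- if (k < length(starts)) starts[k + 1L] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^\\s*(\\S+).*$", "\\1", chunk[1L])
      if (key == "source") next
      body <- trimws(c(sub("^\\s*\\S+\\s*", "", chunk[1L]), trimws(chunk[-1L])))
      # location may continue over lines until the first /qualifier
      qual_at <- grep("^/", body)
      loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(body)
      loc <- paste0(body[seq_len(loc_end)], collapse = "")
      quals <- character()
      if (length(qual_at)) {
        qtxt <- paste0(body[qual_at[1L]:length(body)], collapse = "\n")
        # re-split at qualifier starts; values may span lines
        pieces <- strsplit(qtxt, "\n/", fixed = TRUE)[[1L]]
        pieces[1L] <- sub("^/", "", pieces[1L])
        for (p in pieces) {
          kv <- sub("\n", " ", p, fixed = TRUE)
          kv <- gsub("\n", " ", kv, fixed = TRUE)
          if (grepl("=", kv, fixed = TRUE)) {
            qk <- sub("=.*$", "", kv)
            qv <- sub("^[^=]*=", "", kv)
            qv <- gsub("^\"|\"$", "", qv)
          } else {
            qk <- kv; qv <- ""
          }
          quals[qk] <- qv
        }
      }
      pl <- parse_gb_location(loc, len)
      fid <- if (!is.na(quals["locus_tag"])) unname(quals["locus_tag"]) else NULL
      feats <- rbind(feats, feature(gb_kind(key), pl$start, pl$end,
                                    strand = pl$strand, wraps = pl$wraps,
                                    id = fid, qualifiers = quals))
    }
  }
  list(id = id, sequence = sequence, circular = circular, features = feats)
}

gb_key <- function(kind) {
  switch(kind, CDS = "CDS", tRNA = "tRNA", repeat_region = "repeat_region",
         oriV = "rep_origin", oriT = "oriT", "misc_feature")
}

write_genbank <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (x$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s   UNA",
                     x$id, x$length, topo), con)
  writeLines(sprintf("DEFINITION  %s.", x$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", x$length), con)
  if (nrow(x$features)) {
    for (i in seq_len(nrow(x$features))) {
      f <- x$features[i, ]
      loc <- if (f$wraps)
        sprintf("join(%d..%d,1..%d)", f$start, x$length, f$end)
      else sprintf("%d..%d", f$start, f$end)
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-16s%s", gb_key(f$kind), loc), con)
      q <- f$qualifiers[[1L]]
      q["locus_tag"] <- f$id
      for (qk in names(q))
        writeLines(sprintf("                     /%s=\"%s\"", qk, q[[qk]]), con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, x$length, by = 60L)
  for (p in pos) {
    chunk <- substr(x$sequence, p, min(p + 59L, x$length))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## GFF3 (+ companion FASTA) via rtracklayer

gff_kind <- function(type) {
  ifelse(type %in% c("CDS", "tRNA", "repeat_region", "oriT"), type,
         ifelse(type %in% c("rep_origin", "oriV"), "oriV", "misc"))
}

read_gff3 <- function(path, fasta) {
  if (is.null(fasta)) stop("GFF3 input needs a companion FASTA (fasta = ...)")
  fa <- read_fasta_one(fasta)
  gr <- rtracklayer::import(path, format = "gff3")
  feats <- empty_features()
  if (length(gr)) {
    md <- S4Vectors::mcols(gr)
    for (i in seq_along(gr)) {
      quals <- character()
      if (!is.null(md$product) && !is.na(md$product[i]))
        quals["product"] <- as.character(md$product[i])
      if (!is.null(md$Name) && !is.na(md$Name[i]))
        quals["name"] <- as.character(md$Name[i])
      fid <- if (!is.null(md$ID) && !is.na(md$ID[i]))
        as.character(md$ID[i]) else NULL
      st <- as.character(BiocGenerics::strand(gr[i]))
      feats <- rbind(feats, feature(
        gff_kind(as.character(md$type[i])),
        BiocGenerics::start(gr[i]), BiocGenerics::end(gr[i]),
        strand = if (st == "*") "*" else st, id = fid, qualifiers = quals))
    }
  }
  list(id = fa$id, sequence = fa$sequence, circular = NA, features = feats)
}

gff_type <- function(kind) {
  switch(kind, CDS = "CDS", tRNA = "tRNA", repeat_region = "repeat_region",
         oriV = "rep_origin", oriT = "oriT", "sequence_feature")
}

write_gff3 <- function(x, path, fasta = NULL) {
  feats <- x$features
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", x$id, x$length))
  if (nrow(feats)) {
    for (i in seq_len(nrow(feats))) {
      f <- feats[i, ]
      q <- f$qualifiers[[1L]]
      attrs <- sprintf("ID=%s", f$id)
      if (!is.na(q["product"]))
        attrs <- paste0(attrs, ";product=", q[["product"]])
      pieces <- interval_pieces(f$start, f$end, x$length, f$wraps)
      for (j in seq_len(nrow(pieces)))
        lines <- c(lines, paste(x$id, "imescan", gff_type(f$kind),
                                pieces[j, 1L], pieces[j, 2L], ".",
                                if (f$strand == "*") "." else f$strand,
                                ".", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(x$sequence)
    names(ss) <- x$id
    Biostrings::writeXStringSet(ss, fasta)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------

#' Read a replicon from FASTA, GenBank or GFF3 (+FASTA)
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"fasta"`, `"genbank"` or
#'   `"gff3"`.
#' @param circular Circularity flag; for GenBank the LOCUS topology wins
#'   when present, otherwise this argument is used (default linear).
#' @param fasta Companion FASTA path, required for GFF3 input.
#' @return A [replicon()].
#' @export
read_replicon <- function(path, format = c("auto", "fasta", "genbank", "gff3"),
                          circular = NA, fasta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gb", "gbk", "genbank")) "genbank"
    else if (ext %in% c("gff", "gff3")) "gff3"
    else "fasta"
  }
  rec <- switch(format,
                fasta = c(read_fasta_one(path),
                          list(circular = NA, features = empty_features())),
                genbank = read_genbank(path),
                gff3 = read_gff3(path, fasta))
  circ <- if (!is.na(rec$circular)) rec$circular
  else if (!is.na(circular)) circular else FALSE
  replicon(rec$id, rec$sequence, circular = circ, features = rec$features)
}

#' Write a replicon to FASTA, GenBank or GFF3
#'
#' @param x A [replicon()].
#' @param path Output file.
#' @param format Output format; `"auto"` chooses by extension.
#' @param fasta For GFF3 output, optional companion FASTA path.
#' @return `path`, invisibly.
#' @export
write_replicon <- function(x, path,
                           format = c("auto", "fasta", "genbank", "gff3"),
                           fasta = NULL) {
  stopifnot(inherits(x, "replicon"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gb", "gbk", "genbank")) "genbank"
    else if (ext %in% c("gff", "gff3")) "gff3"
    else "fasta"
  }
  switch(format,
         fasta = {
           ss <- Biostrings::DNAStringSet(x$sequence)
           names(ss) <- x$id
           Biostrings::writeXStringSet(ss, path)
         },
         genbank = write_genbank(x, path),
         gff3 = write_gff3(x, path, fasta = fasta))
  invisible(path)
}

#' Read genomic-island intervals from BED
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention.
#'
#' @param path BED file (>= 3 columns).
#' @return Data frame with columns `molecule`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_genomic_islands <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(molecule = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## tRNA library

#' Build a tRNA library from annotated replicons
#'
#' Extracts every annotated tRNA gene, strand-corrected so the stored
#' sequence reads 5' to 3', together with its 3'-terminal segment (the
#' anchor used for att-site matching) and its genomic flanks.
#'
#' @param replicons A [replicon()] or list of replicons carrying `tRNA`
#'   features.
#' @param flank_bp Flank length to store on either side (truncated at the
#'   ends of linear molecules).
#' @param terminus_bp Length of the 3'-terminal anchor segment.
#' @return A data frame of class `trna_library` with one row per tRNA:
#'   `source_id`, `trna_id`, `isotype`, `sequence`, `three_prime_terminus`,
#'   `upstream_flank`, `downstream_flank`, `n_in_terminus`.
#' @export
build_trna_library <- function(replicons, flank_bp = 500L, terminus_bp = 25L) {
  if (inherits(replicons, "replicon")) replicons <- list(replicons)
  rows <- list()
  for (r in replicons) {
    tr <- r$features[r$features$kind == "tRNA", , drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      f <- tr[i, ]
      if (!f$strand %in% c("+", "-"))
        stop("tRNA feature without a defined strand: ", f$id)
      glen <- if (f$wraps) r$length - f$start + 1L + f$end
      else f$end - f$start + 1L
      gene <- replicon_subseq(r, f$start, glen, strand = f$strand)
      tb <- min(terminus_bp, glen)
      term <- substr(gene, glen - tb + 1L, glen)
      # flanks in gene orientation: upstream precedes the 5' end
      if (f$strand == "+") {
        up_len <- if (r$circular) flank_bp else min(flank_bp, f$start - 1L)
        up_start <- if (r$circular) wrap_pos(f$start - up_len, r$length)
        else f$start - up_len
        up <- if (up_len > 0L) replicon_subseq(r, up_start, up_len, "+") else ""
        dn_start <- wrap_pos(f$start + glen, r$length)
        dn_len <- if (r$circular) flank_bp
        else min(flank_bp, r$length - (f$start + glen - 1L))
        dn <- if (dn_len > 0L) replicon_subseq(r, dn_start, dn_len, "+") else ""
      } else {
        # minus strand: genomic downstream of `end` is the gene's upstream
        up_start <- wrap_pos(f$start + glen, r$length)
        up_len <- if (r$circular) flank_bp
        else min(flank_bp, r$length - (f$start + glen - 1L))
        up <- if (up_len > 0L)
          revcomp(replicon_subseq(r, up_start, up_len, "+")) else ""
        dn_len <- if (r$circular) flank_bp else min(flank_bp, f$start - 1L)
        dn_start <- if (r$circular) wrap_pos(f$start - dn_len, r$length)
        else f$start - dn_len
        dn <- if (dn_len > 0L)
          revcomp(replicon_subseq(r, dn_start, dn_len, "+")) else ""
      }
      q <- f$qualifiers[[1L]]
      iso <- if (!is.na(q["product"])) unname(q[["product"]]) else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = r$id, trna_id = f$id, isotype = iso, sequence = gene,
        three_prime_terminus = term, upstream_flank = up,
        downstream_flank = dn, n_in_terminus = grepl("N", term, fixed = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_id = character(), trna_id = character(),
               isotype = character(), sequence = character(),
               three_prime_terminus = character(),
               upstream_flank = character(), downstream_flank = character(),
               n_in_terminus = logical(), stringsAsFactors = FALSE)
  class(out) <- c("trna_library", class(out))
  out
}
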