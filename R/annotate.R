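# Six-frame ORF calling, GC content, coding density, and the
# functional-module report that assembles all detector outputs.

STOP_CODONS <- c("TAA", "TAG", "TGA")  # genetic code table 11

## scan one strand of a (possibly doubled, for circular molecules) text:
## returns ORFs as text-coordinate start/end (inclusive of the stop codon)
scan_frames <- function(text, L, circular, min_nt, start_codons) {
  n <- nchar(text)
  ch <- s2c(text)
  orfs <- list()
  for (frame in 0:2) {
    cod_starts <- seq(1L + frame, n - 2L, by = 3L)
    codons <- paste0(ch[cod_starts], ch[cod_starts + 1L], ch[cod_starts + 2L])
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons %in% start_codons
    seg_begin <- 1L   # codon index where the current stop-to-stop segment starts
    k <- 1L
    while (k <= length(codons)) {
      if (is_stop[k]) {
        # first start codon in [seg_begin, k-1] gives the longest reading
        if (k > seg_begin) {
          cand <- seg_begin - 1L + which(is_start[seg_begin:(k - 1L)])
          if (length(cand)) {
            a <- cand[1L]
            s <- cod_starts[a]; e <- cod_starts[k] + 2L
            nt <- e - s + 1L
            if (nt >= min_nt && (!circular || (nt <= L && s <= L)))
              orfs[[length(orfs) + 1L]] <-
                c(start = s, end = e, frame = frame, aa = nt %/% 3L - 1L)
          }
        }
        seg_begin <- k + 1L
      }
      k <- k + 1L
    }
  }
  orfs
}

#' Call open reading frames in all six frames
#'
#' Within each stop-to-stop segment the longest open reading (from the
#' first start codon) is reported, ending at (and including) the stop
#' codon.  On circular molecules ORFs may wrap the origin.
#'
#' @param x A [replicon()].
#' @param min_length_aa Minimum protein length in amino acids (>= 10
#'   recommended; smaller values are accepted for toy inputs).
#' @param start_codons Accepted start codons (bacterial defaults ATG, GTG,
#'   TTG).
#' @return Data frame of class `orf_calls`: `start`, `end` (1-based,
#'   inclusive of stop codon), `strand`, `frame`, `length_aa`,
#'   `wraps_origin`.
#' @export
call_orfs <- function(x, min_length_aa = 50L,
                      start_codons = c("ATG", "GTG", "TTG")) {
  stopifnot(inherits(x, "replicon"))
  L <- x$length
  min_nt <- 3L * (as.integer(min_length_aa) + 1L)  # coding codons + stop
  rows <- list()
  for (strand in c("+", "-")) {
    base <- if (strand == "+") x$sequence else revcomp(x$sequence)
    text <- if (x$circular) paste0(base, base) else base
    found <- scan_frames(text, L, x$circular, min_nt, start_codons)
    for (o in found) {
      s <- o[["start"]]; e <- o[["end"]]
      wraps <- x$circular && e > L
      if (strand == "-") {
        # reverse-text position p maps to plus-strand position L - p + 1
        # (wrapping representatives in the doubled text map through mod L)
        p_start <- L - wrap_pos(e, L) + 1L
        p_end <- L - s + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          start = p_start, end = p_end, strand = "-", frame = o[["frame"]],
          length_aa = o[["aa"]], wraps_origin = wraps,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, end = if (wraps) e - L else e, strand = "+",
          frame = o[["frame"]], length_aa = o[["aa"]], wraps_origin = wraps,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), strand = character(),
               frame = integer(), length_aa = integer(),
               wraps_origin = logical(), stringsAsFactors = FALSE)
  if (nrow(out)) {
    out <- unique(out)
    out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("orf_calls", class(out))
  out
}

#' GC content of a replicon
#'
#' @param x A [replicon()] or a nucleotide string.
#' @return Percentage 100 * (G+C) / (A+C+G+T); N is excluded from both
#'   numerator and denominator.
#' @export
#' @examples
#' gc_content(replicon("toy", "ATGC"))  # 50
gc_content <- function(x) {
  s <- if (inherits(x, "replicon")) x$sequence else toupper(x)
  if (!nchar(s)) stop("empty sequence")
  ch <- s2c(s)
  denom <- sum(ch %in% DNA_BASES)
  if (denom == 0L) stop("sequence contains no A/C/G/T (all N?)")
  100 * sum(ch %in% c("G", "C")) / denom
}

#' Coding density from CDS intervals
#'
#' @param features Feature table (only `CDS` rows are used) or a
#'   [replicon()].
#' @param length_bp Molecule length (taken from the replicon if given).
#' @return Percentage 100 * |union of CDS spans| / length; overlapping
#'   intervals counted once, wrap-around intervals handled.
#' @export
coding_density <- function(features, length_bp = NULL) {
  if (inherits(features, "replicon")) {
    length_bp <- features$length
    features <- features$features
  }
  if (is.null(length_bp)) stop("length_bp required")
  cds <- features[features$kind == "CDS", , drop = FALSE]
  if (!nrow(cds)) return(0)
  covered <- logical(length_bp)
  for (i in seq_len(nrow(cds))) {
    if (cds$start[i] < 1L || cds$end[i] > length_bp)
      stop("CDS interval outside [1, length]: row ", i)
    pieces <- interval_pieces(cds$start[i], cds$end[i], length_bp,
                              cds$wraps[i])
    for (j in seq_len(nrow(pieces)))
      covered[pieces[j, 1L]:pieces[j, 2L]] <- TRUE
  }
  100 * sum(covered) / length_bp
}

#' Summary statistics of a replicon
#'
#' @param x A [replicon()].
#' @return A list of class `replicon_stats`: `id`, `length_bp`,
#'   `gc_percent` (2 dp), `cds_count`, `coding_density_percent` (1 dp).
#' @export
replicon_stats <- function(x) {
  stopifnot(inherits(x, "replicon"))
  out <- list(id = x$id, length_bp = x$length,
              gc_percent = round(gc_content(x), 2),
              cds_count = sum(x$features$kind == "CDS"),
              coding_density_percent = round(coding_density(x), 1))
  class(out) <- "replicon_stats"
  out
}

#' @export
print.replicon_stats <- function(x, ...) {
  cat(sprintf("<replicon stats> %s: %d bp, GC %.2f%%, %d CDS, coding density %.1f%%\n",
              x$id, x$length_bp, x$gc_percent, x$cds_count,
              x$coding_density_percent))
  invisible(x)
}

#' Default keyword map for functional-module assignment
#'
#' Maps lower-case substrings of feature qualifiers (`product`, `gene`,
#' `note`) to functional groups.
#'
#' @return Named list of character vectors, group -> keywords.
#' @export
default_keyword_map <- function() {
  list(
    replication = c("repa", "replication initiat", "oriv", "iteron", "dnaa"),
    `partition/maintenance` = c("para", "parb", "partition", "relb", "rele",
                                "toxin", "antitoxin", "addiction"),
    mobilization = c("orit", "repb", "relaxase", "mob", "tra "),
    integration = c("integrase", "recombinase", "attp", "attb", "copg",
                    "xerc", "xerd", "phage int"),
    degradation = c("opd", "hydrolase", "phosphotriesterase", "dioxygenase",
                    "liga", "ligb", "lysr", "facilitator", "transporter",
                    "mutase"),
    `mobile elements` = c("transposase", "resolvase", "insertion sequence",
                          "tnpa", "tnpr", "istb", "ista"))
}

#' Assemble a functional-module report
#'
#' Groups annotated features into functional modules using a keyword map
#' over their qualifiers, attaches detector outputs (ori/ter call, iteron
#' arrays, motif hits, AT-rich windows, inverted repeats, att candidates,
#' transposon units), and cross-references the replication module: an ori
#' call with an iteron array within 2 kb is flagged as a consistent oriV.
#'
#' @param x A [replicon()].
#' @param detections Named list with any of `ori_ter`, `iterons`,
#'   `dnaa_boxes`, `at_rich`, `inverted_repeats`, `att_candidates`,
#'   `transposons`.
#' @param keyword_map See [default_keyword_map()].
#' @return A list of class `module_report`.
#' @export
module_report <- function(x, detections = list(),
                          keyword_map = default_keyword_map()) {
  stopifnot(inherits(x, "replicon"))
  groups <- c(names(keyword_map), "unassigned")
  assign_group <- function(quals) {
    txt <- tolower(paste(quals[intersect(names(quals),
                                         c("product", "gene", "note", "name"))],
                         collapse = " "))
    for (g in names(keyword_map))
      if (any(vapply(keyword_map[[g]], grepl, logical(1L), x = txt,
                     fixed = TRUE)))
        return(g)
    "unassigned"
  }
  feature_groups <- stats::setNames(
    lapply(groups, function(g) character()), groups)
  for (i in seq_len(nrow(x$features))) {
    g <- assign_group(x$features$qualifiers[[i]])
    feature_groups[[g]] <- c(feature_groups[[g]], x$features$id[i])
  }
  # replication cross-reference: ori call near an iteron array
  xref <- NULL
  ot <- detections$ori_ter
  it <- detections$iterons
  if (!is.null(ot) && !ot$no_call && !is.null(it) && nrow(it)) {
    d <- circ_dist(ot$ori_position, it$start, x$length)
    if (any(d <= 2000L))
      xref <- sprintf(
        "predicted ori at %d lies within 2 kb of iteron array at %d (consistent oriV)",
        ot$ori_position, it$start[which.min(d)])
  }
  out <- list(replicon = x$id, length_bp = x$length,
              feature_groups = feature_groups,
              detections = detections,
              replication_crossref = xref)
  class(out) <- "module_report"
  out
}

#' @export
print.module_report <- function(x, ...) {
  cat(sprintf("<module report> %s (%d bp)\n", x$replicon, x$length_bp))
  for (g in names(x$feature_groups))
    cat(sprintf("  %-22s %d feature(s)\n", g, length(x$feature_groups[[g]])))
  if (!is.null(x$replication_crossref))
    cat("  note:", x$replication_crossref, "\n")
  invisible(x)
}

## serializable form of a module report (for JSON output)
report_to_list <- function(report) {
  det <- lapply(report$detections, function(d) {
    if (is.data.frame(d)) {
      d$per_copy_mismatches <- NULL
      d
    } else if (inherits(d, "ori_ter_call")) unclass(d)
    else if (inherits(d, "transposon_calls")) list(copies = d$copies,
                                                   units = d$units)
    else d
  })
  list(replicon = report$replicon, length_bp = report$length_bp,
       feature_groups = report$feature_groups, detections = det,
       replication_crossref = report$replication_crossref)
}

#' Write a module report as JSON
#'
#' @param report A `module_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_module_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
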