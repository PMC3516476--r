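# Full-pipeline orchestration: skew -> repeats -> att -> annotate ->
# module report, with config control and a run manifest.  Outputs are
# plain TSV/JSON/GFF3 with no timestamps, so a rerun with the same config
# and seed is byte-identical.

#' Default pipeline configuration
#'
#' Every module's tunable parameters in one nested list; unknown keys are
#' rejected by [run_all()].
#'
#' @return Nested named list of parameter blocks.
#' @export
default_config <- function() {
  list(
    skew = list(window_bp = 500L, step_bp = 100L, convention = "min_ori"),
    repeats = list(min_arm = 10L, max_spacer = 50L, max_mismatch = 0L),
    iterons = list(unit_min = 15L, unit_max = 25L, min_copies = 3L,
                   max_mismatch_per_copy = 1L),
    motif = list(motif = "TTATCCACA", max_mismatch = 1L),
    at_rich = list(window_bp = 50L, min_at_fraction = 0.8),
    att = list(min_match_bp = 10L, require_terminus_anchor = TRUE,
               intergenic_only = FALSE),
    orf = list(min_length_aa = 50L),
    transposon = list(repeat_seed = NULL, min_copy_identity = 0.9))
}

merge_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  bad <- setdiff(names(config), names(base))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in names(config)) {
    bad <- setdiff(names(config[[blk]]), names(base[[blk]]))
    if (length(bad))
      stop(sprintf("unknown key(s) in config block '%s': %s", blk,
                   paste(bad, collapse = ", ")))
    base[[blk]][names(config[[blk]])] <- config[[blk]]
  }
  base
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  df <- df[, !vapply(df, is.list, logical(1L)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the whole annotation pipeline on a replicon
#'
#' Stages: GC-skew ori/ter prediction, repeat detection (inverted repeats,
#' iterons, DnaA-box motifs, AT-rich windows, transposon delineation), att
#' candidate search (when a tRNA library is supplied), ORF/stats
#' annotation, and the functional-module report.  All stage outputs plus a
#' manifest are written under `outdir`.
#'
#' @param input A [replicon()] or a path readable by [read_replicon()].
#' @param outdir Output directory (created if needed).
#' @param trna_library Optional [build_trna_library()] table for the att
#'   stage.
#' @param gi_intervals Optional genomic-island intervals (see
#'   [read_genomic_islands()]).
#' @param config Partial configuration merged over [default_config()].
#' @param circular Circularity flag for file input.
#' @return Invisibly, a list with `status` (0 on success) and `manifest`.
#' @export
run_all <- function(input, outdir, trna_library = NULL, gi_intervals = NULL,
                    config = NULL, circular = NA) {
  cfg <- merge_config(config)
  if (is.character(input)) {
    if (!file.exists(input)) stop("input path does not exist: ", input)
    input <- read_replicon(input, circular = circular)
  }
  stopifnot(inherits(input, "replicon"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(input = input$id, length_bp = input$length,
                   config = cfg, stages = list(), status = "ok")
  status <- 0L
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(e))
    manifest$status <<- "failed"
    status <<- 1L
  }
  detections <- list()

  # 1. skew --------------------------------------------------------------
  tryCatch({
    prof <- window_skew(input, cfg$skew$window_bp, cfg$skew$step_bp)
    call <- predict_ori_ter(prof, convention = cfg$skew$convention)
    write_tsv(prof, file.path(outdir, "skew_profile.tsv"))
    jsonlite::write_json(unclass(call), file.path(outdir, "ori_ter.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    detections$ori_ter <- call
    manifest$stages$skew <- list(status = "ok",
                                 files = c("skew_profile.tsv", "ori_ter.json"))
  }, error = function(e) fail("skew", e))

  # 2. repeats ------------------------------------------------------------
  tryCatch({
    irs <- find_inverted_repeats(input, cfg$repeats$min_arm,
                                 cfg$repeats$max_spacer,
                                 cfg$repeats$max_mismatch)
    its <- find_iterons(input, cfg$iterons$unit_min, cfg$iterons$unit_max,
                        cfg$iterons$min_copies,
                        cfg$iterons$max_mismatch_per_copy)
    mot <- find_motif(input, cfg$motif$motif, cfg$motif$max_mismatch)
    atr <- find_at_rich(input, cfg$at_rich$window_bp,
                        cfg$at_rich$min_at_fraction)
    tn <- delineate_transposon(input, cfg$transposon$repeat_seed,
                               cfg$transposon$min_copy_identity)
    write_tsv(irs, file.path(outdir, "inverted_repeats.tsv"))
    write_tsv(its, file.path(outdir, "iterons.tsv"))
    write_tsv(mot, file.path(outdir, "motif_hits.tsv"))
    write_tsv(atr, file.path(outdir, "at_rich.tsv"))
    write_tsv(tn$units, file.path(outdir, "transposon_units.tsv"))
    detections$inverted_repeats <- irs
    detections$iterons <- its
    detections$dnaa_boxes <- mot
    detections$at_rich <- atr
    detections$transposons <- tn
    manifest$stages$repeats <- list(
      status = "ok", files = c("inverted_repeats.tsv", "iterons.tsv",
                               "motif_hits.tsv", "at_rich.tsv",
                               "transposon_units.tsv"))
  }, error = function(e) fail("repeats", e))

  # 3. att ----------------------------------------------------------------
  tryCatch({
    if (!is.null(trna_library) && nrow(trna_library)) {
      cands <- find_att_candidates(
        trna_library, input, min_match_bp = cfg$att$min_match_bp,
        require_terminus_anchor = cfg$att$require_terminus_anchor)
      cands <- filter_att_candidates(cands, input, gi_intervals,
                                     intergenic_only = cfg$att$intergenic_only)
    } else {
      cands <- find_att_candidates(build_trna_library(list()), input)
    }
    write_tsv(cands, file.path(outdir, "att_candidates.tsv"))
    detections$att_candidates <- cands
    manifest$stages$att <- list(status = "ok", files = "att_candidates.tsv")
  }, error = function(e) fail("att", e))

  # 4. annotate -----------------------------------------------------------
  tryCatch({
    orfs <- call_orfs(input, cfg$orf$min_length_aa)
    stats <- replicon_stats(input)
    write_tsv(orfs, file.path(outdir, "orfs.tsv"))
    write_tsv(data.frame(id = stats$id, length_bp = stats$length_bp,
                         gc_percent = stats$gc_percent,
                         cds_count = stats$cds_count,
                         coding_density_percent = stats$coding_density_percent),
              file.path(outdir, "stats.tsv"))
    detections$orfs <- orfs
    manifest$stages$annotate <- list(status = "ok",
                                     files = c("orfs.tsv", "stats.tsv"))
  }, error = function(e) fail("annotate", e))

  # 5. report -------------------------------------------------------------
  tryCatch({
    rep <- module_report(input, detections)
    write_module_report(rep, file.path(outdir, "report.json"))
    write_gff3(input, file.path(outdir, "features.gff3"))
    manifest$stages$report <- list(status = "ok",
                                   files = c("report.json", "features.gff3"))
  }, error = function(e) fail("report", e))

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(list(status = status, manifest = manifest))
}
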