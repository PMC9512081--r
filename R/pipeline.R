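# End-to-end study-shaped pipeline: simulate -> consensus -> gene-set
# enrichment -> repeat enrichment -> resampling -> overlap permutation ->
# gene-body signal comparison, with every stage's output written as
# TSV/JSON/BED and a machine-readable run manifest sufficient to re-run
# identically. All randomness flows through explicit seeds recorded in the
# manifest; outputs are byte-identical across re-runs with the same config
# and seed (timestamps live only in messages).

#' Run the full synthetic-study pipeline
#'
#' @param config a \code{\link{studyConfig}}
#' @param outputDir directory for all outputs (created if needed)
#' @param seed master seed; the per-stage seeds derived from it are recorded
#'   in the run manifest
#' @param R resamples/permutations for the empirical-p stages
#' @param maxDistance gene-set proximity cutoff in bp
#' @param window repeat-enrichment window size in bp
#' @param minSupport per-base support for consensus/permutation (default:
#'   all peak tracks)
#' @param quiet suppress progress messages
#' @return invisibly, a list with the per-stage results and the manifest
#' @export
runPipeline <- function(config = studyConfig(), outputDir, seed = config$seed,
                        R = 1000, maxDistance = 50000, window = 100,
                        minSupport = NULL, quiet = FALSE) {
  seed <- .checkSeed(seed)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  studyDir <- file.path(outputDir, "study")

  say("simulating study (seed ", seed, ")")
  bundle <- generateStudy(config, seed = seed, writeDir = studyDir)
  tracks <- studyPeaks(bundle)
  if (is.null(minSupport)) minSupport <- length(tracks)

  say("consensus across ", length(tracks), " tracks (min support ",
      minSupport, ")")
  consensus <- consensusPeaks(as.list(tracks), minSupport = minSupport,
                              genome = studyGenome(bundle))
  writeBed(consensus, file.path(outputDir, "consensus.bed"))

  say("gene-set enrichment (", length(studyGeneSets(bundle)), " sets)")
  enr <- geneSetEnrichment(studyPeaks(bundle, 1), studyGenes(bundle),
                           universe = studyBackgroundPool(bundle),
                           geneSets = studyGeneSets(bundle),
                           maxDistance = maxDistance)
  writeEnrichmentTsv(enr, file.path(outputDir, "geneset_enrichment.tsv"))

  say("repeat-family enrichment (", window, " bp windows)")
  rep_enr <- repeatFamilyEnrichment(studyPeaks(bundle, 1),
                                    studyRepeats(bundle),
                                    studyGenome(bundle),
                                    blacklist = studyBlacklist(bundle),
                                    window = window)
  writeEnrichmentTsv(rep_enr, file.path(outputDir, "repeat_enrichment.tsv"))

  say("gene-set resampling test (R = ", R, ")")
  resamp <- geneSetResamplingTest(studyTargetSet(bundle),
                                  studyBackgroundPool(bundle),
                                  studyPeaks(bundle, 1), studyGenes(bundle),
                                  maxDistance = maxDistance, R = R,
                                  seed = .substream(seed, 101L))
  say("overlap permutation test (R = ", R, ")")
  perm <- multiwayOverlapPermutationTest(as.list(tracks),
                                         studyGenome(bundle),
                                         excluded = studyBlacklist(bundle),
                                         minSupport = minSupport, R = R,
                                         seed = .substream(seed, 102L))
  empJson <- list(
    resampling = list(observed = resamp@observed, R = resamp@R, k = resamp@k,
                      empirical_p = resamp@empiricalP,
                      seed = resamp@seed, direction = resamp@direction),
    permutation = list(observed = perm@observed, R = perm@R, k = perm@k,
                       empirical_p = perm@empiricalP,
                       seed = perm@seed, direction = perm@direction,
                       n_consensus = length(consensus)))
  jsonlite::write_json(empJson, file.path(outputDir, "empirical_tests.json"),
                       auto_unbox = TRUE, digits = NA)

  signalRes <- NULL
  if (!is.null(studySignal(bundle, "wt"))) {
    say("gene-body signal comparison")
    signalRes <- geneBodyRatioComparison(studySignal(bundle, "ko"),
                                         studySignal(bundle, "wt"),
                                         studyGenes(bundle),
                                         studyDeClasses(bundle),
                                         binSize = config$signal$bin)
    utils::write.table(signalRes$perGene,
                       file.path(outputDir, "gene_body_log2_ratio.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(signalRes$tests,
                         file.path(outputDir, "signal_tests.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  inputs <- list.files(studyDir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("chromEnrich")),
    seed = seed,
    stage_seeds = list(resampling = .substream(seed, 101L),
                       permutation = .substream(seed, 102L)),
    parameters = list(R = R, max_distance = maxDistance, window = window,
                      min_support = minSupport),
    config = {
      cfg <- if (inherits(config, "StudyConfig")) unclass(config) else config
      cfg$repeats$families <- as.list(cfg$repeats$families)
      cfg
    },
    input_md5 = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                        basename(inputs))),
    outputs = basename(list.files(outputDir)))
  jsonlite::write_json(manifest, file.path(outputDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done")
  invisible(list(bundle = bundle, consensus = consensus,
                 geneSetEnrichment = enr, repeatEnrichment = rep_enr,
                 resampling = resamp, permutation = perm,
                 signal = signalRes, manifest = manifest))
}
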