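#' @importFrom tools md5sum
NULL

# SimConfig / CallerParams as plain lists for the manifest
.configAsList <- function(config) {
  g <- config@genome
  list(nSamples = config@nSamples,
       tumorTypeWeights = as.list(config@tumorTypeWeights),
       pAmplification = config@pAmplification,
       ampTotalCnRange = config@ampTotalCnRange,
       pFocalDelGivenAmp = config@pFocalDelGivenAmp,
       pFocalDelGivenNoAmp = config@pFocalDelGivenNoAmp,
       delLengthRange = config@delLengthRange,
       pDeletionFirst = config@pDeletionFirst,
       pDelOnAmpHaplotype = config@pDelOnAmpHaplotype,
       allelicMinBp = config@allelicMinBp,
       depthCoverage = config@depthCoverage,
       depthDispersion = config@depthDispersion,
       exprCoeffs = list(
         baselineByType = as.list(config@exprCoeffs@baselineByType),
         betaCN = config@exprCoeffs@betaCN,
         betaDel = config@exprCoeffs@betaDel),
       exprNoiseSd = config@exprNoiseSd,
       pScnaDropout = config@pScnaDropout,
       purity = config@purity,
       genome = list(chrom = g@chrom, genomeLength = g@genomeLength,
                     target = sprintf("%s:%d-%d", geneName(g@target),
                                      BiocGenerics::start(g@target),
                                      BiocGenerics::end(g@target))))
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Orchestrates simulate -> call-deletions -> time-events -> dosage model
#' -> differential expression -> report, writing every stage output plus a
#' run manifest into \code{outDir}.  All randomness derives from the
#' single master \code{seed}, so a rerun with identical config and seed
#' reproduces identical stage outputs.  A stage failure aborts with the
#' failing stage named; outputs of completed stages are retained and the
#' manifest marks the run incomplete.  Degenerate cohorts (no carriers, no
#' informative timing, too few groups) skip the affected downstream
#' stages gracefully, with the skip recorded in report and manifest.
#'
#' @param outDir output directory (created if needed).
#' @param config a \linkS4class{SimConfig}.
#' @param seed master seed.
#' @param params a \code{\link{callerParams}} list.
#' @param logLevel \code{"info"} (stage messages) or \code{"quiet"}.
#' @return Invisibly, a list with the stage results (\code{cohort},
#'   \code{calls}, \code{timing}, \code{dosage}, \code{de},
#'   \code{manifest}).
#' @examples
#' \donttest{
#' res <- runPipeline(tempfile("run"), simConfig(nSamples = 30L), seed = 7)
#' }
#' @export
runPipeline <- function(outDir, config = simConfig(), seed = 1L,
                        params = callerParams(), logLevel = "info") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outDir, "depth"), showWarnings = FALSE)
  say <- function(...) if (logLevel == "info") message(sprintf(...))
  manifest <- list(package = "ampliDel",
                   version = as.character(utils::packageVersion("ampliDel")),
                   seed = as.integer(seed),
                   config = .configAsList(config),
                   caller_params = unclass(params),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   complete = FALSE, stages = list())
  writeManifest <- function()
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      writeManifest()
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  g <- config@genome

  cohort <- stage("simulate", {
    ch <- simulateCohort(config, seed)
    writeSeg(ch$segments, file.path(outDir, "segments.seg"))
    writeBedpe(ch$junctions, file.path(outDir, "junctions.bedpe"))
    for (s in names(ch$depth))
      writeBedgraph(ch$depth[[s]],
                    file.path(outDir, "depth", paste0(s, ".bedgraph")))
    writeExpression(ch$expression, file.path(outDir, "expression.tsv"))
    writeSamples(ch$metadata, file.path(outDir, "metadata.tsv"))
    writeTruth(ch$truth, file.path(outDir, "truth.json"))
    writeBedLoci(list(g@driver, g@target, g@neighbor),
                 file.path(outDir, "loci.bed"))
    ch
  })
  manifest$input_digests <- as.list(md5sum(
    file.path(outDir, c("segments.seg", "junctions.bedpe",
                        "expression.tsv", "metadata.tsv"))))
  names(manifest$input_digests) <-
    basename(names(manifest$input_digests))
  manifest$stages$simulate <- list(status = "ok",
                                   n_samples = config@nSamples)
  say("simulate: %d samples, %d junctions", config@nSamples,
      length(cohort$junctions))

  calls <- stage("call-deletions", {
    cl <- callFocalDeletions(cohort$segments, cohort$junctions,
                             cohort$depth, g@target, g@neighbor, params)
    writeCalls(cl, file.path(outDir, "calls.tsv"))
    cl
  })
  carriers <- carrierSamples(calls)
  evTab <- table(calls$evidence_class)
  manifest$stages$`call-deletions` <-
    list(status = "ok", n_carriers = length(carriers),
         calls_by_class = as.list(evTab))
  say("call-deletions: %d carriers (%s)", length(carriers),
      paste(sprintf("%s=%d", names(evTab), evTab), collapse = ", "))

  timing <- stage("time-events", {
    if (length(carriers) == 0L) {
      say("time-events: skipped (zero carriers)")
      manifest$stages$`time-events` <- list(status = "skipped",
                                            reason = "zero carriers")
      NULL
    } else {
      tm <- tryCatch(runTiming(calls, cohort$segments, g@target, params),
                     error = function(e) {
                       if (grepl("no informative samples",
                                 conditionMessage(e)))
                         NULL else stop(e)
                     })
      if (is.null(tm)) {
        say("time-events: no informative samples")
        manifest$stages$`time-events` <-
          list(status = "skipped", reason = "no informative samples")
      } else {
        write.table(tm$calls, file.path(outDir, "timing.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        jsonlite::write_json(unclass(tm$summary),
                             file.path(outDir, "timing_summary.json"),
                             auto_unbox = TRUE, digits = NA)
        manifest$stages$`time-events` <-
          list(status = "ok", n_informative = tm$summary$n_informative,
               p_value = tm$summary$p_value)
        say("time-events: %d amp-first vs %d del-first, p = %.3g",
            tm$summary$n_amp_first, tm$summary$n_del_first,
            tm$summary$p_value)
      }
      tm
    }
  })

  dosage <- stage("model", {
    md <- cohort$metadata
    fpkm <- SummarizedExperiment::assay(cohort$expression, "fpkm")["BRD4L", ]
    cn <- locusCN(cohort$segments, g@neighbor, md$sample)
    del <- md$sample %in% carriers
    fit <- tryCatch(
      fitDosageModel(unname(fpkm[md$sample]), unname(cn[md$sample]), del,
                     md$tumor_type, md$patient),
      error = function(e) e)
    if (inherits(fit, "error")) {
      say("model: skipped (%s)", conditionMessage(fit))
      manifest$stages$model <- list(status = "skipped",
                                    reason = conditionMessage(fit))
      NULL
    } else {
      jsonlite::write_json(fit$coefficients,
                           file.path(outDir, "dosage_fit.json"),
                           dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
      manifest$stages$model <- list(status = "ok", n = fit$n)
      fit
    }
  })

  de <- stage("de", {
    del <- colnames(cohort$expression) %in% carriers
    rd <- SummarizedExperiment::rowData(cohort$expression)
    geneRows <- rownames(cohort$expression)[rd$class == "gene"]
    if (sum(del) < 2L || sum(!del) < 2L) {
      say("de: skipped (need >= 2 carriers and non-carriers)")
      manifest$stages$de <- list(status = "skipped",
                                 reason = "fewer than 2 carriers or non-carriers")
      NULL
    } else {
      res <- differentialExpression(cohort$expression, del,
                                    cohort$metadata$tumor_type,
                                    genes = geneRows)
      write.table(res, file.path(outDir, "de.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      manifest$stages$de <- list(status = "ok",
                                 n_pass = sum(res$pass))
      res
    }
  })

  stage("report", {
    lines <- character()
    w <- function(...) lines <<- c(lines, sprintf(...))
    w("Focal-deletion analysis report")
    w("==============================")
    w("samples: %d   master seed: %d", config@nSamples, as.integer(seed))
    w("")
    w("Carriers by evidence class:")
    if (length(evTab) == 0L) w("  none") else
      for (k in names(evTab)) w("  %-14s %d", k, evTab[[k]])
    w("Focal-deletion carrier set: %d sample(s)", length(carriers))
    w("")
    if (!is.null(timing)) {
      w("Event timing (informative carriers): %d amplification-first, %d deletion-first",
        timing$summary$n_amp_first, timing$summary$n_del_first)
      w("  exact one-sided binomial p = %.4g (direction: %s)",
        timing$summary$p_value, timing$summary$direction)
      amb <- timing$calls[timing$calls$verdict == "ambiguous", ]
      if (nrow(amb)) {
        w("  ambiguous: %d", nrow(amb))
        tb <- table(amb$reason)
        for (k in names(tb)) w("    %-32s %d", k, tb[[k]])
      }
    } else w("Event timing: skipped")
    w("")
    if (!is.null(dosage)) {
      w("Dosage model coefficients (95%% CI), n = %d patients:", dosage$n)
      co <- dosage$coefficients
      for (i in seq_len(nrow(co)))
        w("  %-12s %8.2f  [%.2f, %.2f]", co$term[i], co$estimate[i],
          co$ci_lower[i], co$ci_upper[i])
    } else w("Dosage model: skipped")
    w("")
    if (!is.null(de)) {
      w("Differential expression: %d gene(s) pass q < %.2g with >= %g-fold change",
        sum(de$pass), attr(de, "thresholds")$qCut,
        2^attr(de, "thresholds")$lfcCut)
      if (any(de$pass))
        w("  pass list: %s", paste(de$gene[de$pass], collapse = ", "))
    } else w("Differential expression: skipped")
    writeLines(lines, file.path(outDir, "report.txt"))
    manifest$stages$report <- list(status = "ok")
    NULL
  })

  manifest$complete <- TRUE
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  writeManifest()
  invisible(list(cohort = cohort, calls = calls, timing = timing,
                 dosage = dosage, de = de, manifest = manifest))
}
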