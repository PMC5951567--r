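## tiny FNV-1a hash of the deparsed config, for provenance stamping
configHash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), ch)
    h <- (as.double(h) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

pipelineStages <- function() {
  list(data = c("simulate", "phantoms"),
       analysis = c("screen", "select", "validate", "ablate", "subset",
                    "demographics"))
}

validatePipelineConfig <- function(config) {
  if (is.null(config$seed)) stop("schema error: config$seed is required")
  if (is.null(config$outputDir))
    stop("schema error: config$outputDir is required")
  st <- pipelineStages()
  stages <- config$stages %||% c("simulate", "screen", "select", "validate")
  unknown <- setdiff(stages, c(st$data, st$analysis))
  if (length(unknown))
    stop("schema error: unknown stages: ", paste(unknown, collapse = ", "))
  dataIdx <- which(stages %in% st$data)
  if (length(dataIdx) != 1L)
    stop("schema error: exactly one data stage (simulate or phantoms) ",
         "is required")
  if (any(which(stages %in% st$analysis) < dataIdx))
    stop("schema error: modeling stages must come after the data stage")
  if ("ablate" %in% stages &&
      match("select", stages, nomatch = 0L) == 0L)
    stop("schema error: 'ablate' requires 'select'")
  if ("ablate" %in% stages &&
      match("ablate", stages) < match("select", stages))
    stop("schema error: 'ablate' must come after 'select'")
  stages
}

#' Run the phantom-to-validation pipeline
#'
#' Orchestrates the package stages from a single declarative config. The
#' config is validated against the stage schema before any computation; every
#' artifact embeds the config hash, package version and seed, and identical
#' config + seed reproduce identical outputs.
#'
#' Config fields: \code{seed}, \code{outputDir}, \code{stages} (ordered subset
#' of simulate/phantoms, screen, select, validate, ablate, subset,
#' demographics; the data stage first), and optional per-stage parameter lists
#' \code{simulate} (nPerClass, correlation, clinical), \code{phantoms}
#' (nBenign, nMalignant, spacing), \code{select} (runs, freqThreshold),
#' \code{validate} (B, innerRuns), \code{subset} (sizeRange).
#'
#' @param config named list (or path to a JSON/YAML-free JSON file).
#' @return list with \code{paths} of written artifacts and the in-memory
#'   \code{objects}, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stages <- validatePipelineConfig(config)
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  stamp <- list(config_hash = configHash(config),
                package_version = as.character(packageVersion("NoduleRadiomics")),
                seed = seed)
  logPath <- file.path(config$outputDir, "log.txt")
  logLine <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                               "\n", file = logPath, append = TRUE)
  cat("", file = logPath)
  paths <- list()
  objects <- list(stamp = stamp)
  writeJson <- function(x, name) {
    p <- file.path(config$outputDir, name)
    jsonlite::write_json(c(stamp, x), p, auto_unbox = TRUE, digits = NA,
                         na = "null", force = TRUE)
    paths[[name]] <<- p
  }
  jsonlite::write_json(c(stamp, list(stages = stages)),
                       file.path(config$outputDir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)

  for (stage in stages) {
    logLine("stage:", stage)
    tryCatch(switch(stage,
      simulate = {
        p <- config$simulate %||% list()
        cfg <- cohortSimConfig(
          nPerClass = p$nPerClass %||% c(benign = 318L, malignant = 408L),
          correlation = p$correlation %||% "block",
          clinical = p$clinical %||% TRUE)
        objects$features <- generateFeatureTable(cfg, seed = seed)
        fp <- file.path(config$outputDir, "features.csv")
        write.csv(objects$features, fp, row.names = FALSE)
        paths$features.csv <- fp
      },
      phantoms = {
        p <- config$phantoms %||% list()
        objects$features <- simulatePhantomCohort(
          nBenign = p$nBenign %||% 20, nMalignant = p$nMalignant %||% 20,
          seed = seed, spacing = p$spacing %||% c(1, 1, 1))
        fp <- file.path(config$outputDir, "features.csv")
        write.csv(objects$features, fp, row.names = FALSE)
        paths$features.csv <- fp
      },
      screen = {
        objects$screen <- univariateScreen(objects$features)
        fp <- file.path(config$outputDir, "screen.csv")
        write.csv(objects$screen, fp, row.names = FALSE)
        paths$screen.csv <- fp
        rho <- spearmanMatrix(objects$features)
        hp <- file.path(config$outputDir, "spearman.csv")
        write.csv(as.data.frame(rho), hp, row.names = TRUE)
        paths$spearman.csv <- hp
      },
      select = {
        p <- config$select %||% list()
        objects$selection <- lassoStabilitySelect(
          objects$features, runs = p$runs %||% 1000L,
          freqThreshold = p$freqThreshold %||% 0.5, seed = seed)
        writeJson(list(frequencies = as.list(objects$selection@frequencies),
                       selected = objects$selection@selected,
                       runs = objects$selection@runs,
                       threshold = objects$selection@threshold),
                  "selection.json")
        objects$model <- fitFinalModel(objects$features,
                                       objects$selection@selected,
                                       onSeparation =
                                         p$onSeparation %||% "error")
        writeJson(list(features = objects$model@features,
                       coefficients = as.list(objects$model@coefficients),
                       center = as.list(objects$model@center),
                       scale = as.list(objects$model@scale),
                       p_values = as.list(objects$model@pValues)),
                  "model.json")
      },
      validate = {
        p <- config$validate %||% list()
        proc <- if (is.null(objects$selection))
          stabilityProcedure(runs = p$innerRuns %||% 50L)
        else fixedModelProcedure(objects$selection@selected)
        objects$validation <- optimismCorrectedAuc(
          objects$features, proc, B = p$B %||% 100L, seed = seed)
        v <- objects$validation
        writeJson(list(apparent_auc = v@apparentAuc, optimism = v@optimism,
                       corrected_auc = v@correctedAuc,
                       youden_cutoff = v@youdenCutoff,
                       sensitivity = v@sensitivity,
                       specificity = v@specificity, B = v@B, n = v@n),
                  "validation.json")
      },
      ablate = {
        p <- config$validate %||% list()
        objects$ablation <- ablationAnalysis(
          objects$features, objects$selection@selected,
          B = p$B %||% 50L, seed = seed)
        fp <- file.path(config$outputDir, "ablation.csv")
        write.csv(objects$ablation, fp, row.names = FALSE)
        paths$ablation.csv <- fp
      },
      subset = {
        p <- config$subset %||% list()
        proc <- if (is.null(objects$selection))
          stabilityProcedure(runs = 50L)
        else fixedModelProcedure(objects$selection@selected)
        objects$subset <- subsetAnalysis(
          objects$features, sizeRange = p$sizeRange %||% c(7, 15),
          procedure = proc, B = (config$validate %||% list())$B %||% 100L,
          seed = seed)
        v <- objects$subset
        writeJson(list(size_range = p$sizeRange %||% c(7, 15),
                       apparent_auc = v@apparentAuc,
                       corrected_auc = v@correctedAuc, n = v@n),
                  "subset.json")
      },
      demographics = {
        objects$demographics <- demographicsReport(objects$features)
        fp <- file.path(config$outputDir, "demographics.csv")
        write.csv(objects$demographics, fp, row.names = FALSE)
        paths$demographics.csv <- fp
      }),
      error = function(e) {
        logLine("ERROR in stage", stage, ":", conditionMessage(e))
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
      })
    logLine("stage", stage, "done")
  }
  invisible(list(paths = paths, objects = objects))
}

#' Demographics and clinical characteristics report
#'
#' Per-covariate summary by class: counts and percentages (one decimal,
#' half-up) with two-sided Fisher exact p-values for categorical covariates,
#' mean +/- SD with pooled t-test p-values for continuous ones. Rows with
#' missing values are excluded from the test and tallied; covariates with a
#' single observed level get no p-value, with a note.
#'
#' @param table feature table with a \code{label} column.
#' @param categorical,continuous covariate column names (defaults: sex and
#'   smoking; age and pack_years; silently skipping absent columns).
#' @return data.frame with columns \code{covariate}, \code{level},
#'   \code{malignant}, \code{benign}, \code{p_value} (2 decimals),
#'   \code{note}.
#' @export
demographicsReport <- function(table,
                               categorical = c("sex", "smoking"),
                               continuous = c("age", "pack_years")) {
  if (!"label" %in% names(table)) stop("table needs a label column")
  pos <- labelsAsLogical(table$label)
  rows <- list()
  addRow <- function(covariate, level, malignant, benign, p = NA_real_,
                     note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      covariate = covariate, level = level, malignant = malignant,
      benign = benign,
      p_value = if (is.na(p)) NA_character_ else sprintf("%.2f", p),
      note = note)
  }
  for (cv in intersect(categorical, names(table))) {
    x <- table[[cv]]
    ok <- !is.na(x)
    lev <- sort(unique(x[ok]))
    counts <- vapply(lev, function(l)
      c(sum(x[ok] == l & pos[ok]), sum(x[ok] == l & !pos[ok])), numeric(2))
    p <- NA_real_
    note <- ""
    if (length(lev) < 2) {
      note <- "single level; p omitted"
    } else {
      p <- fisher.test(matrix(counts, nrow = length(lev), byrow = TRUE))$p.value
    }
    if (any(!ok)) note <- paste0(note, ifelse(nzchar(note), "; ", ""),
                                 sum(!ok), " missing excluded")
    for (i in seq_along(lev)) {
      nm <- counts[1, i]
      nb <- counts[2, i]
      addRow(cv, as.character(lev[i]),
             sprintf("%d (%.1f)", nm, roundHalfUp(100 * nm / sum(pos[ok]))),
             sprintf("%d (%.1f)", nb, roundHalfUp(100 * nb / sum(!pos[ok]))),
             p = if (i == 1) p else NA_real_, note = if (i == 1) note else "")
    }
  }
  for (cv in intersect(continuous, names(table))) {
    x <- table[[cv]]
    ok <- !is.na(x)
    xm <- x[ok & pos]
    xb <- x[ok & !pos]
    t <- tTestFromSummary(mean(xm), sd(xm), length(xm),
                          mean(xb), sd(xb), length(xb))
    addRow(cv, "mean (SD)",
           sprintf("%.1f (%.1f)", roundHalfUp(mean(xm)), roundHalfUp(sd(xm))),
           sprintf("%.1f (%.1f)", roundHalfUp(mean(xb)), roundHalfUp(sd(xb))),
           p = t$p,
           note = if (any(!ok)) paste(sum(!ok), "missing excluded") else "")
  }
  do.call(rbind, rows)
}
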