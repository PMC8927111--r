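#' Analysis configuration
#'
#' Builds (and validates) the configuration driving [runStudy()]. Either
#' supply `sim` (a [simConfig()] object; the cohort is generated) or
#' `pedigreeFile`/`phenotypeFile` paths with their dialects. All randomness
#' (simulation, bootstrap, subsampling) flows from `seed` through
#' independent derived streams.
#'
#' @param sim optional [simConfig()] to generate the cohort.
#' @param pedigreeFile,pedigreeDialect,pedigreeColumns pedigree input (see
#'   [readPedigree()]); ignored when `sim` is given.
#' @param phenotypeFile,phenotypeSep phenotype input (see [readPhenotypes()]).
#' @param binaryTraits character; traits analysed with lambda_R.
#' @param continuousTraits character; traits analysed with REML.
#' @param covariates fixed-effect adjustment set; default age, age^2, sex.
#' @param relativeSets subset of `c("first_degree", "spouse")`.
#' @param nBoot bootstrap resamples for naive lambda_R.
#' @param subsampleN optional subsample size for the sensitivity analysis.
#' @param seed integer master seed.
#' @param yaml optional path to a YAML file holding these fields (list
#'   fields under the same names); explicit arguments override it.
#' @return list of class `AnalysisConfig`.
#' @export
analysisConfig <- function(sim = NULL,
                           pedigreeFile = NULL,
                           pedigreeDialect = "plink_fam",
                           pedigreeColumns = NULL,
                           phenotypeFile = NULL,
                           phenotypeSep = "\t",
                           binaryTraits = character(),
                           continuousTraits = character(),
                           covariates = c("age", "age2", "sex"),
                           relativeSets = c("first_degree", "spouse"),
                           nBoot = 2000L,
                           subsampleN = NULL,
                           seed = 1L,
                           yaml = NULL) {
  cfg <- list(
    sim = sim, pedigreeFile = pedigreeFile,
    pedigreeDialect = pedigreeDialect, pedigreeColumns = pedigreeColumns,
    phenotypeFile = phenotypeFile, phenotypeSep = phenotypeSep,
    binaryTraits = binaryTraits, continuousTraits = continuousTraits,
    covariates = covariates, relativeSets = relativeSets,
    nBoot = as.integer(nBoot), subsampleN = subsampleN,
    seed = as.integer(seed)
  )
  if (!is.null(yaml)) {
    yml <- yaml::read_yaml(yaml)
    bad <- setdiff(names(yml), names(cfg))
    if (length(bad)) {
      stop("unknown config field(s) in YAML: ", paste(bad, collapse = ", "))
    }
    supplied <- names(as.list(match.call()))
    for (k in names(yml)) {
      if (!k %in% supplied) cfg[[k]] <- yml[[k]]
    }
  }
  if (is.null(cfg$sim) &&
      (is.null(cfg$pedigreeFile) || is.null(cfg$phenotypeFile))) {
    stop("either 'sim' or both 'pedigreeFile' and 'phenotypeFile' required")
  }
  bad <- setdiff(cfg$relativeSets, c("first_degree", "spouse"))
  if (length(bad)) stop("unknown relative set(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "AnalysisConfig")
}

#' Descriptive statistics table
#'
#' Per variable: n, and either mean +/- sd or median (IQR) for continuous
#' variables (median/IQR when |skewness| > 1), or n affected and prevalence
#' (%) for binary 0/1 variables.
#'
#' @param t phenotype data.frame.
#' @param variables columns to summarise; default all numeric columns except
#'   `id`/`family`.
#' @return data.frame with columns `variable`, `n`, `form`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `nAffected`, `prevalence`, `summary`.
#' @export
descriptiveTable <- function(t, variables = NULL) {
  if (is.null(variables)) {
    variables <- setdiff(names(t)[vapply(t, is.numeric, logical(1))],
                         c("id", "family"))
  }
  rows <- lapply(variables, function(v) {
    x <- t[[v]]
    x <- x[!is.na(x)]
    n <- length(x)
    if (all(x %in% c(0, 1)) && n > 0) {
      prev <- mean(x) * 100
      return(data.frame(
        variable = v, n = n, form = "prevalence",
        mean = NA_real_, sd = NA_real_, median = NA_real_,
        q1 = NA_real_, q3 = NA_real_,
        nAffected = sum(x), prevalence = prev,
        summary = sprintf("%d (%.2f%%)", sum(x), prev),
        stringsAsFactors = FALSE
      ))
    }
    s <- sd(x)
    skew <- if (n > 2 && s > 0) mean((x - mean(x))^3) / s^3 else 0
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    if (abs(skew) > 1) {
      data.frame(
        variable = v, n = n, form = "median_iqr",
        mean = mean(x), sd = s, median = q[2], q1 = q[1], q3 = q[3],
        nAffected = NA_integer_, prevalence = NA_real_,
        summary = sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3]),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        variable = v, n = n, form = "mean_sd",
        mean = mean(x), sd = s, median = q[2], q1 = q[1], q3 = q[3],
        nAffected = NA_integer_, prevalence = NA_real_,
        summary = sprintf("%.2f +/- %.2f", mean(x), s),
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Complete-vs-missing demographic comparison
#'
#' For every trait with missing values: age and sex summaries of complete
#' versus missing rows, with standardized mean differences (pooled-sd
#' denominator for age; sqrt(p(1-p)) for the female proportion).
#'
#' @param t phenotype data.frame with `age` and `sex`.
#' @param traits trait columns to examine.
#' @return data.frame (zero rows if nothing is missing, with a message).
#' @export
missingDataComparison <- function(t, traits) {
  rows <- list()
  for (v in traits) {
    miss <- is.na(t[[v]])
    if (!any(miss) || all(miss)) next
    ageC <- t$age[!miss]; ageM <- t$age[miss]
    sdPool <- sqrt((var(ageC, na.rm = TRUE) + var(ageM, na.rm = TRUE)) / 2)
    smdAge <- (mean(ageM, na.rm = TRUE) - mean(ageC, na.rm = TRUE)) / sdPool
    fC <- mean(t$sex[!miss] == 2, na.rm = TRUE)
    fM <- mean(t$sex[miss] == 2, na.rm = TRUE)
    pBar <- mean(c(fC, fM))
    smdSex <- (fM - fC) / sqrt(pBar * (1 - pBar))
    rows[[v]] <- data.frame(
      trait = v, nComplete = sum(!miss), nMissing = sum(miss),
      ageComplete = mean(ageC, na.rm = TRUE),
      ageMissing = mean(ageM, na.rm = TRUE), smdAge = smdAge,
      femaleComplete = fC, femaleMissing = fM, smdSex = smdSex,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    message("no missing trait values; empty comparison table")
    return(data.frame(
      trait = character(), nComplete = integer(), nMissing = integer(),
      ageComplete = numeric(), ageMissing = numeric(), smdAge = numeric(),
      femaleComplete = numeric(), femaleMissing = numeric(),
      smdSex = numeric(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full study pipeline
#'
#' Executes, in order: input (simulation or file reading), descriptive
#' statistics, familial aggregation (same-trait lambda_R, naive and adjusted,
#' per relative set), the full co-aggregation matrix, univariate REML
#' heritability per continuous trait (with a boundary-mixture LRT for
#' sigma2_a > 0), bivariate REML for every continuous trait pair (r_G with
#' Wald tests against 0 and 1, r_P, r_E), and the complete-vs-missing
#' comparison. Per-analysis failures are captured in the result tables and
#' the pipeline continues. Reruns with the same configuration are
#' deterministic.
#'
#' @param cfg An [analysisConfig()] (or a bare [simConfig()], wrapped with
#'   defaults).
#' @return list of class `StudyReport`: `descriptive`, `aggregation`,
#'   `coaggregation`, `heritability`, `correlations`, `missingData`, `log`,
#'   `meta` (seed, config hash, package version; no timestamps, so payloads
#'   are rerun-identical).
#' @export
runStudy <- function(cfg) {
  if (inherits(cfg, "SimConfig")) {
    traitNames <- vapply(cfg$traits, `[[`, character(1), "name")
    kinds <- vapply(cfg$traits, `[[`, character(1), "kind")
    cfg <- analysisConfig(sim = cfg,
                          binaryTraits = traitNames[kinds == "binary"],
                          continuousTraits = traitNames[kinds == "continuous"],
                          seed = cfg$seed)
  }
  stopifnot(inherits(cfg, "AnalysisConfig"))
  logLines <- character()
  note <- function(...) {
    logLines <<- c(logLines, paste0(...))
  }

  if (!is.null(cfg$sim)) {
    simOut <- simulateCohort(cfg$sim)
    ped <- simOut$ped
    pheno <- simOut$pheno
    note("simulated cohort: ", length(pedIds(ped)), " individuals in ",
         length(unique(families(ped))), " families")
  } else {
    ped <- readPedigree(cfg$pedigreeFile, cfg$pedigreeDialect,
                        cfg$pedigreeColumns %||%
                          list(id_col = "id", father_col = "father",
                               mother_col = "mother", sex_col = "sex"))
    pheno <- readPhenotypes(cfg$phenotypeFile, sep = cfg$phenotypeSep)
    if (!"family" %in% names(pheno)) {
      pheno$family <- families(ped)[pheno$id]
    }
    note("read cohort: ", nrow(pheno), " phenotyped of ",
         length(pedIds(ped)), " pedigree members")
  }
  missTraits <- c(cfg$binaryTraits, cfg$continuousTraits)
  bad <- setdiff(missTraits, names(pheno))
  if (length(bad)) stop("configured trait(s) missing from phenotype table: ",
                        paste(bad, collapse = ", "))

  report <- list()
  report$descriptive <- descriptiveTable(
    pheno, c("age", cfg$binaryTraits, cfg$continuousTraits))

  # familial aggregation & co-aggregation
  aggOut <- runWithSeed(cfg$seed + 1L, {
    agg <- list()
    coagg <- list()
    for (rs in cfg$relativeSets) {
      if (length(cfg$binaryTraits)) {
        coagg[[rs]] <- coaggregationMatrix(
          ped, pheno, cfg$binaryTraits, relativeSet = rs,
          adjusted = TRUE, covariates = cfg$covariates)
        for (tr in cfg$binaryTraits) {
          row <- tryCatch({
            ex <- suppressMessages(buildExposure(ped, pheno, tr, rs))
            nv <- lambdaNaive(pheno, ex, tr, nBoot = cfg$nBoot,
                              seed = cfg$seed + 17L,
                              design = list(exposureTrait = tr,
                                            relativeSet = rs))
            ad <- lambdaAdjusted(pheno, ex, tr, cfg$covariates,
                                 design = list(exposureTrait = tr,
                                               relativeSet = rs))
            data.frame(
              trait = tr, relativeSet = rs,
              lambdaNaive = nv@lambda, naiveCiLow = nv@ciLow,
              naiveCiHigh = nv@ciHigh,
              lambdaAdjusted = ad@lambda, adjCiLow = ad@ciLow,
              adjCiHigh = ad@ciHigh, pValue = ad@pValue,
              stars = significanceStars(ad@pValue),
              nExposed = ad@nExposed, nEvents = ad@nEvents,
              error = NA_character_, stringsAsFactors = FALSE
            )
          }, error = function(e) data.frame(
            trait = tr, relativeSet = rs,
            lambdaNaive = NA_real_, naiveCiLow = NA_real_,
            naiveCiHigh = NA_real_, lambdaAdjusted = NA_real_,
            adjCiLow = NA_real_, adjCiHigh = NA_real_, pValue = NA_real_,
            stars = "", nExposed = NA_integer_, nEvents = NA_integer_,
            error = conditionMessage(e), stringsAsFactors = FALSE
          ))
          agg[[paste(tr, rs)]] <- row
        }
      }
    }
    list(
      aggregation = if (length(agg)) {
        out <- do.call(rbind, agg); rownames(out) <- NULL; out
      } else NULL,
      coaggregation = coagg
    )
  })
  report$aggregation <- aggOut$aggregation
  report$coaggregation <- aggOut$coaggregation

  # heritability (univariate REML per continuous trait)
  herit <- list()
  for (tr in cfg$continuousTraits) {
    herit[[tr]] <- tryCatch({
      fit <- remlUnivariate(ped, pheno, tr, cfg$covariates)
      null <- remlUnivariate(ped, pheno, tr, cfg$covariates,
                             fixSigmaA = TRUE)
      p <- lrtVariance(fit, null)
      data.frame(
        trait = tr, n = fit@n, sigma2a = fit@G[1, 1], sigma2e = fit@R[1, 1],
        h2 = fit@h2, seH2 = fit@seH2, pValue = p,
        stars = significanceStars(p),
        boundary = isTRUE(fit@convergence$boundary),
        error = NA_character_, stringsAsFactors = FALSE
      )
    }, error = function(e) data.frame(
      trait = tr, n = NA_integer_, sigma2a = NA_real_, sigma2e = NA_real_,
      h2 = NA_real_, seH2 = NA_real_, pValue = NA_real_, stars = "",
      boundary = NA, error = conditionMessage(e), stringsAsFactors = FALSE
    ))
  }
  report$heritability <- if (length(herit)) {
    out <- do.call(rbind, herit); rownames(out) <- NULL; out
  } else NULL

  # genetic / phenotypic / residual correlations (bivariate REML per pair)
  corrs <- list()
  ct <- cfg$continuousTraits
  if (length(ct) >= 2L) {
    for (i in seq_len(length(ct) - 1L)) {
      for (j in seq(i + 1L, length(ct))) {
        key <- paste(ct[i], ct[j], sep = ":")
        corrs[[key]] <- tryCatch({
          fit <- remlBivariate(ped, pheno, c(ct[i], ct[j]), cfg$covariates)
          t0 <- rgWaldTest(fit, 0)
          t1 <- rgWaldTest(fit, 1)
          data.frame(
            traitX = ct[i], traitY = ct[j], n = fit@n,
            rG = fit@rG, seRG = fit@seRG,
            pVs0 = t0$pValue, starsVs0 = significanceStars(t0$pValue),
            pVs1 = t1$pValue, rP = fit@rP, rE = fit@rE,
            boundary = isTRUE(fit@convergence$boundary),
            error = NA_character_, stringsAsFactors = FALSE
          )
        }, error = function(e) data.frame(
          traitX = ct[i], traitY = ct[j], n = NA_integer_,
          rG = NA_real_, seRG = NA_real_, pVs0 = NA_real_, starsVs0 = "",
          pVs1 = NA_real_, rP = NA_real_, rE = NA_real_, boundary = NA,
          error = conditionMessage(e), stringsAsFactors = FALSE
        ))
      }
    }
  }
  report$correlations <- if (length(corrs)) {
    out <- do.call(rbind, corrs); rownames(out) <- NULL; out
  } else NULL

  report$missingData <- suppressMessages(
    missingDataComparison(pheno, missTraits))
  report$log <- logLines
  report$meta <- list(
    seed = cfg$seed,
    configHash = configHash(cfg),
    package = as.character(utils::packageVersion("kinherit")),
    nIndividuals = length(pedIds(ped)),
    nFamilies = length(unique(families(ped)))
  )
  class(report) <- "StudyReport"
  report
}

configHash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %%
            .Machine$integer.max)
}

#' @export
print.StudyReport <- function(x, ...) {
  cat("StudyReport (seed ", x$meta$seed, ", ", x$meta$nIndividuals,
      " individuals in ", x$meta$nFamilies, " families)\n", sep = "")
  cat("Sections: ", paste(setdiff(names(x), c("log", "meta")),
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subsample sensitivity analysis
#'
#' Reruns all analyses on a seeded random subset of roughly `nSub`
#' individuals, drawn family by family so pedigrees stay intact (families are
#' added in random order until the next family would exceed `nSub`). Reports
#' per-analysis-class significance concordance against the full-cohort run
#' and the percentage of significant findings lost.
#'
#' @param cfg An [analysisConfig()] with `sim` input (or file input).
#' @param nSub target subsample size (individuals); must be smaller than the
#'   cohort.
#' @param full optional precomputed full-cohort [runStudy()] report.
#' @return list with `full`, `sub` (both `StudyReport`) and `concordance`
#'   (data.frame: class, nSignificantFull, nRetained, pctLost).
#' @export
subsampleSensitivity <- function(cfg, nSub, full = NULL) {
  stopifnot(inherits(cfg, "AnalysisConfig"))
  if (is.null(full)) full <- runStudy(cfg)
  if (nSub > full$meta$nIndividuals) {
    stop("subsample size exceeds cohort size")
  }

  # materialize the cohort, subsample whole families, rerun via file input
  if (!is.null(cfg$sim)) {
    simOut <- simulateCohort(cfg$sim)
    ped <- simOut$ped
    pheno <- simOut$pheno
  } else {
    ped <- readPedigree(cfg$pedigreeFile, cfg$pedigreeDialect)
    pheno <- readPhenotypes(cfg$phenotypeFile, sep = cfg$phenotypeSep)
    if (!"family" %in% names(pheno)) pheno$family <- families(ped)[pheno$id]
  }
  fam <- families(ped)
  keepIds <- runWithSeed(cfg$seed + 101L, {
    famIds <- unique(fam)
    ord <- sample(famIds)
    sizes <- table(fam)[ord]
    cum <- cumsum(as.integer(sizes))
    take <- ord[cum <= nSub]
    if (!length(take)) take <- ord[1L]
    names(fam)[fam %in% take]
  })
  subPed <- subsetPedigree(ped, keepIds)
  subPheno <- pheno[pheno$id %in% keepIds, , drop = FALSE]

  dir <- tempfile("subsample")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  writeFam(subPed, file.path(dir, "sub.fam"))
  writePhenotypes(subPheno, file.path(dir, "sub.tsv"))
  subCfg <- cfg
  subCfg$sim <- NULL
  subCfg$pedigreeFile <- file.path(dir, "sub.fam")
  subCfg$pedigreeDialect <- "plink_fam"
  subCfg$phenotypeFile <- file.path(dir, "sub.tsv")
  sub <- runStudy(subCfg)

  concordance <- rbind(
    concordanceRow("aggregation", full$aggregation, sub$aggregation,
                   c("trait", "relativeSet"), "pValue"),
    concordanceRow("coaggregation",
                   do.call(rbind, c(full$coaggregation,
                                    make.row.names = FALSE)),
                   do.call(rbind, c(sub$coaggregation,
                                    make.row.names = FALSE)),
                   c("exposure", "outcome", "relativeSet"), "pValue"),
    concordanceRow("heritability", full$heritability, sub$heritability,
                   "trait", "pValue"),
    concordanceRow("geneticCorrelation", full$correlations,
                   sub$correlations, c("traitX", "traitY"), "pVs0")
  )
  list(full = full, sub = sub, concordance = concordance)
}

concordanceRow <- function(class, fullTab, subTab, keys, pCol) {
  if (is.null(fullTab) || !nrow(fullTab)) {
    return(data.frame(class = class, nSignificantFull = 0L, nRetained = 0L,
                      pctLost = NA_real_, stringsAsFactors = FALSE))
  }
  kf <- do.call(paste, fullTab[keys])
  ks <- do.call(paste, subTab[keys])
  sigF <- !is.na(fullTab[[pCol]]) & fullTab[[pCol]] < 0.05
  sigS <- !is.na(subTab[[pCol]]) & subTab[[pCol]] < 0.05
  retained <- sum(sigF & kf %in% ks[sigS])
  nF <- sum(sigF)
  data.frame(
    class = class, nSignificantFull = nF, nRetained = retained,
    pctLost = if (nF > 0) 100 * (nF - retained) / nF else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Restrict a pedigree to a set of individuals
#'
#' Parent links pointing outside the subset become unknown (the retained
#' individual becomes a founder on that side); generation and family labels
#' are recomputed.
#'
#' @param ped A [Pedigree-class].
#' @param ids individuals to keep.
#' @return A [Pedigree-class].
#' @export
subsetPedigree <- function(ped, ids) {
  keep <- pedIds(ped) %in% ids
  id <- ped@id[keep]
  fa <- ped@father[keep]
  mo <- ped@mother[keep]
  fa[!fa %in% id] <- NA_character_
  mo[!mo %in% id] <- NA_character_
  partners <- ped@partners
  if (nrow(partners)) {
    partners <- partners[partners[, 1] %in% id & partners[, 2] %in% id, ,
                         drop = FALSE]
  }
  pedigree(id, fa, mo, ped@sex[keep], partners)
}

#' Write a study report to disk
#'
#' `report.json` (the full payload), one TSV per tabular section under
#' `tables/`, and `log.txt`.
#'
#' @param report A [runStudy()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
  stopifnot(inherits(report, "StudyReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabDir <- file.path(dir, "tables")
  if (!dir.exists(tabDir)) dir.create(tabDir)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  for (sec in c("descriptive", "aggregation", "heritability",
                "correlations", "missingData")) {
    if (!is.null(report[[sec]]) && nrow(report[[sec]])) {
      write.table(report[[sec]], file.path(tabDir, paste0(sec, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  for (rs in names(report$coaggregation)) {
    write.table(report$coaggregation[[rs]],
                file.path(tabDir, paste0("coaggregation_", rs, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(report$log, file.path(dir, "log.txt"))
  invisible(dir)
}
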