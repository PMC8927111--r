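#' Read a pedigree file
#'
#' Supported dialects:
#' \describe{
#'   \item{`plink_fam`}{PLINK `.fam`: six whitespace-separated columns
#'     (FID IID father mother sex phenotype); missing parent `"0"`,
#'     sex 1 = male / 2 = female / 0 = unknown. The phenotype column is
#'     ignored; family membership is recomputed from the links.}
#'   \item{`linkage_ped`}{LINKAGE pre-makeped: same core columns; any
#'     trailing phenotype columns are ignored.}
#'   \item{`csv`}{header row plus configurable column names, given in
#'     `columns` as a list with entries `id_col`, `father_col`, `mother_col`,
#'     `sex_col` (sex optional).}
#' }
#'
#' Missing-parent codes (`"0"`, empty, `NA`) become null links; a parent id
#' that never appears as an individual is added as a founder with a warning;
#' duplicated ids, parent-sex inconsistencies and cycles are errors.
#'
#' @param path file path.
#' @param dialect one of `"plink_fam"`, `"linkage_ped"`, `"csv"`.
#' @param columns column-name mapping for the `csv` dialect.
#' @return A [Pedigree-class].
#' @seealso [writeFam()]
#' @export
readPedigree <- function(path,
                         dialect = c("plink_fam", "linkage_ped", "csv"),
                         columns = list(id_col = "id", father_col = "father",
                                        mother_col = "mother",
                                        sex_col = "sex")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect %in% c("plink_fam", "linkage_ped")) {
    raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character")
    if (ncol(raw) < 5L) {
      stop("expected at least 5 columns (FID IID father mother sex) in ",
           dialect, " file")
    }
    ped <- pedigree(
      id = raw[[2L]], father = raw[[3L]], mother = raw[[4L]],
      sex = suppressWarnings(as.integer(raw[[5L]]))
    )
  } else {
    raw <- read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character")
    need <- c("id_col", "father_col", "mother_col")
    for (k in need) {
      if (is.null(columns[[k]]) || !columns[[k]] %in% names(raw)) {
        stop("csv dialect: column '", columns[[k]], "' (", k,
             ") not found in header")
      }
    }
    sex <- if (!is.null(columns$sex_col) && columns$sex_col %in% names(raw)) {
      sx <- raw[[columns$sex_col]]
      if (all(is.na(suppressWarnings(as.integer(sx))) == is.na(sx))) {
        suppressWarnings(as.integer(sx))
      } else sx
    } else NULL
    ped <- pedigree(
      id = raw[[columns$id_col]],
      father = raw[[columns$father_col]],
      mother = raw[[columns$mother_col]],
      sex = sex
    )
  }
  ped
}

#' Write a pedigree as a PLINK .fam file
#'
#' Six columns: family id (the computed component label), individual id,
#' father, mother, sex (1/2/0) and a constant `-9` phenotype placeholder.
#'
#' @param ped A [Pedigree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFam <- function(ped, path) {
  stopifnot(is(ped, "Pedigree"))
  out <- data.frame(
    fid = ped@familyId,
    iid = ped@id,
    father = ifelse(is.na(ped@father), "0", ped@father),
    mother = ifelse(is.na(ped@mother), "0", ped@mother),
    sex = ped@sex,
    pheno = -9L,
    stringsAsFactors = FALSE
  )
  write.table(out, path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = " ")
  invisible(path)
}

#' Read a phenotype table
#'
#' Reads a CSV/TSV phenotype table keyed by individual id. Column names can
#' be remapped through `mapping` (a named list `new_name = file_column`),
#' e.g. to standardise `age`, `sex` and trait columns for the downstream
#' models. Sex is normalised to 1/2/0 when a `sex` column is present.
#'
#' @param path file path.
#' @param sep field separator; default tab.
#' @param mapping optional named list renaming file columns.
#' @param idCol id column name (after mapping); default `"id"`.
#' @return data.frame, one row per individual id.
#' @export
readPhenotypes <- function(path, sep = "\t", mapping = NULL, idCol = "id") {
  if (!file.exists(path)) stop("file not found: ", path)
  t <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, comment.char = "")
  if (!is.null(mapping)) {
    for (new in names(mapping)) {
      old <- mapping[[new]]
      if (!old %in% names(t)) stop("mapped column not in file: ", old)
      names(t)[names(t) == old] <- new
    }
  }
  if (!idCol %in% names(t)) stop("id column '", idCol, "' not found")
  if (anyDuplicated(t[[idCol]])) {
    stop("duplicate individual id(s) in phenotype table")
  }
  t[[idCol]] <- as.character(t[[idCol]])
  if ("sex" %in% names(t)) t$sex <- normalizeSex(t$sex, nrow(t))
  t
}

#' Write a phenotype table as TSV
#'
#' @param t data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(t, path) {
  write.table(t, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
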