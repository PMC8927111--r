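#' Derive anthropometric variables
#'
#' Adds `bmi` (weight in kg over squared height in m), `whr` (waist over hip
#' circumference), and `obesity` / `overweight` flags to a phenotype table.
#' Adults: obesity is BMI >= 30.0, overweight is BMI >= 25.0 (the inclusive
#' convention: overweight includes obesity). Individuals flagged as children
#' (`child` column, or age < 18 when no such column exists) are classified on
#' BMI z-scores against a supplied reference table: obesity z >= 2.0,
#' overweight z >= 1.0 (again inclusive).
#'
#' The child reference is either a mean/sd table (columns `age`, `sex`,
#' `mean`, `sd`) or an LMS table (columns `age`, `sex`, `L`, `M`, `S`), with
#' one row per completed year of age and sex code 1/2; the nearest tabulated
#' age is used. With the LMS form, z = ((BMI/M)^L - 1) / (L * S).
#'
#' Rows with non-positive height are flagged invalid (`invalid_anthro`),
#' their derived values set missing, and a message logs the count.
#'
#' @param t data.frame with `weight` (kg), `height` (m) and optionally
#'   `waist`, `hip` (cm), `age`, `child`.
#' @param childReference optional reference z-score table (see above);
#'   required if the table contains children.
#' @return `t` with columns `bmi`, `whr`, `obesity`, `overweight`,
#'   `invalid_anthro` added.
#' @export
deriveAnthropometrics <- function(t, childReference = NULL) {
  stopifnot(all(c("weight", "height") %in% names(t)))
  bad <- !is.na(t$height) & t$height <= 0
  if (any(bad)) {
    message(sum(bad), " row(s) with non-positive height flagged invalid")
  }
  t$invalid_anthro <- bad
  t$bmi <- ifelse(bad, NA_real_, t$weight / t$height^2)
  t$whr <- if (all(c("waist", "hip") %in% names(t))) {
    ifelse(!is.na(t$hip) & t$hip > 0, t$waist / t$hip, NA_real_)
  } else NA_real_

  child <- if ("child" %in% names(t)) {
    t$child %in% TRUE
  } else if ("age" %in% names(t)) {
    !is.na(t$age) & t$age < 18
  } else rep(FALSE, nrow(t))

  obesity <- overweight <- rep(NA, nrow(t))
  adult <- !child
  obesity[adult] <- t$bmi[adult] >= 30.0
  overweight[adult] <- t$bmi[adult] >= 25.0
  if (any(child)) {
    if (is.null(childReference)) {
      stop("table contains children but no child BMI reference was supplied")
    }
    z <- childBmiZ(t$bmi[child], t$age[child], t$sex[child], childReference)
    t$bmi_z <- NA_real_
    t$bmi_z[child] <- z
    obesity[child] <- z >= 2.0
    overweight[child] <- z >= 1.0
  }
  t$obesity <- as.integer(obesity)
  t$overweight <- as.integer(overweight)
  t
}

# z-scores against a mean/sd or LMS reference, nearest tabulated age
childBmiZ <- function(bmi, age, sex, ref) {
  stopifnot(all(c("age", "sex") %in% names(ref)))
  lms <- all(c("L", "M", "S") %in% names(ref))
  if (!lms && !all(c("mean", "sd") %in% names(ref))) {
    stop("child reference needs columns mean/sd or L/M/S")
  }
  vapply(seq_along(bmi), function(i) {
    if (is.na(bmi[i]) || is.na(age[i]) || is.na(sex[i])) return(NA_real_)
    rows <- ref[ref$sex == sex[i], , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    r <- rows[which.min(abs(rows$age - age[i])), , drop = FALSE]
    if (lms) {
      ((bmi[i] / r$M)^r$L - 1) / (r$L * r$S)
    } else {
      (bmi[i] - r$mean) / r$sd
    }
  }, numeric(1))
}

#' Derive smoking variables
#'
#' Adds `tobacco_high` (heavy smoking) and `packyears` = (cigarettes per day
#' / 20) * years smoked. One packyear is 20 cigarettes a day for one year,
#' equivalently 1 cigarette a day for 20 years. The heavy-smoking cutoff is
#' cigarettes per day >= 20 by default (`strict = FALSE`); `strict = TRUE`
#' uses a strictly-greater-than rule instead.
#'
#' @param t data.frame with `cigarettes_per_day` and `years_smoked`.
#' @param strict logical; see above.
#' @return `t` with `tobacco_high`, `packyears`, `invalid_smoking` added.
#' @export
deriveSmoking <- function(t, strict = FALSE) {
  stopifnot(all(c("cigarettes_per_day", "years_smoked") %in% names(t)))
  bad <- (!is.na(t$cigarettes_per_day) & t$cigarettes_per_day < 0) |
         (!is.na(t$years_smoked) & t$years_smoked < 0)
  if (any(bad)) message(sum(bad), " row(s) with negative counts flagged invalid")
  t$invalid_smoking <- bad
  cpd <- ifelse(bad, NA_real_, t$cigarettes_per_day)
  t$tobacco_high <- as.integer(if (strict) cpd > 20 else cpd >= 20)
  t$packyears <- ifelse(bad, NA_real_,
                        cpd / 20 * t$years_smoked)
  t
}

#' Derive alcohol variables
#'
#' Adds `alcohol_high`: daily alcohol intake >= 15 g/day by default
#' (`strict = FALSE`); `strict = TRUE` uses strictly greater than. Missing
#' intake propagates to a missing flag.
#'
#' @param t data.frame with `daily_alcohol_g`.
#' @param strict logical; see above.
#' @return `t` with `alcohol_high`, `invalid_alcohol` added.
#' @export
deriveAlcohol <- function(t, strict = FALSE) {
  stopifnot("daily_alcohol_g" %in% names(t))
  bad <- !is.na(t$daily_alcohol_g) & t$daily_alcohol_g < 0
  if (any(bad)) message(sum(bad), " row(s) with negative intake flagged invalid")
  t$invalid_alcohol <- bad
  g <- ifelse(bad, NA_real_, t$daily_alcohol_g)
  t$alcohol_high <- as.integer(if (strict) g > 15 else g >= 15)
  t
}

#' Sum score over binary items
#'
#' Per-individual sum of binary 0/1 item columns (e.g. ten interview items
#' tapping depression or anxiety symptoms). Complete-item rule: any missing
#' item makes the score missing. Non-binary values are an error.
#'
#' @param t data.frame.
#' @param items character vector of item column names.
#' @param name name of the added score column; default `"sum_score"`.
#' @return `t` with the score column added.
#' @export
sumScore <- function(t, items, name = "sum_score") {
  stopifnot(all(items %in% names(t)))
  m <- as.matrix(t[, items, drop = FALSE])
  if (!all(m %in% c(0, 1, NA))) {
    stop("sum-score items must be binary 0/1")
  }
  score <- rowSums(m)           # NA if any item missing
  t[[name]] <- score
  t
}

#' Cronbach's alpha
#'
#' Internal consistency of a set of items, complete-case:
#' alpha = k/(k-1) * (1 - sum(var(item_i)) / var(total)), with n-1 sample
#' variances. Standardized alpha (on scaled items) is available via
#' `standardized = TRUE`; the two agree when item variances are equal.
#'
#' @param t data.frame.
#' @param items character vector of at least two item column names.
#' @param standardized logical; compute alpha on standardized items.
#' @return numeric alpha in (-Inf, 1].
#' @export
cronbachAlpha <- function(t, items, standardized = FALSE) {
  stopifnot(all(items %in% names(t)))
  k <- length(items)
  if (k < 2L) stop("need at least two items")
  m <- as.matrix(t[, items, drop = FALSE])
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L) stop("need at least two complete rows")
  if (standardized) m <- scale(m)
  vTotal <- var(rowSums(m))
  if (vTotal <= 0) stop("zero total variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(m, 2L, var)) / vTotal)
}
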