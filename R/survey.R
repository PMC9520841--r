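## Descriptive survey statistics: prevalence with Wald confidence
## intervals, species composition, flea sex ratios and contingency
## (identification-agreement) analysis.
##
## Rounding conventions follow field reporting practice: percentages to
## whole percent half away from zero, ratios to 2 decimals half to even
## (45/8 = 5.625 prints as 5.62).

.Z95 <- 1.959964

#' Binomial prevalence with a Wald confidence interval
#'
#' Point estimate 100 k/n with the normal-approximation (Wald) interval
#' point +/- z 100 sqrt(p(1-p)/n), clamped to [0, 100]. The Wald interval
#' is the default because it reproduces standard spreadsheet survey
#' reporting (e.g. 43/77 infested dogs -> 56%, 95% CI 45-67%).
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param confidence confidence level (default 0.95).
#' @param method "wald" (default), "wilson" or "clopper-pearson".
#' @return list with \code{percent}, \code{lower}, \code{upper} (whole
#'   percent, rounded half away from zero) and \code{raw} (unrounded
#'   percent, lower, upper, standard error in percent).
#' @examples
#' prevalenceCI(43, 77)   # 56% (45-67%)
#' @export
prevalenceCI <- function(k, n, confidence = 0.95,
                         method = c("wald", "wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (n < 1L) stop("n must be >= 1")
  if (k < 0L || k > n) stop("k must be in [0, n]")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  if (confidence == 0.95) z <- .Z95
  p <- k / n
  se <- sqrt(p * (1 - p) / n)
  ci <- switch(method,
    wald = c(p - z * se, p + z * se),
    wilson = {
      den <- 1 + z^2 / n
      ctr <- (p + z^2 / (2 * n)) / den
      hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
      c(ctr - hw, ctr + hw)
    },
    `clopper-pearson` = c(
      if (k == 0) 0 else stats::qbeta((1 - confidence) / 2, k, n - k + 1),
      if (k == n) 1 else stats::qbeta(1 - (1 - confidence) / 2, k + 1, n - k))
  )
  lo <- max(0, 100 * ci[1]); hi <- min(100, 100 * ci[2])
  list(percent = .roundHalfAway(100 * p),
       lower = .roundHalfAway(lo),
       upper = .roundHalfAway(hi),
       raw = c(percent = 100 * p, lower = lo, upper = hi, se = 100 * se))
}

#' Species composition percentages
#'
#' @param counts named integer vector (species -> count), total >= 1.
#' @return named numeric vector of whole-percent shares (half away from
#'   zero), with the unrounded percentages as attribute \code{"raw"}.
#' @examples
#' speciesComposition(c(canis = 115, orientis = 53, irritans = 22,
#'                      unidentified = 9))
#' @export
speciesComposition <- function(counts) {
  total <- sum(counts)
  if (total < 1) stop("total count must be >= 1")
  raw <- 100 * counts / total
  out <- .roundHalfAway(raw)
  attr(out, "raw") <- raw
  out
}

#' Flea sex ratio
#'
#' females / males, reported to two decimals with round-half-to-even
#' (45 females / 8 males = 5.625 -> 5.62).
#'
#' @param females,males counts; males must be >= 1.
#' @return rounded ratio, with the exact ratio as attribute \code{"raw"}.
#' @export
sexRatio <- function(females, males) {
  if (males < 1) stop("undefined ratio: no males")
  r <- females / males
  out <- round(r, 2)
  attr(out, "raw") <- r
  out
}

#' Identification-agreement contingency table
#'
#' Cross-tabulates a reference identification (rows, normally cox1) against
#' an assigned identification (columns, morphology or morphometrics) and
#' reports the per-true-class misclassification percentage. Specimens
#' assigned "indeterminate" are tabulated but excluded from the
#' misclassification denominator, i.e. only specimens fully identified by
#' both methods count.
#'
#' @param truth character/factor of reference labels.
#' @param assigned character/factor of assigned labels, possibly including
#'   "indeterminate".
#' @param indeterminate label treated as no-call (default "indeterminate").
#' @return list with \code{table} (counts, rows = truth) and
#'   \code{misclassification} (named whole-percent vector per true class;
#'   raw rates as attribute).
#' @examples
#' ## 4 of 7 cox1 C. orientis males called canis by the key -> 57%
#' @export
agreementTable <- function(truth, assigned, indeterminate = "indeterminate") {
  truth <- as.character(truth); assigned <- as.character(assigned)
  if (length(truth) != length(assigned))
    stop("truth and assigned must have equal length")
  t_lv <- sort(unique(truth))
  a_lv <- sort(unique(assigned))
  tab <- table(factor(truth, t_lv), factor(assigned, a_lv))
  tab <- unclass(as.matrix(tab))
  names(dimnames(tab)) <- c("truth", "assigned")
  determinate <- assigned != indeterminate
  mis_raw <- vapply(t_lv, function(cl) {
    sel <- truth == cl & determinate
    if (!sum(sel)) return(NA_real_)
    100 * sum(assigned[sel] != cl) / sum(sel)
  }, 0)
  mis <- .roundHalfAway(mis_raw)
  attr(mis, "raw") <- mis_raw
  list(table = tab, misclassification = mis)
}

#' Build a survey table of per-dog infestation records
#'
#' @param dog_id,region,age_months,dog_sex per-dog vectors (age in months,
#'   > 0; sex F/M).
#' @param fleas data.frame with one row per flea: columns \code{dog_id},
#'   \code{species}, \code{flea_sex}, and optionally \code{morphology_id},
#'   \code{cox1_id}; may be empty.
#' @return list with \code{dogs} (data.frame incl. logical
#'   \code{infested}) and \code{fleas}.
#' @export
surveyTable <- function(dog_id, region, age_months, dog_sex, fleas) {
  if (any(age_months <= 0)) stop("age_months must be > 0")
  dogs <- data.frame(dog_id = as.character(dog_id),
                     region = as.character(region),
                     age_months = as.numeric(age_months),
                     dog_sex = as.character(dog_sex),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(dogs$dog_id)) stop("duplicated dog_id")
  fleas$dog_id <- as.character(fleas$dog_id)
  if (!all(fleas$dog_id %in% dogs$dog_id))
    stop("fleas reference unknown dog_id")
  dogs$infested <- dogs$dog_id %in% fleas$dog_id
  list(dogs = dogs, fleas = fleas)
}

#' Prevalence by dog grouping
#'
#' Applies [prevalenceCI()] within groups of dogs: by age class (threshold
#' in months, juveniles <= threshold), by dog sex, or by region.
#'
#' @param survey a survey table from [surveyTable()] (or a dogs data.frame
#'   with an \code{infested} column).
#' @param by "age", "sex", "region" or "all".
#' @param age_threshold months separating juveniles from adults
#'   (default 12).
#' @param ... passed to [prevalenceCI()].
#' @return data.frame with group, k, n, percent, lower, upper (empty groups
#'   are kept with n = 0 and NA statistics).
#' @export
infestationByGroup <- function(survey, by = c("all", "age", "sex", "region"),
                               age_threshold = 12, ...) {
  dogs <- if (is.data.frame(survey)) survey else survey$dogs
  by <- match.arg(by)
  grp <- switch(by,
    all = rep("all", nrow(dogs)),
    age = ifelse(dogs$age_months <= age_threshold, "juvenile", "adult"),
    sex = dogs$dog_sex,
    region = dogs$region)
  lv <- unique(grp)
  rows <- lapply(lv, function(l) {
    sel <- grp == l
    n <- sum(sel); k <- sum(dogs$infested[sel])
    if (n == 0)
      return(data.frame(group = l, k = 0L, n = 0L, percent = NA_real_,
                        lower = NA_real_, upper = NA_real_))
    ci <- prevalenceCI(k, n, ...)
    data.frame(group = l, k = k, n = n, percent = ci$percent,
               lower = ci$lower, upper = ci$upper)
  })
  do.call(rbind, rows)
}

#' Read / write the survey TSV schema
#'
#' Dog table columns: dog_id, region, age_months, dog_sex. Flea table
#' columns: dog_id, species, flea_sex, morphology_id, cox1_id.
#'
#' @param dogs_path,fleas_path TSV paths.
#' @return a survey table (see [surveyTable()]).
#' @export
readSurveyTSV <- function(dogs_path, fleas_path) {
  dogs <- read.delim(dogs_path, stringsAsFactors = FALSE,
                     colClasses = "character")
  need <- c("dog_id", "region", "age_months", "dog_sex")
  miss <- setdiff(need, colnames(dogs))
  if (length(miss)) stop("dogs table missing column(s): ",
                         paste(miss, collapse = ", "))
  fleas <- read.delim(fleas_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  if (!"dog_id" %in% colnames(fleas))
    stop("fleas table missing column(s): dog_id")
  surveyTable(dogs$dog_id, dogs$region, as.numeric(dogs$age_months),
              dogs$dog_sex, fleas)
}

#' @rdname readSurveyTSV
#' @param survey a survey table.
#' @export
writeSurveyTSV <- function(survey, dogs_path, fleas_path) {
  write.table(survey$dogs[, c("dog_id", "region", "age_months", "dog_sex")],
              dogs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(survey$fleas, fleas_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(dogs_path, fleas_path))
}
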