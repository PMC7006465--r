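#' Sex bias in age at maturation
#'
#' `log10(male age at maturation / female age at maturation)`. Positive
#' values mean males mature later than females; a species in which males
#' mature 60 months later than females at, say, 72 vs 12 months scores
#' `log10(6) > 0`, while the reverse pattern scores negative.
#'
#' @param male_months,female_months ages at sexual maturation in months
#'   (positive; `NA` propagates to `NA`).
#' @return numeric vector of log10 ratios.
#' @export
maturation_bias <- function(male_months, female_months) {
  log_ratio(male_months, female_months, what = "maturation age")
}

#' Sexual size dimorphism
#'
#' `log10(adult male mass / adult female mass)`; positive = males larger.
#' Antisymmetric under swapping the sexes: `ssd(a, b) == -ssd(b, a)`.
#'
#' @param male_mass,female_mass adult body masses in grams (positive).
#' @return numeric vector of log10 ratios.
#' @export
ssd <- function(male_mass, female_mass) {
  log_ratio(male_mass, female_mass, what = "body mass")
}

#' Sex bias in adult mortality
#'
#' `log10(adult male mortality / adult female mortality)` from annual
#' mortality rates estimated for both sexes in the same population.
#'
#' @param male_mortality,female_mortality annual adult mortality rates in
#'   (0, 1].
#' @return numeric vector of log10 ratios.
#' @export
mortality_bias <- function(male_mortality, female_mortality) {
  log_ratio(male_mortality, female_mortality, what = "mortality rate")
}

log_ratio <- function(m, f, what) {
  bad <- (!is.na(m) & m <= 0) | (!is.na(f) & f <= 0)
  if (any(bad)) stop("nonpositive ", what, " value(s); both sexes must be > 0")
  log10(m / f)
}

#' Polygamy bias from per-sex polygamy scores
#'
#' Each sex is scored for the frequency of social polygamy on a 0--4 scale
#' (0 = no or very rare polygamy, 4 = common polygamy). When several scores
#' are available for a sex they are averaged first; polygamy bias is the
#' mean male score minus the mean female score, so the range is \[-4, 4\]
#' and positive values indicate more polygamous males.
#'
#' @param male_scores,female_scores numeric vectors of scores in \[0, 4\]
#'   for one species.
#' @return a single polygamy-bias value, or `NA` if either list is empty.
#' @export
polygamy_bias <- function(male_scores, female_scores) {
  male_scores <- male_scores[!is.na(male_scores)]
  female_scores <- female_scores[!is.na(female_scores)]
  if (!length(male_scores) || !length(female_scores)) return(NA_real_)
  if (any(male_scores < 0 | male_scores > 4) ||
      any(female_scores < 0 | female_scores > 4)) {
    stop("polygamy scores must lie in [0, 4]")
  }
  mean(male_scores) - mean(female_scores)
}

#' Arcsine-square-root transformed adult sex ratio
#'
#' The adult sex ratio (ASR) is the proportion of males among adults,
#' `males / (males + females)`. Multiple estimates for a species are
#' averaged on the proportion scale first, and the average is then
#' arcsine-square-root transformed: `asin(sqrt(mean(asr)))`. The order
#' matters — transforming each estimate and then averaging gives a
#' different (and not used) quantity.
#'
#' @param asr_values numeric vector of ASR estimates in \[0, 1\] for one
#'   species.
#' @return a single transformed value in \[0, pi/2\], or `NA` if empty.
#' @export
asr_transform <- function(asr_values) {
  asr_values <- asr_values[!is.na(asr_values)]
  if (!length(asr_values)) return(NA_real_)
  if (any(asr_values < 0 | asr_values > 1)) {
    stop("ASR values must lie in [0, 1]")
  }
  asin(sqrt(mean(asr_values)))
}

#' Log body mass of a species
#'
#' Mean of the adult male and female masses, log10-transformed; used as a
#' life-history confound in multipredictor models.
#'
#' @param male_mass,female_mass adult body masses in grams (positive).
#' @return numeric vector.
#' @export
log_body_mass <- function(male_mass, female_mass) {
  bad <- (!is.na(male_mass) & male_mass <= 0) |
    (!is.na(female_mass) & female_mass <= 0)
  if (any(bad)) stop("nonpositive body mass value(s)")
  log10((male_mass + female_mass) / 2)
}

#' Chick developmental mode levels
#'
#' @keywords internal
dev_mode_levels <- c("altricial", "semi", "precocial")

#' Build the derived trait table from raw per-sex measurements
#'
#' Takes a raw species table (one row per species) and computes the derived
#' analysis variables: `maturation_bias`, `ssd`, `polygamy_bias`, `asr_t`
#' (arcsine-square-root transformed ASR), `mortality_bias`, `log_mass`, and
#' `dev_mode` as a three-level factor (altricial / semi / precocial,
#' reference level altricial). Missing raw values propagate to missing
#' derived values.
#'
#' Expected raw columns (all but `species` optional; a derived variable is
#' produced only when its inputs are present): `species`,
#' `male_maturation_months`, `female_maturation_months`, `male_mass_g`,
#' `female_mass_g`, `male_polygamy_scores`, `female_polygamy_scores`,
#' `asr_values`, `male_mortality`, `female_mortality`, `dev_mode` (0/1/2).
#' The polygamy-score and ASR columns may hold several values separated by
#' semicolons (e.g. `"2;3"`), which are averaged per species.
#'
#' @param raw data frame or path to a CSV file (header row, decimal point).
#' @return data frame: the derived trait table, one row per species.
#' @export
derive_traits <- function(raw) {
  if (is.character(raw)) raw <- utils::read.csv(raw, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(raw))
  if (!"species" %in% names(raw)) stop("raw table must have a 'species' column")
  if (!nrow(raw)) stop("raw table is empty")
  n <- nrow(raw)
  col <- function(nm) if (nm %in% names(raw)) raw[[nm]] else rep(NA_real_, n)
  multi <- function(nm) {
    v <- col(nm)
    lapply(v, function(s) {
      if (length(s) == 1 && is.na(s)) return(numeric(0))
      as.numeric(strsplit(as.character(s), ";", fixed = TRUE)[[1]])
    })
  }
  out <- data.frame(
    species = as.character(raw$species),
    maturation_bias = maturation_bias(col("male_maturation_months"),
                                      col("female_maturation_months")),
    ssd = ssd(col("male_mass_g"), col("female_mass_g")),
    polygamy_bias = mapply(polygamy_bias,
                           multi("male_polygamy_scores"),
                           multi("female_polygamy_scores")),
    asr_t = vapply(multi("asr_values"), asr_transform, numeric(1)),
    mortality_bias = mortality_bias(col("male_mortality"),
                                    col("female_mortality")),
    log_mass = log_body_mass(col("male_mass_g"), col("female_mass_g")),
    stringsAsFactors = FALSE
  )
  dm <- col("dev_mode")
  if (!all(is.na(dm)) && !all(dm[!is.na(dm)] %in% 0:2)) {
    stop("dev_mode must be coded 0 (altricial), 1 (semi), 2 (precocial)")
  }
  out$dev_mode <- factor(dev_mode_levels[as.integer(dm) + 1L],
                         levels = dev_mode_levels)
  out
}

#' Subset a trait table to rows complete on a set of variables
#'
#' Different variables are available for different species, so each model is
#' fitted on the complete cases of its own variable set. The retained row
#' count is reported via `message()`.
#'
#' @param table trait table (data frame).
#' @param vars character vector of column names that must be non-missing;
#'   empty vector returns the full table.
#' @return the subset, row names reset.
#' @export
complete_rows <- function(table, vars = character(0)) {
  stopifnot(is.data.frame(table))
  unknown <- setdiff(vars, names(table))
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  }
  if (!length(vars)) return(table)
  keep <- stats::complete.cases(table[, vars, drop = FALSE])
  message("complete_rows: ", sum(keep), " of ", nrow(table),
          " species complete on {", paste(vars, collapse = ", "), "}")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Census of species exhibiting maturation bias
#'
#' Counts species whose maturation bias is exactly nonzero (the inputs are
#' month-resolution ages, so no tolerance is applied) among species with a
#' non-missing maturation bias, and reports the fraction.
#'
#' @param table trait table with a `maturation_bias` column.
#' @return list with `n_biased`, `n_total`, `fraction` (class
#'   `"maturation_census"`).
#' @export
maturation_bias_census <- function(table) {
  stopifnot(is.data.frame(table), "maturation_bias" %in% names(table))
  mb <- table$maturation_bias[!is.na(table$maturation_bias)]
  out <- list(n_biased = sum(mb != 0), n_total = length(mb),
              fraction = if (length(mb)) sum(mb != 0) / length(mb) else NA_real_)
  class(out) <- "maturation_census"
  out
}

#' @export
print.maturation_census <- function(x, ...) {
  cat(sprintf("%d of %d species (%.1f%%) exhibit maturation bias\n",
              x$n_biased, x$n_total, 100 * x$fraction))
  invisible(x)
}
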