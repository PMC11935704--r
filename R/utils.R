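# Internal helpers shared across modules.

DAYS_PER_YEAR <- 365.25

#' Convert ages between years and days
#'
#' All internal ages are integer days since birth; the report ages 1/5/10
#' years are `365.25 * k` days.
#'
#' @param x numeric vector of ages.
#' @return numeric vector.
#' @export
years_to_days <- function(x) x * DAYS_PER_YEAR

#' @rdname years_to_days
#' @export
days_to_years <- function(x) x / DAYS_PER_YEAR

#' Default report ages (1, 5, 10 years) in days
#' @export
report_ages_default <- function() years_to_days(c(1, 5, 10))

# Percentage rounded to one decimal, the convention used in all summary tables.
pct1 <- function(num, den) {
  ifelse(den > 0, round(100 * num / den, 1), NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a semicolon-joined multi-value cell into a character vector.
split_codes <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  out <- strsplit(x, ";", fixed = TRUE)[[1]]
  out[nzchar(out)]
}

join_codes <- function(x) paste(x, collapse = ";")

# Derive a 32-bit sub-seed from a master seed and a label, so that editing one
# simulation block does not reshuffle the streams of the others.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 69069 + h * 1013) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

MODALITIES <- c("bypass_surgery", "nonbypass_surgery", "hybrid",
                "catheter", "electrophysiology")

SENTINEL_DIAGNOSES <- c("HLHS", "FUH", "TGA", "PA", "AVSD",
                        "TOF", "AS", "COARCT", "VSD")

PATHWAY_SLOTS <- c("prepathway", "stage1", "stage2", "stage3", "repair")
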