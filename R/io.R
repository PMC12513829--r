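ssfColumns <- c("variant_id", "chromosome", "base_pair_location",
                "effect_allele", "other_allele", "effect_allele_frequency",
                "beta", "standard_error", "z", "p_value", "n", "n_events",
                "info", "mac")

#' Write association records as a GWAS-SSF-style TSV
#'
#' Fixed column order (variant_id, chromosome, base_pair_location,
#' effect_allele, other_allele, effect_allele_frequency, beta,
#' standard_error, z, p_value, n, n_events, info, mac), missing beta/se
#' written as empty fields (Z-only records), any extra columns appended
#' after the standard ones. Numeric fields round-trip to at least 12
#' significant digits.
#'
#' @param records association record data.frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSummaryStats <- function(records, path) {
  miss <- setdiff(ssfColumns, names(records))
  if (length(miss))
    stop("records lack required columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(records), ssfColumns)
  out <- records[, c(ssfColumns, extra), drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 15, scientific = NA,
                                trim = TRUE))
  })
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname writeSummaryStats
#' @return `readSummaryStats()`: the records data.frame, empty fields
#'   restored as NA.
#' @export
readSummaryStats <- function(path) {
  df <- read.delim(path, na.strings = "", stringsAsFactors = FALSE,
                   colClasses = NA)
  for (cc in intersect(c("effect_allele_frequency", "beta", "standard_error",
                         "z", "p_value", "info", "mac"), names(df)))
    df[[cc]] <- as.numeric(df[[cc]])
  for (cc in intersect(c("chromosome", "base_pair_location", "n",
                         "n_events"), names(df)))
    df[[cc]] <- as.integer(df[[cc]])
  for (cc in intersect(c("variant_id", "effect_allele", "other_allele",
                         "flag"), names(df)))
    df[[cc]] <- as.character(df[[cc]])
  df
}
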