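#' Cohort descriptives from fractionation-scheme and characteristic counts
#'
#' Recomputes the arithmetic of a treated-cohort summary table from its
#' printed counts: the number of patients, scheduled and delivered treatment
#' fractions (fractionation schemes summed over patients, minus any skipped
#' fractions), and characteristic percentages. The packaged default tables
#' describe a 21-patient multi-institutional CIED cohort (one patient missed
#' one fraction for a non-cardiac reason).
#'
#' @param schemes Data frame with columns `fractions` and `n_patients`, or a
#'   CSV path. Default: packaged table.
#' @param characteristics Data frame with columns `characteristic`, `level`,
#'   `n`, or a CSV path. Default: packaged table.
#' @param skipped_fractions Number of scheduled fractions not delivered.
#' @return List with `n_patients`, `fractions_scheduled`,
#'   `fractions_delivered`, and `percent` (named vector of rounded
#'   percentages per characteristic level, plus exact values in
#'   `percent_exact`).
#' @examples
#' cohort_summary()$fractions_delivered  # 100
#' @export
cohort_summary <- function(schemes = NULL, characteristics = NULL,
                           skipped_fractions = 1) {
  if (is.null(schemes))
    schemes <- system.file("extdata", "cohort", "cohort_schemes.csv",
                           package = "b0gate")
  if (is.character(schemes)) schemes <- read.csv(schemes)
  if (is.null(characteristics))
    characteristics <- system.file("extdata", "cohort",
                                   "cohort_characteristics.csv",
                                   package = "b0gate")
  if (is.character(characteristics))
    characteristics <- read.csv(characteristics)
  stopifnot(all(c("fractions", "n_patients") %in% names(schemes)),
            all(c("characteristic", "level", "n") %in% names(characteristics)))

  n_patients <- sum(schemes$n_patients)
  scheduled <- sum(schemes$fractions * schemes$n_patients)
  delivered <- scheduled - skipped_fractions

  pct_exact <- numeric(0)
  for (ch in unique(characteristics$characteristic)) {
    sub <- characteristics[characteristics$characteristic == ch, ]
    p <- 100 * sub$n / sum(sub$n)
    names(p) <- paste(ch, sub$level, sep = ".")
    pct_exact <- c(pct_exact, p)
  }

  list(n_patients = n_patients,
       fractions_scheduled = scheduled,
       fractions_delivered = delivered,
       percent = round(pct_exact),
       percent_exact = pct_exact)
}
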