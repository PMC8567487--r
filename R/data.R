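#' Shipped reference tables and example data
#'
#' The package ships two transcribed normative reference tables and the
#' measured parameter values of a worked example: transiliac biopsies from
#' two adult males with early-onset osteoporosis caused by an SGMS2 nonsense
#' mutation (patient 1: 61 years; patient 2: 29 years).
#'
#' \describe{
#'   \item{`"histo_reference"`}{normative iliac histomorphometry
#'     (Rehman et al. series): `parameter,sex,age_lo,age_hi,mean,sd,source`,
#'     male bands 61-70 and 21-30 years.}
#'   \item{`"bmdd_reference"`}{adult trabecular BMDD reference
#'     (Roschger et al. series): `parameter,mean,sd,source`.}
#'   \item{`"sgms2_histo"`}{measured histomorphometric parameters of the two
#'     example patients: `parameter,patient1,patient2`.}
#'   \item{`"sgms2_bmdd"`}{measured BMDD parameters of the two example
#'     patients per compartment: `parameter,compartment,patient1,patient2`.}
#' }
#'
#' @param which one of `"histo_reference"`, `"bmdd_reference"`,
#'   `"sgms2_histo"`, `"sgms2_bmdd"`.
#' @return a data.frame.
#' @export
bonematrix_data <- function(which = c("histo_reference", "bmdd_reference",
                                      "sgms2_histo", "sgms2_bmdd")) {
  which <- match.arg(which)
  file <- switch(which,
    histo_reference = "histo_reference_male.csv",
    bmdd_reference = "bmdd_trabecular_reference.csv",
    sgms2_histo = "sgms2_histo_patients.csv",
    sgms2_bmdd = "sgms2_bmdd_patients.csv")
  path <- system.file("extdata", file, package = "bonematrix")
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
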